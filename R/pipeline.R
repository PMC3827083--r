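#' The packaged miRNA/probe panel
#'
#' Twelve mouse miRNAs with the probe printed for each of two array
#' designs: full-length reverse-complement probes (platform
#' `"affymetrix"`) and 3'-anchored probes of 13-22 nt, most carrying a
#' parenthesized optional tail base (platform `"agilent"`). Used by
#' [thermo_report()] and the package examples.
#'
#' @return Data frame with columns `mirna`, `sequence`, `platform`,
#'   `probe`.
#' @export
probe_panel <- function() {
  utils::read.delim(system.file("extdata", "probe_panel.tsv",
                                package = "crossmir"),
                    stringsAsFactors = FALSE)
}

#' GC / free-energy / melting-temperature report for a probe panel
#'
#' Pairs each probe with its target miRNA and reports, per probe variant
#' (extended and core for tailed probes), the miRNA GC percent, duplex
#' free energy at 37 degC and melting temperature. A probe that fails to
#' pair (internal mismatch, wrong length) yields a flagged row carrying
#' the error message; the run continues.
#'
#' @param panel Data frame with columns `mirna`, `sequence`, `platform`,
#'   `probe` (probe text may use the parenthesized-tail form), or a path
#'   to such a TSV. Defaults to the packaged panel.
#' @param nn A [nn_table()].
#' @param cond A [thermo_conditions()].
#' @param include_initiation See [hybrid_tm()].
#' @return Data frame: `mirna`, `platform`, `probe`, `variant`,
#'   `paired_nt`, `gc_pct`, `dG37_kcal`, `tm_c`, `status` (`"ok"` or the
#'   pairing error).
#' @export
thermo_report <- function(panel = probe_panel(), nn = nn_table(),
                          cond = thermo_conditions(),
                          include_initiation = TRUE) {
  if (is.character(panel) && length(panel) == 1L)
    panel <- utils::read.delim(panel, stringsAsFactors = FALSE)
  need <- c("mirna", "sequence", "platform", "probe")
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(panel)) {
    warning("empty probe panel; empty report")
    return(data.frame(mirna = character(), platform = character(),
                      probe = character(), variant = character(),
                      paired_nt = integer(), gc_pct = integer(),
                      dG37_kcal = numeric(), tm_c = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    rec <- sequence_record(panel$mirna[i], panel$sequence[i], "RNA")
    gc <- gc_content(rec)
    res <- tryCatch({
      pr <- parse_probe(panel$probe[i],
                        sprintf("%s_%s", panel$mirna[i], panel$platform[i]))
      vars <- probe_variants(rec, pr, nn, cond, include_initiation)
      do.call(rbind, lapply(names(vars), function(v)
        data.frame(mirna = panel$mirna[i], platform = panel$platform[i],
                   probe = panel$probe[i], variant = v,
                   paired_nt = vars[[v]]$paired_nt, gc_pct = gc,
                   dG37_kcal = vars[[v]]$dG37, tm_c = vars[[v]]$tm,
                   status = "ok", stringsAsFactors = FALSE)))
    }, error = function(e)
      data.frame(mirna = panel$mirna[i], platform = panel$platform[i],
                 probe = panel$probe[i], variant = NA_character_,
                 paired_nt = NA_integer_, gc_pct = gc,
                 dG37_kcal = NA_real_, tm_c = NA_real_,
                 status = conditionMessage(e), stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, rows)
}

config_defaults <- function() list(
  seed = 1L,
  simulation = list(),
  detection = list(threshold_quantile = 0.5),
  diffexp = list(p_max = 0.05, min_abs_log2fc = 1.5,
                 min_mean_percentile = 50),
  cluster = list(linkage = "average"),
  universe_file = NULL,
  output = NULL
)

#' Read and validate a pipeline run configuration
#'
#' YAML with top-level keys `seed`, `simulation` (arguments of
#' [simulation_config()] except `seed`), `detection`
#' (`threshold_quantile`), `diffexp` (`p_max`, `min_abs_log2fc`,
#' `min_mean_percentile`), `cluster` (`linkage`), and optional
#' `universe_file` and `output`. Unknown keys at either level are
#' rejected, and every referenced path must exist at read time — before
#' any computation runs.
#'
#' @param path YAML file path, or an equivalent named list.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  merged <- utils::modifyList(defaults, cfg)
  sim_ok <- setdiff(names(formals(simulation_config)), "seed")
  bad_sim <- setdiff(names(merged$simulation), sim_ok)
  if (length(bad_sim))
    stop("unknown simulation key(s): ", paste(bad_sim, collapse = ", "),
         call. = FALSE)
  for (section in c("detection", "diffexp", "cluster")) {
    bad <- setdiff(names(merged[[section]]), names(defaults[[section]]))
    if (length(bad))
      stop("unknown ", section, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    merged[[section]] <- utils::modifyList(defaults[[section]],
                                           merged[[section]])
  }
  if (!is.null(merged$universe_file) && !file.exists(merged$universe_file))
    stop("universe file not found: ", merged$universe_file, call. = FALSE)
  if (!is.null(merged$simulation$planted_effects) &&
      !is.data.frame(merged$simulation$planted_effects)) {
    pe <- merged$simulation$planted_effects  # YAML list-of-maps form
    merged$simulation$planted_effects <- data.frame(
      mirna = vapply(pe, `[[`, character(1L), "mirna"),
      log2fc = vapply(pe, `[[`, numeric(1L), "log2fc"),
      gender = vapply(pe, function(x)
        if (is.null(x$gender)) NA_character_ else x$gender, character(1L)),
      stringsAsFactors = FALSE)
  }
  structure(merged, class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full two-platform concordance pipeline
#'
#' Simulate -> normalize (platform A: quantile; platform B:
#' percentile-scale, clamp negatives, summarise replicate spots — in that
#' order) -> detection calls and per-group overlap against the shared
#' universe -> gender-specific Welch differential expression with the
#' compound filter on both platforms and the qPCR arm -> GC discordance
#' diagnostic -> Pearson hierarchical clustering of the log2-ratio
#' profiles. Deterministic given the config seed. Every stage appends a
#' provenance line; when `out_dir` is given all stage outputs are written
#' (TSV, JSON for the concordance summary, Newick for the tree, plain
#' text for the provenance log).
#'
#' @param config A [read_run_config()] result, a YAML path, or a named
#'   list.
#' @param out_dir Output directory (created if needed); `NULL` returns
#'   the bundle without writing files.
#' @return Invisibly, the result bundle: normalized matrices, detection
#'   calls, `concordance` (per-group [overlap_stats()]), `de` (per
#'   platform and gender), `significant` sets, `qpcr` tables,
#'   `gc_discordance`, `tree` and its Newick text, `truth`, and
#'   `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  prov <- character()
  note <- function(fmt, ...) prov <<- c(prov, sprintf(fmt, ...))

  sim_args <- c(config$simulation, list(seed = config$seed))
  cfg <- do.call(simulation_config, sim_args)
  sim <- simulate_two_platforms(cfg)
  note("simulate: %d miRNAs, %d/group, seed %d", cfg$n_mirnas,
       cfg$n_per_group, cfg$seed)

  norm_a <- quantile_normalize(sim$platform_a)
  # platform B chain order is fixed: scale, clamp, summarise
  norm_b <- summarize_replicates(clamp_negatives(percentile_scale(sim$platform_b)))
  prov <- c(prov, norm_a$log, norm_b$log)

  tq <- config$detection$threshold_quantile
  thr_a <- stats::quantile(norm_a$values, tq, names = FALSE)
  thr_b <- stats::quantile(norm_b$values, tq, names = FALSE)
  calls_a <- call_detected(norm_a, threshold = thr_a)
  calls_b <- call_detected(norm_b, threshold = thr_b)
  note("detect: threshold quantile %.2f (A %.4g, B %.4g)", tq, thr_a, thr_b)

  universe <- if (is.null(config$universe_file)) sim$truth$mirna
              else readLines(config$universe_file)
  concord <- lapply(stats::setNames(nm = cfg$groups), function(g)
    overlap_stats(intersect(detected_set(calls_a, g), universe),
                  intersect(detected_set(calls_b, g), universe), universe))
  note("concordance: universe %d, common %s", length(universe),
       paste(vapply(concord, function(s) s$n_common, numeric(1L)),
             collapse = "/"))

  contrasts <- list(M = c("M_cRaf", "M_WT"), F = c("F_cRaf", "F_WT"))
  dx <- config$diffexp
  de <- list(); sig <- list()
  for (p in c("a", "b")) {
    m <- if (p == "a") norm_a else norm_b
    de[[p]] <- lapply(contrasts, function(ct) de_table(m, ct))
    sig[[p]] <- lapply(de[[p]], function(d)
      filter_significant(d, p_max = dx$p_max,
                         min_abs_log2fc = dx$min_abs_log2fc,
                         min_mean_percentile = dx$min_mean_percentile))
    note("diffexp platform %s: %s significant (M/F: %d/%d)", toupper(p),
         paste(vapply(sig[[p]], nrow, integer(1L)), collapse = "+"),
         nrow(sig[[p]]$M), nrow(sig[[p]]$F))
  }
  sig_a <- unique(unlist(lapply(sig$a, `[[`, "mirna")))
  sig_b <- unique(unlist(lapply(sig$b, `[[`, "mirna")))

  gc_vec <- stats::setNames(sim$truth$gc, sim$truth$mirna)
  gcd <- gc_discordance(sig_a, sig_b, gc_vec)

  qpcr_ct <- simulate_qpcr(cfg, sim$truth)
  qpcr <- lapply(contrasts, function(ct) ddct_fold_change(qpcr_ct, ct))
  note("qpcr: %d assays + reference", length(unique(qpcr_ct$assay)) - 1L)

  # log2-ratio profiles of every miRNA significant on either platform,
  # across the four platform x gender contrasts
  interesting <- sort(union(sig_a, sig_b))
  tree <- NULL; newick <- NULL
  if (length(interesting) >= 2L) {
    prof <- matrix(NA_real_, length(interesting), 4L,
                   dimnames = list(interesting,
                                   c("A_M", "A_F", "B_M", "B_F")))
    for (p in c("a", "b")) for (g in names(contrasts)) {
      d <- de[[p]][[g]]
      prof[, sprintf("%s_%s", toupper(p), g)] <-
        stats::setNames(d$log2_ratio, d$mirna)[interesting]
    }
    keep <- apply(prof, 1L, stats::sd) > 0
    if (sum(keep) >= 2L) {
      tree <- hca(prof[keep, , drop = FALSE],
                  linkage = config$cluster$linkage)
      newick <- export_tree(tree)
      note("cluster: %d leaves, %s linkage", sum(keep),
           config$cluster$linkage)
    }
  }
  if (is.null(tree)) note("cluster: skipped (fewer than 2 usable profiles)")

  bundle <- list(config = config, truth = sim$truth,
                 platform_a = norm_a, platform_b = norm_b,
                 calls = list(a = calls_a, b = calls_b),
                 concordance = concord, de = de, significant = sig,
                 significant_sets = list(a = sig_a, b = sig_b),
                 gc_discordance = gcd, qpcr = qpcr, tree = tree,
                 newick = newick, provenance = prov)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(cbind(mirna = rownames(norm_a$values), as.data.frame(norm_a$values)),
              file.path(out_dir, "platform_a_normalized.tsv"))
    write_tsv(cbind(mirna = rownames(norm_b$values), as.data.frame(norm_b$values)),
              file.path(out_dir, "platform_b_summarized.tsv"))
    write_tsv(sim$truth, file.path(out_dir, "ground_truth.tsv"))
    for (p in c("a", "b")) {
      tab <- merge(de[[p]]$F[, c("mirna", "p", "log2_ratio")],
                   de[[p]]$M[, c("mirna", "p", "log2_ratio")],
                   by = "mirna", suffixes = c("_F", "_M"))
      names(tab) <- c("mirna", "p_F", "log2_F", "p_M", "log2_M")
      tab$significant_F <- tab$mirna %in% sig[[p]]$F$mirna
      tab$significant_M <- tab$mirna %in% sig[[p]]$M$mirna
      write_tsv(tab, file.path(out_dir,
                               sprintf("de_platform_%s.tsv", p)))
    }
    for (g in names(qpcr))
      write_tsv(qpcr[[g]], file.path(out_dir, sprintf("qpcr_%s.tsv", g)))
    jsonlite::write_json(
      lapply(concord, function(s)
        s[c("universe_size", "n_a", "frac_a", "n_b", "frac_b",
            "n_common", "frac_common")]),
      file.path(out_dir, "concordance.json"), auto_unbox = TRUE, digits = NA)
    write_tsv(do.call(rbind, lapply(names(concord), function(g)
      cbind(group = g, as.data.frame(concord[[g]])))),
      file.path(out_dir, "concordance.tsv"))
    if (!is.null(newick)) writeLines(newick, file.path(out_dir, "tree.nwk"))
    if (!is.null(tree)) write_tsv(tree$merges,
                                  file.path(out_dir, "cluster_merges.tsv"))
    writeLines(prov, file.path(out_dir, "provenance.log"))
  }
  invisible(bundle)
}
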