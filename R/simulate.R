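#' Configuration for the two-platform simulation
#'
#' Defines the ground-truth model from which paired platform-A
#' (single-spot, GC-biased detection) and platform-B (multi-spot,
#' background-corrected) expression matrices and a qPCR Ct table are
#' drawn. The default design mirrors a 2x2 factorial animal study: four
#' groups (male/female x wild-type/transgenic), six biological replicates
#' each, log2-normal signals with planted group effects, and a shared
#' miRNA universe measured by both platforms.
#'
#' @param n_mirnas Number of simulated miRNAs.
#' @param n_per_group Samples per group (>= 2).
#' @param groups The four group labels, case groups containing `"cRaf"`.
#' @param baseline_log2_mean,baseline_log2_sd Distribution of per-miRNA
#'   baseline log2 signal.
#' @param planted_effects Data frame with columns `mirna`, `log2fc` and
#'   optionally `gender` (`"M"`, `"F"` or `NA` for both): the true
#'   transgenic-vs-wild-type effects. `NULL` for a null simulation.
#' @param noise_sd Per-observation log2 noise SD (>= 0).
#' @param gc_assignments Optional integer vector (length `n_mirnas`) of
#'   per-miRNA GC percent; by default drawn once from a clipped normal
#'   (mean 50, sd 10) under the simulation seed.
#' @param platform_bias `NULL` (every miRNA detectable everywhere) or a
#'   list with elements `a` and `b`, each `list(midpoint=, slope=)`: the
#'   logistic sensitivity of detectability in GC percent. The defaults
#'   make low-GC miRNAs less detectable on platform A.
#' @param n_replicate_spots Technical replicate spots per miRNA on
#'   platform B.
#' @param negative_rate Expected fraction of platform-B spots whose
#'   simulated background exceeds the signal, yielding negative
#'   background-corrected values (in `[0, 1]`).
#' @param background_log2_mean,background_log2_sd Log2 signal distribution
#'   of miRNAs that a platform cannot detect (array background).
#' @param qpcr_intercept Ct of a miRNA with log2 expression 0.
#' @param qpcr_noise_sd Per-measurement Ct noise SD; defaults to
#'   `noise_sd`.
#' @param u6_ct Mean Ct of the U6 reference assay (constant across
#'   groups).
#' @param seed Integer seed; identical seeds give bit-identical output.
#'   The qPCR stage uses `seed + 1`.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_mirnas = 200, n_per_group = 6,
                              groups = c("M_WT", "F_WT", "M_cRaf", "F_cRaf"),
                              baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                              planted_effects = NULL, noise_sd = 0.3,
                              gc_assignments = NULL,
                              platform_bias = list(
                                a = list(midpoint = 45, slope = 0.25),
                                b = list(midpoint = 30, slope = 0.25)),
                              n_replicate_spots = 20, negative_rate = 0.05,
                              background_log2_mean = 2,
                              background_log2_sd = 0.7,
                              qpcr_intercept = 32, qpcr_noise_sd = noise_sd,
                              u6_ct = 15, seed = 1L) {
  stopifnot(n_mirnas >= 1, n_per_group >= 2, length(groups) == 4,
            noise_sd >= 0, negative_rate >= 0, negative_rate <= 1,
            n_replicate_spots >= 1, qpcr_noise_sd >= 0)
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("mirna", "log2fc") %in% names(planted_effects)))
    if (is.null(planted_effects$gender)) planted_effects$gender <- NA_character_
    bad <- !planted_effects$gender %in% c("M", "F", NA)
    if (any(bad)) stop("planted_effects$gender must be 'M', 'F' or NA",
                       call. = FALSE)
  }
  if (!is.null(gc_assignments))
    stopifnot(length(gc_assignments) == n_mirnas,
              all(gc_assignments >= 0 & gc_assignments <= 100))
  if (!is.null(platform_bias))
    stopifnot(is.list(platform_bias), all(c("a", "b") %in% names(platform_bias)))
  structure(list(
    n_mirnas = as.integer(n_mirnas), n_per_group = as.integer(n_per_group),
    groups = groups, baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, planted_effects = planted_effects,
    noise_sd = noise_sd, gc_assignments = gc_assignments,
    platform_bias = platform_bias,
    n_replicate_spots = as.integer(n_replicate_spots),
    negative_rate = negative_rate,
    background_log2_mean = background_log2_mean,
    background_log2_sd = background_log2_sd,
    qpcr_intercept = qpcr_intercept, qpcr_noise_sd = qpcr_noise_sd,
    u6_ct = u6_ct, seed = as.integer(seed)), class = "sim_config")
}

sim_mirna_names <- function(n) sprintf("sim-miR-%04d", seq_len(n))

sim_sample_meta <- function(cfg) {
  samples <- unlist(lapply(cfg$groups, function(g)
    sprintf("%s_%d", g, seq_len(cfg$n_per_group))))
  group <- rep(cfg$groups, each = cfg$n_per_group)
  data.frame(sample = samples, group = group,
             gender = ifelse(startsWith(group, "M"), "M", "F"),
             condition = ifelse(grepl("cRaf", group), "cRaf", "WT"),
             stringsAsFactors = FALSE)
}

# per-miRNA x per-sample matrix of true mean log2 signals (before noise)
sim_mu <- function(cfg, baseline, meta) {
  mu <- matrix(baseline, nrow = cfg$n_mirnas, ncol = nrow(meta))
  pe <- cfg$planted_effects
  if (!is.null(pe)) {
    mirnas <- sim_mirna_names(cfg$n_mirnas)
    unknown <- setdiff(pe$mirna, mirnas)
    if (length(unknown))
      stop("planted effect on unknown miRNA: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (k in seq_len(nrow(pe))) {
      i <- match(pe$mirna[k], mirnas)
      hit <- meta$condition == "cRaf" &
        (is.na(pe$gender[k]) | meta$gender == pe$gender[k])
      mu[i, hit] <- mu[i, hit] + pe$log2fc[k]
    }
  }
  mu
}

#' Simulate paired two-platform expression data with known ground truth
#'
#' Draws per-miRNA baseline log2 signals, adds planted transgenic effects
#' (optionally gender-restricted, as interaction terms), and emits:
#' platform A as a single-spot miRNA-by-sample raw matrix, platform B as a
#' spot-level matrix with `n_replicate_spots` technical replicates per
#' miRNA whose values are background-corrected (a simulated background is
#' subtracted, producing negative values at rate `negative_rate`), and the
#' ground truth. Detectability per platform follows a logistic curve in GC
#' percent; a miRNA a platform cannot detect emits background-level
#' signal on that platform (so group effects are invisible there).
#' Identical seeds give bit-identical output.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `platform_a` (raw [expr_matrix()]),
#'   `platform_b` (raw spot-level `expr_matrix`), `truth` (data frame:
#'   `mirna`, `gc`, `log2fc_M`, `log2fc_F`, `detectable_a`,
#'   `detectable_b`).
#' @export
simulate_two_platforms <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_mirnas
  mirnas <- sim_mirna_names(n)
  meta <- sim_sample_meta(cfg)
  ns <- nrow(meta)

  gc <- cfg$gc_assignments
  if (is.null(gc)) gc <- pmin(85, pmax(15, round(stats::rnorm(n, 50, 10))))
  baseline <- stats::rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  mu <- sim_mu(cfg, baseline, meta)

  if (is.null(cfg$platform_bias)) {
    det_a <- rep(TRUE, n); det_b <- rep(TRUE, n)
  } else {
    pa <- stats::plogis(cfg$platform_bias$a$slope * (gc - cfg$platform_bias$a$midpoint))
    pb <- stats::plogis(cfg$platform_bias$b$slope * (gc - cfg$platform_bias$b$midpoint))
    det_a <- stats::runif(n) < pa
    det_b <- stats::runif(n) < pb
  }

  bg_mu <- function(det) {
    # undetectable features sit at array background, flat across groups
    m <- mu
    nb <- sum(!det)
    if (nb) m[!det, ] <- stats::rnorm(nb, cfg$background_log2_mean,
                                      cfg$background_log2_sd)
    m
  }

  mu_a <- bg_mu(det_a)
  a_vals <- 2^(mu_a + matrix(stats::rnorm(n * ns, 0, cfg$noise_sd), n, ns))
  dimnames(a_vals) <- list(mirnas, meta$sample)
  platform_a <- expr_matrix(a_vals, meta, stage = "raw", platform = "A")
  platform_a <- log_op(platform_a, "simulate: platform A, seed=%d", cfg$seed)

  mu_b <- bg_mu(det_b)
  nspot <- cfg$n_replicate_spots
  spot_feature <- rep(mirnas, each = nspot)
  mu_spots <- mu_b[rep(seq_len(n), each = nspot), , drop = FALSE]
  signal <- 2^(mu_spots + matrix(stats::rnorm(n * nspot * ns, 0, cfg$noise_sd),
                                 n * nspot, ns))
  # background correction: subtract a simulated local background; for a
  # negative_rate fraction of spots the background exceeds the signal
  over <- matrix(stats::runif(n * nspot * ns) < cfg$negative_rate,
                 n * nspot, ns)
  bg_frac <- matrix(stats::runif(n * nspot * ns, 0, 0.25), n * nspot, ns)
  bg_frac[over] <- 1 + abs(stats::rnorm(sum(over), 0, 0.5))
  b_vals <- signal - signal * bg_frac
  rownames(b_vals) <- sprintf("%s_spot%02d", spot_feature,
                              rep(seq_len(nspot), times = n))
  colnames(b_vals) <- meta$sample
  platform_b <- expr_matrix(b_vals, meta, feature = spot_feature,
                            stage = "raw", platform = "B")
  platform_b <- log_op(platform_b,
                       "simulate: platform B, %d spots/miRNA, seed=%d",
                       nspot, cfg$seed)

  lfc <- function(g) {
    out <- numeric(n); pe <- cfg$planted_effects
    if (!is.null(pe)) for (k in seq_len(nrow(pe))) {
      if (is.na(pe$gender[k]) || pe$gender[k] == g)
        out[match(pe$mirna[k], mirnas)] <- out[match(pe$mirna[k], mirnas)] +
          pe$log2fc[k]
    }
    out
  }
  truth <- data.frame(mirna = mirnas, gc = gc,
                      log2fc_M = lfc("M"), log2fc_F = lfc("F"),
                      detectable_a = det_a, detectable_b = det_b,
                      stringsAsFactors = FALSE)
  list(platform_a = platform_a, platform_b = platform_b, truth = truth)
}

#' Simulate a qPCR Ct table consistent with the array ground truth
#'
#' Emits threshold-cycle values `Ct = intercept - log2(expression) +
#' noise` for the selected assays plus a `U6` reference assay whose Ct is
#' constant across groups up to noise. On a noiseless table the
#' delta-delta-Ct of an assay equals minus its planted log2 fold change
#' exactly.
#'
#' @param cfg A [simulation_config()].
#' @param truth The `truth` component of [simulate_two_platforms()], used
#'   to select default assays and validate names.
#' @param assays Character vector of miRNAs to assay; default: every
#'   planted miRNA plus up to four unplanted controls.
#' @return A long data frame `sample`, `assay`, `ct` with the sample
#'   metadata attached as attribute `"samples"` and the reference assay
#'   name as attribute `"reference"`.
#' @export
simulate_qpcr <- function(cfg, truth, assays = NULL) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(truth))
  set.seed(cfg$seed + 1L)
  meta <- sim_sample_meta(cfg)
  planted <- if (is.null(cfg$planted_effects)) character()
             else unique(cfg$planted_effects$mirna)
  if (is.null(assays)) {
    nulls <- setdiff(truth$mirna, planted)
    assays <- c(planted, utils::head(nulls, 4L))
  }
  unknown <- setdiff(assays, truth$mirna)
  if (length(unknown))
    stop("unknown assay(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  baseline <- cfg$baseline_log2_mean  # common intercept; cancels in dCt
  mu <- sim_mu(cfg, baseline, meta)
  rownames(mu) <- truth$mirna
  rows <- do.call(rbind, lapply(assays, function(a) {
    ct <- cfg$qpcr_intercept - mu[a, ] +
      stats::rnorm(nrow(meta), 0, cfg$qpcr_noise_sd)
    data.frame(sample = meta$sample, assay = a, ct = as.numeric(ct),
               stringsAsFactors = FALSE)
  }))
  u6 <- data.frame(sample = meta$sample, assay = "U6",
                   ct = cfg$u6_ct + stats::rnorm(nrow(meta), 0, cfg$qpcr_noise_sd),
                   stringsAsFactors = FALSE)
  out <- rbind(rows, u6)
  attr(out, "samples") <- meta
  attr(out, "reference") <- "U6"
  out
}
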