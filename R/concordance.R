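#' Call per-group detection of each miRNA
#'
#' The default rule declares a miRNA "detected" in a group when its median
#' signal across that group's samples exceeds a threshold; the default
#' threshold is the matrix-wide 50th percentile of the signal values.
#' Alternatively an external present/absent flag matrix can be supplied
#' (`rule = "flag_column"`), mirroring vendor calls. The rule used is
#' recorded in every call.
#'
#' @param m A normalized, feature-level [expr_matrix()].
#' @param rule `"median_above_threshold"` or `"flag_column"`.
#' @param threshold Signal threshold; default `NULL` uses the matrix-wide
#'   median.
#' @param flags For `rule = "flag_column"`: logical matrix, feature x
#'   group, of external detection flags.
#' @return A data frame of class `detection_calls`: one row per miRNA x
#'   group with columns `mirna`, `group`, `detected`, `stat`, `rule`;
#'   attribute `"platform"` carries the matrix's platform tag.
#' @export
call_detected <- function(m, rule = c("median_above_threshold", "flag_column"),
                          threshold = NULL, flags = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  rule <- tryCatch(match.arg(rule),
                   error = function(e) stop("unknown detection rule: ",
                                            rule[1L], call. = FALSE))
  groups <- unique(m$samples$group)
  if (rule == "flag_column") {
    if (is.null(flags) || !is.matrix(flags))
      stop("'flags' matrix required for rule 'flag_column'", call. = FALSE)
    calls <- do.call(rbind, lapply(groups, function(g)
      data.frame(mirna = rownames(m$values), group = g,
                 detected = as.logical(flags[rownames(m$values), g]),
                 stat = NA_real_, rule = rule, stringsAsFactors = FALSE)))
  } else {
    if (is.null(threshold)) threshold <- stats::median(m$values)
    calls <- do.call(rbind, lapply(groups, function(g) {
      cols <- m$samples$group == g
      med <- apply(m$values[, cols, drop = FALSE], 1L, stats::median)
      data.frame(mirna = rownames(m$values), group = g,
                 detected = med > threshold, stat = med,
                 rule = sprintf("%s(threshold=%.4g)", rule, threshold),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(calls) <- NULL
  attr(calls, "platform") <- m$samples$platform[1L]
  class(calls) <- c("detection_calls", class(calls))
  calls
}

#' Extract the detected set for one group
#'
#' @param calls A [call_detected()] result.
#' @param group Group label.
#' @return Character vector of detected miRNA names.
#' @export
detected_set <- function(calls, group) {
  stopifnot(inherits(calls, "detection_calls"))
  calls$mirna[calls$group == group & calls$detected]
}

#' Overlap statistics of two detected sets against a shared universe
#'
#' Counts and fractions (relative to the universe) of the miRNAs detected
#' by each platform, detected by both, and exclusive to each. Both sets
#' must lie inside the universe.
#'
#' @param set_a,set_b Character vectors of detected miRNAs.
#' @param universe Character vector: the features shared by both platforms.
#' @return An object of class `concordance_summary`: `universe_size`,
#'   `n_a`, `frac_a`, `n_b`, `frac_b`, `n_common`, `frac_common`, and the
#'   sets `common`, `a_only`, `b_only`.
#' @export
overlap_stats <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b))
    stop("detection call outside the universe: ",
         paste(utils::head(c(out_a, out_b), 5L), collapse = ", "),
         call. = FALSE)
  common <- intersect(set_a, set_b)
  u <- length(universe)
  structure(list(
    universe_size = u,
    n_a = length(set_a), frac_a = length(set_a) / u,
    n_b = length(set_b), frac_b = length(set_b) / u,
    n_common = length(common), frac_common = length(common) / u,
    common = sort(common),
    a_only = sort(setdiff(set_a, set_b)),
    b_only = sort(setdiff(set_b, set_a))), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "universe %d | A %d (%.0f%%) | B %d (%.0f%%) | common %d (%.0f%%) | A-only %d, B-only %d\n",
    x$universe_size, x$n_a, 100 * x$frac_a, x$n_b, 100 * x$frac_b,
    x$n_common, 100 * x$frac_common, length(x$a_only), length(x$b_only)))
  invisible(x)
}

#' @export
as.data.frame.concordance_summary <- function(x, ...) {
  data.frame(universe_size = x$universe_size, n_a = x$n_a, frac_a = x$frac_a,
             n_b = x$n_b, frac_b = x$frac_b, n_common = x$n_common,
             frac_common = x$frac_common)
}

#' GC-content diagnostic for platform-discordant significance calls
#'
#' Partitions two platforms' significant miRNA sets into platform-A-only,
#' platform-B-only and shared, and reports each partition's members, GC
#' values, min-max range and mean — the diagnostic for GC-dependent
#' detection bias (a platform insensitive to low-GC probes yields an
#' exclusive set with systematically lower GC).
#'
#' @param de_a,de_b Character vectors: miRNAs called significant on each
#'   platform.
#' @param gc Named numeric vector of GC percents covering every named
#'   miRNA.
#' @return An object of class `gc_discordance`: list with elements
#'   `a_only`, `b_only`, `shared`, each `list(members, gc, range, mean)`
#'   (empty partitions have zero-length members and `NA` range/mean).
#' @export
gc_discordance <- function(de_a, de_b, gc) {
  de_a <- unique(as.character(de_a)); de_b <- unique(as.character(de_b))
  all_named <- union(de_a, de_b)
  missing <- all_named[!all_named %in% names(gc)]
  if (length(missing))
    stop("missing GC content for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  part <- function(members) {
    members <- sort(members)
    vals <- unname(gc[members])
    list(members = members, gc = vals,
         range = if (length(vals)) range(vals) else c(NA_real_, NA_real_),
         mean = if (length(vals)) mean(vals) else NA_real_)
  }
  structure(list(a_only = part(setdiff(de_a, de_b)),
                 b_only = part(setdiff(de_b, de_a)),
                 shared = part(intersect(de_a, de_b))),
            class = "gc_discordance")
}

#' @export
print.gc_discordance <- function(x, ...) {
  for (nm in names(x)) {
    p <- x[[nm]]
    if (!length(p$members)) { cat(sprintf("%-7s (empty)\n", nm)); next }
    cat(sprintf("%-7s n=%d  GC %g-%g%%  mean %.1f%%  [%s]\n", nm,
                length(p$members), p$range[1L], p$range[2L], p$mean,
                paste(p$members, collapse = ", ")))
  }
  invisible(x)
}
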