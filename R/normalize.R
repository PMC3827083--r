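#' Construct an expression matrix with sample metadata
#'
#' The container used by the normalization, detection and differential
#' expression stages: a numeric feature-by-sample matrix plus per-sample
#' metadata (group label, platform), a processing stage tag, and a
#' provenance log that every transform appends to. Spot-level matrices
#' (several rows per miRNA) carry a `feature` vector mapping rows to
#' miRNAs; [summarize_replicates()] collapses them.
#'
#' @param values Numeric matrix, features x samples, with dimnames.
#' @param samples Data frame with at least columns `sample` and `group`
#'   (one row per column of `values`); a `platform` column is added if
#'   absent.
#' @param feature Character vector mapping rows to feature (miRNA) names;
#'   defaults to rownames.
#' @param stage One of `"raw"`, `"normalized"`, `"summarized"`.
#' @param platform Platform tag stored in `samples$platform` when that
#'   column is absent.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples, feature = rownames(values),
                        stage = "raw", platform = NA_character_) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row and column names", call. = FALSE)
  stopifnot(is.data.frame(samples), all(c("sample", "group") %in% names(samples)))
  if (nrow(samples) != ncol(values))
    stop("'samples' must have one row per column of 'values'", call. = FALSE)
  if (!identical(as.character(samples$sample), colnames(values)))
    stop("samples$sample must match colnames(values) in order", call. = FALSE)
  if (is.null(samples$platform)) samples$platform <- platform
  if (is.null(feature)) feature <- rownames(values)
  stopifnot(length(feature) == nrow(values))
  stage <- match.arg(stage, c("raw", "normalized", "summarized"))
  structure(list(values = values, samples = samples,
                 feature = as.character(feature), stage = stage,
                 log = character()),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d rows (%d features) x %d samples, stage '%s', platform %s\n",
              nrow(x$values), length(unique(x$feature)), ncol(x$values),
              x$stage, paste(unique(x$samples$platform), collapse = "/")))
  if (length(x$log)) cat("provenance:\n", paste(" ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

log_op <- function(m, fmt, ...) {
  m$log <- c(m$log, sprintf(fmt, ...))
  m
}

#' Quantile normalization across samples
#'
#' Forces every column to share the same sorted value multiset (the
#' row-wise mean of the sorted columns), preserving each column's ranks;
#' tied values receive the mean of their candidate normalized values. The
#' operation is idempotent. Delegates to `limma::normalizeQuantiles()`.
#' Operates on raw intensities; logs are taken downstream.
#'
#' @param m An [expr_matrix()] with at least two samples and no missing
#'   values.
#' @return The normalized `expr_matrix`, stage `"normalized"`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(m$values)) stop("missing values are not allowed", call. = FALSE)
  dn <- dimnames(m$values)
  m$values <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(m$values) <- dn
  m$stage <- "normalized"
  log_op(m, "quantile_normalize: %d x %d", nrow(m$values), ncol(m$values))
}

#' Scale each sample to a common upper-percentile level
#'
#' Divides each column by its q-th percentile (linear interpolation
#' between order statistics, quantile type 7) and rescales by the
#' geometric mean of all columns' q-th percentiles, so that after scaling
#' every column shares one q-th percentile value. Idempotent.
#'
#' @param m An [expr_matrix()].
#' @param q Percentile in (0, 100); default 75.
#' @param qtype Quantile algorithm passed to [stats::quantile()].
#' @return The scaled `expr_matrix`, stage `"normalized"`.
#' @export
percentile_scale <- function(m, q = 75, qtype = 7) {
  stopifnot(inherits(m, "expr_matrix"), q > 0, q < 100)
  if (anyNA(m$values)) stop("missing values are not allowed", call. = FALSE)
  colq <- apply(m$values, 2L, stats::quantile, probs = q / 100, type = qtype,
                names = FALSE)
  if (any(colq <= 0))
    stop(sprintf("non-positive %gth percentile in sample(s): %s", q,
                 paste(colnames(m$values)[colq <= 0], collapse = ", ")),
         call. = FALSE)
  target <- exp(mean(log(colq)))
  m$values <- sweep(m$values, 2L, target / colq, `*`)
  m$stage <- "normalized"
  log_op(m, "percentile_scale: q=%g, target=%.4g", q, target)
}

#' Replace non-positive signals by a small floor
#'
#' Every value less than or equal to zero becomes `floor` (default 0.01);
#' positive values are untouched. Zeros are clamped along with negatives
#' so that downstream log2 transforms stay finite.
#'
#' @param m An [expr_matrix()].
#' @param floor Replacement value, > 0.
#' @return The clamped `expr_matrix`.
#' @export
clamp_negatives <- function(m, floor = 0.01) {
  stopifnot(inherits(m, "expr_matrix"), floor > 0)
  n_clamped <- sum(m$values <= 0)
  m$values[m$values <= 0] <- floor
  log_op(m, "clamp_negatives: floor=%g, clamped=%d", floor, n_clamped)
}

#' Summarise replicate spots per miRNA as median signals
#'
#' Collapses a spot-level matrix to one row per feature by taking the
#' per-sample median across that feature's replicate spots (mean of the
#' two middle order statistics for even spot counts). Features keep their
#' first-appearance order; spot counts are recorded in the provenance log.
#'
#' @param m A spot-level [expr_matrix()] whose `feature` vector maps spots
#'   to miRNAs (every feature must have at least one spot).
#' @return A feature-level `expr_matrix`, stage `"summarized"`.
#' @export
summarize_replicates <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  feats <- unique(m$feature)
  idx <- split(seq_len(nrow(m$values)), factor(m$feature, levels = feats))
  counts <- lengths(idx)
  if (any(counts == 0L))
    stop("feature(s) with zero spots: ",
         paste(feats[counts == 0L], collapse = ", "), call. = FALSE)
  med <- t(vapply(idx, function(ix)
    apply(m$values[ix, , drop = FALSE], 2L, stats::median),
    numeric(ncol(m$values))))
  rownames(med) <- feats
  colnames(med) <- colnames(m$values)
  out <- expr_matrix(med, m$samples, feature = feats, stage = "summarized")
  out$log <- c(m$log, sprintf(
    "summarize_replicates: %d spots -> %d features (spots/feature %s)",
    nrow(m$values), length(feats),
    if (length(unique(counts)) == 1L) as.character(counts[1L])
    else sprintf("%d-%d", min(counts), max(counts))))
  out
}
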