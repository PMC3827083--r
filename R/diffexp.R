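#' Welch's unequal-variance two-sample t-test
#'
#' Closed-form Welch statistic
#' \eqn{t = (\bar y_A - \bar y_B) / \sqrt{s_A^2/n_A + s_B^2/n_B}} with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution. Degenerate corner: when both groups have zero variance
#' and equal means, `t = 0`, `p = 1` (with `df = nA + nB - 2`); zero
#' variance with unequal means gives infinite `t` and `p = 0`.
#'
#' @param a,b Numeric vectors, each with at least two finite values.
#' @return Named list `t`, `df`, `p`.
#' @examples
#' welch_t(c(10, 12, 14), c(20, 22, 24)) # t = -6.124, df = 4
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b))
    stop("each group needs >= 2 finite values", call. = FALSE)
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  se2 <- va + vb
  delta <- mean(a) - mean(b)
  if (se2 == 0) {
    if (delta == 0) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(delta) * Inf, df = na + nb - 2, p = 0))
  }
  t <- delta / sqrt(se2)
  df <- se2^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Per-miRNA differential expression for one contrast
#'
#' For every miRNA, applies [welch_t()] between the case and control
#' groups and reports the signal log ratio (log2 of the ratio of group
#' means of the linear signals — not the mean of per-sample log ratios)
#' plus the mean linear signal across all samples of the contrast. Tests
#' run on `log2` of the clamped signals by default (`on_log2 = FALSE`
#' tests linear signals). Gender-specific contrasts are simply separate
#' calls with the corresponding group pair.
#'
#' @param m A normalized, feature-level [expr_matrix()].
#' @param contrast Character vector `c(case_group, control_group)`.
#' @param on_log2 Run the t-test on log2 signals.
#' @param clamp_floor Floor applied before log2.
#' @return A data frame of class `de_result`: `mirna`, `t`, `df`, `p`,
#'   `log2_ratio`, `mean_all`, plus a BH-adjusted `p_adj` column
#'   (informational; never used for gating).
#' @export
de_table <- function(m, contrast, on_log2 = TRUE, clamp_floor = 0.01) {
  stopifnot(inherits(m, "expr_matrix"), length(contrast) == 2L)
  case <- m$samples$group == contrast[1L]
  ctrl <- m$samples$group == contrast[2L]
  if (!any(case)) stop("no samples in group '", contrast[1L], "'", call. = FALSE)
  if (!any(ctrl)) stop("no samples in group '", contrast[2L], "'", call. = FALSE)
  x <- m$values
  x[x <= 0] <- clamp_floor
  tx <- if (on_log2) log2(x) else x
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    w <- welch_t(tx[i, case], tx[i, ctrl])
    c(t = w$t, df = w$df, p = w$p,
      log2_ratio = log2(mean(x[i, case]) / mean(x[i, ctrl])),
      mean_all = mean(x[i, case | ctrl]))
  }, numeric(5L)))
  out <- data.frame(mirna = rownames(x), res, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", class(out))
  out
}

#' Compound significance filter for a differential expression table
#'
#' Keeps miRNAs satisfying all three gates: `p < p_max`, `|log2_ratio| >=
#' min_abs_log2fc`, and mean signal above the `min_mean_percentile`-th
#' percentile of all `mean_all` values in the table. A linear fold-change
#' gate (`min_abs_fc`) can replace the log2 gate where a |FC| threshold is
#' preferred. No multiple-testing correction gates by default. The
#' thresholds used are recorded in attribute `"filter"`.
#'
#' @param de A [de_table()] result.
#' @param p_max P-value gate.
#' @param min_abs_log2fc Minimum absolute log2 ratio (ignored when
#'   `min_abs_fc` is given).
#' @param min_mean_percentile Percentile (0-100) of `mean_all` the mean
#'   signal must exceed.
#' @param min_abs_fc Optional minimum absolute linear fold change.
#' @return The significant subset of `de`, same columns.
#' @export
filter_significant <- function(de, p_max = 0.05, min_abs_log2fc = 1.5,
                               min_mean_percentile = 50, min_abs_fc = NULL) {
  stopifnot(inherits(de, "de_result"), nrow(de) > 0)
  cut <- stats::quantile(de$mean_all, min_mean_percentile / 100, type = 7,
                         names = FALSE)
  fc_gate <- if (is.null(min_abs_fc)) abs(de$log2_ratio) >= min_abs_log2fc
             else 2^abs(de$log2_ratio) > min_abs_fc
  keep <- de$p < p_max & fc_gate & de$mean_all > cut
  out <- de[keep, , drop = FALSE]
  attr(out, "contrast") <- attr(de, "contrast")
  attr(out, "filter") <- list(p_max = p_max,
                              min_abs_log2fc = min_abs_log2fc,
                              min_abs_fc = min_abs_fc,
                              min_mean_percentile = min_mean_percentile,
                              mean_cut = cut)
  class(out) <- class(de)
  out
}

#' Delta-delta-Ct fold changes from a qPCR Ct table
#'
#' Normalises each assay's Ct to the reference assay per sample
#' (`dCt = Ct_assay - Ct_reference`), forms
#' `ddCt = mean dCt(case) - mean dCt(control)`, and reports
#' `log2 fold change = -ddCt` with a Welch p-value on the per-sample dCt
#' values. The reference assay itself has a log2 fold change of exactly 0.
#'
#' @param ct Long data frame with columns `sample`, `assay`, `ct`; sample
#'   group labels are taken from attribute `"samples"` (as produced by
#'   [simulate_qpcr()]) or from the `samples` argument.
#' @param contrast Character vector `c(case_group, control_group)`.
#' @param reference_assay Name of the housekeeping assay, present in every
#'   sample.
#' @param samples Optional data frame `sample`, `group` overriding the
#'   attribute.
#' @return A data frame of class `qpcr_result`: `assay`, `ddct`,
#'   `log2fc`, `fold_change`, `t`, `df`, `p`.
#' @export
ddct_fold_change <- function(ct, contrast, reference_assay = "U6",
                             samples = attr(ct, "samples")) {
  stopifnot(is.data.frame(ct), all(c("sample", "assay", "ct") %in% names(ct)),
            length(contrast) == 2L)
  if (is.null(samples))
    stop("sample metadata required (attribute 'samples' or argument)",
         call. = FALSE)
  ref <- ct[ct$assay == reference_assay, ]
  if (!nrow(ref)) stop("reference assay '", reference_assay, "' not found",
                       call. = FALSE)
  all_samples <- unique(ct$sample)
  missing_ref <- setdiff(all_samples, ref$sample)
  if (length(missing_ref))
    stop("missing reference Ct for sample(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  grp <- stats::setNames(samples$group, samples$sample)
  assays <- unique(ct$assay)
  out <- do.call(rbind, lapply(assays, function(a) {
    sub <- ct[ct$assay == a, ]
    dct <- sub$ct - ref_ct[sub$sample]
    g <- grp[sub$sample]
    case <- dct[g == contrast[1L]]; ctrl <- dct[g == contrast[2L]]
    if (length(case) < 2L || length(ctrl) < 2L)
      stop("assay '", a, "': fewer than 2 samples in a contrast group",
           call. = FALSE)
    if (a == reference_assay) {
      ddct <- 0; w <- list(t = 0, df = length(case) + length(ctrl) - 2, p = 1)
    } else {
      ddct <- mean(case) - mean(ctrl)
      w <- welch_t(case, ctrl)
    }
    data.frame(assay = a, ddct = ddct, log2fc = -ddct,
               fold_change = 2^(-ddct), t = w$t, df = w$df, p = w$p,
               stringsAsFactors = FALSE)
  }))
  attr(out, "contrast") <- contrast
  attr(out, "reference") <- reference_assay
  class(out) <- c("qpcr_result", class(out))
  out
}
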