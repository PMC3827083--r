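# Reference values for the packaged 12-miRNA probe panel: GC percent of the
# mature miRNA, duplex free energy (kcal/mol) and melting temperature (degC)
# for the full-length probe and for the two variants of the 3'-anchored
# tailed probe. `tm_consistent` marks the eight miRNAs whose reference
# melting temperatures were derived under the same strand-concentration
# convention as the packaged default conditions; the other four reference
# Tm values follow a different convention and are exercised only by the
# acceptance suite (see test-acceptance.R).
panel_expected <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
mirna gc affy_dg affy_tm agl_ext_dg agl_ext_tm agl_core_dg agl_core_tm tm_consistent
mmu-miR-15a  40 -25.0 56.2 -25.0 56.2 -24.4 56.9 FALSE
mmu-miR-21   36 -22.7 39.9 -20.3 37.2 -17.6 32.0 TRUE
mmu-miR-34a  50 -27.7 60.4 -23.2 56.9 -20.5 52.8 FALSE
mmu-miR-96   40 -24.3 38.7 -24.1 39.9 -23.9 41.2 TRUE
mmu-miR-127  59 -30.6 51.4 -23.2 44.3 -22.3 43.9 TRUE
mmu-miR-146a 40 -26.0 59.5 -21.3 55.6 -20.0 54.0 FALSE
mmu-miR-146b 40 -26.2 47.4 -21.5 41.5 -20.2 39.2 TRUE
mmu-miR-182  48 -31.9 62.9 -19.9 62.9 -17.0 58.8 FALSE
mmu-miR-183  40 -26.3 46.3 -23.2 44.7 -20.3 40.0 TRUE
mmu-miR-184  50 -31.9 57.0 -31.9 57.0 -30.3 56.2 TRUE
mmu-miR-322  40 -23.1 37.7 -23.1 37.7 -23.1 37.7 TRUE
mmu-miR-433  54 -30.3 50.9 -20.7 43.7 -17.8 38.0 TRUE
")
  tab
}

panel_records <- function() {
  panel <- probe_panel()
  mir <- panel[!duplicated(panel$mirna), ]
  recs <- lapply(seq_len(nrow(mir)), function(i)
    sequence_record(mir$mirna[i], mir$sequence[i], "RNA"))
  names(recs) <- mir$mirna
  recs
}

panel_probe <- function(mirna, platform) {
  panel <- probe_panel()
  row <- panel[panel$mirna == mirna & panel$platform == platform, ]
  parse_probe(row$probe, sprintf("%s_%s", mirna, platform))
}

# absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_within <- function(actual, expected, tol, label = NULL) {
  expect_lte(abs(actual - expected), tol,
             label = paste(label, sprintf("|%.4g - %.4g|", actual, expected)))
}

# small expr_matrix builder for unit tests
toy_matrix <- function(values, groups = rep("g1", ncol(values)),
                       platform = "A") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("m%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expr_matrix(values,
              data.frame(sample = colnames(values), group = groups,
                         stringsAsFactors = FALSE),
              platform = platform)
}

# Exhaustive O(n^3) reference agglomerator on the 1 - Pearson distance:
# cluster-to-cluster distance recomputed from the full leaf-leaf distance
# matrix at every step (exact for average/complete/single linkage).
ref_agglomerate <- function(mat, linkage = "average") {
  d <- 1 - cor(t(mat))
  clusters <- lapply(seq_len(nrow(mat)), identity)
  heights <- numeric(0)
  formed <- list()
  cluster_dist <- function(ci, cj) {
    vals <- d[ci, cj, drop = FALSE]
    switch(linkage, average = mean(vals), complete = max(vals),
           single = min(vals))
  }
  while (length(clusters) > 1L) {
    best <- NULL; bd <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq(i + 1L, length(clusters))) {
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < bd) { bd <- dd; best <- c(i, j) }
      }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    formed <- c(formed, list(sort(merged)))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, clusters = formed)
}

# leaf-index sets formed at each hclust merge step
hclust_clusters <- function(hc) {
  res <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members <- function(x) if (x < 0) -x else res[[x]]
    res[[k]] <- sort(c(members(hc$merge[k, 1L]), members(hc$merge[k, 2L])))
  }
  res
}
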