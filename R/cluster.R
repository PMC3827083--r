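#' Pearson correlation distance between two profiles
#'
#' `1 - r`, where `r` is the Pearson correlation; ranges over `[0, 2]`
#' (0 for perfectly correlated, 2 for perfectly anti-correlated).
#' Profiles must have equal length of at least 3 and must not be
#' constant (the correlation is undefined for a zero-variance vector).
#'
#' @param x,y Numeric vectors.
#' @return Distance in `[0, 2]`.
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("profiles must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson distance undefined for a constant profile", call. = FALSE)
  1 - stats::cor(x, y)
}

#' Agglomerative hierarchical clustering on Pearson distances
#'
#' Clusters the rows of a profile matrix by agglomerative hierarchical
#' clustering (via [stats::hclust()]) on the `1 - Pearson r` distance,
#' with average linkage by default. Intended for log2-ratio profiles (one
#' row per miRNA, one column per contrast), but axis-agnostic — pass the
#' transpose to cluster samples.
#'
#' @param profiles Numeric matrix with >= 2 named, non-constant rows and
#'   >= 3 columns.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class `hca_tree`: list with the underlying
#'   `hclust` object and `merges`, a data frame `step`, `left`, `right`,
#'   `height` describing each merge (negative entries index leaves, as in
#'   `hclust`).
#' @export
hca <- function(profiles, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(profiles), is.numeric(profiles))
  if (nrow(profiles) < 2L) stop("need at least 2 profiles", call. = FALSE)
  if (ncol(profiles) < 3L) stop("profiles must have >= 3 columns", call. = FALSE)
  if (is.null(rownames(profiles)))
    stop("'profiles' must have row names", call. = FALSE)
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant profile(s): ",
         paste(rownames(profiles)[sds == 0], collapse = ", "), call. = FALSE)
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  hc <- stats::hclust(d, method = linkage)
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       left = hc$merge[, 1L], right = hc$merge[, 2L],
                       height = hc$height)
  structure(list(hclust = hc, merges = merges, linkage = linkage,
                 leaves = rownames(profiles)),
            class = "hca_tree")
}

#' @export
print.hca_tree <- function(x, ...) {
  cat(sprintf("hca_tree: %d leaves, %s linkage, heights %.3g..%.3g\n",
              length(x$leaves), x$linkage,
              min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' Export a cluster tree as Newick text
#'
#' Converts the merge tree to an `ape` phylogeny (branch lengths derived
#' from merge heights; leaves of an average-linkage tree sit at depth
#' height/2 under each merge) and writes Newick text. Leaf names
#' containing Newick metacharacters are quoted by `ape`. The text
#' round-trips through [ape::read.tree()].
#'
#' @param tree An [hca()] result.
#' @param file Optional path; when given, the text is also written there.
#' @return Newick string, invisibly when `file` is given.
#' @export
export_tree <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "hca_tree"))
  phy <- ape::as.phylo(tree$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
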