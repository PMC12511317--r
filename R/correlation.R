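#' Pairwise Pearson correlation matrix with p-values
#'
#' Computes the full feature-by-feature Pearson correlation matrix and
#' two-sided p-values from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param table a complete `cohort_table` or numeric matrix (>= 3 rows).
#' @return List with symmetric `r` (unit diagonal) and `p` matrices.
#' @export
pearson_matrix <- function(table) {
  X <- if (inherits(table, "cohort_table")) table$values else as.matrix(table)
  if (anyNA(X)) stop_config("table must be complete")
  n <- nrow(X)
  stopifnot(n >= 3)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop_config("constant column(s): %s",
                paste(colnames(X)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(X)
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  diag(p) <- 0
  list(r = r, p = p)
}

#' Benjamini–Hochberg adjustment of the correlation p-value matrix
#'
#' Adjusts the `f(f-1)/2` upper-triangle p-values by the step-up false
#' discovery rate procedure and mirrors the result back into a symmetric
#' matrix (diagonal 0).
#'
#' @param p symmetric p-value matrix.
#' @return Symmetric q-value matrix.
#' @export
fdr_adjust <- function(p) {
  p <- as.matrix(p)
  ut <- upper.tri(p)
  q <- p
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  q
}

#' Hierarchical clustering dendrogram over features
#'
#' Agglomerative clustering of features using Euclidean distance between rows
#' of the correlation matrix (average linkage). Returns the merge tree, the
#' leaf order used for heat-map rendering, and the tree in Newick form.
#'
#' @param r symmetric correlation matrix with feature dimnames.
#' @param linkage linkage criterion passed to [stats::hclust()].
#' @return List with `hclust`, `leaf_order` (feature names), and `newick`.
#' @export
cluster_dendrogram <- function(r, linkage = "average") {
  r <- as.matrix(r)
  stopifnot(isSymmetric(unname(r)))
  hc <- stats::hclust(stats::dist(r, method = "euclidean"), method = linkage)
  phy <- ape::as.phylo(hc)
  list(hclust = hc,
       leaf_order = hc$labels[hc$order],
       newick = ape::write.tree(phy))
}

#' Full correlation map stage
#'
#' Convenience wrapper: correlation matrix, FDR-adjusted q-values, and the
#' feature dendrogram in one object.
#'
#' @inheritParams pearson_matrix
#' @param linkage linkage criterion for [cluster_dendrogram()].
#' @return List of class `correlation_map` with `r`, `p`, `q`, `dendrogram`,
#'   and the linkage recorded in `meta`.
#' @export
correlation_map <- function(table, linkage = "average") {
  rp <- pearson_matrix(table)
  q <- fdr_adjust(rp$p)
  dend <- cluster_dendrogram(rp$r, linkage = linkage)
  structure(list(r = rp$r, p = rp$p, q = q, dendrogram = dend,
                 meta = list(linkage = linkage, distance = "euclidean")),
            class = "correlation_map")
}
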