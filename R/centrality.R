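# Weighted centralities and community-level contrasts.

power_iterate <- function(M, tol = 1e-10, max_iter = 10000) {
  n <- nrow(M)
  # shift by a Gershgorin bound: kills sign-flip oscillation on bipartite-like
  # spectra without changing the leading eigenvector of a non-negative matrix
  shift <- max(rowSums(abs(M)))
  M <- M + diag(shift, n)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(M %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) stop_config("zero iterate: matrix has no positive structure")
    y <- y / ny
    if (max(abs(y - x)) < tol) return(y)
    x <- y
  }
  ev <- eigen(M, symmetric = isSymmetric(M), only.values = TRUE)$values
  gap <- if (length(ev) > 1) abs(abs(ev[1]) - abs(ev[2])) else NA_real_
  stop_config("power iteration did not converge in %d iterations (spectral gap %.3g)",
              max_iter, gap)
}

#' Weighted eigenvector centrality
#'
#' Node 'influence' score: the leading eigenvector of the symmetrised weight
#' matrix `W + t(W)` (directionality is captured separately by [hits()]),
#' computed by power iteration to `1e-10`. Non-negative with unit Euclidean
#' norm by Perron–Frobenius.
#'
#' @param graph an `importance_graph` with non-negative weights and at least
#'   one edge.
#' @return Named numeric score vector.
#' @export
eigenvector_centrality <- function(graph) {
  W <- graph_weight_matrix(graph)
  if (all(W == 0)) stop_config("graph has no edges")
  S <- W + t(W)
  x <- power_iterate(S)
  if (sum(x) < 0) x <- -x
  stats::setNames(pmax(x, 0) / sqrt(sum(pmax(x, 0)^2)), graph$nodes$name)
}

#' Hub and authority scores (HITS)
#'
#' Iterates `a <- t(W) h`, `h <- W a` with L2 normalisation until successive
#' change falls below `1e-10`. Equivalently, the authority vector is the
#' leading eigenvector of `t(W) W` and the hub vector of `W t(W)`. A good hub
#' points at many good authorities; a good authority is pointed at by many
#' good hubs.
#'
#' @param graph a directed `importance_graph` with non-negative weights.
#' @return List with named `hub` and `authority` unit-norm vectors.
#' @export
hits <- function(graph) {
  W <- graph_weight_matrix(graph)
  if (all(W == 0)) stop_config("graph has no edges")
  n <- nrow(W)
  h <- rep(1 / sqrt(n), n)
  a <- rep(1 / sqrt(n), n)
  for (it in seq_len(10000)) {
    a2 <- as.numeric(crossprod(W, h))
    a2 <- a2 / sqrt(sum(a2^2))
    h2 <- as.numeric(W %*% a2)
    h2 <- h2 / sqrt(sum(h2^2))
    if (max(abs(a2 - a)) < 1e-10 && max(abs(h2 - h)) < 1e-10) {
      return(list(hub = stats::setNames(h2, graph$nodes$name),
                  authority = stats::setNames(a2, graph$nodes$name)))
    }
    a <- a2
    h <- h2
  }
  stop_config("HITS did not converge in 10000 iterations")
}

#' Per-node centrality table with z-scores and level-1 community
#'
#' Computes weighted eigenvector, hub and authority centralities, z-scores
#' each across nodes, and attaches the level-1 community of each node from a
#' fitted nested block model.
#'
#' @param graph an `importance_graph`.
#' @param nested a `nested_state` fitted on the same graph.
#' @return A data frame of class `centrality_table`.
#' @export
centrality_table <- function(graph, nested) {
  ev <- eigenvector_centrality(graph)
  ha <- hits(graph)
  z <- function(x) (x - mean(x)) / stats::sd(x)
  out <- data.frame(
    node = graph$nodes$name,
    domain = graph$nodes$domain,
    eigenvector = as.numeric(ev),
    hub = as.numeric(ha$hub),
    authority = as.numeric(ha$authority),
    eigenvector_z = z(as.numeric(ev)),
    hub_z = z(as.numeric(ha$hub)),
    authority_z = z(as.numeric(ha$authority)),
    L1_block = nested$l1_of_node,
    stringsAsFactors = FALSE
  )
  class(out) <- c("centrality_table", "data.frame")
  out
}

# Pairwise Tukey HSD table from group summaries via the studentized range.
tukey_pairs <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  ns <- tapply(x, g, length)
  means <- tapply(x, g, mean)
  df_err <- length(x) - k
  mse <- sum(tapply(x, g, function(v) sum((v - mean(v))^2))) / df_err
  pairs <- utils::combn(levels(g), 2)
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    p_adj = vapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
      q <- abs(means[[b]] - means[[a]]) / se
      stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Community-level centrality contrast: one-way ANOVA with Tukey HSD
#'
#' Tests whether the z-scored centrality metric differs across level-1
#' communities, then runs all pairwise Tukey honest-significant-difference
#' comparisons via the studentized range distribution. Communities with fewer
#' than 2 nodes are excluded with a warning. The report flags any block whose
#' mean is significantly greater than every other block — the hub/authority
#' readout. Each metric is tested per panel without cross-metric correction;
#' node centralities within one network are not fully independent, so
#' p-values are conservative screens rather than exact error rates.
#'
#' @param table a `centrality_table`.
#' @param metric `"eigenvector"`, `"hub"` or `"authority"` (z-scored column
#'   used).
#' @param alpha significance level for the top-block flag.
#' @return List of class `block_contrast`: `anova` (F, df, p), `tukey`
#'   (pairwise table), `block_summary`, `top_blocks`.
#' @export
block_contrast <- function(table, metric = c("eigenvector", "hub", "authority"),
                           alpha = 0.05) {
  metric <- match.arg(metric)
  x <- table[[paste0(metric, "_z")]]
  g <- table$L1_block
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("excluding block(s) with < 2 nodes: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(g %in% as.integer(small))
    x <- x[keep]
    g <- g[keep]
  }
  if (length(unique(g)) < 2) stop_config("need >= 2 blocks with >= 2 nodes")
  g <- factor(g)
  fit <- stats::aov(x ~ g)
  an <- summary(fit)[[1]]
  tk <- tukey_pairs(x, g)
  means <- tapply(x, g, mean)
  top <- vapply(levels(g), function(blk) {
    rows <- tk$group1 == blk | tk$group2 == blk
    others <- ifelse(tk$group1[rows] == blk, tk$group2[rows], tk$group1[rows])
    diffs <- ifelse(tk$group1[rows] == blk, -tk$diff[rows], tk$diff[rows])
    all(tk$p_adj[rows] < alpha) && all(means[[blk]] > means[others])
  }, logical(1))
  structure(list(
    metric = metric,
    anova = list(F = an[["F value"]][1], df = an[["Df"]],
                 p = an[["Pr(>F)"]][1]),
    tukey = tk,
    block_summary = data.frame(block = levels(g), n = as.integer(table(g)),
                               mean = as.numeric(means),
                               sd = as.numeric(tapply(x, g, stats::sd))),
    top_blocks = names(top)[top],
    note = "per-metric test; centralities within one network are not independent"
  ), class = "block_contrast")
}

#' @export
print.block_contrast <- function(x, ...) {
  cat(sprintf("<block_contrast> %s: F = %.3f, p = %.3g; top block(s): %s\n",
              x$metric, x$anova$F, x$anova$p,
              if (length(x$top_blocks)) paste(x$top_blocks, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Box-plot summary statistics per block
#'
#' Median, quartiles and whisker ends (1.5 IQR rule) of a z-scored centrality
#' per level-1 community — the numbers behind a box-and-whisker figure.
#'
#' @inheritParams block_contrast
#' @return A data frame, one row per block.
#' @export
block_boxplot_stats <- function(table, metric = c("eigenvector", "hub", "authority")) {
  metric <- match.arg(metric)
  x <- table[[paste0(metric, "_z")]]
  g <- factor(table$L1_block)
  do.call(rbind, lapply(levels(g), function(blk) {
    v <- x[g == blk]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    data.frame(block = blk, n = length(v),
               q1 = qs[1], median = qs[2], q3 = qs[3],
               whisker_lo = min(v[v >= qs[1] - 1.5 * iqr]),
               whisker_hi = max(v[v <= qs[3] + 1.5 * iqr]))
  }))
}
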