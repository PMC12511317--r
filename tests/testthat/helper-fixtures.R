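# Fixtures shared across test files; everything is generated in code.

# Small all-continuous schema driven by `k` latent factors, `per` features
# each, plus `noise` pure-noise features. Ideal for fast model tests.
tiny_schema <- function(k = 2, per = 3, noise = 1) {
  doms <- rep_len(pheno_domains(), k * per + noise)
  feature_schema(
    name = c(paste0("f", seq_len(k * per)), if (noise) paste0("noise", seq_len(noise))),
    domain = doms,
    value_kind = "continuous"
  )
}

tiny_config <- function(n = 300, k = 2, per = 3, noise = 1, noise_sd = 0.5,
                        seed = 11, missing_rate = 0) {
  sch <- tiny_schema(k, per, noise)
  L <- matrix(0, k, nrow(sch))
  for (j in seq_len(k * per)) L[(j - 1) %/% per + 1, j] <- 0.8
  generator_config(n_patients = n, schema = sch, n_latent = k,
                   loading_matrix = L, noise_sd = noise_sd,
                   missing_rate = missing_rate, mar_driver = "f1",
                   imbalance_targets = numeric(), seed = seed)
}

# Directed weighted graph with planted blocks: every ordered pair gets an
# edge with probability `density`; within-block mean weight is `ratio` times
# the between-block mean.
planted_graph <- function(n_blocks = 3, per_block = 10, ratio = 5,
                          density = 0.5, seed = 1) {
  n <- n_blocks * per_block
  plant <- rep(seq_len(n_blocks), each = per_block)
  nodes <- paste0("n", seq_len(n))
  withr::with_seed(seed, {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- stats::runif(nrow(pairs)) < density
    pairs <- pairs[keep, ]
    within <- plant[pairs$from] == plant[pairs$to]
    w <- ifelse(within, stats::rexp(nrow(pairs), 1 / ratio),
                stats::rexp(nrow(pairs), 1))
    g <- importance_graph(nodes,
                          data.frame(from = nodes[pairs$from],
                                     to = nodes[pairs$to],
                                     weight = pmax(w, 1e-8)))
    list(graph = g, plant = plant)
  })
}

# Two-scale plant: `micro` micro-blocks of `per` nodes, grouped pairwise into
# macro-blocks. Within-micro weights are heaviest, within-macro intermediate,
# across-macro lightest.
two_scale_graph <- function(micro = 6, per = 5, seed = 1) {
  n <- micro * per
  micro_of <- rep(seq_len(micro), each = per)
  macro_of <- (micro_of + 1) %/% 2
  nodes <- paste0("n", seq_len(n))
  withr::with_seed(seed, {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    pairs <- pairs[stats::runif(nrow(pairs)) < 0.6, ]
    mean_w <- ifelse(micro_of[pairs$from] == micro_of[pairs$to], 8,
                     ifelse(macro_of[pairs$from] == macro_of[pairs$to], 4, 1))
    w <- stats::rexp(nrow(pairs), 1 / mean_w)
    g <- importance_graph(nodes,
                          data.frame(from = nodes[pairs$from],
                                     to = nodes[pairs$to],
                                     weight = pmax(w, 1e-8)))
    list(graph = g, micro = micro_of, macro = macro_of)
  })
}

# 8-node fixture: two dense 4-cliques joined by one edge, unit-ish weights.
two_clique_graph <- function(seed = 1, bridge_weight = 1) {
  nodes <- paste0("n", 1:8)
  blk <- rep(1:2, each = 4)
  withr::with_seed(seed, {
    pairs <- expand.grid(from = 1:8, to = 1:8)
    pairs <- pairs[pairs$from != pairs$to &
                     blk[pairs$from] == blk[pairs$to], ]
    edges <- data.frame(from = nodes[pairs$from], to = nodes[pairs$to],
                        weight = stats::rexp(nrow(pairs), 1 / 5))
    edges <- rbind(edges, data.frame(from = "n1", to = "n5",
                                     weight = bridge_weight))
    list(graph = importance_graph(nodes, edges), plant = blk)
  })
}

# Centrality table with a single synthetic metric in all three columns.
fake_centrality_table <- function(values, blocks) {
  z <- (values - mean(values)) / stats::sd(values)
  structure(data.frame(node = paste0("n", seq_along(values)),
                       domain = NA_character_,
                       eigenvector = values, hub = values, authority = values,
                       eigenvector_z = z, hub_z = z, authority_z = z,
                       L1_block = blocks),
            class = c("centrality_table", "data.frame"))
}

# Minimal fit_result stub for graph-assembly tests.
stub_result <- function(target, importance, excluded = character()) {
  structure(list(
    target = structure(list(name = target, task = "regression",
                            excluded_predictors = excluded, gated = FALSE),
                       class = "target_spec"),
    importance = importance
  ), class = "fit_result")
}

# Complete cohort table built directly from a values matrix.
manual_table <- function(values, kinds = NULL, domains = NULL) {
  nm <- colnames(values)
  kinds <- kinds %||% rep("continuous", ncol(values))
  sch <- feature_schema(nm, domain = domains %||% rep_len(pheno_domains(), ncol(values)),
                        value_kind = kinds,
                        ordinal_levels = ifelse(kinds == "ordinal", 5L, NA_integer_))
  phenonet:::new_cohort_table(values,
                              matrix(FALSE, nrow(values), ncol(values)),
                              sch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
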