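# Nested weighted stochastic block model by minimum description length.
#
# The objective is a two-part code for a directed weighted graph given a
# partition b: (i) a degree-corrected microcanonical structural term for the
# block edge-count matrix e_rs, plus encodings of e_rs and of the partition
# itself; (ii) an exponential likelihood for the positive edge weights with a
# per-block-pair plug-in MLE rate, penalised by (1/2) log(m_rs) per fitted
# rate. Partition-independent constants (the degree-sequence encoding) are
# dropped: they cancel when comparing partitions of the same graph.

# Internal edge-list view of a graph with per-node incidence indices.
sbm_graph <- function(graph) {
  if (inherits(graph, "importance_graph")) {
    n <- nrow(graph$nodes)
    src <- match(graph$edges$from, graph$nodes$name)
    dst <- match(graph$edges$to, graph$nodes$name)
    w <- graph$edges$weight
    mult <- graph$edges$mult %||% rep(1, length(w))
    names_ <- graph$nodes$name
  } else {
    stop_config("expected an importance_graph")
  }
  if (length(w) && any(w <= 0)) {
    stop_config("edge weights must be positive (exponential support)")
  }
  loops <- which(src == dst)
  out_of <- lapply(seq_len(n), function(i) setdiff(which(src == i), loops))
  in_of <- lapply(seq_len(n), function(i) setdiff(which(dst == i), loops))
  self_of <- lapply(seq_len(n), function(i) loops[src[loops] == i])
  list(n = n, src = src, dst = dst, w = w, mult = mult,
       out_of = out_of, in_of = in_of, self_of = self_of, names = names_)
}

# Block-level sufficient statistics from scratch.
stats_from_b <- function(sg, b, B = max(b)) {
  e <- matrix(0, B, B)
  w <- matrix(0, B, B)
  if (length(sg$src)) {
    k <- b[sg$src] + (b[sg$dst] - 1L) * B  # column-major: e[b_src, b_dst]
    agg <- rowsum(cbind(sg$mult, sg$w), k)
    kk <- as.integer(rownames(agg))
    e[kk] <- agg[, 1]
    w[kk] <- agg[, 2]
  }
  list(b = b, B = B, n_r = tabulate(b, B), e = e, w = w)
}

# Description length (nats) from sufficient statistics.
dl_from_stats <- function(N, st, components = FALSE) {
  e <- st$e
  E <- sum(e)
  pos <- e > 0
  eout <- rowSums(e)
  ein <- colSums(e)
  s_fit <- -sum(e[pos] * log(e[pos])) +
    sum(eout[eout > 0] * log(eout[eout > 0])) +
    sum(ein[ein > 0] * log(ein[ein > 0]))
  l_ers <- if (E > 0) lchoose(st$B^2 + E - 1, E) else 0
  l_part <- lchoose(N - 1, st$B - 1) + lfactorial(N) - sum(lfactorial(st$n_r))
  m <- e[pos]
  W <- st$w[pos]
  l_weight <- if (length(m)) sum(m * (log(W / m) + 1) + 0.5 * log(m)) else 0
  total <- s_fit + l_ers + l_part + l_weight
  if (!components) return(total)
  list(total = total, structural = s_fit + l_ers, partition = l_part,
       weight = l_weight)
}

#' Description length of a partitioned weighted directed graph
#'
#' The minimised objective of the block-model stage: a degree-corrected
#' microcanonical structural code for the block edge counts `e_rs`, the
#' encodings of `e_rs` and of the partition, and the negative exponential
#' log-likelihood of the edge weights under per-block-pair MLE rates with a
#' `(1/2) log(m_rs)` penalty per rate. Lower is better; values are comparable
#' across partitions of the same graph.
#'
#' @param graph an `importance_graph` with positive edge weights.
#' @param b integer block assignment (one label in `1..B` per node).
#' @param components return the additive pieces as well.
#' @return Description length in nats (or a list when `components = TRUE`).
#' @export
description_length <- function(graph, b, components = FALSE) {
  sg <- sbm_graph(graph)
  stopifnot(length(b) == sg$n, all(b >= 1))
  b <- compact_labels(as.integer(b))
  dl_from_stats(sg$n, stats_from_b(sg, b), components = components)
}

compact_labels <- function(b) {
  match(b, sort(unique(b)))
}

#' Annealing configuration for block-model inference
#'
#' Inverse temperature rises geometrically from `beta_start` to `beta_end`
#' over `n_anneal` proposals and stays at `beta_end` thereafter; the search
#' stops once `wait` consecutive proposals pass without a new record-low
#' description length. The move mix is 80% single-node moves and 20%
#' merge/split moves.
#'
#' @param beta_start,beta_end inverse-temperature schedule endpoints.
#' @param wait record-breaking patience (proposals).
#' @param seed integer seed.
#' @param n_anneal proposals over which the schedule ramps.
#' @param p_single probability of a single-node move.
#' @param agglom_cand candidate pairs examined per greedy initial merge.
#' @param restarts independent annealing runs per fit; the best record wins.
#' @export
anneal_config <- function(beta_start = 1, beta_end = 10, wait = 1000,
                          seed = 1, n_anneal = 3000, p_single = 0.8,
                          agglom_cand = 200, restarts = 3) {
  stopifnot(beta_end >= beta_start, beta_start >= 0, wait >= 1, restarts >= 1)
  structure(list(beta_start = beta_start, beta_end = beta_end, wait = wait,
                 seed = seed, n_anneal = n_anneal, p_single = p_single,
                 agglom_cand = agglom_cand, restarts = restarts),
            class = "anneal_config")
}

# Incremental single-node move: node i from its block to block s (s may be
# B + 1, opening a new block). Returns updated stats, compacting empty blocks.
move_single_stats <- function(sg, st, i, s) {
  r <- st$b[i]
  B <- st$B
  e <- st$e
  w <- st$w
  if (s == B + 1) {
    e <- rbind(cbind(e, 0), 0)
    w <- rbind(cbind(w, 0), 0)
    B <- B + 1L
    st$n_r <- c(st$n_r, 0L)
  }
  shift <- function(idx, mult, wt, from_row = TRUE) {
    if (!length(idx)) return(NULL)
    tt <- st$b[idx]
    agg <- rowsum(cbind(mult, wt), tt)
    kk <- as.integer(rownames(agg))
    if (from_row) {
      e[r, kk] <<- e[r, kk] - agg[, 1]; w[r, kk] <<- w[r, kk] - agg[, 2]
      e[s, kk] <<- e[s, kk] + agg[, 1]; w[s, kk] <<- w[s, kk] + agg[, 2]
    } else {
      e[kk, r] <<- e[kk, r] - agg[, 1]; w[kk, r] <<- w[kk, r] - agg[, 2]
      e[kk, s] <<- e[kk, s] + agg[, 1]; w[kk, s] <<- w[kk, s] + agg[, 2]
    }
  }
  oe <- sg$out_of[[i]]
  shift(sg$dst[oe], sg$mult[oe], sg$w[oe], from_row = TRUE)
  ie <- sg$in_of[[i]]
  shift(sg$src[ie], sg$mult[ie], sg$w[ie], from_row = FALSE)
  se <- sg$self_of[[i]]
  if (length(se)) {
    sm <- sum(sg$mult[se]); sw <- sum(sg$w[se])
    e[r, r] <- e[r, r] - sm; w[r, r] <- w[r, r] - sw
    e[s, s] <- e[s, s] + sm; w[s, s] <- w[s, s] + sw
  }
  # zap floating-point residue so emptied block pairs are exactly zero
  e[abs(e) < 1e-9] <- 0
  w[e == 0] <- 0
  b <- st$b
  b[i] <- s
  n_r <- st$n_r
  n_r[r] <- n_r[r] - 1L
  n_r[s] <- n_r[s] + 1L
  if (n_r[r] == 0L) {
    keep <- setdiff(seq_len(B), r)
    e <- e[keep, keep, drop = FALSE]
    w <- w[keep, keep, drop = FALSE]
    n_r <- n_r[keep]
    b <- ifelse(b > r, b - 1L, b)
    B <- B - 1L
  }
  list(b = as.integer(b), B = as.integer(B), n_r = n_r, e = e, w = w)
}

# Merge blocks r and s directly on the sufficient statistics (row/column
# addition), avoiding any edge traversal.
merge_stats <- function(st, r, s) {
  lo <- min(r, s)
  hi <- max(r, s)
  e <- st$e
  w <- st$w
  e[lo, ] <- e[lo, ] + e[hi, ]
  e[, lo] <- e[, lo] + e[, hi]
  w[lo, ] <- w[lo, ] + w[hi, ]
  w[, lo] <- w[, lo] + w[, hi]
  keep <- setdiff(seq_len(st$B), hi)
  n_r <- st$n_r
  n_r[lo] <- n_r[lo] + n_r[hi]
  b <- st$b
  b[b == hi] <- lo
  b <- ifelse(b > hi, b - 1L, b)
  list(b = as.integer(b), B = st$B - 1L, n_r = n_r[keep],
       e = e[keep, keep, drop = FALSE], w = w[keep, keep, drop = FALSE])
}

# One greedy pass of single-node moves: each node (random order) adopts the
# neighbouring block that most decreases the description length, if any.
greedy_sweep <- function(sg, st, dl, allow_new = TRUE) {
  for (i in sample.int(sg$n)) {
    r <- st$b[i]
    nbr_blocks <- unique(st$b[c(sg$dst[sg$out_of[[i]]], sg$src[sg$in_of[[i]]])])
    cands <- setdiff(nbr_blocks, r)
    if (allow_new && st$n_r[r] > 1L) cands <- c(cands, st$B + 1L)
    for (s in cands) {
      st2 <- move_single_stats(sg, st, i, s)
      dl2 <- dl_from_stats(sg$n, st2)
      if (dl2 < dl - 1e-12) {
        st <- st2
        dl <- dl2
        break
      }
    }
  }
  list(st = st, dl = dl)
}

# Agglomerative initialisation: greedily merge the best block pair all the
# way down from B = N to B = 1 (accepting locally worsening merges, as the
# landscape between the singleton and planted-scale partitions is not
# monotone), letting nodes resettle by greedy sweeps between merges, and
# keep the best state seen along the path.
agglomerate <- function(sg, cfg) {
  st <- stats_from_b(sg, seq_len(sg$n))
  dl <- dl_from_stats(sg$n, st)
  best <- st
  best_dl <- dl
  while (st$B > 1) {
    B <- st$B
    n_pairs <- B * (B - 1) / 2
    cand <- if (n_pairs <= cfg$agglom_cand) {
      which(upper.tri(matrix(0, B, B)), arr.ind = TRUE)
    } else {
      r <- sample.int(B, cfg$agglom_cand, replace = TRUE)
      s <- sample.int(B - 1, cfg$agglom_cand, replace = TRUE)
      s <- ifelse(s >= r, s + 1L, s)
      unique(cbind(pmin(r, s), pmax(r, s)))
    }
    m_dl <- Inf
    m_st <- NULL
    for (k in seq_len(nrow(cand))) {
      st2 <- merge_stats(st, cand[k, 1], cand[k, 2])
      d2 <- dl_from_stats(sg$n, st2)
      if (d2 < m_dl) {
        m_dl <- d2
        m_st <- st2
      }
    }
    st <- m_st
    dl <- m_dl
    if (st$B <= max(20, ceiling(sqrt(sg$n)))) {
      # nodes resettle between merges; no new blocks here or the merge
      # ladder would never descend
      repeat {
        sw <- greedy_sweep(sg, st, dl, allow_new = FALSE)
        improved <- sw$dl < dl - 1e-12
        st <- sw$st
        dl <- sw$dl
        if (!improved) break
      }
    }
    if (dl < best_dl) {
      best_dl <- dl
      best <- st
    }
  }
  list(st = best, dl = best_dl)
}

merge_labels <- function(b, r, s) {
  lo <- min(r, s); hi <- max(r, s)
  b[b == hi] <- lo
  compact_labels(b)
}

as_block_state <- function(sg, st, dl) {
  lambda <- matrix(NA_real_, st$B, st$B)
  pos <- st$e > 0
  lambda[pos] <- st$e[pos] / st$w[pos]
  structure(list(b = st$b, B = st$B, n_r = st$n_r, e_rs = st$e,
                 w_rs = st$w, weight_params = lambda, dl = dl,
                 node_names = sg$names),
            class = "block_state")
}

#' @export
print.block_state <- function(x, ...) {
  cat(sprintf("<block_state> %d nodes in %d blocks, description length %.3f nats\n",
              length(x$b), x$B, x$dl))
  invisible(x)
}

#' Infer a block partition by annealed description-length minimisation
#'
#' Initialises by greedy agglomerative merges from one block per node, then
#' runs Metropolis simulated annealing over single-node moves and merge/split
#' moves with the inverse temperature ramping from `beta_start` to
#' `beta_end`. The search terminates when `wait` proposals pass without a new
#' record-low description length and the record state is returned. The
#' trivial one-block partition is always evaluated as a candidate, so the
#' result is never worse than it.
#'
#' @param graph an `importance_graph` with positive edge weights.
#' @param config an [anneal_config()].
#' @return A `block_state`: partition `b`, block count `B`, block edge counts
#'   `e_rs`, summed weights `w_rs`, exponential rate estimates
#'   `weight_params`, and the description length `dl`.
#' @export
fit_blocks <- function(graph, config = anneal_config()) {
  sg <- sbm_graph(graph)
  best <- NULL
  for (rs in seq_len(config$restarts)) {
    cand <- fit_blocks_once(sg, config, child_seed(config$seed, rs))
    if (is.null(best) || cand$dl < best$dl - 1e-12) best <- cand
  }
  best
}

fit_blocks_once <- function(sg, config, seed) {
  N <- sg$n
  with_seed(seed, {
    init <- agglomerate(sg, config)
    st <- init$st
    dl <- init$dl
    triv <- stats_from_b(sg, rep(1L, N))
    triv_dl <- dl_from_stats(N, triv)
    if (triv_dl < dl) {
      st <- triv
      dl <- triv_dl
    }
    record_st <- st
    record_dl <- dl
    since <- 0L
    t <- 0L
    ratio <- if (config$beta_start > 0) config$beta_end / config$beta_start else 1
    while (since < config$wait) {
      t <- t + 1L
      beta <- config$beta_start * ratio^(min(t, config$n_anneal) / config$n_anneal)
      if (N > 1 && stats::runif(1) < config$p_single) {
        i <- sample.int(N, 1)
        r <- st$b[i]
        nbr <- c(sg$dst[sg$out_of[[i]]], sg$src[sg$in_of[[i]]])
        open_new <- st$n_r[r] > 1L && stats::runif(1) < 1 / (st$B + 1)
        s <- if (open_new) {
          st$B + 1L
        } else if (length(nbr) && stats::runif(1) < 0.8) {
          # neighbour-informed proposal: adopt the block of a random neighbour
          st$b[nbr[sample.int(length(nbr), 1)]]
        } else if (st$B > 1) {
          cand <- sample.int(st$B - 1, 1)
          if (cand >= r) cand + 1L else cand
        } else {
          NA_integer_
        }
        if (is.na(s) || s == r) { since <- since + 1L; next }
        st2 <- move_single_stats(sg, st, i, s)
      } else if (st$B > 1 && stats::runif(1) < 0.5) {
        pr <- sample.int(st$B, 2)
        st2 <- stats_from_b(sg, merge_labels(st$b, pr[1], pr[2]))
      } else {
        big <- which(st$n_r >= 2)
        if (!length(big)) { since <- since + 1L; next }
        blk <- big[sample.int(length(big), 1)]
        members <- which(st$b == blk)
        take <- sample(members, max(1, floor(length(members) / 2)))
        b2 <- st$b
        b2[take] <- st$B + 1L
        st2 <- stats_from_b(sg, compact_labels(b2))
      }
      dl2 <- dl_from_stats(N, st2)
      delta <- dl2 - dl
      if (delta < 0 || stats::runif(1) < exp(-beta * delta)) {
        st <- st2
        dl <- dl2
      }
      if (dl < record_dl - 1e-12) {
        record_dl <- dl
        record_st <- st
        since <- 0L
      } else {
        since <- since + 1L
      }
    }
    # final polish: greedy sweeps on the record until no move improves
    repeat {
      sw <- greedy_sweep(sg, record_st, record_dl)
      if (sw$dl >= record_dl - 1e-12) break
      record_st <- sw$st
      record_dl <- sw$dl
    }
    as_block_state(sg, record_st, record_dl)
  })
}

# Block multigraph of a fitted level: nodes = blocks, one edge per occupied
# block pair with multiplicity e_rs and weight = summed weight.
block_multigraph <- function(state) {
  pos <- which(state$e_rs > 0, arr.ind = TRUE)
  nodes <- data.frame(name = paste0("B", seq_len(state$B)),
                      stringsAsFactors = FALSE)
  edges <- if (nrow(pos)) {
    data.frame(from = paste0("B", pos[, 1]), to = paste0("B", pos[, 2]),
               weight = state$w_rs[pos], mult = state$e_rs[pos],
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), weight = numeric(),
               mult = numeric())
  }
  importance_graph(nodes, edges)
}

#' Fit the two-level nested block model
#'
#' Level 0 partitions the feature graph; level 1 partitions the level-0 block
#' multigraph (nodes = blocks, edge multiplicities = `e_rs`, weights = summed
#' weights). All centrality contrasts downstream read the level-1 communities.
#'
#' @inheritParams fit_blocks
#' @return A `nested_state` with `level0`, `level1`, the joint `dl`, and
#'   `l1_of_node` — each feature's level-1 community.
#' @export
fit_nested <- function(graph, config = anneal_config()) {
  level0 <- fit_blocks(graph, config)
  cfg1 <- config
  cfg1$seed <- child_seed(config$seed, 2)
  level1 <- fit_blocks(block_multigraph(level0), cfg1)
  structure(list(level0 = level0, level1 = level1,
                 dl = level0$dl + level1$dl,
                 l1_of_node = level1$b[level0$b]),
            class = "nested_state")
}

#' @export
print.nested_state <- function(x, ...) {
  cat(sprintf("<nested_state> L0: %d blocks, L1: %d blocks, joint DL %.3f nats\n",
              x$level0$B, x$level1$B, x$dl))
  invisible(x)
}

#' Enumerate all partitions of n items
#'
#' Restricted-growth-string enumeration (Bell(n) partitions); the brute-force
#' oracle behind small-graph optimality checks.
#'
#' @param n number of items (keep small; Bell(8) = 4140).
#' @return Integer matrix, one partition per row.
#' @export
enumerate_partitions <- function(n) {
  stopifnot(n >= 1, n <= 10)
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      recurse(c(prefix, lab), max(maxlab, lab))
    }
  }
  recurse(1L, 1L)
  do.call(rbind, out)
}

#' Exhaustive minimum-description-length partition
#'
#' Evaluates every partition of the graph's nodes and returns the global
#' minimiser — independent of the annealed search path.
#'
#' @param graph an `importance_graph` with at most 10 nodes.
#' @return List with the optimal `b` and its `dl`.
#' @export
brute_force_min_dl <- function(graph) {
  sg <- sbm_graph(graph)
  parts <- enumerate_partitions(sg$n)
  dls <- vapply(seq_len(nrow(parts)), function(k) {
    b <- parts[k, ]
    dl_from_stats(sg$n, stats_from_b(sg, b))
  }, numeric(1))
  best <- which.min(dls)
  list(b = parts[best, ], dl = dls[best])
}

#' Write the nested partition and fit report
#'
#' @param nested a `nested_state`.
#' @param graph the fitted `importance_graph`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
write_partition <- function(nested, graph, csv_path = NULL, json_path = NULL) {
  df <- data.frame(node = graph$nodes$name,
                   l0_block = nested$level0$b,
                   l1_block = nested$l1_of_node)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      dl_level0 = nested$level0$dl, dl_level1 = nested$level1$dl,
      dl_joint = nested$dl, B_level0 = nested$level0$B,
      B_level1 = nested$level1$B), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
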