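#' Imputation configuration
#'
#' Defaults follow the full-scale protocol: predictive mean matching inside
#' chained equations, 50 independent imputation chains of 50 sweeps each, and
#' 5 donor candidates per missing cell. The pipeline's desk-scale default
#' (see [pheno_config()]) uses fewer chains/sweeps; the imputed-table
#' stability across chains is what matters, not the exact count.
#'
#' @param n_imputations number of independent chains.
#' @param n_iterations sweeps over incomplete columns per chain.
#' @param pmm_donors donor candidates for predictive mean matching.
#' @param seed integer seed.
#' @export
imputation_config <- function(n_imputations = 50, n_iterations = 50,
                              pmm_donors = 5, seed = 1) {
  stopifnot(n_imputations >= 1, n_iterations >= 1, pmm_donors >= 1)
  structure(list(n_imputations = n_imputations, n_iterations = n_iterations,
                 pmm_donors = pmm_donors, seed = seed),
            class = "imputation_config")
}

#' Remove rows then columns exceeding a missingness threshold
#'
#' Two-pass rule: patients whose missing fraction strictly exceeds
#' `row_thresh` are dropped first; feature columns are then re-assessed on the
#' surviving rows and dropped when their missing fraction strictly exceeds
#' `col_thresh`. The removal report is attached as attribute `"report"`.
#'
#' @param table a `cohort_table`.
#' @param row_thresh,col_thresh fractions in (0, 1]; default 0.4 each.
#' @return The filtered `cohort_table`.
#' @export
filter_missingness <- function(table, row_thresh = 0.4, col_thresh = 0.4) {
  stopifnot(inherits(table, "cohort_table"),
            row_thresh > 0, row_thresh <= 1, col_thresh > 0, col_thresh <= 1)
  m <- table$missing_mask
  row_frac <- rowMeans(m)
  keep_rows <- row_frac <= row_thresh
  col_frac <- colMeans(m[keep_rows, , drop = FALSE])
  keep_cols <- col_frac <= col_thresh
  if (!any(keep_rows) || !any(keep_cols)) {
    stop_config("missingness filters removed every row or column")
  }
  out <- new_cohort_table(
    table$values[keep_rows, keep_cols, drop = FALSE],
    table$missing_mask[keep_rows, keep_cols, drop = FALSE],
    table$schema[keep_cols, , drop = FALSE],
    table$ground_truth[keep_cols]
  )
  attr(out, "report") <- list(
    rows_removed = which(!keep_rows),
    cols_removed = colnames(table$values)[!keep_cols]
  )
  out
}

# One chained-equation sweep (all chains share this routine).
# Regression design uses all other columns at their current filled values;
# binary columns use logistic regression, everything else linear on the codes.
pmm_sweep <- function(filled, mask, schema, donors) {
  for (j in which(colSums(mask) > 0)) {
    obs <- !mask[, j]
    X <- filled[, -j, drop = FALSE]
    y <- filled[, j]
    is_bin <- schema$value_kind[j] == "binary"
    Xd <- cbind(1, X)
    pred <- tryCatch({
      if (is_bin) {
        fit <- suppressWarnings(
          stats::glm.fit(Xd[obs, , drop = FALSE], y[obs],
                         family = stats::binomial()))
        as.numeric(stats::plogis(Xd %*% fit$coefficients))
      } else {
        fit <- stats::lm.fit(Xd[obs, , drop = FALSE], y[obs])
        as.numeric(Xd %*% fit$coefficients)
      }
    }, error = function(e) rep(mean(y[obs]), nrow(Xd)))
    pred[is.na(pred)] <- mean(y[obs])
    obs_idx <- which(obs)
    for (i in which(mask[, j])) {
      d <- abs(pred[obs_idx] - pred[i])
      k <- min(donors, length(obs_idx))
      cand <- obs_idx[order(d)[seq_len(k)]]
      donor <- cand[sample.int(length(cand), 1)]
      filled[i, j] <- y[donor]
    }
  }
  filled
}

#' Chained-equation imputation with predictive mean matching
#'
#' Iterates over incomplete columns, regressing each on all other columns
#' (logistic for binary features, linear on integer codes otherwise) and
#' filling each missing cell with the observed value of one of the
#' `pmm_donors` donors closest in predicted mean — so imputed values always
#' lie in the observed support of their column and observed cells are never
#' altered. `n_imputations` independent chains are run and pooled into one
#' locked table: cell-wise mean for continuous columns, modal value for
#' binary/ordinal columns.
#'
#' @param table a `cohort_table` surviving the 40% filters.
#' @param config an [imputation_config()].
#' @return A complete `cohort_table` with an `"imputation"` attribute listing
#'   imputed positions and the per-chain agreement summary.
#' @export
mice_pmm_impute <- function(table, config = imputation_config()) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "imputation_config"))
  mask <- table$missing_mask
  if (!any(mask)) return(table)
  empty_cols <- colnames(mask)[colSums(!mask) == 0]
  if (length(empty_cols)) {
    stop_config("column(s) with no observed values: %s",
                paste(empty_cols, collapse = ", "))
  }
  sch <- table$schema
  vals <- table$values
  n_chain <- config$n_imputations
  chains <- vector("list", n_chain)
  for (c_i in seq_len(n_chain)) {
    chains[[c_i]] <- with_seed(child_seed(config$seed, c_i), {
      filled <- vals
      # initialise missing cells by sampling the column's observed values
      for (j in which(colSums(mask) > 0)) {
        obs_vals <- vals[!mask[, j], j]
        filled[mask[, j], j] <- sample(obs_vals, sum(mask[, j]), replace = TRUE)
      }
      for (it in seq_len(config$n_iterations)) {
        filled <- pmm_sweep(filled, mask, sch, config$pmm_donors)
      }
      filled
    })
  }
  pooled <- vals
  modal <- function(x) {
    tb <- table(x)
    as.numeric(names(tb)[which.max(tb)])
  }
  for (j in which(colSums(mask) > 0)) {
    draws <- sapply(chains, function(ch) ch[mask[, j], j])
    draws <- matrix(draws, nrow = sum(mask[, j]))
    pooled[mask[, j], j] <- if (sch$value_kind[j] == "continuous") {
      rowMeans(draws)
    } else {
      apply(draws, 1, modal)
    }
  }
  out <- new_cohort_table(pooled,
                          matrix(FALSE, nrow(pooled), ncol(pooled),
                                 dimnames = dimnames(pooled)),
                          sch, table$ground_truth)
  attr(out, "imputation") <- list(mask = mask, n_chains = n_chain)
  out
}

#' Winsorise and min-max normalise, fitted on training rows only
#'
#' Each ordinal/continuous column is clamped at its `[lo_pct, hi_pct]`
#' percentiles (linear-interpolation percentiles) and then scaled to `[0, 1]`.
#' Binary columns are untouched. All parameters (clamp bounds, min, max) are
#' estimated on `train_ids` only and applied unchanged to the remaining rows,
#' so no test-set information leaks into the transform.
#'
#' @param table a complete `cohort_table`.
#' @param lo_pct,hi_pct clamp percentiles (default 0.1 and 99.9).
#' @param train_ids row indices used to fit the transform; `NULL` = all rows.
#' @return The transformed table with a `"clamp_bounds"` attribute.
#' @export
clamp_and_normalise <- function(table, lo_pct = 0.1, hi_pct = 99.9,
                                train_ids = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  if (any(table$missing_mask)) stop_config("table must be complete (impute first)")
  vals <- table$values
  if (is.null(train_ids)) train_ids <- seq_len(nrow(vals))
  sch <- table$schema
  bounds <- list()
  for (j in seq_len(ncol(vals))) {
    if (sch$value_kind[j] == "binary") next
    tr <- vals[train_ids, j]
    qs <- stats::quantile(tr, probs = c(lo_pct, hi_pct) / 100, type = 7,
                          names = FALSE)
    x <- pmin(pmax(vals[, j], qs[1]), qs[2])
    rng <- qs[2] - qs[1]
    if (rng == 0) {
      warning(sprintf("constant column '%s' scaled to zeros", sch$name[j]),
              call. = FALSE)
      vals[, j] <- 0
    } else {
      vals[, j] <- (x - qs[1]) / rng
    }
    bounds[[sch$name[j]]] <- c(lo = qs[1], hi = qs[2])
  }
  out <- new_cohort_table(vals, table$missing_mask, sch, table$ground_truth)
  attr(out, "clamp_bounds") <- bounds
  out
}

#' Fixed 80:20 train/test split
#'
#' Uniform random partition without stratification. The test rows are frozen:
#' every tuning decision downstream sees only `train_ids`.
#'
#' @param table a `cohort_table` (or anything with rows).
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return A list of class `split_index` with `train_ids` and `test_ids`.
#' @export
make_split <- function(table, test_fraction = 0.2, seed = 1) {
  n <- if (inherits(table, "cohort_table")) nrow(table$values) else nrow(table)
  stopifnot(n >= 10)
  n_test <- round(test_fraction * n)
  test_ids <- with_seed(seed, sort(sample.int(n, n_test)))
  structure(list(train_ids = setdiff(seq_len(n), test_ids),
                 test_ids = test_ids),
            class = "split_index")
}

#' Exclude modelling targets with extreme class imbalance
#'
#' A categorical (binary or ordinal-as-class) feature is excluded as a
#' modelling target when the ratio of its largest to smallest class count on
#' the training rows exceeds `ratio` (default 20:1). Gated features remain
#' available as predictors.
#'
#' @param table a `cohort_table`.
#' @param split a `split_index`; counts use training rows only.
#' @param ratio maximum tolerated majority:minority ratio.
#' @param level_cap ordinal features with more levels than this are treated
#'   as regression targets and never gated.
#' @return Character vector of excluded target names.
#' @export
gate_imbalanced_targets <- function(table, split, ratio = 20, level_cap = 7) {
  stopifnot(inherits(table, "cohort_table"), inherits(split, "split_index"))
  sch <- table$schema
  out <- character()
  for (j in seq_len(nrow(sch))) {
    if (!is_classification_kind(sch[j, ], level_cap)) next
    y <- table$values[split$train_ids, j]
    y <- y[!is.na(y)]
    counts <- table(y)
    if (length(counts) < 2 || max(counts) / min(counts) > ratio) {
      out <- c(out, sch$name[j])
    }
  }
  out
}

is_classification_kind <- function(schema_row, level_cap = 7) {
  schema_row$value_kind == "binary" ||
    (schema_row$value_kind == "ordinal" && schema_row$ordinal_levels <= level_cap)
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances class counts by interpolating new minority cases: each synthetic
#' row is `p + u * (q - p)` where `p` is a minority row, `q` one of its `k`
#' nearest minority neighbours (Euclidean), and `u ~ Uniform(0, 1)`. Original
#' rows are preserved verbatim and every class is brought up to the majority
#' count.
#'
#' @param X numeric predictor matrix.
#' @param y class label vector, `length(y) == nrow(X)`.
#' @param k_neighbors neighbour count (reduced with a warning when a minority
#'   class is too small).
#' @param seed integer seed.
#' @return A list with the augmented `X`, `y`, and `n_synthetic`.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  counts <- table(y)
  n_max <- max(counts)
  new_X <- list()
  new_y <- list()
  with_seed(seed, {
    for (cls in names(counts)) {
      need <- n_max - counts[[cls]]
      if (need == 0) next
      idx <- which(y == cls)
      if (length(idx) < 2) {
        stop_config("class '%s' has fewer than 2 members; cannot oversample", cls)
      }
      k <- k_neighbors
      if (length(idx) <= k) {
        k <- length(idx) - 1
        warning(sprintf("class '%s': reducing k to %d (only %d members)",
                        cls, k, length(idx)), call. = FALSE)
      }
      P <- X[idx, , drop = FALSE]
      D <- as.matrix(stats::dist(P))
      diag(D) <- Inf
      nn <- do.call(rbind, lapply(seq_len(nrow(D)),
                                  function(r) order(D[r, ])[seq_len(k)]))
      syn <- matrix(NA_real_, need, ncol(X))
      picks <- sample.int(length(idx), need, replace = TRUE)
      for (s in seq_len(need)) {
        p_i <- picks[s]
        q_i <- nn[p_i, sample.int(k, 1)]
        u <- stats::runif(1)
        syn[s, ] <- P[p_i, ] + u * (P[q_i, ] - P[p_i, ])
      }
      new_X[[cls]] <- syn
      new_y[[cls]] <- rep(cls, need)
    }
  })
  if (length(new_X)) {
    Xs <- do.call(rbind, new_X)
    colnames(Xs) <- colnames(X)
    X_out <- rbind(X, Xs)
    y_out <- c(as.character(y), unlist(new_y, use.names = FALSE))
    if (is.numeric(y)) y_out <- as.numeric(y_out)
  } else {
    X_out <- X
    y_out <- y
  }
  list(X = X_out, y = y_out, n_synthetic = nrow(X_out) - nrow(X))
}
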