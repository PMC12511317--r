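make_masked_table <- function(values, mask) {
  values[mask] <- NA_real_
  tab <- manual_table(values)
  tab$missing_mask <- mask
  tab$values <- values
  tab
}

test_that("missingness filter removes rows first, then columns, strictly above threshold", {
  v <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m <- matrix(FALSE, 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m[1, 1:3] <- TRUE  # 3/4 = 0.75 missing
  out <- filter_missingness(make_masked_table(v, m), 0.4, 0.4)
  expect_equal(dim(out$values), c(4, 4))
  expect_equal(attr(out, "report")$rows_removed, 1L)

  complete <- manual_table(matrix(rnorm(20), 5, 4,
                                  dimnames = list(NULL, paste0("g", 1:4))))
  expect_equal(filter_missingness(complete)$values, complete$values)

  # 10x6 toy: column 1 half missing (survives row removal still > 40%),
  # row 10 half missing -> 9 rows x 5 columns survive
  v <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  m <- matrix(FALSE, 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  m[1:5, 1] <- TRUE
  m[10, 2:4] <- TRUE  # 3/6 = 0.5 of row 10
  out <- filter_missingness(make_masked_table(v, m), 0.4, 0.4)
  expect_equal(dim(out$values), c(9, 5))
  expect_equal(attr(out, "report")$cols_removed, "f1")
})

test_that("PMM imputation preserves observed cells and stays in observed support", {
  cfg <- generator_config(n_patients = 250, missing_rate = 0.15, seed = 31)
  tab <- generate_cohort(cfg)
  imp <- mice_pmm_impute(tab, imputation_config(n_imputations = 3,
                                                n_iterations = 4, seed = 1))
  expect_false(anyNA(imp$values))
  mask <- tab$missing_mask
  expect_identical(imp$values[!mask], tab$values[!mask])
  # modal/mean pooling: categorical imputed values lie in the observed support
  for (j in which(tab$schema$value_kind != "continuous")) {
    obs <- unique(tab$values[!mask[, j], j])
    expect_true(all(imp$values[mask[, j], j] %in% obs))
  }
  # continuous pooled values lie within the observed range (mean of donors)
  for (j in which(tab$schema$value_kind == "continuous")) {
    obs <- tab$values[!mask[, j], j]
    expect_true(all(imp$values[mask[, j], j] >= min(obs) &
                      imp$values[mask[, j], j] <= max(obs)))
  }
})

test_that("a complete table passes through imputation unchanged", {
  tab <- generate_cohort(generator_config(n_patients = 60, missing_rate = 0,
                                          seed = 2))
  expect_identical(mice_pmm_impute(tab), tab)
})

test_that("PMM with an exactly collinear predictor recovers the matching donor value", {
  # a duplicate predictor value guarantees a donor whose predicted mean
  # matches the missing cell's exactly
  x <- c(1, 2, 3, 3, 4, 5, 6, 7)
  v <- cbind(y = 2 * x, x = x)
  v[3, "y"] <- NA
  tab <- manual_table(v)
  tab$missing_mask[3, 1] <- TRUE
  imp <- mice_pmm_impute(tab, imputation_config(n_imputations = 1,
                                                n_iterations = 2,
                                                pmm_donors = 1, seed = 4))
  expect_equal(unname(imp$values[3, "y"]), 6)
})

test_that("PMM beats column-mean imputation on a correlated MAR cohort", {
  cfg <- generator_config(n_patients = 400, missing_rate = 0.15, seed = 33)
  truth <- generate_cohort(generator_config(n_patients = 400, missing_rate = 0,
                                            seed = 33))
  tab <- generate_cohort(cfg)
  mask <- tab$missing_mask
  imp <- mice_pmm_impute(tab, imputation_config(n_imputations = 3,
                                                n_iterations = 4, seed = 9))
  colmean <- tab$values
  for (j in seq_len(ncol(colmean))) {
    colmean[mask[, j], j] <- mean(tab$values[!mask[, j], j])
  }
  mad_pmm <- mean(abs(imp$values[mask] - truth$values[mask]))
  mad_mean <- mean(abs(colmean[mask] - truth$values[mask]))
  expect_lt(mad_pmm, mad_mean)
})

test_that("imputed-cell column means are stable across independent seeds", {
  cfg <- generator_config(n_patients = 250, missing_rate = 0.15, seed = 35)
  tab <- generate_cohort(cfg)
  mask <- tab$missing_mask
  imp1 <- mice_pmm_impute(tab, imputation_config(3, 4, seed = 100))
  imp2 <- mice_pmm_impute(tab, imputation_config(3, 4, seed = 200))
  for (j in which(colSums(mask) > 20)) {
    a <- imp1$values[mask[, j], j]
    b <- imp2$values[mask[, j], j]
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 2 * se + 1e-8)
  }
})

test_that("clamping winsorises at interpolated percentiles and scales to [0,1]", {
  # 999 zeros and one extreme value: the outlier is clamped
  v <- cbind(a = c(rep(0, 999), 1000), b = seq(0, 1, length.out = 1000))
  tab <- manual_table(v)
  out <- clamp_and_normalise(tab)
  expect_equal(max(out$values[, "a"]), 1)  # after min-max on clamped scale
  b_lo <- attr(out, "clamp_bounds")$a
  expect_lt(b_lo["hi"], 1000)
  # already-[0,1] column with full range: essentially unchanged
  expect_equal(out$values[, "b"], unname(v[, "b"]), tolerance = 0.01)

  # integers 1..1000: linear-interpolation percentile bounds
  v <- cbind(x = as.numeric(1:1000), y = rnorm(1000))
  out <- clamp_and_normalise(manual_table(v))
  bounds <- attr(out, "clamp_bounds")$x
  expect_equal(unname(bounds["lo"]), 1.999, tolerance = 1e-9)
  expect_equal(unname(bounds["hi"]), 999.001, tolerance = 1e-9)
  expect_equal(range(out$values[, "x"]), c(0, 1))
})

test_that("binary columns pass through clamping untouched", {
  v <- cbind(b = rep(c(0, 1), 50), c = rnorm(100))
  tab <- manual_table(v, kinds = c("binary", "continuous"))
  out <- clamp_and_normalise(tab)
  expect_identical(out$values[, "b"], v[, "b"])
})

test_that("normalisation is fitted on training rows only (leakage guard)", {
  set.seed(8)
  v <- cbind(x = rnorm(100), y = rnorm(100))
  tab <- manual_table(v)
  tr <- 1:80
  out1 <- clamp_and_normalise(tab, train_ids = tr)
  # permute the test rows: train-row outputs must not move
  tab2 <- tab
  tab2$values[81:100, ] <- tab$values[sample(81:100), ]
  out2 <- clamp_and_normalise(tab2, train_ids = tr)
  expect_identical(out1$values[tr, ], out2$values[tr, ])
})

test_that("80:20 split gives the documented sizes and is deterministic", {
  big <- manual_table(matrix(rnorm(1175 * 2), 1175, 2,
                             dimnames = list(NULL, c("a", "b"))))
  sp <- make_split(big, 0.2, seed = 3)
  expect_length(sp$train_ids, 940)
  expect_length(sp$test_ids, 235)
  expect_setequal(c(sp$train_ids, sp$test_ids), 1:1175)
  small <- manual_table(matrix(rnorm(20), 10, 2,
                               dimnames = list(NULL, c("a", "b"))))
  expect_length(make_split(small, 0.2, seed = 1)$test_ids, 2)
  expect_identical(make_split(big, 0.2, seed = 3), sp)
})

test_that("imbalance gate applies the max:min class-count rule on training rows", {
  mk <- function(counts, labels = seq_along(counts) - 1) {
    y <- rep(labels, counts)
    v <- cbind(t = as.numeric(y), x = rnorm(length(y)))
    manual_table(v, kinds = c("binary", "continuous"))
  }
  sp_all <- function(tab) structure(list(train_ids = seq_len(nrow(tab$values)),
                                         test_ids = integer()),
                                    class = "split_index")
  t1 <- mk(c(950, 50))          # 19:1 retained
  expect_length(gate_imbalanced_targets(t1, sp_all(t1)), 0)
  t2 <- mk(c(1160, 15))         # 77:1 excluded
  expect_equal(gate_imbalanced_targets(t2, sp_all(t2)), "t")
  t3 <- mk(c(800, 150, 10))     # 80:1 on extreme classes
  t3$schema$value_kind[1] <- "ordinal"
  t3$schema$ordinal_levels[1] <- 3L
  expect_equal(gate_imbalanced_targets(t3, sp_all(t3)), "t")
})

test_that("SMOTE balances classes with convex synthetic rows and preserves originals", {
  set.seed(10)
  X <- matrix(rnorm(100), 50, 2)
  y <- rep(c(0, 1), each = 25)
  out <- smote_oversample(X, y, k_neighbors = 3, seed = 1)
  expect_identical(out$X, X)  # already balanced
  expect_equal(out$n_synthetic, 0)

  X <- rbind(matrix(rnorm(80, 5), 40, 2), matrix(rnorm(20), 10, 2))
  y <- rep(c(0, 1), c(40, 10))
  out <- smote_oversample(X, y, k_neighbors = 3, seed = 2)
  expect_equal(as.integer(table(out$y)), c(40L, 40L))
  expect_equal(nrow(out$X), 80)
  expect_identical(out$X[1:50, ], X)
  # synthetic rows lie in the minority bounding box (convex combinations)
  syn <- out$X[51:80, ]
  mino <- X[41:50, ]
  expect_true(all(syn[, 1] >= min(mino[, 1]) & syn[, 1] <= max(mino[, 1])))
  expect_true(all(syn[, 2] >= min(mino[, 2]) & syn[, 2] <= max(mino[, 2])))

  # two-point minority: synthetic point on the segment x = y
  X <- rbind(matrix(rnorm(10, 10), 5, 2), c(0, 0), c(1, 1))
  y <- c(rep(0, 5), 1, 1)
  out <- smote_oversample(X, y, k_neighbors = 1, seed = 3)
  syn <- out$X[-(1:7), , drop = FALSE]
  expect_equal(syn[, 1], syn[, 2])
  expect_true(all(syn >= 0 & syn <= 1))

  expect_error(smote_oversample(X, c(rep(0, 6), 1), k_neighbors = 1),
               "fewer than 2")
  expect_warning(smote_oversample(X, y, k_neighbors = 5, seed = 1),
                 "reducing k")
})
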