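#' Hyperparameter grid for gradient-boosted models
#'
#' Six tuned axes: learning rate, boosting rounds, tree depth, row
#' subsampling, minimum split gain, and minimum child weight. Models are
#' scored by 5-fold cross-validated negative log loss (classifiers) or RMSE
#' (regressors). The `desk` preset (4 combinations) keeps a full suite
#' tractable on one CPU; the `full` preset has the full protocol cardinality
#' (5 x 6 x 4 x 3 x 3 x 3 = 3240 combinations, 16,200 fits per target at
#' 5 folds) and is intended for bookkeeping and full-scale runs.
#'
#' @param learning_rate,n_estimators,max_depth,subsample,gamma,min_child_weight
#'   numeric vectors of candidate values.
#' @param n_folds cross-validation folds (default 5).
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(learning_rate = c(0.1, 0.3),
                        n_estimators = c(50, 150),
                        max_depth = 3,
                        subsample = 1,
                        gamma = 0,
                        min_child_weight = 1,
                        n_folds = 5) {
  axes <- list(learning_rate = learning_rate, n_estimators = n_estimators,
               max_depth = max_depth, subsample = subsample, gamma = gamma,
               min_child_weight = min_child_weight)
  if (any(lengths(axes) == 0)) stop_config("all grid axes must be non-empty")
  structure(c(axes, list(n_folds = n_folds)), class = "grid_config")
}

#' @rdname grid_config
#' @export
grid_config_desk <- function() grid_config()

#' @rdname grid_config
#' @export
grid_config_full <- function() {
  grid_config(
    learning_rate = c(0.01, 0.05, 0.1, 0.2, 0.3),
    n_estimators = c(50, 100, 200, 300, 500, 800),
    max_depth = c(2, 3, 4, 6),
    subsample = c(0.6, 0.8, 1),
    gamma = c(0, 0.1, 1),
    min_child_weight = c(1, 3, 5)
  )
}

#' Fit-count bookkeeping for a grid search
#'
#' Number of individual model fits: folds x grid cardinality x targets.
#'
#' @param grid a `grid_config`.
#' @param n_targets number of modelled targets (default 1).
#' @return Integer-valued count.
#' @export
grid_fit_count <- function(grid, n_targets = 1) {
  axes <- grid[setdiff(names(grid), "n_folds")]
  grid$n_folds * prod(lengths(axes)) * n_targets
}

grid_combos <- function(grid) {
  expand.grid(grid[setdiff(names(grid), "n_folds")],
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Build the target suite: one spec per feature
#'
#' Every feature becomes a modelling target. Binary and ordinal features with
#' at most `level_cap` levels are classification tasks; other ordinal and all
#' continuous features are regression tasks. A target's excluded predictors
#' are all features sharing its relatedness group, plus any features matching
#' a `name_patterns` regex that the target itself matches (the
#' regular-expression leakage rule). Targets named in `gated` are flagged and
#' not fitted but remain nodes (and predictors) downstream.
#'
#' @param table a `cohort_table`.
#' @param gated character vector from [gate_imbalanced_targets()].
#' @param level_cap ordinal-as-class level cap (default 7).
#' @param name_patterns character vector of regexes; for each regex matching
#'   the target name, all other matching features are excluded as predictors.
#' @return List of `target_spec` lists (`name`, `task`, `excluded_predictors`,
#'   `gated`).
#' @export
build_target_suite <- function(table, gated = character(), level_cap = 7,
                               name_patterns = character()) {
  sch <- table$schema
  lapply(seq_len(nrow(sch)), function(j) {
    row <- sch[j, ]
    excl <- sch$name[sch$relatedness_group == row$relatedness_group]
    for (pat in name_patterns) {
      if (grepl(pat, row$name)) excl <- union(excl, sch$name[grepl(pat, sch$name)])
    }
    structure(list(
      name = row$name,
      task = if (is_classification_kind(row, level_cap)) "classification" else "regression",
      excluded_predictors = setdiff(excl, row$name),
      gated = row$name %in% gated
    ), class = "target_spec")
  })
}

xgb_params <- function(combo, objective, seed, extra = list()) {
  c(list(objective = objective,
         eta = combo$learning_rate,
         max_depth = combo$max_depth,
         subsample = combo$subsample,
         gamma = combo$gamma,
         min_child_weight = combo$min_child_weight,
         nthread = 1, seed = seed, verbosity = 0),
    extra)
}

#' Fit one cross-prediction target
#'
#' Trains a gradient-boosted tree model for one target on all eligible
#' predictors: exhaustive grid search with 5-fold cross-validation inside the
#' training partition (negative log loss for classifiers, RMSE for
#' regressors), minority oversampling applied once to the training partition
#' before cross-validation, refit of the selected model on the full
#' (oversampled) training set, and a single evaluation on the frozen test
#' rows. Regression targets are z-scored by training mean/SD so errors are
#' comparable across targets. Feature importance is the model's split-count
#' (frequency) vector normalised to sum 1 over predictors; per-patient
#' additive attributions (SHAP values) and the base value are computed on the
#' test rows and satisfy local accuracy: base value + row sum = raw model
#' output.
#'
#' @param table a preprocessed complete `cohort_table`.
#' @param split a `split_index`.
#' @param spec a `target_spec` (not gated).
#' @param grid a `grid_config`.
#' @param seed integer seed.
#' @param smote apply minority oversampling to classification training data.
#' @param smote_k neighbour count for SMOTE.
#' @return A `fit_result` list, or `NULL` (with a message) when the training
#'   target is degenerate.
#' @export
fit_target <- function(table, split, spec, grid, seed = 1,
                       smote = TRUE, smote_k = 5) {
  stopifnot(inherits(spec, "target_spec"))
  if (spec$gated) stop_config("target '%s' is gated; not fitted", spec$name)
  vals <- table$values
  predictors <- setdiff(colnames(vals), c(spec$name, spec$excluded_predictors))
  X <- vals[, predictors, drop = FALSE]
  y <- vals[, spec$name]
  tr <- split$train_ids
  te <- split$test_ids
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]

  is_cls <- spec$task == "classification"
  if (is_cls) {
    classes <- sort(unique(y))
    if (length(unique(ytr)) < 2) {
      message(sprintf("target '%s': single training class; skipped", spec$name))
      return(NULL)
    }
    label_tr <- match(ytr, classes) - 1
    if (smote && length(unique(table(label_tr))) > 1) {
      sm <- smote_oversample(Xtr, label_tr, k_neighbors = smote_k,
                             seed = child_seed(seed, 101))
      Xtr <- sm$X
      label_tr <- as.numeric(sm$y)
    }
    nclass <- length(classes)
    objective <- if (nclass == 2) "binary:logistic" else "multi:softprob"
    extra <- if (nclass > 2) list(num_class = nclass) else list()
    ytr_fit <- label_tr
    mu <- sd_tr <- NULL
  } else {
    mu <- mean(ytr)
    sd_tr <- stats::sd(ytr)
    if (sd_tr == 0) {
      message(sprintf("target '%s': constant on training rows; skipped", spec$name))
      return(NULL)
    }
    ytr_fit <- (ytr - mu) / sd_tr
    objective <- "reg:squarederror"
    extra <- list()
    nclass <- NULL
  }

  combos <- grid_combos(grid)
  n_tr <- nrow(Xtr)
  folds <- with_seed(child_seed(seed, 102),
                     sample(rep_len(seq_len(grid$n_folds), n_tr)))
  cv_loss <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    combo <- combos[ci, ]
    params <- xgb_params(combo, objective, seed, extra)
    fold_loss <- vapply(seq_len(grid$n_folds), function(fk) {
      in_f <- folds != fk
      dtr <- xgboost::xgb.DMatrix(Xtr[in_f, , drop = FALSE],
                                  label = ytr_fit[in_f])
      bst <- xgboost::xgb.train(params = params, data = dtr,
                                nrounds = combo$n_estimators)
      ph <- predict(bst, Xtr[!in_f, , drop = FALSE])
      if (is_cls) {
        if (!is.null(nclass) && nclass > 2) ph <- matrix(ph, ncol = nclass,
                                                         byrow = TRUE)
        mlogloss(ytr_fit[!in_f], ph)
      } else {
        sqrt(mean((ytr_fit[!in_f] - ph)^2))
      }
    }, numeric(1))
    cv_loss[ci] <- mean(fold_loss)
  }
  best_i <- which.min(cv_loss)
  best <- combos[best_i, ]

  dtrain <- xgboost::xgb.DMatrix(Xtr, label = ytr_fit)
  model <- xgboost::xgb.train(params = xgb_params(best, objective, seed, extra),
                              data = dtrain, nrounds = best$n_estimators)

  # ---- training artefacts are complete; test rows touched only below ----
  imp_tab <- xgboost::xgb.importance(model = model)
  imp <- stats::setNames(numeric(ncol(vals)), colnames(vals))
  if (!is.null(imp_tab) && nrow(imp_tab)) {
    imp[imp_tab$Feature] <- imp_tab$Frequency
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)

  Xte <- X[te, , drop = FALSE]
  yte <- y[te]
  contrib <- predict(model, Xte, predcontrib = TRUE)
  if (length(dim(contrib)) == 3) {
    base_value <- contrib[1, , dim(contrib)[3]]
    attribution <- contrib[, , -dim(contrib)[3], drop = FALSE]
  } else {
    base_value <- contrib[1, ncol(contrib)]
    attribution <- contrib[, -ncol(contrib), drop = FALSE]
  }

  ph <- predict(model, Xte)
  if (is_cls) {
    if (nclass > 2) {
      prob <- matrix(ph, ncol = nclass, byrow = TRUE)
    } else {
      prob <- cbind(1 - ph, ph)
    }
    pred_cls <- classes[max.col(prob, ties.method = "first")]
    cm <- confusion_matrix(yte, pred_cls, levels = classes)
    metrics <- c(balanced_accuracy = balanced_accuracy(cm), macro_prf(cm),
                 auroc = auroc_macro(yte, prob, classes))
  } else {
    yte_z <- (yte - mu) / sd_tr
    err <- yte_z - ph
    metrics <- c(mae = mean(abs(err)), mse = mean(err^2),
                 rmse = sqrt(mean(err^2)),
                 r2 = 1 - sum(err^2) / sum((yte_z - mean(yte_z))^2))
  }

  structure(list(
    target = spec,
    best_params = as.list(best),
    cv_score = if (is_cls) -cv_loss[best_i] else cv_loss[best_i],
    test_metrics = as.list(metrics),
    importance = imp,
    attribution = attribution,
    base_value = base_value,
    model = model,
    classes = if (is_cls) classes else NULL,
    train_moments = if (!is_cls) c(mean = mu, sd = sd_tr) else NULL
  ), class = "fit_result")
}

#' Run the full cross-prediction suite
#'
#' Fits every non-gated target spec and assembles the suite report: the
#' per-target metric table (sorted by test performance within domain), the
#' per-target status, and the feature-occurrence tally — for each predictor,
#' the number of fitted models in which it ranks in the top `top_k`
#' importances.
#'
#' @inheritParams fit_target
#' @param specs list of `target_spec` from [build_target_suite()].
#' @param top_k tally depth for the occurrence table (default 5).
#' @return List of class `suite_result`: `results` (named list of
#'   `fit_result`), `report` (data frame), `occurrence` (named count vector).
#' @export
run_suite <- function(table, split, specs, grid, seed = 1, smote = TRUE,
                      top_k = 5) {
  results <- list()
  rows <- list()
  for (spec in specs) {
    if (spec$gated) {
      rows[[spec$name]] <- data.frame(
        target = spec$name, domain = table$schema$domain[table$schema$name == spec$name],
        task = spec$task, status = "excluded", performance = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch(
      fit_target(table, split, spec, grid,
                 seed = child_seed(seed, match(spec$name, table$schema$name)),
                 smote = smote),
      error = function(e) {
        message(sprintf("target '%s' failed: %s", spec$name, conditionMessage(e)))
        NULL
      })
    status <- if (is.null(res)) "skipped" else "fitted"
    perf <- if (is.null(res)) NA_real_ else {
      if (spec$task == "classification") res$test_metrics$balanced_accuracy
      else res$test_metrics$r2
    }
    rows[[spec$name]] <- data.frame(
      target = spec$name, domain = table$schema$domain[table$schema$name == spec$name],
      task = spec$task, status = status, performance = perf,
      stringsAsFactors = FALSE)
    if (!is.null(res)) results[[spec$name]] <- res
  }
  report <- do.call(rbind, rows)
  report <- report[order(report$domain, -xtfrm(report$performance)), ]
  rownames(report) <- NULL

  occurrence <- stats::setNames(numeric(ncol(table$values)), colnames(table$values))
  for (res in results) {
    imp <- res$importance[res$importance > 0]
    top <- names(sort(imp, decreasing = TRUE))[seq_len(min(top_k, length(imp)))]
    occurrence[top] <- occurrence[top] + 1
  }
  structure(list(results = results, report = report, occurrence = occurrence,
                 top_k = top_k, grid = grid,
                 fits_per_target = grid_fit_count(grid)),
            class = "suite_result")
}
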