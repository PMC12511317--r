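#' Feature schema for synthetic questionnaire cohorts
#'
#' Builds the per-feature metadata table used by the cohort generator and all
#' downstream stages. Each feature has a measurement kind (binary, ordinal or
#' continuous), a questionnaire domain, and a relatedness group: features that
#' trivially determine one another (e.g. use of a treatment and its reported
#' effectiveness) share a group so that cross-prediction can exclude them from
#' each other's predictor sets.
#'
#' @param name character vector of unique feature names.
#' @param domain one of `pheno_domains()` per feature.
#' @param value_kind `"binary"`, `"ordinal"` or `"continuous"` per feature.
#' @param ordinal_levels integer number of levels (>= 2) for ordinal features;
#'   ignored (NA) otherwise.
#' @param relatedness_group character key; defaults to the feature's own name
#'   (i.e. no group-mates).
#' @return A `data.frame` of class `feature_schema`.
#' @export
feature_schema <- function(name, domain, value_kind,
                           ordinal_levels = NA_integer_,
                           relatedness_group = name) {
  if (anyDuplicated(name)) stop_config("feature names must be unique")
  domain <- match.arg(domain, pheno_domains(), several.ok = TRUE)
  value_kind <- match.arg(value_kind, c("binary", "ordinal", "continuous"),
                          several.ok = TRUE)
  sch <- data.frame(
    name = name,
    domain = rep_len(domain, length(name)),
    value_kind = rep_len(value_kind, length(name)),
    ordinal_levels = as.integer(rep_len(ordinal_levels, length(name))),
    relatedness_group = rep_len(relatedness_group, length(name)),
    stringsAsFactors = FALSE
  )
  bad <- sch$value_kind == "ordinal" &
    (is.na(sch$ordinal_levels) | sch$ordinal_levels < 2)
  if (any(bad)) {
    stop_config("ordinal features need ordinal_levels >= 2: %s",
                paste(sch$name[bad], collapse = ", "))
  }
  sch$ordinal_levels[sch$value_kind != "ordinal"] <- NA_integer_
  class(sch) <- c("feature_schema", "data.frame")
  sch
}

#' @rdname feature_schema
#' @export
pheno_domains <- function() {
  c("demographic", "nosology", "pain", "bowel_habit",
    "treatment", "life_impact", "healthcare", "covid")
}

#' Default 40-feature questionnaire schema
#'
#' A desk-scale stand-in for a functional-bowel-disorder questionnaire table:
#' 8 domains x 5 features with a mix of binary, 5/7-level ordinal and
#' continuous measurements. Treatment use/effectiveness pairs share a
#' relatedness group. Two deliberately rare binary features
#' (`hospital_admission`, `covid_test_positive`) exercise the class-imbalance
#' gate downstream.
#'
#' @return A `feature_schema` with 40 rows.
#' @export
default_schema <- function() {
  rows <- list(
    # demographic
    c("age",                  "demographic", "continuous", NA, "age"),
    c("sex",                  "demographic", "binary",     NA, "sex"),
    c("employment_status",    "demographic", "binary",     NA, "employment_status"),
    c("ethnicity_minority",   "demographic", "binary",     NA, "ethnicity_minority"),
    c("education_level",      "demographic", "ordinal",     5, "education_level"),
    # nosology
    c("ibs_diagnosis",        "nosology", "binary",     NA, "ibs_diagnosis"),
    c("functional_constipation", "nosology", "binary",  NA, "functional_constipation"),
    c("functional_diarrhoea", "nosology", "binary",     NA, "functional_diarrhoea"),
    c("evacuatory_difficulty","nosology", "binary",     NA, "evacuatory_difficulty"),
    c("symptom_duration_years","nosology", "continuous",NA, "symptom_duration_years"),
    # pain
    c("abdominal_pain",       "pain", "binary",     NA, "abdominal_pain"),
    c("pain_severity",        "pain", "continuous", NA, "pain_severity"),
    c("pain_frequency",       "pain", "ordinal",     5, "pain_frequency"),
    c("pain_bowel_related",   "pain", "binary",     NA, "pain_bowel_related"),
    c("pain_six_months",      "pain", "binary",     NA, "pain_six_months"),
    # bowel habit
    c("stool_type",           "bowel_habit", "ordinal", 7, "stool_type"),
    c("bowel_frequency",      "bowel_habit", "ordinal", 5, "bowel_frequency"),
    c("straining",            "bowel_habit", "ordinal", 5, "straining"),
    c("incomplete_evacuation","bowel_habit", "binary", NA, "incomplete_evacuation"),
    c("urgency",              "bowel_habit", "binary", NA, "urgency"),
    # treatment (use/effect pairs share a relatedness group)
    c("laxative_use",         "treatment", "binary",  NA, "laxative"),
    c("laxative_effect",      "treatment", "ordinal",  5, "laxative"),
    c("irrigation_use",       "treatment", "binary",  NA, "irrigation"),
    c("irrigation_effect",    "treatment", "ordinal",  5, "irrigation"),
    c("diet_change_effect",   "treatment", "ordinal",  5, "diet_change_effect"),
    # life impact
    c("daily_activity_impact","life_impact", "ordinal",   5, "daily_activity_impact"),
    c("work_productivity_loss","life_impact","continuous",NA, "work_productivity_loss"),
    c("anxiety_depression",   "life_impact", "ordinal",   5, "anxiety_depression"),
    c("mobility_impact",      "life_impact", "ordinal",   5, "mobility_impact"),
    c("health_rating",        "life_impact", "continuous",NA, "health_rating"),
    # healthcare
    c("gp_visits",            "healthcare", "ordinal",  5, "gp_visits"),
    c("consultant_visits",    "healthcare", "ordinal",  5, "consultant_visits"),
    c("nurse_visits",         "healthcare", "binary",  NA, "nurse_visits"),
    c("dietician_visits",     "healthcare", "binary",  NA, "dietician_visits"),
    c("hospital_admission",   "healthcare", "binary",  NA, "hospital_admission"),
    # covid
    c("covid_infection",      "covid", "binary",  NA, "covid_infection"),
    c("covid_healthcare_access","covid","ordinal", 5, "covid_healthcare_access"),
    c("covid_symptom_change", "covid", "ordinal",  5, "covid_symptom_change"),
    c("covid_mental_impact",  "covid", "ordinal",  5, "covid_mental_impact"),
    c("covid_test_positive",  "covid", "binary",  NA, "covid_test_positive")
  )
  m <- do.call(rbind, rows)
  feature_schema(
    name = m[, 1], domain = m[, 2], value_kind = m[, 3],
    ordinal_levels = suppressWarnings(as.integer(m[, 4])),
    relatedness_group = m[, 5]
  )
}

#' Generator configuration for synthetic cohorts
#'
#' The generator draws patient-level latent factors, maps them to features
#' through a loading matrix, adds Gaussian noise, and discretises binary and
#' ordinal features by quantile cut-points so that rank dependence is
#' preserved. Defaults emulate the study conditions the package targets:
#' 1000 patients, 40 features over 8 domains driven by 4 cross-domain latent
#' factors, 15% missing-at-random cells driven by age, and two rare binary
#' features past the 20:1 imbalance gate.
#'
#' @param n_patients number of rows to simulate.
#' @param schema a [feature_schema()].
#' @param n_latent number of latent factors.
#' @param loading_matrix `n_latent x nrow(schema)` matrix of standardised
#'   effect sizes; `NULL` uses the default cross-domain assignment.
#' @param noise_sd per-feature residual standard deviation (recycled).
#' @param missing_rate fraction of maskable cells set missing (0 disables).
#' @param mar_driver feature whose observed value modulates missingness; it is
#'   itself never masked.
#' @param mar_slope logistic slope of masking probability in the standardised
#'   driver.
#' @param imbalance_targets named numeric vector: binary features to generate
#'   at the given minority fraction instead of 0.5. The default applies the
#'   rare-event fractions to whichever of the two default rare flags the
#'   schema actually contains.
#' @param seed integer seed; generation is deterministic given the config.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000,
                             schema = default_schema(),
                             n_latent = 4,
                             loading_matrix = NULL,
                             noise_sd = 0.6,
                             missing_rate = 0.15,
                             mar_driver = "age",
                             mar_slope = 1,
                             imbalance_targets = default_imbalance_targets(schema),
                             seed = 7) {
  if (is.null(loading_matrix)) {
    loading_matrix <- default_loadings(schema, n_latent)
  }
  loading_matrix <- as.matrix(loading_matrix)
  if (!all(dim(loading_matrix) == c(n_latent, nrow(schema)))) {
    stop_config("loading_matrix must be %d x %d (n_latent x n_features), got %d x %d",
                n_latent, nrow(schema), nrow(loading_matrix), ncol(loading_matrix))
  }
  if (missing_rate < 0 || missing_rate >= 0.4) {
    stop_config("missing_rate must be in [0, 0.4) so generated cohorts survive the 40%% filters")
  }
  if (missing_rate > 0 && !mar_driver %in% schema$name) {
    stop_config("mar_driver '%s' is not in the schema", mar_driver)
  }
  if (length(imbalance_targets) &&
      !all(names(imbalance_targets) %in% schema$name)) {
    stop_config("imbalance_targets name features absent from the schema")
  }
  structure(list(
    n_patients = n_patients, schema = schema, n_latent = n_latent,
    loading_matrix = loading_matrix,
    noise_sd = rep_len(noise_sd, nrow(schema)),
    missing_rate = missing_rate, mar_driver = mar_driver,
    mar_slope = mar_slope,
    imbalance_targets = imbalance_targets, seed = seed
  ), class = "generator_config")
}

default_imbalance_targets <- function(schema) {
  rare <- c(hospital_admission = 0.03, covid_test_positive = 0.02)
  rare[names(rare) %in% schema$name]
}

# Default cross-domain loading assignment: factor 1 = disease severity
# (nosology + pain), factor 2 = bowel habit + treatment response, factor 3 =
# life impact + healthcare burden, factor 4 = covid disruption. A handful of
# demographic/noise features load on nothing and act as null targets.
default_loadings <- function(schema, n_latent = 4) {
  stopifnot(n_latent >= 4)
  L <- matrix(0, n_latent, nrow(schema), dimnames = list(NULL, schema$name))
  fac <- c(
    nosology = 1, pain = 1,
    bowel_habit = 2, treatment = 2,
    life_impact = 3, healthcare = 3,
    covid = 4
  )
  for (j in seq_len(nrow(schema))) {
    d <- schema$domain[j]
    if (d %in% names(fac)) L[fac[[d]], j] <- 0.8
  }
  # pure-noise features: demographics and the rare flags
  L[, c("sex", "ethnicity_minority", "hospital_admission",
        "covid_test_positive")] <- 0
  # age weakly tracks burden so it can drive MAR without being pure noise
  L[3, "age"] <- 0.4
  L
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws `n_latent` standard-normal factors per patient, forms each feature as
#' `loadings . latent + noise`, then discretises binary features at the
#' quantile matching their target prevalence and ordinal features at
#' equal-probability quantile cut-points (integer codes `1..L`). If the config
#' requests missingness, a missing-at-random mask driven by `mar_driver` is
#' injected via [inject_mar_missingness()]. The returned table records, per
#' feature, which latent factor dominates it (`ground_truth`; 0 for pure-noise
#' features), enabling structure-recovery tests downstream.
#'
#' @param config a [generator_config()].
#' @return A `cohort_table`: list with `values` (numeric matrix), `missing_mask`
#'   (logical matrix, `TRUE` = absent), `schema`, and `ground_truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  sch <- config$schema
  n <- config$n_patients
  f <- nrow(sch)
  values <- with_seed(config$seed, {
    Z <- matrix(stats::rnorm(n * config$n_latent), n, config$n_latent)
    raw <- Z %*% config$loading_matrix +
      matrix(stats::rnorm(n * f), n, f) %*% diag(config$noise_sd, f)
    colnames(raw) <- sch$name
    out <- raw
    for (j in seq_len(f)) {
      kind <- sch$value_kind[j]
      if (kind == "binary") {
        minority <- config$imbalance_targets[sch$name[j]]
        prev <- if (length(minority) && !is.na(minority)) minority else 0.5
        cut <- stats::quantile(raw[, j], probs = 1 - prev, type = 7)
        out[, j] <- as.numeric(raw[, j] > cut)
      } else if (kind == "ordinal") {
        L <- sch$ordinal_levels[j]
        cuts <- stats::quantile(raw[, j], probs = seq_len(L - 1) / L, type = 7)
        out[, j] <- as.numeric(findInterval(raw[, j], cuts) + 1L)
      }
    }
    out
  })
  dominant <- apply(abs(config$loading_matrix), 2,
                    function(l) if (all(l == 0)) 0L else which.max(l))
  tab <- new_cohort_table(values,
                          missing_mask = matrix(FALSE, n, f,
                                                dimnames = dimnames(values)),
                          schema = sch,
                          ground_truth = as.integer(dominant))
  if (config$missing_rate > 0) {
    tab <- inject_mar_missingness(tab, rate = config$missing_rate,
                                  driver = config$mar_driver,
                                  seed = child_seed(config$seed, 1),
                                  slope = config$mar_slope)
  }
  tab
}

new_cohort_table <- function(values, missing_mask, schema, ground_truth = NULL) {
  values <- as.matrix(values)
  stopifnot(identical(dim(values), dim(missing_mask)),
            ncol(values) == nrow(schema))
  colnames(values) <- schema$name
  colnames(missing_mask) <- schema$name
  structure(list(values = values, missing_mask = missing_mask,
                 schema = schema, ground_truth = ground_truth),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients x %d features (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$missing_mask)))
  cat("domains:", paste(unique(x$schema$domain), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Inject missing-at-random masking driven by one observed feature
#'
#' Each maskable cell is masked with probability `plogis(a + slope * z)` where
#' `z` is the patient's standardised value of the driver feature; the
#' intercept `a` is calibrated so the expected masked fraction equals `rate`.
#' Masking therefore depends only on an always-observed value, never on the
#' masked value itself — the missing-at-random mechanism. The driver column is
#' never masked.
#'
#' @param table a `cohort_table`.
#' @param rate target overall masked fraction of the maskable cells.
#' @param driver name of the driving feature.
#' @param seed integer seed.
#' @param slope logistic slope in the standardised driver.
#' @return The table with an updated `missing_mask` (masked values set `NA`).
#' @export
inject_mar_missingness <- function(table, rate, driver, seed, slope = 1) {
  stopifnot(inherits(table, "cohort_table"))
  if (!driver %in% colnames(table$values)) {
    stop_config("driver '%s' is not a feature", driver)
  }
  if (any(table$missing_mask[, driver])) {
    stop_config("driver '%s' must be fully observed", driver)
  }
  if (rate == 0) return(table)
  z <- as.numeric(scale(table$values[, driver]))
  if (!all(is.finite(z))) z <- rep(0, length(z))
  # calibrate the intercept so mean masking probability hits `rate`
  a <- stats::uniroot(function(a) mean(stats::plogis(a + slope * z)) - rate,
                      interval = c(-30, 30))$root
  p_row <- stats::plogis(a + slope * z)
  maskable <- setdiff(colnames(table$values), driver)
  mask <- table$missing_mask
  with_seed(seed, {
    for (col in maskable) {
      hit <- stats::runif(nrow(mask)) < p_row
      mask[, col] <- mask[, col] | hit
    }
  })
  out <- table
  out$missing_mask <- mask
  out$values[mask] <- NA_real_
  out
}

#' Write / read a cohort as plain-text CSV with sidecars
#'
#' The values table is written as CSV (header = feature names, empty cell =
#' missing), the schema as `<stem>_schema.csv`, and the ground-truth latent
#' assignment (if present) as `<stem>_truth.csv`.
#'
#' @param table a `cohort_table`.
#' @param stem file path stem (no extension).
#' @return `write_cohort_csv` returns the main file path invisibly;
#'   `read_cohort_csv` returns a `cohort_table`.
#' @export
write_cohort_csv <- function(table, stem) {
  main <- paste0(stem, ".csv")
  df <- as.data.frame(table$values)
  utils::write.csv(df, main, row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(table$schema), paste0(stem, "_schema.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(table$ground_truth)) {
    utils::write.csv(data.frame(name = table$schema$name,
                                latent_factor = table$ground_truth),
                     paste0(stem, "_truth.csv"), row.names = FALSE)
  }
  invisible(main)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(stem) {
  values <- as.matrix(utils::read.csv(paste0(stem, ".csv"), check.names = FALSE))
  sch <- utils::read.csv(paste0(stem, "_schema.csv"), stringsAsFactors = FALSE)
  class(sch) <- c("feature_schema", "data.frame")
  truth_path <- paste0(stem, "_truth.csv")
  truth <- if (file.exists(truth_path)) {
    utils::read.csv(truth_path)$latent_factor
  }
  new_cohort_table(values, missing_mask = is.na(values), schema = sch,
                   ground_truth = truth)
}
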