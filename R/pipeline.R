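#' Pipeline configuration
#'
#' One structured object driving every stage. Desk-scale defaults: the
#' 1000 x 40 synthetic cohort, 5 imputation chains of 10 sweeps, the desk
#' hyperparameter grid, and the standard annealing schedule. Any component
#' can be replaced; `grid = "full"` selects the full-cardinality grid.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param generator a [generator_config()].
#' @param imputation an [imputation_config()].
#' @param test_fraction held-out fraction for [make_split()].
#' @param clamp_pcts clamp percentiles for [clamp_and_normalise()].
#' @param gate_ratio imbalance gate (majority:minority).
#' @param level_cap ordinal-as-class level cap.
#' @param grid `"desk"`, `"full"`, or a [grid_config()].
#' @param top_k occurrence-tally depth.
#' @param min_weight edge threshold for [sparsify()].
#' @param anneal an [anneal_config()].
#' @export
pheno_config <- function(seed = 7,
                         generator = generator_config(seed = seed),
                         imputation = imputation_config(n_imputations = 5,
                                                        n_iterations = 10,
                                                        seed = child_seed(seed, 11)),
                         test_fraction = 0.2,
                         clamp_pcts = c(0.1, 99.9),
                         gate_ratio = 20,
                         level_cap = 7,
                         grid = "desk",
                         top_k = 5,
                         min_weight = 0,
                         anneal = anneal_config(seed = child_seed(seed, 12))) {
  if (is.character(grid)) {
    grid <- switch(match.arg(grid, c("desk", "full")),
                   desk = grid_config_desk(), full = grid_config_full())
  }
  structure(list(seed = seed, generator = generator, imputation = imputation,
                 test_fraction = test_fraction, clamp_pcts = clamp_pcts,
                 gate_ratio = gate_ratio, level_cap = level_cap, grid = grid,
                 top_k = top_k, min_weight = min_weight, anneal = anneal),
            class = "pheno_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror [pheno_config()] arguments; nested
#' `generator`, `imputation`, `anneal` maps override the corresponding
#' component fields.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @export
load_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  seed <- seed %||% y$seed %||% 7
  gen_args <- y$generator %||% list()
  gen_args$seed <- gen_args$seed %||% seed
  imp_args <- y$imputation %||% list()
  ann_args <- y$anneal %||% list()
  cfg_args <- y[intersect(names(y), c("test_fraction", "clamp_pcts",
                                      "gate_ratio", "level_cap", "grid",
                                      "top_k", "min_weight"))]
  cfg_args$seed <- seed
  cfg_args$generator <- do.call(generator_config, gen_args)
  if (length(imp_args)) cfg_args$imputation <- do.call(imputation_config, imp_args)
  if (length(ann_args)) cfg_args$anneal <- do.call(anneal_config, ann_args)
  do.call(pheno_config, cfg_args)
}

pipeline_stages <- function() {
  c("simulate", "preprocess", "correlate", "predict", "graph", "sbm",
    "centrality")
}

#' Run the deep-phenotyping pipeline
#'
#' Executes the stage chain simulate -> preprocess -> correlate -> predict ->
#' graph -> sbm -> centrality, writing each stage's outputs as plain-text
#' files under `outdir`, plus a run manifest (config, seeds, per-file MD5
#' checksums, fit counts). Any suffix of the chain can be run alone: stages
#' not requested are loaded from their cached outputs in `outdir`.
#'
#' @param outdir run directory (created if absent).
#' @param config a [pheno_config()] or path to a YAML file.
#' @param seed optional master seed override.
#' @param stages `"all"` or a contiguous subset of
#'   `simulate, preprocess, correlate, predict, graph, sbm, centrality`.
#' @return Invisibly, a list with the in-memory stage outputs and the
#'   manifest.
#' @export
run_pipeline <- function(outdir, config = pheno_config(), seed = NULL,
                         stages = "all") {
  if (is.character(config)) config <- load_config(config, seed = seed)
  if (!is.null(seed)) {
    config$seed <- seed
    config$generator$seed <- seed
    config$imputation$seed <- child_seed(seed, 11)
    config$anneal$seed <- child_seed(seed, 12)
  }
  if (identical(stages, "all")) stages <- pipeline_stages()
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  state <- list(config = config)
  path <- function(...) file.path(outdir, ...)

  jsonlite::write_json(config_manifest(config), path("config.json"),
                       auto_unbox = TRUE, digits = NA)

  if ("simulate" %in% stages) {
    state$cohort <- generate_cohort(config$generator)
    write_cohort_csv(state$cohort, path("cohort"))
  }

  if ("preprocess" %in% stages) {
    cohort <- state$cohort %||% read_cohort_csv(path("cohort"))
    filtered <- filter_missingness(cohort)
    imputed <- mice_pmm_impute(filtered, config$imputation)
    split <- make_split(imputed, config$test_fraction,
                        seed = child_seed(config$seed, 21))
    locked <- clamp_and_normalise(imputed, config$clamp_pcts[1],
                                  config$clamp_pcts[2],
                                  train_ids = split$train_ids)
    gated <- gate_imbalanced_targets(locked, split, config$gate_ratio,
                                     config$level_cap)
    write_cohort_csv(locked, path("locked"))
    jsonlite::write_json(
      list(train_ids = split$train_ids, test_ids = split$test_ids),
      path("split.json"), digits = NA)
    jsonlite::write_json(list(
      rows_removed = attr(filtered, "report")$rows_removed,
      cols_removed = attr(filtered, "report")$cols_removed,
      gated_targets = gated,
      clamp_bounds = attr(locked, "clamp_bounds"),
      split_seed = child_seed(config$seed, 21),
      n_train = length(split$train_ids), n_test = length(split$test_ids)),
      path("preprocess_report.json"), auto_unbox = TRUE, digits = NA)
    state$locked <- locked
    state$split <- split
    state$gated <- gated
  }

  load_locked <- function() {
    state$locked %||% read_cohort_csv(path("locked"))
  }
  load_split <- function() {
    state$split %||% {
      s <- jsonlite::read_json(path("split.json"), simplifyVector = TRUE)
      structure(list(train_ids = s$train_ids, test_ids = s$test_ids),
                class = "split_index")
    }
  }
  load_gated <- function() {
    state$gated %||%
      unlist(jsonlite::read_json(path("preprocess_report.json"),
                                 simplifyVector = TRUE)$gated_targets) %||%
      character()
  }

  if ("correlate" %in% stages) {
    locked <- load_locked()
    cm <- correlation_map(locked)
    utils::write.csv(cm$r, path("correlation_r.csv"))
    utils::write.csv(cm$q, path("correlation_q.csv"))
    writeLines(cm$dendrogram$newick, path("dendrogram.nwk"))
    state$correlation <- cm
  }

  if ("predict" %in% stages) {
    locked <- load_locked()
    split <- load_split()
    gated <- load_gated()
    specs <- build_target_suite(locked, gated = gated,
                                level_cap = config$level_cap)
    suite <- run_suite(locked, split, specs, config$grid,
                       seed = child_seed(config$seed, 31),
                       top_k = config$top_k)
    utils::write.csv(suite$report, path("suite_report.csv"), row.names = FALSE)
    imp_mat <- sapply(suite$results, function(r) r$importance)
    utils::write.csv(imp_mat, path("importance_matrix.csv"))
    utils::write.csv(data.frame(feature = names(suite$occurrence),
                                top_k_count = as.numeric(suite$occurrence)),
                     path("occurrence.csv"), row.names = FALSE)
    state$suite <- suite
  }

  if ("graph" %in% stages) {
    locked <- load_locked()
    if (is.null(state$suite)) {
      stop_config("stage 'graph' needs the in-memory suite; run with stages including 'predict'")
    }
    g <- assemble_graph(state$suite, locked$schema)
    if (config$min_weight > 0) g <- sparsify(g, config$min_weight)
    write_graphml(g, path("graph.graphml"))
    write_edgelist_csv(g, path("edges.csv"))
    state$graph <- g
  }

  load_graph <- function() state$graph %||% read_graphml(path("graph.graphml"))

  if ("sbm" %in% stages) {
    g <- load_graph()
    nested <- fit_nested(g, config$anneal)
    write_partition(nested, g, csv_path = path("partition.csv"),
                    json_path = path("sbm_report.json"))
    state$nested <- nested
  }

  if ("centrality" %in% stages) {
    g <- load_graph()
    nested <- state$nested
    if (is.null(nested)) {
      part <- utils::read.csv(path("partition.csv"))
      part <- part[match(g$nodes$name, part$node), ]
      nested <- list(l1_of_node = part$l1_block)
    }
    ct <- centrality_table(g, nested)
    utils::write.csv(ct, path("centrality.csv"), row.names = FALSE)
    contrasts <- lapply(c("eigenvector", "hub", "authority"), function(m) {
      res <- tryCatch(block_contrast(ct, m), error = function(e) NULL,
                      warning = function(w) suppressWarnings(block_contrast(ct, m)))
      if (is.null(res)) return(NULL)
      list(metric = m, anova = res$anova, tukey = res$tukey,
           block_summary = res$block_summary, top_blocks = res$top_blocks,
           note = res$note)
    })
    jsonlite::write_json(contrasts, path("contrasts.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    for (m in c("eigenvector", "hub", "authority")) {
      utils::write.csv(block_boxplot_stats(ct, m),
                       path(sprintf("boxplot_%s.csv", m)), row.names = FALSE)
    }
    state$centrality <- ct
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenonet")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(path("config.json"))),
    stages_run = stages,
    fits_per_target = grid_fit_count(config$grid),
    files = as.list(tools::md5sum(list.files(outdir, full.names = TRUE)))
  )
  names(manifest$files) <- basename(names(manifest$files))
  manifest$files$manifest.json <- NULL
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  state$manifest <- manifest
  invisible(state)
}

# Flat, JSON-serialisable view of a config (drives the config hash).
config_manifest <- function(config) {
  list(
    seed = config$seed,
    generator = config$generator[setdiff(names(config$generator),
                                         c("schema", "loading_matrix"))],
    schema_md5 = digest_of(config$generator$schema),
    loadings_md5 = digest_of(config$generator$loading_matrix),
    imputation = unclass(config$imputation),
    test_fraction = config$test_fraction,
    clamp_pcts = config$clamp_pcts,
    gate_ratio = config$gate_ratio,
    level_cap = config$level_cap,
    grid = unclass(config$grid),
    top_k = config$top_k,
    min_weight = config$min_weight,
    anneal = unclass(config$anneal)
  )
}

digest_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(print(obj)), f)
  unname(tools::md5sum(f))
}
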