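#' Assemble the directed feature-importance network
#'
#' Nodes are all features of the table; a directed edge `j -> i` carries the
#' scaled (unit-simplex normalised) importance of predictor `j` in the model
#' for target `i`, so the incoming weights of every fitted target sum to 1.
#' Gated or skipped targets appear as nodes with no incoming edges. Node size
#' summarises each feature's importance in predicting all other targets
#' (sum of outgoing weights).
#'
#' @param results named list of `fit_result` (from [run_suite()]`$results`,
#'   or a `suite_result` directly).
#' @param schema the cohort's `feature_schema` (taken from the suite when a
#'   `suite_result` is given together with `table`).
#' @return A list of class `importance_graph` with `nodes`
#'   (name/domain/node_size data frame) and `edges` (from/to/weight/mult).
#' @export
assemble_graph <- function(results, schema) {
  if (inherits(results, "suite_result")) results <- results$results
  if (length(results) < 2) stop_config("need at least 2 fitted targets")
  targets <- vapply(results, function(r) r$target$name, character(1))
  if (anyDuplicated(targets)) stop_config("duplicate target results")
  edges <- list()
  for (res in results) {
    imp <- res$importance[res$importance > 0]
    imp <- imp[names(imp) != res$target$name]
    if (!length(imp)) next
    excl <- res$target$excluded_predictors
    if (any(names(imp) %in% excl)) {
      stop_config("target '%s' has importance on excluded predictors", res$target$name)
    }
    edges[[res$target$name]] <- data.frame(
      from = names(imp), to = res$target$name, weight = as.numeric(imp),
      mult = 1, stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL
  node_size <- stats::setNames(numeric(nrow(schema)), schema$name)
  outsum <- tapply(edges$weight, edges$from, sum)
  node_size[names(outsum)] <- outsum
  structure(list(
    nodes = data.frame(name = schema$name, domain = schema$domain,
                       node_size = as.numeric(node_size),
                       stringsAsFactors = FALSE),
    edges = edges
  ), class = "importance_graph")
}

#' Construct an importance graph from explicit parts
#'
#' Lower-level constructor used by simulations and tests.
#'
#' @param nodes data frame with at least `name` (and optionally `domain`,
#'   `node_size`), or a character vector of names.
#' @param edges data frame with `from`, `to`, `weight` (optional `mult`).
#' @export
importance_graph <- function(nodes, edges) {
  if (is.character(nodes)) {
    nodes <- data.frame(name = nodes, stringsAsFactors = FALSE)
  }
  if (is.null(nodes$domain)) nodes$domain <- NA_character_
  if (is.null(edges$mult)) edges$mult <- rep(1, nrow(edges))
  stopifnot(all(c(edges$from, edges$to) %in% nodes$name))
  if (is.null(nodes$node_size)) {
    ns <- stats::setNames(numeric(nrow(nodes)), nodes$name)
    if (nrow(edges)) {
      s <- tapply(edges$weight, edges$from, sum)
      ns[names(s)] <- s
    }
    nodes$node_size <- as.numeric(ns)
  }
  structure(list(nodes = nodes, edges = edges), class = "importance_graph")
}

#' @export
print.importance_graph <- function(x, ...) {
  cat(sprintf("<importance_graph> %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Drop edges below a weight threshold
#'
#' Weights are not renormalised (they keep the suite scale) and isolated
#' nodes are retained.
#'
#' @param graph an `importance_graph`.
#' @param min_weight threshold; edges with `weight < min_weight` are dropped.
#' @export
sparsify <- function(graph, min_weight = 0) {
  stopifnot(min_weight >= 0)
  graph$edges <- graph$edges[graph$edges$weight >= min_weight, , drop = FALSE]
  graph
}

#' Convert to igraph / write GraphML and edge-list CSV
#'
#' @param graph an `importance_graph`.
#' @return `as_igraph` returns an igraph object with `domain` and `node_size`
#'   node attributes and a `weight` edge attribute.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges[, c("from", "to", "weight")],
                                directed = TRUE, vertices = graph$nodes)
}

#' @rdname as_igraph
#' @param path output file path.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname as_igraph
#' @export
write_edgelist_csv <- function(graph, path) {
  utils::write.csv(graph$edges[, c("from", "to", "weight")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname as_igraph
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(name = igraph::V(g)$name,
                      domain = igraph::V(g)$domain %||% NA_character_,
                      node_size = igraph::V(g)$node_size %||% 0,
                      stringsAsFactors = FALSE)
  e <- igraph::as_data_frame(g, what = "edges")
  importance_graph(nodes, data.frame(from = e$from, to = e$to,
                                     weight = e$weight, mult = 1,
                                     stringsAsFactors = FALSE))
}

# Dense weight matrix W[i, j] = weight of edge i -> j.
graph_weight_matrix <- function(graph) {
  n <- nrow(graph$nodes)
  W <- matrix(0, n, n, dimnames = list(graph$nodes$name, graph$nodes$name))
  if (nrow(graph$edges)) {
    W[cbind(match(graph$edges$from, graph$nodes$name),
            match(graph$edges$to, graph$nodes$name))] <- graph$edges$weight
  }
  W
}
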