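#' Standardize a metric for cross-method comparison
#'
#' Z-score standardization `(v - mean(v)) / sd_pop(v)` with the population
#' standard deviation (divisor `n`), so two centrality metrics on different
#' scales can be drawn on one axis. The output has mean 0 and population
#' standard deviation 1.
#'
#' @param values Numeric vector, length >= 2.
#' @return Standardized numeric vector (names preserved).
#' @export
standardize_metric <- function(values) {
  if (length(values) < 2) {
    stop("keynodes usage error: need at least 2 values to standardize",
         call. = FALSE)
  }
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) {
    stop("keynodes numerical error: metric is constant; standardization ",
         "undefined", call. = FALSE)
  }
  (values - m) / s
}

#' Ranked per-node results table
#'
#' One row per node, sorted by normalized importance descending (the Zipf
#' ordering), ties broken by node label ascending.
#'
#' @param importance An `importance_result`.
#' @param score A `bridge_score_result` on the same graph/c.
#' @param classification A `node_classification` on the same graph/c.
#' @param graph The [key_graph] (for the degree column).
#' @return A data frame with columns `rank`, `node`, `degree`,
#'   `importance_norm`, `score`, `label`.
#' @export
rank_table <- function(importance, score, classification, graph) {
  stopifnot(identical(importance$labels, score$labels),
            identical(importance$labels, classification$labels))
  df <- data.frame(
    node = importance$labels,
    degree = as.numeric(degrees(graph)),
    importance_norm = as.numeric(importance$normalized),
    score = as.numeric(score$score),
    label = as.character(classification$label),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$importance_norm, df$node), ]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Run the full analysis pipeline
#'
#' load (or take) a graph -> estimate `c` if asked -> importance -> bridge
#' score -> classification -> optional TSV/JSON artifacts. This is the
#' function behind the `analyze` CLI subcommand.
#'
#' @param graph A [key_graph], or a file path (loaded with [load_graph]).
#' @param c Number of communities, or `"auto"` to estimate by eigengap.
#' @param c_max Candidate ceiling used when `c = "auto"` (default 8).
#' @param method `"perturbative"` (default) or `"exact"`.
#' @param importance_multiplier,bridge_multiplier Threshold multipliers.
#' @param format,weighted Passed to [load_graph] when `graph` is a path.
#' @param output Optional TSV path for the ranked table.
#' @param json Optional JSON summary path.
#' @param verbose Print a run log to the console.
#' @return Invisibly, a list with `graph`, `c`, `importance`, `score`,
#'   `classification`, `table`.
#' @export
run_pipeline <- function(graph, c = "auto", c_max = 8L,
                         method = c("perturbative", "exact"),
                         importance_multiplier = 1.0, bridge_multiplier = 1.0,
                         format = NULL, weighted = NULL,
                         output = NULL, json = NULL, verbose = FALSE) {
  method <- match.arg(method)
  if (is.character(graph) && length(graph) == 1 && !inherits(graph, "key_graph")) {
    graph <- load_graph(graph, format = format, weighted = weighted)
  }
  stopifnot(inherits(graph, "key_graph"))
  if (identical(c, "auto")) {
    c <- estimate_num_communities(graph, min(c_max, graph$n - 1L))
    if (verbose) message("estimated c = ", c, " by adjacency eigengap")
  }
  c <- as.integer(c)
  imp <- switch(method,
                perturbative = importance_perturbative(graph, c),
                exact = importance_exact(graph, c))
  sc <- bridge_score(graph, c)
  cl <- classify_nodes(imp, sc, importance_multiplier, bridge_multiplier)
  tab <- rank_table(imp, sc, cl, graph)
  if (verbose) {
    message(sprintf("N = %d, m = %d, c = %d, method = %s", graph$n, graph$m,
                    c, method))
    message(sprintf("%d core, %d bridge above/below the 1/N thresholds",
                    sum(cl$label == "core"), sum(cl$label == "bridge")))
  }
  if (!is.null(output)) {
    utils::write.table(tab, output, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(c = c, N = graph$n, method = method,
           n_core = sum(cl$label == "core"),
           n_bridge = sum(cl$label == "bridge"),
           importance_threshold = cl$importance_threshold,
           bridge_threshold = cl$bridge_threshold),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(graph = graph, c = c, importance = imp, score = sc,
                 classification = cl, table = tab))
}
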