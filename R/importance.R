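#' Node importance to community structure (first-order, spectrum-only)
#'
#' Measures how much each node matters to the community structure as the
#' relative change of the `c` largest adjacency eigenvalues upon its removal,
#' approximated to first order from the leading eigenvectors: removing node
#' `i` shifts eigenvalue `lambda_j` by approximately `lambda_j * x_ji^2`, so
#'
#'   `I_i = (1/c) * sum_{j=1}^{c} x_ji^2`
#'
#' where `x_ji` is the `i`-th component of the `j`-th leading eigenvector.
#' `I_i` lies in `[0, 1]`, and since each eigenvector has unit norm the raw
#' values already sum to 1 across nodes. The normalized index `Ibar_i = I_i /
#' sum_j I_j` is reported alongside; its mean is exactly `1/N`, and on an
#' Erdos-Renyi null model (no community structure) every node sits near
#' `1/N`, which is why `Ibar_i > 1/N` serves as the significance criterion
#' (see [classify_importance]).
#'
#' When position `c` falls inside a degenerate eigenvalue block, the whole
#' block's eigenspace is used with fractional weights (see
#' [top_adjacency_eigenpairs]), so the result is basis-invariant — required
#' for disconnected graphs.
#'
#' @param graph A [key_graph]. Disconnected graphs are allowed (a warning is
#'   given); this is deliberate, as the small-community limitation analysis
#'   uses disconnected community pairs.
#' @param c Number of communities, `1 <= c < N`. See
#'   [estimate_num_communities].
#' @param corrected Use the first-order ratio before the large-N
#'   simplification, `x_ji^2 / (1 - x_ji^2)`, instead of `x_ji^2`. Default
#'   `FALSE`: the plain form is the one whose raw values sum to 1.
#' @return An `importance_result`: list with `c`, `raw`, `normalized` (named
#'   numeric vectors), `method = "perturbative"`, `labels`, `n`.
#' @seealso [importance_exact] for the exact removal computation,
#'   [bridge_score] for separating cores from bridges.
#' @examples
#' g <- generate_weighted_toy()
#' imp <- importance_perturbative(g, c = 2)
#' round(imp$normalized, 3)  # nodes 4 and 9 stand out; node 11 is lowest
#' @export
importance_perturbative <- function(graph, c, corrected = FALSE) {
  c <- .check_c(graph, c)
  sp <- top_adjacency_eigenpairs(graph, c)
  w <- .block_weights(sp, c)
  X2 <- sp$eigenvectors^2
  if (corrected) X2 <- X2 / pmax(1 - X2, .Machine$double.eps)
  raw <- as.numeric(X2 %*% w) / c
  .importance_result(graph, c, raw, "perturbative")
}

#' Node importance to community structure (exact removal)
#'
#' The exact counterpart of [importance_perturbative]: for each node `i` the
#' node is deleted and the `c` largest eigenvalues of the reduced adjacency
#' matrix recomputed, giving
#'
#'   `I_i = (1/c) * sum_{j=1}^{c} (lambda_j - lambda'_j) / lambda_j`
#'
#' Eigenvalues are matched by sorted index; Cauchy interlacing guarantees
#' `lambda'_j <= lambda_j`, so every `I_i` is nonnegative.
#'
#' @inheritParams importance_perturbative
#' @return An `importance_result` with `method = "exact"`.
#' @export
importance_exact <- function(graph, c) {
  c <- .check_c(graph, c)
  if (graph$n < c + 1) {
    stop("keynodes usage error: need at least c + 1 nodes for exact removal",
         call. = FALSE)
  }
  lam <- top_adjacency_eigenpairs(graph, c)$eigenvalues[seq_len(c)]
  if (any(lam <= 1e-12)) {
    stop("keynodes numerical error: a leading eigenvalue is <= 0; the relative ",
         "eigenvalue change is undefined for this graph/c", call. = FALSE)
  }
  W <- graph$weights
  raw <- vapply(seq_len(graph$n), function(i) {
    lam2 <- eigen(W[-i, -i, drop = FALSE], symmetric = TRUE,
                  only.values = TRUE)$values[seq_len(c)]
    mean((lam - lam2) / lam)
  }, 0)
  .importance_result(graph, c, raw, "exact")
}

#' Flag nodes important to community structure
#'
#' Applies the null-model criterion: on an Erdos-Renyi random graph with no
#' community structure the normalized importance of every node is expected to
#' be `1/N`, so nodes with `Ibar_i > multiplier / N` (strict) are flagged as
#' important. Ties at exactly the threshold are excluded.
#'
#' @param result An `importance_result` (or any list with `normalized` and
#'   `labels`).
#' @param multiplier Threshold multiplier (default 1: the plain `1/N` rule).
#' @return Character vector of flagged node labels.
#' @export
classify_importance <- function(result, multiplier = 1.0) {
  v <- result$normalized
  n <- length(v)
  # tie guard: values within one part in 1e9 of the threshold count as ties
  result$labels[v > (multiplier / n) * (1 + 1e-9)]
}

.check_c <- function(graph, c) {
  stopifnot(inherits(graph, "key_graph"))
  c <- as.integer(c)
  if (c < 1 || c >= graph$n) {
    stop("keynodes usage error: c must satisfy 1 <= c < N", call. = FALSE)
  }
  if (max(graph_components(graph)) > 1) {
    warning("graph is disconnected; importance is computed on the degenerate-",
            "block eigenspace and small components may be invisible to it")
  }
  c
}

.importance_result <- function(graph, c, raw, method) {
  if (method == "exact" && any(raw < -1e-12)) {
    stop("keynodes numerical error: negative exact importance (interlacing ",
         "violated numerically)", call. = FALSE)
  }
  raw <- pmax(raw, 0)
  names(raw) <- graph$labels
  structure(
    list(
      c = c,
      raw = raw,
      normalized = raw / sum(raw),
      method = method,
      threshold = 1 / graph$n,
      labels = graph$labels,
      n = graph$n
    ),
    class = "importance_result"
  )
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("importance_result (%s, c = %d, N = %d)\n", x$method, x$c, x$n))
  top <- utils::head(sort(x$normalized, decreasing = TRUE), 5)
  cat("  top nodes:", paste(sprintf("%s=%.4g", names(top), top), collapse = ", "),
      "\n  null threshold 1/N =", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Serialize an importance result
#'
#' Writes a TSV (`node`, `degree`, `importance_raw`, `importance_norm`,
#' `method`, `flagged`) and optionally a JSON summary
#' `{c, N, mean, std, threshold}`.
#'
#' @param result An `importance_result`.
#' @param graph The [key_graph] it was computed on (for degrees).
#' @param path TSV output path.
#' @param json_path Optional JSON summary path.
#' @param multiplier Threshold multiplier for the `flagged` column.
#' @return Invisibly, the data frame written.
#' @export
write_importance <- function(result, graph, path, json_path = NULL,
                             multiplier = 1.0) {
  df <- data.frame(
    node = result$labels,
    degree = as.numeric(degrees(graph)),
    importance_raw = as.numeric(result$raw),
    importance_norm = as.numeric(result$normalized),
    method = result$method,
    flagged = result$normalized > multiplier / result$n,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(c = result$c, N = result$n,
           mean = mean(result$normalized),
           std = stats::sd(result$normalized),
           threshold = multiplier / result$n),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
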