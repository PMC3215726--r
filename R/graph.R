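#' Undirected weighted graph container
#'
#' A `key_graph` holds a symmetric, nonnegative, hollow (zero-diagonal) weight
#' matrix together with node labels. Binary graphs are stored with weights in
#' \{0, 1\}; one code path serves weighted and unweighted networks alike.
#'
#' @param weights Symmetric numeric matrix of edge weights (dense or any
#'   matrix coercible with `as.matrix`). Diagonal must be zero, entries
#'   nonnegative.
#' @param labels Character vector of node labels; defaults to the matrix
#'   dimnames or `"1"..."N"`.
#' @param weighted Logical; if `NULL`, inferred (`TRUE` when any weight is
#'   neither 0 nor 1).
#' @param meta Optional named list of metadata (e.g. planted `community`
#'   assignment from a generator).
#'
#' @return An object of class `key_graph` with fields `weights` (dense
#'   matrix), `labels`, `n`, `m` (edge count), `weighted`, `meta`.
#'
#' @details Symmetry is enforced on construction: asymmetry up to `1e-9`
#'   (absolute, relative to the largest magnitude) is silently symmetrized via
#'   `(W + t(W))/2`; anything larger is an error, so directed input cannot
#'   slip through as undirected.
#'
#' @examples
#' g <- key_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' g$m        # 2 edges
#' degrees(g) # 1 2 1
#' @export
key_graph <- function(weights, labels = NULL, weighted = NULL, meta = list()) {
  W <- as.matrix(weights)
  if (nrow(W) != ncol(W)) {
    stop("keynodes validation error: weight matrix must be square", call. = FALSE)
  }
  storage.mode(W) <- "double"
  n <- nrow(W)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(W))) rownames(W) else as.character(seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels)) {
    stop("keynodes validation error: labels must be unique and match the matrix size",
         call. = FALSE)
  }
  asym <- max(abs(W - t(W)))
  tol <- 1e-9 * max(1, max(abs(W)))
  if (asym > tol) {
    stop(sprintf(
      "keynodes validation error: adjacency is asymmetric (max |W - t(W)| = %g); directed graphs are not supported",
      asym), call. = FALSE)
  }
  W <- (W + t(W)) / 2
  if (any(W < 0)) {
    stop("keynodes validation error: negative edge weight", call. = FALSE)
  }
  if (any(diag(W) != 0)) {
    stop("keynodes validation error: self-loops (nonzero diagonal) are not supported",
         call. = FALSE)
  }
  if (is.null(weighted)) {
    weighted <- any(W != 0 & W != 1)
  }
  dimnames(W) <- list(labels, labels)
  structure(
    list(
      weights  = W,
      labels   = labels,
      n        = n,
      m        = sum(W[upper.tri(W)] > 0),
      weighted = weighted,
      meta     = meta
    ),
    class = "key_graph"
  )
}

#' @export
print.key_graph <- function(x, ...) {
  cat(sprintf("key_graph: %d nodes, %d edges (%s)\n",
              x$n, x$m, if (x$weighted) "weighted" else "binary"))
  if (length(x$meta)) {
    cat("  metadata:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Node degrees (strengths)
#'
#' Row sums of the weight matrix: the degree for binary graphs, the strength
#' for weighted graphs.
#'
#' @param graph A [key_graph].
#' @return Named numeric vector of length `n`.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "key_graph"))
  rowSums(graph$weights)
}

#' Graph Laplacian
#'
#' Returns the unnormalized Laplacian `L = D - W`, where `D` is the diagonal
#' matrix of (weighted) degrees. `L` is symmetric positive semi-definite and
#' every row sums to zero; the multiplicity of its zero eigenvalue equals the
#' number of connected components.
#'
#' @param graph A [key_graph].
#' @return A dense symmetric numeric matrix with the graph's labels as
#'   dimnames.
#' @export
laplacian <- function(graph) {
  stopifnot(inherits(graph, "key_graph"))
  L <- -graph$weights
  diag(L) <- degrees(graph)
  L
}

#' Remove one node from a graph
#'
#' Principal submatrix deletion; used by the exact importance metric.
#'
#' @param graph A [key_graph].
#' @param node Node label or 1-based index.
#' @return A [key_graph] on `n - 1` nodes.
#' @export
remove_node <- function(graph, node) {
  stopifnot(inherits(graph, "key_graph"))
  i <- if (is.character(node)) match(node, graph$labels) else as.integer(node)
  if (is.na(i) || i < 1 || i > graph$n) {
    stop("keynodes usage error: unknown node ", node, call. = FALSE)
  }
  key_graph(graph$weights[-i, -i, drop = FALSE],
            labels = graph$labels[-i],
            weighted = graph$weighted)
}

#' Connected components
#'
#' @param graph A [key_graph].
#' @return Integer vector of component ids (1-based), named by node label.
#' @keywords internal
graph_components <- function(graph) {
  ig <- .as_igraph(graph)
  comp <- igraph::components(ig)$membership
  stats::setNames(as.integer(comp), graph$labels)
}

# key_graph -> igraph, carrying weights and planted metadata as attributes
.as_igraph <- function(graph) {
  mode <- "undirected"
  ig <- igraph::graph_from_adjacency_matrix(graph$weights, mode = mode,
                                            weighted = if (graph$weighted) TRUE else NULL)
  igraph::V(ig)$name <- graph$labels
  if (!is.null(graph$meta$community)) {
    comm <- as.integer(graph$meta$community)
    comm[is.na(comm)] <- 0L            # GML cannot carry NA; 0 = "none"
    igraph::V(ig)$community <- comm
  }
  if (!is.null(graph$meta$role)) {
    igraph::V(ig)$role <- as.character(graph$meta$role)
  }
  ig
}

# igraph -> key_graph
.from_igraph <- function(ig) {
  weighted <- "weight" %in% igraph::edge_attr_names(ig)
  W <- igraph::as_adjacency_matrix(ig, type = "both", sparse = FALSE,
                                   attr = if (weighted) "weight" else NULL)
  labels <- if ("name" %in% igraph::vertex_attr_names(ig)) {
    as.character(igraph::V(ig)$name)
  } else if ("label" %in% igraph::vertex_attr_names(ig)) {
    as.character(igraph::V(ig)$label)
  } else {
    as.character(seq_len(igraph::vcount(ig)))
  }
  meta <- list()
  if ("community" %in% igraph::vertex_attr_names(ig)) {
    comm <- as.integer(igraph::V(ig)$community)
    comm[comm == 0L] <- NA_integer_
    meta$community <- comm
  }
  if ("role" %in% igraph::vertex_attr_names(ig)) {
    meta$role <- as.character(igraph::V(ig)$role)
  }
  key_graph(W, labels = labels, meta = meta)
}
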