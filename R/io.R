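#' Read a graph from a file
#'
#' Supported formats:
#' \describe{
#'   \item{`edgelist`}{Whitespace- or comma-delimited lines `src dst [weight]`;
#'     `#` starts a comment. Duplicate undirected edges with identical weight
#'     collapse to one; conflicting duplicate weights are an error unless
#'     `sum_duplicates = TRUE` (then weights are summed, the collaboration-
#'     network convention).}
#'   \item{`gml`}{Standard GML, via igraph. Vertex attributes `community` and
#'     `role` round-trip as graph metadata.}
#'   \item{`adjacency_csv`}{Dense CSV with a header row of node labels.}
#'   \item{`mtx`}{Matrix Market coordinate format (symmetric), via the Matrix
#'     package. Labels are positional (`"1"..."N"`).}
#' }
#'
#' @param path File path.
#' @param format One of `"edgelist"`, `"gml"`, `"adjacency_csv"`, `"mtx"`.
#'   Default guesses from the file extension.
#' @param weighted Logical or `NULL` (infer). For edge lists, `FALSE` ignores
#'   a third column.
#' @param sum_duplicates Sum the weights of repeated undirected edges instead
#'   of erroring on conflict.
#' @return A [key_graph].
#' @export
load_graph <- function(path, format = NULL, weighted = NULL, sum_duplicates = FALSE) {
  if (!file.exists(path)) {
    stop("keynodes I/O error: no such file: ", path, call. = FALSE)
  }
  format <- format %||% .guess_format(path)
  format <- match.arg(format, c("edgelist", "gml", "adjacency_csv", "mtx"))
  switch(format,
    edgelist = .read_edgelist(path, weighted, sum_duplicates),
    gml = .from_igraph(igraph::read_graph(path, format = "gml")),
    adjacency_csv = .read_adjacency_csv(path),
    mtx = {
      M <- as.matrix(Matrix::readMM(path))
      key_graph(M, weighted = weighted)
    }
  )
}

#' Write a graph to a file
#'
#' The emitted file reloads to an identical graph (same labels and weights;
#' `mtx` keeps weights but replaces labels by position).
#'
#' @param graph A [key_graph].
#' @param path Output file path.
#' @param format One of `"edgelist"`, `"gml"`, `"mtx"` (default from the
#'   extension).
#' @return Invisibly, `path`.
#' @export
save_graph <- function(graph, path, format = NULL) {
  stopifnot(inherits(graph, "key_graph"))
  format <- format %||% .guess_format(path)
  if (!format %in% c("edgelist", "gml", "mtx")) {
    stop("keynodes usage error: unknown output format: ", format, call. = FALSE)
  }
  switch(format,
    edgelist = .write_edgelist(graph, path),
    gml = igraph::write_graph(.as_igraph(graph), path, format = "gml"),
    mtx = Matrix::writeMM(methods::as(Matrix::Matrix(graph$weights, sparse = TRUE),
                                      "generalMatrix"), path)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gml = "gml",
    mtx = "mtx",
    csv = "adjacency_csv",
    "edgelist"
  )
}

.read_edgelist <- function(path, weighted, sum_duplicates) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop("keynodes format error: empty edge list: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "[,[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 2 | nf > 3)) {
    bad <- which(nf < 2 | nf > 3)[1]
    stop(sprintf("keynodes format error: line %d of %s has %d fields (expected 2 or 3)",
                 bad, path, nf[bad]), call. = FALSE)
  }
  src <- vapply(parts, `[`, "", 1)
  dst <- vapply(parts, `[`, "", 2)
  w <- vapply(seq_along(parts), function(i) {
    if (nf[i] == 3 && !isFALSE(weighted)) {
      wi <- suppressWarnings(as.numeric(parts[[i]][3]))
      if (is.na(wi)) {
        stop(sprintf("keynodes format error: line %d of %s: non-numeric weight '%s'",
                     i, path, parts[[i]][3]), call. = FALSE)
      }
      wi
    } else 1
  }, 0)
  if (any(src == dst)) {
    stop("keynodes validation error: self-loop in edge list (line ",
         which(src == dst)[1], ")", call. = FALSE)
  }
  labels <- unique(c(rbind(src, dst)))
  n <- length(labels)
  i <- match(src, labels); j <- match(dst, labels)
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  W <- matrix(0, n, n)
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      ws <- w[key == k]
      if (sum_duplicates) {
        w[key == k] <- c(sum(ws), rep(0, length(ws) - 1))
      } else if (length(unique(ws)) > 1) {
        stop("keynodes validation error: duplicate edge with conflicting weights (",
             k, "); pass sum_duplicates = TRUE to sum them", call. = FALSE)
      } else {
        w[key == k] <- c(ws[1], rep(0, length(ws) - 1))
      }
    }
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]; w <- w[keep]
  }
  W[cbind(lo, hi)] <- w
  W[cbind(hi, lo)] <- w
  key_graph(W, labels = labels, weighted = weighted)
}

.write_edgelist <- function(graph, path) {
  W <- graph$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- if (graph$weighted) {
    sprintf("%s %s %.17g", graph$labels[idx[, 1]], graph$labels[idx[, 2]],
            W[idx])
  } else {
    sprintf("%s %s", graph$labels[idx[, 1]], graph$labels[idx[, 2]])
  }
  writeLines(lines, path)
}

.read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- colnames(df)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) {
    stop("keynodes format error: adjacency CSV is not square: ", path, call. = FALSE)
  }
  if (!is.numeric(M)) {
    stop("keynodes format error: adjacency CSV has non-numeric entries: ", path,
         call. = FALSE)
  }
  key_graph(M, labels = labels)
}
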