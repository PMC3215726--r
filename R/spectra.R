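#' Leading eigenpairs of the adjacency matrix
#'
#' Computes the `k` algebraically largest eigenvalues and orthonormal
#' eigenvectors of the (weighted) adjacency matrix. When a network has `c`
#' strong communities, the `c` largest adjacency eigenvalues separate from the
#' bulk of the spectrum and carry the community structure.
#'
#' Eigenvalues are ordered algebraically descending (not by magnitude): the
#' community modes are the large positive eigenvalues, and magnitude ordering
#' would let large negative (bipartite-like) modes displace them. A warning is
#' emitted if a discarded eigenvalue exceeds the retained ones in magnitude.
#'
#' If the `k`-th eigenvalue is degenerate with the `(k+1)`-th (within `1e-8`),
#' the whole degenerate block is returned and `degenerate_block_end` marks its
#' end; downstream squared-component sums then use the full block so results
#' are basis-invariant (this is what makes disconnected graphs well-defined).
#'
#' @param graph A [key_graph].
#' @param k Number of leading eigenpairs, `1 <= k <= N`.
#' @return A `key_spectrum` list: `eigenvalues` (descending), `eigenvectors`
#'   (N x k', orthonormal columns), `k` (requested), `degenerate_block_end`
#'   (>= k), `kind = "adjacency"`.
#' @export
top_adjacency_eigenpairs <- function(graph, k) {
  stopifnot(inherits(graph, "key_graph"))
  .eigenpairs(graph$weights, k, largest = TRUE, kind = "adjacency")
}

#' Smallest eigenpairs of the graph Laplacian
#'
#' The `k` smallest eigenpairs of `L = D - W`. The smallest eigenvalue is 0
#' (with the constant eigenvector on a connected graph); the second
#' eigenvector is the Fiedler vector. Degenerate blocks are extended as for
#' [top_adjacency_eigenpairs].
#'
#' @param graph A [key_graph].
#' @param k Number of eigenpairs, `1 <= k <= N`.
#' @return A `key_spectrum` list with `eigenvalues` ascending and
#'   `kind = "laplacian"`.
#' @export
bottom_laplacian_eigenpairs <- function(graph, k) {
  stopifnot(inherits(graph, "key_graph"))
  .eigenpairs(laplacian(graph), k, largest = FALSE, kind = "laplacian")
}

#' Estimate the number of communities from the adjacency eigengap
#'
#' The spectrum of the adjacency matrix indicates the number of dominant
#' communities: with `c` strong communities the `c` largest eigenvalues are
#' well separated from the rest, so the estimate is the position of the
#' largest gap `lambda_c - lambda_(c+1)` among the algebraically sorted
#' eigenvalues, for `c` in `1..c_max`.
#'
#' @param graph A [key_graph].
#' @param c_max Largest candidate `c`, at most `N - 1`.
#' @return Integer estimate of `c`. If every gap is below `1e-12` (a fully
#'   degenerate spectrum, e.g. a complete graph cannot be split), returns 1
#'   with a warning.
#' @export
estimate_num_communities <- function(graph, c_max) {
  stopifnot(inherits(graph, "key_graph"))
  c_max <- as.integer(c_max)
  if (c_max < 1 || c_max > graph$n - 1) {
    stop("keynodes usage error: c_max must be in 1..N-1", call. = FALSE)
  }
  sp <- .eigenpairs(graph$weights, c_max + 1L, largest = TRUE,
                    kind = "adjacency", extend_block = FALSE,
                    vectors = FALSE)
  lam <- sp$eigenvalues
  gaps <- lam[seq_len(c_max)] - lam[seq_len(c_max) + 1L]
  if (max(gaps) < 1e-12) {
    warning("all eigengaps below 1e-12; defaulting to c = 1")
    return(1L)
  }
  which.max(gaps)
}

# Shared symmetric eigensolver.
#
# Dense eigen() below .dense_cutoff nodes (or when many pairs are wanted);
# ARPACK via igraph::arpack above, with a deterministic start vector so runs
# are reproducible. Returns eigenvalues sorted descending (largest = TRUE) or
# ascending (largest = FALSE), eigenvectors column-orthonormal.
.dense_cutoff <- 500L

.eigenpairs <- function(M, k, largest, kind, extend_block = TRUE, vectors = TRUE) {
  n <- nrow(M)
  k <- as.integer(k)
  if (k < 1 || k > n) {
    stop("keynodes usage error: k must be in 1..N", call. = FALSE)
  }
  # ask for extra pairs to detect a degenerate block at the boundary
  want <- min(n, k + 1L)
  repeat {
    if (n < .dense_cutoff || want > n %/% 3) {
      e <- eigen(M, symmetric = TRUE)      # descending
      vals <- e$values
      vecs <- e$vectors
      if (!largest) {
        vals <- rev(vals)
        vecs <- vecs[, rev(seq_len(n)), drop = FALSE]
      }
      avail <- n
    } else {
      e <- .arpack_sym(M, want, largest)
      vals <- e$values
      vecs <- e$vectors
      avail <- length(vals)
    }
    blk_end <- k
    if (extend_block) {
      tolb <- 1e-8 * max(1, abs(vals[k]))
      while (blk_end < avail && abs(vals[blk_end + 1L] - vals[k]) <= tolb) {
        blk_end <- blk_end + 1L
      }
    }
    # a block that runs to the end of an iterative solve may extend further:
    # widen the request and redo (the dense path always sees the full spectrum)
    if (blk_end == avail && avail < n) {
      want <- min(n, avail + max(4L, avail))
    } else break
  }
  keep <- seq_len(blk_end)
  if (kind == "adjacency" && largest && avail > blk_end) {
    if (max(abs(vals[(blk_end + 1L):avail])) > abs(vals[1L]) + 1e-10) {
      warning("a discarded eigenvalue exceeds the leading one in magnitude; ",
              "the network is strongly bipartite-like")
    }
  }
  structure(
    list(
      eigenvalues = vals[keep],
      eigenvectors = if (vectors) vecs[, keep, drop = FALSE] else NULL,
      k = k,
      degenerate_block_end = blk_end,
      kind = kind
    ),
    class = "key_spectrum"
  )
}

.arpack_sym <- function(M, nev, largest) {
  n <- nrow(M)
  Ms <- Matrix::Matrix(M, sparse = TRUE)
  f <- function(x, extra = NULL) as.numeric(Ms %*% x)
  start <- sin(seq_len(n))  # fixed, nonzero, not an eigenvector of typical graphs
  opts <- list(n = n, nev = nev, ncv = min(n, max(2L * nev + 1L, 20L)),
               which = if (largest) "LA" else "SA",
               maxiter = 3000, tol = 1e-9, start = start)
  res <- tryCatch(
    igraph::arpack(f, options = opts, sym = TRUE),
    error = function(e) {
      stop("keynodes computational error: ARPACK failed to converge (",
           conditionMessage(e),
           "); retry with a dense decomposition (N < 500 path)", call. = FALSE)
    }
  )
  vals <- res$values
  vecs <- res$vectors
  ord <- order(vals, decreasing = largest)
  list(values = vals[ord], vectors = vecs[, ord, drop = FALSE])
}

#' @export
print.key_spectrum <- function(x, ...) {
  cat(sprintf("key_spectrum (%s): %d eigenpair(s)%s\n", x$kind,
              length(x$eigenvalues),
              if (x$degenerate_block_end > x$k)
                sprintf(" (degenerate block extended to %d)", x$degenerate_block_end)
              else ""))
  print(x$eigenvalues)
  invisible(x)
}

# Per-eigenvector weights implementing the degenerate-block projector rule:
# vectors strictly before the block containing position c get weight 1, the
# block's vectors share the remaining (c - a + 1) units equally. Keeps
# sum_i sum_j w_j x_ji^2 = c and is invariant to the basis chosen inside the
# block.
.block_weights <- function(spectrum, c) {
  vals <- spectrum$eigenvalues
  b <- spectrum$degenerate_block_end
  tolb <- 1e-8 * max(1, abs(vals[c]))
  a <- c
  while (a > 1 && abs(vals[a - 1L] - vals[c]) <= tolb) a <- a - 1L
  w <- rep(0, b)
  if (a > 1) w[seq_len(a - 1L)] <- 1
  w[a:b] <- (c - a + 1) / (b - a + 1)
  w
}
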