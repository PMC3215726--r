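#' Bridgeness score from the bottom Laplacian eigenvectors
#'
#' Distinguishes the two kinds of nodes important to community structure.
#' The RatioCut relaxation places community information in the eigenvectors
#' of the smallest Laplacian eigenvalues; collecting node `i`'s components
#' across the first `c` of them gives its vertex vector, whose squared
#' magnitude
#'
#'   `s_i = (1/c) * sum_{k=1}^{c} u_ki^2`
#'
#' is large for nodes sitting firmly inside one community and near zero for
#' nodes with nearly equal membership in several communities. The score is
#' reported normalized to sum 1; its mean is exactly `1/N`, the expected
#' value on an Erdos-Renyi null model, so `s_i < 1/N` is the bridgeness
#' criterion: such a node straddles communities and its removal makes the
#' community structure clearer, not fuzzier.
#'
#' The trivial constant eigenvector (eigenvalue 0) is included in the sum;
#' degenerate eigenvalue blocks crossing position `c` are handled by the
#' basis-invariant block rule (see [top_adjacency_eigenpairs]).
#'
#' @param graph A [key_graph].
#' @param c Number of communities, `1 <= c < N`.
#' @return A `bridge_score_result`: list with `c`, `score` (named, sums to 1),
#'   `threshold = 1/N`, `labels`, `n`.
#' @examples
#' g <- generate_weighted_toy()
#' round(bridge_score(g, c = 2)$score, 4)  # node 11 scores 0.0455, the rest 0.0955
#' @export
bridge_score <- function(graph, c) {
  stopifnot(inherits(graph, "key_graph"))
  c <- as.integer(c)
  if (c < 1 || c >= graph$n) {
    stop("keynodes usage error: c must satisfy 1 <= c < N", call. = FALSE)
  }
  sp <- bottom_laplacian_eigenpairs(graph, c)
  w <- .block_weights(sp, c)
  raw <- as.numeric((sp$eigenvectors^2) %*% w) / c
  score <- raw / sum(raw)
  names(score) <- graph$labels
  structure(
    list(c = c, score = score, threshold = 1 / graph$n,
         labels = graph$labels, n = graph$n),
    class = "bridge_score_result"
  )
}

#' @export
print.bridge_score_result <- function(x, ...) {
  cat(sprintf("bridge_score_result (c = %d, N = %d)\n", x$c, x$n))
  low <- utils::head(sort(x$score), 5)
  cat("  lowest scores (bridge candidates):",
      paste(sprintf("%s=%.4g", names(low), low), collapse = ", "),
      "\n  null threshold 1/N =", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Partition of a graph's nodes into groups
#'
#' @param assignment Integer vector of group indices in `1..c`, optionally
#'   named by node label.
#' @return A `key_partition`: list with `assignment`, `group_sizes`, `c`.
#' @export
key_partition <- function(assignment) {
  assignment <- stats::setNames(as.integer(assignment), names(assignment))
  groups <- sort(unique(assignment))
  if (!identical(groups, seq_along(groups))) {
    stop("keynodes usage error: group indices must be 1..c with no empty group",
         call. = FALSE)
  }
  structure(
    list(assignment = assignment,
         group_sizes = as.integer(table(assignment)),
         c = length(groups)),
    class = "key_partition"
  )
}

#' RatioCut of a partition
#'
#' `RatioCut(A_1..A_c) = sum_j cut(A_j, complement(A_j)) / |A_j|`, where
#' `cut` is the total weight of edges leaving group `A_j` (each inter-group
#' edge contributes once to each of the two groups it borders). Zero iff
#' there are no inter-group edges. Unlike mincut, the `1/|A_j|` factors
#' penalize splitting off tiny groups.
#'
#' @param graph A [key_graph].
#' @param partition A [key_partition] (or plain integer assignment vector)
#'   covering all nodes.
#' @return Nonnegative scalar.
#' @export
ratiocut <- function(graph, partition) {
  p <- .check_partition(graph, partition)
  W <- graph$weights
  total <- 0
  for (j in seq_len(p$c)) {
    inA <- p$assignment == j
    total <- total + sum(W[inA, !inA, drop = FALSE]) / sum(inA)
  }
  total
}

#' RatioCut via its quadratic/trace encoding
#'
#' Evaluates RatioCut through the spectral-clustering identities rather than
#' by counting cut edges, as a cross-check of the relaxation underlying
#' [bridge_score]. For two groups `A`, `B` the index vector `h` with
#' `h_i = +sqrt(|B|/|A|)` on `A` and `-sqrt(|A|/|B|)` on `B` satisfies
#' `h'Lh = N * RatioCut(A, B)` (with `h` orthogonal to the constant vector
#' and `|h|^2 = N`); the value returned is `h'Lh / N`. For `c` groups the
#' indicator matrix `H` with columns `1_{A_j} / sqrt(|A_j|)` gives
#' `Tr(H'LH) = RatioCut` directly. Both agree with [ratiocut] to rounding.
#'
#' @inheritParams ratiocut
#' @return Nonnegative scalar equal to `ratiocut(graph, partition)`.
#' @export
ratiocut_quadratic <- function(graph, partition) {
  p <- .check_partition(graph, partition)
  L <- laplacian(graph)
  if (p$c == 2) {
    nA <- p$group_sizes[1]; nB <- p$group_sizes[2]
    h <- ifelse(p$assignment == 1, sqrt(nB / nA), -sqrt(nA / nB))
    as.numeric(h %*% L %*% h) / graph$n
  } else {
    H <- vapply(seq_len(p$c), function(j) {
      (p$assignment == j) / sqrt(p$group_sizes[j])
    }, numeric(graph$n))
    sum(diag(t(H) %*% L %*% H))
  }
}

.check_partition <- function(graph, partition) {
  if (!inherits(partition, "key_partition")) partition <- key_partition(partition)
  a <- partition$assignment
  if (!is.null(names(a))) {
    if (!setequal(names(a), graph$labels)) {
      stop("keynodes usage error: partition labels do not cover the graph",
           call. = FALSE)
    }
    partition$assignment <- a[graph$labels]
  } else if (length(a) != graph$n) {
    stop("keynodes usage error: partition length != number of nodes", call. = FALSE)
  }
  partition
}

#' Classify nodes as community cores, bridges, or peripheral
#'
#' Combines the two spectral indices: a node is a **bridge** when its
#' bridgeness score falls below `bridge_multiplier / N` (it has nearly equal
#' membership in several communities); otherwise it is a **core** when its
#' normalized importance exceeds `importance_multiplier / N` (it organizes
#' its community); otherwise **peripheral**. The two criteria are applied
#' independently, score first — a bridge need not pass the importance
#' threshold, since spreading over several communities dilutes its leading-
#' eigenvector mass.
#'
#' The multipliers default to 1 (the plain null-model thresholds). Near the
#' threshold the robust signal is the relative ranking of the scores, not
#' the hard cut; the multipliers let the user move the cut.
#'
#' @param importance An `importance_result` from [importance_perturbative] or
#'   [importance_exact].
#' @param score A `bridge_score_result` from [bridge_score] on the same graph
#'   with the same `c`.
#' @param importance_multiplier,bridge_multiplier Threshold multipliers.
#' @return A `node_classification`: list with `label` (named factor with
#'   levels core/bridge/peripheral), thresholds used, `labels`, `n`.
#' @examples
#' g <- generate_weighted_toy()
#' cl <- classify_nodes(importance_perturbative(g, 2), bridge_score(g, 2))
#' cl$label  # node 11 bridge, nodes 4 and 9 core, the rest peripheral
#' @export
classify_nodes <- function(importance, score,
                           importance_multiplier = 1.0,
                           bridge_multiplier = 1.0) {
  if (importance$n != score$n || !identical(importance$labels, score$labels)) {
    stop("keynodes usage error: importance and score were not computed on the ",
         "same graph", call. = FALSE)
  }
  if (importance$c != score$c) {
    stop("keynodes usage error: importance and score use different c", call. = FALSE)
  }
  n <- importance$n
  # strict comparisons with a 1-part-in-1e9 tie guard: values at exactly the
  # threshold (up to eigensolver jitter) are excluded on both sides
  thr_b <- bridge_multiplier / n
  thr_i <- importance_multiplier / n
  lab <- ifelse(score$score < thr_b * (1 - 1e-9), "bridge",
                ifelse(importance$normalized > thr_i * (1 + 1e-9),
                       "core", "peripheral"))
  lab <- factor(lab, levels = c("core", "bridge", "peripheral"))
  names(lab) <- importance$labels
  structure(
    list(label = lab,
         importance_threshold = importance_multiplier / n,
         bridge_threshold = bridge_multiplier / n,
         labels = importance$labels, n = n, c = importance$c),
    class = "node_classification"
  )
}

#' @export
print.node_classification <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("node_classification (N = %d, c = %d): %d core, %d bridge, %d peripheral\n",
              x$n, x$c, tab["core"], tab["bridge"], tab["peripheral"]))
  for (kind in c("core", "bridge")) {
    who <- names(x$label)[x$label == kind]
    if (length(who)) cat(sprintf("  %s: %s\n", kind, paste(who, collapse = ", ")))
  }
  invisible(x)
}

#' Two-community partition from the Fiedler vector
#'
#' Sign-based assignment from the eigenvector of the second-smallest
#' Laplacian eigenvalue: positive components go to group 1, negative to
#' group 2, each group filled in order of decreasing component magnitude
#' (most positive first into group 1, most negative first into group 2).
#' Components within `zero_tol` of zero indicate near-equal membership in
#' both communities and are reported as dual members (assigned to the group
#' of their signless tie-break, group 1).
#'
#' @param graph A connected [key_graph].
#' @param zero_tol Magnitude below which a component counts as zero.
#' @return List with `partition` (a [key_partition]), `order` (node labels in
#'   assignation priority), `dual` (labels of near-zero nodes), `fiedler`
#'   (the vector itself, named).
#' @export
fiedler_partition <- function(graph, zero_tol = 1e-8) {
  sp <- bottom_laplacian_eigenpairs(graph, 2)
  u2 <- sp$eigenvectors[, 2]
  names(u2) <- graph$labels
  assign <- ifelse(u2 > zero_tol, 1L, ifelse(u2 < -zero_tol, 2L, 1L))
  if (length(unique(assign)) == 1) {
    stop("keynodes numerical error: Fiedler vector has a single sign; the ",
         "graph does not split", call. = FALSE)
  }
  ord <- graph$labels[order(-abs(u2))]
  list(
    partition = key_partition(stats::setNames(assign, graph$labels)),
    order = ord,
    dual = graph$labels[abs(u2) <= zero_tol],
    fiedler = u2
  )
}
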