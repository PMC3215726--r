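# Fixture builders shared across tests. Everything is generated in code.

# Erdos-Renyi graph as a key_graph; weighted draws uniform weights in (0, 2].
random_graph <- function(n, p = 0.4, weighted = FALSE, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  on_ <- runif(sum(up)) < p
  w <- if (weighted) runif(sum(up), 0.1, 2) else 1
  W[up][on_] <- (if (weighted) w[on_] else 1)
  W <- W + t(W)
  key_graph(W, weighted = weighted)
}

# n disjoint cliques of size k each
disjoint_cliques <- function(n_cliques, k) {
  n <- n_cliques * k
  W <- matrix(0, n, n)
  for (b in seq_len(n_cliques)) {
    idx <- ((b - 1) * k + 1):(b * k)
    W[idx, idx] <- 1
  }
  diag(W) <- 0
  key_graph(W, weighted = FALSE)
}

path_graph <- function(n) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  key_graph(W, weighted = FALSE)
}

star_graph <- function(n_leaves) {
  n <- n_leaves + 1
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- 1
  key_graph(W, labels = c("hub", paste0("leaf", seq_len(n_leaves))),
            weighted = FALSE)
}

# two triangles joined by one edge
barbell6 <- function() {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
  diag(W) <- 0
  W[3, 4] <- W[4, 3] <- 1
  key_graph(W, weighted = FALSE)
}

karate_path <- function() {
  system.file("extdata", "karate.edgelist", package = "keynodes")
}

# independent brute-force RatioCut: count cut weight directly from edges
ratiocut_brute <- function(W, assignment) {
  groups <- sort(unique(assignment))
  total <- 0
  for (g in groups) {
    cut <- 0
    for (i in which(assignment == g)) {
      for (j in which(assignment != g)) cut <- cut + W[i, j]
    }
    total <- total + cut / sum(assignment == g)
  }
  total
}
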