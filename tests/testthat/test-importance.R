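test_that("weighted toy reproduces the printed importance values", {
  g <- generate_weighted_toy()
  imp <- importance_perturbative(g, 2)
  v <- imp$normalized
  expect_equal(round(unname(v["4"]), 2), 0.15)
  expect_equal(round(unname(v["9"]), 2), 0.15)
  expect_equal(round(unname(v["11"]), 3), 0.067)
  for (node in c("1", "2", "3", "5", "6", "7", "8", "10")) {
    expect_equal(round(unname(v[node]), 3), 0.079)
  }
})

test_that("perturbative importance equals the dense-eigendecomposition formula", {
  for (seed in 1:5) {
    g <- random_graph(8, 0.5, weighted = seed > 3, seed = seed)
    cc <- 2
    imp <- importance_perturbative(g, cc)
    e <- eigen(g$weights, symmetric = TRUE)   # independent dense oracle
    oracle <- rowSums(e$vectors[, 1:cc]^2) / cc
    expect_equal(unname(imp$raw), oracle, tolerance = 1e-10)
  }
})

test_that("symmetric inputs give uniform importance", {
  g <- disjoint_cliques(2, 5)
  imp <- suppressWarnings(importance_perturbative(g, 2))
  expect_equal(unname(imp$normalized), rep(0.1, 10), tolerance = 1e-10)
})

test_that("exact importance matches star-graph closed forms", {
  g <- star_graph(4)           # lambda_1 = sqrt(4) = 2
  imp <- importance_exact(g, 1)
  expect_equal(unname(imp$raw["hub"]), 1, tolerance = 1e-10)
  expect_equal(unname(imp$raw["leaf1"]), (2 - sqrt(3)) / 2, tolerance = 1e-10)
})

test_that("exact importance is nonnegative and normalized on random graphs", {
  for (seed in 1:5) {
    g <- random_graph(12, 0.5, weighted = seed %% 2 == 0, seed = seed)
    imp <- suppressWarnings(importance_exact(g, 2))
    expect_gte(min(imp$raw), 0)
    expect_equal(sum(imp$normalized), 1, tolerance = 1e-9)
  }
})

test_that("both methods sum to one and have mean exactly 1/N", {
  for (seed in 1:4) {
    g <- random_graph(20, 0.3, seed = seed)
    for (imp in list(suppressWarnings(importance_perturbative(g, 3)),
                     suppressWarnings(importance_exact(g, 3)))) {
      expect_equal(sum(imp$normalized), 1, tolerance = 1e-9)
      expect_equal(mean(imp$normalized), 1 / g$n, tolerance = 1e-12)
      expect_true(all(imp$raw >= 0 & imp$raw <= 1))
    }
  }
})

test_that("perturbative and exact importance agree in rank on GN graphs", {
  for (z_out in c(2, 4)) {
    g <- generate_gn(z_out, seed = 3)
    p <- importance_perturbative(g, 4)$normalized
    e <- importance_exact(g, 4)$normalized
    expect_gte(cor(p, e, method = "spearman"), 0.9)
  }
})

test_that("importance threshold flags strictly above multiplier/N", {
  g <- generate_weighted_toy()
  imp <- importance_perturbative(g, 2)
  expect_setequal(classify_importance(imp), c("4", "9"))
  # exact ties at 1/N are excluded
  fake <- list(normalized = rep(1 / 10, 10), labels = as.character(1:10))
  expect_length(classify_importance(fake), 0)
})

test_that("small disconnected community is invisible to the index", {
  g <- generate_er_pair(q = 50, p = 0.1, seed = 5)
  imp <- suppressWarnings(importance_perturbative(g, 2))
  small <- g$meta$community == 1
  expect_lt(max(imp$normalized[small]), 1 / g$n)
  expect_gt(max(imp$normalized[!small]), 1 / g$n)
})

test_that("degenerate-block handling is basis-invariant", {
  g <- disjoint_cliques(2, 5)
  # c = 1 lands inside the two-fold degenerate leading block; any orthonormal
  # basis of that eigenspace must give the same (uniform) importance
  imp <- suppressWarnings(importance_perturbative(g, 1))
  expect_equal(unname(imp$normalized), rep(0.1, 10), tolerance = 1e-9)
})

test_that("usage errors: c out of range, degenerate eigenvalue for exact", {
  g <- random_graph(6, 0.5, seed = 1)
  expect_error(importance_perturbative(g, 6), "1 <= c < N")
  expect_error(importance_perturbative(g, 0), "1 <= c < N")
  empty <- key_graph(matrix(0, 4, 4))
  expect_error(suppressWarnings(importance_exact(empty, 1)), "eigenvalue")
})
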