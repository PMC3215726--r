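test_that("weighted toy bridge score matches printed values and closed form", {
  g <- generate_weighted_toy()
  s <- bridge_score(g, 2)$score
  expect_equal(unname(s["11"]), (1 / 2) * (1 / 11), tolerance = 1e-10)
  for (node in as.character(1:10)) {
    expect_equal(unname(s[node]), (1 / 2) * (1 / 11 + 1 / 10), tolerance = 1e-10)
  }
  # printed rounding: 0.0455 and 0.0955
  expect_equal(round(unname(s["11"]), 4), 0.0455)
  expect_equal(round(unname(s["1"]), 4), 0.0955)
})

test_that("bridge score sums to one with mean exactly 1/N", {
  for (seed in 1:4) {
    g <- random_graph(15, 0.3, weighted = seed %% 2 == 0, seed = seed)
    s <- bridge_score(g, 3)$score
    expect_equal(sum(s), 1, tolerance = 1e-9)
    expect_equal(mean(s), 1 / 15, tolerance = 1e-12)
    expect_gte(min(s), 0)
  }
})

test_that("disjoint cliques give the uniform score under the degenerate block", {
  g <- disjoint_cliques(2, 5)
  s <- bridge_score(g, 2)$score
  expect_equal(unname(s), rep(0.1, 10), tolerance = 1e-9)
})

test_that("ratiocut conventions: components, single edge, brute-force barbell", {
  g <- disjoint_cliques(2, 5)
  expect_equal(ratiocut(g, rep(1:2, each = 5)), 0)

  single <- key_graph(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(ratiocut(single, c(1, 2)), 2)

  # exhaustive 2-partitions of the 6-node barbell: minimum at the triangle cut
  bb <- barbell6()
  best <- Inf; best_assign <- NULL
  for (code in 1:(2^5 - 1)) {           # node 1 fixed in group 1
    assign <- c(1, as.integer(intToBits(code))[1:5] + 1L)
    if (length(unique(assign)) < 2) next
    rc <- ratiocut_brute(bb$weights, assign)
    if (rc < best) { best <- rc; best_assign <- assign }
  }
  expect_equal(best_assign, rep(1:2, each = 3))
  expect_equal(ratiocut(bb, best_assign), best, tolerance = 1e-12)
})

test_that("quadratic and trace encodings reproduce ratiocut exactly", {
  for (seed in 1:6) {
    g <- random_graph(8, 0.5, weighted = seed > 3, seed = seed)
    set.seed(seed + 100)
    a2 <- sample(1:2, 8, replace = TRUE)
    if (length(unique(a2)) < 2) a2[1] <- 3 - a2[1]
    expect_equal(ratiocut_quadratic(g, a2), ratiocut(g, a2), tolerance = 1e-10)
    a3 <- c(1, 2, 3, sample(1:3, 5, replace = TRUE))
    expect_equal(ratiocut_quadratic(g, a3), ratiocut(g, a3), tolerance = 1e-10)
    expect_equal(ratiocut(g, a3), ratiocut_brute(g$weights, a3), tolerance = 1e-10)
  }
})

test_that("balanced two-group index vector has unit entries orthogonal to 1", {
  nA <- 4; nB <- 4
  h <- c(rep(sqrt(nB / nA), nA), rep(-sqrt(nA / nB), nB))
  expect_equal(abs(h), rep(1, 8))
  expect_equal(sum(h), 0)
})

test_that("toy classification: node 11 bridge, 4 and 9 cores, rest peripheral", {
  g <- generate_weighted_toy()
  cl <- classify_nodes(importance_perturbative(g, 2), bridge_score(g, 2))
  expect_equal(as.character(cl$label[["11"]]), "bridge")
  expect_equal(as.character(cl$label[["4"]]), "core")
  expect_equal(as.character(cl$label[["9"]]), "core")
  expect_equal(sum(cl$label == "peripheral"), 8)
})

test_that("two disjoint cliques have no bridges", {
  g <- disjoint_cliques(2, 5)
  cl <- suppressWarnings(
    classify_nodes(importance_perturbative(g, 2), bridge_score(g, 2)))
  expect_equal(sum(cl$label == "bridge"), 0)
})

test_that("planted bridge attains the strictly smallest score across seeds", {
  for (seed in 1:20) {
    g <- generate_core_bridge_sketch(seed = seed)
    s <- bridge_score(g, 2)$score
    bridge <- which(g$meta$role == "bridge")
    expect_equal(which.min(s), bridge, ignore_attr = TRUE)
    expect_true(all(s[-bridge] > s[bridge]))
  }
})

test_that("classify_nodes rejects mismatched inputs", {
  g <- generate_weighted_toy()
  imp <- importance_perturbative(g, 2)
  s3 <- bridge_score(g, 3)
  expect_error(classify_nodes(imp, s3), "different c")
  other <- suppressWarnings(bridge_score(disjoint_cliques(2, 5), 2))
  expect_error(classify_nodes(imp, other), "same graph")
})

test_that("fiedler partition splits the toy symmetrically with a dual bridge", {
  g <- generate_weighted_toy()
  fp <- fiedler_partition(g)
  a <- fp$partition$assignment
  expect_equal(length(unique(a[as.character(1:5)])), 1)
  expect_equal(length(unique(a[as.character(6:10)])), 1)
  expect_false(a[["1"]] == a[["6"]])
  expect_equal(fp$dual, "11")   # the bridge has a ~zero Fiedler component
})
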