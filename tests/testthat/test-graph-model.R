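test_that("edge lists load with labels preserved and binary weights", {
  f <- withr::local_tempfile(lines = c("# comment", "a b", "b c"))
  g <- load_graph(f, format = "edgelist")
  expect_equal(g$n, 3)
  expect_equal(g$m, 2)
  expect_setequal(g$labels, c("a", "b", "c"))
  expect_true(all(g$weights %in% c(0, 1)))
  expect_false(g$weighted)
})

test_that("duplicate edges collapse when consistent and error on conflict", {
  f <- withr::local_tempfile(lines = c("a b 1", "b a 1", "b c 2"))
  g <- load_graph(f, format = "edgelist")
  expect_equal(g$m, 2)
  f2 <- withr::local_tempfile(lines = c("a b 1", "b a 3"))
  expect_error(load_graph(f2, format = "edgelist"), "conflicting weights")
  g2 <- load_graph(f2, format = "edgelist", sum_duplicates = TRUE)
  expect_equal(g2$weights["a", "b"], 4)
})

test_that("format violations are rejected with informative errors", {
  f <- withr::local_tempfile(lines = c("a b", "c"))
  expect_error(load_graph(f, format = "edgelist"), "line 2")
  f2 <- withr::local_tempfile(lines = c("a a"))
  expect_error(load_graph(f2, format = "edgelist"), "self-loop")
  f3 <- withr::local_tempfile(lines = c("u,v,w", "0,1,0", "0,0,1", "0,1,0"))
  expect_error(load_graph(f3, format = "adjacency_csv"), "asymmetric")
  expect_error(load_graph(tempfile(), format = "edgelist"), "no such file")
})

test_that("asymmetry within 1e-9 is symmetrized, larger is an error", {
  W <- matrix(c(0, 1, 1 + 1e-12, 0), 2, 2)
  g <- key_graph(W)
  expect_equal(g$weights[1, 2], g$weights[2, 1])
  W2 <- matrix(c(0, 1, 0.5, 0), 2, 2)
  expect_error(key_graph(W2), "asymmetric")
  expect_error(key_graph(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("save/load round-trips preserve labels and weights", {
  toy <- generate_weighted_toy()
  for (fmt in c("edgelist", "gml")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    save_graph(toy, f, format = fmt)
    g2 <- load_graph(f, format = fmt)
    perm <- match(toy$labels, g2$labels)
    expect_false(anyNA(perm))
    expect_equal(g2$weights[perm, perm], toy$weights, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # mtx keeps weights, positional labels
  f <- withr::local_tempfile(fileext = ".mtx")
  save_graph(toy, f, format = "mtx")
  g3 <- load_graph(f, format = "mtx")
  expect_equal(unname(g3$weights["4", "1"]), 2)
  expect_equal(unname(g3$weights), unname(toy$weights), tolerance = 1e-12)
})

test_that("weighted toy edge list has 55 lines and GML keeps empty graphs", {
  f <- withr::local_tempfile(fileext = ".edgelist")
  save_graph(generate_weighted_toy(), f)
  expect_length(readLines(f), 55)
  empty <- key_graph(matrix(0, 3, 3), labels = c("x", "y", "z"))
  f2 <- withr::local_tempfile(fileext = ".gml")
  save_graph(empty, f2, format = "gml")
  g2 <- load_graph(f2, format = "gml")
  expect_equal(g2$n, 3)
  expect_equal(g2$m, 0)
})

test_that("laplacian has zero row sums, PSD spectrum, and the P3 closed form", {
  p3 <- path_graph(3)
  expect_equal(sort(eigen(laplacian(p3), symmetric = TRUE)$values),
               c(0, 1, 3), tolerance = 1e-8)
  for (seed in 1:5) {
    g <- random_graph(12, 0.3, weighted = seed %% 2 == 0, seed = seed)
    L <- laplacian(g)
    expect_equal(max(abs(rowSums(L))), 0, tolerance = 1e-10)
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("weighted degrees: toy bridge has strength 10", {
  expect_equal(unname(degrees(generate_weighted_toy())["11"]), 10)
})

test_that("zero Laplacian eigenvalues count connected components", {
  for (ncomp in 1:3) {
    g <- disjoint_cliques(ncomp, 4)
    vals <- eigen(laplacian(g), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(vals) < 1e-8), ncomp)
  }
})

test_that("node removal deletes the right row/column", {
  toy <- generate_weighted_toy()
  g <- remove_node(toy, "11")
  expect_equal(g$n, 10)
  expect_false("11" %in% g$labels)
  expect_equal(g$weights, toy$weights[1:10, 1:10], tolerance = 1e-12)
  expect_error(remove_node(toy, "nope"), "unknown node")
})
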