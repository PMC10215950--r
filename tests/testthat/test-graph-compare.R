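test_that("pair classification covers every reference/new state combination", {
  n <- c("A", "B")
  st <- function(ref, new) classify_pair(ref, new, c("A", "B"))
  none <- mixed_graph(n)
  und <- mixed_graph(n, undirected = cbind("A", "B"))
  fwd <- mixed_graph(n, directed = cbind("A", "B"))
  rev <- mixed_graph(n, directed = cbind("B", "A"))
  expect_equal(st(none, none), "both-absent")
  expect_equal(st(none, und), "edge-appeared")
  expect_equal(st(none, fwd), "edge-appeared")
  expect_equal(st(und, und), "common-undirected")
  expect_equal(st(und, fwd), "undirected-to-directed")
  expect_equal(st(und, none), "undirected-vanished")
  expect_equal(st(fwd, fwd), "common-directed")
  expect_equal(st(fwd, und), "directed-to-undirected")
  expect_equal(st(fwd, rev), "directed-reversed")
  expect_equal(st(fwd, none), "directed-vanished")
  expect_error(classify_pair(fwd, mixed_graph(c("A", "C")), c("A", "B")),
               "identical node set")
})

test_that("edge overlap counts match a hand enumeration", {
  nodes <- c("A", "B", "C", "D", "E", "F")
  ref <- mixed_graph(nodes, directed = rbind(c("A", "B"), c("C", "D")),
                     undirected = cbind("E", "F"))
  new <- mixed_graph(nodes, directed = cbind("A", "B"),
                     undirected = rbind(c("C", "D"), c("E", "F")))
  ov <- edge_overlap(ref, new)
  expect_equal(ov$common_directed, 1)
  expect_equal(ov$directed_to_undirected, 1)
  expect_equal(ov$common_undirected, 1)
  expect_equal(ov$directed_reversed, 0)
  expect_equal(ov$directed_vanished, 0)
  expect_equal(ov$n_directed_ref, 2)
  expect_equal(ov$n_undirected_ref, 1)
  expect_equal(ov$shd, 1)
})

test_that("overlap of a graph with itself is total and SHD-free", {
  for (s in 1:5) {
    g <- random_mixed_graph(paste0("v", 1:8), seed = s)
    ov <- edge_overlap(g, g)
    expect_equal(ov$common_undirected, ov$n_undirected_ref)
    expect_equal(ov$common_directed, ov$n_directed_ref)
    expect_equal(ov$shd, 0)
    expect_equal(ov$relative_shd_pct, 0)
  }
})

test_that("the four directed-edge fates partition the reference edges", {
  for (s in 1:10) {
    ref <- random_mixed_graph(paste0("v", 1:7), seed = 100 + s)
    new <- random_mixed_graph(paste0("v", 1:7), seed = 200 + s)
    ov <- edge_overlap(ref, new)
    expect_equal(ov$common_directed + ov$directed_to_undirected +
                   ov$directed_reversed + ov$directed_vanished,
                 ov$n_directed_ref)
  }
})

test_that("SHD obeys the operator costs, symmetry and identity", {
  n <- c("A", "B")
  fwd <- mixed_graph(n, directed = cbind("A", "B"))
  rev <- mixed_graph(n, directed = cbind("B", "A"))
  none <- mixed_graph(n)
  und <- mixed_graph(n, undirected = cbind("A", "B"))
  expect_equal(structural_hamming_distance(fwd, fwd), 0)
  expect_equal(structural_hamming_distance(fwd, rev), 1)
  expect_equal(structural_hamming_distance(fwd, und), 1)
  expect_equal(structural_hamming_distance(und, none), 1)
  expect_equal(structural_hamming_distance(fwd, none), 2)
  expect_equal(structural_hamming_distance(fwd, none, directed_absent_cost = 1), 1)
  expect_error(structural_hamming_distance(fwd, none, directed_absent_cost = 3),
               "must be 1 or 2")
  for (s in 1:10) {
    g1 <- random_mixed_graph(paste0("v", 1:6), seed = s)
    g2 <- random_mixed_graph(paste0("v", 1:6), seed = 50 + s)
    d12 <- structural_hamming_distance(g1, g2)
    expect_equal(d12, structural_hamming_distance(g2, g1))
    expect_true(d12 >= 0)
    expect_equal(d12 == 0, graph_equal(g1, g2))
  }
})

test_that("relative SHD uses the one-alteration-per-pair denominator", {
  expect_equal(relative_shd(0, 10), 0)
  expect_equal(relative_shd(choose(7, 2), 7), 100)
  # 3-node graphs {A->B} vs {}: shd 2 over 3 pairs
  expect_equal(relative_shd(2, 3), 66.67)
  expect_error(relative_shd(10, 2), "feasible range")
  expect_error(relative_shd(1, 1), "at least 2")
})

test_that("percentage helpers reproduce printed-table arithmetic", {
  expect_equal(pct_of(34.21, 40), 85.53)  # plain round() would give 85.52
  expect_equal(round_half_up(85.525), 85.53)
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_true(is.na(pct_of(0, 0)))
  expect_equal(pct_of(c(1, 3), c(0, 4)), c(NA, 75))
})
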