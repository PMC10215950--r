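test_that("random DAGs respect density extremes and stay acyclic", {
  expect_equal(nrow(graph_edges(random_dag(5, 0, seed = 1))), 0)
  full <- random_dag(4, 1, seed = 2)
  expect_equal(nrow(graph_edges(full)), 6)  # C(4,2)
  expect_true(all(graph_edges(full)$type == "directed"))
  for (s in 1:10)
    expect_true(causalstab:::directed_acyclic(random_dag(12, 0.3, seed = s)))
})

test_that("random DAG edge counts follow the binomial expectation", {
  counts <- vapply(1:400, function(s)
    nrow(graph_edges(random_dag(10, 0.2, seed = 1000 + s))), numeric(1))
  # E = 0.2 * 45 = 9; se of the mean ~ 0.134
  expect_lt(abs(mean(counts) - 9), 0.6)
})

test_that("CPT rows are distributions and strength acts as documented", {
  for (s in 1:20) {
    dag <- random_dag(8, 0.35, seed = s)
    cpts <- sample_cpts(dag, strength = runif(1, 0, 8), seed = s)
    for (tab in cpts) expect_equal(rowSums(tab), rep(1, nrow(tab)))
  }
  dag <- mixed_graph(c("P", "Q", "C"),
                     directed = rbind(c("P", "C"), c("Q", "C")))
  flat <- sample_cpts(dag, strength = 0, seed = 4)
  expect_equal(max(apply(flat$C, 2, function(col) diff(range(col)))), 0)
  strong <- sample_cpts(dag, strength = 10, seed = 4)
  expect_true(all(apply(strong$C, 1, max) >= 0.8))
  # heterogeneous strengths still yield valid tables
  het <- sample_cpts(dag, strength = c(0.1, 5), seed = 9)
  expect_equal(rowSums(het$C), rep(1, 9))
})

test_that("ancestral sampling is seed-deterministic and matches marginals", {
  sc <- gess_like_scenario(n_snps = 10, n = 200, seed = 5)
  d1 <- simulate_dataset(sc)
  d2 <- simulate_dataset(sc)
  expect_identical(d1$values, d2$values)
  d3 <- simulate_dataset(gess_like_scenario(n_snps = 10, n = 200, seed = 6))
  expect_false(identical(d1$values, d3$values))

  empty <- simulate_dataset(gess_like_scenario(n_snps = 10, n = 0, seed = 1))
  expect_equal(n_subjects(empty), 0)
  expect_equal(length(empty$variables), 11)

  # single root with a fixed marginal: empirical frequencies within CLT bounds
  root <- mixed_graph("V1")
  scr <- synthetic_scenario(root, list(V1 = matrix(c(.25, .5, .25), 1)),
                            c(V1 = 3L), n = 20000, seed = 8)
  freq <- tabulate(simulate_dataset(scr)$values[, 1] + 1, 3) / 20000
  for (i in 1:3) {
    p <- c(.25, .5, .25)[i]
    expect_lt(abs(freq[i] - p), 3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("a strong collider is recovered end to end from simulated data", {
  dag <- mixed_graph(c("X", "Y", "Z"), directed = rbind(c("X", "Z"), c("Y", "Z")))
  cpts <- sample_cpts(dag, strength = 10, seed = 5)
  sc <- synthetic_scenario(dag, cpts, c(X = 3L, Y = 3L, Z = 3L),
                           n = 5000, seed = 9)
  g <- learn_cpdag(simulate_dataset(sc))
  expect_true(graph_equal(g, dag_to_cpdag(dag)))
})

test_that("outcome planting wires exactly the requested blanket", {
  dag <- mixed_graph(paste0("s", 1:8),
                     directed = rbind(c("s1", "s2"), c("s2", "s3")))
  p <- plant_outcome(dag, parents = "s4", children = "s5",
                     spouses = "s6", outcome_name = "out")
  expect_setequal(p$planted_mb, c("s4", "s5", "s6"))
  expect_setequal(markov_blanket(p$dag, "out"), c("s4", "s5", "s6"))

  p2 <- plant_outcome(dag, parents = c("s7", "s8"), outcome_name = "out")
  expect_setequal(p2$planted_mb, c("s7", "s8"))

  expect_error(plant_outcome(dag, spouses = "s4", outcome_name = "out"),
               "require at least one child")
  # spouse reachable from the child induces a cycle
  lin <- mixed_graph(c("a", "b", "c"), directed = rbind(c("a", "b")))
  expect_error(plant_outcome(lin, children = "a", spouses = "b",
                             outcome_name = "out"),
               "cycle")
  # a child with a parent outside the spouse set would widen the blanket
  expect_error(plant_outcome(lin, children = "b", outcome_name = "out"),
               "outside the spouse set")
})

test_that("every generated scenario satisfies the blanket identity", {
  for (s in 1:20) {
    sc <- gess_like_scenario(n_snps = 20, n = 10, seed = 400 + s)
    expect_setequal(markov_blanket(sc$dag, sc$outcome_name), sc$planted_mb)
    expect_equal(length(sc$planted_mb), 4)
  }
})

test_that("MCAR masking feeds the complete-case filter coherently", {
  sc <- gess_like_scenario(n_snps = 10, n = 500, seed = 12, missing_rate = 0.01)
  ds <- simulate_dataset(sc)
  expect_gt(sum(ds$missing_mask), 0)
  n_inc <- sum(rowSums(ds$missing_mask) > 0)
  filt <- complete_case_filter(ds, quiet = TRUE)
  expect_equal(n_subjects(filt) + n_inc, 500)
  # empirical masking rate near nominal
  rate <- mean(ds$missing_mask)
  expect_lt(abs(rate - 0.01), 4 * sqrt(0.01 * 0.99 / length(ds$values)))
})
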