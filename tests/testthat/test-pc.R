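collider_dag <- function() {
  mixed_graph(c("X", "Y", "Z"), directed = rbind(c("X", "Z"), c("Y", "Z")))
}

test_that("oracle skeleton search recovers collider, chain and empty models", {
  sk <- pc_skeleton(c("X", "Y", "Z"), test = dsep_oracle(collider_dag()))
  ed <- graph_edges(sk$graph)
  expect_setequal(paste(ed$from, ed$to), c("X Z", "Y Z"))
  expect_true(all(ed$type == "undirected"))
  expect_identical(sepset(sk$sepsets, "X", "Y"), character(0))

  chain <- mixed_graph(c("X", "Z", "Y"),
                       directed = rbind(c("X", "Z"), c("Z", "Y")))
  sk2 <- pc_skeleton(c("X", "Z", "Y"), test = dsep_oracle(chain))
  ed2 <- graph_edges(sk2$graph)
  expect_setequal(paste(ed2$from, ed2$to), c("X Z", "Z Y"))
  expect_identical(sepset(sk2$sepsets, "X", "Y"), "Z")

  indep <- mixed_graph(c("A", "B", "C"))
  sk3 <- pc_skeleton(c("A", "B", "C"), test = dsep_oracle(indep))
  expect_equal(nrow(graph_edges(sk3$graph)), 0)

  expect_error(pc_skeleton(c("A", "B"), alpha = 2, test = dsep_oracle(indep)),
               "alpha")
  expect_error(pc_skeleton("A", test = dsep_oracle(indep)), "at least 2")
})

test_that("v-structures orient from sepsets; chains stay undirected", {
  sk <- pc_skeleton(c("X", "Y", "Z"), test = dsep_oracle(collider_dag()))
  g <- orient_v_structures(sk)
  expect_equal(edge_state(g, "X", "Z"),
               list(state = "directed", from = "X", to = "Z"))
  expect_equal(edge_state(g, "Y", "Z"),
               list(state = "directed", from = "Y", to = "Z"))

  # Z in sepset(X, Y) blocks orientation of the chain
  skel <- mixed_graph(c("X", "Z", "Y"),
                      undirected = rbind(c("X", "Z"), c("Z", "Y")))
  ss <- sepset_table(c("X", "Z", "Y"), list(pair = c("X", "Y"), sep = "Z"))
  g2 <- orient_v_structures(skel, ss)
  expect_equal(edge_state(g2, "X", "Z")$state, "undirected")
  expect_equal(edge_state(g2, "Z", "Y")$state, "undirected")
})

test_that("conflicting collider demands revert the edge to undirected", {
  # path X - Y - Z - W; empty sepsets for (X,Z) and (Y,W) demand both
  # Y -> Z and Z -> Y
  nodes <- c("X", "Y", "Z", "W")
  skel <- mixed_graph(nodes, undirected = rbind(c("X", "Y"), c("Y", "Z"),
                                                c("Z", "W")))
  ss <- sepset_table(nodes,
                     list(pair = c("X", "Z"), sep = character(0)),
                     list(pair = c("Y", "W"), sep = character(0)),
                     list(pair = c("X", "W"), sep = character(0)))
  g <- orient_v_structures(skel, ss)
  expect_equal(edge_state(g, "Y", "Z")$state, "undirected")
  conf <- attr(g, "orientation_conflicts")
  expect_true(nrow(conf) >= 1)
  expect_equal(edge_state(g, "X", "Y"),
               list(state = "directed", from = "X", to = "Y"))
  expect_equal(edge_state(g, "W", "Z"),
               list(state = "directed", from = "W", to = "Z"))
})

test_that("Meek rules fire as documented and leave triangles alone", {
  # R1: X -> Y, Y - Z, X and Z non-adjacent
  g <- mixed_graph(c("X", "Y", "Z"), directed = cbind("X", "Y"),
                   undirected = cbind("Y", "Z"))
  m <- apply_meek_rules(g)
  expect_equal(edge_state(m, "Y", "Z"),
               list(state = "directed", from = "Y", to = "Z"))

  # R2: X -> Y -> Z with X - Z
  g2 <- mixed_graph(c("X", "Y", "Z"),
                    directed = rbind(c("X", "Y"), c("Y", "Z")),
                    undirected = cbind("X", "Z"))
  m2 <- apply_meek_rules(g2)
  expect_equal(edge_state(m2, "X", "Z"),
               list(state = "directed", from = "X", to = "Z"))

  # fully undirected triangle: no rule fires
  tri <- mixed_graph(c("A", "B", "C"),
                     undirected = rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_true(graph_equal(apply_meek_rules(tri), tri))

  # R3: a - b, a - c, a - d, c -> b, d -> b, c and d non-adjacent
  g3 <- mixed_graph(c("a", "b", "c", "d"),
                    undirected = rbind(c("a", "b"), c("a", "c"), c("a", "d")),
                    directed = rbind(c("c", "b"), c("d", "b")))
  m3 <- apply_meek_rules(g3)
  expect_equal(edge_state(m3, "a", "b"),
               list(state = "directed", from = "a", to = "b"))
})

test_that("the learned CPDAG matches the true equivalence class end to end", {
  # oracle versions of the canonical motifs
  g <- learn_cpdag(c("X", "Y", "Z"), test = dsep_oracle(collider_dag()))
  expect_true(graph_equal(g, dag_to_cpdag(collider_dag())))

  chain <- mixed_graph(c("X", "Z", "Y"),
                       directed = rbind(c("X", "Z"), c("Z", "Y")))
  gc <- learn_cpdag(c("X", "Z", "Y"), test = dsep_oracle(chain))
  expect_equal(edge_counts(gc), c(undirected = 2L, directed = 0L))

  # data version at large n with a fixed seed
  sc <- gess_like_scenario(n_snps = 19, n = 5000, seed = 11)
  lg <- learn_cpdag(simulate_dataset(sc))
  expect_true(graph_equal(lg, dag_to_cpdag(sc$dag)))
})

test_that("oracle PC output is invariant to variable-order permutation", {
  set.seed(21)
  for (s in 1:5) {
    dag <- random_dag(6, 0.4, seed = 40 + s, names = LETTERS[1:6])
    g1 <- learn_cpdag(LETTERS[1:6], test = dsep_oracle(dag))
    perm <- sample(LETTERS[1:6])
    g2 <- learn_cpdag(perm, test = dsep_oracle(dag))
    e1 <- graph_edges(g1)
    e2 <- graph_edges(g2)
    # canonicalize: undirected endpoints are interchangeable
    key <- function(e) sort(ifelse(e$type == "undirected",
                                   paste(pmin(e$from, e$to),
                                         pmax(e$from, e$to), "undirected"),
                                   paste(e$from, e$to, "directed")))
    expect_identical(key(e1), key(e2))
  }
})

test_that("learned CPDAGs keep a consistent, acyclic edge-state partition", {
  for (s in 1:6) {
    sc <- gess_like_scenario(n_snps = 15, n = 300, seed = 60 + s,
                             strength = c(0.5, 5))
    g <- learn_cpdag(simulate_dataset(sc))
    expect_true(causalstab:::directed_acyclic(g))
    expect_true(all(g$am %in% c(0L, 1L)))
  }
})

test_that("Markov blankets follow the parents/children/spouses definition", {
  g <- mixed_graph(c("A", "T", "B", "C", "D"),
                   directed = rbind(c("A", "T"), c("T", "B"), c("C", "B")))
  expect_setequal(markov_blanket(g, "T"), c("A", "B", "C"))
  expect_equal(markov_blanket(g, "D"), character(0))
  # undirected neighbours are possible parents/children: included
  g2 <- set_edge(g, "T", "D", "undirected")
  expect_true("D" %in% markov_blanket(g2, "T"))
  # spouses only through strictly directed child edges
  g3 <- mixed_graph(c("T", "B", "C"), undirected = cbind("T", "B"),
                    directed = cbind("C", "B"))
  expect_setequal(markov_blanket(g3, "T"), "B")
  expect_error(markov_blanket(g, "nope"), "unknown node")
})

test_that("a planted blanket is recovered exactly at large n", {
  sc <- gess_like_scenario(n_snps = 25, n = 5000, seed = 3)
  g <- learn_cpdag(simulate_dataset(sc))
  expect_setequal(markov_blanket(g, "syntax_score"), sc$planted_mb)
  # and on the true graph itself, by construction
  expect_setequal(markov_blanket(sc$dag, "syntax_score"), sc$planted_mb)
})
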