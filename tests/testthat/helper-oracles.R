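# shared fixtures and independent oracles used across test files

make_ds <- function(..., outcome = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  genotype_dataset(m, outcome_name = outcome)
}

# uniformly random mixed graph: each pair none/undirected/either direction
random_mixed_graph <- function(nodes, seed) {
  set.seed(seed)
  g <- mixed_graph(nodes)
  p <- length(nodes)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    st <- sample(0:3, 1)
    if (st == 1) g <- set_edge(g, nodes[i], nodes[j], "undirected")
    if (st == 2) g <- set_edge(g, nodes[i], nodes[j], "directed")
    if (st == 3) g <- set_edge(g, nodes[j], nodes[i], "directed")
  }
  g
}

# --- brute-force SHD oracle -------------------------------------------------
# A 3-node mixed graph is a triple of pair states in {0 none, 1 undirected,
# 2 forward, 3 backward}. Operators act on a single pair: add/delete an
# undirected edge (0<->1), add/remove an orientation (1<->2, 1<->3), reverse
# an orientation (2<->3). BFS over the 64 graph states yields the exact
# minimum operator count between any two graphs, independently of the
# package's per-pair cost table.
shd_bfs_oracle <- local({
  n_states <- 4^3
  decode <- function(s) c(s %% 4, (s %/% 4) %% 4, (s %/% 16) %% 4)
  encode <- function(v) v[1] + 4 * v[2] + 16 * v[3]
  pair_moves <- list(`0` = 1L, `1` = c(0L, 2L, 3L), `2` = c(1L, 3L),
                     `3` = c(1L, 2L))
  neighbours <- lapply(0:(n_states - 1), function(s) {
    v <- decode(s)
    out <- integer()
    for (p in 1:3) {
      for (m in pair_moves[[as.character(v[p])]]) {
        w <- v; w[p] <- m
        out <- c(out, encode(w))
      }
    }
    out
  })
  dist <- matrix(NA_integer_, n_states, n_states)
  for (s in 0:(n_states - 1)) {
    d <- rep(NA_integer_, n_states)
    d[s + 1] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in neighbours[[v + 1]]) {
        if (is.na(d[w + 1])) {
          d[w + 1] <- d[v + 1] + 1L
          queue <- c(queue, w)
        }
      }
    }
    dist[s + 1, ] <- d
  }
  list(dist = dist, decode = decode)
})

# build the 3-node mixed graph for a state triple (pairs 12, 13, 23)
state_to_graph <- function(v, nodes = c("A", "B", "C")) {
  g <- mixed_graph(nodes)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (p in 1:3) {
    i <- pairs[[p]][1]; j <- pairs[[p]][2]
    if (v[p] == 1) g <- set_edge(g, nodes[i], nodes[j], "undirected")
    if (v[p] == 2) g <- set_edge(g, nodes[i], nodes[j], "directed")
    if (v[p] == 3) g <- set_edge(g, nodes[j], nodes[i], "directed")
  }
  g
}

# sepset table literal for hand-built skeletons
sepset_table <- function(nodes, ...) {
  entries <- list(...)
  out <- list()
  for (e in entries) {
    i <- match(e$pair[1], nodes); j <- match(e$pair[2], nodes)
    out[[paste(min(i, j), max(i, j), sep = "|")]] <- e$sep
  }
  structure(out, class = "sepset_table", nodes = nodes)
}

# drop the outcome column of a dataset, keeping the genotype block
drop_outcome <- function(ds) {
  keep <- setdiff(ds$variables, ds$outcome_name)
  genotype_dataset(ds$values[, keep, drop = FALSE],
                   subject_ids = ds$subject_ids,
                   cardinalities = ds$cardinalities[keep])
}
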