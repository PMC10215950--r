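#' Random DAG by ordered edge inclusion
#'
#' Samples a uniformly random topological order of the nodes and includes
#' each forward pair independently with probability `edge_prob`; acyclic by
#' construction.
#'
#' @param n_nodes number of nodes.
#' @param edge_prob inclusion probability for each of the
#'   `choose(n_nodes, 2)` ordered pairs.
#' @param seed integer seed.
#' @param names optional node names (default `V1..Vn`).
#' @return a directed acyclic `mixed_graph`.
#' @export
random_dag <- function(n_nodes, edge_prob, seed = 1L, names = NULL) {
  stopifnot(n_nodes >= 1, edge_prob >= 0, edge_prob <= 1)
  if (is.null(names)) names <- paste0("V", seq_len(n_nodes))
  set.seed(as_seed(seed))
  ord <- sample.int(n_nodes)
  g <- mixed_graph(names)
  if (n_nodes >= 2) {
    for (i in 1:(n_nodes - 1)) for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < edge_prob)
        g <- set_edge(g, names[ord[i]], names[ord[j]], "directed")
    }
  }
  g
}

rdirichlet1 <- function(k, alpha = 1) {
  x <- stats::rgamma(k, shape = alpha)
  if (sum(x) <= 0) x <- rep(1, k)
  x / sum(x)
}

#' Conditional probability tables for a DAG
#'
#' Every node gets a base category distribution drawn from a symmetric
#' Dirichlet (imitating allele-frequency variation across loci). For a node
#' with parents, each parent configuration is assigned a modal category by
#' an additive dose-response rule — the mode scales with the sum of the
#' parent codes, so every parent has a monotone, individually detectable
#' effect — and the base row is tilted towards that mode with weight
#' `strength`: `row = (base + strength * e_mode) / (1 + strength)`.
#' `strength = 0` leaves every row equal to the base row, i.e. children
#' independent of their parents; large `strength` makes the mode
#' probability at least `strength / (1 + strength)`.
#'
#' @param dag a directed acyclic `mixed_graph`.
#' @param cardinalities named integer vector of category counts per node
#'   (default 3 everywhere, genotype-like).
#' @param strength non-negative dependence strength; a length-2 vector
#'   `c(lo, hi)` draws each node's strength log-uniformly from the range,
#'   giving the heterogeneous effect-size spectrum (some relations strong,
#'   some near the detection boundary) seen in real association data.
#' @param seed integer seed.
#' @param dirichlet_alpha concentration of the base-row Dirichlet.
#' @return named list; element `v` is a matrix with one row per parent
#'   configuration (mixed-radix order over the parents in node order) and
#'   one column per category of `v`. Every row sums to 1.
#' @export
sample_cpts <- function(dag, cardinalities = NULL, strength = 5, seed = 1L,
                        dirichlet_alpha = 1.5) {
  stopifnot(all(strength >= 0), length(strength) %in% c(1L, 2L))
  nodes <- dag$nodes
  if (is.null(cardinalities))
    cardinalities <- stats::setNames(rep(3L, length(nodes)), nodes)
  set.seed(as_seed(seed))
  cpts <- list()
  for (v in nodes) {
    pa <- graph_parents(dag, v)
    k <- cardinalities[[v]]
    base <- rdirichlet1(k, dirichlet_alpha)
    strength_v <- if (length(strength) == 2L)
      exp(stats::runif(1, log(max(strength[1], 1e-6)), log(max(strength[2], 1e-6))))
    else strength
    ncfg <- prod(c(1L, cardinalities[pa]))
    tab <- matrix(rep(base, each = ncfg), nrow = ncfg)
    if (length(pa) && strength_v > 0) {
      # decode the mixed-radix parent configuration of each row and map the
      # summed parent dose onto the child's categories
      cards_pa <- cardinalities[pa]
      max_dose <- sum(cards_pa - 1L)
      for (r in seq_len(ncfg)) {
        rest <- r - 1L
        dose <- 0L
        for (cp in cards_pa) {
          dose <- dose + rest %% cp
          rest <- rest %/% cp
        }
        mode <- 1L + as.integer(round((k - 1) * dose / max(1L, max_dose)))
        row <- tab[r, ]
        row[mode] <- row[mode] + strength_v
        tab[r, ] <- row / (1 + strength_v)
      }
    }
    cpts[[v]] <- tab
  }
  cpts
}

#' Synthetic scenario: ground-truth DAG, CPTs and a planted Markov blanket
#'
#' @param dag directed acyclic `mixed_graph` (including the outcome node, if
#'   any).
#' @param cpts conditional probability tables from [sample_cpts()].
#' @param cardinalities named integer vector.
#' @param n sample size to draw.
#' @param seed integer seed for [simulate_dataset()].
#' @param outcome_name name of the outcome node, or `NULL`.
#' @param planted_mb designated Markov blanket of the outcome; validated
#'   against the graph-theoretic blanket of `dag`.
#' @param missing_rate probability of masking each entry (missing completely
#'   at random); default 0.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(dag, cpts, cardinalities, n, seed = 1L,
                               outcome_name = NULL, planted_mb = NULL,
                               missing_rate = 0) {
  stopifnot(n >= 0, missing_rate >= 0, missing_rate < 1)
  if (!directed_acyclic(dag)) stop("true DAG must be acyclic")
  for (v in dag$nodes) {
    if (any(abs(rowSums(cpts[[v]]) - 1) > 1e-8))
      stop("CPT rows of '", v, "' do not sum to 1")
  }
  if (!is.null(planted_mb)) {
    true_mb <- markov_blanket(dag, outcome_name)
    if (!setequal(true_mb, planted_mb))
      stop("planted_mb does not equal the graph-theoretic Markov blanket (",
           paste(true_mb, collapse = ", "), ")")
  }
  structure(list(dag = dag, cpts = cpts, cardinalities = cardinalities,
                 n = n, seed = as_seed(seed), outcome_name = outcome_name,
                 planted_mb = planted_mb, missing_rate = missing_rate),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("synthetic_scenario: %d variables, n = %d, seed = %d\n",
              length(x$dag$nodes), x$n, x$seed))
  if (!is.null(x$outcome_name))
    cat(sprintf("  outcome '%s' with planted Markov blanket {%s}\n",
                x$outcome_name, paste(x$planted_mb, collapse = ", ")))
  invisible(x)
}

#' Draw a dataset from a synthetic scenario
#'
#' Ancestral sampling in a topological order of the true DAG; seed-
#' deterministic. An optional missing-completely-at-random mask exercises
#' the complete-case filter.
#'
#' @param scenario a `synthetic_scenario`.
#' @return a `genotype_dataset` (with `outcome_name` set when the scenario
#'   has an outcome node).
#' @export
simulate_dataset <- function(scenario) {
  sc <- scenario
  nodes <- sc$dag$nodes
  n <- sc$n
  set.seed(sc$seed)
  vals <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
  ord <- topo_order(sc$dag)
  for (v in nodes[ord]) {
    pa <- graph_parents(sc$dag, v)
    tab <- sc$cpts[[v]]
    if (n == 0) { vals[, v] <- numeric(0); next }
    if (!length(pa)) {
      vals[, v] <- sample.int(ncol(tab), n, replace = TRUE, prob = tab[1, ]) - 1L
    } else {
      cfg <- rep(1L, n)
      mult <- 1L
      for (p in pa) {
        cfg <- cfg + as.integer(vals[, p]) * mult
        mult <- mult * sc$cardinalities[[p]]
      }
      u <- stats::runif(n)
      cum <- t(apply(tab, 1, cumsum))
      vals[, v] <- rowSums(u > cum[cfg, , drop = FALSE])
    }
  }
  if (sc$missing_rate > 0 && n > 0) {
    mask <- matrix(stats::runif(length(vals)) < sc$missing_rate,
                   nrow = n)
    vals[mask] <- NA_real_
  }
  genotype_dataset(vals, outcome_name = sc$outcome_name,
                   cardinalities = sc$cardinalities)
}

topo_order <- function(dag) {
  d <- dir_mat(dag)
  p <- nrow(d)
  indeg <- colSums(d)
  out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (c in which(d[v, ])) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != p) stop("graph has a directed cycle")
  out
}

#' Plant an outcome node with a designated Markov blanket
#'
#' Adds an outcome node to a DAG and wires it so that its graph-theoretic
#' Markov blanket equals `parents U children U spouses`: parent edges into
#' the outcome, outcome edges into each child, and one edge from each spouse
#' into a child. Children must have no other parents outside the spouse set
#' (otherwise those parents would enter the blanket), and spouse wiring must
#' not create a cycle; both conditions are validated.
#'
#' @param dag directed acyclic `mixed_graph` without the outcome node.
#' @param parents,children,spouses character vectors of existing node names;
#'   `spouses` non-empty requires `children` non-empty.
#' @param outcome_name name of the new node.
#' @return list with `dag` (the extended graph) and `planted_mb`.
#' @export
plant_outcome <- function(dag, parents = character(), children = character(),
                          spouses = character(), outcome_name = "outcome") {
  all_named <- c(parents, children, spouses)
  if (anyDuplicated(all_named))
    stop("parents, children and spouses must be disjoint")
  node_index(dag, all_named)
  if (length(spouses) && !length(children))
    stop("spouses require at least one child")
  if (outcome_name %in% dag$nodes) stop("outcome node already present")
  for (ch in children) {
    extra <- setdiff(graph_parents(dag, ch), spouses)
    if (length(extra))
      stop("child '", ch, "' has parent(s) outside the spouse set: ",
           paste(extra, collapse = ", "))
  }
  g <- mixed_graph(c(dag$nodes, outcome_name))
  for (r in seq_len(nrow(graph_edges(dag)))) {
    e <- graph_edges(dag)[r, ]
    g <- set_edge(g, e$from, e$to, e$type)
  }
  for (p in parents) g <- set_edge(g, p, outcome_name, "directed")
  for (ch in children) g <- set_edge(g, outcome_name, ch, "directed")
  if (length(spouses)) {
    ch_i <- rep_len(children, length(spouses))
    for (s in seq_along(spouses)) {
      if (has_directed_path(g, node_index(g, ch_i[s]),
                            node_index(g, spouses[s])))
        stop("edge ", spouses[s], " -> ", ch_i[s], " would create a cycle")
      g <- set_edge(g, spouses[s], ch_i[s], "directed")
    }
  }
  if (!directed_acyclic(g)) stop("outcome wiring created a cycle")
  planted <- unique(c(parents, children, spouses))
  true_mb <- markov_blanket(g, outcome_name)
  if (!setequal(true_mb, planted))
    stop("internal error: planted blanket mismatch")
  list(dag = g, planted_mb = planted)
}

#' Desk-scale scenario shaped like a SNP/outcome study
#'
#' Builds a sparse random DAG over genotype-like variables (three categories
#' each), plants an outcome node whose Markov blanket has the requested
#' size (split into parents, one child and spouses, mirroring a small set of
#' loci that carry the outcome's local structure), and samples CPTs.
#'
#' @param n_snps number of genotype variables.
#' @param n sample size.
#' @param seed integer seed (drives graph, CPTs and sampling).
#' @param strength dependence strength passed to [sample_cpts()].
#' @param edge_prob DAG density; default gives expected degree about 1,
#'   matching the sparsity of learned genotype networks.
#' @param mb_size planted Markov blanket size (>= 3: parents, one child,
#'   spouses).
#' @param outcome_card number of outcome categories.
#' @param missing_rate MCAR masking rate.
#' @return a `synthetic_scenario`.
#' @export
gess_like_scenario <- function(n_snps = 25, n = 597, seed = 1L, strength = 5,
                               edge_prob = NULL, mb_size = 4L,
                               outcome_card = 3L, missing_rate = 0) {
  stopifnot(n_snps >= mb_size + 1, mb_size >= 3)
  if (is.null(edge_prob)) edge_prob <- min(1, 1 / (n_snps - 1))
  seed <- as_seed(seed)
  snps <- paste0("rs", formatC(seq_len(n_snps), width = 3, flag = "0"))
  dag <- random_dag(n_snps, edge_prob, seed = seed, names = snps)
  set.seed(as_seed(seed + 1L))
  # child: prefer a node with neither parents (no accidental extra spouses)
  # nor children (its own descendants would blur the outcome's local
  # structure with orientation ambiguity)
  n_pa <- vapply(snps, function(v) length(graph_parents(dag, v)), integer(1))
  n_ch <- vapply(snps, function(v) length(graph_children(dag, v)), integer(1))
  roots <- snps[n_pa == 0]
  isolated <- snps[n_pa == 0 & n_ch == 0]
  child <- if (length(isolated)) sample(isolated, 1L) else sample(roots, 1L)
  rest <- setdiff(snps, child)
  n_spouse <- 1L
  n_parent <- mb_size - 1L - n_spouse
  # parents and spouse are drawn from parentless loci where possible, so the
  # planted blanket is not entangled with upstream structure (an upstream
  # parent of a blanket member would otherwise be one orientation error away
  # from entering the learned blanket as a false spouse)
  pool <- setdiff(roots, child)
  if (length(pool) < n_parent + n_spouse)
    pool <- unique(c(pool, rest[order(n_pa[rest] + n_ch[rest])]))
  # spouse must not be reachable from the child
  ok_spouse <- pool[!vapply(pool, function(v)
    has_directed_path(dag, node_index(dag, child), node_index(dag, v)),
    logical(1))]
  spouse <- sample(ok_spouse, n_spouse)
  parents <- sample(setdiff(pool, spouse), n_parent)
  planted <- plant_outcome(dag, parents = parents, children = child,
                           spouses = spouse, outcome_name = "syntax_score")
  cards <- stats::setNames(rep(3L, n_snps + 1L),
                           c(snps, "syntax_score"))
  cards[["syntax_score"]] <- as.integer(outcome_card)
  cpts <- sample_cpts(planted$dag, cards, strength = strength,
                      seed = as_seed(seed + 2L))
  synthetic_scenario(planted$dag, cpts, cards, n = n,
                     seed = as_seed(seed + 3L),
                     outcome_name = "syntax_score",
                     planted_mb = planted$planted_mb,
                     missing_rate = missing_rate)
}

# clamp any integer-ish seed into the valid 32-bit range
as_seed <- function(seed) {
  s <- as.numeric(seed) %% 2147483646
  as.integer(s) + 1L
}
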