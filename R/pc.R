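#' PC-stable skeleton search
#'
#' Level-wise conditional-independence search: starting from the complete
#' undirected graph, at level `l` every surviving pair is tested against
#' conditioning sets of size `l` drawn from the adjacency sets of a frozen
#' snapshot taken at the start of the level (the "stable" variant, which
#' makes the result independent of the variable ordering). The edge is
#' removed, and the separating set recorded, at the first test with
#' `p > alpha`.
#'
#' @param x a complete-case `genotype_dataset`, or a character vector of
#'   node names when `test` is an oracle function.
#' @param alpha significance level in (0, 1); edges are kept while every
#'   conditional test rejects independence at `alpha`.
#' @param test `"g2"`, `"symmetric"`, or a function `(x, y, S, ds)`
#'   returning a `ci_test_result` or a p-value.
#' @param max_cond largest conditioning-set size searched; `Inf` for
#'   unbounded.
#' @return list with `graph` (a `mixed_graph` whose edges are all
#'   undirected), `sepsets` (a `sepset_table`), and `n_tests`.
#' @export
pc_skeleton <- function(x, alpha = 0.005, test = "g2", max_cond = 3L) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop("alpha must be a single number in (0, 1)")
  ci <- make_ci_fun(x, test)
  nodes <- if (inherits(x, "genotype_dataset")) x$variables else as.character(x)
  p <- length(nodes)
  if (p < 2) stop("at least 2 variables are required")
  A <- matrix(TRUE, p, p); diag(A) <- FALSE
  sepsets <- list()
  n_tests <- 0L
  l <- 0L
  repeat {
    snapshot <- A
    adj <- lapply(seq_len(p), function(i) which(snapshot[i, ]))
    pairs <- which(snapshot & upper.tri(snapshot), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!A[i, j]) next
      cands <- cond_sets(adj[[i]], adj[[j]], i, j, l)
      for (S in cands) {
        n_tests <- n_tests + 1L
        pval <- ci(nodes[i], nodes[j], nodes[S])
        if (pval > alpha) {
          A[i, j] <- A[j, i] <- FALSE
          sepsets[[pair_key(i, j)]] <- nodes[S]
          break
        }
      }
    }
    l <- l + 1L
    if (l > max_cond) break
    deg <- rowSums(A)
    more <- FALSE
    pr <- which(A & upper.tri(A), arr.ind = TRUE)
    if (nrow(pr) == 0) break
    if (!any(pmax(deg[pr[, 1]], deg[pr[, 2]]) - 1L >= l)) break
  }
  g <- mixed_graph(nodes)
  g$am <- matrix(as.integer(A), p, p, dimnames = list(nodes, nodes))
  structure(list(graph = g,
                 sepsets = structure(sepsets, class = "sepset_table",
                                     nodes = nodes),
                 n_tests = n_tests),
            class = "pc_skeleton")
}

pair_key <- function(i, j) paste(min(i, j), max(i, j), sep = "|")

# unique conditioning sets of size l from adj(i)\{j} and adj(j)\{i}
cond_sets <- function(adj_i, adj_j, i, j, l) {
  ci <- setdiff(adj_i, j)
  cj <- setdiff(adj_j, i)
  sets <- list()
  if (l == 0L) return(list(integer()))
  add <- function(from) {
    if (length(from) < l) return(NULL)
    if (length(from) == l) return(list(from))
    utils::combn(from, l, simplify = FALSE)
  }
  sets <- c(add(ci), add(cj))
  if (!length(sets)) return(list())
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","), character(1))
  sets[!duplicated(keys)]
}

# normalize the test argument to a closure (x, y, S) -> p-value
make_ci_fun <- function(x, test) {
  if (is.function(test)) {
    return(function(a, b, S) {
      r <- test(a, b, S, if (inherits(x, "genotype_dataset")) x else NULL)
      if (inherits(r, "ci_test_result")) r$p_value else as.numeric(r)
    })
  }
  if (!inherits(x, "genotype_dataset"))
    stop("a dataset is required unless `test` is an oracle function")
  test <- match.arg(test, c("g2", "symmetric"))
  switch(test,
         g2 = function(a, b, S) ci_test_g2(x, a, b, S)$p_value,
         symmetric = function(a, b, S) ci_test_symmetric(x, a, b, S)$p_value)
}

#' Look up the recorded separating set of a pair
#'
#' @param sepsets a `sepset_table` from [pc_skeleton()].
#' @param a,b node names.
#' @return character vector of conditioning variables, or `NULL` when the
#'   pair was never separated (i.e. remains adjacent).
#' @export
sepset <- function(sepsets, a, b) {
  nodes <- attr(sepsets, "nodes")
  i <- match(a, nodes); j <- match(b, nodes)
  if (anyNA(c(i, j))) stop("unknown node name")
  sepsets[[pair_key(i, j)]]
}

#' Orient v-structures on a skeleton
#'
#' For every unshielded triple `x - y - z` (with `x`, `z` non-adjacent),
#' decides whether the triple is a collider and, if so, orients
#' `x -> y <- z`. Two decision rules are available:
#' \describe{
#'   \item{`"sepset"`}{the collider is declared when `y` is not in the
#'     recorded separating set of `(x, z)` — the textbook rule.}
#'   \item{`"conservative"`}{all separating subsets of the two endpoints'
#'     skeleton adjacencies (up to `max_cond`) are re-examined with the CI
#'     test: the triple is a collider only when `y` appears in none of
#'     them, a non-collider when it appears in all, and is left unoriented
#'     when the evidence is ambiguous. Identical to the sepset rule under a
#'     perfect-oracle test, but far less sensitive to single false
#'     adjacencies on finite data; requires `ci`.}
#' }
#' All orientation demands are collected first; an edge demanded in both
#' directions reverts to undirected (the conflict is logged in the
#' `"orientation_conflicts"` attribute), and an orientation that would
#' close a directed cycle is skipped and logged likewise.
#'
#' @param skeleton a `mixed_graph` with only undirected edges (or the list
#'   returned by [pc_skeleton()]).
#' @param sepsets a `sepset_table`; not needed when `skeleton` is a
#'   `pc_skeleton` result.
#' @param rule `"sepset"` (default) or `"conservative"`.
#' @param ci a function `(x, y, S)` returning a p-value (required for the
#'   conservative rule).
#' @param alpha significance level for the conservative re-examination.
#' @param max_cond largest conditioning-set size re-examined.
#' @return a partially directed `mixed_graph`.
#' @export
orient_v_structures <- function(skeleton, sepsets = NULL,
                                rule = c("sepset", "conservative"),
                                ci = NULL, alpha = 0.005, max_cond = 3L) {
  rule <- match.arg(rule)
  if (inherits(skeleton, "pc_skeleton")) {
    sepsets <- skeleton$sepsets
    skeleton <- skeleton$graph
  }
  if (any(dir_mat(skeleton))) stop("skeleton must contain only undirected edges")
  if (rule == "conservative" && is.null(ci))
    stop("the conservative rule requires a CI test function")
  nodes <- skeleton$nodes
  p <- length(nodes)
  adj <- adj_mat(skeleton)
  demand <- matrix(FALSE, p, p)
  sep_cache <- list()
  pair_sepsets <- function(i, j) {
    key <- pair_key(i, j)
    if (!is.null(sep_cache[[key]])) return(sep_cache[[key]])
    found <- list()
    seen <- character()
    for (l in 0:min(max_cond, p - 2)) {
      for (S in cond_sets(which(adj[i, ]), which(adj[j, ]), i, j, l)) {
        sk <- paste(sort(S), collapse = ",")
        if (sk %in% seen) next
        seen <- c(seen, sk)
        if (ci(nodes[i], nodes[j], nodes[S]) > alpha)
          found[[length(found) + 1L]] <- S
      }
    }
    if (!length(found)) {
      rec <- sepsets[[pair_key(i, j)]]
      found <- list(match(rec, nodes))
    }
    sep_cache[[key]] <<- found
    found
  }
  for (y in seq_len(p)) {
    nb <- which(adj[y, ])
    if (length(nb) < 2) next
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a >= b) next
      xx <- nb[a]; zz <- nb[b]
      if (adj[xx, zz]) next
      collider <- if (rule == "sepset") {
        ss <- sepsets[[pair_key(xx, zz)]]
        !(nodes[y] %in% ss)
      } else {
        seps <- pair_sepsets(xx, zz)
        inct <- vapply(seps, function(S) y %in% S, logical(1))
        !any(inct)  # ambiguous triples (some but not all) stay unoriented
      }
      if (collider) {
        demand[xx, y] <- TRUE
        demand[zz, y] <- TRUE
      }
    }
  }
  resolve_orientations(skeleton, demand)
}

# apply collected orientation demands with conflict + cycle guards
resolve_orientations <- function(g, demand) {
  nodes <- g$nodes
  conflicts <- data.frame(a = character(), b = character(),
                          reason = character(), stringsAsFactors = FALSE)
  idx <- which(demand | t(demand), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    both <- demand[i, j] && demand[j, i]
    if (both) {
      g <- set_edge(g, nodes[i], nodes[j], "undirected")
      conflicts <- rbind(conflicts,
                         data.frame(a = nodes[i], b = nodes[j],
                                    reason = "bidirectional demand"))
      next
    }
    from <- if (demand[i, j]) i else j
    to <- if (demand[i, j]) j else i
    if (has_directed_path(g, to, from)) {
      conflicts <- rbind(conflicts,
                         data.frame(a = nodes[from], b = nodes[to],
                                    reason = "would create directed cycle"))
      next
    }
    g <- set_edge(g, nodes[from], nodes[to], "directed")
  }
  attr(g, "orientation_conflicts") <- conflicts
  g
}

#' Complete a partially directed graph with Meek's rules
#'
#' Applies Meek's orientation rules 1-4 repeatedly until no rule fires,
#' yielding the completed partially directed graph (the CPDAG representative
#' of the equivalence class when the input comes from a sound skeleton and
#' v-structure set). An orientation that would close a directed cycle is
#' never applied.
#'
#' Rules, for an undirected edge `a - b`:
#' 1. some `c -> a` with `c`, `b` non-adjacent  =>  `a -> b`;
#' 2. a directed path `a -> c -> b`  =>  `a -> b`;
#' 3. `a - c`, `a - d`, `c -> b`, `d -> b`, `c`, `d` non-adjacent  =>
#'    `a -> b`;
#' 4. `a - c`, `c -> d`, `d -> b`, `c`, `b` non-adjacent, `a`, `d`
#'    adjacent  =>  `a -> b`.
#'
#' @param pdag a partially directed `mixed_graph`.
#' @return the completed `mixed_graph`.
#' @export
apply_meek_rules <- function(pdag) {
  g <- pdag
  p <- length(g$nodes)
  repeat {
    changed <- FALSE
    und <- und_mat(g); dir <- dir_mat(g); adj <- adj_mat(g)
    pairs <- which(und, arr.ind = TRUE)  # both orientations visited
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (!und_mat(g)[a, b]) next
      fire <-
        any(dir[, a] & !adj[, b] & seq_len(p) != b) ||                  # R1
        any(dir[a, ] & dir[, b]) ||                                     # R2
        meek_r3(und, dir, adj, a, b) ||                                 # R3
        meek_r4(und, dir, adj, a, b)                                    # R4
      if (fire && !has_directed_path(g, b, a)) {
        g <- set_edge(g, g$nodes[a], g$nodes[b], "directed")
        changed <- TRUE
        und <- und_mat(g); dir <- dir_mat(g); adj <- adj_mat(g)
      }
    }
    if (!changed) break
  }
  attr(g, "orientation_conflicts") <- attr(pdag, "orientation_conflicts")
  g
}

meek_r3 <- function(und, dir, adj, a, b) {
  cand <- which(und[a, ] & dir[, b])
  if (length(cand) < 2) return(FALSE)
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    if (i < j && !adj[cand[i], cand[j]]) return(TRUE)
  }
  FALSE
}

meek_r4 <- function(und, dir, adj, a, b) {
  cs <- which(und[a, ] & !adj[, b])
  for (cc in cs) {
    ds <- which(dir[cc, ] & dir[, b] & adj[a, ])
    if (length(ds)) return(TRUE)
  }
  FALSE
}

#' Learn a CPDAG from categorical data
#'
#' Composition of [pc_skeleton()], [orient_v_structures()] and
#' [apply_meek_rules()]; deterministic given the dataset and settings. By
#' default the collider orientation uses the conservative rule (see
#' [orient_v_structures()]), which re-examines every unshielded triple and
#' leaves ambiguous ones unoriented.
#'
#' @inheritParams pc_skeleton
#' @param v_rule collider-decision rule, `"conservative"` (default) or
#'   `"sepset"`.
#' @return a `mixed_graph` with attributes `sepsets`, `n_tests` and
#'   `orientation_conflicts`.
#' @examples
#' sc <- gess_like_scenario(n_snps = 6, n = 400, seed = 1)
#' ds <- simulate_dataset(sc)
#' learn_cpdag(ds)
#' @export
learn_cpdag <- function(x, alpha = 0.005, test = "g2", max_cond = 3L,
                        v_rule = c("conservative", "sepset")) {
  v_rule <- match.arg(v_rule)
  sk <- pc_skeleton(x, alpha = alpha, test = test, max_cond = max_cond)
  g <- orient_v_structures(sk, rule = v_rule,
                           ci = if (v_rule == "conservative")
                             make_ci_fun(x, test),
                           alpha = alpha, max_cond = max_cond)
  g <- apply_meek_rules(g)
  attr(g, "sepsets") <- sk$sepsets
  attr(g, "n_tests") <- sk$n_tests
  g
}

#' CPDAG of a known DAG
#'
#' Builds the Markov-equivalence-class representative of a DAG directly:
#' its skeleton, the v-structures read off the DAG, and the Meek completion.
#'
#' @param dag a directed acyclic `mixed_graph`.
#' @return a `mixed_graph` CPDAG.
#' @export
dag_to_cpdag <- function(dag) {
  d <- dir_mat(dag)
  if (any(und_mat(dag))) stop("input must be fully directed")
  if (!directed_acyclic(dag)) stop("input must be acyclic")
  nodes <- dag$nodes
  p <- length(nodes)
  skel <- mixed_graph(nodes)
  adj <- d | t(d)
  skel$am <- matrix(as.integer(adj), p, p, dimnames = list(nodes, nodes))
  demand <- matrix(FALSE, p, p)
  for (y in seq_len(p)) {
    pa <- which(d[, y])
    if (length(pa) < 2) next
    for (i in seq_along(pa)) for (j in seq_along(pa)) {
      if (i < j && !adj[pa[i], pa[j]]) {
        demand[pa[i], y] <- TRUE
        demand[pa[j], y] <- TRUE
      }
    }
  }
  apply_meek_rules(resolve_orientations(skel, demand))
}

#' Unshielded colliders of a mixed graph
#'
#' @param g a `mixed_graph`.
#' @return data.frame with columns `x`, `y`, `z` (one row per v-structure
#'   `x -> y <- z`, `x` before `z` in node order), in canonical order.
#' @export
v_structures <- function(g) {
  d <- dir_mat(g); adj <- adj_mat(g)
  nodes <- g$nodes
  out <- list()
  for (y in seq_along(nodes)) {
    pa <- which(d[, y])
    if (length(pa) < 2) next
    for (i in seq_along(pa)) for (j in seq_along(pa)) {
      if (i < j && !adj[pa[i], pa[j]])
        out[[length(out) + 1L]] <- c(nodes[pa[i]], nodes[y], nodes[pa[j]])
    }
  }
  if (!length(out))
    return(data.frame(x = character(), y = character(), z = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  df <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
                   stringsAsFactors = FALSE)
  df <- df[order(df$y, df$x, df$z), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Markov blanket of a node in a CPDAG
#'
#' Returns the target's parents, children, undirected neighbours (possible
#' parents or children in some member of the equivalence class), and
#' spouses — other parents of strictly directed children. Never contains
#' the target itself.
#'
#' @param g a `mixed_graph`.
#' @param target node name.
#' @return character vector of node names (possibly empty), sorted in node
#'   order.
#' @export
markov_blanket <- function(g, target) {
  node_index(g, target)
  pa <- graph_parents(g, target)
  ch <- graph_children(g, target)
  nb <- graph_undirected_neighbours(g, target)
  sp <- unlist(lapply(ch, function(c) graph_parents(g, c)))
  mb <- setdiff(unique(c(pa, ch, nb, sp)), target)
  mb[order(match(mb, g$nodes))]
}
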