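#' Round half away from zero
#'
#' Presentation rounding used for every reported percentage: exact halves
#' round up (`round_half_up(85.525, 2)` is `85.53`), unlike base `round()`'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count relative to a reference total
#'
#' @param count numeric count (may be a mean over replicates).
#' @param total reference total; a zero total yields `NA` (undefined), never
#'   0.
#' @param digits decimal places for presentation rounding.
#' @return percentage in `[0, 100]` rounded half-up, or `NA`.
#' @export
pct_of <- function(count, total, digits = 2) {
  total <- rep_len(total, length(count))
  out <- rep(NA_real_, length(count))
  ok <- total > 0
  out[ok] <- round_half_up(100 * count[ok] / total[ok], digits)
  out
}

#' Classify one node pair between a reference and a re-learned graph
#'
#' @param ref,new `mixed_graph`s on the same node set.
#' @param pair character vector of two node names.
#' @return one of `"both-absent"`, `"common-undirected"`,
#'   `"common-directed"`, `"directed-to-undirected"`, `"directed-reversed"`,
#'   `"directed-vanished"`, `"undirected-to-directed"`,
#'   `"undirected-vanished"`, `"edge-appeared"`.
#' @export
classify_pair <- function(ref, new, pair) {
  check_same_nodes(ref, new)
  a <- pair[1]; b <- pair[2]
  rs <- edge_state(ref, a, b)
  ns <- edge_state(new, a, b)
  if (rs$state == "none") {
    return(if (ns$state == "none") "both-absent" else "edge-appeared")
  }
  if (rs$state == "undirected") {
    return(switch(ns$state,
                  undirected = "common-undirected",
                  directed = "undirected-to-directed",
                  none = "undirected-vanished"))
  }
  switch(ns$state,
         none = "directed-vanished",
         undirected = "directed-to-undirected",
         directed = if (identical(rs$from, ns$from)) "common-directed"
                    else "directed-reversed")
}

check_same_nodes <- function(g1, g2) {
  if (!identical(g1$nodes, g2$nodes))
    stop("graphs must share an identical node set")
  invisible(TRUE)
}

#' Structural Hamming distance between two partially directed graphs
#'
#' Counts the operators needed to turn one graph into the other, the
#' operator set being: add or delete an undirected edge; add, remove, or
#' reverse the orientation of an edge. Per node pair the cost is 0 for equal
#' states, 1 for directed-vs-reversed, directed-vs-undirected and
#' undirected-vs-absent, and `directed_absent_cost` (default 2: remove the
#' orientation, then delete the edge) for directed-vs-absent. Symmetric in
#' its arguments.
#'
#' @param g1,g2 `mixed_graph`s on the same node set.
#' @param directed_absent_cost 2 (the literal operator count) or 1 (the
#'   single-operator variant used by some published implementations).
#' @return non-negative integer; 0 exactly when the graphs are equal.
#' @export
structural_hamming_distance <- function(g1, g2, directed_absent_cost = 2) {
  check_same_nodes(g1, g2)
  if (!directed_absent_cost %in% c(1, 2))
    stop("directed_absent_cost must be 1 or 2")
  a1 <- g1$am; a2 <- g2$am
  up <- upper.tri(a1)
  # per-pair state codes: 0 none, 1 undirected, 2 i->j, 3 j->i
  code <- function(am) {
    ij <- am[up]; ji <- t(am)[up]
    ifelse(ij & ji, 1L, ifelse(ij == 1L, 2L, ifelse(ji == 1L, 3L, 0L)))
  }
  c1 <- code(a1); c2 <- code(a2)
  cost <- matrix(c(0, 1, directed_absent_cost, directed_absent_cost,
                   1, 0, 1, 1,
                   directed_absent_cost, 1, 0, 1,
                   directed_absent_cost, 1, 1, 0), 4, 4)
  sum(cost[cbind(c1 + 1L, c2 + 1L)])
}

#' Relative structural Hamming distance
#'
#' Expresses an SHD as a percentage of the largest value it could take if
#' every node-pair relation were altered, with the convention that one
#' alteration per pair is counted: the denominator is `choose(n_nodes, 2)`.
#'
#' @param shd non-negative SHD value (may be a mean over replicates).
#' @param n_nodes number of nodes in the compared graphs (>= 2).
#' @param digits decimal places for presentation rounding.
#' @return percentage.
#' @export
relative_shd <- function(shd, n_nodes, digits = 2) {
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  max_pairs <- choose(n_nodes, 2)
  if (any(shd < 0) || any(shd > 2 * max_pairs))
    stop("shd outside the feasible range for this node count")
  round_half_up(100 * shd / max_pairs, digits)
}

#' Edge-overlap report between a reference and a re-learned structure
#'
#' Tallies, over all node pairs, the undirected edges of the reference that
#' are preserved and the fate of each directed reference edge (preserved,
#' turned undirected, reversed, vanished — a partition of the reference's
#' directed edges), plus the structural Hamming distance and its relative
#' form.
#'
#' @param ref reference `mixed_graph` (the structure learned on the full
#'   dataset).
#' @param new re-learned `mixed_graph` on the same nodes.
#' @param directed_absent_cost passed to [structural_hamming_distance()].
#' @return object of class `edge_overlap`: list of counts
#'   (`common_undirected`, `common_directed`, `directed_to_undirected`,
#'   `directed_reversed`, `directed_vanished`, `undirected_to_directed`,
#'   `undirected_vanished`, `edge_appeared`), reference totals
#'   (`n_undirected_ref`, `n_directed_ref`), `shd` and `relative_shd_pct`.
#' @export
edge_overlap <- function(ref, new, directed_absent_cost = 2) {
  check_same_nodes(ref, new)
  u1 <- und_mat(ref); d1 <- dir_mat(ref)
  u2 <- und_mat(new); d2 <- dir_mat(new)
  up <- upper.tri(u1)
  common_und <- sum(u1 & u2 & up)
  common_dir <- sum(d1 & d2)                       # same head and tail
  dir_to_und <- sum(d1 & u2)                       # u2 is symmetric
  dir_rev <- sum(d1 & t(d2))
  dir_vanished <- sum(d1) - common_dir - dir_to_und - dir_rev
  und_to_dir <- sum(u1 & up & (d2 | t(d2)))
  und_vanished <- sum(u1 & up & !(u2 | d2 | t(d2)))
  appeared <- sum(((u2 & up) | d2) & !(u1 | d1 | t(d1)))
  n_und_ref <- sum(u1 & up)
  n_dir_ref <- sum(d1)
  stopifnot(common_dir + dir_to_und + dir_rev + dir_vanished == n_dir_ref)
  shd <- structural_hamming_distance(ref, new, directed_absent_cost)
  structure(list(common_undirected = common_und,
                 common_directed = common_dir,
                 directed_to_undirected = dir_to_und,
                 directed_reversed = dir_rev,
                 directed_vanished = dir_vanished,
                 undirected_to_directed = und_to_dir,
                 undirected_vanished = und_vanished,
                 edge_appeared = appeared,
                 n_undirected_ref = n_und_ref,
                 n_directed_ref = n_dir_ref,
                 shd = shd,
                 relative_shd_pct = relative_shd(shd, length(ref$nodes))),
            class = "edge_overlap")
}

#' @export
print.edge_overlap <- function(x, ...) {
  cat("edge overlap vs reference:\n")
  cat(sprintf("  undirected: %d of %d in common (%s%%)\n",
              x$common_undirected, x$n_undirected_ref,
              format(pct_of(x$common_undirected, x$n_undirected_ref))))
  cat(sprintf("  directed:   %d of %d in common (%s%%); %d turned undirected, %d reversed, %d vanished\n",
              x$common_directed, x$n_directed_ref,
              format(pct_of(x$common_directed, x$n_directed_ref)),
              x$directed_to_undirected, x$directed_reversed,
              x$directed_vanished))
  cat(sprintf("  SHD %d (relative %.2f%%)\n", x$shd, x$relative_shd_pct))
  invisible(x)
}
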