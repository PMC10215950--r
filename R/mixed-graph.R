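#' Mixed graphs over a fixed node set
#'
#' A `mixed_graph` stores, for every unordered pair of nodes, exactly one of
#' three edge states: absent, undirected, or directed (with a definite head
#' and tail). It is the representation used both for learned CPDAGs (where
#' undirected edges stand for orientations that differ between members of
#' the Markov equivalence class) and for ground-truth DAGs (all edges
#' directed).
#'
#' Internally the graph is a square 0/1 adjacency-mark matrix `am` with
#' `am[i, j] = am[j, i] = 1` for an undirected edge and `am[i, j] = 1`,
#' `am[j, i] = 0` for the directed edge `i -> j`.
#'
#' @param nodes character vector of unique node names.
#' @param directed optional two-column matrix/data.frame of directed edges
#'   (`from`, `to`).
#' @param undirected optional two-column matrix/data.frame of undirected
#'   edges.
#' @return an object of class `mixed_graph`.
#' @examples
#' g <- mixed_graph(c("X", "Y", "Z"),
#'                  directed = cbind("X", "Z"),
#'                  undirected = cbind("Y", "Z"))
#' graph_edges(g)
#' @export
mixed_graph <- function(nodes, directed = NULL, undirected = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node names must be unique")
  p <- length(nodes)
  am <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  g <- structure(list(nodes = nodes, am = am), class = "mixed_graph")
  pair_mat <- function(x) {
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop("edge input must have two columns")
    x
  }
  if (!is.null(directed) && length(directed)) {
    d <- pair_mat(directed)
    for (r in seq_len(nrow(d))) g <- set_edge(g, d[r, 1], d[r, 2], "directed")
  }
  if (!is.null(undirected) && length(undirected)) {
    u <- pair_mat(undirected)
    for (r in seq_len(nrow(u))) g <- set_edge(g, u[r, 1], u[r, 2], "undirected")
  }
  g
}

node_index <- function(g, x) {
  i <- match(x, g$nodes)
  if (anyNA(i)) stop("unknown node(s): ", paste(x[is.na(i)], collapse = ", "))
  i
}

#' @rdname mixed_graph
#' @param g a `mixed_graph`.
#' @export
graph_nodes <- function(g) g$nodes

#' Set the state of one node pair
#'
#' @param g a `mixed_graph`.
#' @param a,b node names; for `state = "directed"` the edge runs `a -> b`.
#' @param state one of `"none"`, `"undirected"`, `"directed"`.
#' @return the modified graph.
#' @export
set_edge <- function(g, a, b, state = c("none", "undirected", "directed")) {
  state <- match.arg(state)
  i <- node_index(g, a); j <- node_index(g, b)
  if (i == j) stop("self-loops are not allowed")
  g$am[i, j] <- g$am[j, i] <- 0L
  if (state == "undirected") g$am[i, j] <- g$am[j, i] <- 1L
  if (state == "directed") g$am[i, j] <- 1L
  g
}

#' Query the state of one node pair
#'
#' @inheritParams set_edge
#' @return a list with `state` (`"none"`, `"undirected"` or `"directed"`)
#'   and, for directed edges, `from`/`to`.
#' @export
edge_state <- function(g, a, b) {
  i <- node_index(g, a); j <- node_index(g, b)
  if (i == j) stop("self-pairs have no edge state")
  ij <- g$am[i, j]; ji <- g$am[j, i]
  if (ij == 1L && ji == 1L) return(list(state = "undirected"))
  if (ij == 1L) return(list(state = "directed", from = g$nodes[i], to = g$nodes[j]))
  if (ji == 1L) return(list(state = "directed", from = g$nodes[j], to = g$nodes[i]))
  list(state = "none")
}

# logical matrices for the two edge kinds
und_mat <- function(g) (g$am == 1L) & (t(g$am) == 1L)
dir_mat <- function(g) (g$am == 1L) & (t(g$am) == 0L)
adj_mat <- function(g) (g$am == 1L) | (t(g$am) == 1L)

#' Edge list of a mixed graph
#'
#' @param g a `mixed_graph`.
#' @return data.frame with columns `from`, `to`, `type` (`"directed"` or
#'   `"undirected"`); undirected edges are listed once with `from` preceding
#'   `to` in node order. Rows are in a canonical order so that equal graphs
#'   produce identical edge lists.
#' @export
graph_edges <- function(g) {
  und <- und_mat(g); dir <- dir_mat(g)
  up <- upper.tri(und)
  ui <- which(und & up, arr.ind = TRUE)
  di <- which(dir, arr.ind = TRUE)
  out <- data.frame(
    from = c(g$nodes[ui[, 1]], g$nodes[di[, 1]]),
    to = c(g$nodes[ui[, 2]], g$nodes[di[, 2]]),
    type = rep(c("undirected", "directed"), c(nrow(ui), nrow(di))),
    stringsAsFactors = FALSE
  )
  out[order(out$type, match(out$from, g$nodes), match(out$to, g$nodes)), ,
      drop = FALSE]
}

#' Edge counts of a mixed graph
#' @param g a `mixed_graph`.
#' @return named integer vector with `undirected` and `directed` counts.
#' @export
edge_counts <- function(g) {
  c(undirected = sum(und_mat(g)) %/% 2L, directed = sum(dir_mat(g)))
}

#' Test two mixed graphs for equality
#'
#' Graphs are equal when they share the same node vector (same order) and
#' every pair has the same edge state.
#' @param g1,g2 `mixed_graph` objects.
#' @return logical scalar.
#' @export
graph_equal <- function(g1, g2) {
  identical(g1$nodes, g2$nodes) && identical(g1$am, g2$am)
}

#' @export
print.mixed_graph <- function(x, ...) {
  ec <- edge_counts(x)
  cat(sprintf("mixed_graph: %d nodes, %d undirected, %d directed edge(s)\n",
              length(x$nodes), ec[["undirected"]], ec[["directed"]]))
  e <- graph_edges(x)
  if (nrow(e)) {
    sym <- ifelse(e$type == "directed", "->", "--")
    cat(paste0("  ", e$from, " ", sym, " ", e$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Parents, children and neighbours in a mixed graph
#'
#' @param g a `mixed_graph`.
#' @param node a node name.
#' @return character vector of node names.
#' @export
graph_parents <- function(g, node) {
  j <- node_index(g, node)
  g$nodes[dir_mat(g)[, j]]
}

#' @rdname graph_parents
#' @export
graph_children <- function(g, node) {
  i <- node_index(g, node)
  g$nodes[dir_mat(g)[i, ]]
}

#' @rdname graph_parents
#' @export
graph_undirected_neighbours <- function(g, node) {
  i <- node_index(g, node)
  g$nodes[und_mat(g)[i, ]]
}

# TRUE if the directed subgraph contains no cycle
directed_acyclic <- function(g) {
  d <- dir_mat(g)
  p <- nrow(d)
  indeg <- colSums(d)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    ch <- which(d[v, ])
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  seen == p
}

# TRUE if a directed path from `from` (index) to `to` (index) exists
has_directed_path <- function(g, from, to) {
  d <- dir_mat(g)
  stack <- from
  seen <- logical(nrow(d))
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(d[v, ] & !seen))
  }
  FALSE
}

#' Serialize a mixed graph to an edge-list text file
#'
#' The format lists every node on its own line (so isolated nodes survive a
#' round trip), followed by one edge per line: `A -> B` for a directed edge
#' and `A -- B` for an undirected one. Lines beginning with `#` are
#' comments. `read_graph(write_graph(g))` recovers `g` exactly.
#'
#' @param g a `mixed_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  e <- graph_edges(g)
  sym <- ifelse(e$type == "directed", "->", "--")
  lines <- c("# causalstab mixed graph",
             g$nodes,
             if (nrow(e)) paste(e$from, sym, e$to))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  nfield <- lengths(toks)
  if (any(!nfield %in% c(1L, 3L)))
    stop("malformed line in graph file: ", lines[which(!nfield %in% c(1L, 3L))[1]])
  nodes <- unlist(toks[nfield == 1L])
  g <- mixed_graph(nodes)
  for (tk in toks[nfield == 3L]) {
    rel <- tk[2]
    if (rel == "->") g <- set_edge(g, tk[1], tk[3], "directed")
    else if (rel == "--") g <- set_edge(g, tk[1], tk[3], "undirected")
    else stop("unknown relation token '", rel, "' in graph file")
  }
  g
}
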