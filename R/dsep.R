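#' d-separation on a directed acyclic graph
#'
#' `dsep()` decides whether `x` and `y` are d-separated given `S` in the DAG
#' `dag`, via the classical reduction: restrict to the ancestors of
#' `{x, y} U S`, moralize (marry parents, drop directions), delete `S`, and
#' test whether `x` and `y` are still connected.
#'
#' @param dag a `mixed_graph` whose edges are all directed and acyclic.
#' @param x,y node names.
#' @param S character vector of conditioning node names.
#' @return logical: `TRUE` if `x` and `y` are d-separated given `S`.
#' @export
dsep <- function(dag, x, y, S = character()) {
  d <- dir_mat(dag)
  if (any(und_mat(dag))) stop("dsep requires a fully directed graph")
  if (!directed_acyclic(dag)) stop("dsep requires an acyclic graph")
  nodes <- dag$nodes
  ix <- node_index(dag, x); iy <- node_index(dag, y)
  iS <- if (length(S)) node_index(dag, S) else integer()
  if (ix == iy) stop("x and y must differ")
  # ancestral set of {x, y} U S
  anc <- rep(FALSE, length(nodes))
  stack <- c(ix, iy, iS)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (anc[v]) next
    anc[v] <- TRUE
    stack <- c(stack, which(d[, v] & !anc))
  }
  keep <- which(anc)
  dk <- d[keep, keep, drop = FALSE]
  # moralize: undirected skeleton + marriages of common parents
  m <- dk | t(dk)
  for (v in seq_along(keep)) {
    pa <- which(dk[, v])
    if (length(pa) > 1) m[pa, pa] <- TRUE
  }
  diag(m) <- FALSE
  # remove S and test connectivity x -- y
  pos <- match(c(ix, iy, iS), keep)
  m[pos[-(1:2)], ] <- FALSE
  m[, pos[-(1:2)]] <- FALSE
  src <- pos[1]; dst <- pos[2]
  seen <- rep(FALSE, nrow(m))
  stack <- src
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == dst) return(FALSE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(m[v, ] & !seen))
  }
  TRUE
}

#' Exact conditional-independence oracle from a known DAG
#'
#' Returns a test function usable wherever the PC search expects a CI test:
#' it reports `p = 1` when the queried pair is d-separated in `dag` and
#' `p = 0` otherwise, so the search recovers exactly the independence model
#' of the DAG regardless of the significance level.
#'
#' @param dag a directed acyclic `mixed_graph`.
#' @return function `(x, y, S, ds)` returning a `ci_test_result`.
#' @export
dsep_oracle <- function(dag) {
  force(dag)
  function(x, y, S = character(), ds = NULL) {
    sep <- dsep(dag, x, y, S)
    structure(list(statistic = if (sep) 0 else Inf,
                   dof = 1, p_value = if (sep) 1 else 0,
                   method = "dsep-oracle"),
              class = "ci_test_result")
  }
}
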