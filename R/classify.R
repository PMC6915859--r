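# Structural predicates: ancestry, incomparability, class membership,
# and the incomparable-edge-pair statistic u(N).

# Reflexive reachability matrix: R[u, v] TRUE iff v is reachable from
# u.  Ancestry is reflexive throughout the package: every node is an
# ancestor of itself (a root-to-v path contains v).
reach_matrix <- function(N) .reach_matrix_cpp(N$edges, N$next_id - 1L)

check_node <- function(N, v) {
  if (length(v) != 1L || !is.numeric(v) || v < 1L || v >= N$next_id ||
      !(v %in% N$edges))
    stop_tcnet("missing_node", sprintf("node %s is not in the network", v))
  as.integer(v)
}

#' Ancestry and incomparability of nodes
#'
#' `is_ancestor(N, u, v)` is TRUE iff some path from the root to `v`
#' contains `u`, i.e. iff `v` is reachable from `u`; ancestry is
#' reflexive, so every node is an ancestor of itself.
#' `incomparable_nodes(N, u, v)` is TRUE iff neither node is an
#' ancestor of the other.
#'
#' @param N A valid `phynet`.
#' @param u,v Node ids.
#' @return Logical scalar.
#' @export
is_ancestor <- function(N, u, v) {
  u <- check_node(N, u)
  v <- check_node(N, v)
  reach_matrix(N)[u, v]
}

#' @rdname is_ancestor
#' @export
incomparable_nodes <- function(N, u, v) {
  u <- check_node(N, u)
  v <- check_node(N, v)
  D <- reach_matrix(N)
  !D[u, v] && !D[v, u]
}

#' Tree-child and normal class membership
#'
#' A network is tree-child iff every non-leaf node has at least one
#' child that is a tree node or a leaf.  It is normal iff it is
#' tree-child and, for every reticulate node, the two parents are
#' incomparable (neither is an ancestor of the other).
#'
#' @param N A valid `phynet`.
#' @return Logical scalar.
#' @examples
#' is_tree_child(base_network(2))
#' @export
is_tree_child <- function(N) {
  check_valid(N, "is_tree_child")
  .is_tree_child(N)
}

.is_tree_child <- function(N) {
  E <- N$edges
  ret <- which(tabulate(E[, 2L], nbins = N$next_id - 1L) == 2L)
  # every edge head that is a tree node or leaf witnesses its parent
  good_parent <- unique(E[!(E[, 2L] %in% ret), 1L])
  all(unique(E[, 1L]) %in% good_parent)
}

#' @rdname is_tree_child
#' @export
is_normal <- function(N) {
  check_valid(N, "is_normal")
  .is_normal(N)
}

.is_normal <- function(N) {
  if (!.is_tree_child(N)) return(FALSE)
  ret <- which(tabulate(N$edges[, 2L], nbins = N$next_id - 1L) == 2L)
  if (length(ret) == 0L) return(TRUE)
  D <- reach_matrix(N)
  for (r in ret) {
    par <- N$edges[N$edges[, 2L] == r, 1L]
    if (D[par[1L], par[2L]] || D[par[2L], par[1L]]) return(FALSE)
  }
  TRUE
}

#' Incomparability of edges and the u(N) statistic
#'
#' Two edges are incomparable iff neither of their head nodes is an
#' ancestor of the other.  Because ancestry is reflexive, an edge is
#' never incomparable with itself, and two reticulate edges entering
#' the same reticulate node are comparable.  `u_of(N)` counts the
#' unordered pairs of distinct incomparable edges over *all* edges of
#' the network (tree and reticulate); the tree-edge-restricted variant
#' used by the normal generation step is [incomparable_tree_edge_pairs()].
#'
#' @param N A valid `phynet`.
#' @param e1,e2 Integer pairs `c(parent, child)`.
#' @return Logical scalar for `edge_incomparable()`, non-negative
#'   integer for `u_of()`.
#' @examples
#' u_of(base_network(2))  # 1: only the two pendant edges qualify
#' @export
edge_incomparable <- function(N, e1, e2) {
  i <- edge_row(N, e1)
  j <- edge_row(N, e2)
  v1 <- N$edges[i, 2L]
  v2 <- N$edges[j, 2L]
  D <- reach_matrix(N)
  !D[v1, v2] && !D[v2, v1]
}

#' @rdname edge_incomparable
#' @export
u_of <- function(N) {
  check_valid(N, "u_of")
  .u_pairs(N, tree_only = FALSE)
}

# Count unordered pairs of distinct incomparable edges; heads compared
# through the reflexive reachability matrix.  With `tree_only`, pairs
# are restricted to tree edges (the insertion sites of the generation
# procedure).
.u_pairs <- function(N, tree_only = FALSE) {
  E <- N$edges
  if (tree_only) {
    ret <- which(tabulate(E[, 2L], nbins = N$next_id - 1L) == 2L)
    E <- E[!(E[, 2L] %in% ret), , drop = FALSE]
  }
  m <- nrow(E)
  if (m < 2L) return(0L)
  D <- reach_matrix(N)
  heads <- E[, 2L]
  cmp <- D[heads, heads, drop = FALSE]  # cmp[i, j]: head i ancestor of head j
  as.integer(sum(!(cmp | t(cmp))) / 2L)
}
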