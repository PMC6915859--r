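# The three generation operations and the reverse reduction.
#
# Leaf insertion subdivides a tree edge and hangs a new labelled leaf
# from the subdivision node.  Reticulation insertion subdivides one or
# two tree edges, makes both subdivision nodes parents of a new
# reticulate node r, and hangs the new leaf from r.  Child rotation at
# a reticulate node r with tree-node parent u (u not an ancestor of
# the other parent) exchanges r's child with u's other child.  Each of
# the three preserves the tree-child property; rotation additionally
# preserves acyclicity under its admissibility condition.

check_tree_edge <- function(N, e, op) {
  i <- edge_row(N, e)
  if (indegree(N)[N$edges[i, 2L]] == 2L)
    stop_tcnet("domain",
               sprintf("%s requires a tree edge; (%d, %d) is reticulate",
                       op, e[1L], e[2L]))
  i
}

check_fresh_taxon <- function(N, taxon) {
  if (!is.numeric(taxon) || length(taxon) != 1L || taxon < 1 ||
      taxon != round(taxon))
    stop_tcnet("label", "taxon must be a positive integer")
  if (any(N$taxon == taxon))
    stop_tcnet("label", sprintf("taxon %d is already a leaf label", taxon))
  as.integer(taxon)
}

#' Leaf insertion
#'
#' Subdivides the tree edge `e` with a fresh node `w` and attaches a
#' new leaf labelled `taxon` below `w`.  The result is valid, has one
#' more leaf and the same number of reticulations, and is tree-child
#' whenever the input is.
#'
#' @param N A `phynet`.
#' @param e A tree edge, as `c(parent, child)`.
#' @param taxon A label not yet present in `N`.
#' @return A `phynet`.
#' @examples
#' leaf_insert(base_network(2), c(1, 2), 3)
#' @export
leaf_insert <- function(N, e, taxon) {
  i <- check_tree_edge(N, e, "leaf_insert")
  taxon <- check_fresh_taxon(N, taxon)
  .leaf_insert_fast(N, i, taxon)
}

.leaf_insert_fast <- function(N, i, taxon) {
  w <- N$next_id
  l <- w + 1L
  E <- rbind(N$edges, c(w, N$edges[i, 2L]), c(w, l))
  E[i, 2L] <- w
  new_phynet(E, c(N$taxon, 0L, taxon), N$root, l + 1L)
}

#' Reticulation insertion
#'
#' Subdivides the tree edges `e1` and `e2` (not necessarily distinct)
#' with fresh nodes `w1` and `w2`, attaches a new reticulate node `r`
#' as the common child of `w1` and `w2`, and makes a new leaf labelled
#' `taxon` the child of `r`; `r` is said to straddle `e1` and `e2`.
#' When `e1 == e2` the two subdivision nodes are nested in the same
#' edge, `w1` above `w2`.  The result is valid, has one more leaf and
#' one more reticulation, and is tree-child whenever the input is.
#'
#' Node ids are allocated deterministically: `w1`, `w2`, `r`, then the
#' leaf.
#'
#' @param N A `phynet`.
#' @param e1,e2 Tree edges, as `c(parent, child)`.
#' @param taxon A label not yet present in `N`.
#' @return A `phynet`.
#' @examples
#' b1 <- base_network(1)
#' ret_insert(b1, c(1, 2), c(1, 2), 2)  # one of the two networks on {1,2} with k = 1
#' @export
ret_insert <- function(N, e1, e2, taxon) {
  i <- check_tree_edge(N, e1, "ret_insert")
  j <- check_tree_edge(N, e2, "ret_insert")
  taxon <- check_fresh_taxon(N, taxon)
  .ret_insert_fast(N, i, j, taxon)
}

.ret_insert_fast <- function(N, i, j, taxon) {
  w1 <- N$next_id
  w2 <- w1 + 1L
  r <- w1 + 2L
  l <- w1 + 3L
  E <- N$edges
  if (i == j) {
    v <- E[i, 2L]
    E <- rbind(E, c(w1, w2), c(w2, v), c(w1, r), c(w2, r), c(r, l))
    E[i, 2L] <- w1
  } else {
    E <- rbind(E, c(w1, E[i, 2L]), c(w2, E[j, 2L]),
               c(w1, r), c(w2, r), c(r, l))
    E[i, 2L] <- w1
    E[j, 2L] <- w2
  }
  new_phynet(E, c(N$taxon, 0L, 0L, 0L, taxon), N$root, l + 1L)
}

#' Child rotation
#'
#' Let `r` be a reticulate node with parents `u` and `v`, where `u` is
#' a tree node that is not an ancestor of `v` (the admissibility
#' condition, checked here rather than trusted).  The rotation
#' exchanges the unique child of `r` with the other child of `u`.  It
#' preserves validity, acyclicity and the tree-child property, and is
#' an involution while it remains admissible.
#'
#' @param N A `phynet`.
#' @param u A tree-node parent of `r`.
#' @param r A reticulate node.
#' @return A `phynet`.
#' @export
c_rotate <- function(N, u, r) {
  u <- check_node(N, u)
  r <- check_node(N, r)
  ind <- indegree(N)
  if (ind[r] != 2L)
    stop_tcnet("domain", sprintf("node %d is not reticulate", r))
  par <- N$edges[N$edges[, 2L] == r, 1L]
  if (!(u %in% par))
    stop_tcnet("domain", sprintf("node %d is not a parent of %d", u, r))
  if (ind[u] != 1L || outdegree(N)[u] != 2L)
    stop_tcnet("domain", sprintf("node %d is not a tree node", u))
  v <- par[par != u][1L]
  if (reach_matrix(N)[u, v])
    stop_tcnet("inadmissible",
               sprintf("rotation at (%d, %d) is inadmissible: %d is an ancestor of the other parent %d",
                       u, r, u, v))
  .c_rotate_fast(N, u, r)
}

.c_rotate_fast <- function(N, u, r) {
  E <- N$edges
  iz <- which(E[, 1L] == r)                    # (r, z)
  iw <- which(E[, 1L] == u & E[, 2L] != r)     # (u, w)
  z <- E[iz, 2L]
  E[iz, 2L] <- E[iw, 2L]
  E[iw, 2L] <- z
  new_phynet(E, N$taxon, N$root, N$next_id)
}

#' Reduce away the largest taxon
#'
#' The reverse of the generation step: classifies how the leaf
#' carrying the largest label was produced and returns the unique
#' predecessor network.
#'
#' * `"ret_parent"`: the leaf's parent is a reticulate node `r`; the
#'   leaf, `r` and `r`'s two parents are removed, restoring one edge
#'   (when the two parents are adjacent) or two edges; the predecessor
#'   has one reticulation and one taxon fewer.
#' * `"tree_parent_tree_sib"`: the leaf's parent is a tree node and
#'   its sibling is a tree node or leaf; the leaf is deleted and the
#'   parent smoothed; the predecessor has one taxon fewer.
#' * `"tree_parent_ret_sib"`: the sibling is a reticulate node `y`;
#'   the inverse child rotation at `(t, y)` is applied (after which
#'   the leaf hangs from `y`) and the reticulation case is taken; the
#'   recursion depth is at most two, which is asserted.
#'
#' @param N A tree-child `phynet`.
#' @param taxon The largest leaf label of `N`.
#' @return A list with elements `case` (one of the three strings
#'   above) and `net` (the predecessor `phynet`).
#' @export
reduce_last <- function(N, taxon) {
  if (!is_tree_child(N))
    stop_tcnet("contract", "reduce_last requires a tree-child network")
  if (!any(N$taxon == taxon) || taxon != max(N$taxon))
    stop_tcnet("missing_taxon",
               sprintf("taxon %s is not the largest leaf label", taxon))
  res <- .reduce_last_step(N, as.integer(taxon), depth = 1L)
  res
}

.reduce_last_step <- function(N, taxon, depth) {
  stopifnot(depth <= 2L)  # one inverse rotation always exposes a reticulate parent
  l <- which(N$taxon == taxon)
  p <- N$edges[N$edges[, 2L] == l, 1L]
  ind <- indegree(N)
  if (ind[p] == 2L) {
    list(case = "ret_parent", net = .remove_reticulation(N, l, p))
  } else {
    sib <- setdiff(N$edges[N$edges[, 1L] == p, 2L], l)
    if (ind[sib] == 2L) {
      M <- .c_rotate_fast(N, p, sib)
      res <- .reduce_last_step(M, taxon, depth + 1L)
      list(case = "tree_parent_ret_sib", net = res$net)
    } else {
      list(case = "tree_parent_tree_sib", net = delete_leaf_smooth(N, taxon))
    }
  }
}

# Remove leaf l, its reticulate parent r and r's two parents,
# restoring the straddled edge(s).
.remove_reticulation <- function(N, l, r) {
  E <- N$edges
  par <- E[E[, 2L] == r, 1L]  # u1, u2: tree nodes
  u1 <- par[1L]
  u2 <- par[2L]
  other_child <- function(u) setdiff(E[E[, 1L] == u, 2L], r)
  parent_of <- function(u) E[E[, 2L] == u, 1L]
  drop <- c(l, r, u1, u2)
  keep <- !(E[, 1L] %in% drop | E[, 2L] %in% drop)
  if (other_child(u1) == u2) {         # adjacent parents, u1 above u2
    add <- rbind(c(parent_of(u1), other_child(u2)))
  } else if (other_child(u2) == u1) {
    add <- rbind(c(parent_of(u2), other_child(u1)))
  } else {
    add <- rbind(c(parent_of(u1), other_child(u1)),
                 c(parent_of(u2), other_child(u2)))
  }
  taxon2 <- N$taxon
  taxon2[l] <- 0L
  M <- new_phynet(rbind(E[keep, , drop = FALSE], add), taxon2, N$root,
                  N$next_id)
  if (anyDuplicated(M$edges) > 0L)
    stop_tcnet("structural",
               "reticulation removal would create a parallel edge")
  M
}
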