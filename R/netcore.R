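# The network data structure and elementary graph surgery.
#
# A "phynet" is a rooted binary leaf-labelled DAG:
#   * a unique indegree-0 node, the root, of outdegree 1;
#   * leaves of indegree 1 and outdegree 0, labelled bijectively 1..n;
#   * internal non-root nodes are tree nodes (in 1, out 2) or
#     reticulate nodes (in 2, out 1);
#   * acyclic, no parallel edges.
#
# Nodes are opaque integer ids allocated by a per-network monotone
# counter (`next_id`); ids may have gaps after deletions.  Edges are
# rows of an m x 2 integer matrix (parent, child).  `taxon` is indexed
# by node id, 0 meaning unlabelled.

new_phynet <- function(edges, taxon, root, next_id) {
  structure(
    list(edges = edges, taxon = as.integer(taxon), root = as.integer(root),
         next_id = as.integer(next_id)),
    class = "phynet"
  )
}

#' Base networks for the generation procedure
#'
#' Returns the unique phylogenetic tree on one taxon (root and one
#' leaf) or on two taxa (root, one internal tree node, two leaves).
#' All trees, tree-child networks and normal networks on more taxa are
#' generated from these by leaf insertion and reticulation insertion.
#'
#' @param n_taxa 1 or 2.
#' @return A `phynet` object.
#' @examples
#' base_network(2)
#' @export
base_network <- function(n_taxa) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || !(n_taxa %in% c(1, 2)))
    stop_tcnet("parameter", "n_taxa must be 1 or 2")
  if (n_taxa == 1) {
    new_phynet(matrix(c(1L, 2L), 1L, 2L), c(0L, 1L), 1L, 3L)
  } else {
    new_phynet(rbind(c(1L, 2L), c(2L, 3L), c(2L, 4L)),
               c(0L, 0L, 1L, 2L), 1L, 5L)
  }
}

#' @export
print.phynet <- function(x, ...) {
  n <- n_taxa(x)
  k <- length(reticulate_nodes(x))
  cat(sprintf("phylogenetic network: %d taxa, %d reticulation%s, %d edges\n",
              n, k, if (k == 1) "" else "s", nrow(x$edges)))
  cat(" ", write_enewick(x), "\n", sep = "")
  invisible(x)
}

# -- accessors ---------------------------------------------------------

node_ids <- function(N) sort(unique(as.vector(N$edges)))

indegree <- function(N) tabulate(N$edges[, 2L], nbins = N$next_id - 1L)

outdegree <- function(N) tabulate(N$edges[, 1L], nbins = N$next_id - 1L)

#' Node and edge accessors
#'
#' `leaves()` returns the labelled nodes, `reticulate_nodes()` the
#' indegree-2 nodes, `tree_nodes()` the indegree-1/outdegree-2 nodes.
#' `tree_edges()` returns the edges whose head is a tree node or a
#' leaf, `reticulate_edges()` those whose head is a reticulate node,
#' each as an m x 2 matrix of (parent, child) node ids.  A tree-child
#' network with n leaves and k reticulations has 2n + k - 1 tree edges.
#'
#' @param N A `phynet`.
#' @return An integer vector of node ids, or an m x 2 integer matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
leaves <- function(N) which(N$taxon > 0L)

#' @rdname accessors
#' @export
reticulate_nodes <- function(N) which(indegree(N) == 2L)

#' @rdname accessors
#' @export
tree_nodes <- function(N) which(indegree(N) == 1L & outdegree(N) == 2L)

#' @rdname accessors
#' @export
tree_edges <- function(N) {
  ret <- reticulate_nodes(N)
  N$edges[!(N$edges[, 2L] %in% ret), , drop = FALSE]
}

#' @rdname accessors
#' @export
reticulate_edges <- function(N) {
  ret <- reticulate_nodes(N)
  N$edges[N$edges[, 2L] %in% ret, , drop = FALSE]
}

#' @rdname accessors
#' @export
n_taxa <- function(N) sum(N$taxon > 0L)

#' @rdname accessors
#' @export
n_reticulations <- function(N) length(reticulate_nodes(N))

edge_row <- function(N, e) {
  if (length(e) != 2L)
    stop_tcnet("parameter", "an edge must be a (parent, child) pair")
  i <- which(N$edges[, 1L] == e[1L] & N$edges[, 2L] == e[2L])
  if (length(i) == 0L)
    stop_tcnet("missing_edge",
               sprintf("edge (%d, %d) is not in the network", e[1L], e[2L]))
  i[1L]
}

# -- validation --------------------------------------------------------

#' Validate a network
#'
#' Checks all structural invariants and returns a character vector of
#' violation descriptions, empty if and only if the network is valid:
#' a unique indegree-0 root of outdegree 1; labelled nodes of indegree
#' 1 and outdegree 0 with labels a bijection with 1..n; all other
#' non-root nodes tree nodes (in 1, out 2) or reticulate nodes (in 2,
#' out 1); acyclicity; no parallel edges.
#'
#' @param N A `phynet`.
#' @return Character vector of violations (empty when valid).
#' @examples
#' validate_network(base_network(2))
#' @export
validate_network <- function(N) {
  out <- character(0)
  E <- N$edges
  if (!is.matrix(E) || ncol(E) != 2L || nrow(E) < 1L)
    return("edge set must be a non-empty m x 2 matrix")
  if (any(E < 1L) || any(E >= N$next_id))
    return("edge endpoints outside the allocated id range")
  if (anyDuplicated(E) > 0L)
    out <- c(out, "parallel edges present")
  if (any(E[, 1L] == E[, 2L]))
    out <- c(out, "self-loop present")
  ind <- indegree(N)
  outd <- outdegree(N)
  act <- ind + outd > 0L
  roots <- which(act & ind == 0L)
  if (length(roots) != 1L) {
    out <- c(out, sprintf("expected exactly one indegree-0 node, found %d",
                          length(roots)))
  } else {
    if (roots != N$root)
      out <- c(out, "recorded root is not the indegree-0 node")
    if (outd[roots] != 1L)
      out <- c(out, "root must have outdegree 1")
  }
  lab <- which(N$taxon > 0L & act)
  labs <- sort(N$taxon[lab])
  if (!identical(labs, seq_len(length(labs))))
    out <- c(out, "leaf labels are not a bijection with 1..n")
  bad <- lab[ind[lab] != 1L | outd[lab] != 0L]
  if (length(bad))
    out <- c(out, "a labelled node is not of indegree 1 and outdegree 0")
  internal <- which(act & N$taxon == 0L)
  internal <- setdiff(internal, roots)
  degsig <- paste(ind[internal], outd[internal])
  bad <- internal[!(degsig %in% c("1 2", "2 1"))]
  if (length(bad))
    out <- c(out, sprintf(
      "node %s is neither a tree node (in 1, out 2) nor a reticulate node (in 2, out 1)",
      paste(bad, collapse = ", ")))
  # acyclicity by Kahn's algorithm
  pend <- ind
  q <- which(act & pend == 0L)
  seen <- 0L
  while (length(q)) {
    v <- q[[1L]]
    q <- q[-1L]
    seen <- seen + 1L
    kids <- E[E[, 1L] == v, 2L]
    for (w in kids) {
      pend[w] <- pend[w] - 1L
      if (pend[w] == 0L) q <- c(q, w)
    }
  }
  if (seen != sum(act))
    out <- c(out, "the digraph contains a directed cycle")
  out
}

check_valid <- function(N, where) {
  v <- validate_network(N)
  if (length(v))
    stop_tcnet("contract",
               sprintf("%s requires a valid network: %s", where, v[[1L]]))
  invisible(N)
}

# -- elementary surgery ------------------------------------------------

#' Subdivide an edge
#'
#' Replaces edge `e = (u, v)` by `(u, w), (w, v)` with a fresh node
#' `w`.  The returned network is transiently invalid (`w` has indegree
#' 1 and outdegree 1); callers must immediately attach a second child
#' or a second parent to `w`.  Used internally by the insertion
#' operations.
#'
#' @param N A `phynet`.
#' @param e Integer pair `c(parent, child)`; must be an edge of `N`.
#' @return A list with elements `net` (the new network) and `node`
#'   (the id of `w`).
#' @export
subdivide <- function(N, e) {
  i <- edge_row(N, e)
  w <- N$next_id
  E <- rbind(N$edges, c(w, N$edges[i, 2L]))
  E[i, 2L] <- w
  list(net = new_phynet(E, c(N$taxon, 0L), N$root, w + 1L), node = w)
}

#' Delete a leaf and smooth its parent
#'
#' Removes the leaf carrying `taxon` together with its parent, joining
#' the parent's former neighbours by a new edge.  If the parent is a
#' reticulate node, or if smoothing would create a parallel edge, a
#' structural error is signalled rather than silently merging (such
#' cases must be handled by the reticulation-removal reduction
#' instead, see [reduce_last()]).
#'
#' @param N A `phynet`.
#' @param taxon A leaf label present in `N`.
#' @return A `phynet`.
#' @export
delete_leaf_smooth <- function(N, taxon) {
  l <- which(N$taxon == taxon)
  if (length(l) != 1L)
    stop_tcnet("missing_taxon", sprintf("taxon %s is not a leaf label", taxon))
  p <- N$edges[N$edges[, 2L] == l, 1L]
  ind <- indegree(N)
  if (ind[p] == 2L)
    stop_tcnet("structural",
               "the leaf's parent is reticulate; smoothing would leave an invalid node")
  if (p == N$root)
    stop_tcnet("structural", "cannot remove the only leaf below the root")
  u <- N$edges[N$edges[, 2L] == p, 1L]
  v <- setdiff(N$edges[N$edges[, 1L] == p, 2L], l)
  if (any(N$edges[, 1L] == u & N$edges[, 2L] == v))
    stop_tcnet("structural",
               "smoothing would create a parallel edge")
  keep <- !(N$edges[, 1L] %in% c(p) | N$edges[, 2L] %in% c(l, p))
  E <- rbind(N$edges[keep, , drop = FALSE], c(u, v))
  taxon2 <- N$taxon
  taxon2[l] <- 0L
  new_phynet(E, taxon2, N$root, N$next_id)
}

#' Copy a network with fresh node ids
#'
#' Returns a network isomorphic to `N` whose nodes are renumbered
#' 1..|V| by a deterministic structure-preserving map (sorted original
#' ids), so the copy shares no node ids with networks derived from a
#' different allocation history.
#'
#' @param N A `phynet`.
#' @return A `phynet`.
#' @export
copy_network <- function(N) {
  ids <- node_ids(N)
  map <- integer(N$next_id - 1L)
  map[ids] <- seq_along(ids)
  E <- N$edges
  E[] <- map[E]
  taxon <- integer(length(ids))
  taxon[map[ids]] <- N$taxon[ids]
  new_phynet(E, taxon, map[N$root], length(ids) + 1L)
}
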