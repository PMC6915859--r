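# Leaf-label-preserving isomorphism and canonical codes.

#' Leaf-label-preserving isomorphism
#'
#' TRUE iff there is a bijection between the node sets that preserves
#' directed edges and maps every labelled leaf to the leaf with the
#' same label.  Computed by backtracking seeded with the forced
#' root/leaf correspondence, pruned only by indegree/outdegree
#' signatures — deliberately independent of [canonical_code()], so the
#' two can certify each other.
#'
#' @param N1,N2 Valid `phynet` objects.
#' @return Logical scalar.
#' @examples
#' are_isomorphic(base_network(2), copy_network(base_network(2)))
#' @export
are_isomorphic <- function(N1, N2) {
  check_valid(N1, "are_isomorphic")
  check_valid(N2, "are_isomorphic")
  .iso_cpp(N1$edges, N1$taxon, N2$edges, N2$taxon)
}

#' Canonical code of a tree-child network
#'
#' A total-order key that is identical for isomorphic networks: the
#' sorted multiset of per-node path-count vectors (the number of
#' directed paths from each node to each labelled leaf), concatenated
#' with the sorted multiset of per-edge vector pairs.  Path-count
#' vectors are invariant under any leaf-label-preserving isomorphism,
#' so equal networks always receive equal codes; that *distinct*
#' tree-child networks receive distinct codes is certified empirically
#' against [are_isomorphic()] in the test suite rather than assumed.
#' Codes are only certified for tree-child inputs, hence other classes
#' are rejected.
#'
#' @param N A valid tree-child `phynet`.
#' @return A character scalar.
#' @export
canonical_code <- function(N) {
  check_valid(N, "canonical_code")
  if (!.is_tree_child(N))
    stop_tcnet("unsupported_class",
               "canonical codes are only certified for tree-child networks")
  .canon_code_cpp(N$edges, N$taxon, n_taxa(N))
}
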