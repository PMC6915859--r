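# Isomorphism-free exhaustive generation of phylogenetic trees,
# tree-child networks (TCNs) and normal networks.
#
# Networks with k reticulations on {1..n} are generated bottom-up from
# the one-taxon base tree: level (n', k') is obtained from level
# (n'-1, k') by inserting Leaf n' into every tree edge, and from level
# (n'-1, k'-1) by inserting a reticulate node (with the new leaf as
# its child) into every single tree edge and every unordered pair of
# tree edges, followed by every admissible child rotation at the two
# inserted parents.  Unique generation guarantees each network is
# emitted exactly once; `dedup_verify` certifies this with a
# canonical-code pass.
#
# For the normal class, reticulations are inserted only into
# incomparable pairs of distinct tree edges, and a rotation is skipped
# whenever the pre-insertion network contains a reticulate edge (x, y)
# with y below the rotated head v_i, x not an ancestor of v_i, and x
# an ancestor of the other head v_j (the exclusion condition that
# protects the normal condition of existing reticulations).

# -- per-parent expansion ---------------------------------------------

# Emit all children of N reachable by inserting leaf `new_taxon` into
# every tree edge.  emit(child, op, rows, rotated)
.expand_leaf <- function(N, new_taxon, emit) {
  ret <- which(tabulate(N$edges[, 2L], nbins = N$next_id - 1L) == 2L)
  te <- which(!(N$edges[, 2L] %in% ret))
  for (i in te) emit(.leaf_insert_fast(N, i, new_taxon), "leaf_insert", i, 0L)
  invisible(NULL)
}

# Emit all children of N reachable by a reticulation insertion plus
# admissible rotations.  `normal` switches to the restricted scheme.
.expand_ret <- function(N, new_taxon, emit, normal = FALSE) {
  E <- N$edges
  maxid <- N$next_id - 1L
  ret <- which(tabulate(E[, 2L], nbins = maxid) == 2L)
  te <- which(!(E[, 2L] %in% ret))
  D <- .reach_matrix_cpp(E, maxid)
  RE <- E[E[, 2L] %in% ret, , drop = FALSE]  # reticulate edges (x, y) of N
  nt <- length(te)
  m <- nrow(E)
  w1 <- N$next_id
  w2 <- w1 + 1L
  r <- w1 + 2L
  l <- w1 + 3L

  rot1 <- function(M0, v1) {  # make v1 the child of r, leaf the child of w1
    EM <- M0$edges
    EM[m + 1L, 2L] <- l
    EM[m + 5L, 2L] <- v1
    new_phynet(EM, M0$taxon, M0$root, M0$next_id)
  }
  rot2 <- function(M0, v2, same) {
    EM <- M0$edges
    EM[m + 2L, 2L] <- l
    EM[m + 5L, 2L] <- v2
    new_phynet(EM, M0$taxon, M0$root, M0$next_id)
  }

  if (!normal) {
    for (a in seq_len(nt)) {
      i <- te[a]
      # same-edge straddle: only the rotation at the lower parent w2 is
      # admissible (w1 is an ancestor of w2)
      M0 <- .ret_insert_fast(N, i, i, new_taxon)
      emit(M0, "ret_insert", c(i, i), 0L)
      emit(rot2(M0, E[i, 2L], TRUE), "ret_insert_rotated_2", c(i, i), 2L)
      if (a < nt) for (b in (a + 1L):nt) {
        j <- te[b]
        u1 <- E[i, 1L]; v1 <- E[i, 2L]
        u2 <- E[j, 1L]; v2 <- E[j, 2L]
        M0 <- .ret_insert_fast(N, i, j, new_taxon)
        emit(M0, "ret_insert", c(i, j), 0L)
        # rotation at w_a admissible iff w_a is not an ancestor of the
        # other inserted parent, i.e. iff v_a is not an ancestor of u_b
        if (!D[v1, u2]) emit(rot1(M0, v1), "ret_insert_rotated_1", c(i, j), 1L)
        if (!D[v2, u1]) emit(rot2(M0, v2, FALSE), "ret_insert_rotated_2", c(i, j), 2L)
      }
    }
  } else {
    nre <- nrow(RE)
    # Rotation making v_i the child of r is excluded iff some
    # reticulate edge (x, y) of the pre-insertion network has y below
    # v_i, x not an ancestor of v_i, and x a *proper* ancestor of the
    # other head v_j (equivalently, an ancestor of its tail: v_j has
    # indegree 1).  With x = v_j itself the rotation is harmless — x
    # stays below the subdivision node of e_j and gains no new
    # descendants — and excluding it would lose normal networks
    # (certified by cross_validate_normal against the filtered
    # tree-child route).
    blocked <- function(vi, vj) {
      if (nre == 0L) return(FALSE)
      for (q in seq_len(nre)) {
        x <- RE[q, 1L]; y <- RE[q, 2L]
        if (x != vj && D[vi, y] && !D[x, vi] && D[x, vj]) return(TRUE)
      }
      FALSE
    }
    if (nt >= 2L) for (a in seq_len(nt - 1L)) {
      i <- te[a]
      for (b in (a + 1L):nt) {
        j <- te[b]
        v1 <- E[i, 2L]; v2 <- E[j, 2L]
        if (D[v1, v2] || D[v2, v1]) next  # only incomparable pairs
        M0 <- .ret_insert_fast(N, i, j, new_taxon)
        emit(M0, "ret_insert", c(i, j), 0L)
        if (!blocked(v1, v2)) emit(rot1(M0, v1), "ret_insert_rotated_1", c(i, j), 1L)
        if (!blocked(v2, v1)) emit(rot2(M0, v2, FALSE), "ret_insert_rotated_2", c(i, j), 2L)
      }
    }
  }
  invisible(NULL)
}

# -- level engine ------------------------------------------------------

# Expand a full (n', k') level.  `parents_same_k` is the (n'-1, k')
# level, `parents_km1` the (n'-1, k'-1) level (either may be NULL).
# sink(net, parent_route, parent_idx, op, rows, rotated)
.expand_level <- function(parents_same_k, parents_km1, new_taxon, normal,
                          sink) {
  if (!is.null(parents_same_k)) {
    for (pi in seq_along(parents_same_k)) {
      .expand_leaf(parents_same_k[[pi]], new_taxon,
                   function(net, op, rows, rot)
                     sink(net, "leaf", pi, op, rows, rot))
    }
  }
  if (!is.null(parents_km1)) {
    for (pi in seq_along(parents_km1)) {
      .expand_ret(parents_km1[[pi]], new_taxon,
                  function(net, op, rows, rot)
                    sink(net, "ret", pi, op, rows, rot),
                  normal = normal)
    }
  }
  invisible(NULL)
}

.sorted_by_code <- function(nets, n) {
  if (length(nets) <= 1L) return(nets)
  codes <- vapply(nets, function(N) .canon_code_cpp(N$edges, N$taxon, n), "")
  nets[order(codes, method = "radix")]
}

# Run the generation lattice up to (n, k) and stream the final level
# into `sink(net, route, parent_idx, op, rows, rotated)`.  Intermediate
# levels are materialised and sorted by canonical code so that
# emission order is reproducible and independent of the target.
# Returns the list of parent levels used for the final step (for
# provenance checks).
.enum_core <- function(n, k, net_class = c("tcn", "normal"), sink) {
  net_class <- match.arg(net_class)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop_tcnet("parameter", "n must be a positive integer")
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > n - 1 ||
      k != round(k))
    stop_tcnet("parameter", "k must satisfy 0 <= k <= n - 1")
  n <- as.integer(n)
  k <- as.integer(k)
  normal <- net_class == "normal"
  if (n == 1L) {
    sink(base_network(1), "base", 0L, "base", 0L, 0L)
    return(invisible(list()))
  }
  # ks needed at taxa count n' so that (n, k) is reachable
  needed <- function(np) {
    lo <- max(0L, k - (n - np))
    hi <- min(k, np - 1L)
    if (lo > hi) integer(0) else lo:hi
  }
  levels <- list(`0` = list(base_network(1)))
  for (np in 2:n) {
    ks <- needed(np)
    final <- np == n
    nxt <- list()
    for (kp in ks) {
      same_k <- levels[[as.character(kp)]]
      km1 <- levels[[as.character(kp - 1L)]]
      if (final) {
        .expand_level(same_k, km1, np, normal, sink)
      } else {
        acc <- collector()
        .expand_level(same_k, km1, np, normal,
                      function(net, route, pi, op, rows, rot) acc$add(net))
        nxt[[as.character(kp)]] <- .sorted_by_code(acc$get(), np)
      }
    }
    if (!final) levels <- nxt
  }
  invisible(list(same_k = levels[[as.character(k)]],
                 km1 = levels[[as.character(k - 1L)]]))
}

# growing list collector (amortised append)
collector <- function() {
  buf <- vector("list", 64L)
  i <- 0L
  list(
    add = function(x) {
      i <<- i + 1L
      if (i > length(buf)) length(buf) <<- 2L * length(buf)
      buf[[i]] <<- x
    },
    get = function() buf[seq_len(i)],
    n = function() i
  )
}

# -- public API --------------------------------------------------------

#' Exhaustively enumerate networks without duplicates
#'
#' `enumerate_trees(n)` yields the (2n-3)!! phylogenetic trees on
#' {1..n}; `enumerate_tcn(n, k)` every tree-child network with `k`
#' reticulations on {1..n} exactly once; `enumerate_normal(n, k)`
#' every normal network.  Generation is bottom-up by leaf insertion
#' and reticulation insertion (plus admissible child rotations);
#' uniqueness is a consequence of the unique-generation theorems and
#' can be certified at run time with `dedup_verify = TRUE`, which
#' asserts that all canonical codes are distinct.
#'
#' @param n Number of taxa (>= 1).
#' @param k Number of reticulations, `0 <= k <= n - 1`.
#' @param count_only If TRUE, return the count instead of the
#'   networks (every network is still constructed, just not stored).
#' @param dedup_verify If TRUE, assert that no two emitted networks
#'   are isomorphic (canonical-code pass).
#' @param sink Optional callback `function(net)` consuming networks as
#'   they are produced (memory-light streaming); when supplied the
#'   return value is the count.
#' @return A list of `phynet` objects, or a count.
#' @examples
#' length(enumerate_tcn(3, 1))     # 21
#' length(enumerate_normal(3, 1))  # 3
#' @export
enumerate_tcn <- function(n, k, count_only = FALSE, dedup_verify = FALSE,
                          sink = NULL) {
  .enumerate_class(n, k, "tcn", count_only, dedup_verify, sink)
}

#' @rdname enumerate_tcn
#' @export
enumerate_normal <- function(n, k, count_only = FALSE, dedup_verify = FALSE,
                             sink = NULL) {
  .enumerate_class(n, k, "normal", count_only, dedup_verify, sink)
}

#' @rdname enumerate_tcn
#' @export
enumerate_trees <- function(n, count_only = FALSE) {
  .enumerate_class(n, 0L, "tcn", count_only, FALSE, NULL)
}

.enumerate_class <- function(n, k, net_class, count_only, dedup_verify,
                             sink) {
  cnt <- 0L
  codes <- if (dedup_verify) collector()
  out <- if (is.null(sink) && !count_only) collector()
  .enum_core(n, k, net_class, function(net, route, pi, op, rows, rot) {
    cnt <<- cnt + 1L
    if (dedup_verify)
      codes$add(.canon_code_cpp(net$edges, net$taxon, n))
    if (!is.null(sink)) sink(net) else if (!count_only) out$add(net)
  })
  if (dedup_verify) {
    cc <- unlist(codes$get())
    if (anyDuplicated(cc) > 0L)
      stop_tcnet("contract",
                 "duplicate networks detected by the canonical-code pass")
  }
  if (is.null(sink) && !count_only) out$get() else cnt
}

#' Incomparable pairs of tree edges
#'
#' All unordered pairs of distinct tree edges whose heads are
#' incomparable — the insertion sites of the normal generation step.
#'
#' @param N A valid `phynet`.
#' @return A list of 2x2 matrices, each holding one pair of edges as
#'   rows `(parent, child)`.
#' @export
incomparable_tree_edge_pairs <- function(N) {
  check_valid(N, "incomparable_tree_edge_pairs")
  TE <- tree_edges(N)
  m <- nrow(TE)
  if (m < 2L) return(list())
  D <- reach_matrix(N)
  out <- list()
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    v1 <- TE[a, 2L]
    v2 <- TE[b, 2L]
    if (!D[v1, v2] && !D[v2, v1])
      out[[length(out) + 1L]] <- TE[c(a, b), , drop = FALSE]
  }
  out
}

#' Cross-validate the two normal enumeration routes
#'
#' Checks that filtering the tree-child enumeration through
#' [is_normal()] gives the same set of networks, up to isomorphism, as
#' the direct normal enumeration — certifying the rotation-exclusion
#' conditions of the normal generation scheme.
#'
#' @param n,k As in [enumerate_tcn()]; intended for small `n`
#'   (exhaustive enumeration on both sides).
#' @return TRUE or FALSE.
#' @export
cross_validate_normal <- function(n, k) {
  codes_a <- collector()
  enumerate_tcn(n, k, sink = function(net)
    if (.is_normal(net)) codes_a$add(.canon_code_cpp(net$edges, net$taxon, n)))
  codes_b <- collector()
  enumerate_normal(n, k, sink = function(net)
    codes_b$add(.canon_code_cpp(net$edges, net$taxon, n)))
  a <- sort(unlist(codes_a$get()) %||% character(0))
  b <- sort(unlist(codes_b$get()) %||% character(0))
  identical(a, b)
}
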