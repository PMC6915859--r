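# Exact counting: recurrences and closed forms.
#
# Notation (all counts exact integers):
#   a(n, k)  tree-child networks with k reticulations on {1..n}
#   b(n, k)  normal networks with k reticulations on {1..n}
#   u(n, k)  total number of unordered incomparable edge pairs over
#            all tree-child networks with k reticulations on {1..n}
#   c(n)     total number of unordered comparable edge pairs over all
#            phylogenetic trees on {1..n}
#
# The master recurrence is
#   a(n, k) = (2n+k-3) { a(n-1, k) + (2n+k-4) a(n-1, k-1) } + u(n-1, k-1)
# with a(1, 0) = a(2, 0) = 1: a tree-child network with k
# reticulations on n-1 taxa has 2n+k-4 tree edges; each single edge or
# unordered pair of tree edges admits a reticulation insertion, every
# insertion admits exactly one admissible child rotation except
# incomparable pairs, which admit two — whence the u term.
#
# For k = 1 the u term is over trees and has the closed form
#   u(n, 0) = (n+1) (2n-1)!! - 2^n n!,
# obtained from the comparable-pair recurrence
#   c(n) = 2n c(n-1) + 2 (2n-3)!!,  c(2) = 2,
# whose terminal form is c(n) = 2^n n! - 2 (2n-1)!!.  This yields
# closed forms for one reticulation:
#   a(n, 1) = n (2n-1)!! - 2^(n-1) n!
#   b(n, 1) = (n+2) (2n-1)!! - 3 * 2^(n-1) n!
# and the normal recurrence b(n, 1) = (2n-2) b(n-1, 1) + 3 u(n-1, 0).

#' Number of phylogenetic trees
#'
#' The number of rooted binary phylogenetic trees on `n` labelled
#' taxa, `(2n - 3)!!`.
#'
#' @param n Number of taxa (>= 1).
#' @return A [bigint()].
#' @export
trees_count <- function(n) {
  if (n < 1) stop_tcnet("parameter", "n must be >= 1")
  if (n <= 2) return(bigint(1))
  big_double_factorial_odd(2 * n - 3)
}

#' Closed forms and recurrences for incomparable/comparable edge pairs
#'
#' `u_trees_closed(n)` is the total number of unordered pairs of
#' incomparable edges summed over all phylogenetic trees on `n` taxa,
#' `(n+1)(2n-1)!! - 2^n n!`.  `c_trees(n)` is the complementary total
#' of comparable pairs, evaluated by the recurrence
#' `c(n) = 2n c(n-1) + 2 (2n-3)!!` from `c(2) = 2`;
#' `c_trees_closed(n)` is its terminal form `2^n n! - 2 (2n-1)!!`.
#' Since every tree on `n` taxa has `2n - 1` edges, the two totals add
#' up to `(2n-3)!! * choose(2n-1, 2)`.
#'
#' @param n Number of taxa (>= 2 for the `c` forms, >= 1 for `u`).
#' @return A [bigint()].
#' @examples
#' as.numeric(u_trees_closed(4))  # 141
#' @export
u_trees_closed <- function(n) {
  if (n < 1) stop_tcnet("parameter", "n must be >= 1")
  if (n == 1) return(bigint(0))
  big_sub(big_mul(bigint(n + 1), big_double_factorial_odd(2 * n - 1)),
          big_mul(big_pow2(n), big_factorial(n)))
}

#' @rdname u_trees_closed
#' @export
c_trees <- function(n) {
  if (n < 2) stop_tcnet("parameter", "n must be >= 2")
  cc <- bigint(2)
  if (n == 2) return(cc)
  for (m in 3:n)
    cc <- big_add(big_mul(bigint(2 * m), cc),
                  big_mul(bigint(2), big_double_factorial_odd(2 * m - 3)))
  cc
}

#' @rdname u_trees_closed
#' @export
c_trees_closed <- function(n) {
  if (n < 2) stop_tcnet("parameter", "n must be >= 2")
  big_sub(big_mul(big_pow2(n), big_factorial(n)),
          big_mul(bigint(2), big_double_factorial_odd(2 * n - 1)))
}

#' Enumeration-backed totals of incomparable edge pairs
#'
#' Sums the incomparable-pair statistic over every tree-child network
#' with `k` reticulations on `n` taxa, by exhaustive enumeration.
#' With `edge_scope = "all"` pairs range over all edges (the
#' definition of the u statistic); with `"tree_only"` over tree edges
#' only (the insertion sites).  The two coincide for k = 0.  The
#' master recurrence consumes the `"tree_only"` reading for k >= 1:
#' reticulations are inserted into tree-edge pairs only, so only
#' incomparable *tree-edge* pairs contribute the extra rotation (the
#' package's tests certify this against the enumeration).
#'
#' @param n,k As in [enumerate_tcn()].
#' @param edge_scope `"all"` or `"tree_only"`.
#' @param max_count Refuse (resource error) if the number of networks
#'   to enumerate, predicted from the recurrence, exceeds this.
#' @return A [bigint()].
#' @export
u_total <- function(n, k, edge_scope = c("all", "tree_only"),
                    max_count = 1e6) {
  edge_scope <- match.arg(edge_scope)
  guard_enumeration(.a_upper(n, k), max_count, "u_total")
  tree_only <- edge_scope == "tree_only"
  tot <- 0
  enumerate_tcn(n, k, sink = function(net)
    tot <<- tot + .u_pairs(net, tree_only = tree_only))
  bigint(tot)
}

# Cheap arithmetic upper bound on a(n, k) for the size guard: the
# master recurrence with the u term replaced by (number of edge pairs)
# times a(n-1, k-1).  Never enumerates.
.a_upper <- function(n, k, memo = new.env(parent = emptyenv())) {
  if (k < 0 || k >= n) return(bigint(0))
  if (n == 1 || (n == 2 && k == 0)) return(bigint(1))
  key <- paste(n, k)
  if (!is.null(memo[[key]])) return(memo[[key]])
  m_prev <- 2 * (n - 1) + 3 * (k - 1) - 1  # edges at (n-1, k-1)
  upairs <- if (k >= 1 && m_prev >= 2) m_prev * (m_prev - 1) / 2 else 0
  val <- big_add(
    big_mul(bigint(2 * n + k - 3),
            big_add(.a_upper(n - 1, k, memo),
                    big_mul(bigint(2 * n + k - 4),
                            .a_upper(n - 1, k - 1, memo)))),
    big_mul(bigint(upairs), .a_upper(n - 1, k - 1, memo))
  )
  memo[[key]] <- val
  val
}

guard_enumeration <- function(predicted, max_count, where) {
  if (big_cmp(predicted, bigint(max_count)) > 0)
    stop_tcnet("resource",
               sprintf("%s: predicted %s networks exceeds the size guard (%g); raise max_count to override",
                       where, as.character(predicted), max_count))
  invisible(NULL)
}

#' Tree-child counts by recurrence
#'
#' Evaluates the master recurrence for `a(n, k)`, the number of
#' tree-child networks with `k` reticulations on `n` taxa.  The `u`
#' term is supplied by the closed form [u_trees_closed()] when
#' `k = 1` and by enumeration (`u_total(n - 1, k - 1, "tree_only")`)
#' otherwise; an alternative provider may be injected, e.g. to test
#' the `"all"` edge scope.
#'
#' @param n,k Taxa and reticulation counts.
#' @param u_provider `function(n, k)` returning a [bigint()]; the
#'   default is described above.
#' @return A [bigint()].
#' @examples
#' as.numeric(a_recurrence(3, 1))  # 21
#' @export
a_recurrence <- function(n, k, u_provider = NULL) {
  if (n < 1 || k < 0) stop_tcnet("parameter", "need n >= 1 and k >= 0")
  if (is.null(u_provider))
    u_provider <- function(n, k) {
      if (k == 0) u_trees_closed(n) else u_total(n, k, "tree_only")
    }
  memo <- new.env(parent = emptyenv())
  a <- function(n, k) {
    if (k < 0 || k >= n) return(bigint(0))
    if (n == 1 || (n == 2 && k == 0)) return(bigint(1))
    key <- paste(n, k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- big_add(
      big_mul(bigint(2 * n + k - 3),
              big_add(a(n - 1, k),
                      big_mul(bigint(2 * n + k - 4), a(n - 1, k - 1)))),
      if (k >= 1) u_provider(n - 1, k - 1) else bigint(0)
    )
    memo[[key]] <- val
    val
  }
  a(n, k)
}

#' Closed forms for one reticulation
#'
#' `a_one_ret_closed(n) = n (2n-1)!! - 2^(n-1) n!` counts the
#' tree-child networks with exactly one reticulation on `n` taxa —
#' and, because every rooted binary phylogenetic network with one
#' reticulate node is tree-child, all such networks.
#' `b_one_ret_closed(n) = (n+2)(2n-1)!! - 3 * 2^(n-1) n!` counts the
#' normal ones; `b_one_ret_recurrence(n)` evaluates the recurrence
#' `b(n, 1) = (2n-2) b(n-1, 1) + 3 u(n-1, 0)` from `b(2, 1) = 0`.
#'
#' @param n Number of taxa (>= 2).
#' @return A [bigint()].
#' @examples
#' as.numeric(b_one_ret_closed(6))  # 14040
#' @export
a_one_ret_closed <- function(n) {
  if (n < 2) stop_tcnet("parameter", "n must be >= 2")
  big_sub(big_mul(bigint(n), big_double_factorial_odd(2 * n - 1)),
          big_mul(big_pow2(n - 1), big_factorial(n)))
}

#' @rdname a_one_ret_closed
#' @export
b_one_ret_closed <- function(n) {
  if (n < 2) stop_tcnet("parameter", "n must be >= 2")
  big_sub(big_mul(bigint(n + 2), big_double_factorial_odd(2 * n - 1)),
          big_mul(bigint(3), big_mul(big_pow2(n - 1), big_factorial(n))))
}

#' @rdname a_one_ret_closed
#' @export
b_one_ret_recurrence <- function(n) {
  if (n < 2) stop_tcnet("parameter", "n must be >= 2")
  bb <- bigint(0)  # b(2, 1) = 0
  if (n == 2) return(bb)
  for (m in 3:n)
    bb <- big_add(big_mul(bigint(2 * m - 2), bb),
                  big_mul(bigint(3), u_trees_closed(m - 1)))
  bb
}

#' Normal counts by enumeration
#'
#' `|enumerate_normal(n, k)|`, guarded against accidentally huge
#' enumerations (the prediction uses the closed form for `k = 1` and
#' the tree-child recurrence as an upper bound otherwise).
#'
#' @param n,k As in [enumerate_normal()].
#' @param max_count Size guard, see [u_total()].
#' @return A [bigint()].
#' @examples
#' as.numeric(b_by_enumeration(4, 2))  # 48
#' @export
b_by_enumeration <- function(n, k, max_count = 1e6) {
  predicted <- if (k == 1) b_one_ret_closed(n) else .a_upper(n, k)
  guard_enumeration(predicted, max_count, "b_by_enumeration")
  bigint(enumerate_normal(n, k, count_only = TRUE))
}

#' Exact count table
#'
#' Builds the table of counts for `3 <= n <= max_n`,
#' `1 <= k <= n - 2`: tree-child counts `a(n, k)` by the master
#' recurrence and normal counts `b(n, k)` by closed form / recurrence
#' for `k = 1` and by enumeration otherwise.  Each cell records its
#' provenance (`closed_form`, `recurrence`, `enumeration`).
#'
#' @param max_n Largest number of taxa.
#' @param net_class `"normal"` or `"tcn"`.
#' @param max_count Size guard for enumeration-backed cells.
#' @return A data frame with columns `n`, `k`, `count` (character, the
#'   exact integer) and `provenance`.
#' @export
count_table <- function(max_n, net_class = c("normal", "tcn"),
                        max_count = 1e6) {
  net_class <- match.arg(net_class)
  rows <- list()
  for (n in 3:max_n) for (k in 1:(n - 2)) {
    if (net_class == "normal") {
      if (k == 1) {
        val <- b_one_ret_recurrence(n)
        prov <- "recurrence"
      } else {
        val <- b_by_enumeration(n, k, max_count = max_count)
        prov <- "enumeration"
      }
    } else {
      val <- a_recurrence(n, k)
      prov <- if (k == 1) "recurrence" else "recurrence+enumerated_u"
    }
    rows[[length(rows) + 1L]] <-
      data.frame(n = n, k = k, count = as.character(val),
                 provenance = prov, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
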