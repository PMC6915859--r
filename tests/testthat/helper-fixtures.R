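# Shared fixtures and a per-session cache so the expensive enumeration
# scans are computed once and reused across test files.

tc_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(tc_cache[[key]])) tc_cache[[key]] <- fn()
  tc_cache[[key]]
}

code_of <- function(N, ntaxa = n_taxa(N))
  tcnet:::.canon_code_cpp(N$edges, N$taxon, ntaxa)

codes_of <- function(nets, ntaxa)
  vapply(nets, function(N) code_of(N, ntaxa), character(1))

# Canonical-code-sorted parent level, matching the internal expansion
# order of the enumeration engine.
sorted_parent_codes <- function(n, k, net_class) {
  if (k < 0 || k > n - 1) return(character(0))
  enum_fn <- if (net_class == "normal") enumerate_normal else enumerate_tcn
  sort(codes_of(enum_fn(n, k), n), method = "radix")
}

# a cherry ((1,2),3)
cherry3 <- function() leaf_insert(base_network(2), c(1, 2), 3)

# the same-edge straddle on one taxon: a tree-child, non-normal
# network on {1,2} with one reticulation
straddle2 <- function() {
  b1 <- base_network(1)
  ret_insert(b1, c(1, 2), c(1, 2), 2)
}

# a valid RPN that is not tree-child: two tree nodes (3 and 4) whose
# children are both reticulate
non_tree_child_net <- function() {
  E <- rbind(
    c(1L, 2L), c(2L, 3L), c(2L, 4L),
    c(3L, 5L), c(3L, 6L), c(4L, 5L), c(4L, 6L),
    c(5L, 7L), c(6L, 8L)
  )
  tcnet:::new_phynet(E, c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 2L), 1L, 9L)
}

# One full enumeration pass at (n, k): counts, canonical codes, the
# normal-filtered codes (tcn scans), and the reverse-map check of
# every emitted network against its recorded parent.
acc_scan <- function(n, k, net_class = c("tcn", "normal")) {
  net_class <- match.arg(net_class)
  cached(sprintf("scan_%s_%d_%d", net_class, n, k), function() {
    parents_same <- if (n >= 2) sorted_parent_codes(n - 1L, k, net_class)
                    else character(0)
    parents_km1 <- if (n >= 2 && k >= 1) sorted_parent_codes(n - 1L, k - 1L, net_class)
                   else character(0)
    cap <- 1024L
    codes <- character(cap)
    ncap <- 256L
    norm_codes <- character(ncap)
    cnt <- 0L
    ncnt <- 0L
    reduce_fail <- 0L
    cases <- c(ret_parent = 0L, tree_parent_tree_sib = 0L,
               tree_parent_ret_sib = 0L)
    tcnet:::.enum_core(n, k, net_class, function(net, route, pi, op, rows, rot) {
      cnt <<- cnt + 1L
      if (cnt > cap) {
        cap <<- 2L * cap
        length(codes) <<- cap
      }
      code <- tcnet:::.canon_code_cpp(net$edges, net$taxon, n)
      codes[cnt] <<- code
      if (net_class == "tcn" && tcnet:::.is_normal(net)) {
        ncnt <<- ncnt + 1L
        if (ncnt > ncap) {
          ncap <<- 2L * ncap
          length(norm_codes) <<- ncap
        }
        norm_codes[ncnt] <<- code
      }
      if (n >= 2L) {
        res <- tcnet:::.reduce_last_step(net, n, 1L)
        cases[res$case] <<- cases[res$case] + 1L
        pcode <- tcnet:::.canon_code_cpp(res$net$edges, res$net$taxon, n - 1L)
        expected <- if (route == "leaf") parents_same[pi] else parents_km1[pi]
        if (!identical(pcode, expected)) reduce_fail <<- reduce_fail + 1L
      }
    })
    codes <- codes[seq_len(cnt)]
    list(count = cnt, codes = codes,
         normal_codes = norm_codes[seq_len(ncnt)],
         reduce_fail = reduce_fail, cases = cases,
         has_dup = anyDuplicated(codes) > 0L)
  })
}

# All (n, k) pairs with 2 <= n <= nmax, 0 <= k <= n - 1
nk_grid <- function(nmax, kmin = 0L) {
  out <- list()
  for (n in 2:nmax) for (k in kmin:(n - 1L))
    out[[length(out) + 1L]] <- c(n, k)
  out
}

# Streaming count + canonical-code uniqueness at n = 6 (codes are not
# retained; only the count and the duplication verdict).
normal6_scan <- function(k) {
  cached(sprintf("normal6_%d", k), function() {
    cap <- 1024L
    codes <- character(cap)
    cnt <- 0L
    enumerate_normal(6L, k, sink = function(net) {
      cnt <<- cnt + 1L
      if (cnt > cap) {
        cap <<- 2L * cap
        length(codes) <<- cap
      }
      codes[cnt] <<- tcnet:::.canon_code_cpp(net$edges, net$taxon, 6L)
    })
    list(count = cnt, has_dup = anyDuplicated(codes[seq_len(cnt)]) > 0L)
  })
}
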