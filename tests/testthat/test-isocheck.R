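test_that("are_isomorphic on hand-checkable instances", {
  b2 <- base_network(2)
  expect_true(are_isomorphic(b2, copy_network(b2)))
  # the two TCNs on {1,2} with one reticulation differ
  s2 <- straddle2()
  r <- reticulate_nodes(s2)
  par <- s2$edges[s2$edges[, 2] == r, 1]
  D <- tcnet:::reach_matrix(s2)
  lower <- if (D[par[1], par[2]]) par[2] else par[1]
  M <- c_rotate(s2, lower, r)
  expect_false(are_isomorphic(s2, M))
  trees <- enumerate_trees(3)
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(are_isomorphic(trees[[i]], trees[[j]]))
  # label-sensitivity: same shape, different labelling
  t_a <- leaf_insert(base_network(2), c(2, 3), 3)
  t_b <- leaf_insert(base_network(2), c(2, 4), 3)
  expect_false(are_isomorphic(t_a, t_b))
})

test_that("canonical codes are stable under node-id relabelling", {
  N <- enumerate_tcn(4, 2)[[321]]
  M <- copy_network(N)
  expect_equal(canonical_code(N), canonical_code(M))
  # build the same tree along two different insertion orders
  t1 <- leaf_insert(leaf_insert(base_network(2), c(2, 3), 3), c(2, 4), 4)
  t2 <- leaf_insert(leaf_insert(base_network(2), c(2, 4), 4), c(2, 3), 3)
  expect_true(are_isomorphic(t1, t2))
  expect_equal(canonical_code(t1), canonical_code(t2))
})

test_that("canonical_code rejects non-tree-child networks", {
  expect_error(canonical_code(non_tree_child_net()),
               class = "tcnet_unsupported_class_error")
})

test_that("distinct codes over the enumerated populations", {
  expect_equal(length(unique(codes_of(enumerate_tcn(3, 1), 3))), 21L)
  expect_equal(length(unique(codes_of(enumerate_normal(5, 2), 5))), 2310L)
})

pairwise_mismatches <- function(nets, ntaxa, pairs = NULL) {
  codes <- codes_of(nets, ntaxa)
  m <- length(nets)
  bad <- 0L
  check <- function(i, j) {
    same <- tcnet:::.iso_cpp(nets[[i]]$edges, nets[[i]]$taxon,
                             nets[[j]]$edges, nets[[j]]$taxon)
    if (same != (codes[i] == codes[j])) bad <<- bad + 1L
  }
  if (is.null(pairs)) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) check(i, j)
  } else {
    for (q in seq_len(nrow(pairs))) check(pairs[q, 1], pairs[q, 2])
  }
  bad
}

test_that("codes and backtracking isomorphism agree on every pair (n <= 4)", {
  # full pairwise cross-check of the two independent routes
  for (nk in nk_grid(4)) {
    nets <- enumerate_tcn(nk[1], nk[2])
    expect_equal(pairwise_mismatches(nets, nk[1]), 0L,
                 label = sprintf("pairwise mismatches at (%d,%d)", nk[1], nk[2]))
  }
})

test_that("codes and isomorphism agree on 1000 sampled pairs at n = 5", {
  nets5 <- c(enumerate_tcn(5, 1), enumerate_tcn(5, 2)[seq(1, 30300, by = 15)])
  set.seed(421)
  pairs <- matrix(sample(length(nets5), 2000, replace = TRUE), ncol = 2)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  expect_gte(nrow(pairs), 900)
  expect_equal(pairwise_mismatches(nets5, 5, pairs = pairs), 0L)
})
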