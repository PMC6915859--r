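test_that("leaf_insert produces valid trees and rejects bad input", {
  b2 <- base_network(2)
  nets <- apply(b2$edges, 1L, function(e) leaf_insert(b2, e, 3))
  for (N in nets) {
    expect_length(validate_network(N), 0)
    expect_equal(n_taxa(N), 3)
    expect_equal(n_reticulations(N), 0)
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(are_isomorphic(nets[[i]], nets[[j]]))
  s2 <- straddle2()
  re <- reticulate_edges(s2)
  expect_error(leaf_insert(s2, re[1, ], 3), class = "tcnet_domain_error")
  expect_error(leaf_insert(b2, c(1, 2), 2), class = "tcnet_label_error")
})

test_that("leaf insertion is injective across parents and edges (Prop 4 i)", {
  parents <- enumerate_tcn(3, 1)
  out <- list()
  for (N in parents) {
    TE <- tree_edges(N)
    for (i in seq_len(nrow(TE)))
      out[[length(out) + 1L]] <- leaf_insert(N, TE[i, ], 4)
  }
  codes <- codes_of(out, 4)
  expect_equal(anyDuplicated(codes), 0L)
})

test_that("ret_insert adds one reticulation and one leaf", {
  b1 <- base_network(1)
  s2 <- ret_insert(b1, c(1, 2), c(1, 2), 2)
  expect_length(validate_network(s2), 0)
  expect_equal(n_reticulations(s2), 1)
  expect_equal(n_taxa(s2), 2)
  expect_true(is_tree_child(s2))
  expect_false(is_normal(s2))
  N <- cherry3()
  TE <- tree_edges(N)
  M <- ret_insert(N, TE[1, ], TE[4, ], 4)
  expect_length(validate_network(M), 0)
  expect_equal(n_reticulations(M), n_reticulations(N) + 1)
  expect_equal(n_taxa(M), n_taxa(N) + 1)
  re <- reticulate_edges(straddle2())
  expect_error(ret_insert(straddle2(), re[1, ], re[1, ], 3),
               class = "tcnet_domain_error")
})

test_that("ret_insert on comparable edges is never normal", {
  for (N in enumerate_trees(3)) {
    TE <- tree_edges(N)
    D <- tcnet:::reach_matrix(N)
    for (a in seq_len(nrow(TE))) for (b in a:nrow(TE)) {
      M <- ret_insert(N, TE[a, ], TE[b, ], 4)
      comparable <- D[TE[a, 2], TE[b, 2]] || D[TE[b, 2], TE[a, 2]]
      if (comparable) expect_false(is_normal(M))
    }
  }
})

test_that("ret_insert preserves the tree-child property (Prop 1)", {
  pop <- c(enumerate_trees(4), enumerate_tcn(4, 1)[seq(1, 228, by = 10)])
  for (N in pop) {
    TE <- tree_edges(N)
    for (a in seq_len(nrow(TE))) for (b in a:nrow(TE))
      expect_true(is_tree_child(ret_insert(N, TE[a, ], TE[b, ], 5)))
  }
})

test_that("c_rotate admissibility on the one-taxon straddle", {
  s2 <- straddle2()
  r <- reticulate_nodes(s2)
  par <- s2$edges[s2$edges[, 2] == r, 1]
  D <- tcnet:::reach_matrix(s2)
  upper <- if (D[par[1], par[2]]) par[1] else par[2]
  lower <- setdiff(par, upper)
  expect_error(c_rotate(s2, upper, r), class = "tcnet_inadmissible_error")
  M <- c_rotate(s2, lower, r)
  expect_length(validate_network(M), 0)
  expect_true(is_tree_child(M))
  # the rotation yields the second of the two TCNs on {1,2} with k = 1
  expect_false(are_isomorphic(M, s2))
  expect_equal(enumerate_tcn(2, 1, count_only = TRUE), 2L)
  # involution
  expect_true(are_isomorphic(c_rotate(M, lower, r), s2))
  expect_error(c_rotate(s2, lower, lower), class = "tcnet_domain_error")
})

test_that("admissible rotations preserve tree-child and acyclicity (Prop 2)", {
  pop <- c(enumerate_tcn(3, 1), enumerate_tcn(3, 2))
  rotations <- 0L
  for (N in pop) {
    D <- tcnet:::reach_matrix(N)
    ind <- tcnet:::indegree(N)
    outd <- tcnet:::outdegree(N)
    for (r in reticulate_nodes(N)) {
      for (u in N$edges[N$edges[, 2] == r, 1]) {
        v <- setdiff(N$edges[N$edges[, 2] == r, 1], u)
        if (ind[u] == 1 && outd[u] == 2 && !D[u, v]) {
          M <- c_rotate(N, u, r)
          rotations <- rotations + 1L
          expect_length(validate_network(M), 0)
          expect_true(is_tree_child(M))
        }
      }
    }
  }
  expect_gt(rotations, 0L)
})

test_that("reduce_last inverts each generation operation", {
  N <- enumerate_tcn(4, 1)[[57]]
  TE <- tree_edges(N)
  r1 <- reduce_last(leaf_insert(N, TE[2, ], 5), 5)
  expect_equal(r1$case, "tree_parent_tree_sib")
  expect_true(are_isomorphic(r1$net, N))
  r2 <- reduce_last(ret_insert(N, TE[1, ], TE[5, ], 5), 5)
  expect_equal(r2$case, "ret_parent")
  expect_true(are_isomorphic(r2$net, N))
  # rotated insertion: the leaf's sibling becomes the reticulate node
  M0 <- ret_insert(N, TE[1, ], TE[5, ], 5)
  r <- reticulate_nodes(M0)[!reticulate_nodes(M0) %in% reticulate_nodes(N)]
  par <- M0$edges[M0$edges[, 2] == r, 1]
  D <- tcnet:::reach_matrix(M0)
  u <- if (!D[par[1], par[2]]) par[1] else par[2]
  Mrot <- c_rotate(M0, u, r)
  r3 <- reduce_last(Mrot, 5)
  expect_equal(r3$case, "tree_parent_ret_sib")
  expect_true(are_isomorphic(r3$net, N))
})

test_that("reduce_last terminates within two steps on TCN(3,1)", {
  for (N in enumerate_tcn(3, 1)) {
    res <- reduce_last(N, 3)
    expect_length(validate_network(res$net), 0)
    expect_equal(n_taxa(res$net), 2)
  }
})

test_that("reduce_last checks its contract", {
  expect_error(reduce_last(non_tree_child_net(), 2),
               class = "tcnet_contract_error")
  expect_error(reduce_last(cherry3(), 1), class = "tcnet_missing_taxon_error")
})
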