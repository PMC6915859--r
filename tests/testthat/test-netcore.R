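test_that("base networks are valid and have the expected shape", {
  b1 <- base_network(1)
  b2 <- base_network(2)
  expect_length(validate_network(b1), 0)
  expect_length(validate_network(b2), 0)
  expect_equal(nrow(b1$edges), 1)
  expect_equal(nrow(b2$edges), 3)
  expect_equal(nrow(reticulate_edges(b2)), 0)
  expect_equal(nrow(tree_edges(b2)), 3)
  expect_equal(n_taxa(b2), 2)
  # 3 unordered edge pairs minus the 2 comparable ones
  expect_equal(u_of(b2), 1L)
  expect_error(base_network(3), class = "tcnet_parameter_error")
  expect_error(base_network("x"), class = "tcnet_parameter_error")
})

test_that("validate_network reports violations instead of raising", {
  b2 <- base_network(2)
  # parallel edge
  par <- tcnet:::new_phynet(rbind(b2$edges, c(2L, 3L)), b2$taxon, 1L,
                            b2$next_id)
  expect_true(any(grepl("parallel", validate_network(par))))
  # cycle: 2 -> 3 -> 2 with node degrees kept plausible
  cyc <- tcnet:::new_phynet(rbind(c(1L, 2L), c(2L, 3L), c(3L, 2L), c(3L, 4L),
                                  c(2L, 5L)),
                            c(0L, 0L, 0L, 1L, 2L), 1L, 6L)
  expect_true(any(grepl("cycle", validate_network(cyc))))
  # bad degree
  deg <- tcnet:::new_phynet(rbind(c(1L, 2L), c(2L, 3L)), c(0L, 0L, 1L), 1L, 4L)
  expect_true(length(validate_network(deg)) > 0)
})

test_that("subdivide adds exactly one edge and flags missing edges", {
  b1 <- base_network(1)
  s <- subdivide(b1, c(1, 2))
  expect_equal(nrow(s$net$edges), 2)
  expect_equal(s$node, 3L)
  # path of length 2: root -> w -> leaf
  expect_setequal(as.vector(t(s$net$edges)), c(1L, 3L, 3L, 2L))
  b2 <- base_network(2)
  expect_equal(nrow(subdivide(b2, c(2, 4))$net$edges), nrow(b2$edges) + 1L)
  expect_error(subdivide(b2, c(1, 4)), class = "tcnet_missing_edge_error")
})

test_that("subdivide + leaf attachment yields the 3 trees on three taxa", {
  b2 <- base_network(2)
  nets <- apply(b2$edges, 1L, function(e) leaf_insert(b2, e, 3))
  expect_length(nets, 3)
  for (N in nets) expect_length(validate_network(N), 0)
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(are_isomorphic(nets[[i]], nets[[j]]))
})

test_that("delete_leaf_smooth inverts leaf insertion on tree edges", {
  # all tree edges of all TCNs with n <= 4, k <= 1 (spec-scale: k = 1)
  for (N in enumerate_tcn(3, 1)) {
    TE <- tree_edges(N)
    for (i in seq_len(nrow(TE))) {
      M <- delete_leaf_smooth(leaf_insert(N, TE[i, ], 4), 4)
      expect_true(are_isomorphic(M, N))
    }
  }
  ch <- cherry3()
  expect_true(are_isomorphic(delete_leaf_smooth(ch, 3), base_network(2)))
  expect_error(delete_leaf_smooth(ch, 9), class = "tcnet_missing_taxon_error")
})

test_that("delete_leaf_smooth refuses reticulate parents", {
  expect_error(delete_leaf_smooth(straddle2(), 2),
               class = "tcnet_structural_error")
})

test_that("node-degree census follows the generation accounting", {
  # on n taxa with k reticulations: n + k - 1 tree nodes,
  # 2n + 3k - 1 edges, 2n + k - 1 tree edges
  for (nk in list(c(2, 0), c(2, 1), c(3, 1), c(3, 2), c(4, 2))) {
    n <- nk[1]; k <- nk[2]
    for (N in enumerate_tcn(n, k)) {
      expect_length(tree_nodes(N), n + k - 1)
      expect_length(reticulate_nodes(N), k)
      expect_equal(nrow(N$edges), 2 * n + 3 * k - 1)
      expect_equal(nrow(tree_edges(N)), 2 * n + k - 1)
    }
  }
})

test_that("copy_network renumbers nodes and preserves structure", {
  N <- enumerate_tcn(4, 1)[[100]]
  M <- copy_network(N)
  expect_true(are_isomorphic(N, M))
  expect_equal(canonical_code(N), canonical_code(M))
  expect_equal(sort(unique(as.vector(M$edges))),
               seq_along(unique(as.vector(N$edges))))
})
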