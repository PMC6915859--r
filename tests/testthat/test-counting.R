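test_that("bigint arithmetic agrees with R arithmetic below 2^53", {
  set.seed(7)
  for (rep in 1:200) {
    x <- floor(runif(1, 0, 2^40))
    y <- floor(runif(1, 0, 2^40))
    expect_equal(as.numeric(bigint(x) + bigint(y)), x + y)
    expect_equal(as.numeric(bigint(max(x, y)) - bigint(min(x, y))),
                 abs(x - y))
    a <- floor(runif(1, 0, 2^26)); b <- floor(runif(1, 0, 2^26))
    expect_equal(as.numeric(bigint(a) * bigint(b)), a * b)
    expect_identical(bigint(x) < bigint(y), x < y)
    expect_identical(bigint(x) == bigint(x), TRUE)
  }
  expect_equal(as.character(bigint("999999999999999999") + 1),
               "1000000000000000000")
  expect_equal(as.character(bigint("1,000,000")), "1000000")
  expect_error(bigint(-1), class = "tcnet_parameter_error")
  expect_error(bigint(2) - bigint(3), class = "tcnet_parameter_error")
})

test_that("bigint string construction round-trips", {
  s <- "123456789012345678901234567890"
  expect_equal(as.character(bigint(s)), s)
  expect_true(bigint(s) * bigint(s) > bigint(s))
})

test_that("tree counts and the u/c closed forms", {
  expect_equal(as.numeric(trees_count(3)), 3)
  expect_equal(as.numeric(trees_count(6)), 945)
  expect_equal(as.numeric(u_trees_closed(2)), 1)
  expect_equal(as.numeric(u_trees_closed(3)), 12)
  expect_equal(as.numeric(u_trees_closed(4)), 141)
  expect_equal(as.numeric(c_trees(2)), 2)
  expect_equal(as.numeric(c_trees(3)), 18)
})

test_that("c recurrence equals its terminal closed form up to n = 20", {
  for (n in 2:20)
    expect_true(c_trees(n) == c_trees_closed(n))
})

test_that("comparable + incomparable pairs account for all edge pairs", {
  # c_n + u_n = (#trees) * choose(2n-1, 2), exactly, for n = 2..8
  for (n in 2:8) {
    total <- trees_count(n) * bigint((2 * n - 1) * (2 * n - 2) / 2)
    expect_true(c_trees(n) + u_trees_closed(n) == total)
  }
})

test_that("the master recurrence reproduces printed values", {
  expect_equal(as.numeric(a_recurrence(2, 1)), 2)
  expect_equal(as.numeric(a_recurrence(3, 1)), 21)
  expect_equal(as.numeric(a_recurrence(4, 1)), 228)
  expect_equal(as.numeric(a_recurrence(3, 2)), 42)
})

test_that("one-reticulation closed forms", {
  expect_equal(as.numeric(a_one_ret_closed(3)), 21)
  expect_equal(as.numeric(a_one_ret_closed(5)), 2805)
  expect_equal(as.numeric(b_one_ret_closed(3)), 3)
  expect_equal(as.numeric(b_one_ret_closed(2)), 0)
  expect_equal(as.numeric(b_one_ret_closed(6)), 14040)
  for (n in 2:10)
    expect_true(a_one_ret_closed(n) == a_recurrence(n, 1))
})

test_that("normal recurrence matches its closed form and printed cells", {
  expect_equal(as.numeric(b_one_ret_recurrence(3)), 3)
  expect_equal(as.numeric(b_one_ret_recurrence(4)), 54)
  expect_equal(as.numeric(b_one_ret_recurrence(5)), 855)
  for (n in 2:20)
    expect_true(b_one_ret_recurrence(n) == b_one_ret_closed(n))
})

test_that("u totals by enumeration", {
  expect_equal(as.numeric(u_total(1, 0)), 0)
  expect_equal(as.numeric(u_total(2, 0)), 1)
  expect_equal(as.numeric(u_total(3, 0)), 12)
  # for trees the edge scope makes no difference
  expect_true(u_total(4, 0, "all") == u_total(4, 0, "tree_only"))
  # with reticulations it does
  expect_true(u_total(2, 1, "all") > u_total(2, 1, "tree_only"))
  expect_equal(as.numeric(u_total(2, 1, "tree_only")), 2)
})

test_that("enumeration-backed normal counts and the size guard", {
  expect_equal(as.numeric(b_by_enumeration(4, 2)), 48)
  expect_equal(as.numeric(b_by_enumeration(4, 3)), 0)
  expect_error(b_by_enumeration(6, 2, max_count = 10),
               class = "tcnet_resource_error")
  expect_error(u_total(6, 3), class = "tcnet_resource_error")
})

test_that("count_table assembles counts with provenance", {
  tab <- count_table(4, "normal")
  expect_equal(tab$count[tab$n == 3 & tab$k == 1], "3")
  expect_equal(tab$count[tab$n == 4 & tab$k == 1], "54")
  expect_equal(tab$count[tab$n == 4 & tab$k == 2], "48")
  expect_setequal(unique(tab$provenance), c("recurrence", "enumeration"))
  tab2 <- count_table(4, "tcn")
  expect_equal(tab2$count[tab2$n == 4 & tab2$k == 2], "1272")
})
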