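test_that("discretisation applies the strict two-fold rule", {
  expect_equal(unlist(discretise(expr_tbl(matrix(c(0, 0, 0), 1)))[, -1]),
               c(1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(unlist(discretise(expr_tbl(matrix(c(4, 6, 2), 1)))[, -1]),
               c(1L, 2L, 0L), ignore_attr = TRUE)
  # a deviation of exactly 1 log2 unit stays in state 1 (strict >)
  row <- matrix(c(1, -1, 0, 0), 1)  # mean 0, deviations exactly +-1
  expect_equal(unlist(discretise(expr_tbl(row))[, -1]),
               rep(1L, 4), ignore_attr = TRUE)
  expect_error(discretise(expr_tbl(matrix(c(1, NA), 1))), "non-finite")
})

test_that("the BDeu score matches the sequential-predictive oracle on random data", {
  dags3 <- list(
    matrix(0L, 3, 3),
    rbind(c(0L, 1L, 0L), c(0L, 0L, 0L), c(0L, 0L, 0L)),
    rbind(c(0L, 1L, 0L), c(0L, 0L, 1L), c(0L, 0L, 0L)),
    rbind(c(0L, 0L, 1L), c(0L, 0L, 1L), c(0L, 0L, 0L)),
    rbind(c(0L, 1L, 1L), c(0L, 0L, 1L), c(0L, 0L, 0L)))
  for (s in 1:200) {
    withr::with_seed(s, {
      n <- sample(5:50, 1)
      states <- matrix(sample(0:2, 3 * n, replace = TRUE), nrow = 3,
                       dimnames = list(c("A", "B", "C"), NULL))
    })
    adj <- dags3[[(s %% length(dags3)) + 1L]]
    dimnames(adj) <- list(c("A", "B", "C"), c("A", "B", "C"))
    got <- bde_score(adj, expr_tbl(states, genes = rownames(states)))
    expect_equal(got, oracle_bde(adj, states), tolerance = 1e-9)
  }
})

test_that("the empty-graph family score has the closed Dirichlet-multinomial value", {
  # single node, counts (3, 0, 1) over states {0, 2}, ess = 1 over 3 states
  states <- matrix(c(0L, 0L, 0L, 2L), 1, dimnames = list("A", NULL))
  got <- bde_score(matrix(0L, 1, 1, dimnames = list("A", "A")),
                   expr_tbl(states, "A"))
  a <- 1 / 3
  manual <- lgamma(1) - lgamma(1 + 4) +
    (lgamma(a + 3) - lgamma(a)) + (lgamma(a + 0) - lgamma(a)) +
    (lgamma(a + 1) - lgamma(a))
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("two-node scores are Markov-equivalence symmetric", {
  for (s in 1:20) {
    withr::with_seed(100 + s, {
      states <- matrix(sample(0:2, 2 * 40, replace = TRUE), nrow = 2,
                       dimnames = list(c("A", "B"), NULL))
    })
    d <- expr_tbl(states, rownames(states))
    ab <- bde_score(tibble::tibble(from = "A", to = "B"), d)
    ba <- bde_score(tibble::tibble(from = "B", to = "A"), d)
    expect_equal(ab, ba, tolerance = 1e-9)
  }
})

test_that("an irrelevant parent lowers the score on large samples", {
  withr::with_seed(3, {
    states <- matrix(sample(0:2, 2 * 2000, replace = TRUE), nrow = 2,
                     dimnames = list(c("A", "B"), NULL))
  })
  d <- expr_tbl(states, rownames(states))
  with_edge <- bde_score(tibble::tibble(from = "A", to = "B"), d)
  without <- bde_score(tibble::tibble(from = character(), to = character()), d)
  expect_lt(with_edge, without)
})

test_that("family-score caching is coherent under add-then-remove", {
  fix <- sample_compendium(stm_fixture_bn(), 100, seed = 5)
  scorer <- bde_scorer(fix$discrete)
  base <- scorer(2, c(1))
  scorer(2, c(1, 3))   # visit a different family
  expect_identical(scorer(2, c(1)), base)
  expect_identical(scorer(2, c(3, 1)), scorer(2, c(1, 3)))  # order-free
})

test_that("cyclic and unknown-node inputs are rejected", {
  d <- expr_tbl(matrix(0L, 2, 4), c("A", "B"))
  expect_error(bde_score(tibble::tibble(from = c("A", "B"), to = c("B", "A")), d),
               "cycle")
  expect_error(bde_score(tibble::tibble(from = "A", to = "Z"), d), "Z")
})

test_that("exhaustive enumeration covers all 29281 five-node DAGs", {
  fix <- sample_compendium(stm_fixture_bn(), 60, seed = 6)
  d5 <- fix$discrete[fix$discrete$gene != "TCP4", ]
  ex <- exhaustive_search(d5, max_parents = 5)
  expect_equal(ex$n_dags, 29281)
  expect_true(is.finite(ex$best_score))
  # the optimum beats a few arbitrary structures
  expect_gte(ex$best_score, bde_score(matrix(0L, 5, 5,
    dimnames = list(d5$gene, d5$gene)), d5))
})
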