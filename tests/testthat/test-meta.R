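test_that("de_test matches the textbook Welch computation", {
  ctl <- expr_tbl(matrix(c(1.0, 1.2, 0.8), 1))
  trt <- expr_tbl(matrix(c(3.0, 3.3, 2.7), 1))
  res <- de_test(ctl, trt)
  expect_equal(res$p, oracle_welch_p(c(1.0, 1.2, 0.8), c(3.0, 3.3, 2.7)),
               tolerance = 1e-10)
  expect_equal(res$p,
               t.test(c(3.0, 3.3, 2.7), c(1.0, 1.2, 0.8))$p.value,
               tolerance = 1e-10)
  expect_equal(res$lfc, 2, tolerance = 1e-12)
})

test_that("de_test handles near-identical arms and reports exact mean shifts", {
  eps <- .Machine$double.eps
  ctl <- expr_tbl(matrix(c(1, 1, 1), 1))
  trt <- expr_tbl(matrix(c(1, 1 + eps, 1 - eps), 1))
  res <- de_test(ctl, trt)
  expect_gt(res$p, 0.5)
  expect_equal(res$lfc, 0, tolerance = 1e-12)
  jit <- expr_tbl(matrix(c(2, 2 + 1e-9, 2 - 1e-9), 1))
  expect_equal(de_test(expr_tbl(matrix(c(0, 1e-9, -1e-9), 1)), jit)$lfc, 2,
               tolerance = 1e-6)
})

test_that("de_test rejects mismatched gene sets, listing the difference", {
  ctl <- expr_tbl(matrix(0, 2, 2), genes = c("a", "b"))
  trt <- expr_tbl(matrix(0, 2, 2), genes = c("a", "c"))
  expect_error(de_test(ctl, trt), "b.*c|c.*b")
})

test_that("DEG selection applies both filters with deterministic order", {
  tbl <- tibble::tibble(
    gene = paste0("g", 1:5), contrast = "c1",
    p = c(0.001, 0.02, 0.009, 0.5, 0.0099),
    lfc = c(3, 3, 0.5, 3, 1.5))
  kept <- select_degs(tbl, p_cut = 0.01, fold_cut = 2, use_fold = TRUE)
  expect_equal(kept$gene, c("g1", "g5"))
  # boundary behaviour of the fold filter: 2^1.2 passes, 2^0.8 fails
  tbl2 <- tibble::tibble(gene = c("a", "b"), contrast = "c1",
                         p = 0.005, lfc = c(1.2, 0.8))
  expect_equal(select_degs(tbl2)$gene, "a")
  expect_error(select_degs(tbl[, -4]), "lfc")
})

test_that("fisher_combine reproduces closed-form worked values", {
  res <- fisher_combine(c(0.05, 0.05))
  expect_equal(res$statistic, -2 * 2 * log(0.05), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, oracle_chisq_tail_even(res$statistic, 4), tolerance = 1e-12)
  expect_equal(res$p, 0.01747, tolerance = 1e-3)
  expect_equal(fisher_combine(rep(1, 4))$statistic, 0)
  expect_equal(fisher_combine(rep(1, 4))$p, 1)
  expect_equal(fisher_combine(0.037)$p, 0.037, tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "0")
})

test_that("bh_adjust equals the hand-computed step-up and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(1)
  p <- runif(200)
  adj <- bh_adjust(p)
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("storey q-values reduce to BH when pi0 is 1 and calibrate on null data", {
  p <- c(rep(1, 30))
  st <- storey_qvalue(p)
  expect_equal(st$q, rep(1, 30))
  # small n: pi0 fixed at 1, q == BH
  p2 <- c(0.01, 0.2, 0.5, 0.9)
  st2 <- storey_qvalue(p2)
  expect_equal(st2$pi0, 1)
  expect_equal(st2$q, bh_adjust(p2))
  # null simulation: pi0 lands in [0.9, 1] in the vast majority of draws
  pi0s <- vapply(1:30, function(s) {
    withr::with_seed(1000 + s, storey_qvalue(runif(10000))$pi0)
  }, numeric(1))
  expect_gte(mean(pi0s >= 0.9 & pi0s <= 1), 0.9)
})

test_that("discovery sets grow monotonically with the threshold", {
  set.seed(7)
  p <- c(runif(300)^3, runif(200))
  st <- storey_qvalue(p)
  for (fun in list(bh_adjust(p), st$q)) {
    n_disc <- vapply(c(0.01, 0.05, 0.1, 0.2), function(th) sum(fun < th), numeric(1))
    expect_true(all(diff(n_disc) >= 0))
  }
  # q never exceeds BH-adjusted p
  expect_true(all(st$q <= bh_adjust(p) + 1e-12))
})

test_that("meta_analyse combines contrasts and enforces completeness", {
  tbl <- tidyr::expand_grid(gene = c("g1", "g2"), contrast = c("a", "b"))
  tbl$p <- c(0.001, 0.002, 0.5, 0.6)
  res <- meta_analyse(tbl)
  expect_equal(res$df, c(4L, 4L))
  expect_equal(res$statistic[res$gene == "g1"],
               -2 * sum(log(c(0.001, 0.002))), tolerance = 1e-12)
  expect_true(all(diff(res$p_omnibus) >= 0))
  expect_error(meta_analyse(tbl[-1, ]), "missing")
})

test_that("ddct_fold implements relative quantification", {
  expect_equal(ddct_fold(25, 20, 26, 20), 2)
  expect_equal(ddct_fold(20, 20, 20, 20), 1)
  f1 <- ddct_fold(24.3, 19.1, 26.8, 20.2)
  f2 <- ddct_fold(26.8, 20.2, 24.3, 19.1)
  expect_equal(f1 * f2, 1, tolerance = 1e-12)
  expect_error(ddct_fold(Inf, 20, 20, 20), "finite")
})
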