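test_that("degenerate CPTs sample deterministically", {
  bn <- ground_truth_bn(
    nodes = "A",
    edges = tibble::tibble(from = character(), to = character()),
    cpt = list(A = matrix(c(1, 0, 0), 1, 3)))
  fix <- sample_compendium(bn, 5, seed = 1)
  expect_equal(unname(unlist(fix$discrete[1, -1])), rep(0L, 5))
})

test_that("a deterministic copy chain yields identical child and parent columns", {
  copy <- diag(3)
  bn <- ground_truth_bn(
    nodes = c("A", "B"),
    edges = tibble::tibble(from = "A", to = "B"),
    cpt = list(A = matrix(1 / 3, 1, 3), B = copy))
  fix <- sample_compendium(bn, 100, seed = 2)
  expect_equal(unlist(fix$discrete[1, -1]), unlist(fix$discrete[2, -1]),
               ignore_attr = TRUE)
})

test_that("sampled child-parent configuration frequencies match the CPTs", {
  bn <- stm_fixture_bn()
  fix <- sample_compendium(bn, 2000, seed = 3)
  states <- as.matrix(fix$discrete[, -1])
  rownames(states) <- fix$discrete$gene
  stm <- states["STM", ]
  for (child in c("CUC1", "TCP4")) {
    tab <- bn$cpt[[child]]
    for (ps in 0:2) {
      n_ps <- sum(stm == ps)
      for (cs in 0:2) {
        p_true <- tab[ps + 1L, cs + 1L]
        obs <- sum(states[child, ] == cs & stm == ps) / n_ps
        se <- sqrt(p_true * (1 - p_true) / n_ps)
        expect_lt(abs(obs - p_true), 3 * se + 1e-12)
      }
    }
  }
})

test_that("ancestral sampling frequencies pass a goodness-of-fit test at n = 10000", {
  bn <- stm_fixture_bn()
  fix <- sample_compendium(bn, 10000, seed = 11)
  states <- as.matrix(fix$discrete[, -1])
  rownames(states) <- fix$discrete$gene
  # chi-squared GoF of the child distribution within each parent state
  for (ps in 0:2) {
    idx <- states["STM", ] == ps
    obs <- tabulate(states["CUC1", idx] + 1L, nbins = 3)
    gof <- chisq.test(obs, p = bn$cpt$CUC1[ps + 1L, ])
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("the same seed reproduces a compendium bit-exactly", {
  bn <- stm_fixture_bn()
  a <- sample_compendium(bn, 50, seed = 9)
  b <- sample_compendium(bn, 50, seed = 9)
  expect_identical(a, b)
  c <- sample_compendium(bn, 50, seed = 10)
  expect_false(identical(a$expression, c$expression))
})

test_that("noiseless emissions invert through discretisation", {
  bn <- stm_fixture_bn(emission_sd = 0)
  fix <- sample_compendium(bn, 200, seed = 4)
  expect_equal(discretise(fix$expression)[, -1], fix$discrete[, -1])
})

test_that("the STM fixture network honours its contract", {
  bn <- stm_fixture_bn()
  expect_length(bn$nodes, 6)
  expect_true(any(bn$edges$from == "STM" & bn$edges$to == "CUC1"))
  expect_setequal(bn$edges$to, c("CUC1", "AIL7", "CHR40", "TCP3", "TCP4"))
  expect_silent(validate_ground_truth_bn(bn))
  # repressor children carry inverted CPTs with strong diagonal mass
  expect_gte(min(diag(bn$cpt$CUC1)), 0.8)
  expect_gte(min(diag(bn$cpt$TCP4[, 3:1])), 0.8)
})

test_that("cyclic graphs are rejected with a cycle report", {
  copy <- diag(3)
  expect_error(
    ground_truth_bn(c("A", "B"),
                    tibble::tibble(from = c("A", "B"), to = c("B", "A")),
                    cpt = list(A = copy, B = copy)),
    "cycle")
})

test_that("CPT invariants are enforced", {
  bad <- matrix(c(0.5, 0.4, 0.2), 1, 3)
  expect_error(
    ground_truth_bn("A", tibble::tibble(from = character(), to = character()),
                    cpt = list(A = bad)),
    "sum to 1")
  expect_error(
    ground_truth_bn("A", tibble::tibble(from = character(), to = character()),
                    cpt = list(A = matrix(1 / 3, 1, 3)),
                    emission_means = c(0, 0, 1)),
    "increasing")
})

test_that("a noiseless timecourse plants exact effects and empty designs give empty truth", {
  des <- timecourse_design(
    n_genes = 10,
    planted = tibble::tibble(gene = 3L, contrast = "c1", effect = 2),
    contrasts = "c1", replicates = 3, noise_sd = 0, seed = 1)
  tc <- make_timecourse(des)
  trt <- as.matrix(tc$arms$c1$treated[, -1])
  ctl <- as.matrix(tc$arms$c1$control[, -1])
  expect_equal(unname(rowMeans(trt) - rowMeans(ctl)),
               c(0, 0, 2, rep(0, 7)))
  empty <- make_timecourse(timecourse_design(
    5, tibble::tibble(gene = integer(), contrast = character(), effect = numeric()),
    contrasts = "c1", replicates = 2, noise_sd = 0.1, seed = 1))
  expect_equal(nrow(empty$truth), 0)
})

test_that("timecourse designs reject invalid inputs", {
  expect_error(timecourse_design(10, tibble::tibble(
    gene = 1L, contrast = "c1", effect = 1), "c1", replicates = 1), "replicates")
  expect_error(timecourse_design(10, tibble::tibble(
    gene = c(1L, 1L), contrast = "c1", effect = 1), "c1"), "unique")
})

test_that("ground-truth networks round-trip through YAML", {
  bn <- stm_fixture_bn()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_bn_yaml(bn, f)
  bn2 <- read_bn_yaml(f)
  expect_equal(bn2$nodes, bn$nodes)
  expect_equal(as.data.frame(bn2$edges), as.data.frame(bn$edges))
  expect_equal(bn2$cpt$TCP4, bn$cpt$TCP4, ignore_attr = TRUE)
  expect_equal(bn2$emission_sd, bn$emission_sd)
})
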