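test_that("zero is a fixed point when basal production is off", {
  p <- model_parameters(a0 = 0)
  geom <- cell_file_geometry()
  d <- model_rhs(rep(0, 70), p, geom)
  # every species except TCP (driven by PrIF) has zero derivative; TCP
  # production in primordium cells is PrIF-driven even at zero state
  expect_equal(d[-seq(5, 70, by = 7)], rep(0, 60))
  p2 <- model_parameters(a0 = 0, beta_mS = 0, beta_mC1 = 0, beta_T = 0,
                         beta_rC = 0, beta_rAB = 0)
  expect_equal(model_rhs(rep(0, 70), p2, geom), rep(0, 70))
})

test_that("a single cell receives no diffusive flux", {
  p <- model_parameters(diffusion = TRUE, D = 5)
  p0 <- model_parameters(diffusion = FALSE)
  geom1 <- cell_file_geometry(1, prif = 0)
  s <- c(0.3, 0.7, 0.1, 0.2, 0, 0.4, 0)
  expect_equal(model_rhs(s, p, geom1), model_rhs(s, p0, geom1))
})

test_that("the right-hand side matches an independently coded oracle", {
  p <- model_parameters()
  geom <- cell_file_geometry()
  withr::with_seed(11, {
    s <- runif(70, 0, 2)
  })
  expect_equal(model_rhs(s, p, geom), oracle_rhs(s, p, geom$prif),
               tolerance = 1e-12)
  # and with switches flipped
  p2 <- model_parameters(autoregulation = FALSE, diffusion = FALSE)
  expect_equal(model_rhs(s, p2, geom), oracle_rhs(s, p2, geom$prif),
               tolerance = 1e-12)
  expect_error(model_rhs(-s, p, geom), "non-negative")
})

test_that("an all-zero production model converges to the zero profile", {
  p <- model_parameters(a0 = 0, beta_mS = 0, beta_mC1 = 0, beta_T = 0,
                        beta_rC = 0, beta_rAB = 0)
  prof <- simulate_to_steady_state(p)
  expect_true(attr(prof, "converged"))
  expect_equal(max(abs(as.matrix(prof[, SPECIES]))), 0, tolerance = 1e-6)
})

test_that("the default wild-type run resolves CUC1 to the boundary", {
  prof <- simulate_to_steady_state()
  expect_true(attr(prof, "converged"))
  expect_lt(attr(prof, "residual"), 1e-9)
  m <- attr(prof, "metrics")
  expect_true(m$cuc1_peak_cell %in% 4:5)
  expect_true(m$cuc1_peak_unique)
  expect_gte(m$boundary_centre_ratio, 2)
  expect_equal(m$stm_monotonicity_violations, 0)
  expect_lt(m$tcp_leakage_ratio, 0.1)
  expect_true(m$mir164c_argmax_cell %in% 8:10)
})

test_that("the single-cell open loop matches an independent root-finder", {
  # one meristem cell, no feedback loops: autoregulation off and the
  # CUC1 -> STM arm silenced so the fixed point is a one-way cascade
  p <- model_parameters(autoregulation = FALSE, a_C = 0, diffusion = FALSE)
  geom <- cell_file_geometry(1, prif = 0)
  prof <- simulate_to_steady_state(p, geom)
  expect_true(attr(prof, "converged"))
  n <- p$hill_n
  # independent algebra: mS* from basal production, then S*, rC*, mC1*, C1*
  mS_star <- p$beta_mS * (p$a0 / (p$a0 + p$a_C + p$a_S)) / p$delta_mS
  S_star <- uniroot(function(S) p$tau_S * mS_star - p$delta_S * S,
                    c(0, 100), tol = 1e-12)$root
  rC_star <- p$beta_rC * S_star^n / (p$K_rCS^n + S_star^n) / p$delta_rC
  mC1_star <- uniroot(function(m)
    p$beta_mC1 * S_star^n / (p$K_C1S^n + S_star^n) -
      p$delta_mC1 * m - p$kappa * m * rC_star,
    c(0, 100), tol = 1e-14)$root
  C1_star <- p$tau_C1 * mC1_star / p$delta_C1
  expect_equal(prof$S, S_star, tolerance = 1e-6)
  expect_equal(prof$mC1, mC1_star, tolerance = 1e-6)
  expect_equal(prof$C1, C1_star, tolerance = 1e-6)
})

test_that("losing diffusion abolishes boundary localisation", {
  wt <- run_variant(variant = "wild-type")
  nd <- run_variant(variant = "no-diffusion")
  expect_true(attr(nd, "converged"))
  expect_lt(attr(nd, "metrics")$boundary_centre_ratio, 1.2)
  expect_gte(attr(wt, "metrics")$boundary_centre_ratio, 2)
})

test_that("the pattern survives without autoregulation", {
  na <- run_variant(variant = "no-autoregulation")
  expect_true(attr(na, "converged"))
  expect_true(attr(na, "metrics")$cuc1_peak_cell %in% 4:5)
  expect_true(attr(na, "metrics")$cuc1_peak_unique)
})

test_that("wild-type variant equals the plain steady-state call", {
  wt <- run_variant(variant = "wild-type")
  ref <- simulate_to_steady_state()
  expect_equal(as.matrix(wt[, SPECIES]), as.matrix(ref[, SPECIES]),
               tolerance = 1e-12)
})

test_that("in-silico STM overexpression raises miR164c everywhere in the meristem", {
  wt <- run_variant(variant = "wild-type")
  oe <- run_variant(variant = "stm-oe")
  expect_true(all(oe$rC[4:10] > wt$rC[4:10]))
  expect_true(all(oe$S[4:10] > wt$S[4:10]))
  cmp <- compare_to_wildtype(oe, wt)
  expect_true(all(cmp$fold_change[cmp$species == "rC"] > 1))
})

test_that("transient STM induction raises total CUC1 mRNA before miR164c catches up", {
  resp <- induction_response(t_induction = 0.5, oe_strength = 0.5)
  expect_gt(resp$fold_change[resp$species == "mC1"], 1)
  expect_gt(resp$fold_change[resp$species == "mS"], 1)
})

test_that("CUC1 induction raises CUC1 protein", {
  wt <- run_variant(variant = "wild-type")
  ci <- run_variant(variant = "cuc1-ind")
  expect_true(all(ci$C1 > wt$C1))
  expect_error(run_variant(variant = "nonsense"), "arg")
})

test_that("mirrored geometry mirrors the steady state exactly", {
  wt <- simulate_to_steady_state()
  mir <- simulate_to_steady_state(geometry = cell_file_geometry(mirrored = TRUE))
  for (sp in SPECIES) {
    expect_equal(mir[[sp]], rev(wt[[sp]]), tolerance = 1e-10)
  }
})

test_that("the steady state is unique across random initial conditions", {
  ref <- simulate_to_steady_state()
  for (s in 1:3) {
    withr::with_seed(200 + s, {
      y0 <- runif(70, 0, 2)
    })
    alt <- simulate_to_steady_state(initial = y0)
    expect_true(attr(alt, "converged"))
    expect_equal(as.matrix(alt[, SPECIES]), as.matrix(ref[, SPECIES]),
                 tolerance = 1e-6)
  }
})

test_that("profile metrics work on constructed profiles", {
  geom <- cell_file_geometry()
  flat <- tibble::tibble(cell = 1:10, prif = geom$prif,
                         mS = 1, S = 1, mC1 = 1, C1 = 1, T = c(1, 1, 1, rep(0, 7)),
                         rC = 1, rAB = 0)
  m <- profile_metrics(flat, geom)
  expect_equal(m$boundary_centre_ratio, 1)
  expect_equal(m$stm_monotonicity_violations, 0)
  spike <- dplyr::mutate(flat, C1 = c(0, 0, 0, 5, 1, 1, 1, 1, 1, 1))
  m2 <- profile_metrics(spike, geom)
  expect_equal(m2$cuc1_peak_cell, 4)
  expect_equal(m2$boundary_centre_ratio, 5)
})

test_that("local sensitivity reports two rows per scalar parameter", {
  p <- model_parameters()
  geom <- cell_file_geometry()
  # restrict runtime: coarser tolerance is fine for bookkeeping checks
  rep0 <- local_sensitivity(p, geom, perturbation = 0, tol = 1e-6)
  n_scalar <- sum(vapply(p, is.numeric, logical(1)))
  expect_equal(nrow(rep0), 2L * n_scalar)
  expect_true(all(rep0$converged))
  expect_equal(max(abs(rep0$rel_d_peak_amplitude)), 0, tolerance = 1e-6)
  expect_equal(max(abs(rep0$d_peak_cell)), 0)
})

test_that("doubling CUC1 protein turnover halves CUC1 in the open loop", {
  p <- model_parameters(autoregulation = FALSE, a_C = 0, diffusion = FALSE)
  geom <- cell_file_geometry(1, prif = 0)
  base <- simulate_to_steady_state(p, geom)
  p2 <- p; p2$delta_C1 <- 2 * p$delta_C1
  faster <- simulate_to_steady_state(p2, geom)
  expect_equal(faster$C1, base$C1 / 2, tolerance = 1e-6)
  expect_equal(base$C1, p$tau_C1 * base$mC1 / p$delta_C1, tolerance = 1e-8)
})

test_that("trajectories preserve non-negativity", {
  withr::with_seed(42, {
    y0 <- runif(70, 0, 3)
  })
  prof <- simulate_to_steady_state(initial = y0)
  expect_true(all(as.matrix(prof[, SPECIES]) >= -1e-9))
})
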