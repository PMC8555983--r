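test_that("simulations are reproducible under a seed and conserve size at division", {
  p <- small_concurrent(seed = 42, n_cells = 600)
  a <- simulate_concurrent(p)
  b <- simulate_concurrent(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  p2 <- small_concurrent(seed = 43, n_cells = 600)
  expect_false(identical(a$Ld_um, simulate_concurrent(p2)$Ld_um))

  # the two daughters partition the mother exactly
  pa <- small_icd(seed = 3, alpha = 0.05, n_cells = 800)
  sim <- simulate_icd(pa)
  # daughter birth size + recorded sibling = division size
  idx <- match(sim$parent_id, sim$cell_id)
  has <- !is.na(idx)
  expect_equal(sim$L0_um[has] + sim$L0_sibling_um[has], sim$Ld_um[idx[has]],
               tolerance = 1e-12)
  expect_true(all(sim$n_ori_init %in% c(2L, 4L)))
})

test_that("post burn-in birth sizes are stationary", {
  sim <- simulate_concurrent(small_concurrent(seed = 8, n_cells = 5000))
  keep <- !sim$burn_in
  m <- stats::aggregate(log(L0_um) ~ generation, sim[keep, ], mean)
  fit <- stats::lm(`log(L0_um)` ~ generation, m)
  sl <- summary(fit)$coefficients["generation", ]
  expect_lt(abs(sl["Estimate"]), 3 * sl["Std. Error"] + 1e-4)
})

test_that("small-noise ICD simulation matches the double-adder (Witz) correlation pattern", {
  p <- small_icd(seed = 7, alpha = 0, cv = 0.05, n_cells = 10000)
  sim <- simulate_icd(p)
  keep <- !sim$burn_in
  rounds <- latent_rounds(sim)
  vr <- stats::var(sim$L_init_um[keep]) / stats::var(sim$L0_um[keep])
  pred <- predict_witz(growth_factors(var_ratio = vr, n_span = 1))

  g <- raw_ols_slope(subperiod_samples(sim, rounds, "G"))
  b <- raw_ols_slope(b_period_samples(sim))
  expect_lt(abs(g["slope"] - pred$zeta_G), 3 * g["se"])
  expect_lt(abs(b["slope"] - pred$zeta_B), 3 * b["se"])

  # inputs are perfect adders: measured zeta_I and zeta_CD near 0
  zi <- adder_slope(subperiod_samples(sim, rounds, "I"))
  zcd <- adder_slope(subperiod_samples(sim, rounds, "CD"))
  expect_lt(abs(zi$zeta), 4 * zi$se)
  expect_lt(abs(zcd$zeta), 4 * zcd$se)
})

test_that("the AND gate reproduces the single-process limits", {
  # replication/segregation instantaneous: inter-division process always
  # limiting, G behaves as an adder, division size independent of VB
  p_h <- small_concurrent(seed = 5, n_cells = 6000)
  p_h$tau_CDprime <- 0
  p_h$cv_CDprime <- 0
  sim_h <- simulate_concurrent(p_h)
  expect_equal(emergent_ph(sim_h), 1)
  zg <- adder_slope(subperiod_samples(sim_h, latent_rounds(sim_h), "G"))
  expect_lt(abs(zg$zeta), 3 * zg$se)
  zcd_raw <- raw_ols_slope(subperiod_samples(sim_h, latent_rounds(sim_h), "CD"))
  expect_lt(abs(zcd_raw["slope"] - (-1)), 3 * zcd_raw["se"] + 0.02)

  # vanishing inter-division increment: replication always limiting,
  # C+D' behaves as a pure timer with growth factor exp(mu tau')
  p_c <- small_concurrent(seed = 6, n_cells = 6000)
  p_c$mean_dH <- 1e-6
  p_c$cv_dH <- 0
  sim_c <- simulate_concurrent(p_c)
  expect_equal(emergent_ph(sim_c), 0)
  keep <- !sim_c$burn_in
  Qp <- exp(mean(log(sim_c$Ld_um / sim_c$L_init_um)[keep]))
  zcd <- raw_ols_slope(subperiod_samples(sim_c, latent_rounds(sim_c), "CD"))
  expect_lt(abs(zcd["slope"] - (Qp - 1)), 3 * zcd["se"] + 0.02)
})

test_that("the lottery coupling scheme reproduces the concurrent-cycles closed forms", {
  p <- concurrent_params(mean_dH = 1.60, cv_dH = 0.05, mean_dI = 1,
                         cv_dI = 0.05, tau_CDprime = 66.2, cv_CDprime = 0.05,
                         alpha = 0, growth_rate_mean = log(2) / 90,
                         growth_rate_cv = 0.02, n_cells = 10000,
                         n_lineages = 100, seed = 3, burn_in = 10,
                         gate = "lottery", p_H = 0.5)
  sim <- simulate_concurrent(p)
  keep <- !sim$burn_in
  rounds <- latent_rounds(sim)
  vr <- stats::var(sim$L_init_um[keep]) / stats::var(sim$L0_um[keep])
  Qp <- exp(log(2) / 90 * 66.2)
  pred <- predict_concurrent_adder_adder(
    0.5, growth_factors(QCDprime = Qp, var_ratio = vr))

  g <- raw_ols_slope(subperiod_samples(sim, rounds, "G"))
  b <- raw_ols_slope(b_period_samples(sim))
  cd <- raw_ols_slope(subperiod_samples(sim, rounds, "CD"))
  expect_lt(abs(g["slope"] - pred$zeta_G), 3 * g["se"])
  expect_lt(abs(b["slope"] - pred$zeta_B), 3 * b["se"])
  expect_lt(abs(cd["slope"] - pred$zeta_CD), 3 * cd["se"])

  expect_error(concurrent_params(gate = "lottery", p_H = NA), "p_H")
})

test_that("balanced AND-gate preset divides with roughly equal odds", {
  sim <- simulate_concurrent(small_concurrent(seed = 11, n_cells = 6000))
  ph <- emergent_ph(sim)
  expect_gt(ph, 0.4)
  expect_lt(ph, 0.6)
})

test_that("raising the inter-division increment makes H increasingly limiting", {
  base <- small_concurrent(seed = 13, n_cells = 2500)
  sims <- increase_d_series(base, c(1.59, 1.9, 2.2))
  phs <- vapply(sims, emergent_ph, numeric(1))
  expect_true(all(diff(phs) > 0))
  d_means <- vapply(sims, function(s) {
    keep <- !s$burn_in
    mean((s$t_div_min - s$t_init_min)[keep])
  }, numeric(1))
  expect_true(all(diff(d_means) > 0))
  expect_error(increase_d_series(base, c(2, 1.8)), "non-decreasing")
})

test_that("pathological parameters raise a divergence error", {
  p <- small_concurrent(seed = 2, n_cells = 400)
  p$tau_CDprime <- 1e5   # size explodes during an absurd timer period
  expect_error(simulate_concurrent(p), "diverged")
  expect_error(emergent_ph(simulate_icd(small_icd(n_cells = 200))),
               "limiting process")
})
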