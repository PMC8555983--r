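test_that("zeta/lambda conversions reproduce the canonical strategies and round-trip", {
  # adder, timer, sizer correspondences at Q = 2
  expect_equal(zeta_from_lambda(0.5, 2), 0)
  expect_equal(zeta_from_lambda(0, 2), 1)
  expect_equal(zeta_from_lambda(1, 2), -1)
  expect_equal(zeta_from_lambda(0, 1.8), 0.8)
  expect_equal(lambda_from_zeta(0, 2), 0.5)
  expect_equal(lambda_from_zeta(-1, 2), 1)
  expect_equal(lambda_from_zeta(0.8, 1.8), 0)

  for (lam in seq(-1, 2, by = 0.25)) {
    for (Q in c(0.6, 1, 1.8, 2, 4)) {
      expect_equal(lambda_from_zeta(zeta_from_lambda(lam, Q), Q), lam,
                   tolerance = 1e-12)
    }
  }
  expect_error(zeta_from_lambda(0.5, 0), "positive")
  expect_error(lambda_from_zeta(0, -1), "positive")
})

test_that("growth factors and generations spanned follow their definitions", {
  expect_equal(growth_factor(c(1, 2), c(2, 4)), 2)
  expect_equal(growth_factor(1, 0.9, ori_factor = 2), 1.8)
  expect_error(growth_factor(c(1, 2), c(2)), "equal length")
  expect_error(growth_factor(c(-1, 2), c(2, 4)), "positive")

  expect_identical(generations_spanned(73, 80), 1L)
  expect_identical(generations_spanned(0, 60), 1L)
  expect_identical(generations_spanned(130, 60), 3L)
})

test_that("noiseless adder simulation doubles exactly over a cycle", {
  p <- icd_params(mean_dI = 1, cv_dI = 0, mean_dCD = 1.6, cv_dCD = 0,
                  alpha = 0, growth_rate_cv = 0, n_cells = 200,
                  n_lineages = 10, seed = 4, burn_in = 40L)
  sim <- simulate_icd(p)
  keep <- !sim$burn_in
  QG <- growth_factor(sim$L0_um[keep], sim$Ld_um[keep])
  expect_equal(QG, 2, tolerance = 1e-6)
})

test_that("ICD and Witz predictions agree with the closed forms and nest", {
  gf4 <- growth_factors(var_ratio = 4, n_span = 1)
  expect_equal(predict_icd(0, 0, gf4)$zeta_G, 0)
  expect_equal(predict_witz(gf4)$zeta_G, 0)
  gf1 <- growth_factors(var_ratio = 1, n_span = 1)
  expect_equal(predict_witz(gf1)$zeta_G, -0.75)

  # Witz is the zeta_I = zeta_CD = 0 special case of ICD for any inputs
  for (vr in c(0.5, 1, 2.3)) {
    for (n in 1:3) {
      gf <- growth_factors(var_ratio = vr, n_span = n)
      icd <- predict_icd(0, 0, gf)
      witz <- predict_witz(gf)
      expect_equal(icd$zeta_G, witz$zeta_G)
      expect_equal(icd$zeta_B, witz$zeta_B)
      expect_identical(witz$approximate, n > 1)
    }
  }
})

test_that("concurrent-cycles predictions hit the pH limits and reduce to the adder-adder scheme", {
  gf <- growth_factors(QCDprime = 1.8, var_ratio = 1)
  expect_equal(predict_concurrent(1, 0, 0, gf)$zeta_CD, -1)
  expect_equal(predict_concurrent(1, 0, 0, gf)$zeta_G, 0)
  expect_equal(predict_concurrent(0, 0, 0, gf)$zeta_CD, 0.8)
  expect_equal(predict_concurrent_adder_adder(0, gf)$zeta_B, -0.55)

  for (ph in seq(0, 1, by = 0.2)) {
    a <- predict_concurrent(ph, 0, 0, gf)
    b <- predict_concurrent_adder_adder(ph, gf)
    expect_equal(a$zeta_CD, b$zeta_CD)
    expect_equal(a$zeta_G, b$zeta_G)
  }

  # monotone interpolation of zeta_CD between Q-1 (pH=0) and -1 (pH=1)
  ph_grid <- seq(0, 1, by = 0.05)
  zcd <- vapply(ph_grid,
                function(p) predict_concurrent_adder_adder(p, gf)$zeta_CD,
                numeric(1))
  expect_equal(zcd[1], 0.8)
  expect_equal(zcd[length(zcd)], -1)
  expect_true(all(diff(zcd) < 0))

  expect_error(predict_concurrent(1, 1, 1, gf), "singular")
})

test_that("fixed-mode pH fit inverts the adder-adder C+D relation", {
  gf <- growth_factors(QCDprime = 1.8, var_ratio = 1)
  obs <- function(z, se = 0.05) data.frame(period = "CD", zeta = z, se = se)

  expect_equal(fit_ph(obs(-1), gf)$pH, 1)
  expect_equal(fit_ph(obs(-0.10), gf)$pH, 4 / 7, tolerance = 1e-12)
  expect_equal(fit_ph(obs(0.8), gf)$pH, 0)
  expect_warning(f <- fit_ph(obs(0.9), gf), "clipped")
  expect_equal(f$pH, 0)
  expect_warning(f2 <- fit_ph(obs(-1.2), gf), "clipped")
  expect_equal(f2$pH, 1)

  # delta-method uncertainty is positive and scales with the slope error
  expect_gt(fit_ph(obs(-0.10, se = 0.1), gf)$pH_se,
            fit_ph(obs(-0.10, se = 0.05), gf)$pH_se)
})

test_that("pH fitting recovers the generating parameters from noiseless slopes", {
  gf <- growth_factors(QCDprime = 1.8, var_ratio = 1.3)
  for (ph_true in c(0.15, 0.5, 0.9)) {
    pred <- predict_concurrent_adder_adder(ph_true, gf)
    obs <- data.frame(period = "CD", zeta = pred$zeta_CD, se = 0.01)
    expect_equal(fit_ph(obs, gf)$pH, ph_true, tolerance = 1e-6)
  }

  pred <- predict_concurrent(0.6, -0.2, 0, gf)
  obs <- data.frame(period = c("G", "CD"),
                    zeta = c(pred$zeta_G, pred$zeta_CD),
                    se = c(0.01, 0.01))
  fit <- fit_ph(obs, gf, mode = "free_zetaH")
  expect_equal(fit$pH, 0.6, tolerance = 1e-3)
  expect_equal(fit$zeta_H, -0.2, tolerance = 1e-3)

  expect_error(fit_ph(data.frame(period = "G", zeta = 0, se = 1), gf),
               "CD")
  expect_error(fit_ph(data.frame(period = "CD", zeta = 0, se = 1), gf,
                      mode = "free_zetaH"), "G")
})
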