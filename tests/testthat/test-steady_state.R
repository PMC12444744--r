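wt_liq <- weighted_t1(cb_models$cb_liquid)   # 6.8412 s
wt_sol <- weighted_t1(cb_models$cb_solid)    # 98.823 s

test_that("steady-state magnetization reproduces the worked values", {
  # cocoa-butter liquid/solid methylenes at T = D1 + AQ = 25.05 s
  expect_equal(mxy_steady_state(10, 25.05, wt_liq), 0.173, tolerance = 0.002 / 0.173)
  expect_equal(mxy_steady_state(10, 25.05, wt_sol), 0.166, tolerance = 0.002 / 0.166)
  expect_equal(mxy_steady_state(30, 25.05, wt_liq), 0.499, tolerance = 0.002 / 0.499)
  # limits (exp(-T/T1) itself is 7e-3 at T = 5*T1, so use T = 10*T1)
  expect_equal(mxy_steady_state(90, 10 * 3, 3), 1, tolerance = 1e-3)
  expect_lt(mxy_steady_state(45, 1e-6, 100), 1e-6)
  expect_error(mxy_steady_state(95, 25, 10), "flip_angle_deg")
  expect_error(mxy_steady_state(10, -1, 10), "repetition_time_s")
})

test_that("steady-state signal is bounded by sin(beta) and monotone", {
  grid <- expand.grid(beta = c(5, 23, 45, 77, 90),
                      tr = c(0.5, 5, 25.05, 300),
                      t1 = c(0.2, 6.84, 98.8))
  m <- with(grid, mxy_steady_state(beta, tr, t1))
  expect_true(all(m >= 0 & m <= sin(grid$beta * pi / 180) + 1e-12))
  # increasing in T, decreasing in T1
  tr <- seq(1, 400, by = 1)
  expect_true(all(diff(mxy_steady_state(23, tr, 50)) > 0))
  t1 <- seq(1, 400, by = 1)
  expect_true(all(diff(mxy_steady_state(23, 25.05, t1)) < 0))
})

test_that("the Ernst angle maximizes the steady-state signal", {
  expect_equal(ernst_angle(100, 1), 90, tolerance = 1e-6)
  expect_equal(ernst_angle(log(2), 1), 60, tolerance = 1e-9)
  expect_equal(ernst_angle(25.05, wt_sol), 39.1, tolerance = 0.1 / 39.1)
  # numeric maximization check at 0.1-degree resolution over a (T, T1) grid
  betas <- seq(0.1, 90, by = 0.1)
  for (tr in c(2, 25.05, 120)) {
    for (t1 in c(1.06, 6.84, 98.8)) {
      be <- ernst_angle(tr, t1)
      m <- mxy_steady_state(betas, tr, t1)
      expect_lt(abs(betas[which.max(m)] - be), 0.1 + 1e-9)
      for (d in c(-5, 5)) {
        bd <- min(max(be + d, 0.1), 90)
        if (abs(bd - be) > 1)
          expect_gt(mxy_steady_state(be, tr, t1),
                    mxy_steady_state(bd, tr, t1))
      }
    }
  }
})

test_that("the liquid/solid intensity error grows with flip angle", {
  expect_equal(relative_intensity_error(10, 25.05, 5, 5 + 1e-12), 0,
               tolerance = 1e-6)
  # direct evaluation gives ~5% at beta = 10 for the cocoa-butter pair
  err10 <- relative_intensity_error(10, 25.05, wt_liq, wt_sol)
  expect_equal(err10, 5, tolerance = 0.2)
  errs <- vapply(seq(1, 90, by = 1), relative_intensity_error, 0,
                 repetition_time_s = 25.05, t1_fast_s = wt_liq,
                 t1_slow_s = wt_sol)
  expect_true(all(diff(errs) > 0))
  expect_error(relative_intensity_error(10, 25.05, 50, 5), "smaller")
})

test_that("SNR prediction rescales by signal ratio and root-scans", {
  s <- scheme_90m()
  expect_equal(predict_snr(19, s, s, 5), 19)
  s16 <- scheme_90m(n_scans = 16L)
  expect_equal(predict_snr(19, s, s16, 5), 38)
  # 90M SNR 19 -> LAM, dark-chocolate 30 ppm weighted T1 (1.0567 s)
  t1_dc <- weighted_t1(cb_models$dc_liquid)
  expect_equal(predict_snr(19, scheme_90m(), scheme_lam(), t1_dc), 42,
               tolerance = 0.5 / 42)
})

test_that("apparent SFC under partial saturation behaves physically", {
  sol <- cb_models$cb_solid; liq <- cb_models$cb_liquid
  # full recovery at 90 degrees: no bias
  relaxed <- acq_params(90, 5000, 0.05, 1)
  expect_equal(predict_sfc_bias(0.631, relaxed, sol, liq), 63.1,
               tolerance = 1e-6)
  # identical solid and liquid relaxation: common factor cancels
  expect_equal(predict_sfc_bias(0.4, scheme_lam(), liq, liq), 40,
               tolerance = 1e-9)
  # dark-chocolate models, per-component averaging: ~58.7% apparent
  expect_equal(
    predict_sfc_bias(0.631, scheme_lam(), cb_models$dc_solid,
                     cb_models$dc_liquid, convention = "per-component"),
    58.7, tolerance = 0.1 / 58.7)
  # underestimates whenever solid relaxes slower and recovery is partial
  for (s in c(0.2, 0.5, 0.8))
    expect_lt(predict_sfc_bias(s, scheme_lam(), sol, liq), 100 * s)
})

test_that("total measurement time is scans times repetition time", {
  expect_equal(acquisition_time(scheme_90m()), 3400.2)
  expect_equal(acquisition_time(scheme_lam()), 3206.4)
  expect_equal(acquisition_time(acq_params(90, 0, 1, 1)), 1)
})

test_that("the scheme-comparison table carries ratios and times", {
  t1 <- c("34.5 ppm" = wt_sol, "30 ppm" = wt_liq)
  tbl <- compare_schemes(scheme_90m(), scheme_lam(), t1)
  expect_equal(nrow(tbl), 2L)
  expect_equal(tbl$snr_ratio_b_over_a,
               tbl$mxy_ratio_b_over_a * sqrt(128 / 4))
  expect_equal(attr(tbl, "time_a_s"), 3400.2)
  # identical schemes: all ratios 1
  same <- compare_schemes(scheme_90m(), scheme_90m(), t1)
  expect_equal(same$mxy_ratio_b_over_a, c(1, 1))
  expect_equal(same$snr_ratio_b_over_a, c(1, 1))
})
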