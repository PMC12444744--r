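test_that("the average-TAG component list carries the right bookkeeping", {
  comps <- default_tag_components()
  mult <- vapply(comps, `[[`, 0, "multiplicity")
  shift <- vapply(comps, `[[`, 0, "shift_ppm")
  state <- vapply(comps, `[[`, "", "phase_state")
  # inner methylenes: 3 chains x (0.36*12 + 0.33*8 + 0.26*10 + 0.03*8)
  expect_equal(mult[shift == 30 & state == "liquid"], 29.4,
               tolerance = 0.005)
  # exactly one solid component, at the beta-polymorph shift
  expect_identical(sum(state == "solid"), 1L)
  expect_equal(shift[state == "solid"], 34.5)
  # omega-2, beta, omega-3, alpha each contribute one CH2 per chain
  for (p in c(23, 25, 32)) {
    expect_equal(mult[shift == p & state == "liquid"], 3)
  }
  expect_equal(mult[shift == 34.5 & state == "liquid"], 3)
})

test_that("spectrum generation is deterministic under a fixed seed", {
  a <- generate_spectrum("dc70", scheme_lam(), n_points = 2048, seed = 42)
  b <- generate_spectrum("dc70", scheme_lam(), n_points = 2048, seed = 42)
  expect_identical(a$spectrum$intensity, b$spectrum$intensity)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_spectrum("dc70", scheme_lam(), n_points = 2048, seed = 43)
  expect_false(identical(a$spectrum$intensity, c$spectrum$intensity))
  # generation does not disturb the global RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_spectrum("cb", n_points = 512, seed = 1))
  expect_identical(rnorm(3), before)
})

test_that("melted and defatted presets render their defining absences", {
  melted <- generate_spectrum("melted", scheme_90m())
  expect_equal(melted$ground_truth$sfc_percent, 0)
  # no broad solid component: the solid window holds only liquid tails,
  # which the chain-end subtraction cancels
  expect_lt(suppressWarnings(
    sfc_from_spectrum(melted$spectrum))$sfc_percent, 1)
  # with noise at SNR ~19 the melted SFC stays within the detection limit
  # set by the corrected-area noise (a few percent)
  noisy <- generate_spectrum("melted", scheme_90m(), seed = 1)
  expect_lt(suppressWarnings(
    sfc_from_spectrum(noisy$spectrum))$sfc_percent, 10)
  defat <- generate_spectrum("defatted", scheme_90m(), seed = 1)
  aliph <- integrate_window(defat$spectrum, ppm_window(38, 29))
  suc <- integrate_window(defat$spectrum, ppm_window(104, 81))
  expect_lt(abs(aliph), 0.05 * suc)
})

test_that("rendered areas scale with scans and steady-state factors", {
  p <- sample_preset("cb")
  w <- ppm_window(38, 29)
  base <- integrate_window(
    generate_spectrum(p, scheme_90m())$spectrum, w)
  quad <- integrate_window(
    generate_spectrum(p, scheme_90m(n_scans = 16L))$spectrum, w)
  expect_equal(quad / base, 4, tolerance = 1e-6)
})

test_that("IR series generation round-trips the reference models", {
  tau <- make_tau_grid(23, 0.01, 1000)
  expect_equal(
    generate_ir_series(relax_model(1, 1), tau)$amplitude[tau == 1000, 1],
    1, tolerance = 1e-6, ignore_attr = TRUE)
  s <- generate_ir_series(list(solid = cb_models$cb_solid,
                               liquid = cb_models$cb_liquid), tau)
  fs <- fit_ir(s, 3, peak = "solid")
  fl <- fit_ir(s, 3, peak = "liquid")
  expect_equal(fs$components$t1_s, c(0.30, 18.8, 156.0), tolerance = 0.01)
  expect_equal(fl$components$t1_s, c(0.36, 20.0), tolerance = 0.01)
  a <- generate_ir_series(relax_model(1, 1), tau, noise_sigma = 0.02,
                          seed = 9)
  b <- generate_ir_series(relax_model(1, 1), tau, noise_sigma = 0.02,
                          seed = 9)
  expect_identical(a$amplitude, b$amplitude)
})

test_that("realized noise matches the target SNR within 20%", {
  wins <- default_windows()
  snrs <- vapply(1:50, function(seed) {
    sim <- generate_spectrum("cb", scheme_90m(), n_points = 8192,
                             seed = seed)
    estimate_snr(sim$spectrum, wins$liquid, wins$baseline_hi)
  }, 0)
  expect_equal(mean(snrs), 19, tolerance = 0.2)
})

test_that("the LAM scheme roughly doubles the liquid-signal SNR", {
  wins <- default_windows()
  snr_of <- function(scheme) mean(vapply(1:20, function(seed) {
    sim <- generate_spectrum("dc70", scheme, n_points = 8192, seed = seed)
    estimate_snr(sim$spectrum, wins$liquid, wins$baseline_hi)
  }, 0))
  r <- snr_of(scheme_lam()) / snr_of(scheme_90m())
  expect_equal(r, 42 / 19, tolerance = 0.15)
})

test_that("spinning sidebands conserve intensity and land off-window", {
  sim <- generate_spectrum("cb", scheme_90m(), seed = 3)
  full <- ppm_window(sim$spectrum$ppm[1] - 1e-9,
                     sim$spectrum$ppm[length(sim$spectrum$ppm)] + 1e-9)
  before <- integrate_window(sim$spectrum, full)
  out <- add_spinning_sidebands(sim$spectrum, 34.5, 3000, 0.1)
  expect_equal(integrate_window(out, full), before, tolerance = 1e-9)
  # sidebands at 34.5 +/- 29.85 ppm: visible at ~64.35, absent before
  near <- ppm_window(65.4, 63.4)
  expect_gt(integrate_window(out, near),
            10 * abs(integrate_window(sim$spectrum, near)))
  # fraction 0 is the identity
  expect_identical(add_spinning_sidebands(sim$spectrum, 34.5, 3000, 0),
                   sim$spectrum)
  # a spinning rate slow enough to fold into 38-29 ppm warns
  expect_warning(add_spinning_sidebands(sim$spectrum, 34.5, 300, 0.05),
                 "quantification region")
})

test_that("FID generation matches the frequency-domain rendering", {
  fidsim <- generate_fid("cb", scheme_90m())
  sp <- phase_correct(transform(apodize_exponential(fidsim$fid, 20),
                                n_points_out = 32768))
  got <- sfc_from_spectrum(sp)$sfc_percent
  # 20 Hz processing broadening pushes small tails across window edges,
  # so the tolerance is looser than for the direct rendering
  expect_equal(got, 75, tolerance = 3 / 75)
  direct <- generate_spectrum("cb", scheme_90m())
  a_direct <- integrate_window(direct$spectrum, ppm_window(38, 29))
  a_fid <- integrate_window(sp, ppm_window(38, 29))
  expect_equal(a_fid, a_direct, tolerance = 0.05)
})
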