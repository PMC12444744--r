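test_that("exponential apodization follows the line-broadening convention", {
  fid <- damped_fid(nu0_hz = 0, rate = pi * 10, sw_hz = 1e4,
                    duration_s = 0.1)
  expect_identical(apodize_exponential(fid, 0)$samples, fid$samples)
  a <- apodize_exponential(fid, 35)
  expect_equal(a$samples[1L], fid$samples[1L])  # t = 0 unchanged
  expect_error(apodize_exponential(fid, -1), "line_broadening_hz")
  # decay envelope is exp(-pi * LB * t)
  t5 <- 4 * fid$dwell_s
  expect_equal(Mod(a$samples[5L] / fid$samples[5L]), exp(-pi * 35 * t5))
})

test_that("20 Hz broadening widens a 10 Hz Lorentzian to 30 Hz FWHM", {
  fid <- damped_fid(nu0_hz = 2000, rate = pi * 10)
  sp <- transform(apodize_exponential(fid, 20))
  y <- Re(sp$intensity)
  nu <- (sp$ppm - 100) * 100.5
  above <- nu[y > max(y) / 2]
  expect_equal(max(above) - min(above), 30, tolerance = 0.02)
})

test_that("the transform matches the closed-form Lorentzian", {
  rate <- pi * 10
  nu0 <- 2000
  fid <- damped_fid(nu0_hz = nu0, rate = rate)
  sp <- transform(fid)
  nu <- (sp$ppm - 100) * 100.5
  # peak within one grid point of nu0 (grid spacing 1 Hz)
  expect_lt(abs(nu[which.max(Re(sp$intensity))] - nu0), 1 + 1e-9)
  # real part matches A*R/(R^2 + 4 pi^2 (nu - nu0)^2) away from edges
  sel <- abs(nu - nu0) < 200
  analytic <- rate / (rate^2 + 4 * pi^2 * (nu - nu0)^2)
  expect_lt(max(abs(Re(sp$intensity)[sel] - analytic[sel])) * rate, 1e-6)
})

test_that("the processing chain is linear in the FID", {
  f1 <- damped_fid(nu0_hz = 500, rate = pi * 15, sw_hz = 1e4,
                   duration_s = 0.2)
  f2 <- damped_fid(nu0_hz = -800, rate = pi * 40, sw_hz = 1e4,
                   duration_s = 0.2, amp = 0.3)
  fsum <- f1; fsum$samples <- f1$samples + f2$samples
  lhs <- transform(fsum)$intensity
  rhs <- transform(f1)$intensity + transform(f2)$intensity
  expect_lt(max(Mod(lhs - rhs)), 1e-10)
  # apodization commutes with the sum as well
  lhs2 <- transform(apodize_exponential(fsum, 20))$intensity
  rhs2 <- transform(apodize_exponential(f1, 20))$intensity +
    transform(apodize_exponential(f2, 20))$intensity
  expect_lt(max(Mod(lhs2 - rhs2)), 1e-10)
})

test_that("phase correction inverts a known phase error", {
  fid <- damped_fid(nu0_hz = 1000, rate = pi * 20, sw_hz = 2e4,
                    duration_s = 0.5)
  sp <- transform(fid)
  ident <- phase_correct(sp, phase_params(0, 0))
  expect_equal(ident$intensity, Re(sp$intensity))
  rot <- sp; rot$intensity <- sp$intensity * exp(1i * 37 * pi / 180)
  fixed <- phase_correct(rot, phase_params(phi0_deg = -37))
  # residual dispersion below 1e-9 of peak height
  expect_lt(max(abs(fixed$intensity - Re(sp$intensity))),
            1e-9 * max(Re(sp$intensity)))
})

test_that("auto_phase recovers the zeroth-order phase within 0.5 degrees", {
  fid <- damped_fid(nu0_hz = 1000, rate = pi * 20, sw_hz = 2e4,
                    duration_s = 0.5)
  sp <- transform(fid)
  expect_lt(abs(auto_phase(sp)$phi0_deg), 0.5)  # pure absorption
  rot <- sp; rot$intensity <- sp$intensity * exp(1i * 37 * pi / 180)
  expect_equal(auto_phase(rot)$phi0_deg, -37, tolerance = 0.5 / 37)
  # invariant to overall intensity scaling
  big <- rot; big$intensity <- rot$intensity * 1000
  expect_equal(auto_phase(big)$phi0_deg, auto_phase(rot)$phi0_deg,
               tolerance = 0.5 / 37)
  zero <- nmr_spectrum(c(2, 1), complex(real = c(0, 0)))
  expect_error(auto_phase(zero), "no signal")
})

test_that("windowed integration matches the Lorentzian closed form", {
  s <- lorentzian_spectrum(center_ppm = 34.5, fwhm_ppm = 0.2)
  expect_equal(integrate_window(s, ppm_window(38, 31.7)),
               lorentzian_mass(34.5, 0.2, 31.7, 38),  # = 0.97954
               tolerance = 1e-3)
  zero <- nmr_spectrum(seq(45, 25, length.out = 201), rep(0, 201))
  expect_equal(integrate_window(zero, ppm_window(38, 31.7)), 0)
})

test_that("integration is additive and linear over adjacent windows", {
  s <- lorentzian_spectrum(center_ppm = 31.8, fwhm_ppm = 0.3)
  whole <- integrate_window(s, ppm_window(38, 29))
  parts <- integrate_window(s, ppm_window(38, 31.7)) +
    integrate_window(s, ppm_window(31.7, 29))
  expect_equal(parts, whole, tolerance = 1e-9)
  s2 <- s; s2$intensity <- 2.5 * s$intensity
  expect_equal(integrate_window(s2, ppm_window(38, 29)), 2.5 * whole)
  expect_error(integrate_window(s, ppm_window(200, 150)), "overlap")
})

test_that("window sets load from a JSON config", {
  path <- file.path(withr::local_tempdir(), "windows.json")
  jsonlite::write_json(
    list(list(label = "solid", high_ppm = 38, low_ppm = 31.7),
         list(label = "liquid", high_ppm = 31.7, low_ppm = 29)),
    path, auto_unbox = TRUE)
  w <- read_windows(path)
  expect_named(w, c("solid", "liquid"))
  expect_equal(w$solid$high_ppm, 38)
  expect_equal(w$liquid$low_ppm, 29)
})

test_that("offset baseline mode removes a constant pedestal", {
  s <- lorentzian_spectrum(center_ppm = 34.5, fwhm_ppm = 0.2,
                           from_ppm = 50, to_ppm = 15)
  raised <- s; raised$intensity <- s$intensity + 0.7
  w <- ppm_window(38, 31.7)
  # the pedestal is removed exactly: raised and clean agree under "offset"
  expect_equal(integrate_window(raised, w, baseline = "offset"),
               integrate_window(s, w, baseline = "offset"),
               tolerance = 1e-9)
  # and the offset estimate only misses the clean integral by the tiny
  # Lorentzian tail present in the flanking windows
  expect_equal(integrate_window(raised, w, baseline = "offset"),
               integrate_window(s, w), tolerance = 5e-3)
})

test_that("SNR estimation recovers a constructed height/noise ratio", {
  wins <- default_windows()
  h <- 12
  sig <- 0.4
  snrs <- vapply(1:50, function(seed) {
    set.seed(seed)
    pp <- seq(50, 15, length.out = 4001)
    y <- h * (2 / (pi * 0.2)) / (1 + (2 * (pp - 30) / 0.2)^2) / (2 / (pi * 0.2))
    y <- y + rnorm(length(pp), 0, sig)
    estimate_snr(nmr_spectrum(pp, y), wins$liquid, wins$baseline_hi)
  }, 0)
  expect_equal(mean(snrs), h / sig, tolerance = 0.15)
  # scale invariance
  set.seed(1)
  pp <- seq(50, 15, length.out = 4001)
  y <- exp(-((pp - 30) / 0.3)^2) + rnorm(length(pp), 0, 0.05)
  s1 <- estimate_snr(nmr_spectrum(pp, y), wins$liquid, wins$baseline_hi)
  s2 <- estimate_snr(nmr_spectrum(pp, 2 * y), wins$liquid, wins$baseline_hi)
  expect_equal(s1, s2, tolerance = 1e-12)
  # noiseless spectrum flags "no measurable noise"
  clean <- nmr_spectrum(pp, exp(-((pp - 30) / 0.3)^2))
  expect_warning(out <- estimate_snr(clean, wins$liquid, wins$baseline_hi),
                 "no measurable noise")
  expect_identical(out, Inf)
  expect_error(estimate_snr(nmr_spectrum(pp[1:30], y[1:30]),
                            ppm_window(50, 49.8), ppm_window(49.8, 49.7)),
               "16")
})
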