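# Shared fixtures: all synthetic, built in code.

# FID of a single damped complex exponential at offset nu0 (Hz from the
# carrier) with decay rate R (Lorentzian FWHM R/pi Hz).
damped_fid <- function(nu0_hz = 2000, rate = pi * 10, sw_hz = 1e5,
                       duration_s = 1, carrier_ppm = 100, sf_mhz = 100.5,
                       amp = 1) {
  dwell <- 1 / sw_hz
  n <- round(duration_s * sw_hz)
  t <- (seq_len(n) - 1) * dwell
  nmr_fid(amp * exp((2i * pi * nu0_hz - rate) * t), dwell, carrier_ppm,
          params = acq_params(90, duration_s, duration_s, 1, sf_mhz))
}

# analytic absorption Lorentzian on a ppm grid, unit area, FWHM in ppm
lorentzian_spectrum <- function(center_ppm = 34.5, fwhm_ppm = 0.2,
                                from_ppm = 45, to_ppm = 25,
                                n = 20001, amp = 1) {
  pp <- seq(from_ppm, to_ppm, length.out = n)
  y <- amp * (2 / (pi * fwhm_ppm)) / (1 + (2 * (pp - center_ppm) / fwhm_ppm)^2)
  nmr_spectrum(pp, y)
}

# closed-form mass of a unit Lorentzian inside [lo, hi]
lorentzian_mass <- function(center, fwhm, lo, hi) {
  (atan(2 * (hi - center) / fwhm) - atan(2 * (lo - center) / fwhm)) / pi
}

cb_models <- cocoa_t1_models()
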