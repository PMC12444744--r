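# Synthetic cocoa-product spectra with known ground truth.
#
# The generator renders an average triacylglyceride (TAG) carbon skeleton:
# sharp Lorentzian lines for liquid-phase carbons, one broad Gaussian line
# at 34.5 ppm for the solid-phase methylenes, resolved sucrose lines for
# chocolate presets, steady-state amplitude scaling per component T1, and
# seeded Gaussian noise.  Because every component's multiplicity, lineshape
# and relaxation model are known, true window areas, SFC and TAG/sucrose
# ratios are available alongside the rendered data.
#
# Phase bookkeeping: the inner (CH2)n, alpha and omega-3 populations of
# solid chains collapse into the broad 34.5 ppm line, so their sharp liquid
# lines are scaled by (1 - solid_fraction).  The omega-2 (23 ppm) and beta
# (25 ppm) chain-end methylenes stay narrow in both phases (chain-end
# mobility persists in the crystal) and keep full multiplicity, but relax
# with a solid/liquid mixture weighted by the solid fraction -- which is
# what makes the corrected-area subtraction cancel the liquid alpha/omega-3
# overlap under any acquisition scheme, not just at full recovery.

#' Spectral component of a synthetic sample
#'
#' One carbon population: chemical shift, number of carbons contributing
#' per average TAG (or per sucrose), lineshape, linewidth, phase state and
#' relaxation model.  `pool` marks the populations shared between the solid
#' and liquid phases (`"ch2n"`, `"alpha"`, `"omega3"`, `"solid"`): at render
#' time the solid component is scaled by the solid fraction and the pooled
#' liquid lines by its complement.
#'
#' @param shift_ppm chemical shift, ppm.
#' @param multiplicity carbons contributing per molecule (> 0).
#' @param lineshape `"lorentzian"` or `"gaussian"`.
#' @param fwhm_hz full width at half maximum, Hz (> 0).
#' @param phase_state `"liquid"` or `"solid"`.
#' @param relaxation a [relax_model()].
#' @param pool phase-exchange pool tag or `NA`.
#' @return An object of class \code{spectral_component}.
#' @export
spectral_component <- function(shift_ppm, multiplicity,
                               lineshape = c("lorentzian", "gaussian"),
                               fwhm_hz = 25,
                               phase_state = c("liquid", "solid"),
                               relaxation = cocoa_t1_models()$cb_liquid,
                               pool = NA_character_) {
  lineshape <- match.arg(lineshape)
  phase_state <- match.arg(phase_state)
  stopifnot(is.finite(shift_ppm), is.finite(multiplicity), multiplicity > 0,
            is.finite(fwhm_hz), fwhm_hz > 0,
            inherits(relaxation, "relax_model"))
  structure(list(shift_ppm = shift_ppm, multiplicity = multiplicity,
                 lineshape = lineshape, fwhm_hz = fwhm_hz,
                 phase_state = phase_state, relaxation = relaxation,
                 pool = pool),
            class = "spectral_component")
}

#' Default TAG carbon populations
#'
#' Components of an average cocoa-butter TAG built from the fatty-acid
#' composition 36% stearic (S), 33% oleic (O), 26% palmitic (P) and 3%
#' linoleic (Ln, folded into the oleic-like counts since its lines overlap).
#' The inner methylenes number 12 per S chain, 10 per P and 8 per O, giving
#' `3 * (0.36*12 + 0.26*10 + (0.33+0.03)*8) = 29.4` carbons per TAG at
#' 30 ppm.  The alpha, omega-3, beta and omega-2 methylenes contribute one
#' carbon per chain (multiplicity 3) at 34.5, 32, 25 and 23 ppm; CH3 at 15
#' ppm (3), allylic at 28 ppm (2 per unsaturated chain), glycerol at 62 (2)
#' and 70 ppm (1), olefinic at 130 ppm (2 per unsaturated chain) and
#' carboxyl at 172 ppm (3).  One broad solid Gaussian at 34.5 ppm carries
#' the solid-phase inner-methylene + alpha + omega-3 population
#' (`29.4 + 3 + 3 = 35.4` carbons); liquid lines are 20 Hz Lorentzians and
#' the solid line a 250 Hz Gaussian, broad enough to be cleanly non-liquid
#' yet keeping over 99.5% of its area inside the 38-31.7 ppm solid window
#' so the area bookkeeping closes.  The omega-2 and beta lines carry pool
#' tag `"chain_end"`: rendered at full multiplicity but attenuated by the
#' solid-fraction-weighted mixture of solid and liquid steady-state
#' factors, mirroring their population split across the two phases.
#'
#' @param liquid_relax,solid_relax [relax_model()] objects for the liquid
#'   and solid methylene populations (defaults: the cocoa-butter reference
#'   models).
#' @return List of [spectral_component()] objects.
#' @export
default_tag_components <- function(liquid_relax = cocoa_t1_models()$cb_liquid,
                                   solid_relax = cocoa_t1_models()$cb_solid) {
  frac <- c(S = 0.36, O = 0.33, P = 0.26, Ln = 0.03)
  ch2n_counts <- c(S = 12, O = 8, P = 10, Ln = 8)  # Ln folded into O-like
  unsat <- frac[["O"]] + frac[["Ln"]]
  ch2n <- 3 * sum(frac * ch2n_counts)
  liq <- function(ppm, mult, pool = NA_character_)
    spectral_component(ppm, mult, "lorentzian", 20, "liquid",
                       liquid_relax, pool)
  c(list(
    liq(15,   3),                    # terminal CH3
    liq(23,   3, pool = "chain_end"),  # omega-2 CH2
    liq(25,   3, pool = "chain_end"),  # beta CH2
    liq(28,   2 * 3 * unsat),        # allylic CH2 (oleic C8/C11)
    liq(30,   ch2n, pool = "ch2n"),  # inner (CH2)n
    liq(32,   3, pool = "omega3"),   # omega-3 CH2
    liq(34.5, 3, pool = "alpha"),    # alpha CH2
    liq(62,   2),                    # glycerol C1/C3
    liq(70,   1),                    # glycerol C2
    liq(130,  2 * 3 * unsat),        # olefinic CH
    liq(172,  3)),                   # carboxyl
    list(spectral_component(34.5, ch2n + 6, "gaussian", 250, "solid",
                            solid_relax, pool = "solid")))
}

# Sucrose: four resolved carbons (103, 93, 83, 82 ppm) used for
# quantification plus an overlapped 8-carbon cluster between 60 and 75 ppm
# that is excluded from the quantification window.  Sucrose relaxes slowly;
# a single 60 s component stands in for its T1.
.sucrose_components <- function(per_tag) {
  relax <- relax_model(60, 1)
  resolved <- c(103, 93, 83, 82)
  cluster <- c(74.5, 73.5, 72.5, 71.5, 68.5, 66.5, 63.5, 61.5)
  lapply(c(resolved, cluster), function(ppm)
    spectral_component(ppm, per_tag, "lorentzian", 20, "liquid", relax,
                       pool = NA_character_))
}

#' Synthetic sample preset
#'
#' Composition presets emulating cocoa products: `cb` (cocoa butter), `cl`
#' (cocoa liquor), `dc70`/`dc40` (dark chocolate, 70% and 40% cocoa), `mc`
#' (milk chocolate), `melted` (liquid phase only) and `defatted` (sucrose
#' only, no aliphatic TAG signals).  The chocolate presets carry sucrose
#' scaled to nominal TAG/sucrose area ratios of 8.3 (dc70), 3.3 (mc) and
#' 1.7 (dc40) at full longitudinal recovery.  The per-scan noise level is
#' set so a conventional 90-degree, 4-scan acquisition of the preset yields
#' a 30 ppm peak SNR of `target_snr` (default 19).
#'
#' @param name one of `"cb"`, `"cl"`, `"dc70"`, `"dc40"`, `"mc"`,
#'   `"melted"`, `"defatted"`.
#' @param solid_fraction override the preset solid fraction in `[0, 1]`.
#' @param tag_suc_ratio override the nominal TAG/sucrose area ratio
#'   (`Inf` for no sucrose).
#' @param target_snr 30 ppm SNR under the reference 90-degree scheme used
#'   to set the noise level (ignored for `defatted`).
#' @return An object of class \code{sample_preset}: list with `name`,
#'   `components`, `solid_fraction`, `sucrose_per_tag`,
#'   `noise_sigma_per_scan`.
#' @export
sample_preset <- function(name = c("cb", "cl", "dc70", "dc40", "mc",
                                   "melted", "defatted"),
                          solid_fraction = NULL, tag_suc_ratio = NULL,
                          target_snr = 19) {
  name <- match.arg(name)
  defaults <- list(
    cb       = list(s = 0.75,  ratio = Inf),
    cl       = list(s = 0.70,  ratio = Inf),
    dc70     = list(s = 0.631, ratio = 8.3),
    dc40     = list(s = 0.60,  ratio = 1.7),
    mc       = list(s = 0.55,  ratio = 3.3),
    melted   = list(s = 0,     ratio = Inf),
    defatted = list(s = 0,     ratio = 0))[[name]]
  s <- solid_fraction %||% defaults$s
  ratio <- tag_suc_ratio %||% defaults$ratio
  if (s < 0 || s > 1) stop("`solid_fraction` must lie in [0, 1]")
  if (name == "melted" && s != 0) stop("the melted preset has no solid phase")

  tag <- if (name == "defatted") list() else default_tag_components()
  # total methylene mass in the 38-29 ppm TAG window (independent of the
  # solid split): inner (CH2)n + alpha + omega-3 = 35.4 carbons per TAG
  tag_mass <- 3 * sum(c(0.36, 0.33, 0.26, 0.03) * c(12, 8, 10, 8)) + 6
  suc_per_tag <- if (name == "defatted") 1
  else if (is.finite(ratio) && ratio > 0) tag_mass / (4 * ratio) else 0
  suc <- if (suc_per_tag > 0) .sucrose_components(suc_per_tag) else list()

  # per-scan noise sigma giving `target_snr` at the 30 ppm peak under a
  # reference 90-degree, 4-scan, full-recovery acquisition
  sigma <- if (name == "defatted") 0.05 else {
    ch2n <- tag_mass - 6
    height <- max(1 - s, 0.05) * ch2n * 2 / (pi * (20 / 100.5)) * 4
    height / (target_snr * sqrt(4))
  }
  structure(list(name = name,
                 components = c(tag, suc),
                 solid_fraction = s,
                 sucrose_per_tag = suc_per_tag,
                 noise_sigma_per_scan = sigma),
            class = "sample_preset")
}

#' @export
print.sample_preset <- function(x, ...) {
  cat(sprintf(
    "<sample_preset %s> %d components, solid fraction %.3f, sucrose/TAG %.3g\n",
    x$name, length(x$components), x$solid_fraction, x$sucrose_per_tag))
  invisible(x)
}

# effective rendered amplitude of each component: multiplicity x phase
# split x steady-state factor (weighted-T1 convention per relaxation model)
# x n_scans.  chain_end components are a solid/liquid population mixture:
# full multiplicity, attenuation s*m_solid + (1-s)*m_liquid.
.component_amplitudes <- function(preset, scheme) {
  tr <- repetition_time(scheme)
  s <- preset$solid_fraction
  beta <- scheme$flip_angle_deg
  solid_relax <- NULL
  for (cmp in preset$components)
    if (identical(cmp$pool, "solid")) solid_relax <- cmp$relaxation
  m_of <- function(model) mxy_steady_state(beta, tr, weighted_t1(model))
  vapply(preset$components, function(cmp) {
    pool <- cmp$pool
    if (identical(pool, "solid")) {
      if (s == 0) return(0)
      return(cmp$multiplicity * s * m_of(cmp$relaxation) * scheme$n_scans)
    }
    if (!is.na(pool) && pool %in% c("ch2n", "alpha", "omega3")) {
      if (s == 1) return(0)
      return(cmp$multiplicity * (1 - s) * m_of(cmp$relaxation) *
               scheme$n_scans)
    }
    if (identical(pool, "chain_end") && !is.null(solid_relax)) {
      m <- s * m_of(solid_relax) + (1 - s) * m_of(cmp$relaxation)
      return(cmp$multiplicity * m * scheme$n_scans)
    }
    cmp$multiplicity * m_of(cmp$relaxation) * scheme$n_scans
  }, 0)
}

# mass of a unit-area lineshape inside [lo, hi] ppm (closed form)
.line_mass <- function(cmp, lo, hi, sf_mhz) {
  w <- cmp$fwhm_hz / sf_mhz
  if (cmp$lineshape == "lorentzian") {
    (atan(2 * (hi - cmp$shift_ppm) / w) -
       atan(2 * (lo - cmp$shift_ppm) / w)) / pi
  } else {
    sd <- w / (2 * sqrt(2 * log(2)))
    stats::pnorm(hi, cmp$shift_ppm, sd) - stats::pnorm(lo, cmp$shift_ppm, sd)
  }
}

.true_window_areas <- function(preset, scheme, windows) {
  amp <- .component_amplitudes(preset, scheme)
  sf <- scheme$spectrometer_freq_mhz
  vapply(windows, function(w) {
    sum(vapply(seq_along(preset$components), function(i)
      amp[i] * .line_mass(preset$components[[i]], w$low_ppm, w$high_ppm, sf),
      0))
  }, 0)
}

.render_lineshape <- function(ppm, cmp, sf_mhz) {
  w <- cmp$fwhm_hz / sf_mhz
  if (cmp$lineshape == "lorentzian") {
    (2 / (pi * w)) / (1 + (2 * (ppm - cmp$shift_ppm) / w)^2)
  } else {
    (2 / w) * sqrt(log(2) / pi) *
      exp(-4 * log(2) * ((ppm - cmp$shift_ppm) / w)^2)
  }
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic cocoa-product spectrum with ground truth
#'
#' Renders every component of the preset on a uniform ppm grid with its
#' lineshape, scaled by multiplicity, solid/liquid split, steady-state
#' magnetization (weighted-T1 convention) and scan count, then adds seeded
#' Gaussian noise of standard deviation
#' `noise_sigma_per_scan * sqrt(n_scans)`.  Ground truth carries the exact
#' (closed-form) areas of every default window under the same scheme, the
#' composition SFC and the TAG/sucrose area ratio.
#'
#' @param preset a [sample_preset()] (or preset name).
#' @param scheme an [acq_params()] (default [scheme_90m()]).
#' @param n_points grid size (default 32768).
#' @param spectral_width_ppm spanned ppm range (default 250).
#' @param carrier_ppm axis centre (default 100 ppm, so the default axis
#'   runs 225 to -25 ppm).
#' @param seed integer seed for the noise (`NULL` for no noise).
#' @return List with elements `spectrum` ([nmr_spectrum()]) and
#'   `ground_truth` (list: `solid_fraction`, `sfc_percent`, `window_areas`,
#'   `tag_suc_ratio`, `scheme_label`, `noise_sigma`, `seed`).
#' @export
generate_spectrum <- function(preset, scheme = scheme_90m(),
                              n_points = 32768L, spectral_width_ppm = 250,
                              carrier_ppm = 100, seed = NULL) {
  if (is.character(preset)) preset <- sample_preset(preset)
  stopifnot(inherits(preset, "sample_preset"), inherits(scheme, "acq_params"))
  if (n_points < 64L) stop("`n_points` must be at least 64")
  if (spectral_width_ppm <= 0) stop("`spectral_width_ppm` must be > 0")
  sf <- scheme$spectrometer_freq_mhz
  ppm <- seq(carrier_ppm + spectral_width_ppm / 2,
             carrier_ppm - spectral_width_ppm / 2,
             length.out = n_points)
  amp <- .component_amplitudes(preset, scheme)
  y <- rep(0, n_points)
  for (i in seq_along(preset$components))
    if (amp[i] > 0)
      y <- y + amp[i] * .render_lineshape(ppm, preset$components[[i]], sf)
  sigma <- preset$noise_sigma_per_scan * sqrt(scheme$n_scans)
  if (!is.null(seed) && sigma > 0)
    y <- y + .with_seed(seed, stats::rnorm(n_points, 0, sigma))
  wins <- default_windows()
  areas <- .true_window_areas(preset, scheme, wins)
  gt <- list(
    solid_fraction = preset$solid_fraction,
    sfc_percent = 100 * preset$solid_fraction,
    window_areas = areas,
    # rendered area of the solid inner methylenes alone -- what the
    # corrected area A_C = A_ii - (A_3 + A_2) isolates (the broad line's
    # alpha/omega-3 share is cancelled by the chain-end subtraction)
    solid_area = sum(amp[vapply(preset$components, function(c)
      identical(c$pool, "solid"), TRUE)]) * 29.4 / 35.4,
    tag_suc_ratio = if (areas[["sucrose"]] > 0)
      areas[["tag"]] / areas[["sucrose"]] else Inf,
    scheme_label = scheme$label,
    noise_sigma = sigma,
    seed = seed)
  list(spectrum = nmr_spectrum(ppm, y, params = scheme,
                               provenance = paste0("synthetic:", preset$name)),
       ground_truth = gt)
}

#' Generate a synthetic time-domain FID
#'
#' Time-domain twin of [generate_spectrum()]: each component contributes a
#' complex exponential at its offset frequency with Lorentzian (exponential
#' decay) or Gaussian envelope, scaled so that the processed spectrum has
#' the same intensity scale and areas as the direct frequency-domain
#' rendering.  The number of samples follows from the scheme's acquisition
#' time and the spectral width.  Complex Gaussian noise is seeded to give
#' the preset's spectral noise level after transformation.
#'
#' @inheritParams generate_spectrum
#' @return List with elements `fid` ([nmr_fid()]) and `ground_truth` (as in
#'   [generate_spectrum()]).
#' @export
generate_fid <- function(preset, scheme = scheme_90m(),
                         spectral_width_ppm = 250, carrier_ppm = 100,
                         seed = NULL) {
  if (is.character(preset)) preset <- sample_preset(preset)
  stopifnot(inherits(preset, "sample_preset"), inherits(scheme, "acq_params"))
  sf <- scheme$spectrometer_freq_mhz
  sw_hz <- spectral_width_ppm * sf
  dwell <- 1 / sw_hz
  n <- max(8L, round(scheme$acquisition_time_s / dwell))
  t <- (seq_len(n) - 1) * dwell
  amp <- .component_amplitudes(preset, scheme)
  x <- complex(real = rep(0, n))
  for (i in seq_along(preset$components)) {
    if (amp[i] <= 0) next
    cmp <- preset$components[[i]]
    nu <- (cmp$shift_ppm - carrier_ppm) * sf
    env <- if (cmp$lineshape == "lorentzian")
      exp(-pi * cmp$fwhm_hz * t)
    else exp(-(pi * cmp$fwhm_hz * t)^2 / (4 * log(2)))
    # factor 2*sf converts unit spectral area (ppm units) to time domain
    x <- x + (2 * amp[i] * sf) * env * exp(2i * pi * nu * t)
  }
  sigma_spec <- preset$noise_sigma_per_scan * sqrt(scheme$n_scans)
  if (!is.null(seed) && sigma_spec > 0) {
    sigma_t <- sigma_spec / (dwell * sqrt(n))
    x <- x + .with_seed(seed, complex(real = stats::rnorm(n, 0, sigma_t),
                                      imaginary = stats::rnorm(n, 0, sigma_t)))
  }
  wins <- default_windows()
  areas <- .true_window_areas(preset, scheme, wins)
  gt <- list(solid_fraction = preset$solid_fraction,
             sfc_percent = 100 * preset$solid_fraction,
             window_areas = areas,
             tag_suc_ratio = if (areas[["sucrose"]] > 0)
               areas[["tag"]] / areas[["sucrose"]] else Inf,
             scheme_label = scheme$label,
             noise_sigma = sigma_spec,
             seed = seed)
  list(fid = nmr_fid(x, dwell, carrier_ppm, params = scheme),
       ground_truth = gt)
}

#' Generate a synthetic inversion-recovery series
#'
#' Evaluates [ir_model()] for each peak's relaxation model on the delay
#' grid and adds seeded Gaussian noise.
#'
#' @param models named list of [relax_model()] objects, one per tracked
#'   peak (names become the series' peak labels).
#' @param tau_grid inversion delays, e.g. [make_tau_grid()].
#' @param noise_sigma Gaussian noise standard deviation (amplitude units;
#'   models are normalized to total amplitude 1).
#' @param seed integer seed (`NULL` for no noise).
#' @return An [ir_series()] with attribute `ground_truth` (the input
#'   models).
#' @export
generate_ir_series <- function(models, tau_grid = make_tau_grid(),
                               noise_sigma = 0, seed = NULL) {
  if (inherits(models, "relax_model")) models <- list(peak1 = models)
  stopifnot(all(vapply(models, inherits, TRUE, "relax_model")))
  amp <- vapply(models, function(m) ir_model(tau_grid, m),
                numeric(length(tau_grid)))
  amp <- matrix(amp, nrow = length(tau_grid),
                dimnames = list(NULL, names(models)))
  if (!is.null(seed) && noise_sigma > 0)
    amp <- amp + .with_seed(seed,
      matrix(stats::rnorm(length(amp), 0, noise_sigma), nrow = nrow(amp)))
  out <- ir_series(tau_grid, amp)
  attr(out, "ground_truth") <- models
  out
}

#' Add magic-angle-spinning sidebands to a spectrum
#'
#' Moves a fraction of the intensity in a region around the centerband to
#' satellite positions displaced by the spinning rate (in ppm,
#' `spinning_freq_hz / spectrometer_freq_mhz`) on either side, conserving
#' total intensity exactly (displacement is rounded to a whole number of
#' grid points).  A warning is raised if a sideband lands inside the
#' 38–29 ppm quantification region, which a physically sensible spinning
#' rate avoids.
#'
#' @param spectrum a real [nmr_spectrum()] on a uniform grid; its `params`
#'   supply the spectrometer frequency.
#' @param centerband_ppm centre of the line producing the sidebands.
#' @param spinning_freq_hz spinning rate in Hz (> 0).
#' @param fraction intensity fraction moved to each sideband, in
#'   `[0, 0.5]`.
#' @param region_halfwidth_ppm half-width of the centerband region whose
#'   profile is copied (default 3 ppm).
#' @return The modified [nmr_spectrum()].
#' @export
add_spinning_sidebands <- function(spectrum, centerband_ppm = 34.5,
                                   spinning_freq_hz = 3000, fraction = 0.1,
                                   region_halfwidth_ppm = 3) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (fraction < 0 || fraction > 0.5)
    stop("`fraction` must lie in [0, 0.5]")
  if (fraction == 0) return(spectrum)
  if (is.null(spectrum$params))
    stop("spectrum lacks acquisition metadata (spectrometer frequency)")
  sf <- spectrum$params$spectrometer_freq_mhz
  delta_ppm <- hz_to_ppm(spinning_freq_hz, sf)
  sb_pos <- centerband_ppm + c(-1, 1) * delta_ppm
  if (any(sb_pos <= 38 & sb_pos >= 29))
    warning(sprintf(paste0(
      "sideband at %.2f ppm falls inside the 38-29 ppm quantification ",
      "region; spinning rate %.0f Hz is too low"),
      sb_pos[sb_pos <= 38 & sb_pos >= 29][1L], spinning_freq_hz))
  step <- abs(spectrum$ppm[1L] - spectrum$ppm[2L])
  shift_pts <- round(delta_ppm / step)
  sel <- which(abs(spectrum$ppm - centerband_ppm) <= region_halfwidth_ppm)
  if (!length(sel)) stop("centerband region is off the ppm axis")
  y <- spectrum$intensity
  profile <- y[sel]
  y[sel] <- y[sel] * (1 - 2 * fraction)
  for (sgn in c(-1L, 1L)) {
    idx <- sel + sgn * shift_pts   # descending axis: +pts moves upfield
    ok <- idx >= 1L & idx <= length(y)
    y[idx[ok]] <- y[idx[ok]] + fraction * profile[ok]
  }
  spectrum$intensity <- y
  spectrum
}
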