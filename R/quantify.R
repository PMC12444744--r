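# Solid-fat-content quantification.  The solid-window area A_ii (38-31.7
# ppm) contains, besides the broad solid methylene line, the sharp liquid
# alpha (34.5 ppm) and omega-3 (32 ppm) lines.  Because each fatty-acid
# chain contributes exactly one CH2 to each of the alpha, omega-3, beta
# (25 ppm) and omega-2 (23 ppm) signals, the liquid contamination is
# removed by subtracting the beta and omega-2 areas:
#
#   A_C = A_ii - (A_3 + A_2)           corrected solid area
#   SFC(%) = 100 * A_C / (A_C + A_i)   with A_i the liquid 31.7-29 ppm area.

#' Corrected solid area
#'
#' `A_C = A_ii - (A_3 + A_2)`: the solid-window area with the liquid
#' alpha/omega-3 overlap cancelled by the beta (~25 ppm) and omega-2
#' (~23 ppm) areas, which count the same one-CH2-per-chain population.
#'
#' @param a_ii area of the 38–31.7 ppm solid window.
#' @param a_3 area of the ~25 ppm beta-methylene window (27–24 ppm).
#' @param a_2 area of the ~23 ppm omega-2 window (24–22 ppm).
#' @return Corrected solid area (same units as the inputs).
#' @export
corrected_solid_area <- function(a_ii, a_3, a_2) {
  if (any(!is.finite(c(a_ii, a_3, a_2)))) stop("areas must be finite")
  a_c <- a_ii - (a_3 + a_2)
  if (any(a_c < 0))
    stop(sprintf(paste0(
      "inconsistent integrals: corrected solid area is negative ",
      "(A_ii = %g, A_3 = %g, A_2 = %g, A_C = %g); check window placement ",
      "or non-fat interference"), a_ii[1L], a_3[1L], a_2[1L], a_c[1L]))
  a_c
}

#' Solid fat content from corrected areas
#'
#' `SFC(%) = 100 * A_C / (A_C + A_i)`.
#'
#' @param a_c corrected solid area (>= 0), from [corrected_solid_area()].
#' @param a_i liquid-window area (>= 0).
#' @return SFC in percent, in `[0, 100]`.
#' @export
sfc <- function(a_c, a_i) {
  if (any(!is.finite(c(a_c, a_i)))) stop("areas must be finite")
  if (any(a_c < 0) || any(a_i < 0)) stop("areas must be >= 0")
  if (any(a_c + a_i <= 0)) stop("no aliphatic signal: A_C + A_i is zero")
  100 * a_c / (a_c + a_i)
}

#' Solid fat content from a spectrum
#'
#' Integrates the solid (38–31.7 ppm), liquid (31.7–29 ppm), beta (27–24
#' ppm) and omega-2 (24–22 ppm) windows, applies the solid-area correction
#' and reports the SFC.  A noise-negative corrected area is clamped to zero
#' with a recorded warning (consistent with no solid phase); use
#' [corrected_solid_area()] directly for the strict check.  When the
#' acquisition scheme has a flip angle below
#' 90 degrees or a repetition time short relative to the solid T1, a bias
#' advisory is attached (partial saturation suppresses the slow-relaxing
#' solid signal, biasing SFC low).
#'
#' @param spectrum a real [nmr_spectrum()] covering at least 40–20 ppm.
#' @param windows window set as from [default_windows()] (needs elements
#'   `solid`, `liquid`, `a3`, `a2`).
#' @param scheme optional [acq_params()] used for labelling and the bias
#'   advisory; defaults to the spectrum's own `params`.
#' @param baseline baseline mode passed to [integrate_window()].
#' @return An object of class \code{sfc_result}: a list with `areas`
#'   (`a_i`, `a_ii`, `a_2`, `a_3`), `a_c`, `sfc_percent`, `scheme_label`,
#'   `warnings`.
#' @export
sfc_from_spectrum <- function(spectrum, windows = default_windows(),
                              scheme = NULL,
                              baseline = c("none", "offset")) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  baseline <- match.arg(baseline)
  rng <- range(spectrum$ppm)
  if (rng[1L] > 20 || rng[2L] < 40)
    stop("spectrum must cover at least 40..20 ppm (has ",
         sprintf("%.1f..%.1f", rng[2L], rng[1L]), ")")
  needed <- c("solid", "liquid", "a3", "a2")
  if (!all(needed %in% names(windows)))
    stop("`windows` must contain: ", paste(needed, collapse = ", "))
  area <- function(w) integrate_window(spectrum, windows[[w]],
                                       baseline = baseline)
  a_ii <- area("solid"); a_i <- area("liquid")
  a_3 <- area("a3"); a_2 <- area("a2")
  # noise can push the small correction areas slightly negative
  a_3 <- max(a_3, 0); a_2 <- max(a_2, 0)
  a_i <- max(a_i, 0)
  warnings <- character()
  a_c <- a_ii - (a_3 + a_2)
  if (a_c < 0) {
    # for samples with little or no solid phase the corrected area is a
    # small difference of noisy integrals; a negative value is consistent
    # with zero solid, so clamp rather than fail the whole chain
    warnings <- c(warnings, sprintf(
      "corrected solid area %.4g is negative (A_ii = %.4g, A_3 = %.4g, A_2 = %.4g); clamped to 0 as consistent with no solid phase",
      a_c, a_ii, a_3, a_2))
    a_c <- 0
  }
  if (is.null(scheme)) scheme <- spectrum$params
  label <- if (!is.null(scheme)) scheme$label else ""
  if (!is.null(scheme) && scheme$flip_angle_deg < 90)
    warnings <- c(warnings, paste0(
      "low-flip-angle scheme: partial saturation of the long-T1 solid ",
      "signal biases SFC low; see predict_sfc_bias()"))
  structure(list(areas = c(a_i = a_i, a_ii = a_ii, a_2 = a_2, a_3 = a_3),
                 a_c = a_c,
                 sfc_percent = sfc(a_c, a_i),
                 scheme_label = label,
                 warnings = warnings),
            class = "sfc_result")
}

#' @export
print.sfc_result <- function(x, ...) {
  cat(sprintf("<sfc_result%s> SFC = %.2f %%\n",
              if (nzchar(x$scheme_label)) paste0(" ", x$scheme_label) else "",
              x$sfc_percent))
  a <- x$areas
  cat(sprintf("  A_i = %.4g  A_ii = %.4g  A_2 = %.4g  A_3 = %.4g  A_C = %.4g\n",
              a["a_i"], a["a_ii"], a["a_2"], a["a_3"], x$a_c))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Triacylglyceride-to-sucrose area ratio
#'
#' Ratio of the aliphatic TAG area (default 38–29 ppm, covering the solid
#' and liquid methylene signals) to the resolved sucrose area (default
#' 104–81 ppm).  Semiquantitative: sucrose relaxes more slowly than the TAG
#' methylenes, so short-recycle schemes under-represent it unless the
#' recycle delay is extended.
#'
#' @param spectrum a real [nmr_spectrum()].
#' @param tag_window,suc_window [ppm_window()] objects (defaults from
#'   [default_windows()]).
#' @param baseline baseline mode passed to [integrate_window()].
#' @param noise_floor areas below this are treated as "no sucrose" (default
#'   3 x the noise-window standard deviation x the sucrose window width).
#' @return Dimensionless ratio.
#' @export
tag_sucrose_ratio <- function(spectrum,
                              tag_window = default_windows()$tag,
                              suc_window = default_windows()$sucrose,
                              baseline = c("none", "offset"),
                              noise_floor = NULL) {
  baseline <- match.arg(baseline)
  a_tag <- integrate_window(spectrum, tag_window, baseline = baseline)
  a_suc <- integrate_window(spectrum, suc_window, baseline = baseline)
  if (is.null(noise_floor)) {
    sdn <- tryCatch(
      stats::sd(.window_values(spectrum, default_windows()$baseline_hi)),
      error = function(e) 0)
    noise_floor <- 3 * sdn * (suc_window$high_ppm - suc_window$low_ppm) /
      sqrt(max(sum(spectrum$ppm <= suc_window$high_ppm &
                     spectrum$ppm > suc_window$low_ppm), 1L))
  }
  if (a_suc <= noise_floor)
    stop(sprintf(
      "no sucrose detected: sucrose area %.4g is at or below the noise floor %.4g",
      a_suc, noise_floor))
  a_tag / a_suc
}

#' Classify the solid-line polymorph
#'
#' Locates the apex of the solid methylene line inside `solid_window` and
#' calls the beta polymorph (the thermodynamically stable form V/VI) when
#' the apex falls inside `beta_range` (closed interval, default
#' 34.2–34.8 ppm around the 34.5 ppm beta shift).  Other polymorphs are not
#' assigned: the call is `"non-beta/unassigned"`.
#'
#' @param spectrum a real [nmr_spectrum()].
#' @param solid_window [ppm_window()] to search (default 38–31.7 ppm).
#' @param beta_range length-2 numeric, `(low, high)` ppm bounds of the beta
#'   call window.
#' @return An object of class \code{polymorph_call}: list with `apex_ppm`,
#'   `call` (`"beta"` or `"non-beta/unassigned"`), `window_used`.
#' @export
classify_polymorph <- function(spectrum,
                               solid_window = default_windows()$solid,
                               beta_range = c(34.2, 34.8)) {
  stopifnot(inherits(spectrum, "nmr_spectrum"),
            inherits(solid_window, "ppm_window"))
  sel <- spectrum$ppm <= solid_window$high_ppm &
    spectrum$ppm > solid_window$low_ppm
  if (!any(sel)) stop("solid window is off the ppm axis")
  y <- spectrum$intensity[sel]
  if (diff(range(y)) == 0)
    stop("flat solid window: no apex to classify")
  apex <- spectrum$ppm[sel][which.max(y)]
  call <- if (apex >= beta_range[1L] && apex <= beta_range[2L])
    "beta" else "non-beta/unassigned"
  structure(list(apex_ppm = apex, call = call, window_used = solid_window),
            class = "polymorph_call")
}

#' @export
print.polymorph_call <- function(x, ...) {
  cat(sprintf("<polymorph_call> apex %.2f ppm -> %s\n", x$apex_ppm, x$call))
  invisible(x)
}

#' Compare two SFC vectors across samples
#'
#' Pearson correlation plus paired differences, for comparing SFC values
#' from two methods (e.g. a carbon-13 scheme against a reference
#' time-domain protocol) over the same sample set.
#'
#' @param sfc_a,sfc_b numeric vectors of equal length >= 3.
#' @return List with `pearson_r`, `mean_difference` (a - b),
#'   `max_abs_difference`, `n`.
#' @export
compare_sfc_methods <- function(sfc_a, sfc_b) {
  if (length(sfc_a) != length(sfc_b))
    stop("vectors differ in length")
  if (length(sfc_a) < 3L) stop("need at least 3 paired values")
  if (stats::sd(sfc_a) == 0 || stats::sd(sfc_b) == 0)
    stop("zero variance in one of the SFC vectors")
  list(pearson_r = stats::cor(sfc_a, sfc_b, method = "pearson"),
       mean_difference = mean(sfc_a - sfc_b),
       max_abs_difference = max(abs(sfc_a - sfc_b)),
       n = length(sfc_a))
}
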