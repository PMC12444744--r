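#' Acquisition parameter set
#'
#' Bundles the pulse-sequence parameters that determine the steady-state
#' signal of a direct-excitation (HPDEC/DPMAS) experiment: flip angle
#' \eqn{\beta}, recycle delay D1, acquisition time AQ, number of scans, the
#' carbon-13 spectrometer frequency and the magic-angle spinning rate.
#' The repetition time used throughout the steady-state model is
#' \code{recycle_delay_s + acquisition_time_s}.
#'
#' @param flip_angle_deg excitation flip angle in degrees, in (0, 90].
#' @param recycle_delay_s recycle delay D1 in seconds, >= 0.
#' @param acquisition_time_s acquisition time AQ in seconds, > 0.
#' @param n_scans number of accumulated scans, positive integer.
#' @param spectrometer_freq_mhz carbon-13 Larmor frequency in MHz
#'   (100.5 MHz on a 9.4 T magnet).
#' @param spinning_freq_hz magic-angle spinning rate in Hz, >= 0.
#' @param label free-text scheme label, e.g. \code{"90M"} or \code{"LAM"}.
#'
#' @return An object of class \code{acq_params}.
#' @seealso [scheme_90m()], [scheme_lam()] for the two canonical schemes.
#' @export
#' @examples
#' p <- acq_params(90, 850, 0.05, 4)
#' repetition_time(p)  # 850.05 s
acq_params <- function(flip_angle_deg,
                       recycle_delay_s,
                       acquisition_time_s,
                       n_scans = 1L,
                       spectrometer_freq_mhz = 100.5,
                       spinning_freq_hz = 3000,
                       label = "") {
  stopifnot(is.numeric(flip_angle_deg), length(flip_angle_deg) == 1L,
            is.numeric(recycle_delay_s), length(recycle_delay_s) == 1L,
            is.numeric(acquisition_time_s), length(acquisition_time_s) == 1L)
  if (!is.finite(flip_angle_deg) || flip_angle_deg <= 0 || flip_angle_deg > 90)
    stop("`flip_angle_deg` must lie in (0, 90], got ", flip_angle_deg)
  if (!is.finite(recycle_delay_s) || recycle_delay_s < 0)
    stop("`recycle_delay_s` must be >= 0")
  if (!is.finite(acquisition_time_s) || acquisition_time_s <= 0)
    stop("`acquisition_time_s` must be > 0")
  if (!is.numeric(n_scans) || length(n_scans) != 1L || n_scans < 1 ||
      n_scans != round(n_scans))
    stop("`n_scans` must be a positive integer")
  if (!is.finite(spectrometer_freq_mhz) || spectrometer_freq_mhz <= 0)
    stop("`spectrometer_freq_mhz` must be > 0")
  if (!is.finite(spinning_freq_hz) || spinning_freq_hz < 0)
    stop("`spinning_freq_hz` must be >= 0")
  structure(
    list(flip_angle_deg = as.numeric(flip_angle_deg),
         recycle_delay_s = as.numeric(recycle_delay_s),
         acquisition_time_s = as.numeric(acquisition_time_s),
         n_scans = as.integer(n_scans),
         spectrometer_freq_mhz = as.numeric(spectrometer_freq_mhz),
         spinning_freq_hz = as.numeric(spinning_freq_hz),
         label = as.character(label)),
    class = "acq_params")
}

#' Repetition time of an acquisition scheme
#'
#' The time between successive excitation pulses, D1 + AQ.  This is the
#' `T` entering the steady-state magnetization model.
#'
#' @param params an [acq_params()] object.
#' @return Repetition time in seconds.
#' @export
repetition_time <- function(params) {
  stopifnot(inherits(params, "acq_params"))
  params$recycle_delay_s + params$acquisition_time_s
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params%s> beta = %g deg, D1 = %g s, AQ = %g s, %d scan(s), %g MHz, MAS %g Hz\n",
    if (nzchar(x$label)) paste0(" ", x$label) else "",
    x$flip_angle_deg, x$recycle_delay_s, x$acquisition_time_s,
    x$n_scans, x$spectrometer_freq_mhz, x$spinning_freq_hz))
  invisible(x)
}

#' Canonical acquisition schemes
#'
#' `scheme_90m()` is the conventional quantitative scheme: a 90-degree pulse
#' with a recycle delay of at least five times the longest T1 (here 850 s)
#' and four scans.  `scheme_lam()` is the low-flip-angle scheme: a 23-degree
#' pulse, a 25 s recycle delay and 128 scans, giving a comparable total
#' measurement time (just under one hour each) but a higher signal-to-noise
#' ratio on the fast-relaxing liquid signals.
#'
#' @param n_scans number of scans (defaults 4 and 128 respectively).
#' @return An [acq_params()] object.
#' @export
scheme_90m <- function(n_scans = 4L) {
  acq_params(90, 850, 0.05, n_scans, label = "90M")
}

#' @rdname scheme_90m
#' @param flip_angle_deg flip angle in degrees (default 23).
#' @export
scheme_lam <- function(flip_angle_deg = 23, n_scans = 128L) {
  acq_params(flip_angle_deg, 25, 0.05, n_scans, label = "LAM")
}

#' Convert a chemical-shift offset to Hertz
#'
#' One ppm corresponds to one millionth of the Larmor frequency, i.e.
#' `spectrometer_freq_mhz` Hz.  Used to place spinning sidebands and to
#' convert linewidths between Hz and ppm.
#'
#' @param delta_ppm chemical-shift offset in ppm.
#' @param spectrometer_freq_mhz spectrometer frequency in MHz (> 0).
#' @return Offset in Hz.
#' @export
#' @examples
#' ppm_to_hz(29.85, 100.5)  # ~3000 Hz: a 3 kHz sideband spacing
ppm_to_hz <- function(delta_ppm, spectrometer_freq_mhz) {
  if (!is.numeric(spectrometer_freq_mhz) || any(spectrometer_freq_mhz <= 0) ||
      any(!is.finite(spectrometer_freq_mhz)))
    stop("`spectrometer_freq_mhz` must be > 0")
  delta_ppm * spectrometer_freq_mhz
}

#' @rdname ppm_to_hz
#' @param delta_hz frequency offset in Hz.
#' @export
hz_to_ppm <- function(delta_hz, spectrometer_freq_mhz) {
  if (!is.numeric(spectrometer_freq_mhz) || any(spectrometer_freq_mhz <= 0) ||
      any(!is.finite(spectrometer_freq_mhz)))
    stop("`spectrometer_freq_mhz` must be > 0")
  delta_hz / spectrometer_freq_mhz
}
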