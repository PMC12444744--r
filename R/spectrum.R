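#' Frequency-domain NMR spectrum
#'
#' A 1-D carbon-13 spectrum: a strictly decreasing ppm axis (downfield on the
#' left, TMS = 0) and one intensity per point.  Intensities are in arbitrary
#' units; the analysis uses only area ratios, so no absolute calibration is
#' attempted.  Constructors and readers re-sort ascending input so the
#' descending-axis invariant always holds.
#'
#' @param ppm chemical-shift axis in ppm; strictly monotonic, stored
#'   descending.
#' @param intensity real (or, for unphased transforms, complex) intensities,
#'   same length as `ppm`.
#' @param params optional [acq_params()] the spectrum was acquired with.
#' @param provenance free-text origin note.
#' @return An object of class \code{nmr_spectrum} with elements `ppm`,
#'   `intensity`, `params`, `provenance`.
#' @export
nmr_spectrum <- function(ppm, intensity, params = NULL, provenance = "") {
  ppm <- as.numeric(ppm)
  if (length(ppm) < 2L) stop("a spectrum needs at least 2 points")
  if (length(intensity) != length(ppm))
    stop("`ppm` and `intensity` must have the same length (",
         length(ppm), " vs ", length(intensity), ")")
  if (any(!is.finite(ppm))) stop("non-finite values in `ppm`")
  if (is.complex(intensity)) {
    if (any(!is.finite(Re(intensity))) || any(!is.finite(Im(intensity))))
      stop("non-finite values in `intensity`")
  } else {
    intensity <- as.numeric(intensity)
    if (any(!is.finite(intensity))) stop("non-finite values in `intensity`")
  }
  d <- diff(ppm)
  if (all(d > 0)) {               # ascending input: flip to convention
    ppm <- rev(ppm); intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("`ppm` must be strictly monotonic")
  }
  if (!is.null(params)) stopifnot(inherits(params, "acq_params"))
  structure(list(ppm = ppm, intensity = intensity, params = params,
                 provenance = as.character(provenance)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.2f .. %.2f ppm%s%s\n",
              length(x$ppm), x$ppm[1L], x$ppm[length(x$ppm)],
              if (is.complex(x$intensity)) " (complex)" else "",
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Free-induction decay (time-domain signal)
#'
#' Complex time-domain samples with a fixed dwell time.  `carrier_ppm` places
#' the transmitter (zero-frequency) position on the chemical-shift axis so
#' that [transform()] can construct the ppm axis; the spectral width is the
#' reciprocal of the dwell time.
#'
#' @param samples complex vector of at least 8 points.
#' @param dwell_s dwell time in seconds (> 0).
#' @param carrier_ppm chemical shift of the carrier (axis centre), ppm.
#' @param params optional [acq_params()].
#' @return An object of class \code{nmr_fid}.
#' @export
nmr_fid <- function(samples, dwell_s, carrier_ppm = 100, params = NULL) {
  samples <- as.complex(samples)
  if (length(samples) < 8L) stop("an FID needs at least 8 samples")
  if (any(!is.finite(Re(samples))) || any(!is.finite(Im(samples))))
    stop("non-finite FID samples")
  if (!is.numeric(dwell_s) || length(dwell_s) != 1L || !is.finite(dwell_s) ||
      dwell_s <= 0)
    stop("`dwell_s` must be a positive number")
  if (!is.numeric(carrier_ppm) || length(carrier_ppm) != 1L ||
      !is.finite(carrier_ppm))
    stop("`carrier_ppm` must be a finite number")
  if (!is.null(params)) stopifnot(inherits(params, "acq_params"))
  structure(list(samples = samples, dwell_s = as.numeric(dwell_s),
                 carrier_ppm = as.numeric(carrier_ppm), params = params),
            class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d samples, dwell %.3g us, duration %.4g s, SW %.4g Hz\n",
              length(x$samples), x$dwell_s * 1e6,
              x$dwell_s * length(x$samples), 1 / x$dwell_s))
  invisible(x)
}

#' Acquisition duration of an FID
#' @param fid an [nmr_fid()] object.
#' @return Duration in seconds (`dwell_s * length(samples)`).
#' @export
fid_duration <- function(fid) {
  stopifnot(inherits(fid, "nmr_fid"))
  fid$dwell_s * length(fid$samples)
}

#' Inversion-recovery series
#'
#' Signal amplitudes measured after a 180-tau-90 sequence, one row per
#' inversion delay tau and one column per tracked peak (e.g. the solid
#' 34.5 ppm and liquid 30 ppm methylene signals).
#'
#' @param tau_s strictly increasing positive inversion delays, seconds.
#' @param amplitude numeric matrix (or vector for one peak) with
#'   `length(tau_s)` rows; column names label the peaks.
#' @return An object of class \code{ir_series}.
#' @export
ir_series <- function(tau_s, amplitude) {
  tau_s <- as.numeric(tau_s)
  if (length(tau_s) < 2L) stop("need at least 2 inversion delays")
  if (any(!is.finite(tau_s)) || any(tau_s <= 0))
    stop("`tau_s` must be positive and finite")
  if (any(diff(tau_s) <= 0)) stop("`tau_s` must be strictly increasing")
  amplitude <- as.matrix(amplitude)
  if (nrow(amplitude) != length(tau_s))
    stop("`amplitude` must have one row per tau (", length(tau_s),
         " expected, got ", nrow(amplitude), ")")
  if (any(!is.finite(amplitude))) stop("non-finite amplitudes")
  if (is.null(colnames(amplitude)))
    colnames(amplitude) <- paste0("peak", seq_len(ncol(amplitude)))
  structure(list(tau_s = tau_s, amplitude = amplitude), class = "ir_series")
}

#' @export
print.ir_series <- function(x, ...) {
  cat(sprintf("<ir_series> %d delays, %.3g .. %.4g s, peaks: %s\n",
              length(x$tau_s), min(x$tau_s), max(x$tau_s),
              paste(colnames(x$amplitude), collapse = ", ")))
  invisible(x)
}
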