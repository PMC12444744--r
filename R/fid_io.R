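# FID serialization: a plain CSV of (re, im) sample pairs with the dwell
# time, carrier position and acquisition metadata in '#'-prefixed header
# lines.  Used by the command-line pipeline to hand a simulated FID to the
# processing step.

#' Read / write a time-domain FID as CSV
#'
#' The file holds `# key value` header lines (`dwell_s`, `carrier_ppm`,
#' and optionally the acquisition parameters) followed by a `re,im` table,
#' one row per complex sample.  Round-trips are lossless to double
#' precision.
#'
#' @param path CSV file.
#' @return [read_fid()]: an [nmr_fid()]; [write_fid()]: invisibly, `path`.
#' @export
read_fid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(trimws(sub("^#", "", h)), "\\s+")[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- as.numeric(kv[2L])
  }
  if (is.null(meta$dwell_s)) stop("FID file '", path, "' lacks '# dwell_s'")
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  dat <- dat[!grepl("^re", dat)]
  parts <- strsplit(trimws(dat), "[[:space:],]+")
  re <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  im <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(re) || anyNA(im))
    stop("malformed sample row ", which(is.na(re) | is.na(im))[1L],
         " in ", path)
  params <- NULL
  if (!is.null(meta$flip_angle_deg) && !is.null(meta$spectrometer_freq_mhz))
    params <- acq_params(meta$flip_angle_deg, meta$recycle_delay_s %||% 0,
                         meta$acquisition_time_s %||% (meta$dwell_s * length(re)),
                         meta$n_scans %||% 1L,
                         meta$spectrometer_freq_mhz,
                         meta$spinning_freq_hz %||% 0)
  nmr_fid(complex(real = re, imaginary = im), meta$dwell_s,
          meta$carrier_ppm %||% 100, params = params)
}

#' @rdname read_fid
#' @param fid an [nmr_fid()].
#' @export
write_fid <- function(fid, path) {
  stopifnot(inherits(fid, "nmr_fid"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# dwell_s %.17g", fid$dwell_s), con)
  writeLines(sprintf("# carrier_ppm %.17g", fid$carrier_ppm), con)
  p <- fid$params
  if (!is.null(p)) {
    writeLines(sprintf("# flip_angle_deg %.17g", p$flip_angle_deg), con)
    writeLines(sprintf("# recycle_delay_s %.17g", p$recycle_delay_s), con)
    writeLines(sprintf("# acquisition_time_s %.17g", p$acquisition_time_s), con)
    writeLines(sprintf("# n_scans %d", p$n_scans), con)
    writeLines(sprintf("# spectrometer_freq_mhz %.17g",
                       p$spectrometer_freq_mhz), con)
    writeLines(sprintf("# spinning_freq_hz %.17g", p$spinning_freq_hz), con)
  }
  writeLines("re,im", con)
  writeLines(sprintf("%.17g,%.17g", Re(fid$samples), Im(fid$samples)), con)
  invisible(path)
}
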