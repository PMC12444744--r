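# File I/O: JCAMP-DX (interchange) and two-column text (fixtures) for
# spectra; CSV for inversion-recovery series.  Both spectrum dialects are
# lossless to double precision (values written with 17 significant digits).

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jdx", "dx", "jcamp")) "jcamp-dx" else "xy-text"
}

#' Read a 1-D spectrum from file
#'
#' Two dialects are supported: JCAMP-DX (`##XYPOINTS=(XY..XY)` pairs or the
#' equidistant `##XYDATA=(X++(Y..Y))` form with X/Y factors) and plain
#' two-column text (ppm, intensity; whitespace- or comma-separated, `#`
#' comments allowed).  Ascending axes are re-sorted so the returned spectrum
#' always has a descending ppm axis.
#'
#' @param path file to read.
#' @param format `"jcamp-dx"`, `"xy-text"`, or `"auto"` (by extension:
#'   `.jdx`/`.dx`/`.jcamp` are JCAMP, anything else two-column text).
#' @return An [nmr_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "jcamp-dx", "xy-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  if (format == "jcamp-dx") .read_jcamp(path) else .read_xy(path)
}

#' Write a 1-D spectrum to file
#'
#' Counterpart of [read_spectrum()]; round-trips are lossless to better than
#' 1e-9 relative.  Complex spectra cannot be serialized; phase first.
#'
#' @param spectrum an [nmr_spectrum()] with real intensities.
#' @param path output file.
#' @param format `"jcamp-dx"`, `"xy-text"`, or `"auto"` (by extension).
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path,
                           format = c("auto", "jcamp-dx", "xy-text")) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (is.complex(spectrum$intensity))
    stop("cannot serialize a complex spectrum; apply phase_correct() first")
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  ok <- tryCatch({
    if (format == "jcamp-dx") .write_jcamp(spectrum, path)
    else .write_xy(spectrum, path)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

.read_xy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("two-column file '", path, "' has < 2 data rows")
  parts <- strsplit(trimws(lines), "[[:space:],]+")
  n <- vapply(parts, length, 1L)
  bad <- which(n < 2L)
  if (length(bad))
    stop("malformed two-column record at data line ", bad[1L], " of ", path)
  x <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(x) || anyNA(y))
    stop("non-numeric field at data line ",
         which(is.na(x) | is.na(y))[1L], " of ", path)
  nmr_spectrum(x, y, provenance = paste0("xy-text:", basename(path)))
}

.write_xy <- function(spectrum, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# ppm intensity", con)
  writeLines(sprintf("%.17g %.17g", spectrum$ppm, spectrum$intensity), con)
}

.write_jcamp <- function(spectrum, path) {
  p <- spectrum$params
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c(
    "##TITLE=qssnmr spectrum",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    "##DATA CLASS=XYPOINTS",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    if (!is.null(p)) sprintf("##.OBSERVE FREQUENCY=%.17g",
                             p$spectrometer_freq_mhz),
    if (!is.null(p)) sprintf("##$FLIPANGLE=%.17g", p$flip_angle_deg),
    if (!is.null(p)) sprintf("##$RECYCLEDELAY=%.17g", p$recycle_delay_s),
    if (!is.null(p)) sprintf("##$ACQTIME=%.17g", p$acquisition_time_s),
    if (!is.null(p)) sprintf("##$NSCANS=%d", p$n_scans),
    if (!is.null(p)) sprintf("##$SPINFREQ=%.17g", p$spinning_freq_hz),
    if (nzchar(spectrum$provenance))
      paste0("##$PROVENANCE=", spectrum$provenance),
    sprintf("##NPOINTS=%d", length(spectrum$ppm)),
    sprintf("##FIRSTX=%.17g", spectrum$ppm[1L]),
    sprintf("##LASTX=%.17g", spectrum$ppm[length(spectrum$ppm)]),
    "##XYPOINTS=(XY..XY)")
  writeLines(hdr, con)
  writeLines(sprintf("%.17g, %.17g", spectrum$ppm, spectrum$intensity), con)
  writeLines("##END=", con)
}

.read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- grep("^##", lines)
  get_ldr <- function(key) {
    pat <- paste0("^##", key, "\\s*=")
    i <- grep(pat, lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    trimws(sub(pat, "", lines[i[1L]], ignore.case = TRUE))
  }
  num_ldr <- function(key) {
    v <- get_ldr(key)
    if (is.null(v)) NULL else as.numeric(v)
  }
  params <- NULL
  sf <- num_ldr("\\.OBSERVE FREQUENCY")
  beta <- num_ldr("\\$FLIPANGLE")
  if (!is.null(sf) && !is.null(beta)) {
    params <- tryCatch(
      acq_params(beta,
                 num_ldr("\\$RECYCLEDELAY") %||% 0,
                 num_ldr("\\$ACQTIME") %||% 0.05,
                 num_ldr("\\$NSCANS") %||% 1L,
                 sf,
                 num_ldr("\\$SPINFREQ") %||% 0),
      error = function(e) NULL)
  }
  prov <- get_ldr("\\$PROVENANCE") %||% paste0("jcamp-dx:", basename(path))

  i_xy <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  i_tab <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  i_end <- grep("^##END", lines, ignore.case = TRUE)
  if (!length(i_end)) stop("JCAMP-DX file '", path, "' lacks ##END= record")
  if (length(i_xy)) {
    start <- i_xy[1L] + 1L
    stopl <- min(c(ldr[ldr > i_xy[1L]], length(lines) + 1L)) - 1L
    dat <- lines[start:stopl]
    dat <- dat[nzchar(trimws(dat))]
    parts <- strsplit(trimws(dat), "[[:space:],;]+")
    vals <- suppressWarnings(as.numeric(unlist(parts)))
    if (anyNA(vals) || length(vals) %% 2L != 0L)
      stop("malformed XYPOINTS table near line ", start, " of ", path)
    x <- vals[seq(1L, length(vals), by = 2L)]
    y <- vals[seq(2L, length(vals), by = 2L)]
  } else if (length(i_tab)) {
    # equidistant (X++(Y..Y)) table
    xf <- num_ldr("XFACTOR") %||% 1
    yf <- num_ldr("YFACTOR") %||% 1
    firstx <- num_ldr("FIRSTX")
    lastx <- num_ldr("LASTX")
    np <- num_ldr("NPOINTS")
    if (is.null(firstx) || is.null(lastx) || is.null(np))
      stop("JCAMP-DX (X++(Y..Y)) table in '", path,
           "' lacks FIRSTX/LASTX/NPOINTS")
    start <- i_tab[1L] + 1L
    stopl <- min(c(ldr[ldr > i_tab[1L]], length(lines) + 1L)) - 1L
    dat <- lines[start:stopl]
    dat <- dat[nzchar(trimws(dat))]
    y <- unlist(lapply(dat, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:],;]+")[[1L]]))
      if (anyNA(v)) stop("malformed XYDATA line in ", path, ": ", l)
      v[-1L]  # first number on each line is the X check value
    }))
    if (length(y) != np)
      stop("XYDATA table in '", path, "' has ", length(y),
           " Y values, NPOINTS says ", np)
    x <- seq(firstx * xf, lastx * xf, length.out = np)
    y <- y * yf
  } else {
    stop("JCAMP-DX file '", path, "' has neither ##XYPOINTS nor ##XYDATA")
  }
  nmr_spectrum(x, y, params = params, provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write an inversion-recovery series as CSV
#'
#' The CSV has a header row `tau_s` followed by one column per tracked peak
#' label (e.g. `"34.5 ppm"`, `"30 ppm"`), one row per inversion delay.
#'
#' @param path CSV file.
#' @return [read_ir_series()]: an [ir_series()]; [write_ir_series()]:
#'   invisibly, `path`.
#' @export
read_ir_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || !identical(names(df)[1L], "tau_s"))
    stop("IR CSV must have columns: tau_s, then one per peak label")
  if (!all(vapply(df, is.numeric, TRUE)))
    stop("non-numeric column in IR CSV '", path, "'")
  ir_series(df[[1L]], as.matrix(df[, -1L, drop = FALSE]))
}

#' @rdname read_ir_series
#' @param series an [ir_series()].
#' @export
write_ir_series <- function(series, path) {
  stopifnot(inherits(series, "ir_series"))
  df <- data.frame(tau_s = series$tau_s, check.names = FALSE)
  df <- cbind(df, as.data.frame(series$amplitude, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
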