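#' Default plausibility band for facial skin temperature
#'
#' Brackets facial skin temperature plus fever margins.  Values outside the
#' band are rejected at frame construction unless masked as invalid pixels
#' (`NA`/`NaN`).
#' @keywords internal
DEFAULT_BAND <- c(15, 45)

#' Construct a calibrated thermal frame
#'
#' A thermal frame holds a full-face (or hemiface) raster of calibrated skin
#' temperatures in degrees Celsius together with its acquisition metadata.
#' Pixel `[0, 0]` is the top-left corner of the image; all pixel coordinates
#' in this package are 0-based and ranges are half-open.
#'
#' Temperatures are stored already calibrated in deg C.  Emissivity (human
#' skin is close to 0.98) is carried as metadata only — radiometric cameras
#' apply it internally before exporting temperatures, so no correction is
#' applied here.  Invalid or dead pixels are represented as non-finite values
#' and propagate through all arithmetic; region statistics ignore them.
#'
#' @param temps Numeric matrix of temperatures, deg C, one row per image row.
#' @param emissivity Skin emissivity used at acquisition, in (0, 1].
#' @param capture_time Optional acquisition timestamp (character).
#' @param subject_id Optional subject identifier (character).
#' @param band Length-2 numeric plausibility band, deg C.  Finite values
#'   outside the band raise a validation error.
#'
#' @return An object of class `thermal_frame`: a list with elements `temps`,
#'   `height`, `width`, `emissivity`, `capture_time`, `subject_id`, `band`
#'   and `units` (always `"degC"`).
#' @export
#' @examples
#' fr <- thermal_frame(matrix(c(33, 34, 33.5, 33.2, 34.1, 33.6), 2, byrow = TRUE))
#' fr$height; fr$width
thermal_frame <- function(temps, emissivity = 0.98, capture_time = NULL,
                          subject_id = NULL, band = DEFAULT_BAND) {
  if (is.vector(temps) && is.numeric(temps)) temps <- matrix(temps, nrow = 1)
  if (!is.matrix(temps) || !is.numeric(temps))
    ht_validation_error("temps must be a numeric matrix")
  if (nrow(temps) < 1L || ncol(temps) < 1L)
    ht_validation_error("frame must be at least 1x1, got %dx%d",
                        nrow(temps), ncol(temps))
  if (!is.numeric(band) || length(band) != 2L || band[1] >= band[2])
    ht_validation_error("band must be an increasing length-2 numeric vector")
  if (!is.numeric(emissivity) || length(emissivity) != 1L ||
      !is.finite(emissivity) || emissivity <= 0 || emissivity > 1)
    ht_validation_error("emissivity must lie in (0, 1], got %s",
                        format(emissivity))
  storage.mode(temps) <- "double"
  bad <- which(is.finite(temps) & (temps < band[1] | temps > band[2]))
  if (length(bad)) {
    rc <- arrayInd(bad, dim(temps)) - 1L  # report 0-based coordinates
    show <- seq_len(min(5L, length(bad)))
    ht_validation_error(
      "%d temperature(s) outside plausibility band [%g, %g] degC: %s%s",
      length(bad), band[1], band[2],
      paste(sprintf("%.6g at (%d,%d)", temps[bad[show]],
                    rc[show, 1], rc[show, 2]), collapse = ", "),
      if (length(bad) > 5L) ", ..." else "")
  }
  structure(list(temps = temps,
                 height = nrow(temps),
                 width = ncol(temps),
                 emissivity = emissivity,
                 capture_time = if (is.null(capture_time)) NULL else as.character(capture_time),
                 subject_id = if (is.null(subject_id)) NULL else as.character(subject_id),
                 band = as.numeric(band),
                 units = "degC"),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf("<thermal_frame> %d x %d px, emissivity %.3g\n",
              x$height, x$width, x$emissivity))
  v <- x$temps[is.finite(x$temps)]
  if (length(v))
    cat(sprintf("  temperature range %.2f .. %.2f degC (%d invalid px)\n",
                min(v), max(v), sum(!is.finite(x$temps))))
  else cat("  all pixels invalid\n")
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.null(x$capture_time)) cat("  captured:", x$capture_time, "\n")
  invisible(x)
}

is_thermal_frame <- function(x) inherits(x, "thermal_frame")
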