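#' Path of the metadata sidecar for a temperature grid
#'
#' Sidecar metadata (emissivity, capture_time, subject_id) lives in a small
#' YAML file next to the grid, named `<stem>.meta.yaml`.
#'
#' @param path Path of the temperature-grid file.
#' @return Sidecar path (character).
#' @export
sidecar_path <- function(path) {
  stem <- tools::file_path_sans_ext(path)
  if (!nzchar(stem)) stem <- path
  paste0(stem, ".meta.yaml")
}

# Split one grid line into fields, honouring the dialect.
split_fields <- function(line, delim) {
  trimws(strsplit(line, delim, fixed = TRUE)[[1]])
}

#' Read a plain-text temperature grid
#'
#' Parses a delimited text file of calibrated temperatures (deg C), one image
#' row per line, into a [thermal_frame()].  European thermography exports
#' often use semicolons and decimal commas; both are supported through the
#' dialect arguments.  Tokens `NA`, `NaN` and the empty string are read as
#' invalid pixels.  If a metadata sidecar (see [sidecar_path()]) exists it
#' supplies emissivity, capture time and subject id; otherwise the default
#' emissivity 0.98 is applied.
#'
#' @param path Grid file path.
#' @param delim Field delimiter: `","` (default), `";"` or `"\t"`.
#' @param dec Decimal mark: `"."` (default) or `","`.  A decimal comma
#'   requires a non-comma delimiter.
#' @param band Plausibility band passed to [thermal_frame()].
#' @param sidecar Read the metadata sidecar if present? Default `TRUE`.
#'
#' @return A validated [thermal_frame()].
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("33.0,34.0,33.5", "33.2,34.1,33.6"), p)
#' fr <- read_temperature_grid(p)
#' fr$temps
read_temperature_grid <- function(path, delim = ",", dec = ".",
                                  band = DEFAULT_BAND, sidecar = TRUE) {
  if (!file.exists(path)) ht_io_error("no such file: %s", path)
  if (!delim %in% c(",", ";", "\t"))
    ht_precondition_error("delimiter must be one of ',', ';', tab")
  if (!dec %in% c(".", ","))
    ht_precondition_error("decimal mark must be '.' or ','")
  if (dec == "," && delim == ",")
    ht_precondition_error("decimal comma requires a non-comma delimiter")

  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) ht_format_error("empty grid file: %s", path)

  rows <- lapply(lines, split_fields, delim = delim)
  n <- length(rows[[1L]])
  widths <- lengths(rows)
  if (any(widths != n)) {
    bad <- which(widths != n)[1L]
    ht_format_error("ragged grid in %s: row %d has %d field(s); expected %d (as in row 1)",
                    path, bad, widths[bad], n)
  }
  parse_row <- function(fields, i) {
    if (dec == ",") fields <- gsub(",", ".", fields, fixed = TRUE)
    miss <- fields %in% c("", "NA", "NaN", "nan")
    v <- suppressWarnings(as.numeric(fields))
    badcol <- which(is.na(v) & !miss)
    if (length(badcol))
      ht_format_error("unparseable token '%s' at row %d, column %d of %s",
                      fields[badcol[1L]], i, badcol[1L], path)
    v[miss] <- NA_real_
    v
  }
  temps <- do.call(rbind, Map(parse_row, rows, seq_along(rows)))

  meta <- list(emissivity = 0.98, capture_time = NULL, subject_id = NULL)
  sp <- sidecar_path(path)
  if (isTRUE(sidecar) && file.exists(sp)) {
    got <- yaml::read_yaml(sp)
    for (k in intersect(names(meta), names(got))) meta[[k]] <- got[[k]]
  }
  thermal_frame(temps, emissivity = meta$emissivity,
                capture_time = meta$capture_time,
                subject_id = meta$subject_id, band = band)
}

#' Write a thermal frame as a plain-text temperature grid
#'
#' Writes one image row per line at full double precision (17 significant
#' digits), so that `read_temperature_grid()` reproduces the frame exactly.
#' Invalid pixels are written as `NA`.  A YAML metadata sidecar is written
#' next to the grid unless `sidecar = FALSE`.
#'
#' @param frame A [thermal_frame()].
#' @param path Output file path.
#' @inheritParams read_temperature_grid
#' @param sidecar Write the metadata sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_temperature_grid <- function(frame, path, delim = ",", dec = ".",
                                   sidecar = TRUE) {
  stopifnot(is_thermal_frame(frame))
  if (dec == "," && delim == ",")
    ht_precondition_error("decimal comma requires a non-comma delimiter")
  fmt <- function(v) {
    s <- vapply(v, function(x)
      if (is.finite(x)) sprintf("%.17g", x) else "NA", character(1))
    if (dec == ",") s <- gsub(".", ",", s, fixed = TRUE)
    paste(s, collapse = delim)
  }
  lines <- apply(frame$temps, 1L, fmt)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) ht_io_error("cannot write temperature grid to %s", path)
  if (isTRUE(sidecar)) {
    meta <- list(emissivity = frame$emissivity)
    if (!is.null(frame$capture_time)) meta$capture_time <- frame$capture_time
    if (!is.null(frame$subject_id)) meta$subject_id <- frame$subject_id
    yaml::write_yaml(meta, sidecar_path(path))
  }
  invisible(path)
}

#' Affine radiometric calibration
#'
#' Raw radiometric rasters store digital numbers (DN); calibration to deg C
#' is affine: `temperature = gain * DN + offset`.
#'
#' @param gain deg C per digital number; must be nonzero.
#' @param offset deg C.
#' @param invalid_value Optional sentinel DN marking dead/invalid pixels.
#' @return An object of class `radiometric_calibration`.
#' @export
#' @examples
#' cal <- radiometric_calibration(gain = 0.01, offset = 20)
radiometric_calibration <- function(gain, offset, invalid_value = NULL) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain == 0)
    ht_precondition_error("calibration gain must be a nonzero finite number")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
    ht_precondition_error("calibration offset must be a finite number")
  structure(list(gain = gain, offset = offset,
                 invalid_value = invalid_value),
            class = "radiometric_calibration")
}

#' Read a 16-bit radiometric raster and convert to temperatures
#'
#' Reads a single-channel integer raster (TIFF or PNG) of digital numbers and
#' applies an affine [radiometric_calibration()].  Pixels equal to the
#' calibration's `invalid_value` sentinel become invalid (`NA`) and are
#' excluded from all downstream statistics.
#'
#' @param path Raster path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @param calib A [radiometric_calibration()].
#' @inheritParams thermal_frame
#' @return A validated [thermal_frame()].
#' @export
read_radiometric_image <- function(path, calib, emissivity = 0.98,
                                   band = DEFAULT_BAND) {
  if (!inherits(calib, "radiometric_calibration"))
    ht_precondition_error("calib must be a radiometric_calibration")
  if (!file.exists(path)) ht_io_error("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    img <- round(img * (2^depth - 1))
  } else {
    ht_format_error("unsupported raster format '.%s' (use TIFF or PNG)", ext)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] > 1L)
      ht_format_error("raster %s has %d channels; a radiometric raster must be single-channel",
                      path, dim(img)[3L])
    img <- img[, , 1L]
  }
  dn <- matrix(as.numeric(img), nrow = nrow(img))
  if (!is.null(calib$invalid_value))
    dn[dn == calib$invalid_value] <- NA_real_
  temps <- calib$gain * dn + calib$offset
  if (!any(is.finite(temps)) || all(!is.finite(temps) |
                                    temps < band[1] | temps > band[2]))
    ht_validation_error("all calibrated temperatures in %s fall outside band [%g, %g] degC",
                        path, band[1], band[2])
  thermal_frame(temps, emissivity = emissivity, band = band)
}
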