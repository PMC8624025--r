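#' Placement of ROI-local coordinates in the full frame
#'
#' Describes how pixels expressed in ROI-local coordinates are repositioned
#' onto the acquisition frame.  When `mirrored = TRUE` the coordinates are in
#' mirrored-healthy orientation and the column axis is un-mirrored before
#' the offset is applied.
#'
#' @param roi The [roi_spec()] the coordinates are local to.
#' @param mirrored Are the coordinates in mirrored orientation?
#' @return An object of class `frame_placement`.
#' @export
frame_placement <- function(roi, mirrored = FALSE) {
  stopifnot(inherits(roi, "roi_spec"), is.logical(mirrored))
  structure(list(roi = roi, mirrored = isTRUE(mirrored)),
            class = "frame_placement")
}

as_pixels <- function(x) {
  if (inherits(x, "hotspot_region")) x <- x$pixels
  if (is.logical(x) && is.matrix(x)) x <- arrayInd(which(x), dim(x)) - 1L
  if (!is.matrix(x) || ncol(x) != 2L)
    ht_precondition_error("pixels must be a two-column (row, col) matrix, a logical mask, or a hotspot_region")
  storage.mode(x) <- "integer"
  unname(x)
}

#' Reposition a detected region onto the acquisition frame
#'
#' Maps ROI-local 0-based pixel coordinates `(i, j)` to frame coordinates
#' `(top + i, left + j)`, or `(top + i, left + (width - 1 - j))` when the
#' placement is mirrored.  The mapping is a bijection on the region; use
#' [map_frame_to_roi()] to invert it.
#'
#' @param region A `hotspot_region`, a logical ROI-shaped mask, or a
#'   two-column 0-based `(row, col)` matrix.
#' @param placement A [frame_placement()].
#' @param frame Optional [thermal_frame()]; if given, mapped pixels are
#'   checked to land inside it.
#' @return Two-column integer matrix of 0-based frame coordinates.
#' @export
#' @examples
#' roi <- roi_spec(10, 20, 5, 5)
#' map_region_to_frame(rbind(c(0, 0)), frame_placement(roi))  # (10, 20)
map_region_to_frame <- function(region, placement, frame = NULL) {
  stopifnot(inherits(placement, "frame_placement"))
  px <- as_pixels(region)
  roi <- placement$roi
  if (nrow(px) && (min(px) < 0L || max(px[, 1L]) >= roi$height ||
                   max(px[, 2L]) >= roi$width))
    ht_bounds_error("region pixels fall outside the %dx%d ROI",
                    roi$height, roi$width)
  j <- if (placement$mirrored) roi$width - 1L - px[, 2L] else px[, 2L]
  out <- cbind(roi$top + px[, 1L], roi$left + j)
  if (!is.null(frame)) {
    stopifnot(is_thermal_frame(frame))
    if (nrow(out) && (max(out[, 1L]) >= frame$height ||
                      max(out[, 2L]) >= frame$width || min(out) < 0L))
      ht_placement_error("mapped pixels fall outside the %dx%d frame",
                         frame$height, frame$width)
  }
  out
}

#' Inverse of [map_region_to_frame()]
#'
#' @param pixels Two-column 0-based frame-coordinate matrix.
#' @inheritParams map_region_to_frame
#' @return Two-column integer matrix of ROI-local 0-based coordinates.
#' @export
map_frame_to_roi <- function(pixels, placement) {
  stopifnot(inherits(placement, "frame_placement"))
  px <- as_pixels(pixels)
  roi <- placement$roi
  i <- px[, 1L] - roi$top
  j <- px[, 2L] - roi$left
  if (placement$mirrored) j <- roi$width - 1L - j
  if (nrow(px) && (min(i) < 0L || min(j) < 0L ||
                   max(i) >= roi$height || max(j) >= roi$width))
    ht_placement_error("frame pixels fall outside the placement ROI")
  cbind(i, j, deparse.level = 0L)
}

#' Convert between pixel lists and logical masks
#'
#' @param pixels Two-column 0-based `(row, col)` matrix.
#' @param height,width Mask dimensions.
#' @return `pixels_to_mask`: a logical matrix; `mask_to_pixels`: a
#'   two-column 0-based integer matrix.
#' @export
pixels_to_mask <- function(pixels, height, width) {
  px <- as_pixels(pixels)
  m <- matrix(FALSE, height, width)
  if (nrow(px)) {
    if (min(px) < 0L || max(px[, 1L]) >= height || max(px[, 2L]) >= width)
      ht_bounds_error("pixels fall outside a %dx%d mask", height, width)
    m[px + 1L] <- TRUE
  }
  m
}

#' @rdname pixels_to_mask
#' @param mask Logical matrix.
#' @export
mask_to_pixels <- function(mask) as_pixels(mask)

# Map a temperature matrix to an RGB array using a named palette.
# "inferno" (perceptually uniform, default) or "legacy_rainbow" (the
# orange-red / blue-green display common in clinical thermography software).
thermal_rgb <- function(v, palette = c("inferno", "legacy_rainbow")) {
  palette <- match.arg(palette)
  cols <- switch(palette,
                 inferno = grDevices::hcl.colors(256L, "Inferno"),
                 legacy_rainbow = rev(grDevices::rainbow(256L, end = 0.7)))
  rng <- range(v[is.finite(v)])
  if (!diff(rng)) rng <- rng + c(-0.5, 0.5)
  idx <- pmin(255L, pmax(0L, floor((v - rng[1L]) / diff(rng) * 255.999)))
  rgb <- grDevices::col2rgb(cols) / 255
  arr <- array(0.5, c(nrow(v), ncol(v), 3L))  # invalid pixels mid-gray
  ok <- is.finite(v)
  for (ch in 1:3) {
    plane <- arr[, , ch]
    plane[ok] <- rgb[ch, idx[ok] + 1L]
    arr[, , ch] <- plane
  }
  arr
}

# Boundary pixels of a mask: member pixels with at least one 4-neighbour
# outside the mask (or on the image edge).
mask_contour <- function(mask) {
  m <- nrow(mask); n <- ncol(mask)
  pad <- matrix(FALSE, m + 2L, n + 2L)
  pad[2:(m + 1L), 2:(n + 1L)] <- mask
  interior <- pad[1:m, 2:(n + 1L)] & pad[3:(m + 2L), 2:(n + 1L)] &
    pad[2:(m + 1L), 1:n] & pad[2:(m + 1L), 3:(n + 2L)]
  mask & !interior
}

#' Render a hotspot mask over a thermal frame
#'
#' Writes a PNG of the frame's temperature field under a chosen palette with
#' the detected region outlined (`style = "contour"`) or filled
#' (`style = "fill"`).  Rendering is pixel-exact and deterministic: with
#' `style = "contour"` only contour pixels differ from the base render.  An
#' empty mask renders the base image with an amber warning banner across the
#' top rows and raises an R warning.
#'
#' @param frame A [thermal_frame()].
#' @param mask Frame-coordinate mask: logical matrix of the frame's shape or
#'   a two-column 0-based pixel matrix.
#' @param path Output PNG path.
#' @param style `"contour"` (default) or `"fill"`.
#' @param palette `"inferno"` (default) or `"legacy_rainbow"`.
#' @param color Highlight colour (any R colour), default `"cyan"`.
#' @param alpha Fill opacity in (0, 1] when `style = "fill"`.
#' @return `path`, invisibly.
#' @export
render_overlay <- function(frame, mask, path, style = c("contour", "fill"),
                           palette = "inferno", color = "cyan", alpha = 0.6) {
  style <- match.arg(style)
  stopifnot(is_thermal_frame(frame))
  if (!is.logical(mask) || !is.matrix(mask))
    mask <- pixels_to_mask(mask, frame$height, frame$width)
  if (!identical(dim(mask), dim(frame$temps)))
    ht_dimension_error("mask shape %s does not match frame %dx%d",
                       paste(dim(mask), collapse = "x"),
                       frame$height, frame$width)
  arr <- thermal_rgb(frame$temps, palette)
  hl <- as.numeric(grDevices::col2rgb(color)) / 255
  if (!any(mask)) {
    warning("empty mask: rendering base image with warning banner")
    banner <- seq_len(min(6L, frame$height))
    for (ch in 1:3) arr[banner, , ch] <- c(1, 0.75, 0)[ch]
  } else if (style == "contour") {
    sel <- mask_contour(mask)
    for (ch in 1:3) {
      plane <- arr[, , ch]; plane[sel] <- hl[ch]; arr[, , ch] <- plane
    }
  } else {
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[mask] <- (1 - alpha) * plane[mask] + alpha * hl[ch]
      arr[, , ch] <- plane
    }
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Render a 3-D surface of a temperature matrix
#'
#' Perspective surface of temperature (z) over the ROI pixel grid, the
#' standard qualitative display of an ROI weighted by temperature.  Facets
#' are coloured by mean temperature with the same palettes as
#' [render_overlay()].
#'
#' @param M A [temperature_matrix()].
#' @param path Output PNG path.
#' @param palette Palette name, see [render_overlay()].
#' @param theta,phi Viewing angles (degrees) passed to [graphics::persp()].
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
render_surface <- function(M, path, palette = "inferno",
                           theta = 35, phi = 30, width = 800, height = 600) {
  if (!inherits(M, "temperature_matrix"))
    ht_precondition_error("M must be a temperature_matrix")
  z <- unclass_tm(M)
  if (!any(is.finite(z)))
    ht_empty_error("cannot render a surface: all pixels invalid")
  if (nrow(z) < 2L || ncol(z) < 2L)
    ht_precondition_error("surface rendering needs at least a 2x2 matrix")
  zlim <- range(z, na.rm = TRUE)
  if (!diff(zlim)) zlim <- zlim + c(-0.5, 0.5)
  cols <- switch(match.arg(palette, c("inferno", "legacy_rainbow")),
                 inferno = grDevices::hcl.colors(128L, "Inferno"),
                 legacy_rainbow = rev(grDevices::rainbow(128L, end = 0.7)))
  # facet colour from mean of the four corner temperatures
  zf <- z
  if (nrow(z) > 1L && ncol(z) > 1L) {
    zf <- (z[-1L, -1L] + z[-1L, -ncol(z)] + z[-nrow(z), -1L] +
             z[-nrow(z), -ncol(z)]) / 4
  }
  idx <- pmin(127L, pmax(0L, floor((zf - zlim[1L]) / diff(zlim) * 127.999)))
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::persp(x = seq_len(nrow(z)) - 1, y = seq_len(ncol(z)) - 1,
                  z = z, zlim = zlim, theta = theta, phi = phi,
                  col = cols[idx + 1L], border = NA, shade = NA,
                  xlab = "row (px)", ylab = "col (px)",
                  zlab = "temperature (degC)",
                  ticktype = "detailed", expand = 0.6)
  invisible(path)
}

#' Write a region label image
#'
#' 8-bit PNG label image: background 0, region pixels carry the region's
#' rank label (1 = main site).  Labels above 255 are clamped to 255.
#'
#' @param regions List from [segment_hotspots()].
#' @param height,width Image dimensions (the thresholded ROI's shape).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(regions, height, width, path) {
  lab <- matrix(0L, height, width)
  for (r in regions) lab[r$pixels + 1L] <- min(r$label, 255L)
  png::writePNG(lab / 255, path)
  invisible(path)
}
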