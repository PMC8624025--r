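#' Specify a rectangular region of interest
#'
#' Pixel coordinates are 0-based with the origin at the image top-left, and
#' the ROI covers the half-open ranges `[top, top + height)` x
#' `[left, left + width)`.  Paired healthy/diseased ROIs must share the same
#' height and width; pixel correspondence between the two hemifaces is taken
#' as given (no registration is performed).
#'
#' @param top,left 0-based row/column of the ROI's top-left pixel.
#' @param height,width ROI size in pixels, both at least 1.
#' @param laterality Which hemiface the ROI covers: `"left"` or `"right"`.
#' @param label Free-text label.
#' @return An object of class `roi_spec`.
#' @export
#' @examples
#' roi_spec(top = 100, left = 200, height = 350, width = 250, laterality = "left")
roi_spec <- function(top, left, height, width,
                     laterality = c("left", "right"), label = "") {
  laterality <- match.arg(laterality)
  for (v in list(top, left, height, width))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v != round(v))
      ht_precondition_error("ROI top/left/height/width must be whole numbers")
  if (top < 0 || left < 0)
    ht_precondition_error("ROI top/left must be >= 0, got top=%d left=%d",
                          top, left)
  if (height < 1 || width < 1)
    ht_precondition_error("ROI must have positive area, got %dx%d",
                          height, width)
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width),
                 laterality = laterality, label = as.character(label)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> rows [%d,%d) x cols [%d,%d), %s hemiface%s\n",
              x$top, x$top + x$height, x$left, x$left + x$width,
              x$laterality,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}

check_roi_in_frame <- function(frame, roi) {
  over_r <- roi$top + roi$height - frame$height
  over_c <- roi$left + roi$width - frame$width
  if (over_r > 0L || over_c > 0L)
    ht_bounds_error("ROI [%d,%d)x[%d,%d) overhangs the %dx%d frame by %d row(s) and %d column(s)",
                    roi$top, roi$top + roi$height,
                    roi$left, roi$left + roi$width,
                    frame$height, frame$width,
                    max(over_r, 0L), max(over_c, 0L))
  invisible(TRUE)
}

#' Extract a region of interest from a thermal frame
#'
#' Copies the rectangular ROI out of the frame as a [temperature_matrix()]
#' with `values[i, j] = frame$temps[top + i, left + j]` (0-based).
#'
#' @param frame A [thermal_frame()].
#' @param roi A [roi_spec()] lying fully inside the frame.
#' @param kind Role of the extract: `"healthy"` (default) or `"diseased"`.
#' @return An `height x width` [temperature_matrix()].
#' @export
extract_roi <- function(frame, roi, kind = c("healthy", "diseased")) {
  kind <- match.arg(kind)
  stopifnot(is_thermal_frame(frame), inherits(roi, "roi_spec"))
  check_roi_in_frame(frame, roi)
  v <- frame$temps[roi$top + seq_len(roi$height),
                   roi$left + seq_len(roi$width), drop = FALSE]
  temperature_matrix(v, kind)
}

#' Split a frontal frame into contralateral hemiface ROIs
#'
#' Convenience for single frontal acquisitions: extracts two ROIs of equal
#' size placed at mirrored horizontal offsets on either side of a vertical
#' symmetry axis.  `axis_col` names the mirror line at the left edge of
#' column `axis_col` (0-based), so the left ROI covers columns
#' `[axis_col - width, axis_col)` and the right ROI `[axis_col, axis_col + width)`.
#' The axis is a column boundary, not a pixel column, so no pixel belongs to
#' both sides.  The axis must be supplied by the user; no midline detection
#' is attempted.
#'
#' @param frame A [thermal_frame()].
#' @param axis_col 0-based column position of the sagittal symmetry axis.
#' @param roi_height,roi_width ROI size in pixels.
#' @param top 0-based top row of both ROIs (default 0).
#' @param diseased_side Which side of the axis is the diseased hemiface.
#' @return A list with `diseased` and `healthy` [temperature_matrix()]
#'   extracts and the corresponding `diseased_roi`/`healthy_roi`
#'   [roi_spec()]s.
#' @export
split_hemifaces <- function(frame, axis_col, roi_height, roi_width,
                            top = 0, diseased_side = c("left", "right")) {
  diseased_side <- match.arg(diseased_side)
  stopifnot(is_thermal_frame(frame))
  if (axis_col - roi_width < 0 || axis_col + roi_width > frame$width)
    ht_bounds_error("ROIs of width %d around axis_col=%d do not fit a frame %d columns wide",
                    roi_width, axis_col, frame$width)
  left_roi <- roi_spec(top, axis_col - roi_width, roi_height, roi_width,
                       laterality = "left")
  right_roi <- roi_spec(top, axis_col, roi_height, roi_width,
                        laterality = "right")
  if (diseased_side == "left") {
    list(diseased = extract_roi(frame, left_roi, "diseased"),
         healthy = extract_roi(frame, right_roi, "healthy"),
         diseased_roi = left_roi, healthy_roi = right_roi)
  } else {
    list(diseased = extract_roi(frame, right_roi, "diseased"),
         healthy = extract_roi(frame, left_roi, "healthy"),
         diseased_roi = right_roi, healthy_roi = left_roi)
  }
}
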