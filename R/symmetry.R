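#' Mirror a temperature matrix across its vertical axis
#'
#' Reverses the column order: `output[i, j] = M[i, n - 1 - j]` (0-based).
#' Applied to the healthy hemiface matrix `<H>` this yields the mirrored
#' matrix `<H*>` whose pixels correspond positionally to the diseased
#' hemiface, so the two can be compared pixel by pixel.  Mirroring is an
#' involution: `mirror_matrix(mirror_matrix(M))` equals `M`.
#'
#' @param M A [temperature_matrix()].
#' @return A [temperature_matrix()] of the same size.  Kind `"healthy"`
#'   becomes `"mirrored_healthy"` and vice versa; other kinds are kept.
#' @export
#' @examples
#' M <- temperature_matrix(matrix(1:6, 2, byrow = TRUE) + 30, "healthy")
#' mirror_matrix(M)
mirror_matrix <- function(M) {
  if (!inherits(M, "temperature_matrix"))
    ht_precondition_error("M must be a temperature_matrix")
  kind <- switch(matrix_kind(M),
                 healthy = "mirrored_healthy",
                 mirrored_healthy = "healthy",
                 matrix_kind(M))
  out <- temperature_matrix(unclass_tm(M)[, rev(seq_len(ncol(M))), drop = FALSE],
                            kind)
  attr(out, "delta_t") <- attr(M, "delta_t")
  out
}

#' Differential map between diseased and mirrored healthy matrices
#'
#' Computes the pixel-wise thermal gradient `<R> = <D> - <H*>`, where `<H*>`
#' is the mirrored healthy matrix.  Under healthy conditions contralateral
#' facial regions are thermally near-symmetric, so `<R>` isolates the
#' temperature elevation attributable to inflammation.  Invalid pixels in
#' either operand propagate as invalid.
#'
#' @param D Diseased [temperature_matrix()] (kind `"diseased"`).
#' @param H Healthy [temperature_matrix()]: either kind `"healthy"` (it is
#'   mirrored internally) or an already mirrored `"mirrored_healthy"` matrix.
#' @return A [temperature_matrix()] of kind `"differential"`; values may be
#'   negative where the diseased side is cooler.
#' @export
#' @examples
#' D <- temperature_matrix(matrix(c(37.2, 33.0), 1), "diseased")
#' H <- temperature_matrix(matrix(c(33.0, 34.0), 1), "healthy")
#' differential_map(D, H)  # 3.2, 0.0
differential_map <- function(D, H) {
  expect_kind(D, "diseased", "D")
  expect_kind(H, c("healthy", "mirrored_healthy"), "H")
  if (!identical(dim(D), dim(H)))
    ht_dimension_error("matrix shapes differ: D is %dx%d, H is %dx%d",
                       nrow(D), ncol(D), nrow(H), ncol(H))
  Hm <- if (matrix_kind(H) == "healthy") mirror_matrix(H) else H
  temperature_matrix(unclass_tm(D) - unclass_tm(Hm), "differential")
}

#' Severity threshold policy
#'
#' The cut-off Delta-T below which differential values are zeroed.  Use
#' [threshold_for_grade()] to obtain the published severity-grade cut-offs
#' (moderate: 2 degC, severe: 3 degC) or construct an explicit policy here.
#'
#' @param delta_t Cut-off in deg C, strictly positive.
#' @param source How the cut-off was chosen: `"explicit"` or
#'   `"severity_grade"`.
#' @param grade Grade name when `source = "severity_grade"`.
#' @return An object of class `threshold_policy`.
#' @export
threshold_policy <- function(delta_t, source = c("explicit", "severity_grade"),
                             grade = NULL) {
  source <- match.arg(source)
  if (!is.numeric(delta_t) || length(delta_t) != 1L || !is.finite(delta_t) ||
      delta_t <= 0)
    ht_precondition_error("delta_t threshold must be a positive number, got %s",
                          format(delta_t))
  structure(list(delta_t = as.numeric(delta_t), source = source, grade = grade),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("<threshold_policy> delta_t = %g degC (%s%s)\n", x$delta_t,
              x$source, if (!is.null(x$grade)) paste0(": ", x$grade) else ""))
  invisible(x)
}

as_threshold_policy <- function(x) {
  if (inherits(x, "threshold_policy")) x else threshold_policy(x)
}

#' Zero sub-threshold values of a differential map
#'
#' Applies the severity cut-off: entries with `R[i, j] < delta_t` are set to
#' 0; entries greater than or equal to the cut-off are kept unchanged (a
#' value exactly equal to the cut-off survives).  Negative differentials are
#' always zeroed since the cut-off is positive.  Invalid pixels stay invalid.
#'
#' @param R A differential [temperature_matrix()].
#' @param policy A [threshold_policy()], or a single positive number taken as
#'   an explicit cut-off in deg C.
#' @return A [temperature_matrix()] of kind `"thresholded"` carrying the
#'   cut-off as attribute `delta_t`.  No value lies strictly between 0 and
#'   the cut-off.
#' @export
#' @examples
#' R <- temperature_matrix(matrix(c(3.2, 0, 2.9, -1), 2, byrow = TRUE),
#'                         "differential")
#' threshold_map(R, 3)
threshold_map <- function(R, policy) {
  expect_kind(R, "differential", "R")
  policy <- as_threshold_policy(policy)
  v <- unclass_tm(R)
  v[is.finite(v) & v < policy$delta_t] <- 0
  out <- temperature_matrix(v, "thresholded")
  attr(out, "delta_t") <- policy$delta_t
  out
}

#' Summary statistics of a differential map
#'
#' Reports the maximum and mean Delta-T over valid pixels and, for each
#' caller-supplied threshold, the count and fraction of valid pixels at or
#' above it.
#'
#' @param R A [temperature_matrix()] of kind `"differential"` or
#'   `"thresholded"`.
#' @param thresholds Numeric vector of Delta-T levels, deg C.  Default
#'   `c(2, 3)`, the published moderate/severe cut-offs.
#' @return A list with `max_delta_t`, `mean_delta_t`, `n_valid`,
#'   `n_invalid`, and a data frame `at_or_above` with columns `threshold`,
#'   `count`, `fraction`.
#' @export
asymmetry_summary <- function(R, thresholds = c(2, 3)) {
  expect_kind(R, c("differential", "thresholded"), "R")
  v <- unclass_tm(R)
  v <- v[is.finite(v)]
  if (!length(v))
    ht_empty_error("all %d pixels of the map are invalid", length(R))
  counts <- vapply(thresholds, function(t) sum(v >= t), numeric(1))
  list(max_delta_t = max(v),
       mean_delta_t = mean(v),
       n_valid = length(v),
       n_invalid = length(R) - length(v),
       at_or_above = data.frame(threshold = as.numeric(thresholds),
                                count = as.integer(counts),
                                fraction = counts / length(v)))
}
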