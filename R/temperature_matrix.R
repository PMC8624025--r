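MATRIX_KINDS <- c("healthy", "mirrored_healthy", "diseased",
                  "differential", "thresholded")

#' Construct a temperature matrix
#'
#' An `m x n` region-of-interest extract in deg C (or deg C difference for
#' differential/thresholded matrices), tagged with its role in the bilateral
#' differential procedure: the healthy matrix `<H>`, its mirror `<H*>`, the
#' diseased matrix `<D>`, the differential `<R> = <D> - <H*>` or the
#' severity-thresholded map.
#'
#' @param values Numeric matrix.
#' @param kind One of `"healthy"`, `"mirrored_healthy"`, `"diseased"`,
#'   `"differential"`, `"thresholded"`.
#' @return A `temperature_matrix`: a numeric matrix carrying a `kind`
#'   attribute.  Ordinary matrix operations (`dim`, `[`, arithmetic) apply.
#' @export
#' @examples
#' temperature_matrix(matrix(33:36 + 0.5, 2), "healthy")
temperature_matrix <- function(values, kind) {
  kind <- match.arg(kind, MATRIX_KINDS)
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values) || !is.numeric(values))
    ht_validation_error("values must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    ht_validation_error("temperature matrix must be at least 1x1")
  storage.mode(values) <- "double"
  structure(values, kind = kind,
            class = c("temperature_matrix", "matrix", "array"))
}

#' @export
print.temperature_matrix <- function(x, ...) {
  cat(sprintf("<temperature_matrix kind=%s> %d x %d\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  if (!is.null(attr(x, "delta_t")))
    cat(sprintf("  threshold: %g degC\n", attr(x, "delta_t")))
  print(unclass_tm(x), ...)
  invisible(x)
}

matrix_kind <- function(x) attr(x, "kind")

unclass_tm <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

expect_kind <- function(x, kinds, what) {
  if (!inherits(x, "temperature_matrix"))
    ht_precondition_error("%s must be a temperature_matrix", what)
  if (!matrix_kind(x) %in% kinds)
    ht_precondition_error("%s must have kind %s, got '%s'", what,
                          paste(sQuote(kinds), collapse = " or "),
                          matrix_kind(x))
  invisible(x)
}
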