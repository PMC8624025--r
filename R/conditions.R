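#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can map failures to distinct
# error classes / exit codes.  All inherit from "hemitherm_error".
ht_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "hemitherm_error")))
}

ht_format_error        <- function(msg, ...) ht_stop("ht_format_error", msg, ...)
ht_validation_error    <- function(msg, ...) ht_stop("ht_validation_error", msg, ...)
ht_bounds_error        <- function(msg, ...) ht_stop("ht_bounds_error", msg, ...)
ht_dimension_error     <- function(msg, ...) ht_stop("ht_dimension_error", msg, ...)
ht_precondition_error  <- function(msg, ...) ht_stop("ht_precondition_error", msg, ...)
ht_io_error            <- function(msg, ...) ht_stop("ht_io_error", msg, ...)
ht_empty_error         <- function(msg, ...) ht_stop("ht_empty_error", msg, ...)
ht_enum_error          <- function(msg, ...) ht_stop("ht_enum_error", msg, ...)
ht_spec_error          <- function(msg, ...) ht_stop("ht_spec_error", msg, ...)
ht_placement_error     <- function(msg, ...) ht_stop("ht_placement_error", msg, ...)
ht_comparability_error <- function(msg, ...) ht_stop("ht_comparability_error", msg, ...)

#' Exit codes used by the command-line interface
#'
#' Maps each error condition class raised by the package to the distinct
#' process exit code used by the `hemitherm` command-line script.  Exit code
#' 0 means success; 1 is reserved for unclassified failures.
#'
#' @return Named integer vector of exit codes.
#' @export
#' @examples
#' cli_exit_codes()
cli_exit_codes <- function() {
  c(ht_format_error        = 2L,
    ht_validation_error    = 3L,
    ht_bounds_error        = 4L,
    ht_dimension_error     = 5L,
    ht_precondition_error  = 6L,
    ht_io_error            = 7L,
    ht_empty_error         = 8L,
    ht_enum_error          = 9L,
    ht_spec_error          = 10L,
    ht_placement_error     = 11L,
    ht_comparability_error = 12L)
}
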