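#' @importFrom rlang abort warn
NULL

# Condition helpers. Transport failures (a backend that cannot be reached)
# must be distinguishable from "no match"/"not found", which are ordinary
# values: callers may retry the former but never the latter.

abort_config <- function(message, ...) {
  abort(message, class = "lcscreen_config_error", ...)
}

abort_schema <- function(message, missing = character(), ...) {
  abort(message, class = "lcscreen_schema_error", missing = missing, ...)
}

#' Signal a retriable transport error
#'
#' Used by backends to report that the underlying service could not be
#' reached. Distinct by class from every other condition the package raises,
#' so callers can retry transport errors without masking data errors.
#'
#' @param message Description of the failure.
#' @param ... Additional condition fields.
#' @export
transport_error <- function(message = "backend unreachable", ...) {
  abort(message, class = "lcscreen_transport_error", ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
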