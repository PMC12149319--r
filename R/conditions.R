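# Classed conditions used across the package. Every error raised here carries
# the superclass "fhirtable_error" so callers can distinguish engine errors
# from programming errors.

fhir_condition <- function(class, message, ...) {
  structure(
    class = c(class, "fhirtable_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
}

stop_syntax <- function(message, offset) {
  stop(fhir_condition(
    "fhir_syntax_error",
    sprintf("FHIRPath syntax error at offset %d: %s", offset, message),
    offset = offset
  ))
}

stop_type <- function(message) {
  stop(fhir_condition("fhir_type_error", message))
}

stop_cardinality <- function(message) {
  stop(fhir_condition("fhir_cardinality_error", message))
}

# `location` is a JSON-pointer-like path into the offending view document.
stop_view_parse <- function(message, location) {
  stop(fhir_condition(
    "fhir_view_parse_error",
    sprintf("invalid view definition at %s: %s", location, message),
    location = location
  ))
}

stop_read <- function(message, line) {
  stop(fhir_condition(
    "fhir_read_error",
    sprintf("line %d: %s", line, message),
    line = line
  ))
}

stop_key <- function(message) {
  stop(fhir_condition("fhir_key_error", message))
}

stop_config <- function(message) {
  stop(fhir_condition("fhir_config_error", message))
}

stop_validation <- function(message, issues) {
  stop(fhir_condition("fhir_validation_error", message, issues = issues))
}

stop_execution <- function(message) {
  stop(fhir_condition("fhir_execution_error", message))
}
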