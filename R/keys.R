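# Join-key generation behind getResourceKey() / getReferenceKey(). The form
# of the keys is deliberately pluggable: any pair of functions that keeps
# resource keys unique within a dataset and makes a reference's key equal to
# its target's resource key will support equijoins between views.

#' Default resource key
#'
#' Returns the canonical key `"<resourceType>/<id>"` for a resource, as a
#' character vector of length one, or length zero when the resource has no
#' `id`. The canonical form is unique across resource types within a dataset.
#'
#' @param resource A FHIR resource (nested list with `resourceType`).
#' @return Character vector of length 0 or 1.
#' @examples
#' resource_key(list(resourceType = "Patient", id = "patient-1"))
#' @export
resource_key <- function(resource) {
  id <- resource[["id"]]
  if (is.null(id) || !is.character(id) || length(id) != 1L) return(character(0))
  type <- resource[["resourceType"]]
  if (is.null(type)) return(character(0))
  paste0(type, "/", id)
}

#' Default reference key
#'
#' Derives the key of the resource a Reference element points at. Literal
#' relative references (`"Type/id"`) and absolute URLs whose final two path
#' segments form `"Type/id"` resolve to the canonical key; fragment
#' references (`"#..."`) and logical-identifier-only references resolve to
#' nothing. When `type` is given and the reference points at a different
#' resource type, the result is empty.
#'
#' @param ref_element A Reference-shaped list (may hold `reference` text).
#' @param type Optional resource-type name to restrict the key to.
#' @return Character vector of length 0 or 1.
#' @examples
#' reference_key(list(reference = "Patient/patient-1"), "Patient")
#' reference_key(list(reference = "Patient/patient-1"), "Observation")  # empty
#' @export
reference_key <- function(ref_element, type = NULL) {
  ref <- ref_element[["reference"]]
  if (is.null(ref) || !is.character(ref) || length(ref) != 1L) return(character(0))
  if (startsWith(ref, "#")) return(character(0))
  parts <- strsplit(sub("\\?.*$", "", ref), "/", fixed = FALSE)[[1L]]
  parts <- parts[nzchar(parts)]
  n <- length(parts)
  if (n < 2L) return(character(0))
  rtype <- parts[[n - 1L]]
  rid <- parts[[n]]
  # history-aware form Type/id/_history/vid
  if (n >= 4L && identical(parts[[n - 1L]], "_history")) {
    rtype <- parts[[n - 3L]]
    rid <- parts[[n - 2L]]
  }
  if (!grepl("^[A-Z][A-Za-z]*$", rtype)) return(character(0))
  if (!is.null(type) && !identical(rtype, type)) return(character(0))
  paste0(rtype, "/", rid)
}

#' Key strategies for join-key generation
#'
#' A key strategy bundles the two capabilities behind `getResourceKey()` and
#' `getReferenceKey()`. The `"canonical"` strategy emits `"Type/id"` keys,
#' which are unique across resource types. The `"display"` strategy emits the
#' bare `id`, matching the shorter keys often shown in human-readable output;
#' it is safe whenever a join involves a single referenced resource type.
#' Either way, a reference's key always equals its target's resource key, so
#' equijoins behave identically under both strategies.
#'
#' @param name `"canonical"` (default) or `"display"`.
#' @return An object of class `fhir_key_strategy`: a list with function
#'   elements `resource_key(resource)` and `reference_key(ref_element, type)`.
#' @examples
#' ks <- key_strategy("display")
#' ks$resource_key(list(resourceType = "Patient", id = "patient-1"))  # "patient-1"
#' @export
key_strategy <- function(name = c("canonical", "display")) {
  name <- match.arg(name)
  strategy <- if (name == "canonical") {
    list(
      name = "canonical",
      resource_key = resource_key,
      reference_key = reference_key
    )
  } else {
    list(
      name = "display",
      resource_key = function(resource) {
        sub("^[^/]+/", "", resource_key(resource))
      },
      reference_key = function(ref_element, type = NULL) {
        sub("^[^/]+/", "", reference_key(ref_element, type))
      }
    )
  }
  structure(strategy, class = "fhir_key_strategy")
}
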