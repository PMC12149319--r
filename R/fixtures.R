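# Bundled example resources and views. The three Patients and three
# Encounters are synthetic, constructed so that every bundled example view
# produces a small, fully characterized table: Aisha Khan (patient-1,
# active, three addresses, two phones), Juan Rodriguez (patient-2, inactive,
# no addresses, one phone), Wei Zhang (patient-3, active, one address, two
# phones), and three ambulatory encounters referring to patients 1 and 2.
# Elements not pinned down by those tables (address `use`, encounter
# `status`/`class`, telecom `use`) are fixture-author's choice.

example_patients <- function() {
  list(
    list(
      resourceType = "Patient",
      id = "patient-1",
      active = TRUE,
      name = list(list(use = "official", family = "Khan", given = list("Aisha"))),
      birthDate = "1980-01-01",
      address = list(
        list(use = "home", line = list("1 Main St"), city = "Springfield",
             state = "IL", postalCode = "62701"),
        list(use = "work", line = list("42 Second Ave"), city = "Chicago",
             state = "IL", postalCode = "60601"),
        list(use = "temp", line = list("789 Third St"), city = "Peoria",
             state = "IL", postalCode = "61602")
      ),
      telecom = list(
        list(system = "phone", value = "555551234", use = "home"),
        list(system = "phone", value = "555559876", use = "work")
      )
    ),
    list(
      resourceType = "Patient",
      id = "patient-2",
      active = FALSE,
      name = list(list(use = "official", family = "Rodriguez", given = list("Juan"))),
      birthDate = "1992-07-15",
      telecom = list(
        list(system = "phone", value = "555542233", use = "home")
      )
    ),
    list(
      resourceType = "Patient",
      id = "patient-3",
      active = TRUE,
      name = list(list(use = "official", family = "Zhang", given = list("Wei"))),
      birthDate = "1965-12-31",
      address = list(
        list(use = "home", line = list("42 Second Ave"), city = "Chicago",
             state = "IL", postalCode = "60601")
      ),
      telecom = list(
        list(system = "phone", value = "555554321", use = "home"),
        list(system = "phone", value = "555555678", use = "work")
      )
    )
  )
}

example_encounters <- function() {
  enc <- function(id, patient, start) {
    list(
      resourceType = "Encounter",
      id = id,
      status = "finished",
      class = list(system = "http://terminology.hl7.org/CodeSystem/v3-ActCode",
                   code = "AMB"),
      subject = list(reference = paste0("Patient/", patient)),
      period = list(start = start)
    )
  }
  list(
    enc("encounter-1", "patient-1", "2023-01-01"),
    enc("encounter-2", "patient-2", "2023-02-15"),
    enc("encounter-3", "patient-1", "2023-03-10")
  )
}

#' Bundled example resources
#'
#' Returns the synthetic example resources the bundled views are written
#' against: Patients `patient-1..3` and Encounters `encounter-1..3`. The same
#' resources ship as a JSON array at
#' `system.file("extdata", "resources", "example-resources-synthetic.json",
#' package = "fhirtable")` for command-line use.
#'
#' @param type Optional resource type (`"Patient"` or `"Encounter"`) to
#'   filter by.
#' @return A list of resources.
#' @export
example_resources <- function(type = NULL) {
  all <- c(example_patients(), example_encounters())
  if (is.null(type)) return(all)
  Filter(function(r) identical(r$resourceType, type), all)
}

#' Path to a bundled data file
#'
#' Convenience wrapper over `system.file()` for the files shipped under
#' `inst/extdata`: example resources, example views, and declarative test
#' cases.
#'
#' @param ... Path components below `extdata`.
#' @return Absolute file path ("" if not found).
#' @export
fhirtable_example <- function(...) {
  system.file("extdata", ..., package = "fhirtable")
}

EXAMPLE_VIEW_NAMES <- c(
  "patient_demographics", "patient_addresses", "patient_addresses_or_null",
  "patient_contacts", "patient_contacts_union", "active_patients",
  "patient_join", "encounter_join"
)

#' Bundled example views
#'
#' Eight ready-made view definitions over the [example_resources()]:
#' \describe{
#'   \item{patient_demographics}{id and birth date — plain column selection.}
#'   \item{patient_addresses}{one row per address via `forEach` (patients
#'     without addresses drop out).}
#'   \item{patient_addresses_or_null}{same via `forEachOrNull` (patients
#'     without addresses keep one null row).}
#'   \item{patient_contacts}{name columns cross-joined with one row per
#'     phone number via `forEach`.}
#'   \item{patient_contacts_union}{the same table expressed with `unionAll`
#'     over home and work phones.}
#'   \item{active_patients}{a `where` clause keeping active patients only.}
#'   \item{patient_join, encounter_join}{key-bearing views using
#'     `getResourceKey()` / `getReferenceKey(Patient)`, made to be equijoined
#'     on `patient_id`.}
#' }
#' All eight conform to the shareable and tabular profiles.
#'
#' @param name One of the names above; `example_views()` returns all of them
#'   as a named list.
#' @return A `fhir_view`, or a named list of them.
#' @export
example_view <- function(name) {
  name <- match.arg(name, EXAMPLE_VIEW_NAMES)
  path <- fhirtable_example("views", paste0(name, ".json"))
  if (!nzchar(path)) stop_key(sprintf("bundled view '%s' not found", name))
  read_view(path)
}

#' @rdname example_view
#' @export
example_views <- function() {
  stats::setNames(lapply(EXAMPLE_VIEW_NAMES, example_view), EXAMPLE_VIEW_NAMES)
}
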