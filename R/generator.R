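# Seeded synthetic FHIR corpus generator. Produces Patient and Encounter
# resources that are structurally realistic for the engine — repeating
# names, addresses and telecoms, encounters referencing generated patients —
# without claiming full FHIR R4 validity. The same seed and configuration
# always produce a byte-identical corpus.

GIVEN_NAMES <- c("Aisha", "Juan", "Wei", "Maria", "Liam", "Noor", "Kenji",
                 "Olga", "Sipho", "Elena", "Tariq", "Ingrid", "Ravi", "Ana")
FAMILY_NAMES <- c("Khan", "Rodriguez", "Zhang", "Okafor", "Muller", "Tanaka",
                  "Silva", "Novak", "Haddad", "Jensen", "Patel", "Costa")
STREETS <- c("Main St", "Second Ave", "Third St", "Oak Lane", "Maple Dr",
             "River Rd", "Hill Top", "Station Way")
CITIES <- list(
  list(city = "Springfield", state = "IL", zip = "62701"),
  list(city = "Chicago", state = "IL", zip = "60601"),
  list(city = "Peoria", state = "IL", zip = "61602"),
  list(city = "Madison", state = "WI", zip = "53703"),
  list(city = "Des Moines", state = "IA", zip = "50309"),
  list(city = "St Louis", state = "MO", zip = "63101")
)
TELECOM_USES <- c("home", "work", "mobile")

check_count_dist <- function(dist, what) {
  if (length(dist) == 0L || is.null(names(dist)) || any(!nzchar(names(dist)))) {
    stop_config(sprintf("%s must be a named probability vector", what))
  }
  counts <- suppressWarnings(as.integer(names(dist)))
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop_config(sprintf("%s has negative or non-integer counts", what))
  }
  if (any(dist < 0) || abs(sum(dist) - 1) > 1e-6) {
    stop_config(sprintf("%s probabilities must be non-negative and sum to 1", what))
  }
  invisible(counts)
}

#' Configuration for the synthetic corpus generator
#'
#' Count distributions are named numeric vectors: names are the counts,
#' values the probabilities (summing to 1). Defaults emulate a small
#' primary-care panel: most patients have one recorded name, up to two
#' addresses and telecoms, up to three encounters, and a fifth of the panel
#' is marked inactive.
#'
#' @param seed RNG seed; same seed and config give a byte-identical corpus.
#' @param n_patients Number of Patient resources.
#' @param address_counts,telecom_counts,name_counts Per-patient count
#'   distributions.
#' @param encounter_counts Encounters-per-patient distribution.
#' @param inactive_fraction Probability that a patient is `active = false`.
#' @return A list of class `fhir_corpus_config`.
#' @export
corpus_config <- function(seed = 1L,
                          n_patients = 100L,
                          address_counts = c("0" = 0.2, "1" = 0.5, "2" = 0.3),
                          telecom_counts = c("0" = 0.25, "1" = 0.5, "2" = 0.25),
                          name_counts = c("1" = 0.9, "2" = 0.1),
                          encounter_counts = c("0" = 0.3, "1" = 0.4,
                                               "2" = 0.2, "3" = 0.1),
                          inactive_fraction = 0.2) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0) {
    stop_config("n_patients must be a non-negative count")
  }
  check_count_dist(address_counts, "address_counts")
  check_count_dist(telecom_counts, "telecom_counts")
  check_count_dist(name_counts, "name_counts")
  check_count_dist(encounter_counts, "encounter_counts")
  if (inactive_fraction < 0 || inactive_fraction > 1) {
    stop_config("inactive_fraction must be a probability")
  }
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         address_counts = address_counts, telecom_counts = telecom_counts,
         name_counts = name_counts, encounter_counts = encounter_counts,
         inactive_fraction = inactive_fraction),
    class = "fhir_corpus_config"
  )
}

with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

draw_count <- function(dist) {
  counts <- as.integer(names(dist))
  if (length(counts) == 1L) return(counts)
  sample(counts, 1L, prob = dist)
}

random_date <- function(from, to) {
  format(as.Date(from) + sample.int(as.integer(as.Date(to) - as.Date(from)), 1L) - 1L,
         "%Y-%m-%d")
}

generate_address <- function() {
  place <- CITIES[[sample.int(length(CITIES), 1L)]]
  list(
    use = sample(c("home", "work", "temp"), 1L),
    line = list(paste(sample.int(999L, 1L), STREETS[[sample.int(length(STREETS), 1L)]])),
    city = place$city,
    state = place$state,
    postalCode = place$zip
  )
}

generate_patient <- function(i, config) {
  p <- list(resourceType = "Patient", id = paste0("patient-", i))
  p$active <- stats::runif(1L) >= config$inactive_fraction
  n_names <- draw_count(config$name_counts)
  if (n_names > 0L) {
    p$name <- lapply(seq_len(n_names), function(k) {
      list(
        use = if (k == 1L) "official" else "nickname",
        family = FAMILY_NAMES[[sample.int(length(FAMILY_NAMES), 1L)]],
        given = list(GIVEN_NAMES[[sample.int(length(GIVEN_NAMES), 1L)]])
      )
    })
  }
  p$birthDate <- random_date("1930-01-01", "2010-12-31")
  n_addr <- draw_count(config$address_counts)
  if (n_addr > 0L) {
    p$address <- lapply(seq_len(n_addr), function(k) generate_address())
  }
  n_tel <- draw_count(config$telecom_counts)
  if (n_tel > 0L) {
    p$telecom <- lapply(seq_len(n_tel), function(k) {
      list(
        system = "phone",
        value = paste0("555", sprintf("%06d", sample.int(999999L, 1L))),
        use = TELECOM_USES[[((k - 1L) %% length(TELECOM_USES)) + 1L]]
      )
    })
  }
  p
}

#' Generate a synthetic FHIR corpus
#'
#' Deterministically generates Patients followed by the Encounters that
#' reference them. Every Encounter's `subject` reference points at a
#' generated Patient, so the reference key of each encounter always matches
#' the resource key of some patient in the corpus (join closure).
#'
#' @param config A [corpus_config()].
#' @return A list of resources: all Patients first, then all Encounters.
#' @examples
#' corpus <- generate_corpus(corpus_config(seed = 42, n_patients = 5))
#' length(corpus)
#' @export
generate_corpus <- function(config = corpus_config()) {
  stopifnot(inherits(config, "fhir_corpus_config"))
  with_local_seed(config$seed, {
    patients <- lapply(seq_len(config$n_patients), generate_patient,
                       config = config)
    encounters <- list()
    eid <- 0L
    for (p in patients) {
      n_enc <- draw_count(config$encounter_counts)
      for (k in seq_len(n_enc)) {
        eid <- eid + 1L
        encounters[[eid]] <- list(
          resourceType = "Encounter",
          id = paste0("encounter-", eid),
          status = sample(c("finished", "in-progress", "cancelled"), 1L,
                          prob = c(0.8, 0.15, 0.05)),
          class = list(
            system = "http://terminology.hl7.org/CodeSystem/v3-ActCode",
            code = sample(c("AMB", "IMP", "EMER"), 1L, prob = c(0.7, 0.2, 0.1))
          ),
          subject = list(reference = paste0("Patient/", p$id)),
          period = list(start = random_date("2020-01-01", "2023-12-31"))
        )
      }
    }
    c(patients, encounters)
  })
}
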