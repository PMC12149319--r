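# Declarative test cases: a JSON document bundling resources, a view, and
# the expected rows, mirroring the practice of validating independent view
# runner implementations against a common machine-readable test suite.
#
# Case document fields:
#   title         short description
#   resources     inline array of resources, or
#   resourceFile  path to an NDJSON/JSON-array file (relative to the case file)
#   view          inline view definition, or
#   viewFile      path to a view JSON file (relative to the case file)
#   expect        array of row objects keyed by column name
#   ordered       compare row order (default true)
#   keyStrategy   "canonical" (default) or "display"

normalize_case <- function(doc, base_dir = ".") {
  if (!is_json_object(doc)) stop_view_parse("test case must be a JSON object", "/")
  resources <- doc[["resources"]]
  if (is.null(resources) && !is.null(doc[["resourceFile"]])) {
    path <- file.path(base_dir, view_scalar(doc[["resourceFile"]]))
    resources <- if (grepl("\\.ndjson$", path)) read_ndjson(path)
                 else read_resource_array(path)
  }
  if (is.null(resources)) stop_view_parse("test case has no resources", "/resources")
  view <- doc[["view"]]
  if (is.null(view) && !is.null(doc[["viewFile"]])) {
    view <- read_view(file.path(base_dir, view_scalar(doc[["viewFile"]])))
  }
  if (is.null(view)) stop_view_parse("test case has no view", "/view")
  if (!inherits(view, "fhir_view")) view <- parse_view(view)
  expect <- doc[["expect"]]
  if (is.null(expect) || !is_json_array(expect)) {
    stop_view_parse("test case requires an 'expect' array", "/expect")
  }
  ordered <- view_scalar(doc[["ordered"]])
  keys <- view_scalar(doc[["keyStrategy"]])
  list(
    title = view_scalar(doc[["title"]]),
    resources = resources,
    view = view,
    expect = expect,
    ordered = if (is.null(ordered)) TRUE else isTRUE(ordered),
    keys = key_strategy(if (is.null(keys)) "canonical" else keys)
  )
}

table_row_objects <- function(table) {
  nm <- table$schema$name
  lapply(table$rows, function(row) stats::setNames(row, nm))
}

cells_equal <- function(actual, expected) {
  if (is.null(actual) || is.null(expected)) return(is.null(actual) && is.null(expected))
  if (is.list(actual) || is.list(expected)) return(identical(actual, expected))
  if (is.numeric(actual) && is.numeric(expected)) return(isTRUE(actual == expected))
  identical(actual, expected)
}

row_diff <- function(actual, expected, schema_names, row_index) {
  for (col in schema_names) {
    if (!cells_equal(actual[[col]], expected[[col]])) {
      return(list(row = row_index, column = col,
                  expected = expected[[col]], actual = actual[[col]]))
    }
  }
  NULL
}

#' Run a declarative view test case
#'
#' Executes the case's view over its resources and compares the result with
#' the expected rows — ordered by default, as a multiset when the case sets
#' `ordered: false`. Failures are reported, not raised; the report names the
#' first differing row and column.
#'
#' @param case A case document: a JSON string, a decoded list, or a list
#'   produced by reading a case file.
#' @param base_dir Directory against which `resourceFile`/`viewFile`
#'   references are resolved.
#' @return A list with `pass` (logical), `title`, `message`, and `diff`
#'   (NULL, or the first mismatch as `list(row, column, expected, actual)`).
#' @export
run_case <- function(case, base_dir = ".") {
  if (is.character(case) && length(case) == 1L) {
    case <- jsonlite::fromJSON(case, simplifyVector = FALSE)
  }
  case <- normalize_case(case, base_dir)
  table <- tryCatch(
    execute_view(case$view, case$resources, keys = case$keys),
    error = function(e) e
  )
  if (inherits(table, "error")) {
    return(list(pass = FALSE, title = case$title,
                message = paste("execution failed:", conditionMessage(table)),
                diff = NULL))
  }
  actual <- table_row_objects(table)
  expected <- lapply(case$expect, function(row) row)
  nm <- table$schema$name
  for (row in expected) {
    bad <- setdiff(names(row), nm)
    if (length(bad) > 0L) {
      return(list(pass = FALSE, title = case$title,
                  message = sprintf("expected row uses unknown column(s): %s",
                                    paste(bad, collapse = ", ")),
                  diff = NULL))
    }
  }
  if (length(actual) != length(expected)) {
    return(list(pass = FALSE, title = case$title,
                message = sprintf("row count mismatch: expected %d, got %d",
                                  length(expected), length(actual)),
                diff = NULL))
  }
  if (case$ordered) {
    for (i in seq_along(expected)) {
      d <- row_diff(actual[[i]], expected[[i]], nm, i)
      if (!is.null(d)) {
        return(list(pass = FALSE, title = case$title,
                    message = sprintf("row %d differs in column '%s'",
                                      d$row, d$column),
                    diff = d))
      }
    }
  } else {
    used <- rep(FALSE, length(actual))
    for (i in seq_along(expected)) {
      found <- FALSE
      for (j in seq_along(actual)) {
        if (used[[j]]) next
        if (is.null(row_diff(actual[[j]], expected[[i]], nm, i))) {
          used[[j]] <- TRUE
          found <- TRUE
          break
        }
      }
      if (!found) {
        return(list(pass = FALSE, title = case$title,
                    message = sprintf("expected row %d has no match", i),
                    diff = list(row = i, column = NA_character_,
                                expected = expected[[i]], actual = NULL)))
      }
    }
  }
  list(pass = TRUE, title = case$title, message = "ok", diff = NULL)
}

#' @rdname run_case
#' @param path Path to a case JSON file (one case object, or an array of
#'   cases).
#' @export
run_case_file <- function(path) {
  doc <- jsonlite::fromJSON(
    paste0(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
    simplifyVector = FALSE
  )
  base_dir <- dirname(path)
  cases <- if (is_json_object(doc)) list(doc) else doc
  lapply(cases, run_case, base_dir = base_dir)
}

#' Run every test case in a directory
#'
#' @param dir Directory holding `*.json` case files.
#' @return A data frame with one row per case: `file`, `title`, `pass`,
#'   `message`.
#' @export
run_case_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  rows <- list()
  for (f in files) {
    reports <- run_case_file(f)
    for (rep in reports) {
      rows[[length(rows) + 1L]] <- data.frame(
        file = basename(f),
        title = if (is.null(rep$title)) NA_character_ else rep$title,
        pass = rep$pass,
        message = rep$message,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    data.frame(file = character(0), title = character(0),
               pass = logical(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
}
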