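# Parsing, serialization and validation of view definitions.
#
# A view definition is a JSON document describing one tabular projection of
# one FHIR resource type. The dialect understood here uses the fields
# `name`, `resource`, `select[]` (with `column[]`, `forEach`, `forEachOrNull`,
# `unionAll[]`, nested `select[]`), `where[]` (with `path`), `fhirVersion`,
# `version`, `url`, and `meta.profile[]`.

VIEW_KNOWN_FIELDS <- c(
  "resourceType", "name", "resource", "select", "where", "fhirVersion",
  "version", "url", "meta", "status", "description", "title"
)

SHAREABLE_PROFILE_SUFFIX <- "ShareableViewDefinition"
TABULAR_PROFILE_SUFFIX <- "TabularViewDefinition"

# FHIR R4 primitive types admissible for the tabular profile.
FHIR_PRIMITIVE_TYPES <- c(
  "boolean", "integer", "decimal", "string", "date", "dateTime", "time",
  "code", "id", "uri", "url", "canonical", "oid", "uuid", "positiveInt",
  "unsignedInt", "instant", "base64Binary", "markdown"
)

view_scalar <- function(x) {
  if (is.list(x) && length(x) == 1L && is.null(names(x))) x <- x[[1L]]
  x
}

parse_column <- function(col, ptr) {
  if (!is_json_object(col)) stop_view_parse("column must be an object", ptr)
  name <- view_scalar(col[["name"]])
  path <- view_scalar(col[["path"]])
  if (!is.character(name) || length(name) != 1L) {
    stop_view_parse("column requires a string 'name'", paste0(ptr, "/name"))
  }
  if (!is.character(path) || length(path) != 1L) {
    stop_view_parse("column requires a string 'path'", paste0(ptr, "/path"))
  }
  collection <- col[["collection"]]
  if (is.null(collection)) {
    collection <- FALSE
  } else {
    collection <- view_scalar(collection)
    if (!is.logical(collection) || length(collection) != 1L || is.na(collection)) {
      stop_view_parse("'collection' must be a boolean", paste0(ptr, "/collection"))
    }
  }
  list(
    name = name,
    path = path,
    collection = collection,
    type = view_scalar(col[["type"]]),
    tags = col[["tag"]]
  )
}

parse_select <- function(sel, ptr) {
  if (!is_json_object(sel)) stop_view_parse("select must be an object", ptr)
  cols <- sel[["column"]]
  columns <- if (is.null(cols)) list() else {
    if (!is_json_array(cols)) stop_view_parse("'column' must be an array", paste0(ptr, "/column"))
    lapply(seq_along(cols), function(i) {
      parse_column(cols[[i]], paste0(ptr, "/column/", i - 1L))
    })
  }
  for_each <- view_scalar(sel[["forEach"]])
  for_each_or_null <- view_scalar(sel[["forEachOrNull"]])
  if (!is.null(for_each) && (!is.character(for_each) || length(for_each) != 1L)) {
    stop_view_parse("'forEach' must be a string expression", paste0(ptr, "/forEach"))
  }
  if (!is.null(for_each_or_null) &&
      (!is.character(for_each_or_null) || length(for_each_or_null) != 1L)) {
    stop_view_parse("'forEachOrNull' must be a string expression", paste0(ptr, "/forEachOrNull"))
  }
  nested <- sel[["select"]]
  nested_selects <- if (is.null(nested)) list() else {
    if (!is_json_array(nested)) stop_view_parse("'select' must be an array", paste0(ptr, "/select"))
    lapply(seq_along(nested), function(i) {
      parse_select(nested[[i]], paste0(ptr, "/select/", i - 1L))
    })
  }
  ua <- sel[["unionAll"]]
  union_all <- if (is.null(ua)) list() else {
    if (!is_json_array(ua)) stop_view_parse("'unionAll' must be an array", paste0(ptr, "/unionAll"))
    lapply(seq_along(ua), function(i) {
      parse_select(ua[[i]], paste0(ptr, "/unionAll/", i - 1L))
    })
  }
  list(
    columns = columns,
    for_each = for_each,
    for_each_or_null = for_each_or_null,
    nested = nested_selects,
    union_all = union_all
  )
}

#' Parse a view definition document
#'
#' Maps a view definition JSON document onto the internal representation,
#' applying defaults (`collection = FALSE`). Structural faults — a missing
#' `resource`, an empty or absent `select`, a non-boolean `collection` —
#' raise a parse error whose message carries a JSON-pointer-like location.
#' Unknown top-level fields are preserved but ignored, with a warning.
#'
#' @param document JSON text, or an already-decoded nested list.
#' @return An object of class `fhir_view`.
#' @seealso [read_view()], [validate_view()], [execute_view()]
#' @export
parse_view <- function(document) {
  doc <- if (is.character(document)) {
    jsonlite::fromJSON(paste0(document, collapse = "\n"), simplifyVector = FALSE)
  } else {
    document
  }
  if (!is_json_object(doc)) stop_view_parse("view document must be a JSON object", "/")
  unknown <- setdiff(names(doc), VIEW_KNOWN_FIELDS)
  if (length(unknown) > 0L) {
    warning(sprintf("ignoring unknown view field(s): %s",
                    paste(unknown, collapse = ", ")),
            call. = FALSE)
  }
  resource <- view_scalar(doc[["resource"]])
  if (!is.character(resource) || length(resource) != 1L || !nzchar(resource)) {
    stop_view_parse("view requires a single 'resource' type", "/resource")
  }
  sels <- doc[["select"]]
  if (is.null(sels) || !is_json_array(sels) || length(sels) == 0L) {
    stop_view_parse("view requires at least one 'select'", "/select")
  }
  selects <- lapply(seq_along(sels), function(i) {
    parse_select(sels[[i]], paste0("/select/", i - 1L))
  })
  whs <- doc[["where"]]
  wheres <- if (is.null(whs)) list() else {
    if (!is_json_array(whs)) stop_view_parse("'where' must be an array", "/where")
    lapply(seq_along(whs), function(i) {
      w <- whs[[i]]
      path <- view_scalar(w[["path"]])
      if (!is.character(path) || length(path) != 1L) {
        stop_view_parse("where clause requires a string 'path'",
                        paste0("/where/", i - 1L, "/path"))
      }
      list(path = path, description = view_scalar(w[["description"]]))
    })
  }
  meta <- doc[["meta"]]
  profile_urls <- if (is_json_object(meta) && !is.null(meta[["profile"]])) {
    vapply(meta[["profile"]], function(x) as.character(view_scalar(x)), "")
  } else {
    character(0)
  }
  profiles <- "base"
  if (any(endsWith(profile_urls, SHAREABLE_PROFILE_SUFFIX))) {
    profiles <- c(profiles, "shareable")
  }
  if (any(endsWith(profile_urls, TABULAR_PROFILE_SUFFIX))) {
    profiles <- c(profiles, "tabular")
  }
  structure(
    list(
      name = view_scalar(doc[["name"]]),
      resource = resource,
      selects = selects,
      wheres = wheres,
      fhir_version = view_scalar(doc[["fhirVersion"]]),
      version = view_scalar(doc[["version"]]),
      url = view_scalar(doc[["url"]]),
      profiles = profiles,
      profile_urls = profile_urls,
      extra_fields = unknown
    ),
    class = "fhir_view"
  )
}

#' Read a view definition from a JSON file
#'
#' @param path Path to a view definition JSON document.
#' @return An object of class `fhir_view`.
#' @export
read_view <- function(path) {
  parse_view(paste0(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n"))
}

serialize_select <- function(sel) {
  out <- list()
  if (length(sel$columns) > 0L) {
    out$column <- lapply(sel$columns, function(col) {
      c <- list(name = col$name, path = col$path)
      if (isTRUE(col$collection)) c$collection <- TRUE
      if (!is.null(col$type)) c$type <- col$type
      if (!is.null(col$tags)) c$tag <- col$tags
      c
    })
  }
  if (!is.null(sel$for_each)) out$forEach <- sel$for_each
  if (!is.null(sel$for_each_or_null)) out$forEachOrNull <- sel$for_each_or_null
  if (length(sel$union_all) > 0L) out$unionAll <- lapply(sel$union_all, serialize_select)
  if (length(sel$nested) > 0L) out$select <- lapply(sel$nested, serialize_select)
  out
}

#' Serialize a view definition back to JSON text
#'
#' Inverse of [parse_view()] on the structural core: re-parsing the output
#' yields a structurally identical view.
#'
#' @param view A `fhir_view`.
#' @param pretty Pretty-print the JSON.
#' @return JSON text (a single string).
#' @export
serialize_view <- function(view, pretty = TRUE) {
  stopifnot(inherits(view, "fhir_view"))
  doc <- list()
  if (!is.null(view$name)) doc$name <- view$name
  if (!is.null(view$version)) doc$version <- view$version
  if (!is.null(view$url)) doc$url <- view$url
  if (length(view$profile_urls) > 0L) doc$meta <- list(profile = as.list(view$profile_urls))
  if (!is.null(view$fhir_version)) doc$fhirVersion <- view$fhir_version
  doc$resource <- view$resource
  doc$select <- lapply(view$selects, serialize_select)
  if (length(view$wheres) > 0L) {
    doc$where <- lapply(view$wheres, function(w) {
      out <- list(path = w$path)
      if (!is.null(w$description)) out$description <- w$description
      out
    })
  }
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty, null = "null"))
}

#' @export
print.fhir_view <- function(x, ...) {
  schema <- tryCatch(flattened_schema(x), error = function(e) NULL)
  cat(sprintf("<fhir_view> %s on %s\n",
              if (is.null(x$name)) "(unnamed)" else x$name, x$resource))
  cat(sprintf("  profiles: %s\n", paste(x$profiles, collapse = ", ")))
  if (!is.null(schema)) {
    cat(sprintf("  columns:  %s\n", paste(schema$name, collapse = ", ")))
  }
  if (length(x$wheres) > 0L) {
    cat(sprintf("  where:    %s\n",
                paste(vapply(x$wheres, `[[`, "", "path"), collapse = " AND ")))
  }
  invisible(x)
}

# Schema of one select subtree, in output order: local columns, then nested
# selects, then the unionAll block (whose branches share one schema).
select_schema <- function(sel) {
  out <- list()
  for (col in sel$columns) {
    out[[length(out) + 1L]] <- data.frame(
      name = col$name,
      type = if (is.null(col$type)) NA_character_ else col$type,
      collection = col$collection,
      stringsAsFactors = FALSE
    )
  }
  for (nested in sel$nested) out[[length(out) + 1L]] <- select_schema(nested)
  if (length(sel$union_all) > 0L) out[[length(out) + 1L]] <- select_schema(sel$union_all[[1L]])
  if (length(out) == 0L) {
    data.frame(name = character(0), type = character(0),
               collection = logical(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Flattened output schema of a view
#'
#' Depth-first, document-order traversal of the view's selects, yielding the
#' ordered column list of the output table. The schema is a pure function of
#' the view document; it never depends on the data the view is executed over.
#'
#' @param view A `fhir_view`.
#' @return A data frame with columns `name`, `type`, `collection`.
#' @export
flattened_schema <- function(view) {
  stopifnot(inherits(view, "fhir_view"))
  schemas <- lapply(view$selects, select_schema)
  out <- do.call(rbind, schemas)
  rownames(out) <- NULL
  out
}

issue <- function(severity, code, location, message) {
  data.frame(severity = severity, code = code, location = location,
             message = message, stringsAsFactors = FALSE)
}

validate_exprs <- function(sel, ptr, add) {
  for (i in seq_along(sel$columns)) {
    col <- sel$columns[[i]]
    loc <- paste0(ptr, "/column/", i - 1L, "/path")
    tryCatch(fp_parse(col$path), error = function(e) {
      add(issue("error", "INVALID_EXPRESSION", loc, conditionMessage(e)))
    })
    if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", col$name)) {
      add(issue("error", "BAD_COLUMN_NAME", paste0(ptr, "/column/", i - 1L, "/name"),
                sprintf("column name '%s' is not a valid identifier", col$name)))
    }
  }
  if (!is.null(sel$for_each) && !is.null(sel$for_each_or_null)) {
    add(issue("error", "FOREACH_CONFLICT", ptr,
              "'forEach' and 'forEachOrNull' are mutually exclusive"))
  }
  for (f in c(sel$for_each, sel$for_each_or_null)) {
    tryCatch(fp_parse(f), error = function(e) {
      add(issue("error", "INVALID_EXPRESSION", ptr, conditionMessage(e)))
    })
  }
  if (nrow(select_schema(sel)) == 0L) {
    add(issue("error", "NO_COLUMNS", ptr, "select contributes no column"))
  }
  if (length(sel$union_all) > 0L) {
    ref <- select_schema(sel$union_all[[1L]])$name
    for (i in seq_along(sel$union_all)) {
      branch <- select_schema(sel$union_all[[i]])$name
      if (!identical(branch, ref)) {
        add(issue("error", "UNION_COLUMN_MISMATCH", paste0(ptr, "/unionAll/", i - 1L),
                  sprintf("unionAll branch columns (%s) differ from first branch (%s)",
                          paste(branch, collapse = ", "), paste(ref, collapse = ", "))))
      }
    }
    for (i in seq_along(sel$union_all)) {
      validate_exprs(sel$union_all[[i]], paste0(ptr, "/unionAll/", i - 1L), add)
    }
  }
  for (i in seq_along(sel$nested)) {
    validate_exprs(sel$nested[[i]], paste0(ptr, "/select/", i - 1L), add)
  }
}

validate_shareable_types <- function(sel, ptr, add) {
  for (i in seq_along(sel$columns)) {
    if (is.null(sel$columns[[i]]$type)) {
      add(issue("error", "MISSING_COLUMN_TYPE", paste0(ptr, "/column/", i - 1L),
                sprintf("column '%s' declares no FHIR type", sel$columns[[i]]$name)))
    }
  }
  for (i in seq_along(sel$union_all)) {
    validate_shareable_types(sel$union_all[[i]], paste0(ptr, "/unionAll/", i - 1L), add)
  }
  for (i in seq_along(sel$nested)) {
    validate_shareable_types(sel$nested[[i]], paste0(ptr, "/select/", i - 1L), add)
  }
}

validate_tabular <- function(sel, ptr, add) {
  for (i in seq_along(sel$columns)) {
    col <- sel$columns[[i]]
    loc <- paste0(ptr, "/column/", i - 1L)
    if (isTRUE(col$collection)) {
      add(issue("error", "TABULAR_COLLECTION", loc,
                sprintf("column '%s' is a collection; tabular columns must be scalar",
                        col$name)))
    }
    if (is.null(col$type) || !(col$type %in% FHIR_PRIMITIVE_TYPES)) {
      add(issue("error", "TABULAR_NONPRIMITIVE", loc,
                sprintf("column '%s' must declare a primitive FHIR type", col$name)))
    }
  }
  for (i in seq_along(sel$union_all)) {
    validate_tabular(sel$union_all[[i]], paste0(ptr, "/unionAll/", i - 1L), add)
  }
  for (i in seq_along(sel$nested)) {
    validate_tabular(sel$nested[[i]], paste0(ptr, "/select/", i - 1L), add)
  }
}

#' Validate a view definition against conformance profiles
#'
#' Runs the progressively stricter profile checks. The base profile always
#' runs: column-name syntax and uniqueness, unionAll column parity, mutual
#' exclusion of `forEach`/`forEachOrNull`, and parseability of every
#' expression. The shareable profile additionally requires identification
#' metadata (`name`, `version`), a declared `fhirVersion`, and a FHIR type on
#' every column. The tabular profile further restricts columns to scalar
#' primitive types. Issue sets are monotone in the requested profile set.
#'
#' @param view A `fhir_view`.
#' @param profiles Character vector of profiles to enforce; defaults to the
#'   profiles the view itself claims via `meta.profile` (plus `base`).
#' @return A data frame of issues (`severity`, `code`, `location`,
#'   `message`); zero rows means the view is valid. Any `error` row makes
#'   [execute_view()] refuse to run.
#' @examples
#' v <- parse_view('{"resource": "Patient",
#'   "select": [{"column": [{"name": "id", "path": "id"}]}]}')
#' validate_view(v)  # no issues
#' @export
validate_view <- function(view, profiles = NULL) {
  stopifnot(inherits(view, "fhir_view"))
  if (is.null(profiles)) profiles <- view$profiles
  profiles <- union("base", profiles)
  issues <- list()
  add <- function(x) issues[[length(issues) + 1L]] <<- x

  for (f in view$extra_fields) {
    add(issue("warning", "UNKNOWN_FIELD", paste0("/", f),
              sprintf("unknown field '%s' is ignored", f)))
  }
  for (i in seq_along(view$selects)) {
    validate_exprs(view$selects[[i]], paste0("/select/", i - 1L), add)
  }
  for (i in seq_along(view$wheres)) {
    tryCatch(fp_parse(view$wheres[[i]]$path), error = function(e) {
      add(issue("error", "INVALID_EXPRESSION", paste0("/where/", i - 1L, "/path"),
                conditionMessage(e)))
    })
  }
  all_names <- tryCatch(flattened_schema(view)$name, error = function(e) character(0))
  dup <- unique(all_names[duplicated(all_names)])
  for (d in dup) {
    add(issue("error", "DUPLICATE_COLUMN", "/select",
              sprintf("column name '%s' appears more than once", d)))
  }

  if ("shareable" %in% profiles || "tabular" %in% profiles) {
    if (is.null(view$name)) {
      add(issue("error", "MISSING_NAME", "/name",
                "shareable views must declare a name"))
    }
    if (is.null(view$version)) {
      add(issue("error", "MISSING_VERSION", "/version",
                "shareable views must declare a version"))
    }
    if (is.null(view$fhir_version)) {
      add(issue("error", "MISSING_FHIR_VERSION", "/fhirVersion",
                "shareable views must declare the FHIR version they target"))
    }
    for (i in seq_along(view$selects)) {
      validate_shareable_types(view$selects[[i]], paste0("/select/", i - 1L), add)
    }
  }
  if ("tabular" %in% profiles) {
    for (i in seq_along(view$selects)) {
      validate_tabular(view$selects[[i]], paste0("/select/", i - 1L), add)
    }
  }
  if (length(issues) == 0L) {
    data.frame(severity = character(0), code = character(0),
               location = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, issues)
    rownames(out) <- NULL
    out
  }
}
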