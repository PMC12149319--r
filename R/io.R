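# Reading FHIR resources from NDJSON / JSON-array files and writing tables
# as RFC 4180 CSV or row-stream NDJSON. Encoding is UTF-8 without BOM
# throughout; the CSV line ending defaults to LF.

parse_resource_line <- function(line, lineno) {
  resource <- tryCatch(
    jsonlite::fromJSON(line, simplifyVector = FALSE),
    error = function(e) stop_read(sprintf("malformed JSON (%s)", conditionMessage(e)), lineno)
  )
  if (!is_json_object(resource)) {
    stop_read("line is not a JSON object", lineno)
  }
  resource
}

#' Read FHIR resources from an NDJSON file
#'
#' One resource per non-blank line, in file order; blank lines are skipped.
#' Each returned resource carries its 1-based source line number in the
#' attribute `"line"`.
#'
#' @param path File path or connection holding UTF-8 NDJSON text.
#' @return A list of resources (nested lists).
#' @export
read_ndjson <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    resource <- parse_resource_line(lines[[i]], i)
    attr(resource, "line") <- i
    out[[length(out) + 1L]] <- resource
  }
  out
}

#' Read FHIR resources from a JSON array file
#'
#' Accepts a file whose top level is a JSON array of resources (the layout
#' used for the bundled example resources), or a single resource object.
#'
#' @param path File path to a UTF-8 JSON document.
#' @return A list of resources (nested lists).
#' @export
read_resource_array <- function(path) {
  doc <- jsonlite::fromJSON(
    paste0(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n"),
    simplifyVector = FALSE
  )
  if (is_json_object(doc)) return(list(doc))
  if (!is.list(doc)) stop_read("file is neither a JSON array nor an object", 1L)
  for (i in seq_along(doc)) {
    if (!is_json_object(doc[[i]])) {
      stop_read(sprintf("array element %d is not a JSON object", i), 1L)
    }
  }
  doc
}

#' Read FHIR resources in either supported format
#'
#' @param path File path.
#' @param format `"ndjson"` (one resource per line) or `"array"` (a JSON
#'   array of resources).
#' @return A list of resources.
#' @export
read_resources <- function(path, format = c("ndjson", "array")) {
  format <- match.arg(format)
  if (format == "ndjson") read_ndjson(path) else read_resource_array(path)
}

#' Write one or more resources as NDJSON
#'
#' @param resources A list of resources.
#' @param path File path or connection.
#' @return The number of resources written, invisibly.
#' @export
write_ndjson <- function(resources, path) {
  lines <- vapply(resources, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", digits = NA))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(length(lines))
}

csv_field <- function(cell) {
  txt <- cell_text(cell)
  if (is.na(txt)) return("")
  if (grepl('[",\r\n]', txt)) {
    txt <- paste0('"', gsub('"', '""', txt), '"')
  }
  txt
}

csv_row <- function(cells, delim) {
  paste(vapply(cells, csv_field, ""), collapse = delim)
}

#' Write a view result as RFC 4180 CSV
#'
#' Writes a header row of column names followed by one line per row. Null
#' cells become empty fields; booleans print as `true`/`false`; dates stay
#' ISO-8601 text; fields are quoted only when they contain the delimiter, a
#' quote, or a line break. Array cells (collection columns) and complex
#' cells are serialized as compact JSON text.
#'
#' @param table A `fhir_table`.
#' @param path File path or writable connection.
#' @param delim Field delimiter (default `,`).
#' @param eol Line ending, `"\n"` (default) or `"\r\n"`.
#' @return The number of data rows written, invisibly.
#' @export
write_table_csv <- function(table, path, delim = ",", eol = "\n") {
  stopifnot(inherits(table, "fhir_table"))
  con <- if (inherits(path, "connection")) path else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    con
  }
  header <- csv_row(as.list(table$schema$name), delim)
  writeLines(header, con, sep = eol, useBytes = TRUE)
  for (row in table$rows) {
    writeLines(csv_row(row, delim), con, sep = eol, useBytes = TRUE)
  }
  invisible(length(table$rows))
}

row_to_json <- function(row, names) {
  obj <- stats::setNames(row, names)
  # jsonlite drops NULL object members; substitute an explicit JSON null.
  txt <- vapply(seq_along(obj), function(j) {
    v <- obj[[j]]
    if (is.null(v)) "null"
    else as.character(jsonlite::toJSON(v, auto_unbox = TRUE, null = "null", digits = NA))
  }, "")
  paste0("{", paste0('"', names, '":', txt, collapse = ","), "}")
}

#' Write a view result as row-stream NDJSON
#'
#' One JSON object per row, keyed by column name; null cells serialize as
#' JSON `null`, collection cells as JSON arrays.
#'
#' @inheritParams write_table_csv
#' @return The number of rows written, invisibly.
#' @export
write_table_ndjson <- function(table, path) {
  stopifnot(inherits(table, "fhir_table"))
  con <- if (inherits(path, "connection")) path else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    con
  }
  nm <- table$schema$name
  for (row in table$rows) {
    writeLines(row_to_json(row, nm), con, sep = "\n", useBytes = TRUE)
  }
  invisible(length(table$rows))
}

#' Stream a view over NDJSON files into a tabular output file
#'
#' Reads resources in fixed-size chunks, executes the view chunk by chunk,
#' and appends rows to the output as they are produced, so memory use stays
#' bounded by the chunk size rather than the file size. Output is identical
#' to materializing the whole file with [execute_view()] and writing it in
#' one go. Multiple data files are processed in argument order.
#'
#' @param view A `fhir_view`.
#' @param data_paths Character vector of input file paths.
#' @param output Output file path or writable connection.
#' @param input_format `"ndjson"` or `"array"` (array files are read whole).
#' @param output_format `"csv"` or `"ndjson"`.
#' @param keys A [key_strategy()].
#' @param profiles Profiles to enforce at validation.
#' @param chunk_size Resources evaluated per chunk for NDJSON input.
#' @param strict If `TRUE` (default) abort on the first execution error; if
#'   `FALSE`, skip offending resources and report them via `on_skip`.
#' @param on_skip Callback `function(message)` invoked for each resource
#'   skipped in lenient mode.
#' @return Invisibly, a list with `resources` read (of the view's type or
#'   not) and `rows` written.
#' @export
run_view_file <- function(view, data_paths, output,
                          input_format = c("ndjson", "array"),
                          output_format = c("csv", "ndjson"),
                          keys = key_strategy(), profiles = NULL,
                          chunk_size = 1000L, strict = TRUE,
                          on_skip = function(message) {}) {
  input_format <- match.arg(input_format)
  output_format <- match.arg(output_format)
  issues <- validate_view(view, profiles)
  errors <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errors) > 0L) {
    stop_validation(
      sprintf("view has %d validation error(s); first: [%s] %s",
              nrow(errors), errors$code[[1L]], errors$message[[1L]]),
      issues = issues
    )
  }
  view <- compile_view(view)

  con_out <- if (inherits(output, "connection")) output else {
    con_out <- file(output, open = "wb")
    on.exit(close(con_out), add = TRUE)
    con_out
  }
  if (output_format == "csv") {
    writeLines(csv_row(as.list(view$schema$name), ","), con_out, sep = "\n",
               useBytes = TRUE)
  }
  n_res <- 0L
  n_rows <- 0L
  emit_chunk <- function(resources) {
    n_res <<- n_res + length(resources)
    tbl <- if (strict) {
      execute_view(view, resources, keys = keys, validate = FALSE)
    } else {
      rows <- list()
      for (r in resources) {
        t1 <- tryCatch(
          execute_view(view, list(r), keys = keys, validate = FALSE),
          fhirtable_error = function(e) {
            on_skip(conditionMessage(e))
            NULL
          }
        )
        if (!is.null(t1)) rows <- c(rows, t1$rows)
      }
      fhir_table(view$schema, rows)
    }
    if (output_format == "csv") {
      for (row in tbl$rows) {
        writeLines(csv_row(row, ","), con_out, sep = "\n", useBytes = TRUE)
      }
    } else {
      nm <- view$schema$name
      for (row in tbl$rows) {
        writeLines(row_to_json(row, nm), con_out, sep = "\n", useBytes = TRUE)
      }
    }
    n_rows <<- n_rows + length(tbl$rows)
  }

  for (path in data_paths) {
    if (input_format == "array") {
      emit_chunk(read_resource_array(path))
      next
    }
    con_in <- file(path, open = "r", encoding = "UTF-8")
    tryCatch({
      lineno <- 0L
      repeat {
        lines <- readLines(con_in, n = chunk_size, warn = FALSE)
        if (length(lines) == 0L) break
        resources <- list()
        for (line in lines) {
          lineno <- lineno + 1L
          if (!nzchar(trimws(line))) next
          resources[[length(resources) + 1L]] <- parse_resource_line(line, lineno)
        }
        emit_chunk(resources)
      }
    }, finally = close(con_in))
  }
  invisible(list(resources = n_res, rows = n_rows))
}
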