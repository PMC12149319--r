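# The tabular result container. A fhir_table holds an ordered schema
# (name, type, collection) and a list of rows; each row is a list of cells
# aligned to the schema. A cell is NULL (missing), a scalar, a named list
# (complex element, base profile only), or — for collection columns — always
# a list of values, possibly empty.

fhir_table <- function(schema, rows) {
  structure(list(schema = schema, rows = rows), class = "fhir_table")
}

#' @export
dim.fhir_table <- function(x) c(length(x$rows), nrow(x$schema))

#' @export
print.fhir_table <- function(x, n = 10L, ...) {
  cat(sprintf("<fhir_table> %d row(s), %d column(s)\n",
              length(x$rows), nrow(x$schema)))
  df <- as.data.frame(x)
  print(utils::head(df, n))
  if (nrow(df) > n) cat(sprintf("# ... %d more row(s)\n", nrow(df) - n))
  invisible(x)
}

# Scalar cell to display text (shared by CSV output and the data.frame
# conversion): booleans print as true/false, numbers without scientific
# notation, arrays and complex cells as compact JSON.
cell_text <- function(cell) {
  if (is.null(cell)) return(NA_character_)
  if (is.list(cell)) {
    return(as.character(jsonlite::toJSON(cell, auto_unbox = TRUE, null = "null",
                                         digits = NA)))
  }
  if (is.logical(cell)) return(if (cell) "true" else "false")
  if (is.numeric(cell)) return(format(cell, scientific = FALSE, trim = TRUE, digits = 15))
  as.character(cell)
}

#' Convert a view result to a data frame
#'
#' Scalar columns become atomic vectors (`NA` for null cells); collection
#' columns and columns holding complex elements become list-columns.
#'
#' @param x A `fhir_table`.
#' @param row.names,optional,... Passed over for S3 compatibility; unused.
#' @return A `data.frame` with one column per view column.
#' @export
as.data.frame.fhir_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  schema <- x$schema
  n <- length(x$rows)
  cols <- vector("list", nrow(schema))
  names(cols) <- schema$name
  for (j in seq_len(nrow(schema))) {
    cells <- lapply(x$rows, `[[`, j)
    complex <- any(vapply(cells, is.list, TRUE))
    logical_col <- any(vapply(cells, is.logical, TRUE))
    numeric_col <- any(vapply(cells, is.numeric, TRUE))
    character_col <- any(vapply(cells, is.character, TRUE))
    mixed <- sum(logical_col, numeric_col, character_col) > 1L
    if (schema$collection[[j]] || complex || mixed) {
      cols[[j]] <- I(cells)
    } else {
      cols[[j]] <- vapply(cells, function(cell) {
        if (is.null(cell)) {
          if (logical_col) NA else if (numeric_col) NA_real_ else NA_character_
        } else {
          cell
        }
      }, if (logical_col) logical(1) else if (numeric_col) numeric(1) else character(1))
    }
  }
  out <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  if (n == 0L) out <- out[0L, , drop = FALSE]
  names(out) <- schema$name
  out
}

#' Inner equijoin of two view results
#'
#' Joins two tables on scalar key columns, the way two views over
#' referencing resource types are combined on `getResourceKey()` /
#' `getReferenceKey()` columns. Column order is the left table's columns
#' followed by the right table's columns minus the (redundant) right key;
#' row order is left-major: for each left row in order, every matching right
#' row in order.
#'
#' @param left,right `fhir_table` objects.
#' @param left_key,right_key Key column names.
#' @return A `fhir_table`.
#' @examples
#' pv <- execute_view(example_view("patient_join"),
#'                    example_resources("Patient"), key_strategy("display"))
#' ev <- execute_view(example_view("encounter_join"),
#'                    example_resources("Encounter"), key_strategy("display"))
#' as.data.frame(table_equijoin(pv, ev, "patient_id", "patient_id"))
#' @export
table_equijoin <- function(left, right, left_key, right_key = left_key) {
  stopifnot(inherits(left, "fhir_table"), inherits(right, "fhir_table"))
  li <- match(left_key, left$schema$name)
  ri <- match(right_key, right$schema$name)
  if (is.na(li)) stop_key(sprintf("left table has no column '%s'", left_key))
  if (is.na(ri)) stop_key(sprintf("right table has no column '%s'", right_key))
  keep_right <- setdiff(seq_len(nrow(right$schema)), ri)
  schema <- rbind(left$schema, right$schema[keep_right, , drop = FALSE])
  rownames(schema) <- NULL
  rows <- list()
  for (lr in left$rows) {
    lk <- lr[[li]]
    if (is.null(lk) || is.list(lk)) next
    for (rr in right$rows) {
      rk <- rr[[ri]]
      if (is.null(rk) || is.list(rk)) next
      if (isTRUE(lk == rk)) {
        rows[[length(rows) + 1L]] <- c(lr, rr[keep_right])
      }
    }
  }
  fhir_table(schema, rows)
}
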