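# Execution of validated view definitions over resources.
#
# Row semantics: for each resource passing every where clause, each top-level
# select produces a row-set, and the resource's rows are the Cartesian
# product (cross-join) of those row-sets, in select order. Within a select,
# the iteration axis (none / forEach / forEachOrNull) determines the items;
# for each item the row-set is the cross-join of the local column fragment,
# each nested select's recursive row-set, and the unionAll block's
# concatenated row-set. forEachOrNull emits exactly one all-null fragment —
# spanning every column of its subtree — when the iterated collection is
# empty. Row order is deterministic: input resource order, then traversal
# order within a resource.

compile_select <- function(sel) {
  sel$ccolumns <- lapply(sel$columns, function(col) {
    col$cpath <- fp_parse(col$path)
    col
  })
  iter <- NULL
  kind <- "none"
  if (!is.null(sel$for_each)) {
    iter <- fp_parse(sel$for_each)
    kind <- "forEach"
  } else if (!is.null(sel$for_each_or_null)) {
    iter <- fp_parse(sel$for_each_or_null)
    kind <- "forEachOrNull"
  }
  sel$citer <- iter
  sel$iter_kind <- kind
  sel$cnested <- lapply(sel$nested, compile_select)
  sel$cunion <- lapply(sel$union_all, compile_select)
  sel$schema <- select_schema(sel)
  sel$width <- nrow(sel$schema)
  sel
}

compile_view <- function(view) {
  view$cselects <- lapply(view$selects, compile_select)
  view$cwheres <- lapply(view$wheres, function(w) fp_parse(w$path))
  view$schema <- flattened_schema(view)
  view$compiled <- TRUE
  view
}

# Cross-join of row-sets, left-major: the leftmost set varies slowest.
# An empty set annihilates the product (zero rows).
cross_join_sets <- function(sets) {
  acc <- list(list())
  for (s in sets) {
    n <- length(s)
    if (n == 0L) return(list())
    out <- vector("list", length(acc) * n)
    k <- 0L
    for (a in acc) {
      for (b in s) {
        k <- k + 1L
        out[[k]] <- c(a, b)
      }
    }
    acc <- out
  }
  acc
}

null_fragment <- function(sel) {
  row <- vector("list", sel$width)
  coll <- sel$schema$collection
  for (i in seq_len(sel$width)) {
    if (isTRUE(coll[[i]])) row[i] <- list(list())
  }
  list(row)
}

column_fragment <- function(sel, item, ctx) {
  ncol <- length(sel$ccolumns)
  row <- vector("list", ncol)
  inner <- ctx
  inner$focus <- list(item)
  for (i in seq_len(ncol)) {
    col <- sel$ccolumns[[i]]
    items <- fp_eval(col$cpath$root, inner)
    if (isTRUE(col$collection)) {
      row[i] <- list(lapply(items, `[[`, "val"))
    } else if (length(items) == 1L) {
      row[i] <- list(items[[1L]]$val)
    } else if (length(items) > 1L) {
      stop_cardinality(sprintf(
        "multiple values for non-collection column '%s' (%d items)",
        col$name, length(items)
      ))
    }
  }
  list(row)
}

rows_for_select <- function(sel, item, ctx) {
  items <- if (sel$iter_kind == "none") {
    list(item)
  } else {
    inner <- ctx
    inner$focus <- list(item)
    fp_eval(sel$citer$root, inner)
  }
  if (length(items) == 0L) {
    if (sel$iter_kind == "forEachOrNull") return(null_fragment(sel))
    return(list())
  }
  rowsets <- vector("list", length(items))
  for (k in seq_along(items)) {
    it <- items[[k]]
    sets <- list(column_fragment(sel, it, ctx))
    for (nested in sel$cnested) {
      sets[[length(sets) + 1L]] <- rows_for_select(nested, it, ctx)
    }
    if (length(sel$cunion) > 0L) {
      urows <- list()
      for (branch in sel$cunion) {
        urows <- c(urows, rows_for_select(branch, it, ctx))
      }
      sets[[length(sets) + 1L]] <- urows
    }
    rowsets[[k]] <- cross_join_sets(sets)
  }
  do.call(c, rowsets)
}

count_select <- function(sel, item, ctx) {
  items <- if (sel$iter_kind == "none") {
    list(item)
  } else {
    inner <- ctx
    inner$focus <- list(item)
    fp_eval(sel$citer$root, inner)
  }
  if (length(items) == 0L) {
    return(if (sel$iter_kind == "forEachOrNull") 1L else 0L)
  }
  total <- 0L
  for (it in items) {
    n <- 1L
    for (nested in sel$cnested) n <- n * count_select(nested, it, ctx)
    if (length(sel$cunion) > 0L) {
      u <- 0L
      for (branch in sel$cunion) u <- u + count_select(branch, it, ctx)
      n <- n * u
    }
    total <- total + n
  }
  total
}

#' Predicted row count of a view for one resource
#'
#' Computes the number of rows a resource contributes to a view without
#' materializing them, from the row-count algebra: an iteration axis
#' contributes its item count (or `max(1, n)` for `forEachOrNull`), nested
#' selects multiply, and `unionAll` branches add. Where clauses are applied
#' first; a filtered-out resource contributes zero rows.
#'
#' @param view A `fhir_view`.
#' @param resource A FHIR resource.
#' @param keys A [key_strategy()].
#' @return A non-negative integer equal to the number of rows
#'   [execute_view()] would emit for this resource.
#' @export
count_rows <- function(view, resource, keys = key_strategy()) {
  stopifnot(inherits(view, "fhir_view"))
  if (!isTRUE(view$compiled)) view <- compile_view(view)
  if (!identical(resource[["resourceType"]], view$resource)) return(0L)
  if (!passes_where_compiled(view, resource, keys)) return(0L)
  ctx <- fp_context(resource, keys = keys)
  root <- fp_item(resource)
  total <- 1L
  for (sel in view$cselects) total <- total * count_select(sel, root, ctx)
  total
}

passes_where_compiled <- function(view, resource, keys) {
  ctx <- fp_context(resource, keys = keys)
  for (w in view$cwheres) {
    items <- fp_eval(w$root, ctx)
    if (!to_filter_boolean(lapply(items, `[[`, "val"))) return(FALSE)
  }
  TRUE
}

#' Does a resource pass a view's inclusion criteria?
#'
#' Conjunction over the view's where clauses of the filter-boolean of each
#' expression, evaluated with the resource root as focus. A view with no
#' where clauses accepts every resource.
#'
#' @inheritParams count_rows
#' @return `TRUE` or `FALSE`.
#' @export
passes_where <- function(view, resource, keys = key_strategy()) {
  stopifnot(inherits(view, "fhir_view"))
  if (!isTRUE(view$compiled)) view <- compile_view(view)
  tryCatch(
    passes_where_compiled(view, resource, keys),
    fhirtable_error = function(e) {
      id <- resource[["id"]]
      stop_execution(sprintf("where clause failed for resource %s: %s",
                             if (is.null(id)) "<no id>" else id,
                             conditionMessage(e)))
    }
  )
}

rows_for_resource <- function(view, resource, keys) {
  ctx <- fp_context(resource, keys = keys)
  root <- fp_item(resource)
  sets <- lapply(view$cselects, function(sel) rows_for_select(sel, root, ctx))
  cross_join_sets(sets)
}

#' Execute a view definition over resources
#'
#' Runs a validated view over a list of FHIR resources and materializes the
#' result table. Resources whose `resourceType` differs from the view's are
#' skipped silently (mixed bulk-export files can be fed directly); resources
#' with no `resourceType` are an error. The header is always emitted, even
#' for zero rows. A `collection = false` column whose expression yields more
#' than one value aborts execution with a cardinality error naming the
#' resource and column.
#'
#' @param view A `fhir_view` (see [parse_view()]).
#' @param resources A list of FHIR resources, e.g. from [read_ndjson()].
#' @param keys A [key_strategy()] used by the join-key functions.
#' @param validate Validate the view first and refuse to run on any error
#'   issue (default `TRUE`).
#' @param profiles Profiles to enforce when validating.
#' @return An object of class `fhir_table`; see [as.data.frame.fhir_table()],
#'   [write_table_csv()], [write_table_ndjson()].
#' @examples
#' v <- parse_view('{"resource": "Patient",
#'   "select": [{"column": [{"name": "id", "path": "id"},
#'                          {"name": "birth_date", "path": "birthDate"}]}]}')
#' pats <- example_resources("Patient")
#' as.data.frame(execute_view(v, pats))
#' @export
execute_view <- function(view, resources, keys = key_strategy(),
                         validate = TRUE, profiles = NULL) {
  stopifnot(inherits(view, "fhir_view"))
  if (validate) {
    issues <- validate_view(view, profiles)
    errors <- issues[issues$severity == "error", , drop = FALSE]
    if (nrow(errors) > 0L) {
      stop_validation(
        sprintf("view has %d validation error(s); first: [%s] %s",
                nrow(errors), errors$code[[1L]], errors$message[[1L]]),
        issues = issues
      )
    }
  }
  if (!isTRUE(view$compiled)) view <- compile_view(view)
  out <- vector("list", length(resources))
  n_out <- 0L
  for (i in seq_along(resources)) {
    resource <- resources[[i]]
    rt <- resource[["resourceType"]]
    if (is.null(rt)) {
      stop_execution(sprintf("resource %d has no resourceType", i))
    }
    if (!identical(rt, view$resource)) next
    keep <- withCallingHandlers(
      passes_where_compiled(view, resource, keys),
      fhirtable_error = function(e) annotate_resource(e, resource, i)
    )
    if (!keep) next
    rows <- withCallingHandlers(
      rows_for_resource(view, resource, keys),
      fhirtable_error = function(e) annotate_resource(e, resource, i)
    )
    if (length(rows) > 0L) {
      n_out <- n_out + 1L
      out[[n_out]] <- rows
    }
  }
  rows <- if (n_out > 0L) do.call(c, out[seq_len(n_out)]) else list()
  fhir_table(view$schema, rows)
}

annotate_resource <- function(e, resource, index) {
  if (inherits(e, "fhir_annotated")) return(invisible(NULL))
  id <- resource[["id"]]
  if (!is.character(id) || length(id) != 1L) id <- NULL
  cond <- fhir_condition(
    c(class(e)[[1L]], "fhir_annotated"),
    sprintf("resource %d (%s): %s", index,
            if (is.null(id)) "<no id>" else id, conditionMessage(e))
  )
  stop(cond)
}
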