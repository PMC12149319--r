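# Evaluation of parsed FHIRPath expressions against FHIR JSON trees.
#
# Resources are the nested lists produced by jsonlite::fromJSON(...,
# simplifyVector = FALSE): objects are named lists, arrays unnamed lists,
# primitives length-1 atomics. Evaluation always yields a collection —
# an ordered, possibly empty list of items. Each item records the payload
# (`val`), the JSON key through which it was reached (`key`, used for
# choice-type resolution and ofType()), and an optional literal type tag
# (`t`, used for date/dateTime comparison checks). Missing elements yield
# empty collections, never errors; evaluation never mutates the resource.

fp_item <- function(val, key = "", t = NULL) list(val = val, key = key, t = t)

is_json_object <- function(x) is.list(x) && !is.null(names(x))
is_json_array <- function(x) is.list(x) && is.null(names(x))

# One path step over a collection: objects contribute the child at `name`
# (arrays flatten one level, one item per element); when `name` is absent a
# unique choice-type key (name + upper-case suffix, e.g. valueQuantity) is
# used instead; scalar and array items contribute nothing.
fp_resolve_step <- function(items, name) {
  out <- list()
  for (item in items) {
    v <- item$val
    if (!is_json_object(v)) next
    key <- name
    child <- v[[name]]
    if (is.null(child)) {
      cand <- grep(paste0("^", name, "[A-Z]"), names(v), value = TRUE)
      if (length(cand) == 1L) {
        key <- cand
        child <- v[[cand]]
      }
    }
    if (is.null(child)) next
    if (is_json_array(child)) {
      for (el in child) {
        if (!is.null(el)) out[[length(out) + 1L]] <- fp_item(el, key)
      }
    } else {
      out[[length(out) + 1L]] <- fp_item(child, key)
    }
  }
  out
}

fp_scalar_kind <- function(v) {
  if (is.logical(v)) "boolean"
  else if (is.numeric(v)) "number"
  else if (is.character(v)) "string"
  else "complex"
}

ISO_TEMPORAL_RE <- "^\\d{4}(-\\d{2}(-\\d{2}(T\\d{2}:\\d{2}:\\d{2})?)?)?$"

fp_is_temporal <- function(item) {
  (!is.null(item$t) && item$t %in% c("date", "dateTime")) ||
    (is.character(item$val) && grepl(ISO_TEMPORAL_RE, item$val))
}

# Extract the single item of a collection, or NULL when empty.
fp_singleton <- function(items, what) {
  if (length(items) > 1L) {
    stop_cardinality(sprintf("%s requires a singleton, got %d items", what, length(items)))
  }
  if (length(items) == 0L) NULL else items[[1L]]
}

# Three-valued boolean of a collection: TRUE/FALSE, or NA for empty.
fp_tristate <- function(items, what) {
  item <- fp_singleton(items, what)
  if (is.null(item)) return(NA)
  v <- item$val
  if (!is.logical(v) || length(v) != 1L || is.na(v)) {
    stop_type(sprintf("%s requires a boolean operand", what))
  }
  v
}

fp_eval <- function(node, ctx) {
  switch(node$kind,
    Literal = list(fp_item(node$value, "", t = node$ltype)),
    Step = {
      base <- if (is.null(node$operand)) ctx$focus else fp_eval(node$operand, ctx)
      fp_resolve_step(base, node$name)
    },
    Index = {
      base <- fp_eval(node$operand, ctx)
      if (node$index < length(base)) list(base[[node$index + 1L]]) else list()
    },
    Invoke = fp_eval_invoke(node, ctx),
    Binary = fp_eval_binary(node, ctx),
    stop_execution(sprintf("unknown AST node kind '%s'", node$kind))
  )
}

fp_eval_invoke <- function(node, ctx) {
  base <- if (is.null(node$operand)) ctx$focus else fp_eval(node$operand, ctx)
  switch(node$name,
    where = {
      out <- list()
      for (item in base) {
        inner <- ctx
        inner$focus <- list(item)
        res <- fp_eval(node$args[[1L]], inner)
        keep <- fp_singleton(res, "where() criterion")
        if (is.null(keep)) next
        if (!is.logical(keep$val)) stop_type("where() criterion must evaluate to a boolean")
        if (isTRUE(keep$val)) out[[length(out) + 1L]] <- item
      }
      out
    },
    exists = {
      if (length(node$args) == 1L) {
        filtered <- fp_eval_invoke(
          list(kind = "Invoke", operand = node$operand, name = "where", args = node$args),
          ctx
        )
        list(fp_item(length(filtered) > 0L))
      } else {
        list(fp_item(length(base) > 0L))
      }
    },
    empty = list(fp_item(length(base) == 0L)),
    first = if (length(base) > 0L) list(base[[1L]]) else list(),
    not = {
      b <- fp_tristate(base, "not()")
      if (is.na(b)) list() else list(fp_item(!b))
    },
    ofType = {
      tname <- node$args[[1L]]$name
      Filter(function(item) fp_oftype_match(item, tname), base)
    },
    getResourceKey = {
      key <- ctx$keys$resource_key(ctx$root)
      lapply(key, fp_item)
    },
    getReferenceKey = {
      tname <- if (length(node$args) == 1L) node$args[[1L]]$name else NULL
      out <- list()
      for (item in base) {
        if (!is_json_object(item$val)) next
        key <- ctx$keys$reference_key(item$val, tname)
        for (k in key) out[[length(out) + 1L]] <- fp_item(k)
      }
      out
    },
    extension = {
      url <- node$args[[1L]]$value
      exts <- fp_resolve_step(base, "extension")
      Filter(function(item) {
        is_json_object(item$val) && identical(item$val[["url"]], url)
      }, exts)
    },
    stop_execution(sprintf("unregistered function '%s'", node$name))
  )
}

# Choice-type filter: an upper-case initial matches the element-key suffix
# (value.ofType(Quantity) keeps items reached through "valueQuantity");
# a lower-case name matches the primitive kind of a scalar payload.
fp_oftype_match <- function(item, tname) {
  if (grepl("^[A-Z]", tname)) {
    key <- item$key
    identical(key, tname) ||
      (nchar(key) > nchar(tname) &&
         substr(key, nchar(key) - nchar(tname) + 1L, nchar(key)) == tname &&
         grepl("^[A-Z]", tname))
  } else {
    kind <- fp_scalar_kind(item$val)
    switch(tname,
      boolean = kind == "boolean",
      integer = ,
      decimal = ,
      positiveInt = ,
      unsignedInt = kind == "number",
      string = ,
      code = ,
      id = ,
      uri = ,
      url = ,
      canonical = ,
      markdown = kind == "string" && !grepl(ISO_TEMPORAL_RE, item$val),
      date = ,
      dateTime = ,
      instant = ,
      time = kind == "string" && grepl(ISO_TEMPORAL_RE, item$val),
      FALSE
    )
  }
}

fp_eval_binary <- function(node, ctx) {
  op <- node$op
  if (op %in% c("and", "or")) {
    l <- fp_tristate(fp_eval(node$left, ctx), sprintf("'%s'", op))
    r <- fp_tristate(fp_eval(node$right, ctx), sprintf("'%s'", op))
    v <- if (op == "and") {
      if (isFALSE(l) || isFALSE(r)) FALSE
      else if (isTRUE(l) && isTRUE(r)) TRUE
      else NA
    } else {
      if (isTRUE(l) || isTRUE(r)) TRUE
      else if (isFALSE(l) && isFALSE(r)) FALSE
      else NA
    }
    return(if (is.na(v)) list() else list(fp_item(v)))
  }
  li <- fp_singleton(fp_eval(node$left, ctx), sprintf("operator '%s'", op))
  ri <- fp_singleton(fp_eval(node$right, ctx), sprintf("operator '%s'", op))
  # FHIRPath tri-state: an empty operand makes the comparison empty.
  if (is.null(li) || is.null(ri)) return(list())
  if (op %in% c("=", "!=")) {
    eq <- fp_equal(li, ri)
    return(list(fp_item(if (op == "=") eq else !eq)))
  }
  cmp <- fp_compare(li, ri, op)
  list(fp_item(cmp))
}

fp_equal <- function(li, ri) {
  lv <- li$val
  rv <- ri$val
  lk <- fp_scalar_kind(lv)
  rk <- fp_scalar_kind(rv)
  if (lk == "complex" || rk == "complex") return(identical(lv, rv))
  if (lk != rk) return(FALSE)
  isTRUE(lv == rv)
}

fp_compare <- function(li, ri, op) {
  lv <- li$val
  rv <- ri$val
  lk <- fp_scalar_kind(lv)
  rk <- fp_scalar_kind(rv)
  if (lk == "complex" || rk == "complex") {
    stop_type(sprintf("operator '%s' is not defined for complex values", op))
  }
  if (lk == "boolean" || rk == "boolean") {
    stop_type(sprintf("operator '%s' is not defined for booleans", op))
  }
  if (lk != rk) {
    stop_type(sprintf("operator '%s' requires operands of the same type", op))
  }
  if (lk == "string" && (fp_is_temporal(li) || fp_is_temporal(ri))) {
    if (!grepl(ISO_TEMPORAL_RE, lv) || !grepl(ISO_TEMPORAL_RE, rv)) {
      stop_type(sprintf("operator '%s': cannot compare a date with a non-date string", op))
    }
    if (nchar(lv) != nchar(rv)) {
      stop_type(sprintf("operator '%s': date operands differ in precision", op))
    }
    # equal-precision ISO-8601 text sorts correctly as plain text
  }
  switch(op,
    "<" = isTRUE(lv < rv),
    "<=" = isTRUE(lv <= rv),
    ">" = isTRUE(lv > rv),
    ">=" = isTRUE(lv >= rv)
  )
}

fp_context <- function(resource, focus = NULL, keys = key_strategy()) {
  list(
    root = resource,
    focus = if (is.null(focus)) list(fp_item(resource)) else focus,
    keys = keys
  )
}

#' Evaluate a FHIRPath expression against a resource
#'
#' Evaluates a parsed (or textual) expression against one FHIR resource and
#' returns the resulting collection as a plain list of values, in document
#' order. Missing elements produce an empty list; they are never an error.
#'
#' @param expr A `fhirpath` object from [fp_parse()], or expression text.
#' @param resource A FHIR resource as a nested list (see [read_ndjson()]).
#' @param keys A [key_strategy()] supplying `getResourceKey()` /
#'   `getReferenceKey()` implementations.
#' @return A list of values: scalars for primitive elements, nested lists for
#'   complex elements. Length 0 means the expression selected nothing.
#' @examples
#' pat <- list(resourceType = "Patient", id = "p1",
#'             name = list(list(family = "Khan", given = list("Aisha"))))
#' fp_evaluate("name.family", pat)
#' fp_evaluate("id", list(resourceType = "Patient"))  # empty list
#' @export
fp_evaluate <- function(expr, resource, keys = key_strategy()) {
  if (is.character(expr)) expr <- fp_parse(expr)
  stopifnot(inherits(expr, "fhirpath"))
  items <- fp_eval(expr$root, fp_context(resource, keys = keys))
  lapply(items, `[[`, "val")
}

#' Interpret a collection as an inclusion-criterion boolean
#'
#' Maps the result of evaluating a `where` expression onto the two-valued
#' logic used for row inclusion: a collection holding exactly one `TRUE` is
#' true; an empty collection or a single `FALSE` is false. Anything else is
#' an error — absence of evidence is never treated as truth.
#'
#' @param collection A list of values as returned by [fp_evaluate()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' to_filter_boolean(list(TRUE))   # TRUE
#' to_filter_boolean(list())       # FALSE
#' to_filter_boolean(list(FALSE))  # FALSE
#' @export
to_filter_boolean <- function(collection) {
  if (length(collection) == 0L) return(FALSE)
  if (length(collection) > 1L) {
    stop_cardinality(sprintf(
      "inclusion criterion returned %d values; expected at most one",
      length(collection)
    ))
  }
  v <- collection[[1L]]
  if (is.list(v) && !is.null(v$val)) v <- v$val
  if (!is.logical(v) || length(v) != 1L || is.na(v)) {
    stop_type("inclusion criterion must evaluate to a boolean")
  }
  v
}
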