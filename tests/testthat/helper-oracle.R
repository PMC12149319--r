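# Independent naive oracles used by the property tests: a plain recursive
# JSON-walk evaluator for path expressions, and a row enumerator for views
# built on expand.grid index products. Both are written directly from the
# documented semantics and share no evaluation code with the package.

ORACLE_ISO_RE <- "^\\d{4}(-\\d{2}(-\\d{2}(T\\d{2}:\\d{2}:\\d{2})?)?)?$"

oracle_is_obj <- function(x) is.list(x) && !is.null(names(x))

oracle_step <- function(vals, name) {
  out <- list()
  for (v in vals) {
    if (!oracle_is_obj(v)) next
    ch <- v[[name]]
    if (is.null(ch)) {
      hits <- grep(paste0("^", name, "[A-Z]"), names(v), value = TRUE)
      if (length(hits) == 1L) ch <- v[[hits]]
    }
    if (is.null(ch)) next
    if (is.list(ch) && is.null(names(ch))) {
      for (el in ch) if (!is.null(el)) out <- c(out, list(el))
    } else {
      out <- c(out, list(ch))
    }
  }
  out
}

oracle_kind <- function(v) {
  if (is.logical(v)) "boolean"
  else if (is.numeric(v)) "number"
  else if (is.character(v)) "string"
  else "complex"
}

oracle_one <- function(vals) {
  if (length(vals) > 1L) stop("cardinality")
  if (length(vals) == 0L) NULL else vals[[1L]]
}

oracle_tristate <- function(vals) {
  v <- oracle_one(vals)
  if (is.null(v)) return(NA)
  if (!is.logical(v)) stop("type")
  v
}

oracle_where <- function(vals, arg, res, keys) {
  keep <- list()
  for (v in vals) {
    r <- oracle_eval(arg, res, list(v), keys)
    b <- oracle_one(r)
    if (is.null(b)) next
    if (!is.logical(b)) stop("type")
    if (isTRUE(b)) keep <- c(keep, list(v))
  }
  keep
}

oracle_eval <- function(node, res, focus, keys = fhirtable::key_strategy()) {
  k <- node$kind
  if (k == "Literal") return(list(node$value))
  if (k == "Step") {
    base <- if (is.null(node$operand)) focus else oracle_eval(node$operand, res, focus, keys)
    return(oracle_step(base, node$name))
  }
  if (k == "Index") {
    base <- oracle_eval(node$operand, res, focus, keys)
    i <- node$index + 1L
    return(if (i <= length(base)) base[i] else list())
  }
  if (k == "Invoke") {
    base <- if (is.null(node$operand)) focus else oracle_eval(node$operand, res, focus, keys)
    nm <- node$name
    if (nm == "first") return(if (length(base) > 0L) base[1L] else list())
    if (nm == "empty") return(list(length(base) == 0L))
    if (nm == "exists") {
      if (length(node$args) == 1L) base <- oracle_where(base, node$args[[1L]], res, keys)
      return(list(length(base) > 0L))
    }
    if (nm == "where") return(oracle_where(base, node$args[[1L]], res, keys))
    if (nm == "not") {
      b <- oracle_tristate(base)
      return(if (is.na(b)) list() else list(!b))
    }
    if (nm == "getResourceKey") return(as.list(keys$resource_key(res)))
    if (nm == "getReferenceKey") {
      tn <- if (length(node$args) == 1L) node$args[[1L]]$name else NULL
      out <- list()
      for (v in base) {
        if (!oracle_is_obj(v)) next
        out <- c(out, as.list(keys$reference_key(v, tn)))
      }
      return(out)
    }
    stop("oracle does not cover function ", nm)
  }
  # Binary
  op <- node$op
  if (op %in% c("and", "or")) {
    l <- oracle_tristate(oracle_eval(node$left, res, focus, keys))
    r <- oracle_tristate(oracle_eval(node$right, res, focus, keys))
    v <- if (op == "and") {
      if (isFALSE(l) || isFALSE(r)) FALSE else if (isTRUE(l) && isTRUE(r)) TRUE else NA
    } else {
      if (isTRUE(l) || isTRUE(r)) TRUE else if (isFALSE(l) && isFALSE(r)) FALSE else NA
    }
    return(if (is.na(v)) list() else list(v))
  }
  a <- oracle_one(oracle_eval(node$left, res, focus, keys))
  b <- oracle_one(oracle_eval(node$right, res, focus, keys))
  if (is.null(a) || is.null(b)) return(list())
  ka <- oracle_kind(a)
  kb <- oracle_kind(b)
  if (op %in% c("=", "!=")) {
    eq <- if (ka == "complex" || kb == "complex") identical(a, b)
          else if (ka != kb) FALSE
          else isTRUE(a == b)
    return(list(if (op == "=") eq else !eq))
  }
  if (ka == "complex" || kb == "complex" || ka == "boolean" || kb == "boolean" ||
      ka != kb) {
    stop("type")
  }
  if (ka == "string" && (grepl(ORACLE_ISO_RE, a) || grepl(ORACLE_ISO_RE, b))) {
    if (!grepl(ORACLE_ISO_RE, a) || !grepl(ORACLE_ISO_RE, b)) stop("type")
    if (nchar(a) != nchar(b)) stop("type")
  }
  list(switch(op,
    "<" = isTRUE(a < b), "<=" = isTRUE(a <= b),
    ">" = isTRUE(a > b), ">=" = isTRUE(a >= b)))
}

oracle_eval_path <- function(text, res, focus = list(res),
                             keys = fhirtable::key_strategy()) {
  oracle_eval(fhirtable::fp_parse(text)$root, res, focus, keys)
}

# --- naive view enumerator -------------------------------------------------

oracle_select_schema <- function(sel) {
  names <- character(0)
  coll <- logical(0)
  for (col in sel$columns) {
    names <- c(names, col$name)
    coll <- c(coll, isTRUE(col$collection))
  }
  for (n in sel$nested) {
    s <- oracle_select_schema(n)
    names <- c(names, s$names)
    coll <- c(coll, s$coll)
  }
  if (length(sel$union_all) > 0L) {
    s <- oracle_select_schema(sel$union_all[[1L]])
    names <- c(names, s$names)
    coll <- c(coll, s$coll)
  }
  list(names = names, coll = coll)
}

# Left-major index product: the leftmost row-set varies slowest.
oracle_cross <- function(sets) {
  if (length(sets) == 0L) return(list(list()))
  if (any(vapply(sets, length, 1L) == 0L)) return(list())
  idx <- expand.grid(rev(lapply(sets, seq_along)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(sets)), drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r) {
    do.call(c, lapply(seq_along(sets), function(j) sets[[j]][[idx[r, j]]]))
  })
}

oracle_select_rows <- function(sel, val, res, keys) {
  items <- if (!is.null(sel$for_each)) {
    oracle_eval_path(sel$for_each, res, list(val), keys)
  } else if (!is.null(sel$for_each_or_null)) {
    oracle_eval_path(sel$for_each_or_null, res, list(val), keys)
  } else {
    list(val)
  }
  if (length(items) == 0L) {
    if (!is.null(sel$for_each_or_null)) {
      s <- oracle_select_schema(sel)
      row <- vector("list", length(s$names))
      for (j in seq_along(s$names)) if (s$coll[[j]]) row[j] <- list(list())
      return(list(row))
    }
    return(list())
  }
  rows <- list()
  for (it in items) {
    frag <- vector("list", length(sel$columns))
    for (j in seq_along(sel$columns)) {
      col <- sel$columns[[j]]
      vals <- oracle_eval_path(col$path, res, list(it), keys)
      if (isTRUE(col$collection)) {
        frag[j] <- list(vals)
      } else if (length(vals) == 1L) {
        frag[j] <- vals[1L]
      } else if (length(vals) > 1L) {
        stop("cardinality")
      }
    }
    sets <- list(list(frag))
    for (n in sel$nested) {
      sets <- c(sets, list(oracle_select_rows(n, it, res, keys)))
    }
    if (length(sel$union_all) > 0L) {
      u <- list()
      for (br in sel$union_all) u <- c(u, oracle_select_rows(br, it, res, keys))
      sets <- c(sets, list(u))
    }
    rows <- c(rows, oracle_cross(sets))
  }
  rows
}

oracle_execute <- function(view, resources, keys = fhirtable::key_strategy()) {
  rows <- list()
  for (res in resources) {
    if (!identical(res$resourceType, view$resource)) next
    ok <- TRUE
    for (w in view$wheres) {
      vals <- oracle_eval_path(w$path, res, list(res), keys)
      if (length(vals) > 1L) stop("cardinality")
      if (length(vals) == 1L && !is.logical(vals[[1L]])) stop("type")
      if (!(length(vals) == 1L && isTRUE(vals[[1L]]))) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    sets <- lapply(view$selects, function(s) oracle_select_rows(s, res, res, keys))
    rows <- c(rows, oracle_cross(sets))
  }
  rows
}
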