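# Randomized inputs for the property tests: random resources (realistic
# corpus patients plus adversarial random JSON trees), random path
# expressions over the Patient element vocabulary, and random views
# exercising every directive. All draws go through R's RNG so tests fix
# their own seed.

rnd_pick <- function(x) x[[sample.int(length(x), 1L)]]

random_json <- function(depth = 2L) {
  keys <- c("id", "active", "birthDate", "name", "address", "telecom",
            "value", "given", "line", "city", "use", "system", "family")
  n <- sample.int(4L, 1L)
  obj <- list()
  for (k in sample(keys, n)) {
    r <- stats::runif(1)
    obj[[k]] <- if (depth > 0L && r < 0.3) {
      random_json(depth - 1L)
    } else if (depth > 0L && r < 0.5) {
      lapply(seq_len(sample.int(3L, 1L)), function(i) {
        if (stats::runif(1) < 0.5) random_json(depth - 1L)
        else rnd_pick(list("x", "home", "1985-03-04", TRUE, 7, 2.5))
      })
    } else {
      rnd_pick(list("x", "y", "home", "official", "1985-03-04",
                    "2001-11-23", TRUE, FALSE, 1, 42, 3.14))
    }
  }
  obj$resourceType <- "Patient"
  obj
}

random_resource <- function(patients) {
  if (stats::runif(1) < 0.6) rnd_pick(patients) else random_json()
}

# A random path over the Patient vocabulary, optionally decorated with
# where()/first()/[n] and optionally lifted into a boolean expression.
random_path <- function() {
  chains <- list(
    "id", "active", "birthDate",
    "name", "name.family", "name.given", "name.use",
    "address", "address.city", "address.state", "address.use",
    "address.line",
    "telecom", "telecom.system", "telecom.value", "telecom.use"
  )
  path <- rnd_pick(chains)
  r <- stats::runif(1)
  if (r < 0.15) {
    field <- rnd_pick(list(c("use", "'home'"), c("use", "'official'"),
                           c("system", "'phone'"), c("city", "'Chicago'")))
    seg <- strsplit(path, ".", fixed = TRUE)[[1L]]
    path <- paste0(seg[[1L]], ".where(", field[[1L]], " = ", field[[2L]], ")")
    if (length(seg) > 1L) path <- paste0(path, ".", seg[[2L]])
  } else if (r < 0.3) {
    path <- paste0(path, ".first()")
  } else if (r < 0.4) {
    path <- paste0(path, "[", sample(0:2, 1L), "]")
  }
  path
}

random_fhirpath <- function(depth = 1L) {
  r <- stats::runif(1)
  if (r < 0.45) return(random_path())
  if (r < 0.6) {
    return(paste0(random_path(), rnd_pick(list(".exists()", ".empty()"))))
  }
  if (r < 0.8) {
    lit <- rnd_pick(list("true", "false", "'home'", "'phone'", "'Chicago'",
                         "@1970-01-01", "1", "2"))
    op <- rnd_pick(list("=", "!=", "<", "<=", ">", ">="))
    return(paste(random_path(), op, lit))
  }
  if (depth > 0L) {
    return(paste0("(", random_fhirpath(depth - 1L), ") ",
                  rnd_pick(list("and", "or")), " (",
                  random_fhirpath(depth - 1L), ")"))
  }
  paste0(random_path(), ".exists()")
}

# Random Patient view touching columns, forEach/forEachOrNull, nested
# selects, unionAll and where, with unique generated column names.
random_view <- function() {
  i <- 0L
  cnt <- function() {
    i <<- i + 1L
    paste0("c", i)
  }
  root_col <- function() {
    list(name = cnt(),
         path = rnd_pick(list("id", "birthDate", "active",
                              "name.first().family", "address.first().city",
                              "telecom.first().value")))
  }
  iter_select <- function(kind) {
    axis <- rnd_pick(list(
      list(expr = "address", cols = list("city", "state", "use", "line.first()")),
      list(expr = "telecom", cols = list("system", "value", "use")),
      list(expr = "name", cols = list("family", "use", "given.first()")),
      list(expr = "telecom.where(system = 'phone')", cols = list("value", "use")),
      list(expr = "address.where(use = 'home')", cols = list("city", "state"))
    ))
    sel <- list(column = lapply(seq_len(sample.int(2L, 1L)), function(k) {
      list(name = cnt(), path = rnd_pick(axis$cols))
    }))
    if (kind == "forEach") sel$forEach <- axis$expr else sel$forEachOrNull <- axis$expr
    sel
  }
  union_block <- function() {
    nm <- cnt()
    list(
      list(forEach = "telecom.where(use = 'home')",
           column = list(list(name = nm, path = "value"))),
      list(forEach = "telecom.where(use = 'work')",
           column = list(list(name = nm, path = "value")))
    )
  }
  root_sel <- list(column = lapply(seq_len(sample.int(2L, 1L)),
                                   function(k) root_col()))
  if (stats::runif(1) < 0.2) {
    root_sel$column <- c(root_sel$column,
                         list(list(name = cnt(), path = "name.first().given",
                                   collection = TRUE)))
  }
  if (stats::runif(1) < 0.3) root_sel$unionAll <- union_block()
  if (stats::runif(1) < 0.3) {
    root_sel$select <- list(iter_select(rnd_pick(c("forEach", "forEachOrNull"))))
  }
  extra <- list()
  r <- stats::runif(1)
  if (r < 0.35) {
    extra <- list(iter_select("forEach"))
  } else if (r < 0.6) {
    extra <- list(iter_select("forEachOrNull"))
  } else if (r < 0.75) {
    extra <- list(iter_select("forEach"), iter_select("forEachOrNull"))
  }
  doc <- list(resource = "Patient", select = c(list(root_sel), extra))
  if (stats::runif(1) < 0.4) {
    doc$where <- list(list(path = rnd_pick(list(
      "active = true", "birthDate.exists()", "telecom.exists()",
      "active != false"
    ))))
  }
  fhirtable::parse_view(doc)
}

# Evaluate both engines on one (expression, resource) pair and compare:
# equal collections, or both raising a cardinality/type error.
both_engines_agree <- function(text, res) {
  mine <- tryCatch(fhirtable::fp_evaluate(text, res), error = function(e) e)
  theirs <- tryCatch(oracle_eval_path(text, res), error = function(e) e)
  if (inherits(mine, "error") || inherits(theirs, "error")) {
    return(inherits(mine, "error") && inherits(theirs, "error"))
  }
  identical(mine, theirs)
}
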