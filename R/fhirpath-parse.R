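# Recursive-descent parser for the FHIRPath subset used by view definitions.
#
# Supported grammar (precedence from loosest to tightest binding):
#   orExpr   := andExpr ('or' andExpr)*
#   andExpr  := eqExpr ('and' eqExpr)*
#   eqExpr   := relExpr (('=' | '!=') relExpr)?
#   relExpr  := postfix (('<' | '<=' | '>' | '>=') postfix)?
#   postfix  := primary ('.' step-or-call | '[' integer ']')*
#   primary  := literal | identifier | call | '(' orExpr ')'
# Literals: 'string', integer, decimal, true/false, @YYYY-MM-DD,
# @YYYY-MM-DDThh:mm:ss. Functions outside the registered set (notably
# resolve()) are rejected at parse time.

FP_FUNCTIONS <- list(
  where           = c(1L, 1L),
  exists          = c(0L, 1L),
  empty           = c(0L, 0L),
  first           = c(0L, 0L),
  not             = c(0L, 0L),
  ofType          = c(1L, 1L),
  getResourceKey  = c(0L, 0L),
  getReferenceKey = c(0L, 1L),
  extension       = c(1L, 1L)
)

fp_tokenize <- function(src) {
  n <- nchar(src)
  toks <- vector("list", 16L)
  ntok <- 0L
  push <- function(type, text, value = NULL, pos) {
    ntok <<- ntok + 1L
    toks[[ntok]] <<- list(type = type, text = text, value = value, pos = pos)
  }
  i <- 1L
  while (i <= n) {
    ch <- substr(src, i, i)
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      i <- i + 1L
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      j <- i + 1L
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(src, j, j))) j <- j + 1L
      word <- substr(src, i, j - 1L)
      if (word == "and" || word == "or") {
        push("op", word, pos = i)
      } else if (word == "true" || word == "false") {
        push("bool", word, identical(word, "true"), i)
      } else {
        push("ident", word, pos = i)
      }
      i <- j
      next
    }
    if (grepl("^[0-9]$", ch)) {
      j <- i + 1L
      while (j <= n && grepl("^[0-9]$", substr(src, j, j))) j <- j + 1L
      if (j < n && substr(src, j, j) == "." &&
          grepl("^[0-9]$", substr(src, j + 1L, j + 1L))) {
        j <- j + 1L
        while (j <= n && grepl("^[0-9]$", substr(src, j, j))) j <- j + 1L
        push("dec", substr(src, i, j - 1L), as.numeric(substr(src, i, j - 1L)), i)
      } else {
        push("int", substr(src, i, j - 1L), as.numeric(substr(src, i, j - 1L)), i)
      }
      i <- j
      next
    }
    if (ch == "'") {
      j <- i + 1L
      buf <- character(0)
      closed <- FALSE
      while (j <= n) {
        cj <- substr(src, j, j)
        if (cj == "\\") {
          if (j + 1L > n) stop_syntax("dangling escape in string literal", j)
          esc <- substr(src, j + 1L, j + 1L)
          rep <- switch(esc,
            "'" = "'", "\\" = "\\", n = "\n", t = "\t", r = "\r",
            stop_syntax(sprintf("unsupported escape '\\%s'", esc), j)
          )
          buf <- c(buf, rep)
          j <- j + 2L
        } else if (cj == "'") {
          closed <- TRUE
          j <- j + 1L
          break
        } else {
          buf <- c(buf, cj)
          j <- j + 1L
        }
      }
      if (!closed) stop_syntax("unterminated string literal", i)
      push("str", substr(src, i, j - 1L), paste0(buf, collapse = ""), i)
      i <- j
      next
    }
    if (ch == "@") {
      j <- i + 1L
      while (j <= n && grepl("^[0-9T:\\-]$", substr(src, j, j))) j <- j + 1L
      text <- substr(src, i + 1L, j - 1L)
      if (grepl("^\\d{4}-\\d{2}-\\d{2}$", text)) {
        push("date", text, text, i)
      } else if (grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$", text)) {
        push("datetime", text, text, i)
      } else {
        stop_syntax(sprintf("malformed date/dateTime literal '@%s'", text), i)
      }
      i <- j
      next
    }
    two <- substr(src, i, min(i + 1L, n))
    if (two %in% c("!=", "<=", ">=")) {
      push("op", two, pos = i)
      i <- i + 2L
      next
    }
    if (ch %in% c("=", "<", ">")) {
      push("op", ch, pos = i)
      i <- i + 1L
      next
    }
    sym <- switch(ch,
      "." = "dot", "(" = "lparen", ")" = "rparen",
      "[" = "lbracket", "]" = "rbracket", "," = "comma",
      NULL
    )
    if (is.null(sym)) stop_syntax(sprintf("unexpected character '%s'", ch), i)
    push(sym, ch, pos = i)
    i <- i + 1L
  }
  push("eof", "", pos = n + 1L)
  toks[seq_len(ntok)]
}

# Parser state lives in an environment so helpers can advance the cursor.
fp_parser <- function(toks) {
  p <- new.env(parent = emptyenv())
  p$toks <- toks
  p$pos <- 1L
  p
}

fp_peek <- function(p) p$toks[[p$pos]]

fp_next <- function(p) {
  tok <- p$toks[[p$pos]]
  p$pos <- p$pos + 1L
  tok
}

fp_expect <- function(p, type, what) {
  tok <- fp_peek(p)
  if (!identical(tok$type, type)) {
    stop_syntax(sprintf("expected %s, found '%s'", what, tok$text), tok$pos)
  }
  fp_next(p)
}

fp_accept_op <- function(p, ops) {
  tok <- fp_peek(p)
  if (identical(tok$type, "op") && tok$text %in% ops) fp_next(p)$text else NULL
}

fp_parse_or <- function(p) {
  node <- fp_parse_and(p)
  while (!is.null(fp_accept_op(p, "or"))) {
    node <- list(kind = "Binary", op = "or", left = node, right = fp_parse_and(p))
  }
  node
}

fp_parse_and <- function(p) {
  node <- fp_parse_eq(p)
  while (!is.null(fp_accept_op(p, "and"))) {
    node <- list(kind = "Binary", op = "and", left = node, right = fp_parse_eq(p))
  }
  node
}

fp_parse_eq <- function(p) {
  node <- fp_parse_rel(p)
  op <- fp_accept_op(p, c("=", "!="))
  if (!is.null(op)) {
    node <- list(kind = "Binary", op = op, left = node, right = fp_parse_rel(p))
  }
  node
}

fp_parse_rel <- function(p) {
  node <- fp_parse_postfix(p)
  op <- fp_accept_op(p, c("<", "<=", ">", ">="))
  if (!is.null(op)) {
    node <- list(kind = "Binary", op = op, left = node, right = fp_parse_postfix(p))
  }
  node
}

fp_parse_postfix <- function(p) {
  node <- fp_parse_primary(p)
  repeat {
    tok <- fp_peek(p)
    if (identical(tok$type, "dot")) {
      fp_next(p)
      node <- fp_parse_member(p, node)
    } else if (identical(tok$type, "lbracket")) {
      fp_next(p)
      idx <- fp_peek(p)
      if (!identical(idx$type, "int")) {
        stop_syntax("indexer requires a non-negative integer", idx$pos)
      }
      fp_next(p)
      fp_expect(p, "rbracket", "']'")
      node <- list(kind = "Index", operand = node, index = as.integer(idx$value))
    } else {
      break
    }
  }
  node
}

# A member after '.' is either a plain path step or a function invocation.
fp_parse_member <- function(p, operand) {
  tok <- fp_peek(p)
  if (!identical(tok$type, "ident")) {
    stop_syntax(sprintf("expected identifier after '.', found '%s'", tok$text), tok$pos)
  }
  fp_next(p)
  if (identical(fp_peek(p)$type, "lparen")) {
    fp_parse_call(p, operand, tok)
  } else {
    list(kind = "Step", operand = operand, name = tok$text)
  }
}

fp_parse_call <- function(p, operand, name_tok) {
  name <- name_tok$text
  arity <- FP_FUNCTIONS[[name]]
  if (is.null(arity)) {
    stop_syntax(sprintf("unsupported function '%s'", name), name_tok$pos)
  }
  fp_expect(p, "lparen", "'('")
  args <- list()
  if (!identical(fp_peek(p)$type, "rparen")) {
    repeat {
      args[[length(args) + 1L]] <- fp_parse_or(p)
      if (identical(fp_peek(p)$type, "comma")) fp_next(p) else break
    }
  }
  fp_expect(p, "rparen", "')'")
  if (length(args) < arity[[1L]] || length(args) > arity[[2L]]) {
    stop_syntax(
      sprintf("%s() takes %s argument(s), got %d",
              name,
              if (arity[[1L]] == arity[[2L]]) arity[[1L]]
              else paste(arity[[1L]], "to", arity[[2L]]),
              length(args)),
      name_tok$pos
    )
  }
  # Type-name arguments must be bare identifiers.
  if (name %in% c("ofType", "getReferenceKey") && length(args) == 1L) {
    a <- args[[1L]]
    if (!identical(a$kind, "Step") || !is.null(a$operand)) {
      stop_syntax(sprintf("%s() takes a bare type name", name), name_tok$pos)
    }
  }
  if (name == "extension") {
    a <- args[[1L]]
    if (!identical(a$kind, "Literal") || !identical(a$ltype, "string")) {
      stop_syntax("extension() takes a string literal url", name_tok$pos)
    }
  }
  list(kind = "Invoke", operand = operand, name = name, args = args)
}

fp_parse_primary <- function(p) {
  tok <- fp_peek(p)
  switch(tok$type,
    ident = {
      fp_next(p)
      if (identical(fp_peek(p)$type, "lparen")) {
        fp_parse_call(p, NULL, tok)
      } else {
        list(kind = "Step", operand = NULL, name = tok$text)
      }
    },
    str = { fp_next(p); list(kind = "Literal", ltype = "string", value = tok$value) },
    int = { fp_next(p); list(kind = "Literal", ltype = "integer", value = tok$value) },
    dec = { fp_next(p); list(kind = "Literal", ltype = "decimal", value = tok$value) },
    bool = { fp_next(p); list(kind = "Literal", ltype = "boolean", value = tok$value) },
    date = { fp_next(p); list(kind = "Literal", ltype = "date", value = tok$value) },
    datetime = { fp_next(p); list(kind = "Literal", ltype = "dateTime", value = tok$value) },
    lparen = {
      fp_next(p)
      node <- fp_parse_or(p)
      fp_expect(p, "rparen", "')'")
      node
    },
    stop_syntax(sprintf("unexpected token '%s'", tok$text), tok$pos)
  )
}

#' Parse a FHIRPath expression
#'
#' Parses the FHIRPath subset used by view definitions into an abstract syntax
#' tree. The subset covers identifier paths with `.` chaining, `[n]` indexing,
#' literals (string, integer, decimal, boolean, `@date`, `@dateTime`), the
#' operators `= != < <= > >= and or`, and the functions `where()`, `exists()`,
#' `empty()`, `first()`, `not()`, `ofType()`, `extension()`, and the join-key
#' functions `getResourceKey()` / `getReferenceKey()`. Anything outside the
#' subset (for example `resolve()`) is rejected with a syntax error carrying a
#' character offset.
#'
#' @param source Expression text (a single non-empty string).
#' @return An object of class `fhirpath` with elements `source` (the original
#'   text) and `root` (the AST).
#' @examples
#' fp_parse("name.family")
#' fp_parse("telecom.where(system = 'phone').value")
#' @export
fp_parse <- function(source) {
  if (!is.character(source) || length(source) != 1L || is.na(source) || !nzchar(source)) {
    stop_syntax("expression must be a single non-empty string", 1L)
  }
  p <- fp_parser(fp_tokenize(source))
  root <- fp_parse_or(p)
  tok <- fp_peek(p)
  if (!identical(tok$type, "eof")) {
    stop_syntax(sprintf("unexpected trailing input '%s'", tok$text), tok$pos)
  }
  structure(list(source = source, root = root), class = "fhirpath")
}

# Serialize an AST back to expression text. fp_parse(format(x)) is
# structurally identical to x; parenthesization follows operator precedence.
fp_format_node <- function(node, prec = 0L) {
  out <- switch(node$kind,
    Literal = switch(node$ltype,
      string = paste0("'", gsub("'", "\\\\'", gsub("\\\\", "\\\\\\\\", node$value)), "'"),
      boolean = if (isTRUE(node$value)) "true" else "false",
      integer = format(node$value, scientific = FALSE),
      decimal = format(node$value, scientific = FALSE),
      date = paste0("@", node$value),
      dateTime = paste0("@", node$value)
    ),
    Step = if (is.null(node$operand)) node$name
           else paste0(fp_format_node(node$operand, 5L), ".", node$name),
    Invoke = {
      args <- vapply(node$args, fp_format_node, "", prec = 0L)
      call <- paste0(node$name, "(", paste0(args, collapse = ", "), ")")
      if (is.null(node$operand)) call
      else paste0(fp_format_node(node$operand, 5L), ".", call)
    },
    Index = paste0(fp_format_node(node$operand, 5L), "[", node$index, "]"),
    Binary = {
      p <- switch(node$op, or = 1L, and = 2L, "=" = 3L, "!=" = 3L, 4L)
      txt <- paste(fp_format_node(node$left, p), node$op,
                   fp_format_node(node$right, p + 1L))
      if (p < prec) paste0("(", txt, ")") else txt
    }
  )
  out
}

#' @export
format.fhirpath <- function(x, ...) fp_format_node(x$root)

#' @export
print.fhirpath <- function(x, ...) {
  cat("<fhirpath> ", format(x), "\n", sep = "")
  invisible(x)
}
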