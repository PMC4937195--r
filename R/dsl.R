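#' @title Transformation expression language
#'
#' @description
#' Generated algorithms are written in a small, closed, chained-method
#' expression language modelled on the Magma harmonization syntax: a source
#' attribute is accessed as `$('name')` and transformed by chaining the
#' methods `div()`, `times()`, `plus()`, `pow()`, `map()`, `unit()`,
#' `toUnit()` and the terminal `value()`. `map()` takes a literal
#' `{'src':'tgt', ...}` of string codes; `unit('cm').toUnit('m')` rescales a
#' value between compatible measurement units. The language is interpreted
#' directly (it is not embedded JavaScript), which makes generated scripts
#' testable and injection-safe. A conditional extension
#' (`cond ? a : b` with `>=`, `>` , `<=`, `<`, `==`, `!=`, `||`, `&&`)
#' exists for algorithm templates only and is enabled explicitly with
#' `allow_conditional = TRUE`.
#'
#' Missing values are absorbing: any arithmetic on a null yields null, an
#' unmapped `map()` code yields null, and division by zero yields null with
#' a warning.
#'
#' @name transform-dsl
NULL

.dsl_methods <- c("div", "times", "plus", "pow", "map", "unit", "toUnit",
                  "value")

# straight quotes are canonical; typographic quotes are accepted on input
.dsl_normalize <- function(x) {
  x <- gsub("[\u2018\u2019\u201b\u2032]", "'", x)
  gsub("[\u201c\u201d]", '"', x)
}

# ---- lexer -----------------------------------------------------------------

.dsl_lex <- function(text) {
  tokens <- list()
  pos <- 1L
  n <- nchar(text)
  push <- function(type, value, at) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = at)
  }
  while (pos <= n) {
    rest <- substring(text, pos)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws)) { pos <- pos + nchar(ws); next }
    rest <- substring(text, pos)
    m <- regmatches(rest, regexpr("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", rest))
    if (length(m)) {
      push("number", as.numeric(m), pos); pos <- pos + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^'[^']*'|^\"[^\"]*\"", rest))
    if (length(m)) {
      push("string", substring(m, 2, nchar(m) - 1), pos)
      pos <- pos + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m)) { push("ident", m, pos); pos <- pos + nchar(m); next }
    m <- regmatches(rest, regexpr("^(\\|\\||&&|>=|<=|==|!=)", rest))
    if (length(m)) { push("op", m, pos); pos <- pos + nchar(m); next }
    ch <- substring(text, pos, pos)
    if (ch %in% c("$", "(", ")", "{", "}", ".", ",", ":", "?", ">", "<")) {
      push(if (ch %in% c(">", "<")) "op" else ch, ch, pos)
      pos <- pos + 1L; next
    }
    stop("syntax error at position ", pos, ": unexpected character '", ch, "'")
  }
  push("eof", "", pos)
  tokens
}

# ---- parser ----------------------------------------------------------------

.node_attr <- function(name) list(kind = "attr", name = name)
.node_const <- function(value, is_string) {
  list(kind = "const", value = value, is_string = is_string)
}

#' Parse a transformation script
#'
#' @param script script text, e.g. `"$('Height').div(100).value()"`.
#'   Typographic (curly) quotes are accepted and normalized.
#' @param allow_conditional enable the template-only conditional extension
#'   (`cond ? a : b`, comparisons, `||`/`&&`).
#' @return an object of class `dsl_script` with elements `source_text`
#'   (original input), `text` (canonical rendering), `ast` and
#'   `referenced_attributes`.
#' @export
dsl_parse <- function(script, allow_conditional = FALSE) {
  if (is.null(script) || !nzchar(trimws(script))) {
    stop("script must be non-empty")
  }
  norm <- .dsl_normalize(script)
  tokens <- .dsl_lex(norm)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  peek <- function() tokens[[st$i]]
  advance <- function() { t <- tokens[[st$i]]; st$i <- st$i + 1L; t }
  expect <- function(type, what = type) {
    t <- peek()
    if (!identical(t$type, type)) {
      stop("syntax error at position ", t$pos, ": expected ", what,
           ", got '", t$value, "'")
    }
    advance()
  }

  parse_primary <- function() {
    t <- peek()
    if (t$type == "$") {
      advance(); expect("(", "'('")
      s <- expect("string", "attribute name string")
      expect(")", "')'")
      return(.node_attr(s$value))
    }
    if (t$type == "number") { advance(); return(.node_const(t$value, FALSE)) }
    if (t$type == "string") { advance(); return(.node_const(t$value, TRUE)) }
    if (t$type == "(" && allow_conditional) {
      advance()
      e <- parse_ternary()
      expect(")", "')'")
      return(e)
    }
    stop("syntax error at position ", t$pos, ": unexpected '", t$value, "'")
  }

  parse_map_literal <- function() {
    expect("{", "'{'")
    keys <- character(0); vals <- character(0)
    if (peek()$type != "}") {
      repeat {
        k <- expect("string", "map key string")
        expect(":", "':'")
        v <- expect("string", "map value string")
        keys <- c(keys, k$value); vals <- c(vals, v$value)
        if (peek()$type == ",") { advance(); next }
        break
      }
    }
    expect("}", "'}'")
    list(kind = "map_literal", pairs = setNames(vals, keys))
  }

  parse_chain <- function() {
    node <- parse_primary()
    while (peek()$type == ".") {
      advance()
      mt <- expect("ident", "method name")
      method <- mt$value
      if (!method %in% .dsl_methods) {
        stop("unknown method '", method, "' at position ", mt$pos)
      }
      expect("(", "'('")
      args <- list()
      if (method == "map") {
        args[[1]] <- parse_map_literal()
      } else if (method != "value" && peek()$type != ")") {
        repeat {
          args[[length(args) + 1L]] <- parse_chain()
          if (peek()$type == ",") { advance(); next }
          break
        }
      }
      expect(")", "')'")
      n_expected <- if (method == "value") 0L else 1L
      if (length(args) != n_expected) {
        stop("method ", method, "() takes ", n_expected, " argument(s), got ",
             length(args), " at position ", mt$pos)
      }
      if (method %in% c("unit", "toUnit") &&
          !(args[[1]]$kind == "const" && args[[1]]$is_string)) {
        stop(method, "() takes a unit symbol string at position ", mt$pos)
      }
      node <- list(kind = "call", method = method, receiver = node, args = args)
    }
    node
  }

  parse_cmp <- function() {
    l <- parse_chain()
    t <- peek()
    if (t$type == "op" && t$value %in% c(">=", "<=", ">", "<", "==", "!=")) {
      advance()
      r <- parse_chain()
      return(list(kind = "cmp", op = t$value, left = l, right = r))
    }
    l
  }

  parse_and <- function() {
    l <- parse_cmp()
    while (peek()$type == "op" && peek()$value == "&&") {
      advance()
      l <- list(kind = "logic", op = "&&", left = l, right = parse_cmp())
    }
    l
  }

  parse_or <- function() {
    l <- parse_and()
    while (peek()$type == "op" && peek()$value == "||") {
      advance()
      l <- list(kind = "logic", op = "||", left = l, right = parse_and())
    }
    l
  }

  parse_ternary <- function() {
    l <- parse_or()
    if (peek()$type == "?") {
      advance()
      yes <- parse_ternary()
      expect(":", "':'")
      no <- parse_ternary()
      return(list(kind = "ternary", cond = l, yes = yes, no = no))
    }
    l
  }

  ast <- if (allow_conditional) parse_ternary() else parse_chain()
  t <- peek()
  if (t$type != "eof") {
    stop("syntax error at position ", t$pos, ": unexpected '", t$value, "'",
         if (!allow_conditional &&
             t$type %in% c("op", "?")) " (conditional syntax is template-only)"
         else "")
  }
  structure(list(source_text = script, text = .dsl_format_node(ast),
                 ast = ast, conditional = allow_conditional,
                 referenced_attributes = .collect_refs(ast)),
            class = "dsl_script")
}

.collect_refs <- function(node) {
  if (is.null(node) || !is.list(node) || is.null(node$kind)) return(character(0))
  switch(node$kind,
         attr = node$name,
         call = unique(c(.collect_refs(node$receiver),
                         unlist(lapply(node$args, .collect_refs)))),
         cmp = unique(c(.collect_refs(node$left), .collect_refs(node$right))),
         logic = unique(c(.collect_refs(node$left), .collect_refs(node$right))),
         ternary = unique(c(.collect_refs(node$cond), .collect_refs(node$yes),
                            .collect_refs(node$no))),
         character(0))
}

#' Attribute names referenced by a script
#'
#' @param script a `dsl_script` (or script text, which is parsed first).
#' @param allow_conditional passed to [dsl_parse()] when `script` is text.
#' @return sorted character vector of distinct attribute names.
#' @export
dsl_referenced_attributes <- function(script, allow_conditional = TRUE) {
  if (is.character(script)) script <- dsl_parse(script, allow_conditional)
  sort(unique(script$referenced_attributes))
}

# ---- printer ---------------------------------------------------------------

.dsl_format_node <- function(node) {
  switch(node$kind,
    attr = sprintf("$('%s')", node$name),
    const = if (node$is_string) sprintf("'%s'", node$value) else
      .num_str(node$value),
    map_literal = paste0("{", paste(sprintf("'%s':'%s'", names(node$pairs),
                                            node$pairs), collapse = ","), "}"),
    call = paste0(.dsl_format_node(node$receiver), ".", node$method, "(",
                  paste(vapply(node$args, .dsl_format_node, character(1)),
                        collapse = ","), ")"),
    cmp = paste(.dsl_format_node(node$left), node$op,
                .dsl_format_node(node$right)),
    logic = paste(.dsl_format_node(node$left), node$op,
                  .dsl_format_node(node$right)),
    ternary = paste(.dsl_format_node(node$cond), "?",
                    .dsl_format_node(node$yes), ":",
                    .dsl_format_node(node$no)),
    stop("unknown node kind: ", node$kind))
}

#' Canonical text of a script
#'
#' `dsl_format(dsl_parse(x))` is a fixpoint: re-parsing the canonical text
#' yields an equal syntax tree.
#'
#' @param script a `dsl_script`.
#' @return single string, single-quoted, canonical spacing.
#' @export
dsl_format <- function(script) {
  stopifnot(inherits(script, "dsl_script"))
  script$text
}

#' @export
print.dsl_script <- function(x, ...) {
  cat("<dsl>", x$text, "\n")
  invisible(x)
}

# ---- evaluator -------------------------------------------------------------

# internal evaluation state: value (number/string/NA) + optional unit tag
.ev <- function(v, unit = NULL) list(v = v, unit = unit)

.eval_node <- function(node, row, entity, rules) {
  switch(node$kind,
    attr = {
      name <- node$name
      if (!is.null(entity)) {
        a <- entity$attributes[[name]]
        if (is.null(a)) {
          stop("script references attribute '", name,
               "' absent from entity '", entity$name, "'")
        }
        raw <- row[[name]]
        if (is.null(raw) || .is_missing_cell(raw)) return(.ev(NA))
        if (a$data_type %in% c("int", "decimal")) {
          num <- .as_num(raw)
          if (is.na(num)) stop("non-numeric value '", raw,
                               "' in numeric attribute '", name, "'")
          return(.ev(num))
        }
        return(.ev(as.character(raw)))
      }
      if (!name %in% names(row)) {
        stop("script references attribute '", name, "' absent from the row")
      }
      raw <- row[[name]]
      if (is.null(raw) || (length(raw) == 1 && .is_missing_cell(as.character(raw))))
        return(.ev(NA))
      .ev(if (is.numeric(raw)) raw else as.character(raw))
    },
    const = .ev(node$value),
    call = {
      rec <- .eval_node(node$receiver, row, entity, rules)
      m <- node$method
      if (m == "value") return(rec)
      if (m == "map") {
        if (length(rec$v) == 1 && is.na(rec$v)) return(.ev(NA))
        key <- as.character(rec$v)
        pairs <- node$args[[1]]$pairs
        if (key %in% names(pairs)) return(.ev(unname(pairs[key])))
        return(.ev(NA))
      }
      if (m == "unit") return(.ev(rec$v, unit = node$args[[1]]$value))
      if (m == "toUnit") {
        if (is.null(rec$unit)) {
          stop("toUnit() called before unit(): no source unit is set")
        }
        to <- node$args[[1]]$value
        f <- conversion_factor(rec$unit, to, rules)
        if (length(rec$v) == 1 && is.na(rec$v)) return(.ev(NA, unit = to))
        return(.ev(.as_num(rec$v) * f, unit = to))
      }
      # arithmetic: div, times, plus, pow
      arg <- .eval_node(node$args[[1]], row, entity, rules)
      x <- rec$v; y <- arg$v
      if ((length(x) == 1 && is.na(x)) || (length(y) == 1 && is.na(y))) {
        return(.ev(NA, unit = rec$unit))
      }
      x <- .as_num(x); y <- .as_num(y)
      if (is.na(x) || is.na(y)) return(.ev(NA, unit = rec$unit))
      v <- switch(m,
        div = if (y == 0) { warning("division by zero yields null"); NA }
              else x / y,
        times = x * y,
        plus = x + y,
        pow = x^y)
      .ev(v, unit = rec$unit)
    },
    cmp = {
      l <- .eval_node(node$left, row, entity, rules)$v
      r <- .eval_node(node$right, row, entity, rules)$v
      if ((length(l) == 1 && is.na(l)) || (length(r) == 1 && is.na(r)))
        return(.ev(NA))
      ln <- .as_num(l); rn <- .as_num(r)
      if (!is.na(ln) && !is.na(rn)) {
        v <- switch(node$op, ">=" = ln >= rn, "<=" = ln <= rn, ">" = ln > rn,
                    "<" = ln < rn, "==" = ln == rn, "!=" = ln != rn)
        return(.ev(v))
      }
      if (node$op %in% c("==", "!=")) {
        eq <- identical(as.character(l), as.character(r))
        return(.ev(if (node$op == "==") eq else !eq))
      }
      .ev(NA)
    },
    logic = {
      l <- .eval_node(node$left, row, entity, rules)$v
      r <- .eval_node(node$right, row, entity, rules)$v
      lb <- if (length(l) == 1 && is.na(l)) NA else isTRUE(as.logical(l))
      rb <- if (length(r) == 1 && is.na(r)) NA else isTRUE(as.logical(r))
      .ev(if (node$op == "||") (lb | rb) else (lb & rb))
    },
    ternary = {
      c_ <- .eval_node(node$cond, row, entity, rules)$v
      if (length(c_) == 1 && is.na(c_)) return(.ev(NA))
      if (isTRUE(as.logical(c_))) .eval_node(node$yes, row, entity, rules)
      else .eval_node(node$no, row, entity, rules)
    },
    stop("unknown node kind: ", node$kind))
}

#' Evaluate a script on one data row
#'
#' Arithmetic is carried out on doubles; `map()` looks up string codes
#' (unmapped code gives null); `unit(u)` tags the running value with a
#' measurement unit and `toUnit(v)` multiplies by the corresponding
#' conversion factor. Any operation on null yields null. Referencing an
#' attribute absent from the source entity is an evaluation error (counted
#' as a failure by the integration engine); division by zero yields null
#' with a warning.
#'
#' @param script a `dsl_script` (or script text).
#' @param row named list / one-row data frame of raw (character) cell
#'   values.
#' @param source_entity the [emx_entity()] the row comes from; used for
#'   attribute existence checks and typed access. May be `NULL` for free
#'   rows.
#' @param unit_rules conversion-rule table for `toUnit()`, default
#'   [default_conversion_rules()].
#' @return a single value: number, string, or `NA` (null).
#' @export
dsl_evaluate <- function(script, row, source_entity = NULL,
                         unit_rules = default_conversion_rules()) {
  if (is.character(script)) script <- dsl_parse(script, allow_conditional = TRUE)
  res <- .eval_node(script$ast, row, source_entity, unit_rules)
  res$v
}
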