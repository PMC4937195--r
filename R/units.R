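#' @title Measurement-unit detection and conversion
#'
#' @description
#' Units are detected in attribute *labels* by exact (case-insensitive)
#' matching of tokens against the formal names, synonyms and symbols of a
#' units vocabulary (an OBO-subset file modelled on the Units of Measurement
#' Ontology). Composite/derived units such as `kg/m^2` are decomposed into
#' atomic units; atomic units detected on the target side become the
#' standard, and source atoms are converted towards them via a packaged,
#' user-overridable table of linear conversion rules (`cm = m x 100`,
#' `g = kg x 1000`, ...). Only multiplicative conversions are supported;
#' affine scales (degree Celsius/Fahrenheit) are treated as incompatible
#' because the chained arithmetic methods cannot express offsets.
#'
#' @name unit-harmonization
NULL

#' Load a units vocabulary
#'
#' Each `[Term]` is a unit; its synonym lines carry alternative spellings
#' and the formal symbol. The canonical symbol of a unit is its shortest
#' alias (e.g. `m` for meter, `kg` for kilogram).
#'
#' @param path OBO-subset file; defaults to the packaged vocabulary.
#' @return an object of class `unit_store` (also an `ontology_store`).
#' @export
load_unit_store <- function(path = .extdata("units.obo")) {
  store <- load_ontology(path)
  alias <- list()
  for (t in store$terms) {
    strings <- unique(c(t$label, t$synonyms))
    # leaf units have at least one short alias; grouping terms do not count
    if (!length(strings)) next
    symbol <- strings[order(nchar(strings), strings)][1]
    for (s in strings) alias[[tolower(s)]] <- symbol
  }
  store$alias <- alias
  class(store) <- c("unit_store", class(store))
  store
}

.default_unit_store_cache <- new.env(parent = emptyenv())

#' Packaged default units vocabulary
#' @return a `unit_store` (cached).
#' @export
default_unit_store <- function() {
  if (is.null(.default_unit_store_cache$store)) {
    .default_unit_store_cache$store <- load_unit_store()
  }
  .default_unit_store_cache$store
}

.resolve_unit_alias <- function(store, text) {
  if (is.null(store)) return(NULL)
  store$alias[[tolower(trimws(text))]]
}

# a unit is a table of (atomic symbol, signed exponent), canonically sorted
.make_unit <- function(symbols, exponents) {
  agg <- tapply(exponents, symbols, sum)
  agg <- agg[agg != 0]
  if (!length(agg)) stop("degenerate unit: all exponents cancel")
  ord <- order(names(agg))
  structure(data.frame(symbol = names(agg)[ord],
                       exponent = as.integer(agg[ord]),
                       stringsAsFactors = FALSE),
            class = c("harmonix_unit", "data.frame"))
}

#' @export
format.harmonix_unit <- function(x, ...) {
  paste(ifelse(x$exponent == 1, x$symbol,
               paste0(x$symbol, "^", x$exponent)), collapse = "\u00b7")
}

#' @export
print.harmonix_unit <- function(x, ...) {
  cat("<unit>", format(x), "\n")
  invisible(x)
}

.superscript_map <- c("\u00b2" = "^2", "\u00b3" = "^3", "\u00b9" = "^1",
                      "\u2070" = "^0", "\u2074" = "^4", "\u207b" = "-")

#' Parse a composite unit expression into atomic units
#'
#' Grammar: `atom ("^" int)? (("/" | "·" | "*" | ".") atom ("^" int)?)*`.
#' A `/` negates the exponents of every subsequent atom. Superscript digits
#' are accepted (`kg/m²` equals `kg/m^2`).
#'
#' @param text unit expression, e.g. `"kg/m^2"`.
#' @param store optional `unit_store`; when given, every atom must resolve
#'   (case-insensitively) to a known unit and is rewritten to its canonical
#'   symbol.
#' @return a `harmonix_unit`: data frame of `symbol`, `exponent`.
#' @export
parse_composite_unit <- function(text, store = NULL) {
  s <- trimws(text)
  for (ch in names(.superscript_map)) {
    s <- gsub(ch, .superscript_map[[ch]], s, fixed = TRUE)
  }
  s <- gsub("\\^-", "^@", s)        # protect exponent sign from the lexer
  pos <- 1L
  n <- nchar(s)
  symbols <- character(0); exponents <- integer(0)
  sign_mult <- 1L
  expect_atom <- TRUE
  while (pos <= n) {
    rest <- substring(s, pos)
    ws <- regmatches(rest, regexpr("^\\s+", rest))
    if (length(ws)) { pos <- pos + nchar(ws); next }
    rest <- substring(s, pos)
    if (expect_atom) {
      m <- regmatches(rest, regexpr("^[A-Za-zµ%]+", rest))
      if (!length(m)) stop("cannot parse unit expression '", text,
                           "' at position ", pos)
      atom <- m
      pos <- pos + nchar(m)
      exp_ <- 1L
      rest <- substring(s, pos)
      me <- regmatches(rest, regexpr("^\\^@?[0-9]+", rest))
      if (length(me)) {
        exp_ <- as.integer(sub("@", "-", sub("\\^", "", me)))
        pos <- pos + nchar(me)
      }
      if (!is.null(store)) {
        canon <- .resolve_unit_alias(store, atom)
        if (is.null(canon)) stop("unknown unit '", atom, "' in '", text, "'")
        atom <- canon
      }
      symbols <- c(symbols, atom)
      exponents <- c(exponents, sign_mult * exp_)
      expect_atom <- FALSE
    } else {
      ch <- substring(s, pos, pos)
      if (ch == "/") sign_mult <- -1L
      else if (!ch %in% c("\u00b7", "*", ".")) {
        stop("cannot parse unit expression '", text, "' at position ", pos)
      }
      pos <- pos + 1L
      expect_atom <- TRUE
    }
  }
  if (expect_atom) stop("cannot parse unit expression '", text, "'")
  .make_unit(symbols, exponents)
}

#' Detect the measurement unit of an attribute from its label
#'
#' The label is tokenized on whitespace and punctuation; a token (or a
#' parenthesized composite expression such as `(kg/m^2)`) counts as a unit
#' only on exact, case-insensitive equality with a unit's name, synonym or
#' symbol — no fuzzy matching, to avoid false positives. Descriptions are
#' not scanned.
#'
#' @param attr an [emx_attribute()] (or any list with a `label`).
#' @param store a `unit_store`, default the packaged vocabulary.
#' @return a `harmonix_unit` or `NULL` when no unit is present. When the
#'   label mentions two distinct units, the first is returned with
#'   attribute `ambiguous = TRUE` (and all matches under `matches`).
#' @export
detect_unit <- function(attr, store = default_unit_store()) {
  label <- attr$label
  if (is.null(label) || !nzchar(label)) return(NULL)
  found <- list()
  seen <- character(0)
  note <- function(u) {
    key <- format(u)
    if (!key %in% seen) {
      seen <<- c(seen, key)
      found[[length(found) + 1L]] <<- u
    }
  }
  # parenthesized composite expressions first
  groups <- regmatches(label, gregexpr("\\(([^()]*)\\)", label))[[1]]
  remainder <- label
  for (g in groups) {
    inner <- trimws(substring(g, 2, nchar(g) - 1))
    u <- tryCatch(parse_composite_unit(inner, store), error = function(e) NULL)
    if (!is.null(u)) {
      note(u)
      remainder <- sub(g, " ", remainder, fixed = TRUE)
    }
  }
  # multi-word unit names (e.g. "millimeter of mercury")
  for (a in names(store$alias)) {
    if (grepl(" ", a, fixed = TRUE) &&
        grepl(paste0("(?<![a-z0-9])", a, "(?![a-z0-9])"),
              tolower(remainder), perl = TRUE)) {
      note(.make_unit(store$alias[[a]], 1L))
    }
  }
  # single tokens and inline composites
  toks <- unlist(strsplit(remainder, "[\\s,;:()]+", perl = TRUE))
  toks <- toks[nzchar(toks)]
  for (tok in toks) {
    tok <- gsub("^[.,;:!?'\"]+|[.,;:!?'\"]+$", "", tok)
    if (!nzchar(tok)) next
    if (grepl("[/^\u00b7\u00b2\u00b3]", tok)) {
      u <- tryCatch(parse_composite_unit(tok, store), error = function(e) NULL)
      if (!is.null(u)) note(u)
    } else {
      canon <- .resolve_unit_alias(store, tok)
      if (!is.null(canon)) note(.make_unit(canon, 1L))
    }
  }
  if (!length(found)) return(NULL)
  out <- found[[1]]
  attr(out, "ambiguous") <- length(found) > 1
  if (length(found) > 1) attr(out, "matches") <- found
  out
}

#' Packaged conversion-rule table
#'
#' Linear rules `value_in_to = value_in_from x factor`, one row per edge;
#' the table is closed under inversion and transitive chaining by
#' [conversion_factor()].
#'
#' @param path TSV with columns `from`, `to`, `factor`; defaults to the
#'   packaged table (SI length/mass/volume/time plus common clinical
#'   units).
#' @return data frame `from`, `to`, `factor`.
#' @export
default_conversion_rules <- function(path = .extdata("conversion_rules.tsv")) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
  stopifnot(all(c("from", "to", "factor") %in% names(rules)),
            all(rules$factor > 0))
  rules
}

#' Conversion factor between two atomic units
#'
#' Returns `f` such that `value_to = value_from x f`, composing rules
#' transitively through common base units. Identical symbols give 1.
#'
#' @param from,to atomic unit symbols.
#' @param rules rule table, default [default_conversion_rules()].
#' @return positive number.
#' @export
conversion_factor <- function(from, to, rules = default_conversion_rules()) {
  if (identical(from, to)) return(1)
  known <- unique(c(rules$from, rules$to))
  for (s in c(from, to)) {
    if (!s %in% known) stop("unknown unit symbol: ", s)
  }
  # breadth-first search over the bidirectional rule graph
  edges <- rbind(
    data.frame(a = rules$from, b = rules$to, f = rules$factor,
               stringsAsFactors = FALSE),
    data.frame(a = rules$to, b = rules$from, f = 1 / rules$factor,
               stringsAsFactors = FALSE))
  frontier <- list(list(sym = from, f = 1))
  visited <- from
  while (length(frontier)) {
    nxt <- list()
    for (node in frontier) {
      out <- edges[edges$a == node$sym, , drop = FALSE]
      for (i in seq_len(nrow(out))) {
        if (out$b[i] %in% visited) next
        f2 <- node$f * out$f[i]
        if (out$b[i] == to) return(f2)
        visited <- c(visited, out$b[i])
        nxt[[length(nxt) + 1L]] <- list(sym = out$b[i], f = f2)
      }
    }
    frontier <- nxt
  }
  stop("incompatible units: no conversion path from '", from, "' to '", to, "'")
}

#' Align source atoms to the target's standard units
#'
#' The atoms detected on the target side are the standard. Each source atom
#' is matched by dimension (existence of a conversion path) to a target
#' atom and given its factor. If either side carries no unit, the units are
#' assumed equal and the plan is empty.
#'
#' @param target_unit,source_unit `harmonix_unit` objects or `NULL`.
#' @param rules conversion-rule table.
#' @return data frame `from`, `to`, `factor` (zero rows when no conversion
#'   is needed); an error when a source atom has no dimension-compatible
#'   target atom.
#' @export
align_units <- function(target_unit, source_unit,
                        rules = default_conversion_rules()) {
  empty <- data.frame(from = character(0), to = character(0),
                      factor = numeric(0), stringsAsFactors = FALSE)
  if (is.null(target_unit) || is.null(source_unit)) return(empty)
  if (identical(format(target_unit), format(source_unit))) return(empty)
  plan <- list()
  for (i in seq_len(nrow(source_unit))) {
    s <- source_unit$symbol[i]
    matched <- FALSE
    for (t in target_unit$symbol) {
      f <- tryCatch(conversion_factor(s, t, rules), error = function(e) NULL)
      if (!is.null(f)) {
        if (s != t) {
          plan[[length(plan) + 1L]] <- data.frame(
            from = s, to = t, factor = f, stringsAsFactors = FALSE)
        }
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop("incompatible units: source atom '", s,
           "' matches no target atom of ", format(target_unit))
    }
  }
  if (length(plan)) do.call(rbind, plan) else empty
}

# conversion expression fragment (no terminal), used by snippet generation
# and template filling
.conversion_expr <- function(source_attr_name, from, to, rules) {
  base <- sprintf("$('%s')", source_attr_name)
  f <- conversion_factor(from, to, rules)
  if (f == 1) return(base)
  inv <- 1 / f
  if (f < 1 && abs(inv - round(inv)) < 1e-9) {
    sprintf("%s.div(%s)", base, .num_str(round(inv)))
  } else if (abs(f - round(f)) < 1e-9) {
    sprintf("%s.times(%s)", base, .num_str(round(f)))
  } else {
    sprintf("%s.times(%s)", base, .num_str(f))
  }
}

#' Generate a unit-conversion script snippet
#'
#' Two equivalent syntaxes are produced: an explicit method chain
#' (`$('Height').unit('cm').toUnit('m').value()`) or the evaluated
#' calculation formula (`$('Height').div(100).value()`). Identical units
#' give the bare rename `$('Height').value()`.
#'
#' @param source_attr_name source attribute name.
#' @param from,to atomic unit symbols.
#' @param style `"formula"` or `"chain"`.
#' @param rules conversion-rule table.
#' @return script text (parseable by [dsl_parse()]).
#' @export
generate_unit_snippet <- function(source_attr_name, from, to,
                                  style = c("formula", "chain"),
                                  rules = default_conversion_rules()) {
  style <- match.arg(style)
  if (identical(from, to)) {
    return(sprintf("$('%s').value()", source_attr_name))
  }
  conversion_factor(from, to, rules)  # errors on incompatible dimensions
  if (style == "chain") {
    sprintf("$('%s').unit('%s').toUnit('%s').value()",
            source_attr_name, from, to)
  } else {
    paste0(.conversion_expr(source_attr_name, from, to, rules), ".value()")
  }
}
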