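#' @title Categorical value matching
#'
#' @description
#' Recoding maps between a source attribute's category codes and a target
#' attribute's codes are produced by a three-stage pipeline: (1) hard
#' rules (e.g. "never" on one side matches "no" on the other), (2)
#' frequency quantification for consumption/activity scales ("2-4 times a
#' week" has average amount 3 per week), and (3) lexical fallback by
#' character-bigram Dice similarity. Each source code maps to at most one
#' target code; many-to-one maps are allowed. The resulting map renders as
#' a `map()` snippet for the transformation language.
#'
#' @name category-harmonization
NULL

.norm_cat <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

.bigrams <- function(s) {
  if (!nzchar(s)) return(character(0))
  padded <- paste0(" ", s, " ")
  n <- nchar(padded)
  substring(padded, 1:(n - 1), 2:n)
}

#' Character-bigram Dice similarity between two strings
#'
#' Strings are normalized (lowercased, punctuation stripped), padded with
#' one space on each side, and decomposed into character bigrams; the
#' score is the Dice coefficient of the two bigram multisets. Symmetric,
#' bounded in \[0, 1\], and exactly 1 when the normalized strings are
#' equal.
#'
#' @param a,b strings (empty allowed).
#' @return similarity in \[0, 1\].
#' @export
ngram_similarity <- function(a, b) {
  na_ <- .norm_cat(a); nb <- .norm_cat(b)
  if (identical(na_, nb)) return(1)
  A <- .bigrams(na_); B <- .bigrams(nb)
  if (!length(A) || !length(B)) return(0)
  ta <- table(A); tb <- table(B)
  shared <- intersect(names(ta), names(tb))
  inter <- sum(pmin(ta[shared], tb[shared]))
  2 * inter / (length(A) + length(B))
}

.as_cats <- function(cats) {
  data.frame(code = as.character(cats$code), label = as.character(cats$label),
              stringsAsFactors = FALSE)
}

.empty_pairs <- function() {
  data.frame(source_code = character(0), target_code = character(0),
             provenance = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

.category_map <- function(pairs, unmapped = character(0)) {
  structure(list(pairs = pairs, unmapped = unmapped), class = "category_map")
}

#' @export
print.category_map <- function(x, ...) {
  cat("category map:", nrow(x$pairs), "pairs\n")
  if (nrow(x$pairs)) {
    for (i in seq_len(nrow(x$pairs))) {
      cat(sprintf("  '%s' -> %s  [%s]\n", x$pairs$source_code[i],
                  ifelse(is.na(x$pairs$target_code[i]), "null",
                         sprintf("'%s'", x$pairs$target_code[i])),
                  x$pairs$provenance[i]))
    }
  }
  if (length(x$unmapped)) {
    cat("  unmapped:", paste(x$unmapped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Lexical category matching
#'
#' Every source category is assigned the target category with the best
#' bigram-Dice similarity between labels; ties are broken by the lowest
#' target code. Many source categories may share one target.
#'
#' @param target_cats,source_cats data frames with character columns
#'   `code`, `label` (both non-empty).
#' @return a `category_map` with per-pair `lexical` provenance and scores.
#' @export
match_lexical <- function(target_cats, source_cats) {
  target_cats <- .as_cats(target_cats); source_cats <- .as_cats(source_cats)
  stopifnot(nrow(target_cats) > 0, nrow(source_cats) > 0)
  pairs <- lapply(seq_len(nrow(source_cats)), function(i) {
    sims <- vapply(target_cats$label, function(tl)
      ngram_similarity(source_cats$label[i], tl), numeric(1))
    best <- max(sims)
    cand <- which(sims == best)
    pick <- cand[order(target_cats$code[cand])][1]
    data.frame(source_code = source_cats$code[i],
               target_code = target_cats$code[pick],
               provenance = "lexical", score = best, stringsAsFactors = FALSE)
  })
  .category_map(do.call(rbind, pairs))
}

.time_unit_days <- c(day = 1, week = 7, month = 30.44, year = 365.25)

#' Extract a quantified frequency from a category label
#'
#' Recognized shapes (case-insensitive; hyphen, en- and em-dash ranges):
#' `"N times a/per U"`, `"N-M times a/per U"` (amount `(N+M)/2`),
#' `"once/twice a U"`, bare `"daily"/"weekly"/"monthly"/"yearly"` and
#' `"every U"`, with U a day/week/month/year time unit. The amount is
#' normalized to a per-day rate using calendar averages (week = 7,
#' month = 30.44, year = 365.25 days).
#'
#' @param label category label.
#' @return list with `amount`, `time_unit`, `rate_per_day` (class
#'   `frequency_amount`), or `NULL` when the label is not a frequency.
#' @export
parse_frequency <- function(label) {
  s <- tolower(trimws(label))
  s <- gsub("[\u2013\u2014\u2212]", "-", s)
  num <- "([0-9]+(?:\\.[0-9]+)?)"
  unit <- "(day|week|month|year)s?"
  hit <- function(amount, time_unit) {
    structure(list(amount = amount, time_unit = time_unit,
                   rate_per_day = amount / .time_unit_days[[time_unit]]),
              class = "frequency_amount")
  }
  m <- regmatches(s, regexec(paste0(
    num, "\\s*-\\s*", num, "\\s*(?:times?|x)?\\s*(?:a|an|per|each|every)?\\s*",
    unit), s))[[1]]
  if (length(m)) {
    return(hit((as.numeric(m[2]) + as.numeric(m[3])) / 2, m[4]))
  }
  m <- regmatches(s, regexec(paste0(
    num, "\\s*(?:times?|x)\\s*(?:a|an|per|each|every)\\s*", unit), s))[[1]]
  if (length(m)) return(hit(as.numeric(m[2]), m[3]))
  m <- regmatches(s, regexec(paste0(num, "\\s*(?:a|per)\\s+", unit), s))[[1]]
  if (length(m)) return(hit(as.numeric(m[2]), m[3]))
  m <- regmatches(s, regexec(paste0(
    "(once|twice)\\s*(?:a|an|per|each|every)\\s*", unit), s))[[1]]
  if (length(m)) return(hit(if (m[2] == "twice") 2 else 1, m[3]))
  m <- regmatches(s, regexec("^(daily|weekly|monthly|yearly|annually)$", s))[[1]]
  if (length(m)) {
    u <- c(daily = "day", weekly = "week", monthly = "month",
           yearly = "year", annually = "year")[[m[2]]]
    return(hit(1, u))
  }
  m <- regmatches(s, regexec(paste0("^every\\s+", unit, "$"), s))[[1]]
  if (length(m)) return(hit(1, m[2]))
  NULL
}

# frequency matching restricted to categories that actually parse
.match_frequency_core <- function(target_cats, source_cats) {
  tf <- lapply(target_cats$label, parse_frequency)
  ok_t <- which(!vapply(tf, is.null, logical(1)))
  pairs <- list()
  leftovers <- character(0)
  for (i in seq_len(nrow(source_cats))) {
    f <- parse_frequency(source_cats$label[i])
    if (is.null(f) || !length(ok_t)) {
      leftovers <- c(leftovers, source_cats$code[i])
      next
    }
    rates <- vapply(tf[ok_t], `[[`, numeric(1), "rate_per_day")
    d <- abs(rates - f$rate_per_day)
    cand <- ok_t[d == min(d)]
    # nearest rate; ties -> lower target rate, then lower code
    if (length(cand) > 1) {
      cr <- vapply(tf[cand], `[[`, numeric(1), "rate_per_day")
      cand <- cand[cr == min(cr)]
      cand <- cand[order(target_cats$code[cand])]
    }
    pick <- cand[1]
    pairs[[length(pairs) + 1L]] <- data.frame(
      source_code = source_cats$code[i], target_code = target_cats$code[pick],
      provenance = "frequency", score = NA_real_, stringsAsFactors = FALSE)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs) else .empty_pairs(),
       leftovers = leftovers)
}

#' Frequency-based category matching
#'
#' Both category sets are quantified with [parse_frequency()]; each source
#' amount maps to the target amount with the nearest per-day rate
#' (many-to-one allowed; rate ties resolve to the lower target rate).
#' Categories that do not parse as frequencies fall back to lexical
#' matching against all targets.
#'
#' @inheritParams match_lexical
#' @return a `category_map` with `frequency` (and possibly `lexical`)
#'   provenance.
#' @export
match_frequency <- function(target_cats, source_cats) {
  target_cats <- .as_cats(target_cats); source_cats <- .as_cats(source_cats)
  core <- .match_frequency_core(target_cats, source_cats)
  pairs <- core$pairs
  if (length(core$leftovers)) {
    lex <- match_lexical(target_cats,
                         source_cats[source_cats$code %in% core$leftovers, ,
                                     drop = FALSE])
    pairs <- rbind(pairs, lex$pairs)
  }
  pairs <- pairs[order(match(pairs$source_code, source_cats$code)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  .category_map(pairs)
}

#' Packaged hard category-matching rules
#'
#' @param path TSV with columns `source_pattern`, `target_pattern`,
#'   `priority`; defaults to the packaged table (never/no, ever/yes,
#'   missing-to-null). Fully user-overridable.
#' @return data frame of rules.
#' @export
default_category_rules <- function(path = .extdata("category_rules.tsv")) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#", na.strings = NULL,
                             colClasses = c("character", "character", "integer"))
  stopifnot(all(c("source_pattern", "target_pattern", "priority") %in%
                  names(rules)))
  rules
}

#' Apply hard matching rules to category sets
#'
#' Rules are regular expressions over labels, evaluated before the other
#' matchers; pairs they fix are final. An empty target pattern maps the
#' source category to null (`NA` target code). Two applicable rules of
#' equal priority that disagree are a configuration error.
#'
#' @inheritParams match_lexical
#' @param rules rule table, see [default_category_rules()].
#' @return a partial `category_map` (only rule-fixed pairs).
#' @export
apply_rules <- function(target_cats, source_cats,
                        rules = default_category_rules()) {
  target_cats <- .as_cats(target_cats); source_cats <- .as_cats(source_cats)
  pairs <- list()
  if (is.null(rules) || nrow(rules) == 0) return(.category_map(.empty_pairs()))
  for (i in seq_len(nrow(source_cats))) {
    lab <- source_cats$label[i]
    hits <- which(vapply(rules$source_pattern, function(p)
      grepl(p, lab, ignore.case = TRUE, perl = TRUE), logical(1)))
    if (!length(hits)) next
    hits <- hits[rules$priority[hits] == max(rules$priority[hits])]
    resolved <- lapply(hits, function(h) {
      tp <- rules$target_pattern[h]
      if (!nzchar(tp)) return(NA_character_)
      tm <- which(vapply(target_cats$label, function(tl)
        grepl(tp, tl, ignore.case = TRUE, perl = TRUE), logical(1)))
      if (!length(tm)) return(NULL)  # rule not applicable to these targets
      exact <- tm[.norm_cat(target_cats$label[tm]) == .norm_cat(lab)]
      pick <- if (length(exact)) exact[1] else tm[order(target_cats$code[tm])][1]
      target_cats$code[pick]
    })
    resolved <- resolved[!vapply(resolved, is.null, logical(1))]
    if (!length(resolved)) next
    distinct <- unique(vapply(resolved, function(x)
      ifelse(is.na(x), "\r<null>", x), character(1)))
    if (length(distinct) > 1) {
      stop("conflicting category rules of equal priority for label '",
           lab, "'")
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      source_code = source_cats$code[i], target_code = resolved[[1]],
      provenance = "rule", score = NA_real_, stringsAsFactors = FALSE)
  }
  .category_map(if (length(pairs)) do.call(rbind, pairs) else .empty_pairs())
}

#' Full category-matching pipeline
#'
#' Rules are applied first; the remaining source categories are matched by
#' frequency when both sides quantify, and lexically otherwise. Every pair
#' carries exactly one provenance tag (`rule` > `frequency` > `lexical`).
#' Source categories mapped to null by a rule are listed under `unmapped`.
#'
#' @inheritParams apply_rules
#' @return a `category_map`.
#' @export
match_categories <- function(target_cats, source_cats,
                             rules = default_category_rules()) {
  target_cats <- .as_cats(target_cats); source_cats <- .as_cats(source_cats)
  fixed <- apply_rules(target_cats, source_cats, rules)
  done <- fixed$pairs$source_code
  rest <- source_cats[!source_cats$code %in% done, , drop = FALSE]
  pairs <- fixed$pairs
  if (nrow(rest)) {
    parses <- !vapply(lapply(rest$label, parse_frequency), is.null, logical(1))
    t_parses <- any(!vapply(lapply(target_cats$label, parse_frequency),
                            is.null, logical(1)))
    if (any(parses) && t_parses) {
      fr <- .match_frequency_core(target_cats, rest[parses, , drop = FALSE])
      pairs <- rbind(pairs, fr$pairs)
      rest <- rest[!parses, , drop = FALSE]
    }
    if (nrow(rest)) {
      lex <- match_lexical(target_cats, rest)
      pairs <- rbind(pairs, lex$pairs)
    }
  }
  pairs <- pairs[order(match(pairs$source_code, source_cats$code)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  null_mapped <- pairs$source_code[is.na(pairs$target_code)]
  .category_map(pairs[!is.na(pairs$target_code), , drop = FALSE],
                unmapped = null_mapped)
}

#' Render a category map as a `map()` snippet
#'
#' @param map a `category_map` with at least one (non-null) pair.
#' @param source_attr_name source attribute name for the accessor.
#' @return script text `"$('SRC').map({'s1':'t1',...})"`, pairs ordered by
#'   source code; an error when the map is empty.
#' @export
generate_map_snippet <- function(map, source_attr_name) {
  pairs <- map$pairs[!is.na(map$pairs$target_code), , drop = FALSE]
  if (nrow(pairs) == 0) stop("cannot generate map(): the category map is empty")
  pairs <- pairs[order(pairs$source_code), , drop = FALSE]
  literal <- paste(sprintf("'%s':'%s'", pairs$source_code, pairs$target_code),
                   collapse = ",")
  sprintf("$('%s').map({%s})", source_attr_name, literal)
}
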