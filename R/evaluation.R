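#' @title Scoring matches and algorithms against a gold standard
#'
#' @description
#' Quality is scored separately for the search and the generated
#' algorithms, with three classes each. Search: `perfect` when a
#' human-matched source attribute ranks first; `good` when every
#' human-matched attribute appears within the top 20 of the shortlist;
#' `bad` otherwise. Algorithm: `perfect` when the generated script is
#' textually identical or functionally equivalent to the hand-curated
#' reference (same values on every row of the source data); `good` when it
#' is almost right (at least half the reference map pairs present and none
#' contradicted, or the right source attribute with a wrong/missing
#' conversion); `bad` otherwise. A result is *useful* when both classes
#' are perfect/good, or when one side is perfect while the other failed.
#'
#' @name evaluation
NULL

#' Read / write a gold standard
#'
#' Tab-separated with columns `target`, `source`, `source_attrs`
#' (semicolon-separated attribute names) and `reference_script`.
#'
#' @param path TSV file.
#' @return data frame of gold mappings.
#' @export
read_gold <- function(path) {
  gold <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  stopifnot(all(c("target", "source", "source_attrs", "reference_script")
                %in% names(gold)))
  gold
}

#' @rdname read_gold
#' @param gold data frame of gold mappings.
#' @export
write_gold <- function(gold, path) {
  utils::write.table(gold, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Classify a shortlist result against the gold standard
#'
#' @param candidates a `match_candidates` data frame (may be `NULL`).
#' @param gold_attrs character vector of human-matched source attribute
#'   names.
#' @param k the "good search" window (default 20).
#' @return `"perfect"`, `"good"` or `"bad"`.
#' @export
classify_search <- function(candidates, gold_attrs, k = 20) {
  stopifnot(length(gold_attrs) > 0)
  if (is.null(candidates) || nrow(candidates) == 0) return("bad")
  ranks <- candidates$rank[match(gold_attrs, candidates$name)]
  if (any(!is.na(ranks) & ranks == 1)) return("perfect")
  if (!anyNA(ranks) && all(ranks <= k)) return("good")
  "bad"
}

#' Functional equivalence of two scripts on a dataset
#'
#' Two algorithms are functionally equivalent when they yield the same
#' target values on every row of the source data: numbers within 1e-9
#' (relative for large magnitudes), strings and nulls exactly.
#'
#' @param a,b `dsl_script` objects (or script text).
#' @param data an [emx_entity()] providing the rows.
#' @param unit_rules conversion rules.
#' @return logical.
#' @export
functionally_equivalent <- function(a, b, data,
                                    unit_rules = default_conversion_rules()) {
  if (is.character(a)) a <- dsl_parse(a, allow_conditional = TRUE)
  if (is.character(b)) b <- dsl_parse(b, allow_conditional = TRUE)
  same_value <- function(x, y) {
    xna <- length(x) != 1 || is.na(x); yna <- length(y) != 1 || is.na(y)
    if (xna || yna) return(xna && yna)
    xn <- .as_num(x); yn <- .as_num(y)
    if (!is.na(xn) && !is.na(yn)) {
      return(abs(xn - yn) <= 1e-9 * max(1, abs(xn), abs(yn)))
    }
    identical(as.character(x), as.character(y))
  }
  for (i in seq_len(nrow(data$data))) {
    row <- as.list(data$data[i, , drop = FALSE])
    va <- tryCatch(suppressWarnings(dsl_evaluate(a, row, data, unit_rules)),
                   error = function(e) structure(NA, failed = TRUE))
    vb <- tryCatch(suppressWarnings(dsl_evaluate(b, row, data, unit_rules)),
                   error = function(e) structure(NA, failed = TRUE))
    if (isTRUE(attr(va, "failed")) != isTRUE(attr(vb, "failed"))) return(FALSE)
    if (!same_value(va, vb)) return(FALSE)
  }
  TRUE
}

# first map() literal of a script, or NULL
.script_map_pairs <- function(script) {
  found <- NULL
  walk <- function(node) {
    if (!is.null(found) || !is.list(node) || is.null(node$kind)) return()
    if (node$kind == "call" && node$method == "map") {
      found <<- node$args[[1]]$pairs
      return()
    }
    for (child in node[c("receiver", "args", "left", "right", "cond",
                         "yes", "no")]) {
      if (is.null(child)) next
      if (is.list(child) && is.null(child$kind)) lapply(child, walk)
      else walk(child)
    }
  }
  walk(script$ast)
  found
}

#' Classify a generated algorithm against the reference
#'
#' @param generated a `generated_algorithm` (or `NULL` when none was
#'   generated).
#' @param reference the hand-curated reference `dsl_script` (or text).
#' @param data the source [emx_entity()] used for functional comparison.
#' @param unit_rules conversion rules.
#' @return `"perfect"`, `"good"` or `"bad"`.
#' @export
classify_algorithm <- function(generated, reference, data,
                               unit_rules = default_conversion_rules()) {
  if (is.character(reference)) {
    reference <- dsl_parse(reference, allow_conditional = TRUE)
  }
  if (is.null(generated)) return("bad")
  gen <- if (inherits(generated, "generated_algorithm")) generated$script
         else generated
  if (is.character(gen)) gen <- dsl_parse(gen, allow_conditional = TRUE)
  if (identical(gen$text, reference$text) ||
      functionally_equivalent(gen, reference, data, unit_rules)) {
    return("perfect")
  }
  gmap <- .script_map_pairs(gen); rmap <- .script_map_pairs(reference)
  if (!is.null(gmap) && !is.null(rmap)) {
    shared <- intersect(names(gmap), names(rmap))
    agree <- sum(gmap[shared] == rmap[shared])
    contradicted <- sum(gmap[shared] != rmap[shared])
    if (contradicted == 0 && agree >= ceiling(length(rmap) / 2)) {
      return("good")
    }
    return("bad")
  }
  if (setequal(gen$referenced_attributes, reference$referenced_attributes)) {
    return("good")  # right source attribute(s), wrong/missing conversion
  }
  "bad"
}

.eval_classes <- c("perfect", "good", "bad")

#' Evaluate a mapping project against a gold standard
#'
#' Every gold mapping is scored with [classify_search()] (on the cell's
#' shortlist) and [classify_algorithm()] (against the reference script on
#' the source data), and the classes are cross-tabulated in percentages.
#' The *useful* total sums the four perfect/good cells plus
#' (bad search, perfect algorithm) and (perfect search, bad algorithm).
#'
#' @param project a `mapping_project` (with candidates populated).
#' @param gold data frame as in [read_gold()].
#' @param k top-k window for the search classes.
#' @return an `evaluation_report`: per-target data frame, percentage
#'   cross-tab (search x algorithm) and `useful_pct`.
#' @export
evaluate_project <- function(project, gold, k = 20) {
  rows <- list()
  for (i in seq_len(nrow(gold))) {
    g <- gold[i, ]
    if (!g$source %in% names(project$cells)) next
    cell <- project$cells[[g$source]][[g$target]]
    gold_attrs <- trimws(strsplit(g$source_attrs, ";")[[1]])
    search_class <- classify_search(cell$candidates, gold_attrs, k)
    reference <- dsl_parse(g$reference_script, allow_conditional = TRUE)
    entity <- .resolve_entity(project$sources[[g$source]],
                              reference$referenced_attributes)
    if (is.null(entity)) {
      stop("gold reference for '", g$target, "'/'", g$source,
           "' references attributes absent from the source schema")
    }
    algorithm_class <- classify_algorithm(
      if (is.null(cell)) NULL else cell$algorithm, reference, entity)
    rows[[length(rows) + 1L]] <- data.frame(
      target = g$target, source = g$source, search_class = search_class,
      algorithm_class = algorithm_class, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no gold mapping references a source present in the project ",
         "(project sources: ", paste(names(project$cells), collapse = ", "),
         "; gold sources: ", paste(unique(gold$source), collapse = ", "), ")")
  }
  per_target <- do.call(rbind, rows)
  tab <- table(factor(per_target$search_class, levels = .eval_classes),
               factor(per_target$algorithm_class, levels = .eval_classes),
               dnn = c("search", "algorithm"))
  pct <- 100 * tab / sum(tab)
  useful_pct <- sum(pct[c("perfect", "good"), c("perfect", "good")]) +
    pct["bad", "perfect"] + pct["perfect", "bad"]
  structure(list(per_target = per_target, table_pct = pct,
                 useful_pct = useful_pct, n = nrow(per_target)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation of", x$n, "gold mappings (percentages):\n")
  print(round(x$table_pct, 1))
  cat(sprintf("useful: %.1f%%\n", x$useful_pct))
  invisible(x)
}
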