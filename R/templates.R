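#' @title Algorithm templates
#'
#' @description
#' Complex target attributes with a recurring definition (body-mass index,
#' hypertension cutoffs) are generated from reusable templates. A template
#' names the target concepts that trigger it, its building-block slots —
#' each with the measurement unit the slot is standardized to — and a
#' script body with `$('<slot>')` placeholders. Filling a template picks
#' the best-matching shortlist candidate for each slot by bigram
#' similarity, inserts the unit conversions the slots require, and
#' substitutes the converted attribute accessors into the body.
#'
#' @name algorithm-templates
NULL

#' Load a template catalogue from a YAML file
#'
#' Validates that every `$('slot')` placeholder in a body corresponds to a
#' declared slot and that every slot unit parses.
#'
#' @param path YAML file; see the packaged `templates.yaml` for the shape.
#' @return object of class `template_catalogue` (list of templates).
#' @export
load_template_catalogue <- function(path = .extdata("templates.yaml")) {
  raw <- yaml::read_yaml(path)
  templates <- lapply(raw$templates, function(t) {
    stopifnot(!is.null(t$name), !is.null(t$slots), !is.null(t$body))
    placeholders <- regmatches(t$body,
                               gregexpr("\\$\\('([^']+)'\\)", t$body))[[1]]
    slot_refs <- unique(gsub("\\$\\('|'\\)", "", placeholders))
    unknown <- setdiff(slot_refs, names(t$slots))
    if (length(unknown)) {
      stop("template '", t$name, "' body references undeclared slot(s): ",
           paste(unknown, collapse = ", "))
    }
    for (sn in names(t$slots)) {
      parse_composite_unit(t$slots[[sn]]$unit)  # must parse
    }
    t$conditional <- isTRUE(t$conditional)
    structure(t, class = "algorithm_template")
  })
  names(templates) <- vapply(templates, `[[`, character(1), "name")
  structure(templates, class = "template_catalogue")
}

.default_catalogue_cache <- new.env(parent = emptyenv())

#' Packaged default template catalogue (BMI, hypertension)
#' @return a `template_catalogue` (cached).
#' @export
default_template_catalogue <- function() {
  if (is.null(.default_catalogue_cache$cat)) {
    .default_catalogue_cache$cat <- load_template_catalogue()
  }
  .default_catalogue_cache$cat
}

# best bigram similarity between a slot (any synonym) and a candidate
# label, compared against the full label, its tokens and adjacent token
# pairs so that a one-word slot name can match inside a long label
.slot_similarity <- function(candidate_label, synonyms) {
  toks <- .tokenize(candidate_label, drop_stopwords = FALSE)
  views <- c(candidate_label, toks,
             if (length(toks) > 1) paste(toks[-length(toks)], toks[-1]))
  best <- 0
  for (syn in synonyms) {
    for (v in views) best <- max(best, ngram_similarity(syn, v))
  }
  best
}

#' Find an applicable template for a target attribute
#'
#' A template is proposed when the target label contains all tokens of one
#' of the template's trigger phrases (basis `"target"`), or — failing that
#' — when at least one shortlist candidate matches a slot name above the
#' similarity threshold (basis `"candidate"`). The automatic generator
#' applies only target-triggered templates; candidate-triggered ones are
#' proposals for the curating user.
#'
#' @param target an [emx_attribute()].
#' @param catalogue a `template_catalogue`.
#' @param candidates optional `match_candidates` for the candidate basis.
#' @param threshold slot-trigger bigram-similarity threshold (default 0.5).
#' @return the matching `algorithm_template` with attribute `basis`, or
#'   `NULL`.
#' @export
find_template <- function(target, catalogue = default_template_catalogue(),
                          candidates = NULL, threshold = 0.5) {
  label_tokens <- .tokenize(target$label)
  for (t in catalogue) {
    for (trig in t$triggers) {
      tt <- .tokenize(trig)
      if (length(tt) && all(tt %in% label_tokens)) {
        attr(t, "basis") <- "target"
        return(t)
      }
    }
  }
  if (!is.null(candidates) && nrow(candidates)) {
    for (t in catalogue) {
      for (sn in names(t$slots)) {
        syns <- unique(c(sn, unlist(t$slots[[sn]]$synonyms)))
        sims <- vapply(candidates$label, .slot_similarity, numeric(1),
                       synonyms = syns)
        if (any(sims >= threshold)) {
          attr(t, "basis") <- "candidate"
          return(t)
        }
      }
    }
  }
  NULL
}

#' Fill a template's slots from shortlist candidates
#'
#' Slots are assigned greedily to distinct candidates in decreasing
#' bigram-similarity order; every slot must reach the threshold. The
#' detected unit of each chosen candidate is converted towards the slot's
#' standard unit and the converted accessor replaces the placeholder.
#'
#' @param template an `algorithm_template`.
#' @param candidates a `match_candidates` data frame.
#' @param unit_rules conversion-rule table.
#' @param unit_store units vocabulary for detection.
#' @param threshold minimum slot similarity (default 0.5).
#' @return a `generated_algorithm` (provenance `template`), or `NULL` when
#'   a slot cannot be filled (no candidate above threshold, or an
#'   incompatible unit).
#' @export
fill_template <- function(template, candidates,
                          unit_rules = default_conversion_rules(),
                          unit_store = default_unit_store(),
                          threshold = 0.5) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  slot_names <- names(template$slots)
  sims <- matrix(0, nrow = length(slot_names), ncol = nrow(candidates),
                 dimnames = list(slot_names, NULL))
  for (sn in slot_names) {
    syns <- unique(c(sn, unlist(template$slots[[sn]]$synonyms)))
    sims[sn, ] <- vapply(candidates$label, .slot_similarity, numeric(1),
                         synonyms = syns)
  }
  assignment <- setNames(rep(NA_integer_, length(slot_names)), slot_names)
  free_slots <- slot_names
  free_cands <- seq_len(nrow(candidates))
  while (length(free_slots) && length(free_cands)) {
    sub <- sims[free_slots, free_cands, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    if (max(sub) < threshold) break
    slot <- free_slots[best[1]]
    cand <- free_cands[best[2]]
    assignment[slot] <- cand
    free_slots <- setdiff(free_slots, slot)
    free_cands <- setdiff(free_cands, cand)
  }
  if (anyNA(assignment)) return(NULL)  # unfillable slot -> template failure
  body <- template$body
  for (sn in slot_names) {
    i <- assignment[[sn]]
    expected <- parse_composite_unit(template$slots[[sn]]$unit, unit_store)
    detected <- detect_unit(list(label = candidates$label[i]), unit_store)
    expr <- sprintf("$('%s')", candidates$name[i])
    if (!is.null(detected) && !identical(format(detected), format(expected))) {
      if (nrow(detected) != 1 || nrow(expected) != 1) return(NULL)
      f <- tryCatch(conversion_factor(detected$symbol, expected$symbol,
                                      unit_rules),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)  # wrong dimension for this slot
      expr <- .conversion_expr(candidates$name[i], detected$symbol,
                               expected$symbol, unit_rules)
    }
    body <- gsub(sprintf("$('%s')", sn), expr, body, fixed = TRUE)
  }
  script <- dsl_parse(body, allow_conditional = template$conditional)
  used <- candidates[assignment, , drop = FALSE]
  .generated_algorithm(script = script, provenance = "template",
                       used_candidates = used, template = template$name)
}
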