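#' @title Automatic algorithm generation and mapping projects
#'
#' @description
#' For every target attribute the generator runs the full pipeline:
#' shortlist candidates with the expanded query, try a target-triggered
#' algorithm template, and otherwise fall back — in fixed order — to a
#' categorical recoding map, a unit conversion, or a bare rename of the
#' best candidate. A mapping project holds one generated (or curated)
#' algorithm per target attribute and source; curated cells survive
#' regeneration.
#'
#' @name algorithm-generator
NULL

.generated_algorithm <- function(script, provenance, used_candidates,
                                 confidence = NA_character_,
                                 target = NULL, template = NA_character_) {
  refs <- script$referenced_attributes
  if (!all(refs %in% used_candidates$name)) {
    stop("generated script references attributes outside its candidates: ",
         paste(setdiff(refs, used_candidates$name), collapse = ", "))
  }
  structure(list(target = target, script = script, provenance = provenance,
                 used_candidates = used_candidates, confidence = confidence,
                 template = template),
            class = "generated_algorithm")
}

#' @export
print.generated_algorithm <- function(x, ...) {
  cat(sprintf("<algorithm %s/%s> %s\n", x$provenance,
              ifelse(is.na(x$confidence), "?", x$confidence), x$script$text))
  invisible(x)
}

#' Generate a transformation algorithm for one target attribute
#'
#' Pipeline: shortlist candidates; if a template is triggered by the
#' target and fills, use it; otherwise take the best candidate and emit a
#' category map (categorical target and source), a unit-conversion snippet
#' (detected units differ), or a bare rename. If only one side carries a
#' unit the units are assumed equal and no conversion is inserted.
#'
#' @param target an [emx_attribute()].
#' @param source_schema the source [emx_schema()].
#' @param index optional prebuilt [index_source()] index.
#' @param store `ontology_store` for query expansion (or `NULL`).
#' @param catalogue template catalogue.
#' @param cat_rules category-rule table.
#' @param unit_rules conversion-rule table.
#' @param unit_store units vocabulary.
#' @param k shortlist size.
#' @param unit_style `"formula"` (`div()`/`times()`) or `"chain"`
#'   (`unit().toUnit()`).
#' @return a `generated_algorithm` (with the shortlist attached as
#'   attribute `"candidates"`), or `NULL` when there are no candidates.
#' @export
generate_algorithm <- function(target, source_schema, index = NULL,
                               store = NULL,
                               catalogue = default_template_catalogue(),
                               cat_rules = default_category_rules(),
                               unit_rules = default_conversion_rules(),
                               unit_store = default_unit_store(),
                               k = 20, unit_style = "formula") {
  if (is.null(index)) index <- index_source(source_schema)
  cands <- shortlist(target, index, store, k = k)
  if (nrow(cands) == 0) return(NULL)
  confidence <- classify_confidence(cands, target)
  finish <- function(alg) {
    if (is.null(alg)) return(NULL)
    alg$target <- target
    alg$confidence <- confidence
    attr(alg, "candidates") <- cands
    alg
  }

  tmpl <- find_template(target, catalogue, cands)
  if (!is.null(tmpl) && identical(attr(tmpl, "basis"), "target")) {
    filled <- fill_template(tmpl, cands, unit_rules, unit_store)
    if (!is.null(filled)) return(finish(filled))
  }

  best <- cands[1, , drop = FALSE]
  src <- get_attribute(source_schema, best$name, best$entity)

  if (target$data_type %in% c("categorical", "xref") &&
      src$data_type %in% c("categorical", "xref") &&
      !is.null(target$categories) && !is.null(src$categories)) {
    map <- match_categories(target$categories, src$categories, cat_rules)
    if (nrow(map$pairs)) {
      snippet <- generate_map_snippet(map, src$name)
      return(finish(.generated_algorithm(
        script = dsl_parse(snippet), provenance = "category_map",
        used_candidates = best)))
    }
  }

  t_u <- detect_unit(target, unit_store)
  s_u <- detect_unit(src, unit_store)
  plan <- tryCatch(align_units(t_u, s_u, unit_rules), error = function(e) NULL)
  if (!is.null(plan) && nrow(plan) == 1) {
    snippet <- generate_unit_snippet(src$name, plan$from, plan$to,
                                     style = unit_style, rules = unit_rules)
    return(finish(.generated_algorithm(
      script = dsl_parse(snippet), provenance = "unit_conversion",
      used_candidates = best)))
  }
  # no conversion needed/derivable: plain rename of the best candidate
  finish(.generated_algorithm(
    script = dsl_parse(sprintf("$('%s').value()", src$name)),
    provenance = "rename", used_candidates = best))
}

.cell_state <- function(alg, curated = FALSE) {
  if (curated) return("curated")
  if (is.null(alg)) return("missing")
  if (identical(alg$confidence, "high")) "generated-high" else "generated-low"
}

#' Generate a complete mapping project
#'
#' One cell per (target attribute x source); each holds the generated
#' algorithm (or none), the candidate shortlist, and a state among
#' `generated-high`, `generated-low`, `curated`, `missing`.
#'
#' @param target_schema the target [emx_schema()].
#' @param sources named list of source [emx_schema()]s.
#' @param target_entity entity of `target_schema` holding the target
#'   attributes; defaults to the first entity.
#' @inheritParams generate_algorithm
#' @return an object of class `mapping_project`.
#' @export
generate_project <- function(target_schema, sources, store = NULL,
                             target_entity = NULL,
                             catalogue = default_template_catalogue(),
                             cat_rules = default_category_rules(),
                             unit_rules = default_conversion_rules(),
                             unit_store = default_unit_store(),
                             k = 20, unit_style = "formula") {
  stopifnot(length(sources) > 0, !is.null(names(sources)))
  if (is.null(target_entity)) target_entity <- names(target_schema$entities)[1]
  tent <- target_schema$entities[[target_entity]]
  project <- structure(list(
    target_schema = target_schema, target_entity = target_entity,
    sources = sources, store = store,
    settings = list(catalogue = catalogue, cat_rules = cat_rules,
                    unit_rules = unit_rules, unit_store = unit_store,
                    k = k, unit_style = unit_style),
    cells = list()), class = "mapping_project")
  regenerate_project(project)
}

#' Regenerate the algorithms of a mapping project
#'
#' Recomputes every cell except those curated by hand (unless
#' `force = TRUE`).
#'
#' @param project a `mapping_project`.
#' @param force overwrite curated cells too.
#' @return the updated project.
#' @export
regenerate_project <- function(project, force = FALSE) {
  tent <- project$target_schema$entities[[project$target_entity]]
  s <- project$settings
  for (sn in names(project$sources)) {
    index <- index_source(project$sources[[sn]])
    if (is.null(project$cells[[sn]])) project$cells[[sn]] <- list()
    for (an in names(tent$attributes)) {
      old <- project$cells[[sn]][[an]]
      if (!is.null(old) && identical(old$state, "curated") && !force) next
      alg <- generate_algorithm(tent$attributes[[an]], project$sources[[sn]],
                                index = index, store = project$store,
                                catalogue = s$catalogue,
                                cat_rules = s$cat_rules,
                                unit_rules = s$unit_rules,
                                unit_store = s$unit_store,
                                k = s$k, unit_style = s$unit_style)
      project$cells[[sn]][[an]] <- list(
        algorithm = alg,
        candidates = if (is.null(alg)) NULL else attr(alg, "candidates"),
        state = .cell_state(alg))
    }
  }
  project
}

#' Replace a cell's algorithm with a hand-curated script
#'
#' @param project a `mapping_project`.
#' @param source source name.
#' @param target_attr target attribute name.
#' @param script_text script for the cell (conditional syntax allowed).
#' @return the updated project; the cell state becomes `curated` and is
#'   preserved by [regenerate_project()].
#' @export
curate_cell <- function(project, source, target_attr, script_text) {
  stopifnot(source %in% names(project$sources))
  tent <- project$target_schema$entities[[project$target_entity]]
  stopifnot(target_attr %in% names(tent$attributes))
  script <- dsl_parse(script_text, allow_conditional = TRUE)
  old <- project$cells[[source]][[target_attr]]
  project$cells[[source]][[target_attr]] <- list(
    algorithm = structure(list(target = tent$attributes[[target_attr]],
                               script = script, provenance = "curated",
                               used_candidates = NULL, confidence = NA,
                               template = NA),
                          class = "generated_algorithm"),
    candidates = if (is.null(old)) NULL else old$candidates,
    state = "curated")
  project
}

#' @export
print.mapping_project <- function(x, ...) {
  tent <- x$target_schema$entities[[x$target_entity]]
  cat(sprintf("mapping project: %d targets x %d sources\n",
              length(tent$attributes), length(x$sources)))
  for (sn in names(x$cells)) {
    states <- vapply(x$cells[[sn]], `[[`, character(1), "state")
    cat(sprintf("  %s: %s\n", sn,
                paste(sprintf("%s=%s", names(states), states),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Persist a mapping project as a JSON document
#'
#' Stores per-cell script text, provenance, confidence and state (plus the
#' candidate shortlist summary); schemas and ontologies are not embedded
#' and must be supplied again on [read_project()].
#'
#' @param project a `mapping_project`.
#' @param path output JSON file.
#' @export
write_project <- function(project, path) {
  cells <- list()
  for (sn in names(project$cells)) {
    cells[[sn]] <- lapply(project$cells[[sn]], function(cell) {
      list(state = cell$state,
           script = if (is.null(cell$algorithm)) NULL else
             cell$algorithm$script$text,
           conditional = if (is.null(cell$algorithm)) NULL else
             cell$algorithm$script$conditional,
           provenance = if (is.null(cell$algorithm)) NULL else
             cell$algorithm$provenance,
           confidence = if (is.null(cell$algorithm)) NULL else
             cell$algorithm$confidence,
           candidates = if (is.null(cell$candidates)) NULL else
             cell$candidates[, c("rank", "entity", "name", "score")])
    })
  }
  doc <- list(target_entity = project$target_entity,
              sources = names(project$sources), cells = cells)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a mapping project from JSON
#'
#' @param path JSON produced by [write_project()].
#' @param target_schema,sources the schemas the project refers to.
#' @param store optional `ontology_store` for later regeneration.
#' @return a `mapping_project` (candidate shortlists restored as plain
#'   data frames).
#' @export
read_project <- function(path, target_schema, sources, store = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  stopifnot(setequal(doc$sources, names(sources)))
  tent <- target_schema$entities[[doc$target_entity]]
  project <- structure(list(
    target_schema = target_schema, target_entity = doc$target_entity,
    sources = sources, store = store,
    settings = list(catalogue = default_template_catalogue(),
                    cat_rules = default_category_rules(),
                    unit_rules = default_conversion_rules(),
                    unit_store = default_unit_store(),
                    k = 20, unit_style = "formula"),
    cells = list()), class = "mapping_project")
  for (sn in names(doc$cells)) {
    project$cells[[sn]] <- lapply(doc$cells[[sn]], function(cell) {
      alg <- NULL
      if (!is.null(cell$script)) {
        script <- dsl_parse(cell$script,
                            allow_conditional = isTRUE(cell$conditional))
        alg <- structure(list(target = NULL, script = script,
                              provenance = cell$provenance,
                              confidence = cell$confidence,
                              used_candidates = NULL, template = NA),
                         class = "generated_algorithm")
      }
      list(algorithm = alg, candidates = cell$candidates, state = cell$state)
    })
    # restore targets on the algorithms
    for (an in names(project$cells[[sn]])) {
      if (!is.null(project$cells[[sn]][[an]]$algorithm) &&
          an %in% names(tent$attributes)) {
        project$cells[[sn]][[an]]$algorithm$target <- tent$attributes[[an]]
      }
    }
  }
  project
}
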