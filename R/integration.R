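#' @title Executing a mapping project
#'
#' @description
#' Integration runs every cell's algorithm over the source rows to derive
#' a dataset in the target schema. Evaluation errors (e.g. a script
#' referencing an attribute the source does not have) are counted as
#' per-row failures and yield null; nulls propagated from missing source
#' data are *not* failures. Results can be previewed on the first rows and
#' exported as a CSV-set workbook that reads back losslessly.
#'
#' @name integration-engine
NULL

# entity of a source schema that contains all referenced attributes
.resolve_entity <- function(schema, refs) {
  for (e in schema$entities) {
    if (all(refs %in% names(e$attributes))) return(e)
  }
  NULL
}

.render_value <- function(v) {
  if (length(v) != 1 || is.na(v)) return(NA_character_)
  if (is.numeric(v)) return(.num_str(v))
  if (is.logical(v)) return(if (v) "true" else "false")
  as.character(v)
}

#' Apply a mapping project to one source
#'
#' @param project a `mapping_project`.
#' @param source_data the source [emx_schema()] to integrate (defaults to
#'   the project's only source).
#' @param source_name name of the source within the project.
#' @param unit_rules conversion rules used by `toUnit()`.
#' @return an `integration_result`: the derived [emx_entity()] in the
#'   target schema, per-attribute failure counts, and a per-row error log
#'   (`row`, `attribute`, `message`).
#' @export
apply_project <- function(project, source_data = NULL, source_name = NULL,
                          unit_rules = default_conversion_rules()) {
  if (is.null(source_name)) {
    if (length(project$sources) != 1 && is.null(source_data)) {
      stop("source_name must be given for a multi-source project")
    }
    source_name <- names(project$sources)[1]
  }
  if (is.null(source_data)) source_data <- project$sources[[source_name]]
  cells <- project$cells[[source_name]]
  if (is.null(cells)) stop("project has no cells for source '", source_name, "'")
  tent <- project$target_schema$entities[[project$target_entity]]

  executed <- Filter(function(an) {
    !is.null(cells[[an]]) && !is.null(cells[[an]]$algorithm)
  }, names(tent$attributes))
  if (!length(executed)) {
    warning("project holds no algorithms for source '", source_name, "'")
  }
  # the data entity is the one carrying the referenced attributes
  entity <- NULL
  for (an in executed) {
    refs <- cells[[an]]$algorithm$script$referenced_attributes
    entity <- .resolve_entity(source_data, refs)
    if (!is.null(entity)) break
  }
  if (is.null(entity) && length(source_data$entities)) {
    entity <- source_data$entities[[1]]
  }
  n <- if (is.null(entity)) 0L else nrow(entity$data)

  out <- setNames(rep(list(rep(NA_character_, n)), length(tent$attributes)),
                  names(tent$attributes))
  failures <- setNames(integer(length(tent$attributes)),
                       names(tent$attributes))
  log <- list()
  for (an in executed) {
    script <- cells[[an]]$algorithm$script
    for (i in seq_len(n)) {
      row <- as.list(entity$data[i, , drop = FALSE])
      v <- tryCatch(
        suppressWarnings(dsl_evaluate(script, row, entity, unit_rules)),
        error = function(e) {
          failures[[an]] <<- failures[[an]] + 1L
          log[[length(log) + 1L]] <<- data.frame(
            row = i, attribute = an, message = conditionMessage(e),
            stringsAsFactors = FALSE)
          NA
        })
      out[[an]][i] <- .render_value(v)
    }
  }
  derived <- emx_entity(tent$name, tent$attributes,
                        as.data.frame(out, check.names = FALSE,
                                      stringsAsFactors = FALSE))
  structure(list(entity = derived, failures = failures,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(row = integer(0), attribute = character(0),
                              message = character(0), stringsAsFactors = FALSE),
                 n_rows = n, executed = executed, source = source_name),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("integration result: %d rows, %d attributes executed\n",
              x$n_rows, length(x$executed)))
  bad <- x$failures[x$failures > 0]
  if (length(bad)) {
    cat("  failures:", paste(sprintf("%s=%d", names(bad), bad),
                             collapse = ", "), "\n")
  } else cat("  failures: none\n")
  invisible(x)
}

#' Preview an algorithm on the first rows of a source entity
#'
#' Values are identical to a full [apply_project()] run restricted to the
#' first `n` rows.
#'
#' @param algorithm a `generated_algorithm`.
#' @param source_entity the [emx_entity()] holding the rows.
#' @param n number of rows (default 10; capped at the available rows).
#' @param unit_rules conversion rules.
#' @return list with `values` (character, rendered) and `failures` count.
#' @export
preview_algorithm <- function(algorithm, source_entity, n = 10,
                              unit_rules = default_conversion_rules()) {
  n <- min(n, nrow(source_entity$data))
  values <- character(n)
  failures <- 0L
  for (i in seq_len(n)) {
    row <- as.list(source_entity$data[i, , drop = FALSE])
    v <- tryCatch(
      suppressWarnings(dsl_evaluate(algorithm$script, row, source_entity,
                                    unit_rules)),
      error = function(e) { failures <<- failures + 1L; NA })
    values[i] <- .render_value(v)
  }
  list(values = values, failures = failures)
}

#' Export an integration result
#'
#' Writes the derived entity (with its category reference entities) as a
#' CSV-set EMX workbook, so that [read_emx()] on the exported directory
#' reproduces it. Nulls are exported as empty cells.
#'
#' @param result an `integration_result`.
#' @param path output directory.
#' @param format only `"csv"` is supported; `"xlsx"` raises an error
#'   (no spreadsheet writer is bundled).
#' @export
export_result <- function(result, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("xlsx export is not supported; export as CSV-set instead")
  }
  entities <- list(result$entity)
  # carry the category reference entities so the workbook revalidates
  for (a in result$entity$attributes) {
    if (!is.null(a$categories) && !is.na(a$ref_entity)) {
      ref_attrs <- list(emx_attribute("code", a$ref_entity, "string"),
                        emx_attribute("label", a$ref_entity, "string"))
      entities[[length(entities) + 1L]] <-
        emx_entity(a$ref_entity, ref_attrs,
                   data.frame(code = a$categories$code,
                              label = a$categories$label,
                              stringsAsFactors = FALSE))
    }
  }
  names(entities) <- vapply(entities, `[[`, character(1), "name")
  write_emx(emx_schema(entities[!duplicated(names(entities))]), path)
  invisible(path)
}
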