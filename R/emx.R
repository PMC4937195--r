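#' @title Entity-Attribute metadata model (EMX-style workbooks)
#'
#' @description
#' Target data schemas and source biobank data dictionaries are exchanged as
#' lightweight entity/attribute workbooks: a special `attributes` sheet
#' declares, for every entity (table), its attributes (columns) with a name,
#' data type, human-readable label, free-text description and, for
#' categorical/cross-reference attributes, the entity holding the category
#' codes. Every other sheet carries the data rows of one entity. Two dialects
#' are understood: a directory of UTF-8 CSV files (one per sheet) and an xlsx
#' workbook (read-only, via the readxl package).
#'
#' @name emx
NULL

.emx_types <- c("string", "int", "decimal", "categorical", "xref", "date",
                "bool", "text")
.attr_sheet_cols <- c("name", "entity", "dataType", "label", "description",
                      "refEntity")

#' Construct a single attribute definition
#'
#' @param name attribute (column) identifier, unique within its entity.
#' @param entity identifier of the entity the attribute belongs to.
#' @param data_type one of `string`, `int`, `decimal`, `categorical`,
#'   `xref`, `date`, `bool`, `text`.
#' @param label human-readable label; defaults to the name.
#' @param description free-text description (may be empty).
#' @param ref_entity for `categorical`/`xref` attributes, the name of the
#'   entity holding the category codes and labels.
#' @param categories optional data frame with character columns `code` and
#'   `label`; normally resolved from `ref_entity` by [read_emx()].
#' @return an object of class `emx_attribute`.
#' @export
emx_attribute <- function(name, entity, data_type = "string", label = name,
                          description = "", ref_entity = NA_character_,
                          categories = NULL) {
  stopifnot(is.character(name), nzchar(name))
  if (!data_type %in% .emx_types) {
    stop("unknown data type '", data_type, "' for attribute '", name, "'")
  }
  if (!is.null(categories)) {
    categories <- data.frame(code = as.character(categories$code),
                             label = as.character(categories$label),
                             stringsAsFactors = FALSE)
  }
  structure(list(name = name, entity = entity, data_type = data_type,
                 label = if (is.na(label)) "" else label,
                 description = if (is.na(description)) "" else description,
                 ref_entity = ref_entity, categories = categories),
            class = "emx_attribute")
}

#' Construct an entity (one table: attribute definitions plus data rows)
#'
#' @param name entity identifier.
#' @param attributes list of [emx_attribute()] objects, in column order.
#' @param data data frame of character cells, one column per attribute;
#'   missing cells are `NA`. Defaults to zero rows.
#' @return an object of class `emx_entity`.
#' @export
emx_entity <- function(name, attributes, data = NULL) {
  attr_names <- vapply(attributes, function(a) a$name, character(1))
  if (anyDuplicated(attr_names)) {
    stop("duplicate attribute names in entity '", name, "'")
  }
  names(attributes) <- attr_names
  if (is.null(data)) {
    data <- as.data.frame(setNames(rep(list(character(0)), length(attr_names)),
                                   attr_names),
                          check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    data <- as.data.frame(lapply(data, function(col) .clean_cells(as.character(col))),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          optional = TRUE)
    names(data) <- names(data)  # keep as supplied
  }
  structure(list(name = name, attributes = attributes, data = data),
            class = "emx_entity")
}

#' Construct a schema (a named set of entities)
#'
#' @param entities list of [emx_entity()] objects.
#' @return an object of class `emx_schema`.
#' @export
emx_schema <- function(entities = list()) {
  names(entities) <- vapply(entities, function(e) e$name, character(1))
  structure(list(entities = entities), class = "emx_schema")
}

#' @export
print.emx_schema <- function(x, ...) {
  cat("EMX schema:", length(x$entities), "entities\n")
  for (e in x$entities) {
    cat(sprintf("  %s: %d attributes, %d rows\n",
                e$name, length(e$attributes), nrow(e$data)))
  }
  invisible(x)
}

#' @export
print.emx_attribute <- function(x, ...) {
  cat(sprintf("<attribute> %s.%s [%s] \"%s\"\n", x$entity, x$name,
              x$data_type, x$label))
  if (!is.null(x$categories)) {
    cat("  categories:",
        paste(sprintf("%s=%s", x$categories$code, x$categories$label),
              collapse = ", "), "\n")
  }
  invisible(x)
}

.read_sheets_csv <- function(path) {
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  sheets <- lapply(files, function(f) {
    utils::read.csv(f, colClasses = "character", check.names = FALSE,
                    na.strings = character(0), fileEncoding = "UTF-8")
  })
  names(sheets) <- tools::file_path_sans_ext(basename(files))
  sheets
}

.read_sheets_xlsx <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading xlsx workbooks requires the 'readxl' package")
  }
  sheet_names <- readxl::excel_sheets(path)
  sheets <- lapply(sheet_names, function(s) {
    df <- readxl::read_excel(path, sheet = s, col_types = "text")
    as.data.frame(df, check.names = FALSE, stringsAsFactors = FALSE)
  })
  names(sheets) <- sheet_names
  sheets
}

#' Read an EMX workbook (xlsx file or directory of CSV sheets)
#'
#' @param path either a directory containing one CSV file per sheet (the
#'   metadata sheet named `attributes.csv`) or an `.xlsx` workbook.
#' @param strict if `TRUE` (default), any validation violation is an error;
#'   otherwise violations are reported as a warning and the schema returned
#'   as-is.
#' @return a validated [emx_schema()].
#' @details Empty cells and the literal string `"NA"` are both read as the
#'   internal missing value. Category codes are always handled as strings.
#'   Attribute sheet columns beyond `name`, `entity`, `dataType`, `label`,
#'   `description`, `refEntity` are ignored with a warning.
#' @export
read_emx <- function(path, strict = TRUE) {
  if (dir.exists(path)) {
    sheets <- .read_sheets_csv(path)
  } else if (file.exists(path) && grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    sheets <- .read_sheets_xlsx(path)
  } else {
    stop("path does not exist or is not an EMX workbook: ", path)
  }
  if (!"attributes" %in% names(sheets)) {
    stop("not an EMX workbook: no 'attributes' metadata sheet in ", path)
  }
  meta <- sheets[["attributes"]]
  required <- c("name", "entity", "dataType")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("attributes sheet lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(meta), .attr_sheet_cols)
  if (length(extra)) {
    warning("ignoring unknown attributes-sheet column(s): ",
            paste(extra, collapse = ", "))
  }
  for (opt in c("label", "description", "refEntity")) {
    if (!opt %in% names(meta)) meta[[opt]] <- NA_character_
  }
  bad_type <- which(!meta$dataType %in% .emx_types)
  if (length(bad_type)) {
    stop("unknown data type token(s) in attributes sheet row(s) ",
         paste(bad_type, collapse = ", "), ": ",
         paste(unique(meta$dataType[bad_type]), collapse = ", "))
  }

  entity_names <- unique(meta$entity)
  entities <- list()
  for (en in entity_names) {
    rows <- meta[meta$entity == en, , drop = FALSE]
    attrs <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      emx_attribute(
        name = r$name, entity = en, data_type = r$dataType,
        label = if (.is_missing_cell(r$label)) r$name else r$label,
        description = if (.is_missing_cell(r$description)) "" else r$description,
        ref_entity = if (.is_missing_cell(r$refEntity)) NA_character_ else r$refEntity
      )
    })
    data <- sheets[[en]]
    if (!is.null(data)) {
      unknown <- setdiff(names(data), rows$name)
      if (length(unknown)) {
        stop("data sheet '", en, "' has column(s) not declared as attributes: ",
             paste(unknown, collapse = ", "))
      }
    }
    entities[[en]] <- emx_entity(en, attrs, data)
  }
  orphan <- setdiff(names(sheets), c("attributes", entity_names))
  if (length(orphan)) {
    warning("ignoring data sheet(s) without attribute definitions: ",
            paste(orphan, collapse = ", "))
  }
  schema <- emx_schema(entities)
  schema <- .resolve_categories(schema)
  violations <- validate_schema(schema)
  if (nrow(violations)) {
    msg <- paste0(utils::capture.output(print(violations)), collapse = "\n")
    if (strict) stop("schema validation failed:\n", msg) else
      warning("schema validation problems:\n", msg)
  }
  schema
}

# attach category code/label tables from referenced entities
.resolve_categories <- function(schema) {
  for (en in names(schema$entities)) {
    e <- schema$entities[[en]]
    for (an in names(e$attributes)) {
      a <- e$attributes[[an]]
      if (a$data_type %in% c("categorical", "xref")) {
        if (is.na(a$ref_entity) || !a$ref_entity %in% names(schema$entities)) {
          stop("attribute '", en, ".", an, "' is ", a$data_type,
               " but its refEntity '", a$ref_entity, "' cannot be resolved")
        }
        ref <- schema$entities[[a$ref_entity]]
        if (!all(c("code", "label") %in% names(ref$data))) {
          stop("reference entity '", a$ref_entity,
               "' must have 'code' and 'label' attributes")
        }
        a$categories <- data.frame(code = ref$data$code,
                                   label = ref$data$label,
                                   stringsAsFactors = FALSE)
        e$attributes[[an]] <- a
      }
    }
    schema$entities[[en]] <- e
  }
  schema
}

#' Write a schema as a CSV-set EMX workbook
#'
#' Emits the same dialect [read_emx()] accepts: a directory holding
#' `attributes.csv` plus one CSV file per entity. Missing values are written
#' as empty cells. `read_emx(write_emx(x))` is the identity on valid schemas.
#'
#' @param schema an [emx_schema()].
#' @param path target directory (created if needed).
#' @export
write_emx <- function(schema, path) {
  if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    stop("writing xlsx workbooks is not supported; use the CSV-set dialect")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  rows <- list()
  for (e in schema$entities) {
    for (a in e$attributes) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = a$name, entity = a$entity, dataType = a$data_type,
        label = a$label, description = a$description,
        refEntity = ifelse(is.na(a$ref_entity), "", a$ref_entity),
        stringsAsFactors = FALSE)
    }
  }
  meta <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(.attr_sheet_cols)),
                           .attr_sheet_cols), check.names = FALSE)
  utils::write.csv(meta, file.path(path, "attributes.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  for (e in schema$entities) {
    out <- e$data
    out[] <- lapply(out, function(col) ifelse(is.na(col), "", col))
    utils::write.csv(out, file.path(path, paste0(e$name, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  }
  invisible(path)
}

#' Validate a schema against the metadata-model invariants
#'
#' Violations are data, not exceptions: each row of the returned data frame
#' names the entity, attribute and (1-based) data row concerned.
#'
#' Checked: attribute names unique within an entity; data types in the
#' allowed set; categorical/xref attributes resolvable with non-empty,
#' unique category codes; every data column declared; categorical cells
#' restricted to the declared codes (or missing); int/decimal cells numeric.
#'
#' @param schema an [emx_schema()].
#' @return data frame with columns `entity`, `attribute`, `row`, `problem`;
#'   zero rows when the schema is valid.
#' @export
validate_schema <- function(schema) {
  v <- list()
  note <- function(entity, attribute, row, problem) {
    v[[length(v) + 1L]] <<- data.frame(entity = entity, attribute = attribute,
                                       row = row, problem = problem,
                                       stringsAsFactors = FALSE)
  }
  for (e in schema$entities) {
    attr_names <- vapply(e$attributes, function(a) a$name, character(1))
    dup <- attr_names[duplicated(attr_names)]
    for (d in unique(dup)) note(e$name, d, NA_integer_, "duplicate attribute name")
    for (a in e$attributes) {
      if (!a$data_type %in% .emx_types) {
        note(e$name, a$name, NA_integer_,
             paste0("unknown data type '", a$data_type, "'"))
      }
      if (a$data_type %in% c("categorical", "xref")) {
        if (is.null(a$categories) || nrow(a$categories) == 0) {
          note(e$name, a$name, NA_integer_, "no resolvable categories")
        } else {
          if (any(!nzchar(a$categories$code) | is.na(a$categories$code))) {
            note(e$name, a$name, NA_integer_, "empty category code")
          }
          if (anyDuplicated(a$categories$code)) {
            note(e$name, a$name, NA_integer_, "duplicate category codes")
          }
        }
      } else if (!is.null(a$categories) && nrow(a$categories) > 0) {
        note(e$name, a$name, NA_integer_,
             "categories present on non-categorical attribute")
      }
    }
    for (cn in names(e$data)) {
      if (!cn %in% attr_names) {
        note(e$name, cn, NA_integer_, "data column not declared as attribute")
        next
      }
      a <- e$attributes[[cn]]
      col <- e$data[[cn]]
      present <- which(!is.na(col))
      if (a$data_type %in% c("categorical", "xref") &&
          !is.null(a$categories)) {
        bad <- present[!col[present] %in% a$categories$code]
        for (i in bad) {
          note(e$name, cn, i, paste0("value '", col[i],
                                     "' not among category codes"))
        }
      }
      if (a$data_type %in% c("int", "decimal")) {
        bad <- present[is.na(suppressWarnings(as.numeric(col[present])))]
        for (i in bad) {
          note(e$name, cn, i, paste0("value '", col[i], "' is not numeric"))
        }
      }
    }
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(entity = character(0), attribute = character(0),
               row = integer(0), problem = character(0),
               stringsAsFactors = FALSE)
}

#' Look up one attribute in a schema
#'
#' @param schema an [emx_schema()].
#' @param entity entity name; if `NULL`, all entities are searched and the
#'   attribute name must be unique across the schema.
#' @param name attribute name.
#' @return the [emx_attribute()], or an error if absent/ambiguous.
#' @export
get_attribute <- function(schema, name, entity = NULL) {
  if (!is.null(entity)) {
    e <- schema$entities[[entity]]
    if (is.null(e)) stop("no entity '", entity, "' in schema")
    a <- e$attributes[[name]]
    if (is.null(a)) stop("no attribute '", name, "' in entity '", entity, "'")
    return(a)
  }
  hits <- list()
  for (e in schema$entities) {
    if (name %in% names(e$attributes)) hits[[e$name]] <- e$attributes[[name]]
  }
  if (length(hits) == 0) stop("no attribute '", name, "' in schema")
  if (length(hits) > 1) stop("attribute '", name, "' is ambiguous across entities")
  hits[[1]]
}

# typed view of one data column, following the attribute's declared type
.typed_column <- function(entity, name) {
  a <- entity$attributes[[name]]
  col <- entity$data[[name]]
  if (is.null(a) || is.null(col)) stop("no attribute '", name, "' in entity '",
                                       entity$name, "'")
  switch(a$data_type,
         int = as.integer(suppressWarnings(as.numeric(col))),
         decimal = suppressWarnings(as.numeric(col)),
         bool = tolower(col) %in% c("true", "1", "yes"),
         col)
}
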