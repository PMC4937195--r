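#' @title Ontology store: load, look up, annotate, expand
#'
#' @description
#' Phenotype vocabularies and the units vocabulary are exchanged in a flat
#' OBO subset: `[Term]` stanzas with `id`, `name`, `synonym` and `is_a`
#' lines. A loaded store supports case-insensitive lookup by label or
#' synonym and descendant traversal over the `is_a` graph, which drives
#' query expansion: the query for a target attribute is enriched with the
#' synonyms and subclass labels of its annotated terms (never with
#' superclass labels, which would flood the search with false positives).
#'
#' @name ontology
NULL

#' Load an ontology from a flat OBO-subset file
#'
#' Recognised stanza lines: `id:`, `name:`, `synonym: "text" ...`,
#' `is_a: ID ! comment`. Other lines and `[Typedef]` stanzas are ignored.
#' The `is_a` graph must be acyclic; a cycle is a load error naming the
#' terms involved.
#'
#' @param path path to the file.
#' @return an object of class `ontology_store`.
#' @export
load_ontology <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <<- cur
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); cur <- list(synonyms = character(0), parents = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (grepl("^name:", ln)) {
      cur$label <- trimws(sub("^name:", "", ln))
    } else if (grepl("^synonym:", ln)) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      if (length(m)) cur$synonyms <- c(cur$synonyms, gsub('"', "", m))
    } else if (grepl("^is_a:", ln)) {
      target <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      if (nzchar(target)) cur$parents <- c(cur$parents, target)
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      cur$obsolete <- TRUE
    }
  }
  flush()
  terms <- Filter(function(t) is.null(t$obsolete), terms)
  for (id in names(terms)) {
    if (is.null(terms[[id]]$label)) terms[[id]]$label <- id
    dangling <- setdiff(terms[[id]]$parents, names(terms))
    if (length(dangling)) {
      stop("term ", id, " has unresolved is_a parent(s): ",
           paste(dangling, collapse = ", "))
    }
  }
  children <- setNames(vector("list", length(terms)), names(terms))
  for (id in names(terms)) {
    for (p in terms[[id]]$parents) children[[p]] <- c(children[[p]], id)
  }
  .check_acyclic(terms)
  store <- structure(list(terms = terms, children = children),
                     class = "ontology_store")
  store
}

.check_acyclic <- function(terms) {
  state <- new.env(parent = emptyenv())  # 1 = visiting, 2 = done
  visit <- function(id, trail) {
    s <- get0(id, envir = state)
    if (identical(s, 2L)) return(invisible())
    if (identical(s, 1L)) {
      cyc <- c(trail[which(trail == id):length(trail)], id)
      stop("cyclic is_a chain: ", paste(cyc, collapse = " -> "))
    }
    assign(id, 1L, envir = state)
    for (p in terms[[id]]$parents) visit(p, c(trail, id))
    assign(id, 2L, envir = state)
  }
  for (id in names(terms)) visit(id, character(0))
  invisible()
}

#' @export
print.ontology_store <- function(x, ...) {
  cat("ontology store:", length(x$terms), "terms\n")
  invisible(x)
}

#' Look up terms by exact label or synonym (case-insensitive)
#'
#' @param store an `ontology_store`.
#' @param text label or synonym text.
#' @return list of matching term records (possibly empty).
#' @export
find_term <- function(store, text) {
  key <- tolower(trimws(text))
  Filter(function(t) {
    key %in% tolower(c(t$label, t$synonyms))
  }, store$terms)
}

#' Descendants of a term in the is_a graph
#'
#' @param store an `ontology_store`.
#' @param term_id starting term.
#' @param max_depth traversal depth cap (default unlimited).
#' @return character vector of descendant term ids (excluding the start).
#' @export
ontology_descendants <- function(store, term_id, max_depth = Inf) {
  if (!term_id %in% names(store$terms)) stop("unknown term id: ", term_id)
  out <- character(0)
  frontier <- term_id
  depth <- 0
  while (length(frontier) && depth < max_depth) {
    nxt <- unique(unlist(store$children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(out, term_id))
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  out
}

#' Annotate an attribute with ontology terms
#'
#' A term is selected when all tokens of its label, or of one of its
#' synonyms, occur among the tokens of the attribute's label and
#' description (exact token containment, case-insensitive). Selected terms
#' are ranked by the fraction of the attribute's tokens they share, ties
#' broken by shorter term label.
#'
#' @param attr an [emx_attribute()] (or any list with `label`/`description`).
#' @param store an `ontology_store`.
#' @param max_terms cap on the number of returned terms.
#' @return list of term records, best-scoring first (possibly empty).
#' @export
annotate_attribute <- function(attr, store, max_terms = 5) {
  if (is.null(store)) return(list())
  target_tokens <- unique(.tokenize(c(attr$label, attr$description)))
  if (!length(target_tokens)) return(list())
  scored <- list()
  for (t in store$terms) {
    best <- 0
    for (s in c(t$label, t$synonyms)) {
      st <- unique(.tokenize(s))
      if (length(st) && all(st %in% target_tokens)) {
        best <- max(best, length(st) / length(target_tokens))
      }
    }
    if (best > 0) {
      scored[[length(scored) + 1L]] <- list(term = t, score = best)
    }
  }
  if (!length(scored)) return(list())
  ord <- order(-vapply(scored, `[[`, numeric(1), "score"),
               vapply(scored, function(s) nchar(s$term$label), integer(1)),
               vapply(scored, function(s) s$term$id, character(1)))
  lapply(utils::head(scored[ord], max_terms), `[[`, "term")
}

#' Expand a query with synonyms and subclass labels
#'
#' The expanded query always contains the original tokens; the labels and
#' synonyms of the annotated terms are added with origin `synonym`, and the
#' labels of their descendants (to `max_subclass_depth`) with origin
#' `subclass`. Superclass labels are never added.
#'
#' @param terms list of term records (e.g. from [annotate_attribute()]).
#' @param store an `ontology_store`.
#' @param max_subclass_depth subclass traversal depth (default 3).
#' @param base_tokens original query tokens (always retained).
#' @return data frame with columns `term` (string) and `origin`
#'   (`original`/`synonym`/`subclass`), duplicates removed.
#' @export
expand_query <- function(terms, store, max_subclass_depth = 3,
                         base_tokens = character(0)) {
  out_term <- base_tokens
  out_origin <- rep("original", length(base_tokens))
  add <- function(strings, origin) {
    for (s in strings) {
      if (!tolower(s) %in% tolower(out_term)) {
        out_term <<- c(out_term, s)
        out_origin <<- c(out_origin, origin)
      }
    }
  }
  for (t in terms) {
    add(c(t$label, t$synonyms), "synonym")
    if (!is.null(store) && t$id %in% names(store$terms)) {
      desc <- ontology_descendants(store, t$id, max_subclass_depth)
      add(vapply(store$terms[desc], `[[`, character(1), "label"), "subclass")
    }
  }
  data.frame(term = out_term, origin = out_origin, stringsAsFactors = FALSE)
}
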