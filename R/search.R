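#' @title Lexical search over source attributes
#'
#' @description
#' Source data dictionaries are indexed attribute-by-attribute on the
#' tokens of their labels and descriptions. Queries built from a target
#' attribute (after ontology expansion) are scored with Okapi BM25
#' (k1 = 1.2, b = 0.75), the modern Lucene default; expansion terms enter
#' the query at equal weight. An attribute whose label tokens equal the
#' target's label tokens receives a x2 boost so that verbatim matches
#' always rank first. Ties are broken by attribute name for deterministic
#' output.
#'
#' @name semantic-search
NULL

.bm25_k1 <- 1.2
.bm25_b <- 0.75

#' Build a search index over all attributes of a source schema
#'
#' @param source_schema a valid [emx_schema()].
#' @return an object of class `search_index`.
#' @export
index_source <- function(source_schema) {
  docs <- list()
  for (e in source_schema$entities) {
    for (a in e$attributes) {
      docs[[length(docs) + 1L]] <- data.frame(
        entity = e$name, name = a$name, label = a$label,
        description = a$description, stringsAsFactors = FALSE)
    }
  }
  docs <- if (length(docs)) do.call(rbind, docs) else
    data.frame(entity = character(0), name = character(0),
               label = character(0), description = character(0),
               stringsAsFactors = FALSE)
  tokens <- lapply(seq_len(nrow(docs)), function(i) {
    .tokenize(c(docs$label[i], docs$description[i]))
  })
  df <- table(unlist(lapply(tokens, unique)))
  structure(list(docs = docs, tokens = tokens,
                 df = setNames(as.integer(df), names(df)),
                 N = nrow(docs),
                 avgdl = if (nrow(docs)) mean(lengths(tokens)) else 0),
            class = "search_index")
}

#' @export
print.search_index <- function(x, ...) {
  cat("search index:", x$N, "attributes,", length(x$df), "distinct tokens\n")
  invisible(x)
}

.bm25_scores <- function(index, qtokens) {
  if (index$N == 0 || !length(qtokens)) return(numeric(index$N))
  scores <- numeric(index$N)
  dl <- lengths(index$tokens)
  for (q in unique(qtokens)) {
    n_q <- index$df[q]
    if (is.na(n_q)) next
    idf <- log(1 + (index$N - n_q + 0.5) / (n_q + 0.5))
    tf <- vapply(index$tokens, function(t) sum(t == q), numeric(1))
    denom <- tf + .bm25_k1 * (1 - .bm25_b + .bm25_b * dl / index$avgdl)
    scores <- scores + ifelse(tf > 0, idf * tf * (.bm25_k1 + 1) / denom, 0)
  }
  scores
}

# shared ranking core: query tokens -> ranked candidate data frame
.run_query <- function(index, qtokens, target_label_tokens, k, query) {
  scores <- .bm25_scores(index, qtokens)
  exact <- vapply(seq_len(index$N), function(i) {
    setequal(.tokenize(index$docs$label[i]), target_label_tokens) &&
      length(target_label_tokens) > 0
  }, logical(1))
  scores[exact] <- scores[exact] * 2  # verbatim-label boost
  keep <- which(scores > 0)
  if (!length(keep)) {
    out <- index$docs[0, ]
    out$score <- numeric(0)
    out$rank <- integer(0)
  } else {
    ord <- keep[order(-scores[keep], index$docs$name[keep])]
    ord <- utils::head(ord, k)
    out <- index$docs[ord, , drop = FALSE]
    out$score <- scores[ord]
    out$rank <- seq_along(ord)
    rownames(out) <- NULL
  }
  structure(out, query = query, class = c("match_candidates", "data.frame"))
}

#' Shortlist candidate source attributes for a target attribute
#'
#' The target is annotated with ontology terms, the query is expanded with
#' their synonyms and subclass labels, and all indexed attributes are
#' scored. At most `k` candidates are returned, ordered by score.
#'
#' @param target an [emx_attribute()].
#' @param index a [index_source()] result.
#' @param store an `ontology_store` (or `NULL` for no expansion).
#' @param k shortlist size, default 20.
#' @param max_subclass_depth expansion depth (see [expand_query()]).
#' @return a `match_candidates` data frame (`entity`, `name`, `label`,
#'   `description`, `score`, `rank`) with the expanded query attached as
#'   attribute `"query"`.
#' @export
shortlist <- function(target, index, store = NULL, k = 20,
                      max_subclass_depth = 3) {
  base <- unique(.tokenize(c(target$label, target$description)))
  terms <- if (is.null(store)) list() else annotate_attribute(target, store)
  query <- expand_query(terms, store, max_subclass_depth, base_tokens = base)
  qtokens <- unique(unlist(lapply(query$term, .tokenize)))
  .run_query(index, qtokens, unique(.tokenize(target$label)), k, query)
}

#' Free-text query over the index (`term1 or term2` syntax)
#'
#' Each `or`-separated term is ontology-expanded like a pseudo-attribute
#' with that label, and matching uses OR semantics across all terms.
#'
#' @param query_string non-empty query, terms separated by `or`.
#' @inheritParams shortlist
#' @return a `match_candidates` data frame.
#' @export
manual_query <- function(query_string, index, store = NULL, k = 20,
                         max_subclass_depth = 3) {
  if (is.null(query_string) || !nzchar(trimws(query_string))) {
    stop("query string must be non-empty")
  }
  parts <- trimws(strsplit(query_string, "\\s+or\\s+",
                           perl = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  all_q <- list()
  label_tokens <- character(0)
  for (p in parts) {
    pseudo <- list(label = p, description = "")
    base <- unique(.tokenize(p))
    terms <- if (is.null(store)) list() else annotate_attribute(pseudo, store)
    all_q[[length(all_q) + 1L]] <-
      expand_query(terms, store, max_subclass_depth, base_tokens = base)
    label_tokens <- c(label_tokens, base)
  }
  query <- do.call(rbind, all_q)
  query <- query[!duplicated(tolower(query$term)), , drop = FALSE]
  qtokens <- unique(unlist(lapply(query$term, .tokenize)))
  .run_query(index, qtokens, unique(label_tokens), k, query)
}

#' Highlight query tokens in candidate labels and descriptions
#'
#' For every candidate, finds the query-term tokens occurring
#' (case-insensitively, at token boundaries) in its label or description
#' and records their character spans into the original strings.
#'
#' @param candidates a `match_candidates` data frame.
#' @param query expanded-query data frame; defaults to the query attached
#'   to `candidates`.
#' @return `candidates` with an added list-column `highlights`; each element
#'   is a data frame `token`, `field`, `start`, `end` (1-based, inclusive).
#' @export
highlight_candidate <- function(candidates, query = attr(candidates, "query")) {
  qtokens <- unique(unlist(lapply(query$term, .tokenize)))
  spans_in <- function(text, field) {
    hits <- list()
    for (tok in qtokens) {
      pat <- paste0("(?<![a-zA-Z0-9])", tok, "(?![a-zA-Z0-9])")
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] != -1) {
        for (j in seq_along(m)) {
          hits[[length(hits) + 1L]] <- data.frame(
            token = tok, field = field, start = m[j],
            end = m[j] + attr(m, "match.length")[j] - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
    hits
  }
  candidates$highlights <- lapply(seq_len(nrow(candidates)), function(i) {
    h <- c(spans_in(candidates$label[i], "label"),
           spans_in(candidates$description[i], "description"))
    if (length(h)) do.call(rbind, h) else
      data.frame(token = character(0), field = character(0),
                 start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  })
  candidates
}

#' Confidence of a match list for a target attribute
#'
#' `high` when the rank-1 candidate's label tokens cover every non-stop-word
#' token of the target label (a perfect match in the search); `low` for
#' partial coverage; `none` when there are no candidates.
#'
#' @param candidates a `match_candidates` data frame.
#' @param target the target [emx_attribute()].
#' @return one of `"high"`, `"low"`, `"none"`.
#' @export
classify_confidence <- function(candidates, target) {
  if (is.null(candidates) || nrow(candidates) == 0) return("none")
  target_tokens <- unique(.tokenize(target$label))
  if (!length(target_tokens)) return("high")
  top_tokens <- .tokenize(candidates$label[1])
  if (all(target_tokens %in% top_tokens)) "high" else "low"
}
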