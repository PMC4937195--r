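# fixture builders and independent oracles shared across the suite

# minimal two-sheet workbook: a patients entity with a categorical gender
make_gender_schema <- function() {
  genders <- emx_entity(
    "genders",
    list(emx_attribute("code", "genders", "string", "code"),
         emx_attribute("label", "genders", "string", "label")),
    data.frame(code = c("M", "F"), label = c("Male", "Female"),
               stringsAsFactors = FALSE))
  patients <- emx_entity(
    "patients",
    list(emx_attribute("id", "patients", "string", "Identifier"),
         emx_attribute("gender", "patients", "categorical", "Gender",
                       "Gender of the patient", ref_entity = "genders",
                       categories = data.frame(code = c("M", "F"),
                                               label = c("Male", "Female"),
                                               stringsAsFactors = FALSE))),
    data.frame(id = c("p1", "p2", "p3"), gender = c("M", "F", NA),
               stringsAsFactors = FALSE))
  emx_schema(list(patients, genders))
}

# random valid schema for round-trip properties
random_schema <- function(seed, n_entities = 2, n_rows = 8) {
  set.seed(seed)
  rnd_word <- function(n = 1) {
    vapply(seq_len(n), function(i)
      paste(sample(letters, sample(3:8, 1), replace = TRUE), collapse = ""),
      character(1))
  }
  entities <- list()
  for (ei in seq_len(n_entities)) {
    en <- paste0("ent_", ei)
    codes <- as.character(seq_len(sample(2:4, 1)))
    cat_ent_name <- paste0("codes_", ei)
    cat_labels <- rnd_word(length(codes))
    attrs <- list(
      emx_attribute("id", en, "string", "Identifier", "row id"),
      emx_attribute("num", en, "decimal", paste("Measure", rnd_word()),
                    "a number"),
      emx_attribute("cnt", en, "int", paste("Count", rnd_word()),
                    "an integer"),
      emx_attribute("cat", en, "categorical", paste("Class", rnd_word()),
                    "a code", ref_entity = cat_ent_name,
                    categories = data.frame(code = codes, label = cat_labels,
                                            stringsAsFactors = FALSE)))
    maybe_na <- function(x) {
      x[runif(length(x)) < 0.15] <- NA
      x
    }
    data <- data.frame(
      id = paste0("r", seq_len(n_rows)),
      num = maybe_na(as.character(round(runif(n_rows, 0, 100), 2))),
      cnt = maybe_na(as.character(sample(0:9, n_rows, replace = TRUE))),
      cat = maybe_na(sample(codes, n_rows, replace = TRUE)),
      stringsAsFactors = FALSE)
    entities[[length(entities) + 1L]] <- emx_entity(en, attrs, data)
    entities[[length(entities) + 1L]] <- emx_entity(
      cat_ent_name,
      list(emx_attribute("code", cat_ent_name, "string", "code"),
           emx_attribute("label", cat_ent_name, "string", "label")),
      data.frame(code = codes, label = cat_labels, stringsAsFactors = FALSE))
  }
  emx_schema(entities)
}

schemas_identical <- function(a, b) {
  if (!setequal(names(a$entities), names(b$entities))) return(FALSE)
  for (en in names(a$entities)) {
    ea <- a$entities[[en]]; eb <- b$entities[[en]]
    if (!identical(names(ea$attributes), names(eb$attributes))) return(FALSE)
    for (an in names(ea$attributes)) {
      aa <- ea$attributes[[an]]; ab <- eb$attributes[[an]]
      for (f in c("name", "entity", "data_type", "label", "description")) {
        if (!identical(aa[[f]], ab[[f]])) return(FALSE)
      }
      if (!identical(is.null(aa$categories), is.null(ab$categories))) {
        return(FALSE)
      }
      if (!is.null(aa$categories) &&
          !identical(aa$categories, ab$categories)) return(FALSE)
    }
    if (!identical(dim(ea$data), dim(eb$data))) return(FALSE)
    if (nrow(ea$data) &&
        !identical(as.matrix(ea$data), as.matrix(eb$data))) return(FALSE)
  }
  TRUE
}

# brute-force bigram Dice oracle, written independently of the package code
oracle_dice <- function(a, b) {
  norm <- function(x) {
    x <- gsub("[^a-z0-9]+", " ", tolower(x))
    trimws(gsub(" +", " ", x))
  }
  grams <- function(s) {
    if (s == "") return(character(0))
    p <- paste0(" ", s, " ")
    out <- character(0)
    for (i in 1:(nchar(p) - 1)) out <- c(out, substr(p, i, i + 1))
    out
  }
  a <- norm(a); b <- norm(b)
  if (a == b) return(1)
  ga <- grams(a); gb <- grams(b)
  if (!length(ga) || !length(gb)) return(0)
  inter <- 0
  gb_left <- gb
  for (g in ga) {
    hit <- match(g, gb_left)
    if (!is.na(hit)) {
      inter <- inter + 1
      gb_left <- gb_left[-hit]
    }
  }
  2 * inter / (length(ga) + length(gb))
}

# random word sampler for string properties
random_strings <- function(n, seed) {
  set.seed(seed)
  vocab <- c("never", "once a day", "2-4 times a week", "male", "female",
             "often", "", "x", "yes", "no", "weekly", "6-7 times a week")
  c(vocab, vapply(seq_len(n), function(i)
    paste(sample(c(letters, " "), sample(1:12, 1), replace = TRUE),
          collapse = ""), character(1)))
}

# random DAG ontology in OBO text, plus its edge list
random_dag_obo <- function(seed, n_terms = 30) {
  set.seed(seed)
  ids <- sprintf("RD:%04d", seq_len(n_terms))
  lines <- c("format-version: 1.2")
  edges <- list()
  for (i in seq_len(n_terms)) {
    lines <- c(lines, "", "[Term]", paste0("id: ", ids[i]),
               paste0("name: term ", i))
    if (i > 1) {
      n_par <- sample(0:min(2, i - 1), 1)
      if (n_par > 0) {
        parents <- sample(ids[seq_len(i - 1)], n_par)
        for (p in parents) {
          lines <- c(lines, paste0("is_a: ", p))
          edges[[length(edges) + 1L]] <- c(child = ids[i], parent = p)
        }
      }
    }
  }
  list(lines = lines, edges = if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 2, dimnames = list(NULL, c("child", "parent"))))
}

# transitive-closure descendants oracle over an edge list
oracle_descendants <- function(edges, root, max_depth = Inf) {
  out <- character(0)
  frontier <- root
  depth <- 0
  while (length(frontier) && depth < max_depth) {
    nxt <- unique(edges[edges[, "parent"] %in% frontier, "child"])
    nxt <- setdiff(nxt, c(out, root))
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  sort(out)
}
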