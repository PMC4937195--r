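# shared internal helpers

# small English stop-word list used by the search tokenizer; kept short on
# purpose so that clinically meaningful single letters ("m", "g") survive
.stopwords <- c(
  "a", "an", "and", "are", "as", "at", "be", "but", "by", "do", "for",
  "from", "had", "has", "have", "if", "in", "into", "is", "it", "its",
  "of", "on", "or", "that", "the", "their", "then", "this", "to", "was",
  "were", "which", "will", "with"
)

# lowercase, split on non-alphanumeric, optionally drop stop words
.tokenize <- function(x, drop_stopwords = TRUE) {
  x <- tolower(paste(x[!is.na(x)], collapse = " "))
  toks <- unlist(strsplit(x, "[^a-z0-9]+"))
  toks <- toks[nzchar(toks)]
  if (drop_stopwords) toks <- toks[!toks %in% .stopwords]
  toks
}

# missing-value sentinel: empty cells and literal "NA" are both null
.is_missing_cell <- function(x) {
  is.na(x) | x == "" | x == "NA"
}

.clean_cells <- function(x) {
  x[.is_missing_cell(x)] <- NA_character_
  x
}

# minimal round-trip rendering of a double (used by the DSL printer and
# the integration exporter)
.num_str <- function(v) {
  if (is.na(v)) return(NA_character_)
  if (v == floor(v) && abs(v) < 1e15) {
    return(format(v, scientific = FALSE, trim = TRUE))
  }
  format(v, digits = 15, scientific = FALSE, trim = TRUE)
}

.as_num <- function(x) {
  if (is.numeric(x)) return(x)
  suppressWarnings(as.numeric(x))
}

# run an expression with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "harmonix")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}
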