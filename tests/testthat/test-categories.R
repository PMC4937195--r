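cats <- function(codes, labels) {
  data.frame(code = codes, label = labels, stringsAsFactors = FALSE)
}

test_that("bigram similarity is symmetric, bounded, and exact on equality", {
  expect_equal(ngram_similarity("Male", "Male"), 1)
  expect_equal(ngram_similarity("", "x"), 0)
  expect_equal(ngram_similarity("", ""), 1)
  expect_lt(ngram_similarity("Male", "Female"),
            ngram_similarity("Female", "Female"))
  strs <- random_strings(40, seed = 21)
  for (i in seq_len(30)) {
    a <- sample(strs, 1); b <- sample(strs, 1)
    s <- ngram_similarity(a, b)
    expect_equal(s, ngram_similarity(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("bigram similarity equals the brute-force Dice oracle on random pairs", {
  strs <- random_strings(60, seed = 8)
  set.seed(9)
  for (i in seq_len(1000)) {
    a <- sample(strs, 1); b <- sample(strs, 1)
    expect_equal(ngram_similarity(a, b), oracle_dice(a, b),
                 tolerance = 1e-12, info = paste(a, "|", b))
  }
})

test_that("lexical matching recodes the gender example and is the identity on itself", {
  target <- cats(c("0", "1"), c("Male", "Female"))
  source <- cats(c("1", "2"), c("Male", "Female"))
  m <- match_lexical(target, source)
  expect_equal(m$pairs$target_code[m$pairs$source_code == "1"], "0")
  expect_equal(m$pairs$target_code[m$pairs$source_code == "2"], "1")
  expect_true(all(m$pairs$provenance == "lexical"))
  expect_equal(generate_map_snippet(m, "SEX"),
               "$('SEX').map({'1':'0','2':'1'})")

  # identity on any category list with distinct labels
  for (seed in c(2, 31)) {
    set.seed(seed)
    labels <- unique(replicate(5, paste(sample(letters, 6), collapse = "")))
    cc <- cats(as.character(seq_along(labels)), labels)
    self <- match_lexical(cc, cc)
    expect_equal(self$pairs$target_code, self$pairs$source_code)
  }

  # many-to-one is allowed, each source takes its argmax target
  t2 <- cats(c("a", "b"), c("red wine", "beer"))
  s3 <- cats(c("1", "2", "3"), c("red wine", "white wine", "lager beer"))
  m3 <- match_lexical(t2, s3)
  expect_equal(nrow(m3$pairs), 3)
  for (i in seq_len(3)) {
    sims <- vapply(t2$label, ngram_similarity, numeric(1), a = s3$label[i])
    expect_equal(m3$pairs$target_code[i], t2$code[which.max(sims)])
  }
})

test_that("frequency labels quantify as amount, time unit and daily rate", {
  f <- parse_frequency("2–4 times a week")
  expect_equal(f$amount, 3)
  expect_equal(f$time_unit, "week")
  expect_equal(f$rate_per_day, 3 / 7)

  expect_equal(parse_frequency("once a day")$amount, 1)
  expect_equal(parse_frequency("once a day")$time_unit, "day")
  expect_equal(parse_frequency("twice per week")$amount, 2)
  expect_equal(parse_frequency("5 times a month")$rate_per_day, 5 / 30.44)
  expect_equal(parse_frequency("daily")$rate_per_day, 1)
  expect_equal(parse_frequency("every day")$rate_per_day, 1)
  expect_equal(parse_frequency("3 per week")$amount, 3)
  expect_null(parse_frequency("Male"))
  expect_null(parse_frequency("never"))
})

test_that("frequency matching picks the nearest daily rate, many-to-one allowed", {
  targets <- cats(c("1", "2"), c("1-3 per week", "5-7 per week"))
  m <- match_frequency(targets, cats("a", "2-4 times a week"))
  expect_equal(m$pairs$target_code, "1")  # |3-2|/7 < |3-6|/7
  expect_equal(m$pairs$provenance, "frequency")

  ident <- match_frequency(targets, targets)
  expect_equal(ident$pairs$target_code, ident$pairs$source_code)

  t_day <- cats(c("1", "2"), c("4-6 times a week", "every day"))
  m2 <- match_frequency(t_day, cats(c("x", "y"),
                                    c("daily", "6-7 times a week")))
  expect_equal(m2$pairs$target_code, c("2", "2"))
})

test_that("hard rules fire before other matchers and conflicts are errors", {
  target <- cats(c("0", "1"), c("No", "Yes"))
  source <- cats(c("1", "2"), c("Never", "Ever"))
  fixed <- apply_rules(target, source)
  expect_equal(fixed$pairs$target_code[fixed$pairs$source_code == "1"], "0")
  expect_equal(fixed$pairs$target_code[fixed$pairs$source_code == "2"], "1")
  expect_true(all(fixed$pairs$provenance == "rule"))

  expect_equal(nrow(apply_rules(target, source, rules = NULL)$pairs), 0)

  # a higher-priority rule overrides the lexical best match
  t2 <- cats(c("0", "1"), c("no", "none"))
  s2 <- cats("9", "never")
  lex_pick <- match_lexical(t2, s2)$pairs$target_code  # "none" is closer
  expect_equal(lex_pick, "1")
  piped <- match_categories(t2, s2)
  expect_equal(piped$pairs$target_code, "0")  # rule never->no wins
  expect_equal(piped$pairs$provenance, "rule")

  conflicting <- data.frame(
    source_pattern = c("^never$", "^never$"),
    target_pattern = c("^no$", "^none$"), priority = c(5L, 5L),
    stringsAsFactors = FALSE)
  expect_error(apply_rules(t2, s2, conflicting), "conflicting")

  # missing-like labels map to null and are reported unmapped
  t3 <- cats(c("0", "1"), c("No", "Yes"))
  m3 <- match_categories(t3, cats(c("1", "9"), c("Yes", "Unknown")))
  expect_equal(m3$unmapped, "9")
  expect_false("9" %in% m3$pairs$source_code)
})

test_that("the pipeline records one provenance per pair with rules > frequency > lexical", {
  target <- cats(c("1", "2", "3", "4"),
                 c("Never", "1-3 times a week", "4-6 times a week",
                   "Every day"))
  source <- cats(c("1", "2", "3", "4"),
                 c("never", "2-4 times a week", "6-7 times a week",
                   "once a day"))
  m <- match_categories(target, source)
  prov <- setNames(m$pairs$provenance, m$pairs$source_code)
  expect_equal(unname(prov["1"]), "rule")
  expect_true(all(prov[c("2", "3", "4")] == "frequency"))
  expect_equal(setNames(m$pairs$target_code, m$pairs$source_code),
               c("1" = "1", "2" = "2", "3" = "4", "4" = "4"))

  # a gender-style fixture goes through lexically
  g <- match_categories(cats(c("0", "1"), c("Male", "Female")),
                        cats(c("1", "2"), c("Male", "Female")))
  expect_true(all(g$pairs$provenance == "lexical"))
})

test_that("map snippets round-trip through the interpreter on all source codes", {
  target <- cats(c("0", "1"), c("Male", "Female"))
  source <- cats(c("1", "2"), c("Male", "Female"))
  m <- match_categories(target, source)
  snippet <- generate_map_snippet(m, "SEX")
  e <- emx_entity("t", list(emx_attribute("SEX", "t", "string", "Sex")))
  for (i in seq_len(nrow(source))) {
    got <- dsl_evaluate(snippet, list(SEX = source$code[i]), e)
    expect_equal(got, m$pairs$target_code[m$pairs$source_code ==
                                            source$code[i]])
  }
  empty <- structure(list(pairs = m$pairs[0, ], unmapped = character(0)),
                     class = "category_map")
  expect_error(generate_map_snippet(empty, "SEX"), "empty")
})
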