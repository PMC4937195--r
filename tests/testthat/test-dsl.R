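test_that("chained calls, maps and accessors parse to the expected trees", {
  s <- dsl_parse("$('var').div(2)")
  expect_equal(s$ast$kind, "call")
  expect_equal(s$ast$method, "div")
  expect_equal(s$ast$receiver, list(kind = "attr", name = "var"))
  expect_equal(s$ast$args[[1]]$value, 2)

  bare <- dsl_parse("$('x')")
  expect_equal(bare$ast, list(kind = "attr", name = "x"))

  m <- dsl_parse("$('SEX').map({'1':'0','2':'1'})")
  expect_equal(m$ast$args[[1]]$pairs, c("1" = "0", "2" = "1"))

  # typographic quotes from typeset text are accepted
  curly <- dsl_parse("$(‘var’).div(2)")
  expect_equal(curly$text, "$('var').div(2)")
})

test_that("syntax errors carry a position and unknown methods are rejected", {
  expect_error(dsl_parse("$('x').frobnicate(1)", ), "unknown method")
  expect_error(dsl_parse("$('x').div(2"), "syntax error at position")
  expect_error(dsl_parse("$('x') ? '1' : '0'"), "template-only")
  expect_error(dsl_parse(""), "non-empty")
})

test_that("print-parse is a fixpoint on handwritten and generated scripts", {
  fix <- c("$('Height').div(100).value()",
           "$('SEX').map({'1':'0','2':'1'})",
           "$('w').div($('h').div(100).pow(2)).value()",
           "$('x').unit('cm').toUnit('m').value()",
           "$('x').times(0.001).value()")
  for (txt in fix) {
    s <- dsl_parse(txt)
    expect_equal(dsl_format(s), txt)
    expect_equal(dsl_parse(dsl_format(s))$ast, s$ast)
  }
  # randomly generated arithmetic chains
  set.seed(7)
  for (i in 1:25) {
    ops <- sample(c("div", "times", "plus", "pow"), sample(1:4, 1),
                  replace = TRUE)
    consts <- round(runif(length(ops), 0.5, 99), 3)
    txt <- paste0("$('x')",
                  paste0(".", ops, "(", vapply(consts, harmonix:::.num_str,
                                               character(1)), ")",
                         collapse = ""),
                  ".value()")
    s <- dsl_parse(txt)
    expect_equal(dsl_format(s), txt)
    expect_equal(dsl_parse(dsl_format(s))$ast, s$ast)
  }
})

test_that("evaluation reproduces the printed conversions and recodes", {
  e <- emx_entity("t", list(
    emx_attribute("Height", "t", "decimal", "Height"),
    emx_attribute("SEX", "t", "string", "Sex")))
  row <- list(Height = "180", SEX = "1")
  expect_equal(dsl_evaluate("$('Height').div(100).value()", row, e), 1.8)
  expect_equal(dsl_evaluate("$('SEX').map({'1':'0','2':'1'})", row, e), "0")
  expect_equal(dsl_evaluate("$('Height').unit('cm').toUnit('m').value()",
                            row, e), 1.8)
  expect_equal(dsl_evaluate("$('Height').plus(5).times(2).value()", row, e),
               370)
  expect_equal(dsl_evaluate("$('Height').pow(2).value()", row, e), 32400)
})

test_that("null is absorbing and error cases behave as documented", {
  e <- emx_entity("t", list(emx_attribute("Height", "t", "decimal", "Height"),
                            emx_attribute("SEX", "t", "string", "Sex")))
  null_row <- list(Height = NA, SEX = NA)
  set.seed(11)
  for (i in 1:20) {
    ops <- sample(c("div", "times", "plus", "pow"), sample(1:3, 1),
                  replace = TRUE)
    txt <- paste0("$('Height')",
                  paste0(".", ops, "(", sample(1:9, length(ops), TRUE), ")",
                         collapse = ""), ".value()")
    expect_true(is.na(dsl_evaluate(txt, null_row, e)), info = txt)
  }
  # unmapped code -> null, not an error
  expect_true(is.na(dsl_evaluate("$('SEX').map({'1':'0'})",
                                 list(Height = "1", SEX = "9"), e)))
  # division by zero -> null with a warning
  expect_warning(
    v <- dsl_evaluate("$('Height').div(0).value()", list(Height = "2"), e),
    "division by zero")
  expect_true(is.na(v))
  # absent attribute -> evaluation error
  expect_error(dsl_evaluate("$('Nope').value()", list(Height = "2"), e),
               "absent")
  # toUnit without unit -> evaluation error
  expect_error(dsl_evaluate("$('Height').toUnit('m').value()",
                            list(Height = "2"), e), "unit\\(\\)")
})

test_that("evaluation is pure and the two unit syntaxes agree", {
  e <- emx_entity("t", list(emx_attribute("Height", "t", "decimal", "H")))
  set.seed(5)
  for (h in c(sample(120:210, 10), 0.5)) {
    row <- list(Height = as.character(h))
    chain <- dsl_evaluate("$('Height').unit('cm').toUnit('m').value()", row, e)
    formula <- dsl_evaluate("$('Height').div(100).value()", row, e)
    expect_equal(chain, formula, tolerance = 1e-9)
    expect_identical(chain,
                     dsl_evaluate("$('Height').unit('cm').toUnit('m').value()",
                                  row, e))
  }
})

test_that("referenced attributes are exactly the accessors in the tree", {
  bmi <- "$('WEIGHT_1').div($('LENGT_1').div(100).pow(2)).value()"
  expect_setequal(dsl_referenced_attributes(bmi), c("WEIGHT_1", "LENGT_1"))
  expect_length(dsl_referenced_attributes(dsl_parse("$('x').div(2)")), 1)
  dup <- "$('a').plus($('a')).value()"
  expect_equal(dsl_referenced_attributes(dup), "a")
})

test_that("the conditional extension evaluates cutoff logic for templates", {
  e <- emx_entity("t", list(emx_attribute("SBP", "t", "decimal", "sbp"),
                            emx_attribute("DBP", "t", "decimal", "dbp")))
  script <- dsl_parse("$('SBP') >= 140 || $('DBP') >= 90 ? '1' : '0'",
                      allow_conditional = TRUE)
  expect_equal(dsl_evaluate(script, list(SBP = "150", DBP = "80"), e), "1")
  expect_equal(dsl_evaluate(script, list(SBP = "120", DBP = "95"), e), "1")
  expect_equal(dsl_evaluate(script, list(SBP = "120", DBP = "80"), e), "0")
  expect_true(is.na(dsl_evaluate(script, list(SBP = NA, DBP = "80"), e)))
  # one sufficient TRUE decides an OR even when the other side is null
  expect_equal(dsl_evaluate(script, list(SBP = "150", DBP = NA), e), "1")
  # canonical form reparses equal
  expect_equal(dsl_parse(script$text, allow_conditional = TRUE)$ast,
               script$ast)
})
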