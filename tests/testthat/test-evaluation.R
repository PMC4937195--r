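test_that("search classes follow the rank-1 / top-20 definitions", {
  cands <- structure(
    data.frame(entity = "s", name = paste0("a", 1:25),
               label = paste0("a", 1:25), description = "",
               score = seq(25, 1), rank = 1:25, stringsAsFactors = FALSE),
    class = c("match_candidates", "data.frame"))
  expect_equal(classify_search(cands, "a1"), "perfect")
  expect_equal(classify_search(cands, c("a2", "a15")), "good")
  expect_equal(classify_search(cands, c("a2", "a25")), "bad")
  expect_equal(classify_search(cands, "zzz"), "bad")
  expect_equal(classify_search(NULL, "a1"), "bad")
  # a gold attribute at rank 1 among several decides perfect
  expect_equal(classify_search(cands, c("a1", "a19")), "perfect")
})

test_that("functional equivalence compares values row by row", {
  e <- emx_entity("t", list(
    emx_attribute("H", "t", "decimal", "Height (cm)"),
    emx_attribute("S", "t", "string", "Sex")),
    data.frame(H = c("180", "164.4", NA, "150"),
               S = c("1", "2", "1", "9"), stringsAsFactors = FALSE))
  expect_true(functionally_equivalent("$('H').div(100).value()",
                                      "$('H').unit('cm').toUnit('m').value()",
                                      e))
  s <- "$('S').map({'1':'0','2':'1'})"
  expect_true(functionally_equivalent(s, s, e))
  # a map missing a pair differs on data containing that code
  expect_false(functionally_equivalent("$('S').map({'1':'0'})",
                                       "$('S').map({'1':'0','9':'2'})", e))
  expect_false(functionally_equivalent("$('H').div(100).value()",
                                       "$('H').div(10).value()", e))
})

test_that("algorithm classes distinguish perfect, half-right and wrong scripts", {
  e <- emx_entity("t", list(
    emx_attribute("W", "t", "decimal", "Weight (kg)"),
    emx_attribute("H", "t", "decimal", "Length (cm)"),
    emx_attribute("S", "t", "string", "Sex"),
    emx_attribute("X", "t", "decimal", "Other")),
    data.frame(W = c("81", "70"), H = c("180", "164"), S = c("1", "2"),
               X = c("1", "2"), stringsAsFactors = FALSE))
  ref_bmi <- "$('W').div($('H').div(100).pow(2)).value()"
  # an equivalent variant counts as perfect even when written differently
  variant <- "$('W').times(10000).div($('H').pow(2)).value()"
  expect_equal(classify_algorithm(variant, ref_bmi, e), "perfect")
  expect_equal(classify_algorithm(ref_bmi, ref_bmi, e), "perfect")

  ref_map <- "$('S').map({'1':'0','2':'1'})"
  expect_equal(classify_algorithm("$('S').map({'1':'0'})", ref_map, e),
               "good")
  expect_equal(classify_algorithm("$('S').map({'1':'9'})", ref_map, e),
               "bad")
  # right attribute, missing conversion: good
  expect_equal(classify_algorithm("$('H').value()",
                                  "$('H').div(100).value()", e), "good")
  # wrong source attribute entirely: bad
  expect_equal(classify_algorithm("$('X').value()",
                                  "$('H').div(100).value()", e), "bad")
  expect_equal(classify_algorithm(NULL, ref_map, e), "bad")
})

test_that("project evaluation cross-tabulates and sums the useful cells", {
  fx <- generate_fixture(seed = 13, n_rows = 15, n_biobanks = 2)
  project <- generate_project(fx$target, fx$sources, store = fx$ontology)
  report <- evaluate_project(project, fx$gold)
  expect_equal(sum(report$table_pct), 100, tolerance = 0.1)
  expect_equal(nrow(report$per_target), nrow(fx$gold))
  expect_true(all(report$per_target$search_class %in%
                    c("perfect", "good", "bad")))
  # an all-perfect toy project concentrates in one cell
  if (all(report$per_target$search_class == "perfect") &&
      all(report$per_target$algorithm_class == "perfect")) {
    expect_equal(unname(report$table_pct["perfect", "perfect"]), 100)
    expect_equal(report$useful_pct, 100)
  }
  # classifications are order-independent
  rev_gold <- fx$gold[rev(seq_len(nrow(fx$gold))), ]
  report2 <- evaluate_project(project, rev_gold)
  merged <- merge(report$per_target, report2$per_target,
                  by = c("target", "source"))
  expect_equal(merged$search_class.x, merged$search_class.y)
  expect_equal(merged$algorithm_class.x, merged$algorithm_class.y)
})

test_that("hand-classified mixed fixture matches the report", {
  fx <- generate_fixture(seed = 17, n_rows = 10, n_biobanks = 1)
  project <- generate_project(fx$target, fx$sources, store = fx$ontology)
  # sabotage two cells to known classes
  project <- curate_cell(project, "biobank_a", "gender",
                         "$('SEX').map({'1':'9','2':'8'})")  # contradicts ref
  project <- curate_cell(project, "biobank_a", "height",
                         "$('HEIGHT').div(100).value()")  # wrong conversion
  report <- evaluate_project(project, fx$gold)
  pt <- report$per_target
  expect_equal(pt$algorithm_class[pt$target == "gender"], "bad")
  expect_equal(pt$algorithm_class[pt$target == "height"], "good")
  expect_equal(pt$algorithm_class[pt$target == "bmi"], "perfect")
})

test_that("gold standards round-trip through their TSV form", {
  fx <- generate_fixture(seed = 3, n_rows = 5, n_biobanks = 2)
  path <- tempfile(fileext = ".tsv")
  write_gold(fx$gold, path)
  back <- read_gold(path)
  expect_equal(back, fx$gold)
  unlink(path)
})
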