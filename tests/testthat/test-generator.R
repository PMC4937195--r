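fx <- generate_fixture(seed = 42, n_rows = 20, n_biobanks = 3)
tgt <- fx$target$entities$hop$attributes

test_that("the BMI template is found for a BMI target but not for plain attributes", {
  cat <- default_template_catalogue()
  t_bmi <- find_template(tgt$bmi, cat)
  expect_equal(t_bmi$name, "bmi")
  expect_equal(attr(t_bmi, "basis"), "target")

  expect_null(find_template(tgt$gender, cat))

  # a length-in-cm candidate proposes the template via its height slot,
  # but only as a candidate-based proposal
  idx <- index_source(fx$sources$biobank_b)
  cands <- shortlist(tgt$height, idx, fx$ontology)
  t_prop <- find_template(tgt$height, cat, cands)
  expect_equal(attr(t_prop, "basis"), "candidate")
})

test_that("template filling inserts the cm-to-m conversion and picks the right slots", {
  idx <- index_source(fx$sources$biobank_b)
  cands <- shortlist(tgt$bmi, idx, fx$ontology)
  alg <- fill_template(default_template_catalogue()$bmi, cands)
  expect_equal(alg$script$text,
               "$('WEIGHT_1').div($('LENGT_1').div(100).pow(2)).value()")
  expect_setequal(alg$script$referenced_attributes,
                  c("WEIGHT_1", "LENGT_1"))
  expect_equal(alg$provenance, "template")

  # slots already in the expected units: no conversion inserted
  src3 <- fx$sources$biobank_c
  cands3 <- shortlist(tgt$bmi, index_source(src3), fx$ontology)
  alg3 <- fill_template(default_template_catalogue()$bmi, cands3)
  expect_true(grepl("\\$\\('STATURE'\\)\\.pow\\(2\\)", alg3$script$text))

  # wrong-dimension candidates for a slot make the template fail
  odd <- emx_schema(list(emx_entity("o", list(
    emx_attribute("W", "o", "decimal", "Body weight in mmHg"),
    emx_attribute("H", "o", "decimal", "Standing height in cm")))))
  cands_odd <- shortlist(tgt$bmi, index_source(odd), fx$ontology)
  expect_null(fill_template(default_template_catalogue()$bmi, cands_odd))
})

test_that("generated algorithms follow the fallback order and reference only candidates", {
  src <- fx$sources$biobank_a
  store <- fx$ontology

  height <- generate_algorithm(tgt$height, src, store = store)
  expect_equal(height$provenance, "rename")
  expect_equal(height$script$text, "$('HEIGHT').value()")

  gender <- generate_algorithm(tgt$gender, src, store = store)
  expect_equal(gender$provenance, "category_map")
  expect_equal(gender$script$text, "$('SEX').map({'1':'0','2':'1'})")

  bmi <- generate_algorithm(tgt$bmi, src, store = store)
  expect_equal(bmi$provenance, "template")

  weight3 <- generate_algorithm(tgt$weight, fx$sources$biobank_c,
                                store = store)
  expect_equal(weight3$provenance, "unit_conversion")
  expect_equal(weight3$script$text, "$('WT_G').div(1000).value()")

  # every generated script parses and references only schema attributes
  for (sn in names(fx$sources)) {
    for (an in names(tgt)) {
      alg <- generate_algorithm(tgt[[an]], fx$sources[[sn]], store = store)
      if (is.null(alg)) next
      refs <- alg$script$referenced_attributes
      ent_attrs <- unlist(lapply(fx$sources[[sn]]$entities,
                                 function(e) names(e$attributes)))
      expect_true(all(refs %in% ent_attrs), info = paste(sn, an))
    }
  }
  # no candidates at all -> no algorithm
  empty <- emx_schema(list(emx_entity("e", list(
    emx_attribute("Z", "e", "string", "zirconium trace")))))
  expect_null(generate_algorithm(tgt$gender, empty, store = store))
})

test_that("chain and formula styles generate functionally equivalent projects", {
  src <- fx$sources$biobank_c
  w_formula <- generate_algorithm(tgt$weight, src, store = fx$ontology,
                                  unit_style = "formula")
  w_chain <- generate_algorithm(tgt$weight, src, store = fx$ontology,
                                unit_style = "chain")
  expect_equal(w_chain$script$text,
               "$('WT_G').unit('g').toUnit('kg').value()")
  entity <- src$entities$biobank_c
  expect_true(functionally_equivalent(w_formula$script, w_chain$script,
                                      entity))
})

test_that("a project covers targets x sources and curation survives regeneration", {
  small <- generate_fixture(seed = 1, n_rows = 5, n_biobanks = 2)
  project <- generate_project(small$target, small$sources,
                              store = small$ontology)
  expect_equal(length(project$cells), 2)
  for (sn in names(project$cells)) {
    expect_equal(length(project$cells[[sn]]),
                 length(small$target$entities$hop$attributes))
  }
  states <- unlist(lapply(project$cells, function(cs)
    vapply(cs, `[[`, character(1), "state")))
  expect_true(all(states %in% c("generated-high", "generated-low", "missing")))

  project <- curate_cell(project, "biobank_a", "height",
                         "$('HEIGHT').div(100).value()")
  expect_equal(project$cells$biobank_a$height$state, "curated")
  before <- project$cells$biobank_a$height$algorithm$script$text
  project2 <- regenerate_project(project)
  expect_equal(project2$cells$biobank_a$height$algorithm$script$text, before)
  expect_equal(project2$cells$biobank_a$height$state, "curated")
  # other cells regenerate to the same states
  expect_equal(project2$cells$biobank_a$gender$state,
               project$cells$biobank_a$gender$state)
  # forcing overwrites curated content
  project3 <- regenerate_project(project2, force = TRUE)
  expect_true(grepl("^generated-", project3$cells$biobank_a$height$state))
  expect_equal(project3$cells$biobank_a$height$algorithm$script$text,
               "$('HEIGHT').value()")
})

test_that("projects persist to JSON and read back with their scripts", {
  small <- generate_fixture(seed = 2, n_rows = 5, n_biobanks = 1)
  project <- generate_project(small$target, small$sources,
                              store = small$ontology)
  path <- tempfile(fileext = ".json")
  write_project(project, path)
  back <- read_project(path, small$target, small$sources)
  for (an in names(project$cells$biobank_a)) {
    a1 <- project$cells$biobank_a[[an]]
    a2 <- back$cells$biobank_a[[an]]
    expect_equal(a2$state, a1$state, info = an)
    if (!is.null(a1$algorithm)) {
      expect_equal(a2$algorithm$script$text, a1$algorithm$script$text,
                   info = an)
    }
  }
  unlink(path)
})
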