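#' @title Synthetic multi-biobank fixtures
#'
#' @description
#' The fixture generator emulates the setting of a pooled-analysis
#' harmonization study: a target schema of core phenotype variables
#' (standing height, body weight, gender, body-mass index, a
#' food-frequency scale, hypertension) and up to three source biobanks
#' whose dictionaries diverge in terminology (height vs length vs
#' stature), units (cm vs m, kg vs g), and category codings (1/2 vs M/F
#' vs m/f gender codes; different frequency scales), plus distractor
#' attributes. Participants are shared across biobanks, so the cm-coded
#' heights are exactly 100 times the m-coded biobank's values for the
#' same participant id. A gold standard of human mappings and reference
#' scripts, and a small phenotype ontology whose synonyms are required to
#' find some of the matches (hypertension is only findable via its
#' "high blood pressure" synonym), complete the fixture.
#'
#' @name fixtures
NULL

.fixture_ontology_text <- function() {
  c("format-version: 1.2",
    "",
    "[Term]", "id: FX:0000000", "name: phenotype",
    "",
    "[Term]", "id: FX:0000010", "name: anthropometry",
    "is_a: FX:0000000 ! phenotype",
    "",
    "[Term]", "id: FX:0000011", "name: height",
    'synonym: "standing height" EXACT []',
    'synonym: "body length" EXACT []',
    'synonym: "length" RELATED []',
    'synonym: "stature" EXACT []',
    "is_a: FX:0000010 ! anthropometry",
    "",
    "[Term]", "id: FX:0000012", "name: weight",
    'synonym: "body weight" EXACT []',
    "is_a: FX:0000010 ! anthropometry",
    "",
    "[Term]", "id: FX:0000013", "name: body mass index",
    'synonym: "BMI" EXACT []',
    'synonym: "Quetelet index" RELATED []',
    "is_a: FX:0000010 ! anthropometry",
    "",
    "[Term]", "id: FX:0000020", "name: gender",
    'synonym: "sex" EXACT []',
    "is_a: FX:0000000 ! phenotype",
    "",
    "[Term]", "id: FX:0000030", "name: hypertension",
    'synonym: "high blood pressure" EXACT []',
    'synonym: "elevated blood pressure" RELATED []',
    "is_a: FX:0000000 ! phenotype",
    "",
    "[Term]", "id: FX:0000040", "name: food",
    "is_a: FX:0000000 ! phenotype",
    "",
    "[Term]", "id: FX:0000041", "name: vegetable",
    "is_a: FX:0000040 ! food",
    "",
    "[Term]", "id: FX:0000042", "name: potato",
    'synonym: "potatoes" EXACT []',
    "is_a: FX:0000041 ! vegetable",
    "",
    "[Term]", "id: FX:0000043", "name: poultry",
    "is_a: FX:0000040 ! food",
    "",
    "[Term]", "id: FX:0000044", "name: chicken",
    "is_a: FX:0000043 ! poultry")
}

.cat_entity <- function(name, codes, labels) {
  emx_entity(name,
             list(emx_attribute("code", name, "string"),
                  emx_attribute("label", name, "string")),
             data.frame(code = codes, label = labels,
                        stringsAsFactors = FALSE))
}

.cat_attr <- function(name, entity, label, ref, codes, labels,
                      description = "") {
  emx_attribute(name, entity, "categorical", label, description,
                ref_entity = ref,
                categories = data.frame(code = codes, label = labels,
                                        stringsAsFactors = FALSE))
}

.fixture_target <- function() {
  ent <- "hop"
  attrs <- list(
    emx_attribute("height", ent, "decimal", "Measured Standing Height",
                  "Standing height of the participant"),
    emx_attribute("weight", ent, "decimal", "Body weight in kg",
                  "Measured body weight of the participant"),
    .cat_attr("gender", ent, "Gender", "genders",
              c("0", "1"), c("Male", "Female")),
    emx_attribute("bmi", ent, "decimal", "Body Mass Index (kg/m^2)",
                  "Calculated from standing height and body weight"),
    .cat_attr("potato", ent, "Frequency of potato consumption",
              "potato_freq", c("1", "2", "3", "4"),
              c("Never", "1-3 times a week", "4-6 times a week",
                "Every day")),
    .cat_attr("hypertension", ent, "Hypertension", "yesno",
              c("0", "1"), c("No", "Yes")))
  emx_schema(list(
    emx_entity(ent, attrs),
    .cat_entity("genders", c("0", "1"), c("Male", "Female")),
    .cat_entity("potato_freq", c("1", "2", "3", "4"),
                c("Never", "1-3 times a week", "4-6 times a week",
                  "Every day")),
    .cat_entity("yesno", c("0", "1"), c("No", "Yes"))))
}

# shared participant table; biobank sheets are derived views of it
.fixture_participants <- function(n_rows, missing_rate = 0.02) {
  height_cm <- round(stats::rnorm(n_rows, 170, 10), 1)
  weight_kg <- round(stats::rnorm(n_rows, 75, 12), 1)
  miss <- function(x) {
    x[stats::runif(length(x)) < missing_rate] <- NA
    x
  }
  data.frame(
    id = as.character(seq_len(n_rows)),
    height_cm = miss(height_cm),
    weight_kg = miss(weight_kg),
    sex12 = sample(c("1", "2"), n_rows, replace = TRUE),
    potato = sample(c("1", "2", "3", "4"), n_rows, replace = TRUE),
    hbp12 = sample(c("1", "2"), n_rows, replace = TRUE),
    smoke = sample(c("0", "1"), n_rows, replace = TRUE),
    edu = sample(c("1", "2", "3"), n_rows, replace = TRUE),
    stringsAsFactors = FALSE)
}

.chr <- function(x) ifelse(is.na(x), NA_character_, as.character(x))

.fixture_biobank <- function(archetype, name, p) {
  if (archetype == 1) {  # cm heights, kg weights, 1/2 gender codes
    ent <- name
    attrs <- list(
      emx_attribute("ID", ent, "string", "Participant identifier"),
      emx_attribute("HEIGHT", ent, "decimal", "Height in cm"),
      emx_attribute("WEIGHT", ent, "decimal", "Weight in kg"),
      .cat_attr("SEX", ent, "Sex", "sex_codes",
                c("1", "2"), c("Male", "Female")),
      .cat_attr("POTATO", ent, "Potato consumption", "potato_codes",
                c("1", "2", "3", "4"),
                c("never", "2-4 times a week", "6-7 times a week",
                  "once a day")),
      .cat_attr("HBP", ent, "High blood pressure ever diagnosed",
                "hbp_codes", c("1", "2"), c("Yes", "No")),
      .cat_attr("SMOKE", ent, "Current smoking status", "smoke_codes",
                c("0", "1"), c("No", "Yes")),
      emx_attribute("EDU", ent, "string", "Highest education level"))
    data <- data.frame(ID = p$id, HEIGHT = .chr(p$height_cm),
                       WEIGHT = .chr(p$weight_kg), SEX = p$sex12,
                       POTATO = p$potato, HBP = p$hbp12, SMOKE = p$smoke,
                       EDU = p$edu, stringsAsFactors = FALSE)
    cats <- list(
      .cat_entity("sex_codes", c("1", "2"), c("Male", "Female")),
      .cat_entity("potato_codes", c("1", "2", "3", "4"),
                  c("never", "2-4 times a week", "6-7 times a week",
                    "once a day")),
      .cat_entity("hbp_codes", c("1", "2"), c("Yes", "No")),
      .cat_entity("smoke_codes", c("0", "1"), c("No", "Yes")))
  } else if (archetype == 2) {  # "length" terminology, parenthesized units
    ent <- name
    attrs <- list(
      emx_attribute("ID_2", ent, "string", "Participant identifier"),
      emx_attribute("LENGT_1", ent, "decimal", "Length (cm)"),
      emx_attribute("WEIGHT_1", ent, "decimal", "Weight (kg)"),
      .cat_attr("GENDER_P", ent, "Sex of participant", "gp_codes",
                c("F", "M"), c("Female", "Male")),
      .cat_attr("POTATO_2", ent, "Consumption of potatoes", "pf_codes",
                c("1", "2", "3", "4"),
                c("never", "1-3 times per week", "4-6 times per week",
                  "every day")),
      .cat_attr("HT_2", ent, "Diagnosed high blood pressure", "ht_codes",
                c("0", "1"), c("no", "yes")),
      emx_attribute("CREAT", ent, "decimal", "Serum creatinine (mg/dL)"))
    data <- data.frame(ID_2 = p$id, LENGT_1 = .chr(p$height_cm),
                       WEIGHT_1 = .chr(p$weight_kg),
                       GENDER_P = ifelse(p$sex12 == "1", "M", "F"),
                       POTATO_2 = p$potato,
                       HT_2 = ifelse(p$hbp12 == "1", "1", "0"),
                       CREAT = .chr(round(stats::runif(nrow(p), 0.6, 1.3), 2)),
                       stringsAsFactors = FALSE)
    cats <- list(
      .cat_entity("gp_codes", c("F", "M"), c("Female", "Male")),
      .cat_entity("pf_codes", c("1", "2", "3", "4"),
                  c("never", "1-3 times per week", "4-6 times per week",
                    "every day")),
      .cat_entity("ht_codes", c("0", "1"), c("no", "yes")))
  } else {  # m heights, gram weights, letter gender codes
    ent <- name
    attrs <- list(
      emx_attribute("ID_3", ent, "string", "Participant identifier"),
      emx_attribute("STATURE", ent, "decimal", "Standing height in m"),
      emx_attribute("WT_G", ent, "decimal", "Body weight in gram"),
      .cat_attr("SEX3", ent, "Gender", "sx_codes",
                c("f", "m"), c("Female", "Male")),
      .cat_attr("POTATO_3", ent, "Potato intake frequency", "pi_codes",
                c("A", "B", "C", "D"),
                c("never", "2-4 times a week", "once a day",
                  "6-7 times a week")),
      .cat_attr("HBP3", ent, "High blood pressure", "hb_codes",
                c("n", "y"), c("No", "Yes")),
      emx_attribute("DOB", ent, "string", "Date of birth"))
    data <- data.frame(
      ID_3 = p$id,
      STATURE = .chr(ifelse(is.na(p$height_cm), NA, p$height_cm / 100)),
      WT_G = .chr(ifelse(is.na(p$weight_kg), NA, p$weight_kg * 1000)),
      SEX3 = ifelse(p$sex12 == "1", "m", "f"),
      POTATO_3 = c("1" = "A", "2" = "B", "3" = "D", "4" = "C")[p$potato],
      HBP3 = ifelse(p$hbp12 == "1", "y", "n"),
      DOB = paste0(sample(1940:1990, nrow(p), replace = TRUE), "-06-15"),
      stringsAsFactors = FALSE)
    cats <- list(
      .cat_entity("sx_codes", c("f", "m"), c("Female", "Male")),
      .cat_entity("pi_codes", c("A", "B", "C", "D"),
                  c("never", "2-4 times a week", "once a day",
                    "6-7 times a week")),
      .cat_entity("hb_codes", c("n", "y"), c("No", "Yes")))
  }
  emx_schema(c(list(emx_entity(ent, attrs, data)), cats))
}

.fixture_gold <- function(source_names, archetypes) {
  rows <- list()
  add <- function(target, source, attrs, script) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, source = source, source_attrs = attrs,
      reference_script = script, stringsAsFactors = FALSE)
  }
  for (i in seq_along(source_names)) {
    sn <- source_names[i]
    if (archetypes[i] == 1) {
      add("height", sn, "HEIGHT", "$('HEIGHT').value()")
      add("weight", sn, "WEIGHT", "$('WEIGHT').value()")
      add("gender", sn, "SEX", "$('SEX').map({'1':'0','2':'1'})")
      add("bmi", sn, "WEIGHT;HEIGHT",
          "$('WEIGHT').div($('HEIGHT').div(100).pow(2)).value()")
      add("potato", sn, "POTATO",
          "$('POTATO').map({'1':'1','2':'2','3':'4','4':'4'})")
      add("hypertension", sn, "HBP", "$('HBP').map({'1':'1','2':'0'})")
    } else if (archetypes[i] == 2) {
      add("height", sn, "LENGT_1", "$('LENGT_1').value()")
      add("weight", sn, "WEIGHT_1", "$('WEIGHT_1').value()")
      add("gender", sn, "GENDER_P", "$('GENDER_P').map({'F':'1','M':'0'})")
      add("bmi", sn, "WEIGHT_1;LENGT_1",
          "$('WEIGHT_1').div($('LENGT_1').div(100).pow(2)).value()")
      add("potato", sn, "POTATO_2",
          "$('POTATO_2').map({'1':'1','2':'2','3':'3','4':'4'})")
      add("hypertension", sn, "HT_2", "$('HT_2').map({'0':'0','1':'1'})")
    } else {
      add("height", sn, "STATURE", "$('STATURE').value()")
      add("weight", sn, "WT_G", "$('WT_G').div(1000).value()")
      add("gender", sn, "SEX3", "$('SEX3').map({'f':'1','m':'0'})")
      add("bmi", sn, "WT_G;STATURE",
          "$('WT_G').div(1000).div($('STATURE').pow(2)).value()")
      add("potato", sn, "POTATO_3",
          "$('POTATO_3').map({'A':'1','B':'2','C':'4','D':'4'})")
      add("hypertension", sn, "HBP3", "$('HBP3').map({'n':'0','y':'1'})")
    }
  }
  do.call(rbind, rows)
}

#' Generate a deterministic multi-biobank fixture with gold standard
#'
#' @param seed RNG seed; the whole fixture is a pure function of it.
#' @param n_rows participants per biobank (default 50).
#' @param n_biobanks number of source biobanks, 1-3 distinct archetypes
#'   (more recycle the archetypes under new names; default 3).
#' @return list with `target` (schema), `sources` (named list of
#'   schemas), `gold` (data frame, see [read_gold()]), `ontology`
#'   (phenotype `ontology_store`) and `units` (the packaged `unit_store`).
#' @export
generate_fixture <- function(seed = 42, n_rows = 50, n_biobanks = 3) {
  stopifnot(n_biobanks >= 1)
  .with_seed(seed, {
    p <- .fixture_participants(n_rows)
    archetypes <- ((seq_len(n_biobanks) - 1) %% 3) + 1
    base_names <- c("biobank_a", "biobank_b", "biobank_c")
    source_names <- vapply(seq_len(n_biobanks), function(i) {
      if (i <= 3) base_names[i] else paste0(base_names[archetypes[i]], "_", i)
    }, character(1))
    sources <- list()
    for (i in seq_len(n_biobanks)) {
      sources[[source_names[i]]] <-
        .fixture_biobank(archetypes[i], source_names[i], p)
    }
    obo <- tempfile(fileext = ".obo")
    writeLines(.fixture_ontology_text(), obo)
    ontology <- load_ontology(obo)
    unlink(obo)
    list(target = .fixture_target(), sources = sources,
         gold = .fixture_gold(source_names, archetypes),
         ontology = ontology, units = default_unit_store())
  })
}
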