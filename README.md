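# harmonix

Semi-automatic harmonization and integration of biobank phenotype data.

## The problem

Pooling phenotype data from several biobanks or registries for a combined
analysis requires *retrospective harmonization*: every variable of the
pooled study's target schema must be matched to the right attribute(s) in
each source data dictionary, and a transformation must be written that
makes the source values inferentially equivalent to the target definition
— renaming, unit conversion (`cm → m`, `g → kg`), categorical recoding
(`SEX 1/2 → Gender 0/1`), or a derived quantity such as body-mass index,
`BMI = weight_kg / height_m²`. Done by hand across thousands of candidate
attributes, this is the dominant cost of pooled studies.

harmonix is for the data managers and research teams doing that work. It

1. loads target schemas and source dictionaries from entity/attribute
   workbooks (CSV-set or xlsx),
2. shortlists candidate source attributes per target with BM25 lexical
   search over labels and descriptions, with the query expanded through an
   ontology (synonyms and subclasses — never superclasses),
3. auto-generates transformation algorithms in a small chained-expression
   language (`$('Height').div(100).value()`,
   `$('SEX').map({'1':'0','2':'1'})`), using unit detection and a
   conversion-rule table, a three-stage category matcher
   (rules → frequency quantification → bigram-Dice lexical), and slot-based
   templates for recurring definitions such as BMI,
4. executes a mapping project to derive the integrated dataset with
   per-attribute failure accounting, and
5. scores generated matches and algorithms against a gold standard
   (`perfect` / `good` / `bad` for search and algorithm separately).

## Worked example

The packaged fixture generator builds a deterministic mini-study: a target
schema (height, weight, gender, BMI, a food-frequency scale,
hypertension), three source biobanks with divergent terminology, units and
codings, a phenotype ontology and a gold standard.

```r
library(harmonix)
fx <- generate_fixture(seed = 42, n_rows = 50, n_biobanks = 3)

# shortlist candidates for the BMI target in the cm/kg biobank
idx <- index_source(fx$sources$biobank_b)
bmi <- fx$target$entities$hop$attributes$bmi
shortlist(bmi, idx, fx$ontology)[, c("rank", "name", "label", "score")]
#>   rank     name       label    score
#> 1    1 WEIGHT_1 Weight (kg) 4.319915
#> 2    2  LENGT_1 Length (cm) 2.159957

# the generator fills the BMI template, inserting the cm -> m conversion
generate_algorithm(bmi, fx$sources$biobank_b, store = fx$ontology)
#> <algorithm template/low> $('WEIGHT_1').div($('LENGT_1').div(100).pow(2)).value()
```

Both `Weight (kg)` and `Length (cm)` are found (the length only via the
ontology's height synonyms), and the generated script divides the height
by 100 before squaring because the template standardizes its height slot
to meters.

```r
project <- generate_project(fx$target, fx$sources, store = fx$ontology)
evaluate_project(project, fx$gold)
#> evaluation of 18 gold mappings (percentages):
#>          algorithm
#> search    perfect good bad
#>   perfect     100    0   0
#>   good          0    0   0
#>   bad           0    0   0
#> useful: 100.0%

res <- apply_project(project, source_name = "biobank_b")
res
#> integration result: 50 rows, 6 attributes executed
#>   failures: none
head(res$entity$data[, c("height", "weight", "gender", "bmi")], 3)
#>   height weight gender              bmi
#> 1  183.7   78.9      0 23.3807635878834
#> 2  164.4   65.6      1  24.271700972644
#> 3  173.6   93.9      1 31.1577544649494
```

On this synthetic fixture all 18 gold mappings land in the
(perfect search, perfect algorithm) cell; the integrated dataset carries
the recoded gender codes and the derived BMI (81 kg at 1.80 m would give
exactly 25.0). Real dictionaries are far messier — see the methods
vignette (`vignettes/harmonization-methods.Rmd`) for what the fixture
does and does not demonstrate.

A thin command-line front end over the same functions lives at
`inst/cli/connect.R` (`match`, `generate`, `apply`, `evaluate`
subcommands; EMX paths are CSV-set directories or xlsx workbooks).

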