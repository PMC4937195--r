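---
title: "Methods: semi-automatic harmonization of phenotype data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic harmonization of phenotype data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmonix)
```

## The problem

Pooled analyses across biobanks and patient registries need variables that
are *inferentially equivalent*: the same quantity, on the same scale, with
the same coding. In practice every collection defines its own data
dictionary — `Height in cm` here, `Length (cm)` there, `Standing height in
m` elsewhere; gender coded `1/2`, `M/F` or `m/f`; food-frequency scales cut
at different boundaries. Harmonizing a target schema against several such
dictionaries by hand means reading thousands of attribute labels and writing
hundreds of small transformation scripts.

harmonix automates the two expensive steps of that workflow: *finding* the
right source attributes for each target variable, and *writing* the
transformation algorithm that converts their values. A human curator stays
in the loop: generated algorithms are proposals, colour-codeable by
confidence, that can be accepted, edited or replaced per cell of the
(target × source) mapping matrix.

## Metadata model

Schemas travel as entity/attribute workbooks: an `attributes` sheet declares
each entity's attributes (name, data type, label, description, and a
reference entity for categorical codes), and each other sheet holds one
entity's rows. Two dialects are read — a directory of UTF-8 CSV files and
xlsx workbooks (via readxl) — and the CSV-set dialect is written, so
`read_emx(write_emx(x))` is the identity cell-for-cell. Two conventions are
fixed deliberately:

* **Missing values.** Both the empty cell and the literal string `"NA"`
  denote missing; spreadsheets edited by hand contain both.
* **Codes are strings.** Category codes are never coerced to numbers
  (`"01"` must not become `1`), and all cells are stored as text, typed
  only on access through the attribute's declared data type.

`validate_schema()` returns violations as data (entity, attribute, row,
problem), not exceptions, so a curator can fix a workbook incrementally;
`read_emx()` is strict by default.

## Search: ontology-expanded lexical matching

Source attributes are indexed on the tokens of their labels and
descriptions (lowercase, split on non-alphanumerics, ~35 English stop words
removed). The query for a target attribute starts from its own tokens and
is *expanded* through an ontology: terms annotated to the target contribute
their synonyms and the labels of their subclasses (to a default depth of 3,
a pragmatic cap mirroring how production systems truncate large clinical
ontologies for performance). Superclass labels are deliberately **not**
added — expanding `beer` to `alcoholic drink` is safe, expanding
`alcoholic drink` to every kind of drink floods the shortlist with false
positives.

Two design points were genuinely open and are resolved as follows:

* **Term selection for annotation.** A term is annotated to an attribute
  when all tokens of its label, or of one synonym, occur in the attribute's
  text. Selected terms are *ranked* by the fraction of the attribute's
  tokens they cover (ties to the shorter label). Pure overlap-ratio
  thresholds were rejected: a `Body Mass Index` target must still annotate
  the `height` and `weight` concepts mentioned in its description, or the
  template machinery downstream can never see `Length (cm)` as a
  candidate.
* **Scoring.** Candidates are ranked by Okapi BM25 (`k1 = 1.2`,
  `b = 0.75`), with expansion terms entering the query at equal weight, and
  a ×2 boost for a candidate whose label tokens equal the target's label
  tokens. The boost keeps two desirable properties simultaneously: scores
  are non-increasing in rank, and a verbatim label match always ranks
  first. Ties break on attribute name so output is deterministic.

`manual_query()` gives the curator the same machinery for free-text
queries with `term1 or term2` semantics, and `highlight_candidate()`
returns the exact character spans of query tokens inside each candidate's
label and description, which is what makes a shortlist skimmable.

## The transformation language

All generated algorithms are expressed in a small chained-method language:
`$('name')` accesses a source attribute; `div()`, `times()`, `plus()`,
`pow()` do arithmetic; `map({'1':'0','2':'1'})` recodes categories;
`unit('cm').toUnit('m')` rescales between units; `value()` terminates a
chain. The language is a **closed interpreter**, not embedded JavaScript:
only these methods exist, which makes every generated script statically
checkable (parse + referenced-attribute analysis) and injection-safe.

Semantics fixed here because no published definition exists:

* nulls are absorbing — arithmetic on a missing value, an unmapped
  `map()` code, and division by zero (with a warning) all yield null;
* numbers are IEEE doubles printed with up to 15 significant digits, a
  minimal round-trip rendering (`print ∘ parse` is a fixpoint); all
  conversion factors in the packaged table are exactly representable or
  agree with the chained form within 1e-9 relative;
* single quotes are canonical, and the typographic quotes that appear in
  typeset documents are accepted on input.

A conditional extension (`cond ? a : b` with comparisons and `||`/`&&`)
exists solely for algorithm templates such as a hypertension cutoff; the
open-ended generator never synthesizes conditionals, so
`dsl_parse()` rejects them unless a template explicitly enables them.

## Unit harmonization

Units are detected in attribute *labels only* (descriptions are prose and
too noisy) by exact, case-insensitive equality of tokens with the names,
synonyms or symbols of a packaged units vocabulary; `(kg/m^2)`-style
composites are decomposed into atomic units, superscripts included. Exact
matching is the false-positive guard: `cms` never matches `cm`. When a
label mentions two different units the result carries an ambiguity flag
and the caller decides.

Atoms detected on the *target* side are the standard; each source atom is
matched to a target atom by dimension and converted with a factor composed
transitively from the packaged rule table (`value_to = value_from ×
factor`; the table row `m → cm = 100` encodes "cm = m × 100"). When only
one side declares a unit, the units are assumed equal and no conversion is
inserted — the pragmatic reading used when a unit-less `Measured Standing
Height` target meets `Height in cm`. Only linear multiplicative
conversions are expressible (the language has no offsets), so affine
temperature scales are treated as incompatible by design.

Both generated syntaxes — `$('Height').unit('cm').toUnit('m').value()` and
`$('Height').div(100).value()` — are emitted and tested to be
interchangeable.

## Category matching

Three matchers run in a fixed precedence: **rules → frequency → lexical**,
and every resulting pair carries exactly one provenance tag.

* **Rules** are case-insensitive regular expressions over labels
  (packaged defaults: `never↔no`, `ever↔yes`, and missing-like labels to
  null), evaluated first so that domain knowledge beats string similarity.
  The shipped table is a documented stand-in for a site-specific rule set
  and is fully user-overridable; equal-priority rules that disagree are a
  configuration error, not a silent choice.
* **Frequency matching** quantifies labels like `2–4 times a week`
  (amount 3, unit week) with regular expressions and assigns each source
  amount to the target with the nearest per-day rate. Rates are normalized
  with calendar averages (week = 7, month = 30.44, year = 365.25 days) to
  avoid month-length bias; rate ties resolve to the *lower* target rate —
  deterministic and conservative, under- rather than over-reporting a
  behaviour. Many-to-one maps are expected (`daily` and `6–7 times a
  week` may both be `every day`).
* **Lexical matching** uses Dice similarity over padded character bigrams
  (the conventional n-gram choice, pinned by a brute-force oracle in the
  tests); each source category takes its argmax target, ties to the lowest
  target code.

The final map renders as a `map()` snippet with pairs ordered by source
code; sources mapped to null by a rule are reported as unmapped rather
than silently dropped.

## Templates and the overall generator

Templates capture target variables with a fixed, recurring definition. The
packaged catalogue (a user-editable YAML stand-in for a site template
library) ships body-mass index (`weight_kg / height_m²`) and a
hypertension flag (`SBP ≥ 140 || DBP ≥ 90`). A template names trigger
concepts, slots with expected units, and a body with placeholders. Slot
filling assigns shortlist candidates to slots greedily by bigram
similarity (threshold 0.5, pinned by fixture tests), never reusing a
candidate, inserts per-slot unit conversions toward the slot's standard
unit, and fails — falling back to the simpler generators — when a slot has
no acceptable candidate or an incompatible unit.

One deviation from a literal reading of the design deserves a note: a
template can be *proposed* either because the target matches a trigger or
because a candidate resembles a slot, but the automatic pipeline only
*applies* target-triggered templates. Applying candidate-triggered ones
would route every plain height or weight target into the BMI template the
moment both kinds of candidates appear in its shortlist; candidate-based
proposals are therefore left to the curating user.

The full per-target pipeline is: shortlist → template (if target-triggered
and fillable) → category map (categorical on both sides) → unit conversion
(detected units differ) → bare rename. Confidence (`high`/`low`) reflects
whether the top candidate's label covers all target-label tokens, and
drives the project cell states (`generated-high`, `generated-low`,
`curated`, `missing`).

## Integration and evaluation

`apply_project()` executes every cell's script per row. A *failure* is an
evaluation error (e.g. a script referencing an attribute the source lacks);
nulls propagated from missing data are not failures — the distinction is
pinned in tests because failure counts are the curator's main debugging
signal. Integration is deterministic and row-local (permuting input rows
permutes outputs identically). Results export as a CSV-set workbook that
`read_emx()` reproduces exactly; nulls become empty cells.

Evaluation scores search and algorithms separately against a gold standard
of human-matched attributes and reference scripts: search is `perfect`
(a gold attribute at rank 1), `good` (all gold attributes within the
top 20) or `bad`; an algorithm is `perfect` when textually identical or
functionally equivalent to the reference on the actual source rows
(numbers within 1e-9, strings and nulls exact), `good` when almost right,
`bad` otherwise. "Almost right" is operationalized as: for categorical
maps, at least half the reference pairs present and none contradicted; for
numeric scripts, the right source attribute with a wrong or missing
conversion. The cross-tab's *useful* total sums the four
perfect/good cells plus (bad search, perfect algorithm) and (perfect
search, bad algorithm) — the cells where either the match or the script
already saves the curator most of the work.

## What the synthetic fixture does and does not show

`generate_fixture()` builds, as a pure function of a seed, a target schema
of six phenotype variables and up to three source biobanks that diverge in
terminology, units (cm vs m, kg vs g), and category codings, with shared
participants (so cm-coded heights are exactly 100× the m-coded biobank's
values), ~2% missing cells, distractor attributes, a phenotype ontology,
and a gold standard. It plants the situations the method must handle: a
template case, two unit-conversion cases, three gender recodings, a
frequency scale, and a target (`Hypertension`) findable only through its
ontology synonym `high blood pressure` — removing the ontology demotes
that search to `bad`, which the regression suite checks.

The fixture is deliberately *easy* in ways real dictionaries are not: a
few dozen attributes rather than thousands, clean labels, no repeated
measurements, no negated phrasing ("I do not smoke"), no free-text values.
Passing the regression (100% useful on the core height/weight/gender/BMI
targets at seed 42, 50 rows, 3 biobanks) shows the pipeline is wired
correctly end to end, not that real biobanks would score anywhere near
that; published evaluations against real cohorts report useful rates
around three quarters, with the rest needing manual work. Tests use
10–50 rows and ≤3 biobanks so the whole suite runs in well under a minute
on one CPU.

## Known limitations

* Composite-unit conversion is applied per slot inside templates; the
  single-attribute generator converts one atomic unit (the common clinical
  case) and falls back to a rename otherwise.
* No xlsx writer is bundled: xlsx is read-only, CSV-set is the writable
  dialect.
* No fuzzy/edit-distance matching at the search layer (that lives in
  category matching by design), no statistical unit inference from value
  distributions, no learning of templates from past curated algorithms,
  and no free-text value recoding.
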