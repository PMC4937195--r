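Package: harmonix
Title: Semi-Automatic Harmonization and Integration of Biobank Phenotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooling phenotype data across biobanks and patient
    registries. Given a target data schema and one or more source data
    dictionaries (EMX-style workbooks), harmonix shortlists matching source
    attributes with ontology-expanded lexical search, automatically generates
    executable transformation algorithms (unit conversions, categorical
    recodings and complex templates such as body-mass index) in a small
    chained-expression language, executes them to derive an integrated
    dataset, and scores generated matches and algorithms against
    gold-standard mappings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
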