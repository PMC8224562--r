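Package: recipemine
Title: Mining Cuisine Structure and Nutrition from Free-Form Recipe Corpora
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for turning free-form, user-uploaded recipe ingredient
    lists into structured dietary data. Normalizes ingredient synonyms
    against a lexicon, imputes quantities in grams (including vague "few"
    style amounts and piece units), computes per-cuisine Specialty scores
    to extract featured and common ingredients, classifies recipes into
    cuisine categories from tf-idf ingredient vectors with stratified
    cross-validation, links ingredients to a per-100g food-composition
    table to derive nutrient and energy profiles, and clusters recipes in
    nutrient space into health-characterized groups. Ships a fully seeded
    synthetic corpus generator with planted ground truth so every pipeline
    stage is testable without proprietary recipe or composition data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
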