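Package: nppm
Title: Rule Engine for the WHO Nutrient and Promotion Profile Model for
    Commercial Infant and Toddler Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores commercial food products for infants and young children
    (6-36 months) against the WHO Regional Office for Europe's Nutrient and
    Promotion Profile Model (NPPM). Implements the Part A composition and
    content-labelling checks (energy density, sodium and sugar per 100 kcal,
    added free sugars, fruit and added-water rules, protein and fat limits,
    the "high in sugar" flag) and the Part B labelling and promotion checks
    (claims, name and ingredient-list clarity, pouch and spout requirements,
    age labelling, breastfeeding statements), all driven by an editable
    per-subcategory ruleset. Includes the rapid-evaluation sampling protocol
    (up to five products per subcategory across brands), Table-style
    compliance summaries with per-package-type compliance fractions, readers
    and writers for product tables and assessments, and synthetic product
    generators for end-to-end testing of the engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
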