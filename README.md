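# nppm

Rule engine for the WHO Regional Office for Europe's **Nutrient and
Promotion Profile Model** (NPPM) for commercial food products for infants
and young children aged 6–36 months.

Commercial infant and toddler foods — purees, snacks, dairy desserts and
meals sold in pouches, jars, bowls and boxes — are a growing part of young
children's diets, are frequently high in sugar, and carry dense on-pack
marketing. The NPPM sets two families of requirements for such products:

* **Part A — composition and content labelling.** Per-subcategory nutrient
  thresholds: minimum energy density (or, for snacks, at most 50 kcal per
  serve), sodium at most 50 mg/100 kcal (100 mg/100 kcal where cheese is
  named in the product name), total sugar at most 15 % of energy where a
  hard limit applies and a front-of-pack "high in sugar" flag where instead
  a flag threshold applies, prohibitions on added free sugars and
  industrially produced trans fats, fruit-content and added-water rules
  (100 % fruit for fruit-only products, at most 25 % added water for
  vegetable-only products, declaration of added fruit amounts), and protein
  and fat limits.
* **Part B — promotion and labelling.** No compositional, nutritional,
  health or marketing claims; product-name and ingredient-list clarity;
  pouch-specific requirements for spouted pouches (spoon/bowl serving
  suggestion, explicit instruction not to suck from the spout, an upper-age
  label, no "on-the-go" convenience claims); a statement on the importance
  of continued breastfeeding; age labelling from no earlier than 6 months;
  suitable preparation instructions where preparation is required.

The package provides, as plain tidyverse-style R:

* a validated flat product table (CSV or JSON; column dictionary in
  `inst/extdata/product_columns.csv`) and assessment readers/writers;
* a fully config-driven ruleset (`default_ruleset()`, YAML/JSON round-trip
  via `load_ruleset()`/`write_ruleset()`; shipped default in
  `inst/extdata/nppm_default.yaml`) — no threshold lives in engine code;
* the Part A and Part B engines (`evaluate_part_a()`, `evaluate_part_b()`)
  producing one check result per requirement with observed value,
  threshold, verdict and signed percentage deviation
  `(observed − threshold)/threshold × 100`, reported half-up to the nearest
  integer;
* the rapid-evaluation sampling protocol (`sample_products()`: up to five
  products per subcategory, covering the brands present, seeded);
* compliance summaries (`summarize_compliance()`,
  `package_type_compliance()`) mirroring the published
  numerator/denominator/percentage reporting;
* synthetic data: `generate_fixture()` — a deterministic engineered
  45-product sample whose assessment reproduces the published marginal
  results exactly — and `generate_random()` with per-requirement
  noncompliance probabilities for property testing.

## Worked example

```r
library(nppm)

rules    <- default_ruleset()
products <- generate_fixture(rules)   # engineered 45-product sample
result   <- summarize_compliance(assess(products, rules))
result
```

```
NPPM compliance summary (45 products)

Requirement compliance (products meeting / subject to):
  energy_density                21 /  40  (53%)
  sodium                        38 /  40  (95%)
  total_sugar                   13 /  23  (57%)
  added_sugar                   34 /  40  (85%)
  fruit_content                 28 /  30  (93%)
  added_water                    0 /   1  (0%)
  protein_content               15 /  19  (79%)
  protein_weight                 6 /  10  (60%)
  fat                           39 /  40  (98%)
  trans_fat                     40 /  40  (100%)
  high_sugar_flag (required)     9 /  17  (53%)
  category_permitted            40 /  45  (89%)
  no_claims                      0 /  45  (0%)
  name_clarity                  18 /  45  (40%)
  ingredient_clarity            29 /  45  (64%)
  pouch_spoon_suggestion        16 /  16  (100%)
  pouch_no_spout_instruction     3 /  16  (19%)
  pouch_upper_age_label          0 /  16  (0%)
  no_on_the_go_claim            13 /  16  (81%)
  breastfeeding_statement        0 /  45  (0%)
  age_min_label                 42 /  45  (93%)
  upper_age_label                0 /  45  (0%)
  preparation_instructions       5 /   5  (100%)

Overall:
  meets_all_nutrient             9 /  40  (23%)
  meets_all_promotion            0 /  45  (0%)

Criteria met by package type:
  bowl                           30 /   54 (56%)
  jar                            68 /  114 (60%)
  multi-serve box/packet        118 /  165 (72%)
  pouch                         166 /  300 (55%)
  single-serve packet/sachet     18 /   34 (53%)
```

Reading it: of the 40 products subject to nutrient content requirements
(confectionery is not a permitted category and is excluded), 9 (23 %) meet
every applicable composition requirement; 13 of the 23 products under a
hard sugar limit (57 %) stay within 15 % of energy from total sugar; 9 of
the 17 products evaluated for the "high in sugar" flag would have to carry
it; and no product meets all promotional requirements, because every pack
carries at least one claim. Per-product detail — observed values,
thresholds and signed deviations such as a vegetable puree at 42.8 % added
water exceeding its 25 % limit by +71 % — lives in `assess()$checks` and in
`write_assessments()` output.

A thin command-line front end with `validate`, `sample`, `assess`,
`report` and `fixture` subcommands ships in `inst/cli/nppm.R`:

```sh
Rscript inst/cli/nppm.R fixture --out fixture.csv
Rscript inst/cli/nppm.R report  --products fixture.csv
```

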