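---
title: "Scoring infant and toddler foods against the NPPM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring infant and toddler foods against the NPPM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nppm)
```

## The model

The WHO/Europe Nutrient and Promotion Profile Model (NPPM) scores a
commercial food product for children aged 6–36 months in two parts.
**Part A** compares the product's composition against per-subcategory
thresholds; most are expressed per unit of energy, so the engine first
normalises label values reported per 100 g:

* sodium density: `sodium_mg / energy_kcal × 100` (mg/100 kcal),
* share of energy from total sugar: `sugar_g × f / energy_kcal × 100`
  (% energy), with `f` the sugar energy factor in kcal/g,
* energy per serve: `energy_kcal × serve_g / 100` (kcal/serve),
* protein and fat per 100 kcal analogously.

**Part B** is a set of boolean labelling and promotion requirements: no
claims of any kind, name and ingredient-list clarity, four extra
requirements for spouted pouches, a continued-breastfeeding statement, a
minimum-age label of at least 6 months, upper-age information, and
suitable preparation instructions where preparation is needed.

Every check yields a `CheckResult` row: whether it applies to the product,
whether it passed, the observed value and threshold in stated units, and
the signed relative deviation `(observed − threshold)/threshold × 100`.
The "high in sugar" flag is deliberately *informational*: its row records
whether a front-of-pack flag would be required (share of energy from sugar
above the subcategory's flag threshold), never a pass or a failure, and it
is excluded from all compliance rollups — it is reported on its own
denominator.

Two rollups summarise a product: `meets_all_nutrient` (conjunction over
the applicable, decided Part A checks other than the flag; `NA` when no
nutrient-threshold check applies) and `meets_all_promotion` (conjunction
over applicable Part B checks). Summaries count, per requirement, passing
products over products subject to the requirement with a decided verdict.

## Assumptions and conventions

* **Thresholds are inclusive.** A product observed exactly at a limit
  passes; the model states its limits as "at most"/"at least". Verdicts
  always compare exact values.
* **Rounding is half away from zero, and only for reporting.** Printed
  percentages and deviations are integers (42.8 % added water against a
  25 % cap is reported as +71 %); `round_half_up()` reproduces the
  published rounding behaviour (22.5 → 23, 97.5 → 98). No verdict is ever
  taken on a rounded value.
* **Missing is never zero.** Optional numerics (fruit percentage, added
  water, ages, serve size) stay `NA`. A check whose inputs are missing
  where it applies returns a *missing verdict* with an explanatory note
  and is excluded from both the numerator and the denominator of its
  summary row: published denominators count products "subject to" a
  requirement, and a product whose serve size is unknown cannot be
  decided either way.
* **Total sugar.** The sugar limit is evaluated on total sugar, as the
  model's content requirement is phrased; the added-free-sugars
  prohibition is a separate boolean fact taken from the ingredient list.
* **Degenerate inputs.** Zero energy makes every per-energy quantity
  undefined; the standalone helpers raise a typed error and the engine
  records a missing verdict. Confectionery is handled by a dedicated
  `category_permitted` requirement that fails, while its (undefined)
  nutrient thresholds stay not-applicable — this is what reconciles a
  45-product sample with 40 products "subject to nutrient content
  requirements".

## Tunable parameters

All thresholds live in the ruleset (`default_ruleset()`, or a YAML/JSON
file via `load_ruleset()`), never in engine code; a test mutates the
config and observes verdicts flip. Values stated by the model and restated
in public evaluations are encoded directly:

| parameter | default | unit |
|---|---|---|
| sodium limit (base / cheese named) | 50 / 100 | mg/100 kcal |
| total sugar limit, where a hard limit applies | 15 | % energy |
| snack energy cap | 50 | kcal/serve |
| added water cap, vegetable-only | 25 | % by weight |
| required fruit content, fruit-only | 100 | % by weight |
| sugar energy factor | 4.0 | kcal/g |
| kJ→kcal conversion | 4.184 | kJ/kcal |
| minimum labelled age | 6 | months |

Four families of values the model defines but whose exact numbers are not
restated in the public summaries this package follows are shipped as
**documented placeholders**, deliberately config-level so they can be
corrected against the NPPM publication without touching code: minimum
energy density (60 kcal/100 g for the four wet-food groups), protein
minima (3.0 g/100 kcal; 4.0 % by weight for meal subcategories), the fat
cap (4.5 g/100 kcal) and the high-sugar flag threshold (40 % energy). The
shipped config marks these in `inst/extdata/nppm_default.yaml`.

The taxonomy maps 14 subcategory codes onto six product groups (dry
cereals and starches; dairy foods; fruit and vegetable purees; savoury
meals; snacks and finger foods; confectionery). The Ingredients and
Drinks categories of the wider model are out of scope here beyond schema
support, since the evaluations this package mirrors found no such
products.

## Design decisions that were genuinely open

* **Sampling under the brand cap.** The rapid-evaluation protocol selects
  up to five products per subcategory "ensuring at least one product per
  brand". When a subcategory has more than five brands that instruction is
  underdetermined; `sample_products()` draws five brands uniformly and one
  product per drawn brand, preserving the one-per-brand spirit within the
  cap. All randomness flows through a single integer seed.
* **Package-type compliance basis.** Published per-package-type
  compliance ("x % of criteria met for pouches") does not state which
  checks are counted. `package_type_compliance()` counts *all* applicable
  Part A + Part B checks with decided verdicts, excluding the
  informational flag rows, and the summary's metadata records that
  convention.
* **Name clarity.** The full NPPM product-name rules need human judgement;
  the machine-checkable core — ingredients listed in descending order —
  drives the verdict, and richer name annotations can be added as input
  columns without engine changes.
* **Upper-age labelling** is both a pouch requirement (for spouted
  pouches) and a general informational labelling check; the two are
  reported as separate rows with separate denominators.
* **Claim categories** are curated input; `tag_claim()` offers an
  assistive ordered-regex lexicon with a `marketing` fallback, but it
  never overrides categories supplied in the table, because claim
  classification on real packs is an assessor judgement.
* **Energy in kJ.** Labels in some jurisdictions print kJ;
  `read_products()` accepts `energy_kj_per_100g` and converts at the
  ruleset's 4.184 kJ/kcal when the kcal column is absent.

## What the synthetic data emulates — and what it does not

The evaluation study this package operationalises worked from a
45-product supermarket sample that is not deposited. `generate_fixture()`
therefore builds an **engineered stand-in**: 45 synthetic products across
the six groups (subcategory allocation 5, 2, 5, 5, 5, 1, 2, 0, 5, 0, 5,
5, 0, 5 — three non-empty subcategories hold fewer than five products,
and sixteen products are spouted pouches: eight savoury meals, four
purees, four dairy). Its assessment reproduces, exactly, every published
marginal count — the `fixture_spec()` table — and the individual
violators sit at the printed deviation extremes (sodium +38 % and +7 %,
sugar +16 % to +97 %, fat +16 %, added water +71 %, energy −0.1 % to
−48 %, protein −17 % to −39 % per 100 kcal and −13 % to −65 % by weight).
Violating values are expressed *relative to the ruleset's thresholds*, so
editing the config moves the fixture coherently; a consistency checker
(`check_fixture_spec()`) refuses generation when the target marginals and
the ruleset's applicability pattern cannot coexist. Generation is pure
arithmetic — no random numbers — hence bit-reproducible.

What passing on the fixture shows: the engines, the applicability logic,
the rollups and the reporting arithmetic are correct for a sample with
exactly the published structure. What it cannot show: anything about real
products. Per-product nutrient values between the pinned extremes are
arbitrary mid-range choices; cell-level allocations that the published
tables do not print (e.g. group-by-package counts beyond the pouch
breakdown) were chosen freely to satisfy the printed text; and a dry
cereal engineered to miss a wet-food energy floor is not a plausible
grocery item. The fixture validates software, not nutrition.

`generate_random()` complements it for property testing: products are
drawn across the permitted subcategories from a fully compliant base, and
each requirement is violated independently with a configured probability.
With all probabilities zero the assessment must be 100 % compliant — a
soundness probe of the engines — and observed noncompliance converges on
the configured rate (checked against binomial 99 % bounds at n = 1000).
Physically coupled quantities cannot be violated independently (a protein
injection can flip both protein checks; removing the upper-age label
fails both upper-age checks), and the tests use uncoupled requirements
for calibration.

## Problem sizes and runtime

The test suite assesses the 45-product fixture (seconds), cross-checks the
engines against an independent brute-force evaluator on 1 000 random
products spanning all requirements, and calibrates the generator at
n = 1 000 with seeded draws. These sizes keep the full suite comfortably
fast while leaving each statistical check well-powered.

## Known limitations

* Placeholder thresholds (energy minima, protein minima, fat cap, flag
  threshold) must be verified against the NPPM publication before any
  regulatory use; they are honest defaults, not sourced values.
* Visual and child-appeal marketing cues (characters, colour, imagery)
  are outside the model and the package; so are micronutrient rules from
  national codes, OCR of pack images, and web scraping.
* The breastfeeding-statement and preparation-suitability checks are
  presence booleans; semantic adequacy of the wording is an assessor
  judgement upstream of the table.
* Statistical inference across groups is deliberately absent: the
  workflow mirrors a rapid evaluation, which makes no power claims.
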