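# Deterministic 45-product fixture -------------------------------------------
#
# The study sample behind the published marginal results is not deposited, so
# the package ships a generator for an engineered stand-in: 45 synthetic
# products across the six product groups whose assessment reproduces every
# marginal count exactly (see fixture_spec()). Individual engineered values
# carry the printed deviation extremes (a vegetable-only product at 42.8 %
# added water, a fruit product at 99.5 % fruit, sodium violators at +38 % and
# +7 %, sugar violators spanning +16 % to +97 %, a fat violator at +16 %,
# energy shortfalls from -0.1 % to -48 %, protein shortfalls of -17..-39 %
# per 100 kcal and -13..-65 % by weight). Everything else is an arbitrary but
# documented mid-range choice. The fixture validates the engine and the
# reporting, not any real-world product.

#' Target marginals for the packaged fixture
#'
#' The counts the fixture is engineered to reproduce, with structural
#' constraints (sample size, pouch counts by product group, subcategory
#' allocation). `check_fixture_spec()` verifies internal consistency before
#' generation.
#'
#' @return List with `requirements` (tibble: requirement_id, numerator,
#'   denominator -- for `high_sugar_flag` the numerator counts products
#'   required to carry the flag), `overall`, `structure` and `allocation`.
#' @export
fixture_spec <- function() {
  requirements <- tribble(
    ~requirement_id,              ~numerator, ~denominator,
    "energy_density",              21, 40,
    "sodium",                      38, 40,
    "total_sugar",                 13, 23,
    "added_sugar",                 34, 40,
    "fruit_content",               28, 30,
    "added_water",                  0,  1,
    "protein_content",             15, 19,
    "protein_weight",               6, 10,
    "fat",                         39, 40,
    "trans_fat",                   40, 40,
    "high_sugar_flag",              9, 17,
    "category_permitted",          40, 45,
    "no_claims",                    0, 45,
    "name_clarity",                18, 45,
    "ingredient_clarity",          29, 45,
    "pouch_spoon_suggestion",      16, 16,
    "pouch_no_spout_instruction",   3, 16,
    "pouch_upper_age_label",        0, 16,
    "no_on_the_go_claim",          13, 16,
    "breastfeeding_statement",      0, 45,
    "age_min_label",               42, 45,
    "upper_age_label",              0, 45,
    "preparation_instructions",     5,  5
  )
  overall <- tribble(
    ~measure,              ~numerator, ~denominator,
    "meets_all_nutrient",   9, 40,
    "meets_all_promotion",  0, 45
  )
  structure_counts <- list(
    n_products = 45L,
    n_pouches = 16L,
    pouches_by_group = c("savoury meals" = 8L,
                         "fruit and vegetable purees" = 4L,
                         "dairy foods" = 4L),
    n_age_labels_below_minimum = 3L,
    n_requiring_preparation = 5L
  )
  allocation <- c("1.1" = 5L, "1.2" = 2L, "2.1" = 5L, "2.2" = 5L,
                  "3.1" = 5L, "3.2" = 1L, "3.3" = 2L, "3.4" = 0L,
                  "4.1" = 5L, "4.2" = 0L, "4.3" = 5L, "5.1" = 5L,
                  "5.2" = 0L, "6.1" = 5L)
  list(requirements = requirements, overall = overall,
       structure = structure_counts, allocation = allocation)
}

#' Consistency check for the fixture specification
#'
#' Verifies that the target marginals are mutually consistent and achievable
#' under a ruleset: numerators within denominators, the subcategory
#' allocation summing to the sample size, the sugar-limit and sugar-flag
#' denominators partitioning the nutrient-assessed products, pouch counts
#' matching the pouch-check denominators, and every threshold the targets
#' rely on being defined in the ruleset.
#'
#' @param spec A fixture specification from [fixture_spec()].
#' @param rules Ruleset the fixture will be generated against.
#' @return `TRUE` invisibly; otherwise an error naming the conflict.
#' @export
check_fixture_spec <- function(spec = fixture_spec(),
                               rules = default_ruleset()) {
  req <- spec$requirements
  bad <- req$numerator > req$denominator | req$numerator < 0
  if (any(bad)) {
    abort(paste0("fixture spec: numerator out of range for ",
                 toString(req$requirement_id[bad])),
          class = "nppm_generation_error")
  }
  n <- spec$structure$n_products
  if (sum(spec$allocation) != n) {
    abort("fixture spec: subcategory allocation does not sum to the sample size",
          class = "nppm_generation_error")
  }
  tax <- rules$taxonomy
  unknown <- setdiff(names(spec$allocation), tax$subcategory)
  if (length(unknown)) {
    abort(paste0("fixture spec: allocation references unknown subcategories: ",
                 toString(unknown)), class = "nppm_generation_error")
  }
  den <- function(id) req$denominator[req$requirement_id == id]
  rr <- rules$rules
  alloc <- spec$allocation
  n_with <- function(col) {
    codes <- rr$subcategory[!is.na(rr[[col]])]
    sum(alloc[codes])
  }
  if (n_with("sugar_max_pct_energy") != den("total_sugar")) {
    abort("fixture spec: sugar-limit denominator inconsistent with ruleset applicability",
          class = "nppm_generation_error")
  }
  if (n_with("sugar_flag_threshold_pct_energy") != den("high_sugar_flag")) {
    abort("fixture spec: flag denominator inconsistent with ruleset applicability",
          class = "nppm_generation_error")
  }
  if (den("total_sugar") + den("high_sugar_flag") !=
      sum(alloc[rr$subcategory[rr$category_permitted]])) {
    abort("fixture spec: sugar-limit and flag products must partition the permitted sample",
          class = "nppm_generation_error")
  }
  if (sum(spec$structure$pouches_by_group) != spec$structure$n_pouches ||
      den("pouch_spoon_suggestion") != spec$structure$n_pouches) {
    abort("fixture spec: pouch counts inconsistent",
          class = "nppm_generation_error")
  }
  needed <- c("energy_min_kcal_per_100g", "energy_max_kcal_per_serve",
              "sodium_max_mg_per_100kcal_base",
              "sodium_max_mg_per_100kcal_cheese", "sugar_max_pct_energy",
              "sugar_flag_threshold_pct_energy", "added_water_max_pct",
              "fruit_required_pct", "protein_min_g_per_100kcal",
              "protein_min_pct_weight", "fat_max_g_per_100kcal")
  undefined <- needed[map_lgl(needed, function(col) all(is.na(rr[[col]])))]
  if (length(undefined)) {
    abort(paste0("fixture spec: ruleset defines no subcategory for threshold(s): ",
                 toString(undefined)), class = "nppm_generation_error")
  }
  invisible(TRUE)
}

#' Generate the deterministic 45-product fixture
#'
#' Builds the engineered stand-in sample described in [fixture_spec()].
#' Generation is pure arithmetic (no random numbers), so repeated calls are
#' identical. Violating products are placed at the printed deviation
#' extremes relative to the supplied ruleset's thresholds; compliant
#' products sit mid-range. Brands, names and serve sizes are synthetic.
#'
#' @param rules Ruleset to engineer the fixture against
#'   (default [default_ruleset()]).
#' @return A validated products tibble of 45 rows.
#' @examples
#' prods <- generate_fixture()
#' table(prods$package_type)
#' @export
generate_fixture <- function(rules = default_ruleset()) {
  spec <- fixture_spec()
  check_fixture_spec(spec, rules)

  r <- function(code) ruleset_row(rules, code)
  factor <- rules$options$sugar_energy_factor_kcal_per_g
  emin <- r("2.1")$energy_min_kcal_per_100g
  eserve <- r("5.1")$energy_max_kcal_per_serve
  na_base <- r("4.3")$sodium_max_mg_per_100kcal_base
  na_cheese <- r("4.1")$sodium_max_mg_per_100kcal_cheese
  smax <- r("4.3")$sugar_max_pct_energy
  wmax <- r("3.2")$added_water_max_pct
  pc_min <- r("4.3")$protein_min_g_per_100kcal
  pw_min <- r("4.3")$protein_min_pct_weight
  fat_max <- r("4.3")$fat_max_g_per_100kcal

  # energy at a relative shortfall from the minimum density
  e_dev <- function(dev_pct) emin * (1 + dev_pct / 100)
  # % energy from sugar at a relative exceedance of the hard limit
  s_dev <- function(dev_pct) smax * (1 + dev_pct / 100)

  # savoury products failing both protein rules: the per-100 kcal and
  # per-weight shortfalls pin down the energy density (pw = pc * E / 100)
  p31_pc <- pc_min * (1 - 0.39); p31_pw <- pw_min * (1 - 0.13)
  p31_E <- p31_pw / p31_pc * 100                      # 190.2 kcal/100 g
  p32_E <- e_dev(-10 / 3); p32_pw <- 2.45 * p32_E / 100   # pc -18.3 %, pw -64.5 %
  p33_E <- e_dev(-5 / 6); p33_pw <- 2.40 * p33_E / 100    # pc -20 %,   pw -64.3 %
  p34_pc <- pc_min * (1 - 0.17); p34_pw <- pw_min * (1 - 0.65)
  p34_E <- p34_pw / p34_pc * 100                      # 56.2 kcal/100 g

  # one row per product: engineered energy (kcal/100 g), sugar as % energy,
  # sodium mg/100 kcal, protein g/100 g, fat g/100 kcal, plus label facts
  d <- tribble(
    ~product_id, ~subcategory, ~brand, ~name_text, ~package_type, ~serve,
    ~energy, ~sugar_pctE, ~na100, ~protein_g, ~fat100,
    ~added, ~fruit, ~fruit_decl, ~water, ~cheese,
    ~name_ok, ~ingr_ok, ~age_min, ~otg, ~nospout, ~prep,

    # 1.1 dry cereals, plain (require preparation; multi-serve boxes)
    "p01", "1.1", "Little Harvest", "Baby rice cereal",    "multi-serve box/packet", 25, e_dev(-10/3), s_dev(20),  25, 8.0, 3, FALSE, NA,   TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, TRUE,
    "p02", "1.1", "Little Harvest", "Baby oat cereal",     "multi-serve box/packet", 25, e_dev(-25),   10,         25, 8.0, 3, FALSE, NA,   TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, TRUE,
    "p03", "1.1", "Tiny Spoon",     "Multigrain porridge", "multi-serve box/packet", 25, e_dev(-100/3), 12,        25, 8.5, 3, FALSE, NA,   TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, TRUE,
    "p04", "1.1", "Tiny Spoon",     "Semolina starter",    "multi-serve box/packet", 25, e_dev(-40/3), s_dev(25),  25, 8.0, 3, FALSE, NA,   TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, TRUE,
    "p05", "1.1", "Bubba Fields",   "Baby barley cereal",  "multi-serve box/packet", 25, 390,          10,         25, 8.0, 3, FALSE, NA,   TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, TRUE,
    # 1.2 dry cereals with added fruit
    "p06", "1.2", "Little Harvest", "Oat & apple porridge",  "multi-serve box/packet", 25, 400, 12, 25, NA, 3, FALSE, 15, TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, FALSE,
    "p07", "1.2", "Tiny Spoon",     "Wheat & banana cereal", "multi-serve box/packet", 25, 410, 11, 25, NA, 3, FALSE, 12, TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, FALSE,
    # 2.1 dairy-based foods, desserts and cereals
    "p08", "2.1", "Milky Moo", "Vanilla custard pouch",   "pouch", 100, e_dev(-25/3), 45, 25, NA, 3, TRUE,  0, TRUE, NA, FALSE, FALSE, FALSE, 6, FALSE, TRUE,  FALSE,
    "p09", "2.1", "Milky Moo", "Caramel rice pudding",    "pouch", 100, e_dev(-50/3), 48, 25, NA, 3, TRUE,  0, TRUE, NA, FALSE, FALSE, FALSE, 6, FALSE, FALSE, FALSE,
    "p10", "2.1", "Milky Moo", "Chocolate semolina cup",  "bowl",  100, 95,           50, 25, NA, 3, TRUE,  0, TRUE, NA, FALSE, FALSE, TRUE,  6, NA, NA, FALSE,
    "p11", "2.1", "Happy Tum", "Vanilla yoghurt dessert", "jar",   100, e_dev(-40/3), 30, 25, NA, 3, FALSE, 0, TRUE, NA, FALSE, FALSE, FALSE, 4, NA, NA, FALSE,
    "p12", "2.1", "Happy Tum", "Creamy milk rice",        "jar",   100, 95,           25, 25, NA, 3, FALSE, 0, TRUE, NA, FALSE, FALSE, FALSE, 6, NA, NA, FALSE,
    # 2.2 fruit-containing products incl. breakfast/dairy
    "p13", "2.2", "Milky Moo", "Berry yoghurt smoothie",   "pouch", 90, 85, 44, 25, NA, 3, TRUE,  25, TRUE, NA, FALSE, FALSE, FALSE, 6, TRUE,  FALSE, FALSE,
    "p14", "2.2", "Milky Moo", "Mango breakfast blend",    "pouch", 90, 90, 42, 25, NA, 3, TRUE,  25, TRUE, NA, FALSE, FALSE, FALSE, 6, FALSE, FALSE, FALSE,
    "p15", "2.2", "Happy Tum", "Apple bircher bowl",       "bowl",  90, 88, 38, 25, NA, 3, TRUE,  25, TRUE, NA, FALSE, TRUE,  TRUE,  6, NA, NA, FALSE,
    "p16", "2.2", "Happy Tum", "Peach & oat breakfast",    "bowl",  90, e_dev(-110/3), 30, 25, NA, 3, FALSE, 25, TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, FALSE,
    "p17", "2.2", "Happy Tum", "Banana porridge cup",      "single-serve packet/sachet", 90, 92, 28, 25, NA, 3, FALSE, 25, TRUE, NA, FALSE, TRUE, TRUE, 6, NA, NA, FALSE,
    # 3.1 fruit only products
    "p18", "3.1", "Orchard Lane", "Pear puree",          "jar",   120, 70,         55, 25, NA, 3, FALSE, 99.5, TRUE, NA, FALSE, FALSE, FALSE, 6, NA, NA, FALSE,
    "p19", "3.1", "Orchard Lane", "Apple & berry puree", "jar",   120, e_dev(-48), 58, 25, NA, 3, FALSE, 100,  TRUE, NA, FALSE, FALSE, FALSE, 6, NA, NA, FALSE,
    "p20", "3.1", "Orchard Lane", "Summer fruits pouch", "pouch", 120, e_dev(-50/3), 45, 25, NA, 3, FALSE, 100, TRUE, NA, FALSE, FALSE, TRUE, 6, FALSE, FALSE, FALSE,
    "p21", "3.1", "Green Sprout", "Apple & mango pouch", "pouch", 120, 72,         35, 25, NA, 3, FALSE, 100,  TRUE, NA, FALSE, FALSE, TRUE,  6, FALSE, TRUE,  FALSE,
    "p22", "3.1", "Green Sprout", "Just apples",         "jar",   120, 68,         30, 25, NA, 3, FALSE, 100,  TRUE, NA, FALSE, FALSE, TRUE,  4, NA, NA, FALSE,
    # 3.2 vegetable only products
    "p23", "3.2", "Green Sprout", "Garden pea & spinach puree", "jar", 120, e_dev(-125/3), 10, 25, NA, 3, FALSE, 0, TRUE, 42.8, FALSE, FALSE, FALSE, 6, NA, NA, FALSE,
    # 3.3 fruit/vegetable products with other ingredients
    "p24", "3.3", "Orchard Lane", "Pumpkin, apple & quinoa pouch", "pouch", 120, e_dev(-0.1),  47, 25, NA, 3, FALSE, 40, TRUE, NA, FALSE, FALSE, TRUE, 6, TRUE,  FALSE, FALSE,
    "p25", "3.3", "Green Sprout", "Sweetcorn, pear & oat pouch",   "pouch", 120, e_dev(-80/3), 30, 25, NA, 3, FALSE, 40, TRUE, NA, FALSE, FALSE, TRUE, 6, FALSE, FALSE, FALSE,
    # 4.1 food with cheese named but no protein
    "p26", "4.1", "Mini Mealtime", "Cheesy tomato pasta pouch",   "pouch", 170, 120,         s_dev(97), 40, 4.2, 3, FALSE, 0, TRUE, NA, TRUE, FALSE, TRUE, 8, FALSE, TRUE,  FALSE,
    "p27", "4.1", "Mini Mealtime", "Cheddar & veggie mash",       "pouch", 170, e_dev(-10),  s_dev(40), 40, 4.1, 3, FALSE, 0, TRUE, NA, TRUE, FALSE, TRUE, 8, FALSE, FALSE, FALSE,
    "p28", "4.1", "Mini Mealtime", "Cheesy cauliflower bake",     "pouch", 170, e_dev(-50/3), s_dev(70), 40, 4.0, 3, FALSE, 0, TRUE, NA, TRUE, FALSE, TRUE, 8, FALSE, FALSE, FALSE,
    "p29", "4.1", "Bubba Fields",  "Mac & cheese with apple",     "pouch", 170, 95,          14,        40, 4.3, 3, FALSE, NA, FALSE, NA, TRUE, FALSE, FALSE, 8, FALSE, FALSE, FALSE,
    "p30", "4.1", "Bubba Fields",  "Cheese & broccoli risotto",   "jar",   170, e_dev(-10),  12,        80, 4.2, 3, FALSE, 0, TRUE, NA, TRUE, FALSE, TRUE, 8, NA, NA, FALSE,
    # 4.3 food without protein or cheese named
    "p31", "4.3", "Mini Mealtime", "Garden vegetable medley",  "pouch", 170, p31_E, s_dev(16), na_base * 1.38, p31_pw, 3, FALSE, 0, TRUE, NA, FALSE, FALSE, FALSE, 8, TRUE,  FALSE, FALSE,
    "p32", "4.3", "Mini Mealtime", "Harvest vegetable mash",   "pouch", 170, p32_E, s_dev(55), 25,             p32_pw, 3, FALSE, 0, TRUE, NA, FALSE, FALSE, FALSE, 8, FALSE, FALSE, FALSE,
    "p33", "4.3", "Bubba Fields",  "Rainbow veggie dinner",    "pouch", 170, p33_E, s_dev(30), 25,             p33_pw, 3, FALSE, 0, TRUE, NA, FALSE, FALSE, FALSE, 8, FALSE, FALSE, FALSE,
    "p34", "4.3", "Bubba Fields",  "Country vegetable stew",   "pouch", 170, p34_E, 13,        25,             p34_pw, 3, FALSE, 0, TRUE, NA, FALSE, FALSE, TRUE,  8, FALSE, FALSE, FALSE,
    "p35", "4.3", "Bubba Fields",  "Tuscan vegetable bake",    "jar",   170, 88,    12,        25,             4.2,    3, FALSE, 0, TRUE, NA, FALSE, FALSE, FALSE, 8, NA, NA, FALSE,
    # 5.1 dry or semi-dry snacks and finger foods
    "p36", "5.1", "Snack Sprouts", "Apple rice wafers",      "multi-serve box/packet", 10, 400, s_dev(20), 25,  6, 3,    FALSE, NA, TRUE, NA, FALSE, TRUE, TRUE, 12, NA, NA, FALSE,
    "p37", "5.1", "Snack Sprouts", "Berry oat bites",        "multi-serve box/packet", 10, 395, s_dev(45), 25,  6, 3,    FALSE, NA, TRUE, NA, FALSE, TRUE, TRUE, 12, NA, NA, FALSE,
    "p38", "5.1", "Snack Sprouts", "Veggie straw snacks",    "multi-serve box/packet", 10, 410, 10, na_base * 1.07, 6, 3, FALSE, NA, TRUE, NA, FALSE, TRUE, TRUE, 4,  NA, NA, FALSE,
    "p39", "5.1", "Tiny Spoon",    "Carrot crunch sticks",   "multi-serve box/packet", 10, 400, 11, 25,  6, fat_max * 1.16, FALSE, NA, TRUE, NA, FALSE, TRUE, TRUE, 12, NA, NA, FALSE,
    "p40", "5.1", "Tiny Spoon",    "Plain corn puffs",       "multi-serve box/packet", 10, 380, 10, 25,  6, 3,    FALSE, NA, TRUE, NA, FALSE, TRUE, TRUE, 12, NA, NA, FALSE,
    # 6.1 confectionery (category not permitted; no nutrient thresholds)
    "p41", "6.1", "Sweet Pea",     "Fruit jelly drops",   "bowl", 15, 350, NA, 20, 1, NA, TRUE, NA, TRUE, NA, FALSE, FALSE, FALSE, 12, NA, NA, FALSE,
    "p42", "6.1", "Sweet Pea",     "Yoghurt buttons",     "bowl", 15, 360, NA, 20, 1, NA, TRUE, NA, TRUE, NA, FALSE, FALSE, TRUE,  12, NA, NA, FALSE,
    "p43", "6.1", "Sweet Pea",     "Rainbow fruit chews", "single-serve packet/sachet", 15, 380, NA, 20, 1, NA, TRUE, NA, TRUE, NA, FALSE, TRUE, FALSE, 12, NA, NA, FALSE,
    "p44", "6.1", "Snack Sprouts", "Berry gummy bears",   "single-serve packet/sachet", 15, 370, NA, 20, 1, NA, TRUE, NA, TRUE, NA, FALSE, TRUE, TRUE,  12, NA, NA, FALSE,
    "p45", "6.1", "Snack Sprouts", "Choc-dipped rusks",   "single-serve packet/sachet", 15, 390, NA, 20, 1, NA, TRUE, NA, TRUE, NA, FALSE, TRUE, TRUE,  12, NA, NA, FALSE
  )

  # derive raw per-100 g nutrients from the engineered per-energy quantities
  sugar_g <- ifelse(is.na(d$sugar_pctE),
                    55,                            # confectionery: g/100 g direct
                    d$sugar_pctE * d$energy / (100 * factor))
  sodium_mg <- d$na100 * d$energy / 100
  protein_g <- ifelse(is.na(d$protein_g),
                      3.5 * d$energy / 100,        # mid-range g/100 kcal
                      d$protein_g)
  fat_g <- ifelse(is.na(d$fat100), 2, d$fat100 * d$energy / 100)

  claim_pool <- tribble(
    ~text,                      ~category,
    "no nasties",               "marketing",
    "source of protein",        "nutritional",
    "organic",                  "compositional",
    "supports healthy growth",  "health",
    "no added sugar",           "nutritional",
    "made with real fruit",     "compositional",
    "perfect for little hands", "marketing"
  )
  claims <- map(seq_len(nrow(d)), function(i) {
    claim_pool[(i - 1) %% nrow(claim_pool) + 1, ]
  })

  is_pouch <- d$package_type == "pouch"
  products <- tibble(
    product_id = d$product_id,
    brand = d$brand,
    name_text = d$name_text,
    subcategory = d$subcategory,
    product_group = NA_character_,
    package_type = d$package_type,
    has_spout = is_pouch,
    serve_size_g = d$serve,
    energy_kcal_per_100g = d$energy,
    total_sugar_g_per_100g = sugar_g,
    sodium_mg_per_100g = sodium_mg,
    protein_g_per_100g = protein_g,
    total_fat_g_per_100g = fat_g,
    industrial_trans_fat_present = FALSE,
    added_free_sugars_present = d$added,
    fruit_pct = d$fruit,
    added_water_pct = d$water,
    fruit_amount_declared = d$fruit_decl,
    water_amount_declared = !is.na(d$water),
    cheese_named = d$cheese,
    protein_named = FALSE,
    requires_preparation = d$prep,
    claims = claims,
    ingredients_descending_order = d$name_ok,
    ingredient_list_amounts_complete = d$ingr_ok,
    age_min_months = d$age_min,
    age_max_months = NA_real_,
    breastfeeding_statement_present = FALSE,
    spoon_or_bowl_suggestion = ifelse(is_pouch, TRUE, NA),
    no_spout_consumption_instruction = ifelse(is_pouch,
                                              !is.na(d$nospout) & d$nospout,
                                              NA),
    on_the_go_claim_present = ifelse(is_pouch, !is.na(d$otg) & d$otg, NA),
    preparation_instructions_present = ifelse(d$prep, TRUE, NA),
    preparation_instructions_suitable = ifelse(d$prep, TRUE, NA)
  )
  validate_products(products, rules)
}
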