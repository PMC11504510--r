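# Closed vocabularies used across the package -------------------------------

.product_groups <- c(
  "dry cereals and starches", "dairy foods", "fruit and vegetable purees",
  "savoury meals", "snacks and finger foods", "confectionery"
)

.package_types <- c(
  "pouch", "jar", "bowl", "single-serve packet/sachet",
  "multi-serve box/packet"
)

.claim_categories <- c("compositional", "nutritional", "health", "marketing")

.threshold_cols <- c(
  "energy_min_kcal_per_100g", "energy_max_kcal_per_serve",
  "sodium_max_mg_per_100kcal_base", "sodium_max_mg_per_100kcal_cheese",
  "sugar_max_pct_energy", "sugar_flag_threshold_pct_energy",
  "added_water_max_pct", "fruit_required_pct",
  "protein_min_g_per_100kcal", "protein_min_pct_weight",
  "fat_max_g_per_100kcal"
)

.rule_flag_cols <- c(
  "fruit_declaration_required", "added_sugar_prohibited",
  "trans_fat_prohibited", "category_permitted"
)

#' Requirement identifiers evaluated by the engines
#'
#' The closed vocabulary of requirement ids. Part A covers composition and
#' content-labelling; Part B covers labelling and promotion. The
#' `high_sugar_flag` row is informational (records whether a front-of-pack
#' "high in sugar" flag is required) and never enters pass/fail rollups.
#'
#' @param part `"A"`, `"B"` or `"all"`.
#' @return Character vector of requirement ids.
#' @export
nppm_requirements <- function(part = c("all", "A", "B")) {
  part <- arg_match(part)
  a <- c(
    "energy_density", "sodium", "total_sugar", "added_sugar",
    "fruit_content", "added_water", "protein_content", "protein_weight",
    "fat", "trans_fat", "high_sugar_flag", "category_permitted"
  )
  b <- c(
    "no_claims", "name_clarity", "ingredient_clarity",
    "pouch_spoon_suggestion", "pouch_no_spout_instruction",
    "pouch_upper_age_label", "no_on_the_go_claim",
    "breastfeeding_statement", "age_min_label", "upper_age_label",
    "preparation_instructions"
  )
  switch(part, A = a, B = b, all = c(a, b))
}

# Ruleset ---------------------------------------------------------------------

#' Default NPPM ruleset
#'
#' Builds the per-subcategory threshold table used by [evaluate_part_a()] and
#' [evaluate_part_b()]. The taxonomy maps 14 subcategory codes onto the six
#' product groups covered by the model for solid foods; the Ingredients and
#' Drinks categories are outside its scope.
#'
#' Thresholds with published values are encoded directly: sodium at most
#' 50 mg/100 kcal (100 mg/100 kcal where cheese is named in the product
#' name), total sugar at most 15 % of energy where a hard limit applies,
#' snack energy at most 50 kcal per serve, added water at most 25 % for
#' vegetable-only products, 100 % fruit for fruit-only products, and
#' prohibitions on added free sugars and industrial trans fats. Confectionery
#' is not a permitted category (`category_permitted = FALSE`) and carries no
#' nutrient thresholds.
#'
#' Values the model defines but that are not restated here ship as documented
#' placeholders and should be verified against the NPPM publication before
#' regulatory use: minimum energy density 60 kcal/100 g for the four wet-food
#' groups, minimum protein 3.0 g/100 kcal and 4.0 % by weight where protein
#' rules apply, maximum fat 4.5 g/100 kcal, and a 40 % energy "high in sugar"
#' flag threshold for subcategories evaluated for the flag rather than a hard
#' sugar limit. All of them live in the config, never in engine code, so they
#' can be corrected without touching the package.
#'
#' @return A `nppm_ruleset`: list with `taxonomy` (tibble: subcategory code,
#'   label, product group), `rules` (tibble of per-subcategory thresholds;
#'   `NA` means "requirement not applicable"), and `options`
#'   (`sugar_energy_factor_kcal_per_g`, default 4; `kj_per_kcal`, 4.184).
#' @examples
#' rs <- default_ruleset()
#' rs$rules[rs$rules$subcategory == "3.2", "added_water_max_pct"]
#' @export
default_ruleset <- function() {
  taxonomy <- tribble(
    ~subcategory, ~subcategory_label,                                   ~product_group,
    "1.1", "Dry cereals and starches, plain",                           "dry cereals and starches",
    "1.2", "Dry cereals and starches with added fruit",                 "dry cereals and starches",
    "2.1", "Dairy-based foods, desserts, and cereals",                  "dairy foods",
    "2.2", "Fruit-containing product, including breakfast/dairy",       "dairy foods",
    "3.1", "Fruit only products",                                       "fruit and vegetable purees",
    "3.2", "Vegetable only products",                                   "fruit and vegetable purees",
    "3.3", "Fruit/vegetable products with other ingredients",           "fruit and vegetable purees",
    "3.4", "Mixed fruit and vegetable only products",                   "fruit and vegetable purees",
    "4.1", "Food with cheese named but no protein",                     "savoury meals",
    "4.2", "Food with protein named",                                   "savoury meals",
    "4.3", "Food without protein or cheese named",                      "savoury meals",
    "5.1", "Dry or semi-dry snacks and finger foods",                   "snacks and finger foods",
    "5.2", "Other snacks and finger foods",                             "snacks and finger foods",
    "6.1", "Confectionery",                                             "confectionery"
  )

  # NA = requirement not applicable for the subcategory
  rules <- tribble(
    ~subcategory, ~energy_min_kcal_per_100g, ~energy_max_kcal_per_serve,
    ~sodium_max_mg_per_100kcal_base, ~sodium_max_mg_per_100kcal_cheese,
    ~sugar_max_pct_energy, ~sugar_flag_threshold_pct_energy,
    ~added_water_max_pct, ~fruit_required_pct, ~fruit_declaration_required,
    ~protein_min_g_per_100kcal, ~protein_min_pct_weight,
    ~fat_max_g_per_100kcal, ~added_sugar_prohibited, ~trans_fat_prohibited,
    ~category_permitted,
    "1.1", 60, NA, 50, 100, 15, NA, NA,  NA, FALSE, NA,  NA, 4.5, TRUE, TRUE, TRUE,
    "1.2", 60, NA, 50, 100, 15, NA, NA,  NA, TRUE,  3.0, NA, 4.5, TRUE, TRUE, TRUE,
    "2.1", 60, NA, 50, 100, NA, 40, NA,  NA, TRUE,  3.0, NA, 4.5, TRUE, TRUE, TRUE,
    "2.2", 60, NA, 50, 100, NA, 40, NA,  NA, TRUE,  NA,  NA, 4.5, TRUE, TRUE, TRUE,
    "3.1", 60, NA, 50, 100, NA, 40, NA, 100, TRUE,  NA,  NA, 4.5, TRUE, TRUE, TRUE,
    "3.2", 60, NA, 50, 100, 15, NA, 25,  NA, TRUE,  NA,  NA, 4.5, TRUE, TRUE, TRUE,
    "3.3", 60, NA, 50, 100, NA, 40, NA,  NA, TRUE,  3.0, NA, 4.5, TRUE, TRUE, TRUE,
    "3.4", 60, NA, 50, 100, NA, 40, 25,  NA, TRUE,  NA,  NA, 4.5, TRUE, TRUE, TRUE,
    "4.1", 60, NA, 50, 100, 15, NA, NA,  NA, TRUE,  3.0, 4.0, 4.5, TRUE, TRUE, TRUE,
    "4.2", 60, NA, 50, 100, 15, NA, NA,  NA, TRUE,  3.0, 4.0, 4.5, TRUE, TRUE, TRUE,
    "4.3", 60, NA, 50, 100, 15, NA, NA,  NA, TRUE,  3.0, 4.0, 4.5, TRUE, TRUE, TRUE,
    "5.1", NA, 50, 50, 100, 15, NA, NA,  NA, FALSE, NA,  NA, 4.5, TRUE, TRUE, TRUE,
    "5.2", NA, 50, 50, 100, 15, NA, NA,  NA, FALSE, NA,  NA, 4.5, TRUE, TRUE, TRUE,
    "6.1", NA, NA, NA, NA,  NA, NA, NA,  NA, FALSE, NA,  NA, NA, FALSE, FALSE, FALSE
  )

  new_ruleset(
    taxonomy = taxonomy,
    rules = rules,
    options = list(
      sugar_energy_factor_kcal_per_g = 4.0,
      kj_per_kcal = 4.184,
      # Part B switches and the labelling minimum age (months)
      age_min_label_months = 6,
      pouch_rules = TRUE,
      preparation_rules = TRUE
    )
  )
}

new_ruleset <- function(taxonomy, rules, options) {
  rules <- as_tibble(rules)
  canonical <- c("subcategory", .threshold_cols, .rule_flag_cols)
  if (all(canonical %in% names(rules))) {
    rules <- rules[, canonical]
  }
  rs <- structure(
    list(taxonomy = as_tibble(taxonomy), rules = rules, options = options),
    class = "nppm_ruleset"
  )
  validate_ruleset(rs)
}

validate_ruleset <- function(rs) {
  tax <- rs$taxonomy
  rules <- rs$rules
  if (anyDuplicated(tax$subcategory)) {
    abort("duplicated subcategory codes in taxonomy", class = "nppm_config_error")
  }
  bad_group <- setdiff(unique(tax$product_group), .product_groups)
  if (length(bad_group)) {
    abort(paste0("unknown product group(s): ", toString(bad_group)),
          class = "nppm_config_error")
  }
  unknown <- setdiff(rules$subcategory, tax$subcategory)
  if (length(unknown)) {
    abort(paste0("rules reference unknown subcategory code(s): ",
                 toString(unknown)), class = "nppm_config_error")
  }
  missing_rules <- setdiff(tax$subcategory, rules$subcategory)
  if (length(missing_rules)) {
    abort(paste0("no rules for subcategory code(s): ",
                 toString(missing_rules)), class = "nppm_config_error")
  }
  for (col in .threshold_cols) {
    v <- rules[[col]]
    if (is.null(v)) {
      abort(paste0("ruleset missing threshold column '", col, "'"),
            class = "nppm_config_error")
    }
    if (any(!is.na(v) & v < 0)) {
      abort(paste0("negative threshold in '", col, "'"),
            class = "nppm_config_error")
    }
  }
  cheese_lt <- !is.na(rules$sodium_max_mg_per_100kcal_cheese) &
    !is.na(rules$sodium_max_mg_per_100kcal_base) &
    rules$sodium_max_mg_per_100kcal_cheese < rules$sodium_max_mg_per_100kcal_base
  if (any(cheese_lt)) {
    abort("cheese sodium limit below base limit", class = "nppm_config_error")
  }
  for (opt in c("sugar_energy_factor_kcal_per_g", "kj_per_kcal",
                "age_min_label_months")) {
    val <- rs$options[[opt]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val <= 0) {
      abort(paste0("option '", opt, "' must be a positive number"),
            class = "nppm_config_error")
    }
  }
  for (opt in c("pouch_rules", "preparation_rules")) {
    val <- rs$options[[opt]]
    if (!is.logical(val) || length(val) != 1 || is.na(val)) {
      abort(paste0("option '", opt, "' must be TRUE or FALSE"),
            class = "nppm_config_error")
    }
  }
  rs
}

#' @export
print.nppm_ruleset <- function(x, ...) {
  cat("<nppm_ruleset>\n")
  cat("  subcategories:", nrow(x$taxonomy),
      "in", length(unique(x$taxonomy$product_group)), "product groups\n")
  cat("  sugar-to-energy factor:", x$options$sugar_energy_factor_kcal_per_g,
      "kcal/g;  kJ per kcal:", x$options$kj_per_kcal, "\n")
  n_applicable <- colSums(!is.na(x$rules[.threshold_cols]))
  cat("  thresholds defined:\n")
  for (col in .threshold_cols) {
    cat(sprintf("    %-34s %2d subcategories\n", col, n_applicable[[col]]))
  }
  invisible(x)
}

#' Load a ruleset from a YAML or JSON config file
#'
#' Optional thresholds absent from the file load as not-applicable (`NA`),
#' never as zero. Unknown subcategory codes or negative thresholds are
#' config errors.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` ruleset written by
#'   [write_ruleset()] (or by hand in the same layout).
#' @return A validated `nppm_ruleset`.
#' @seealso [default_ruleset()], [write_ruleset()]
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("ruleset file not found: ", path), class = "nppm_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$subcategories)) {
    abort("ruleset config lacks a 'subcategories' section",
          class = "nppm_config_error")
  }
  tax <- map_dfr(names(raw$subcategories), function(code) {
    sc <- raw$subcategories[[code]]
    tibble(
      subcategory = code,
      subcategory_label = sc$label %||% code,
      product_group = sc$product_group %||% NA_character_
    )
  })
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  lgl_or <- function(x, default) if (is.null(x)) default else as.logical(x)
  rules <- map_dfr(names(raw$subcategories), function(code) {
    sc <- raw$subcategories[[code]]
    row <- tibble(subcategory = code)
    for (col in .threshold_cols) row[[col]] <- num_or_na(sc[[col]])
    row$fruit_declaration_required <- lgl_or(sc$fruit_declaration_required, FALSE)
    row$added_sugar_prohibited <- lgl_or(sc$added_sugar_prohibited, FALSE)
    row$trans_fat_prohibited <- lgl_or(sc$trans_fat_prohibited, FALSE)
    row$category_permitted <- lgl_or(sc$category_permitted, TRUE)
    row
  })
  opts <- raw$options %||% list()
  new_ruleset(
    taxonomy = tax, rules = rules,
    options = list(
      sugar_energy_factor_kcal_per_g =
        opts$sugar_energy_factor_kcal_per_g %||% 4.0,
      kj_per_kcal = opts$kj_per_kcal %||% 4.184,
      age_min_label_months = opts$age_min_label_months %||% 6,
      pouch_rules = opts$pouch_rules %||% TRUE,
      preparation_rules = opts$preparation_rules %||% TRUE
    )
  )
}

#' Write a ruleset config file
#'
#' Serialises a ruleset to YAML (or JSON, by file extension). Not-applicable
#' thresholds are omitted from the file; [load_ruleset()] restores them as
#' `NA`, so `load_ruleset(write_ruleset(rs, path))` reproduces `rs`.
#'
#' @param rules A `nppm_ruleset`.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(rules, path) {
  stopifnot(inherits(rules, "nppm_ruleset"))
  subcats <- list()
  for (i in seq_len(nrow(rules$rules))) {
    row <- rules$rules[i, ]
    code <- row$subcategory
    tax <- rules$taxonomy[rules$taxonomy$subcategory == code, ]
    entry <- list(label = tax$subcategory_label,
                  product_group = tax$product_group)
    for (col in .threshold_cols) {
      if (!is.na(row[[col]])) entry[[col]] <- row[[col]]
    }
    for (col in .rule_flag_cols) entry[[col]] <- row[[col]]
    subcats[[code]] <- entry
  }
  out <- list(options = rules$options, subcategories = subcats)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(out, path, precision = 12)
  }
  invisible(path)
}

# threshold row for one subcategory; errors on unknown codes
ruleset_row <- function(rules, subcategory) {
  row <- rules$rules[rules$rules$subcategory == subcategory, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown subcategory code: ", subcategory),
          class = "nppm_config_error")
  }
  row
}
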