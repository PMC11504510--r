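# Part A: composition and content-labelling checks ---------------------------

#' Percentage of energy supplied by sugar
#'
#' `sugar * factor / energy * 100`, the quantity compared against the "% of
#' energy from total sugar" limits and the high-in-sugar flag threshold.
#'
#' @param sugar_g_per_100g Total sugar, g/100 g.
#' @param energy_kcal_per_100g Energy, kcal/100 g (> 0).
#' @param factor_kcal_per_g Energy conversion factor for sugar
#'   (default 4 kcal/g, configurable in the ruleset).
#' @return Percent of energy from sugar.
#' @examples
#' pct_energy_from_sugar(3.75, 100) # exactly at a 15 % limit
#' @export
pct_energy_from_sugar <- function(sugar_g_per_100g, energy_kcal_per_100g,
                                  factor_kcal_per_g = 4.0) {
  if (any(is.na(energy_kcal_per_100g)) || any(energy_kcal_per_100g <= 0)) {
    abort("energy must be > 0 to express sugar as % of energy",
          class = "nppm_undefined_input")
  }
  sugar_g_per_100g * factor_kcal_per_g / energy_kcal_per_100g * 100
}

#' Sodium density per 100 kcal
#'
#' Rescales sodium per 100 g to sodium per 100 kcal, the basis of the sodium
#' limits (50 mg/100 kcal, or 100 mg/100 kcal where cheese is named).
#'
#' @param sodium_mg_per_100g Sodium, mg/100 g.
#' @param energy_kcal_per_100g Energy, kcal/100 g (> 0).
#' @return Sodium in mg per 100 kcal.
#' @export
sodium_per_100kcal <- function(sodium_mg_per_100g, energy_kcal_per_100g) {
  if (any(is.na(energy_kcal_per_100g)) || any(energy_kcal_per_100g <= 0)) {
    abort("energy must be > 0 to express sodium per 100 kcal",
          class = "nppm_undefined_input")
  }
  sodium_mg_per_100g / energy_kcal_per_100g * 100
}

#' Energy per serve
#'
#' @param energy_kcal_per_100g Energy, kcal/100 g.
#' @param serve_size_g Serve size, g (> 0).
#' @return Energy in kcal per serve.
#' @export
energy_per_serve <- function(energy_kcal_per_100g, serve_size_g) {
  if (any(is.na(serve_size_g)) || any(serve_size_g <= 0)) {
    abort("serve size must be > 0 to compute energy per serve",
          class = "nppm_undefined_input")
  }
  energy_kcal_per_100g * serve_size_g / 100
}

#' Signed percentage deviation from a threshold
#'
#' `(observed - threshold) / threshold * 100`, rounded half away from zero to
#' the nearest integer for reporting; positive above the threshold. A product
#' with 42.8 % added water against a 25 % limit deviates by +71 %.
#'
#' @param observed Observed value.
#' @param threshold Threshold on the same scale (> 0).
#' @return Signed integer percentage.
#' @examples
#' deviation_pct(42.8, 25)
#' @export
deviation_pct <- function(observed, threshold) {
  if (any(is.na(threshold)) || any(threshold <= 0)) {
    abort("threshold must be > 0 to express a relative deviation",
          class = "nppm_undefined_input")
  }
  round_half_up((observed - threshold) / threshold * 100)
}

# one CheckResult row; deviation filled in later from observed/threshold
check_row <- function(product_id, part, requirement_id, applicable,
                      passed = NA, observed = NA_real_, unit = NA_character_,
                      threshold = NA_real_, note = NA_character_) {
  tibble(
    product_id = product_id, part = part, requirement_id = requirement_id,
    applicable = applicable, passed = passed, observed = observed,
    unit = unit, threshold = threshold, note = note
  )
}

finish_checks <- function(rows) {
  rows$deviation_pct <- ifelse(
    !is.na(rows$observed) & !is.na(rows$threshold) & rows$threshold > 0,
    round_half_up((rows$observed - rows$threshold) / rows$threshold * 100),
    NA_real_
  )
  rows[, c("product_id", "part", "requirement_id", "applicable", "passed",
           "observed", "unit", "threshold", "deviation_pct", "note")]
}

part_a_one <- function(p, r, opts) {
  id <- p$product_id
  rows <- list()
  energy <- p$energy_kcal_per_100g
  factor <- opts$sugar_energy_factor_kcal_per_g

  # energy density: per-serve cap for snack subcategories, else minimum per 100 g
  if (!is.na(r$energy_max_kcal_per_serve)) {
    if (is.na(p$serve_size_g)) {
      rows$energy <- check_row(id, "A", "energy_density", TRUE,
                               note = "insufficient input: serve_size_g missing")
    } else {
      obs <- energy_per_serve(energy, p$serve_size_g)
      rows$energy <- check_row(id, "A", "energy_density", TRUE,
                               passed = obs <= r$energy_max_kcal_per_serve,
                               observed = obs, unit = "kcal/serve",
                               threshold = r$energy_max_kcal_per_serve)
    }
  } else if (!is.na(r$energy_min_kcal_per_100g)) {
    rows$energy <- check_row(id, "A", "energy_density", TRUE,
                             passed = energy >= r$energy_min_kcal_per_100g,
                             observed = energy, unit = "kcal/100 g",
                             threshold = r$energy_min_kcal_per_100g)
  } else {
    rows$energy <- check_row(id, "A", "energy_density", FALSE)
  }

  energy_ok <- !is.na(energy) && energy > 0
  per_100kcal <- function(req_id, observed_fun, threshold, unit, pass_fun) {
    if (is.na(threshold)) return(check_row(id, "A", req_id, FALSE))
    if (!energy_ok) {
      return(check_row(id, "A", req_id, TRUE,
                       note = "insufficient input: energy must be > 0"))
    }
    obs <- observed_fun()
    check_row(id, "A", req_id, TRUE, passed = pass_fun(obs), observed = obs,
              unit = unit, threshold = threshold)
  }

  sodium_limit <- if (isTRUE(p$cheese_named) &&
                      !is.na(r$sodium_max_mg_per_100kcal_cheese)) {
    r$sodium_max_mg_per_100kcal_cheese
  } else {
    r$sodium_max_mg_per_100kcal_base
  }
  rows$sodium <- per_100kcal(
    "sodium", function() sodium_per_100kcal(p$sodium_mg_per_100g, energy),
    sodium_limit, "mg/100 kcal", function(obs) obs <= sodium_limit
  )

  rows$sugar <- per_100kcal(
    "total_sugar",
    function() pct_energy_from_sugar(p$total_sugar_g_per_100g, energy, factor),
    r$sugar_max_pct_energy, "% energy",
    function(obs) obs <= r$sugar_max_pct_energy
  )

  rows$added_sugar <- if (isTRUE(r$added_sugar_prohibited)) {
    check_row(id, "A", "added_sugar", TRUE,
              passed = !isTRUE(p$added_free_sugars_present),
              note = if (isTRUE(p$added_free_sugars_present))
                "added free sugars or sweeteners present" else NA_character_)
  } else {
    check_row(id, "A", "added_sugar", FALSE)
  }

  # fruit content: minimum % fruit and/or declaration of the amount added
  fruit_applicable <- !is.na(r$fruit_required_pct) ||
    isTRUE(r$fruit_declaration_required)
  if (fruit_applicable) {
    fail_min <- !is.na(r$fruit_required_pct) &&
      (is.na(p$fruit_pct) || p$fruit_pct < r$fruit_required_pct)
    fruit_maybe_present <- is.na(p$fruit_pct) || p$fruit_pct > 0
    fail_decl <- isTRUE(r$fruit_declaration_required) && fruit_maybe_present &&
      !isTRUE(p$fruit_amount_declared)
    rows$fruit <- check_row(
      id, "A", "fruit_content", TRUE, passed = !(fail_min || fail_decl),
      observed = p$fruit_pct, unit = "% by weight",
      threshold = r$fruit_required_pct,
      note = if (fail_decl) "amount of added fruit not declared" else NA_character_
    )
  } else {
    rows$fruit <- check_row(id, "A", "fruit_content", FALSE)
  }

  if (!is.na(r$added_water_max_pct)) {
    if (is.na(p$added_water_pct)) {
      rows$water <- check_row(id, "A", "added_water", TRUE,
                              note = "insufficient input: added_water_pct missing")
    } else {
      rows$water <- check_row(id, "A", "added_water", TRUE,
                              passed = p$added_water_pct <= r$added_water_max_pct,
                              observed = p$added_water_pct, unit = "% by weight",
                              threshold = r$added_water_max_pct)
    }
  } else {
    rows$water <- check_row(id, "A", "added_water", FALSE)
  }

  rows$protein_content <- per_100kcal(
    "protein_content",
    function() p$protein_g_per_100g / energy * 100,
    r$protein_min_g_per_100kcal, "g/100 kcal",
    function(obs) obs >= r$protein_min_g_per_100kcal
  )

  rows$protein_weight <- if (!is.na(r$protein_min_pct_weight)) {
    check_row(id, "A", "protein_weight", TRUE,
              passed = p$protein_g_per_100g >= r$protein_min_pct_weight,
              observed = p$protein_g_per_100g, unit = "% by weight",
              threshold = r$protein_min_pct_weight)
  } else {
    check_row(id, "A", "protein_weight", FALSE)
  }

  rows$fat <- per_100kcal(
    "fat", function() p$total_fat_g_per_100g / energy * 100,
    r$fat_max_g_per_100kcal, "g/100 kcal",
    function(obs) obs <= r$fat_max_g_per_100kcal
  )

  rows$trans_fat <- if (isTRUE(r$trans_fat_prohibited)) {
    check_row(id, "A", "trans_fat", TRUE,
              passed = !isTRUE(p$industrial_trans_fat_present))
  } else {
    check_row(id, "A", "trans_fat", FALSE)
  }

  # informational: does the product need a front-of-pack "high in sugar" flag?
  if (!is.na(r$sugar_flag_threshold_pct_energy)) {
    if (!energy_ok) {
      rows$flag <- check_row(id, "A", "high_sugar_flag", TRUE,
                             note = "insufficient input: energy must be > 0")
    } else {
      obs <- pct_energy_from_sugar(p$total_sugar_g_per_100g, energy, factor)
      required <- obs > r$sugar_flag_threshold_pct_energy
      rows$flag <- check_row(id, "A", "high_sugar_flag", TRUE, passed = NA,
                             observed = obs, unit = "% energy",
                             threshold = r$sugar_flag_threshold_pct_energy,
                             note = if (required) "high-in-sugar flag required"
                                    else "high-in-sugar flag not required")
    }
  } else {
    rows$flag <- check_row(id, "A", "high_sugar_flag", FALSE)
  }

  rows$category <- check_row(
    id, "A", "category_permitted", TRUE, passed = isTRUE(r$category_permitted),
    note = if (!isTRUE(r$category_permitted))
      "product category not permitted under the model" else NA_character_
  )

  bind_rows(rows)
}

#' Evaluate Part A composition requirements
#'
#' Scores each product against every Part A requirement in
#' `nppm_requirements("A")`, with applicability driven entirely by the
#' ruleset: a missing threshold means "not applicable", never zero. Sodium
#' uses the cheese limit exactly when cheese is named in the product name;
#' the added-sugar and trans-fat checks are prohibitions; the fruit check
#' fails either on a shortfall from the required fruit percentage or on a
#' missing declaration of added fruit; the high-sugar-flag row records
#' whether a front-of-pack flag is required (its `passed` stays `NA`).
#' Verdicts compare exact values, thresholds are inclusive, and only the
#' reported `deviation_pct` is rounded (half away from zero, integer).
#'
#' Checks whose inputs are insufficient (missing serve size or added-water
#' percentage, zero energy) stay applicable but get a missing verdict and an
#' explanatory note; summaries exclude them from numerator and denominator.
#'
#' @param products Validated products tibble (one or more rows).
#' @param rules A `nppm_ruleset`.
#' @return Long tibble of check results: `product_id`, `part`,
#'   `requirement_id`, `applicable`, `passed`, `observed`, `unit`,
#'   `threshold`, `deviation_pct`, `note`.
#' @seealso [evaluate_part_b()], [assess()]
#' @export
evaluate_part_a <- function(products, rules = default_ruleset()) {
  stopifnot(inherits(rules, "nppm_ruleset"))
  out <- map_dfr(seq_len(nrow(products)), function(i) {
    p <- products[i, ]
    part_a_one(p, ruleset_row(rules, p$subcategory), rules$options)
  })
  finish_checks(out)
}

#' Does a product meet all applicable nutrient content requirements?
#'
#' Conjunction over the applicable, decided Part A checks, excluding the
#' informational high-sugar flag. Returns `NA` for products with no
#' applicable nutrient-threshold checks (e.g. confectionery, which instead
#' fails `category_permitted`), so such products never enter the
#' "met all nutrient requirements" numerator or denominator.
#'
#' @param results Check results for a single product from
#'   [evaluate_part_a()].
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
meets_all_nutrient_requirements <- function(results) {
  a <- results[results$part == "A", ]
  nutrient_ids <- setdiff(nppm_requirements("A"),
                          c("high_sugar_flag", "category_permitted"))
  subject <- a$applicable & a$requirement_id %in% nutrient_ids & !is.na(a$passed)
  if (!any(subject)) return(NA)
  decided <- a$applicable & a$requirement_id != "high_sugar_flag" &
    !is.na(a$passed)
  all(a$passed[decided])
}
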