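# Randomised product generator -----------------------------------------------

#' Configuration for the random product generator
#'
#' @param n_products Number of products to generate.
#' @param noncompliance Named list of per-requirement noncompliance
#'   probabilities in `[0, 1]`; unnamed requirements default to 0.
#'   Supported names: the Part A ids `energy_density`, `sodium`,
#'   `total_sugar`, `added_sugar`, `fruit_content`, `added_water`,
#'   `protein_content`, `protein_weight`, `fat`, `trans_fat`, and the Part B
#'   ids `no_claims`, `name_clarity`, `ingredient_clarity`,
#'   `breastfeeding_statement`, `age_min_label`, `upper_age_label`,
#'   `pouch_spoon_suggestion`, `pouch_no_spout_instruction`,
#'   `no_on_the_go_claim`, `preparation_instructions`.
#' @param seed Integer seed making the draw reproducible.
#' @return A `nppm_generator_config` list.
#' @export
generator_config <- function(n_products = 100, noncompliance = list(),
                             seed = 1L) {
  if (!is.numeric(n_products) || n_products < 0) {
    abort("n_products must be a non-negative integer",
          class = "nppm_config_error")
  }
  known <- c(setdiff(nppm_requirements("A"),
                     c("high_sugar_flag", "category_permitted")),
             setdiff(nppm_requirements("B"), "pouch_upper_age_label"))
  bad <- setdiff(names(noncompliance), known)
  if (length(bad)) {
    abort(paste0("unknown requirement in noncompliance config: ",
                 toString(bad)), class = "nppm_config_error")
  }
  probs <- map_dbl(noncompliance, as.numeric)
  if (any(probs < 0 | probs > 1)) {
    abort("noncompliance probabilities must lie in [0, 1]",
          class = "nppm_config_error")
  }
  structure(list(n_products = as.integer(n_products),
                 noncompliance = as.list(probs), seed = as.integer(seed)),
            class = "nppm_generator_config")
}

#' Generate random products with configurable noncompliance
#'
#' Draws products across the permitted subcategories, starting from a fully
#' compliant base (mid-range nutrients, claim-free label, complete
#' ingredient declarations, suitable ages) and independently injecting a
#' violation for each requirement with its configured probability. With all
#' probabilities zero every product passes every applicable check -- a
#' soundness probe for the engines; with probability `p`, the empirical
#' noncompliance rate of a requirement converges to `p` among products where
#' it applies.
#'
#' Physically coupled quantities cannot be violated independently: a protein
#' injection can flip both protein checks where both apply, and removing the
#' upper-age label fails the pouch and the general upper-age checks
#' together.
#'
#' @param config A [generator_config()].
#' @param rules Ruleset the products are generated against.
#' @return A validated products tibble with `config$n_products` rows.
#' @export
generate_random <- function(config = generator_config(),
                            rules = default_ruleset()) {
  stopifnot(inherits(config, "nppm_generator_config"),
            inherits(rules, "nppm_ruleset"))
  n <- config$n_products
  if (n == 0) {
    return(validate_products(generate_fixture(rules)[0, ], rules))
  }
  prob <- function(id) config$noncompliance[[id]] %||% 0
  permitted <- rules$rules$subcategory[rules$rules$category_permitted]
  brands <- c("Little Harvest", "Tiny Spoon", "Bubba Fields", "Milky Moo",
              "Happy Tum", "Orchard Lane", "Green Sprout", "Snack Sprouts")

  withr::with_seed(config$seed, {
    rows <- map_dfr(seq_len(n), function(i) {
      code <- sample(permitted, 1)
      r <- ruleset_row(rules, code)
      opts <- rules$options
      factor <- opts$sugar_energy_factor_kcal_per_g
      hit <- function(id) runif(1) < prob(id)

      pkg <- sample(.package_types, 1)
      is_pouch <- pkg == "pouch"
      snack <- !is.na(r$energy_max_kcal_per_serve)
      serve <- if (snack) 10 else 100

      # energy first; per-100 kcal quantities then scale with it
      energy <- if (snack) {
        per_serve <- r$energy_max_kcal_per_serve *
          if (hit("energy_density")) runif(1, 1.05, 1.6) else runif(1, 0.5, 0.95)
        per_serve / serve * 100
      } else if (!is.na(r$energy_min_kcal_per_100g)) {
        r$energy_min_kcal_per_100g *
          if (hit("energy_density")) runif(1, 0.5, 0.95) else runif(1, 1.1, 2.5)
      } else {
        runif(1, 60, 150)
      }

      sodium_limit <- r$sodium_max_mg_per_100kcal_base
      na100 <- if (is.na(sodium_limit)) 20 else {
        sodium_limit *
          if (hit("sodium")) runif(1, 1.05, 1.8) else runif(1, 0.2, 0.9)
      }

      pctE <- if (!is.na(r$sugar_max_pct_energy)) {
        r$sugar_max_pct_energy *
          if (hit("total_sugar")) runif(1, 1.05, 2) else runif(1, 0.2, 0.9)
      } else if (!is.na(r$sugar_flag_threshold_pct_energy)) {
        r$sugar_flag_threshold_pct_energy * runif(1, 0.3, 0.9)
      } else {
        10
      }

      protein <- if (!is.na(r$protein_min_pct_weight) ||
                     !is.na(r$protein_min_g_per_100kcal)) {
        floor_w <- if (is.na(r$protein_min_pct_weight)) 0 else r$protein_min_pct_weight
        floor_c <- if (is.na(r$protein_min_g_per_100kcal)) 0 else
          r$protein_min_g_per_100kcal * energy / 100
        base <- max(floor_w, floor_c) * 1.3
        mult <- if (hit("protein_content") || hit("protein_weight"))
          runif(1, 0.3, 0.9 * max(floor_w, floor_c) / base) else 1
        base * mult
      } else {
        runif(1, 1, 8)
      }

      fat100 <- if (is.na(r$fat_max_g_per_100kcal)) 3 else {
        r$fat_max_g_per_100kcal *
          if (hit("fat")) runif(1, 1.05, 1.6) else runif(1, 0.3, 0.9)
      }

      fruit_required <- !is.na(r$fruit_required_pct)
      fruit_fail <- (fruit_required || isTRUE(r$fruit_declaration_required)) &&
        hit("fruit_content")
      fruit <- if (fruit_required) {
        if (fruit_fail) runif(1, 70, 99) else r$fruit_required_pct
      } else if (isTRUE(r$fruit_declaration_required)) {
        if (fruit_fail) runif(1, 5, 50) else 0
      } else {
        NA_real_
      }
      fruit_decl <- !(fruit_fail && !fruit_required)

      water <- if (!is.na(r$added_water_max_pct)) {
        r$added_water_max_pct *
          if (hit("added_water")) runif(1, 1.05, 2) else runif(1, 0, 0.9)
      } else {
        NA_real_
      }

      age_min <- if (hit("age_min_label")) 4 else opts$age_min_label_months
      age_max <- if (hit("upper_age_label")) NA_real_ else 36

      tibble(
        product_id = sprintf("r%05d", i),
        brand = sample(brands, 1),
        name_text = paste("synthetic product", i),
        subcategory = code,
        product_group = NA_character_,
        package_type = pkg,
        has_spout = is_pouch,
        serve_size_g = serve,
        energy_kcal_per_100g = energy,
        total_sugar_g_per_100g = pctE * energy / (100 * factor),
        sodium_mg_per_100g = na100 * energy / 100,
        protein_g_per_100g = protein,
        total_fat_g_per_100g = fat100 * energy / 100,
        industrial_trans_fat_present = hit("trans_fat"),
        added_free_sugars_present =
          isTRUE(r$added_sugar_prohibited) && hit("added_sugar"),
        fruit_pct = fruit,
        added_water_pct = water,
        fruit_amount_declared = fruit_decl,
        water_amount_declared = !is.na(water),
        cheese_named = FALSE,
        protein_named = code == "4.2",
        requires_preparation = code == "1.1",
        claims = list(if (hit("no_claims")) {
          tag_claim("no nasties")
        } else {
          empty_claims()
        }),
        ingredients_descending_order = !hit("name_clarity"),
        ingredient_list_amounts_complete = !hit("ingredient_clarity"),
        age_min_months = age_min,
        age_max_months = age_max,
        breastfeeding_statement_present = !hit("breastfeeding_statement"),
        spoon_or_bowl_suggestion =
          if (is_pouch) !hit("pouch_spoon_suggestion") else NA,
        no_spout_consumption_instruction =
          if (is_pouch) !hit("pouch_no_spout_instruction") else NA,
        on_the_go_claim_present =
          if (is_pouch) hit("no_on_the_go_claim") else NA,
        preparation_instructions_present =
          if (code == "1.1") TRUE else NA,
        preparation_instructions_suitable =
          if (code == "1.1") !hit("preparation_instructions") else NA
      )
    })
    validate_products(rows, rules)
  })
}
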