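# Brute-force re-implementation of the checks, deliberately sharing no code
# with the engines: plain base-R arithmetic applied product by product.
# Used to cross-check verdicts and reported deviations.

oracle_round <- function(x) trunc(x + 0.5 * sign(x))

oracle_assess <- function(products, rules) {
  rr <- rules$rules
  factor <- rules$options$sugar_energy_factor_kcal_per_g
  min_age <- rules$options$age_min_label_months
  out <- list()
  for (i in seq_len(nrow(products))) {
    p <- products[i, ]
    r <- rr[rr$subcategory == p$subcategory, ]
    E <- p$energy_kcal_per_100g
    add <- function(req, passed, obs = NA_real_, thr = NA_real_) {
      dev <- if (!is.na(obs) && !is.na(thr) && thr > 0) {
        oracle_round((obs - thr) / thr * 100)
      } else {
        NA_real_
      }
      out[[length(out) + 1]] <<- data.frame(
        product_id = p$product_id, requirement_id = req,
        passed = passed, deviation_pct = dev, stringsAsFactors = FALSE
      )
    }

    # energy: per-serve cap for snacks, otherwise minimum density
    if (!is.na(r$energy_max_kcal_per_serve)) {
      if (is.na(p$serve_size_g)) {
        add("energy_density", NA)
      } else {
        obs <- E * p$serve_size_g / 100
        add("energy_density", obs <= r$energy_max_kcal_per_serve, obs,
            r$energy_max_kcal_per_serve)
      }
    } else if (!is.na(r$energy_min_kcal_per_100g)) {
      add("energy_density", E >= r$energy_min_kcal_per_100g, E,
          r$energy_min_kcal_per_100g)
    }

    if (!is.na(r$sodium_max_mg_per_100kcal_base)) {
      lim <- if (isTRUE(p$cheese_named) &&
                 !is.na(r$sodium_max_mg_per_100kcal_cheese)) {
        r$sodium_max_mg_per_100kcal_cheese
      } else {
        r$sodium_max_mg_per_100kcal_base
      }
      if (E > 0) {
        obs <- p$sodium_mg_per_100g / E * 100
        add("sodium", obs <= lim, obs, lim)
      } else {
        add("sodium", NA)
      }
    }

    if (!is.na(r$sugar_max_pct_energy)) {
      if (E > 0) {
        obs <- p$total_sugar_g_per_100g * factor / E * 100
        add("total_sugar", obs <= r$sugar_max_pct_energy, obs,
            r$sugar_max_pct_energy)
      } else {
        add("total_sugar", NA)
      }
    }

    if (isTRUE(r$added_sugar_prohibited)) {
      add("added_sugar", !isTRUE(p$added_free_sugars_present))
    }

    if (!is.na(r$fruit_required_pct) || isTRUE(r$fruit_declaration_required)) {
      short <- !is.na(r$fruit_required_pct) &&
        (is.na(p$fruit_pct) || p$fruit_pct < r$fruit_required_pct)
      present <- is.na(p$fruit_pct) || p$fruit_pct > 0
      undeclared <- isTRUE(r$fruit_declaration_required) && present &&
        !isTRUE(p$fruit_amount_declared)
      add("fruit_content", !(short || undeclared), p$fruit_pct,
          r$fruit_required_pct)
    }

    if (!is.na(r$added_water_max_pct)) {
      if (is.na(p$added_water_pct)) {
        add("added_water", NA)
      } else {
        add("added_water", p$added_water_pct <= r$added_water_max_pct,
            p$added_water_pct, r$added_water_max_pct)
      }
    }

    if (!is.na(r$protein_min_g_per_100kcal)) {
      if (E > 0) {
        obs <- p$protein_g_per_100g / E * 100
        add("protein_content", obs >= r$protein_min_g_per_100kcal, obs,
            r$protein_min_g_per_100kcal)
      } else {
        add("protein_content", NA)
      }
    }

    if (!is.na(r$protein_min_pct_weight)) {
      add("protein_weight", p$protein_g_per_100g >= r$protein_min_pct_weight,
          p$protein_g_per_100g, r$protein_min_pct_weight)
    }

    if (!is.na(r$fat_max_g_per_100kcal)) {
      if (E > 0) {
        obs <- p$total_fat_g_per_100g / E * 100
        add("fat", obs <= r$fat_max_g_per_100kcal, obs,
            r$fat_max_g_per_100kcal)
      } else {
        add("fat", NA)
      }
    }

    if (isTRUE(r$trans_fat_prohibited)) {
      add("trans_fat", !isTRUE(p$industrial_trans_fat_present))
    }

    add("category_permitted", isTRUE(r$category_permitted))

    # Part B
    add("no_claims", nrow(p$claims[[1]]) == 0)
    add("name_clarity", isTRUE(p$ingredients_descending_order))
    add("ingredient_clarity", isTRUE(p$ingredient_list_amounts_complete))
    spouted <- p$package_type == "pouch" && isTRUE(p$has_spout)
    if (spouted && isTRUE(rules$options$pouch_rules)) {
      add("pouch_spoon_suggestion", isTRUE(p$spoon_or_bowl_suggestion))
      add("pouch_no_spout_instruction",
          isTRUE(p$no_spout_consumption_instruction))
      add("pouch_upper_age_label", !is.na(p$age_max_months))
      add("no_on_the_go_claim", !isTRUE(p$on_the_go_claim_present))
    }
    add("breastfeeding_statement", isTRUE(p$breastfeeding_statement_present))
    if (is.na(p$age_min_months)) {
      add("age_min_label", NA)
    } else {
      add("age_min_label", p$age_min_months >= min_age, p$age_min_months,
          min_age)
    }
    add("upper_age_label", !is.na(p$age_max_months))
    if (isTRUE(p$requires_preparation) &&
        isTRUE(rules$options$preparation_rules)) {
      add("preparation_instructions",
          isTRUE(p$preparation_instructions_present) &&
            isTRUE(p$preparation_instructions_suitable))
    }
  }
  do.call(rbind, out)
}

# flag requirement re-derived independently
oracle_flag_required <- function(products, rules) {
  rr <- rules$rules
  factor <- rules$options$sugar_energy_factor_kcal_per_g
  vapply(seq_len(nrow(products)), function(i) {
    p <- products[i, ]
    r <- rr[rr$subcategory == p$subcategory, ]
    thr <- r$sugar_flag_threshold_pct_energy
    if (is.na(thr) || p$energy_kcal_per_100g <= 0) return(NA)
    p$total_sugar_g_per_100g * factor / p$energy_kcal_per_100g * 100 > thr
  }, logical(1))
}
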