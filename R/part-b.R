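# Part B: labelling and promotion checks -------------------------------------

part_b_one <- function(p, opts) {
  id <- p$product_id
  rows <- list()

  n_claims <- nrow(p$claims[[1]])
  rows$no_claims <- check_row(
    id, "B", "no_claims", TRUE, passed = n_claims == 0,
    observed = n_claims, unit = "claims",
    note = if (n_claims > 0)
      "compositional/nutritional/health/marketing claims present"
    else NA_character_
  )

  bool_check <- function(req_id, applicable, value, fail_note = NA_character_) {
    if (!applicable) return(check_row(id, "B", req_id, FALSE))
    if (is.na(value)) {
      return(check_row(id, "B", req_id, TRUE,
                       note = paste0("insufficient input for ", req_id)))
    }
    check_row(id, "B", req_id, TRUE, passed = value,
              note = if (!value) fail_note else NA_character_)
  }

  rows$name <- bool_check("name_clarity", TRUE, p$ingredients_descending_order,
                          "ingredients not listed in descending order")
  rows$ingr <- bool_check("ingredient_clarity", TRUE,
                          p$ingredient_list_amounts_complete,
                          "amount of added water or fruit missing from ingredient list")

  is_spouted_pouch <- isTRUE(opts$pouch_rules) &&
    p$package_type == "pouch" && isTRUE(p$has_spout)
  rows$spoon <- bool_check("pouch_spoon_suggestion", is_spouted_pouch,
                           p$spoon_or_bowl_suggestion,
                           "no suggestion to serve from a spoon or bowl")
  rows$spout <- bool_check("pouch_no_spout_instruction", is_spouted_pouch,
                           p$no_spout_consumption_instruction,
                           "no explicit instruction not to consume from the spout")
  rows$pouch_age <- if (is_spouted_pouch) {
    check_row(id, "B", "pouch_upper_age_label", TRUE,
              passed = !is.na(p$age_max_months),
              observed = p$age_max_months, unit = "months",
              note = if (is.na(p$age_max_months)) "no upper-age label"
                     else NA_character_)
  } else {
    check_row(id, "B", "pouch_upper_age_label", FALSE)
  }
  rows$otg <- bool_check("no_on_the_go_claim", is_spouted_pouch,
                         !p$on_the_go_claim_present,
                         "'on-the-go' convenience claim present")

  rows$bf <- bool_check("breastfeeding_statement", TRUE,
                        p$breastfeeding_statement_present,
                        "no statement on the importance of continued breastfeeding")

  min_age <- opts$age_min_label_months
  rows$age_min <- if (is.na(p$age_min_months)) {
    check_row(id, "B", "age_min_label", TRUE,
              note = "insufficient input: no minimum-age label")
  } else {
    check_row(id, "B", "age_min_label", TRUE,
              passed = p$age_min_months >= min_age,
              observed = p$age_min_months, unit = "months",
              threshold = min_age,
              note = if (p$age_min_months < min_age)
                "labelled suitable before the minimum recommended age"
              else NA_character_)
  }

  # informational labelling check reported for every product, alongside the
  # pouch-specific upper-age requirement above
  rows$upper_age <- check_row(
    id, "B", "upper_age_label", TRUE, passed = !is.na(p$age_max_months),
    observed = p$age_max_months, unit = "months",
    note = if (is.na(p$age_max_months)) "no upper-age information"
           else NA_character_
  )

  prep_applicable <- isTRUE(opts$preparation_rules) &&
    isTRUE(p$requires_preparation)
  rows$prep <- if (prep_applicable) {
    check_row(id, "B", "preparation_instructions", TRUE,
              passed = isTRUE(p$preparation_instructions_present) &&
                isTRUE(p$preparation_instructions_suitable),
              note = if (!isTRUE(p$preparation_instructions_present))
                "no preparation instructions"
              else if (!isTRUE(p$preparation_instructions_suitable))
                "preparation instructions unsuitable"
              else NA_character_)
  } else {
    check_row(id, "B", "preparation_instructions", FALSE)
  }

  bind_rows(rows)
}

#' Evaluate Part B labelling and promotion requirements
#'
#' Scores each product against the promotional-message requirements:
#' `no_claims` passes only for a claim-free pack; name and ingredient-list
#' clarity follow the machine-checkable label flags; the four pouch checks
#' (spoon/bowl suggestion, explicit no-spout instruction, upper-age label,
#' no "on-the-go" claim) apply exactly to spouted pouches; a continued-
#' breastfeeding statement is required on every product; the minimum-age
#' label must be at least the ruleset's `age_min_label_months` (default 6);
#' the upper-age label is additionally reported for every product as an
#' informational labelling check; and products requiring preparation must
#' carry suitable preparation instructions. Claim order never affects
#' verdicts.
#'
#' @inheritParams evaluate_part_a
#' @return Long tibble of check results in the same layout as
#'   [evaluate_part_a()].
#' @export
evaluate_part_b <- function(products, rules = default_ruleset()) {
  stopifnot(inherits(rules, "nppm_ruleset"))
  out <- map_dfr(seq_len(nrow(products)), function(i) {
    part_b_one(products[i, ], rules$options)
  })
  finish_checks(out)
}

#' Does a product meet all applicable promotional requirements?
#'
#' Conjunction over the applicable, decided Part B checks. An empty
#' applicable set is vacuously `TRUE` and flagged with a warning.
#'
#' @param results Check results for a single product from
#'   [evaluate_part_b()].
#' @return `TRUE` or `FALSE`.
#' @export
meets_all_promotional_requirements <- function(results) {
  b <- results[results$part == "B", ]
  decided <- b$applicable & !is.na(b$passed)
  if (!any(decided)) {
    warn("no applicable Part B checks; vacuously compliant")
    return(TRUE)
  }
  all(b$passed[decided])
}
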