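# Assessment pipeline ---------------------------------------------------------

#' Assess products against Part A and Part B
#'
#' Runs [evaluate_part_a()] and [evaluate_part_b()] on every product and
#' computes the per-product rollups: `meets_all_nutrient` (conjunction over
#' applicable nutrient checks; `NA` for products subject to none),
#' `meets_all_promotion`, and `high_sugar_flag_required`.
#'
#' @param products Validated products tibble.
#' @param rules A `nppm_ruleset`.
#' @return An `nppm_assessment`: list with `checks` (long tibble of every
#'   check result), `rollups` (one row per product) and `products`.
#' @export
assess <- function(products, rules = default_ruleset()) {
  products <- validate_products(products, rules)
  if (nrow(products) == 0) {
    return(structure(list(checks = finish_checks(check_row(character(), character(),
                                                           character(), logical())[0, ]),
                          rollups = tibble(product_id = character(),
                                           meets_all_nutrient = logical(),
                                           meets_all_promotion = logical(),
                                           high_sugar_flag_required = logical()),
                          products = products),
                     class = "nppm_assessment"))
  }
  checks <- bind_rows(evaluate_part_a(products, rules),
                      evaluate_part_b(products, rules))
  rollups <- map_dfr(products$product_id, function(id) {
    res <- checks[checks$product_id == id, ]
    flag <- res[res$requirement_id == "high_sugar_flag", ]
    flag_required <- if (nrow(flag) && flag$applicable && !is.na(flag$observed)) {
      flag$observed > flag$threshold
    } else {
      NA
    }
    tibble(
      product_id = id,
      meets_all_nutrient = meets_all_nutrient_requirements(res),
      meets_all_promotion = suppressWarnings(
        meets_all_promotional_requirements(res)),
      high_sugar_flag_required = flag_required
    )
  })
  structure(list(checks = checks, rollups = rollups, products = products),
            class = "nppm_assessment")
}

#' @export
print.nppm_assessment <- function(x, ...) {
  cat("<nppm_assessment>\n")
  cat("  products:", nrow(x$products), "  checks:", nrow(x$checks), "\n")
  cat("  met all nutrient requirements:",
      sum(x$rollups$meets_all_nutrient, na.rm = TRUE), "of",
      sum(!is.na(x$rollups$meets_all_nutrient)), "\n")
  cat("  met all promotional requirements:",
      sum(x$rollups$meets_all_promotion, na.rm = TRUE), "of",
      nrow(x$rollups), "\n")
  invisible(x)
}

# decided = enters a compliance denominator
decided_checks <- function(checks) {
  checks[checks$applicable & !is.na(checks$passed), ]
}

#' Summarise compliance across products
#'
#' Builds the per-requirement compliance table: for each requirement, the
#' number of products passing it (numerator), the number of products subject
#' to it with a decided verdict (denominator), and the half-up integer
#' percentage. Products whose inputs were insufficient for a check are
#' excluded from both numerator and denominator. The high-sugar-flag row
#' counts products *required to carry the flag* over products evaluated for
#' it. Overall rollup rows report products meeting all nutrient requirements
#' (denominator: products subject to any nutrient requirement) and all
#' promotional requirements (denominator: all products). Per-package-type
#' compliance fractions from [package_type_compliance()] are attached.
#'
#' @param assessment An `nppm_assessment` from [assess()].
#' @return An `nppm_summary`: list with `requirements`, `overall`,
#'   `package_type` tibbles and `meta` (counting conventions, product count).
#' @export
summarize_compliance <- function(assessment) {
  stopifnot(inherits(assessment, "nppm_assessment"))
  checks <- assessment$checks
  if (nrow(checks) == 0) {
    abort("cannot summarise an empty assessment", class = "nppm_empty_input")
  }
  req_order <- tibble(requirement_id = nppm_requirements(),
                      .order = seq_along(nppm_requirements()))

  flag <- checks[checks$requirement_id == "high_sugar_flag" &
                   checks$applicable & !is.na(checks$observed), ]
  flag_row <- tibble(
    part = "A", requirement_id = "high_sugar_flag",
    numerator = sum(flag$observed > flag$threshold),
    denominator = nrow(flag),
    proportion_pct = pct_half_up(sum(flag$observed > flag$threshold), nrow(flag))
  )

  rest <- decided_checks(checks[checks$requirement_id != "high_sugar_flag", ])
  req_rows <- rest |>
    group_by(.data$part, .data$requirement_id) |>
    summarise(numerator = sum(.data$passed),
              denominator = dplyr::n(), .groups = "drop") |>
    mutate(proportion_pct = pct_half_up(.data$numerator, .data$denominator))

  requirements <- bind_rows(req_rows, flag_row) |>
    left_join(req_order, by = "requirement_id") |>
    arrange(.data$.order) |>
    select(-".order")

  ru <- assessment$rollups
  overall <- tibble(
    measure = c("meets_all_nutrient", "meets_all_promotion"),
    numerator = c(sum(ru$meets_all_nutrient, na.rm = TRUE),
                  sum(ru$meets_all_promotion, na.rm = TRUE)),
    denominator = c(sum(!is.na(ru$meets_all_nutrient)), nrow(ru))
  ) |>
    mutate(proportion_pct = pct_half_up(.data$numerator, .data$denominator))

  structure(
    list(
      requirements = requirements,
      overall = overall,
      package_type = package_type_compliance(assessment),
      meta = list(
        n_products = nrow(assessment$products),
        package_type_basis = paste(
          "all applicable Part A + Part B checks with decided verdicts;",
          "informational high-sugar-flag rows excluded"
        )
      )
    ),
    class = "nppm_summary"
  )
}

#' Per-package-type compliance fractions
#'
#' For each package type present in the sample: the share of applicable,
#' decided checks (Part A and Part B combined, high-sugar-flag rows excluded
#' as informational) that were met across all products of that type, as a
#' half-up integer percentage. Package types with no products are omitted.
#'
#' @param assessment An `nppm_assessment`.
#' @return Tibble: `package_type`, `criteria_met`, `criteria_applicable`,
#'   `proportion_pct`.
#' @export
package_type_compliance <- function(assessment) {
  stopifnot(inherits(assessment, "nppm_assessment"))
  decided <- decided_checks(assessment$checks)
  decided |>
    left_join(assessment$products[, c("product_id", "package_type")],
              by = "product_id") |>
    group_by(.data$package_type) |>
    summarise(criteria_met = sum(.data$passed),
              criteria_applicable = dplyr::n(), .groups = "drop") |>
    mutate(proportion_pct = pct_half_up(.data$criteria_met,
                                        .data$criteria_applicable)) |>
    arrange(.data$package_type)
}

#' @export
print.nppm_summary <- function(x, ...) {
  cat("NPPM compliance summary (", x$meta$n_products, " products)\n\n", sep = "")
  req <- x$requirements
  cat("Requirement compliance (products meeting / subject to):\n")
  for (i in seq_len(nrow(req))) {
    label <- if (req$requirement_id[i] == "high_sugar_flag") {
      "high_sugar_flag (required)"
    } else {
      req$requirement_id[i]
    }
    cat(sprintf("  %-28s %3d / %3d  (%s%%)\n", label, req$numerator[i],
                req$denominator[i],
                ifelse(is.na(req$proportion_pct[i]), "-",
                       req$proportion_pct[i])))
  }
  cat("\nOverall:\n")
  for (i in seq_len(nrow(x$overall))) {
    cat(sprintf("  %-28s %3d / %3d  (%s%%)\n", x$overall$measure[i],
                x$overall$numerator[i], x$overall$denominator[i],
                x$overall$proportion_pct[i]))
  }
  cat("\nCriteria met by package type:\n")
  pt <- x$package_type
  for (i in seq_len(nrow(pt))) {
    cat(sprintf("  %-28s %4d / %4d (%d%%)\n", pt$package_type[i],
                pt$criteria_met[i], pt$criteria_applicable[i],
                pt$proportion_pct[i]))
  }
  invisible(x)
}

# Assessment IO ---------------------------------------------------------------

#' Write assessment results
#'
#' CSV is long-form, one row per (product, requirement):
#' `product_id, part, requirement_id, applicable, passed, observed, unit,
#' threshold, deviation_pct, note`. JSON nests the Part A and Part B results
#' and the rollups per product (lossless).
#'
#' @param assessment An `nppm_assessment` (non-empty).
#' @param path Output file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessment, path,
                              format = c("auto", "csv", "json")) {
  stopifnot(inherits(assessment, "nppm_assessment"))
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (nrow(assessment$checks) == 0) {
    abort("refusing to write an empty assessment", class = "nppm_empty_input")
  }
  if (format == "csv") {
    readr::write_csv(assessment$checks, path)
  } else {
    recs <- map(assessment$rollups$product_id, function(id) {
      res <- assessment$checks[assessment$checks$product_id == id, ]
      ru <- assessment$rollups[assessment$rollups$product_id == id, ]
      list(
        product_id = id,
        part_a = res[res$part == "A", setdiff(names(res), c("product_id", "part"))],
        part_b = res[res$part == "B", setdiff(names(res), c("product_id", "part"))],
        meets_all_nutrient = ru$meets_all_nutrient,
        meets_all_promotion = ru$meets_all_promotion,
        high_sugar_flag_required = ru$high_sugar_flag_required
      )
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read assessment results written by [write_assessments()]
#'
#' @param path File to read (`.csv` long form or `.json` nested form).
#' @return Long tibble of check results.
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nppm_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    map_dfr(recs, function(r) {
      parts <- bind_rows(
        mutate(map_dfr(r$part_a, function(row)
          as_tibble(map(row, function(v) v %||% NA))), part = "A"),
        mutate(map_dfr(r$part_b, function(row)
          as_tibble(map(row, function(v) v %||% NA))), part = "B")
      )
      parts$product_id <- r$product_id
      parts
    }) |>
      mutate(
        applicable = as.logical(.data$applicable),
        passed = as.logical(.data$passed),
        observed = as.numeric(.data$observed),
        unit = as.character(.data$unit),
        threshold = as.numeric(.data$threshold),
        deviation_pct = as.numeric(.data$deviation_pct),
        note = as.character(.data$note)
      ) |>
      select("product_id", "part", "requirement_id", "applicable", "passed",
             "observed", "unit", "threshold", "deviation_pct", "note")
  } else {
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      product_id = readr::col_character(),
                      part = readr::col_character(),
                      requirement_id = readr::col_character(),
                      applicable = readr::col_logical(),
                      passed = readr::col_logical(),
                      observed = readr::col_double(),
                      unit = readr::col_character(),
                      threshold = readr::col_double(),
                      deviation_pct = readr::col_double(),
                      note = readr::col_character()
                    ))
  }
}

# Sampling --------------------------------------------------------------------

#' Rapid-evaluation product sampling
#'
#' Implements the rapid-evaluation protocol: within each subcategory select
#' up to `max_per_subcategory` products at random while representing the
#' brands present. Subcategories with at most the cap return every product.
#' Otherwise one product is drawn uniformly per brand and the remaining
#' slots are filled uniformly from the rest; when there are more brands than
#' slots, a uniform subset of brands contributes one product each.
#'
#' @param products Products tibble (classified into subcategories).
#' @param max_per_subcategory Cap per subcategory (default 5).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return Tibble of sampled products, ordered by subcategory then
#'   product id.
#' @export
sample_products <- function(products, max_per_subcategory = 5, seed = 1L) {
  if (nrow(products) == 0) {
    warn("no products to sample from")
    return(products)
  }
  withr::with_seed(seed, {
    picked <- products |>
      group_by(.data$subcategory) |>
      dplyr::group_map(function(g, key) {
        g$subcategory <- key$subcategory
        if (nrow(g) <= max_per_subcategory) return(g)
        brands <- unique(g$brand)
        pick_one_per_brand <- function(brands) {
          idx <- map_dbl(brands, function(b) {
            cand <- which(g$brand == b)
            if (length(cand) == 1) cand else sample(cand, 1)
          })
          as.integer(idx)
        }
        if (length(brands) >= max_per_subcategory) {
          chosen_brands <- if (length(brands) == max_per_subcategory) {
            brands
          } else {
            sample(brands, max_per_subcategory)
          }
          g[sort(pick_one_per_brand(chosen_brands)), ]
        } else {
          first <- pick_one_per_brand(brands)
          rest <- setdiff(seq_len(nrow(g)), first)
          extra <- if (length(rest) == 1) rest else {
            sample(rest, max_per_subcategory - length(first))
          }
          g[sort(c(first, extra)), ]
        }
      }) |>
      bind_rows()
  })
  arrange(picked, .data$subcategory, .data$product_id)
}
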