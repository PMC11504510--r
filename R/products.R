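# Product table schema --------------------------------------------------------

# column -> prototype; claims is a list-column of tibble(text, category)
.product_cols <- c(
  product_id = "character", brand = "character", name_text = "character",
  subcategory = "character", product_group = "character",
  package_type = "character", has_spout = "logical",
  serve_size_g = "numeric", energy_kcal_per_100g = "numeric",
  total_sugar_g_per_100g = "numeric", sodium_mg_per_100g = "numeric",
  protein_g_per_100g = "numeric", total_fat_g_per_100g = "numeric",
  industrial_trans_fat_present = "logical",
  added_free_sugars_present = "logical",
  fruit_pct = "numeric", added_water_pct = "numeric",
  fruit_amount_declared = "logical", water_amount_declared = "logical",
  cheese_named = "logical", protein_named = "logical",
  requires_preparation = "logical",
  claims = "list",
  ingredients_descending_order = "logical",
  ingredient_list_amounts_complete = "logical",
  age_min_months = "numeric", age_max_months = "numeric",
  breastfeeding_statement_present = "logical",
  spoon_or_bowl_suggestion = "logical",
  no_spout_consumption_instruction = "logical",
  on_the_go_claim_present = "logical",
  preparation_instructions_present = "logical",
  preparation_instructions_suitable = "logical"
)

# label-side fields, nested under "label" in the JSON representation
.label_cols <- c(
  "claims", "ingredients_descending_order",
  "ingredient_list_amounts_complete", "age_min_months", "age_max_months",
  "breastfeeding_statement_present", "spoon_or_bowl_suggestion",
  "no_spout_consumption_instruction", "on_the_go_claim_present",
  "preparation_instructions_present", "preparation_instructions_suitable"
)

#' Column dictionary for the products table
#'
#' One row per column of the flat product table accepted by
#' [read_products()] / [validate_products()]: name, type and the unit or
#' closed vocabulary where one applies. The same dictionary ships as
#' `inst/extdata/product_columns.csv`.
#'
#' @return A tibble with columns `column`, `type`, `detail`.
#' @export
product_column_dictionary <- function() {
  tibble(
    column = names(.product_cols),
    type = unname(.product_cols),
    detail = c(
      "unique identifier", "brand name", "product name as printed",
      "NPPM subcategory code, e.g. '3.2'",
      paste0("one of: ", toString(.product_groups)),
      paste0("one of: ", toString(.package_types)),
      "TRUE for spouted pouches", "grams per serve (> 0)",
      "kcal per 100 g (>= 0)", "g per 100 g (0-100)", "mg per 100 g (>= 0)",
      "g per 100 g (>= 0)", "g per 100 g (>= 0)",
      "industrially produced trans fat in ingredients",
      "added free sugars or sweeteners in ingredients",
      "% fruit by weight (0-100) or missing", "% added water (0-100) or missing",
      "amount of fruit declared on label where fruit present",
      "amount of added water declared on label where water added",
      "cheese named in the product name", "protein named in the product name",
      "product requires preparation before serving",
      "'category: text' pairs separated by ' ; ' in CSV",
      "ingredient list in descending order by weight",
      "ingredient list declares amounts of added water/fruit",
      "labelled minimum age, months (0-48) or missing",
      "labelled upper age, months (0-48) or missing",
      "statement on continued breastfeeding present",
      "suggestion to serve from a spoon or bowl",
      "explicit instruction not to consume from the spout",
      "'on-the-go' convenience claim present",
      "preparation instructions present",
      "preparation instructions classified suitable"
    )
  )
}

empty_claims <- function() tibble(text = character(), category = character())

claims_to_string <- function(claims) {
  map_chr(claims, function(cl) {
    if (is.null(cl) || nrow(cl) == 0) return("")
    paste(paste0(cl$category, ": ", cl$text), collapse = " ; ")
  })
}

string_to_claims <- function(x) {
  map(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(empty_claims())
    parts <- strsplit(s, "\\s*;\\s*")[[1]]
    parsed <- map_dfr(parts, function(p) {
      m <- regmatches(p, regexec("^([a-z]+)\\s*:\\s*(.+)$", p))[[1]]
      if (length(m) == 3 && m[2] %in% .claim_categories) {
        tibble(text = m[3], category = m[2])
      } else {
        tibble(text = trimws(p), category = "marketing")
      }
    })
    parsed
  })
}

# Validation ------------------------------------------------------------------

#' Validate a product table
#'
#' Checks the table against the documented schema: all columns present, types
#' coercible, values inside their ranges (nutrients non-negative, total sugar
#' at most 100 g/100 g, percentages in 0-100, ages in 0-48 months with upper
#' age at least the minimum, serve size positive), subcategory codes drawn
#' from the ruleset taxonomy and product group consistent with the
#' subcategory. Missing optional numerics (`fruit_pct`, `added_water_pct`,
#' ages) stay `NA` -- missing is a distinct state, never silently zero.
#'
#' @param products A data frame in the layout of
#'   [product_column_dictionary()].
#' @param rules A `nppm_ruleset` supplying the taxonomy
#'   (default [default_ruleset()]).
#' @return The validated products tibble (product group filled in from the
#'   taxonomy where absent), invisibly usable in pipelines.
#' @export
validate_products <- function(products, rules = default_ruleset()) {
  stopifnot(inherits(rules, "nppm_ruleset"))
  products <- as_tibble(products)

  missing_cols <- setdiff(setdiff(names(.product_cols), "product_group"),
                          names(products))
  if (length(missing_cols)) {
    abort(paste0("product table is missing mandatory column(s): ",
                 toString(missing_cols)), class = "nppm_schema_error")
  }
  if (!"product_group" %in% names(products)) {
    products$product_group <- NA_character_
  }

  for (col in names(.product_cols)) {
    target <- .product_cols[[col]]
    if (target == "list") next
    products[[col]] <- switch(
      target,
      character = as.character(products[[col]]),
      numeric = as.numeric(products[[col]]),
      logical = as.logical(products[[col]])
    )
  }
  if (!is.list(products$claims)) {
    products$claims <- string_to_claims(products$claims)
  }

  ids <- products$product_id
  if (any(is.na(ids) | !nzchar(ids))) {
    abort("product_id must be non-missing and non-empty",
          class = "nppm_validation_error")
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated product_id: ", toString(ids[duplicated(ids)])),
          class = "nppm_validation_error")
  }

  tax <- rules$taxonomy
  for (i in seq_len(nrow(products))) {
    p <- products[i, ]
    id <- p$product_id
    if (!p$subcategory %in% tax$subcategory) {
      abort_field(id, "subcategory",
                  paste0("unknown code '", p$subcategory, "'"))
    }
    expected_group <- tax$product_group[tax$subcategory == p$subcategory]
    if (is.na(p$product_group)) {
      products$product_group[i] <- expected_group
    } else if (p$product_group != expected_group) {
      abort_field(id, "product_group",
                  paste0("'", p$product_group, "' inconsistent with subcategory ",
                         p$subcategory, " (expected '", expected_group, "')"))
    }
    if (!p$package_type %in% .package_types) {
      abort_field(id, "package_type",
                  paste0("'", p$package_type, "' not one of: ",
                         toString(.package_types)))
    }
    if (!is.na(p$serve_size_g) && p$serve_size_g <= 0) {
      abort_field(id, "serve_size_g", "must be > 0 when present")
    }
    for (col in c("energy_kcal_per_100g", "total_sugar_g_per_100g",
                  "sodium_mg_per_100g", "protein_g_per_100g",
                  "total_fat_g_per_100g")) {
      if (is.na(p[[col]]) || p[[col]] < 0) {
        abort_field(id, col, "must be a non-negative number")
      }
    }
    if (p$total_sugar_g_per_100g > 100) {
      abort_field(id, "total_sugar_g_per_100g", "cannot exceed 100 g/100 g")
    }
    for (col in c("fruit_pct", "added_water_pct")) {
      if (!is.na(p[[col]]) && (p[[col]] < 0 || p[[col]] > 100)) {
        abort_field(id, col, "must lie in [0, 100] when present")
      }
    }
    for (col in c("age_min_months", "age_max_months")) {
      if (!is.na(p[[col]]) && (p[[col]] < 0 || p[[col]] > 48)) {
        abort_field(id, col, "must lie in [0, 48] months when present")
      }
    }
    if (!is.na(p$age_min_months) && !is.na(p$age_max_months) &&
        p$age_max_months < p$age_min_months) {
      abort_field(id, "age_max_months", "upper age below minimum age")
    }
    cl <- products$claims[[i]]
    if (!is.data.frame(cl)) {
      abort_field(id, "claims", "must be a data frame of text + category")
    }
    cl <- as_tibble(cl)
    if (nrow(cl)) {
      if (any(is.na(cl$text) | !nzchar(cl$text))) {
        abort_field(id, "claims", "claim text must be non-empty")
      }
      bad <- setdiff(unique(cl$category), .claim_categories)
      if (length(bad)) {
        abort_field(id, "claims",
                    paste0("claim category not in closed set: ", toString(bad)))
      }
    }
    products$claims[[i]] <- cl
  }
  # canonical column order; user-supplied extras follow the schema columns
  extras <- setdiff(names(products), names(.product_cols))
  products[, c(names(.product_cols), extras)]
}

# IO --------------------------------------------------------------------------

#' Read a product table from CSV or JSON
#'
#' CSV uses one row per product with claims serialised as
#' `"category: text ; category: text"` and booleans as `true`/`false`;
#' JSON uses one object per product with label features nested under
#' `label`. Both are validated with [validate_products()] before being
#' returned, so malformed files fail with errors naming the offending
#' column, product and field.
#'
#' Energy may be supplied as `energy_kj_per_100g` instead of
#' `energy_kcal_per_100g` (labels in some jurisdictions print kJ); it is
#' converted at the ruleset's `kj_per_kcal` (default 4.184) when the kcal
#' column is absent or missing.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param rules Ruleset supplying the taxonomy and the kJ conversion factor.
#' @return A validated products tibble.
#' @seealso [write_products()], [product_column_dictionary()]
#' @export
read_products <- function(path, format = c("auto", "csv", "json"),
                          rules = default_ruleset()) {
  format <- arg_match(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "nppm_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_guess(),
                                                  claims = readr::col_character(),
                                                  subcategory = readr::col_character(),
                                                  product_id = readr::col_character()))
  } else {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- map_dfr(recs, function(r) {
      label <- r$label %||% list()
      flat <- r[setdiff(names(r), "label")]
      for (col in setdiff(.label_cols, "claims")) {
        flat[[col]] <- label[[col]] %||% NA
      }
      flat <- map(flat, function(v) if (is.null(v)) NA else v)
      row <- as_tibble(flat)
      cl <- label$claims %||% list()
      row$claims <- list(if (length(cl)) {
        map_dfr(cl, function(c1) tibble(text = c1$text, category = c1$category))
      } else {
        empty_claims()
      })
      row
    })
  }
  # optional kJ energy column: convert when kcal is absent or missing
  if ("energy_kj_per_100g" %in% names(df)) {
    kj <- as.numeric(df$energy_kj_per_100g)
    if (!"energy_kcal_per_100g" %in% names(df)) {
      df$energy_kcal_per_100g <- NA_real_
    }
    use_kj <- is.na(df$energy_kcal_per_100g) & !is.na(kj)
    df$energy_kcal_per_100g[use_kj] <- kj[use_kj] / rules$options$kj_per_kcal
    df$energy_kj_per_100g <- NULL
  }
  validate_products(df, rules)
}

#' Write a product table to CSV or JSON
#'
#' Inverse of [read_products()]: `read_products(write_products(x, path))`
#' returns a table assessed identically to `x`.
#'
#' @param products Validated products tibble.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_products <- function(products, path, format = c("auto", "csv", "json")) {
  format <- arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    out <- products
    out$claims <- claims_to_string(products$claims)
    readr::write_csv(out, path)
  } else {
    recs <- map(seq_len(nrow(products)), function(i) {
      p <- as.list(products[i, setdiff(names(.product_cols), .label_cols)])
      label <- as.list(products[i, setdiff(.label_cols, "claims")])
      cl <- products$claims[[i]]
      label$claims <- if (nrow(cl)) {
        map(seq_len(nrow(cl)),
            function(j) list(text = cl$text[j], category = cl$category[j]))
      } else {
        list()
      }
      c(p, list(label = label))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

# Claim tagging ---------------------------------------------------------------

#' Default claim-category lexicon
#'
#' Ordered regex patterns mapping on-pack claim text to the four claim
#' categories. Earlier patterns win; anything unmatched defaults to
#' `"marketing"`. The lexicon is assistive only -- curated category
#' annotations in the input table always take precedence, since claim
#' categorisation on real packs is a judgement call for trained assessors.
#'
#' @return Named character vector: names are case-insensitive regex patterns,
#'   values are claim categories.
#' @export
default_claim_lexicon <- function() {
  c(
    "source of (protein|iron|calcium|fibre|fiber)" = "nutritional",
    "no added (sugar|salt)"                        = "nutritional",
    "(high|low|rich) in [a-z]+"                    = "nutritional",
    "good source"                                  = "nutritional",
    "(protein|iron|calcium|fibre|vitamin)"         = "nutritional",
    "(immun|growth|development|brain|gut|digest)"  = "health",
    "(strong bones|healthy tummies?)"              = "health",
    "(organic|no preservatives|no artificial|100\\s?% fruit)" = "compositional",
    "made with real"                               = "compositional"
  )
}

#' Tag free-text claims with a category
#'
#' Matches claim text against an ordered pattern lexicon; the first matching
#' pattern assigns the category, and unmatched text falls through to
#' `"marketing"` (the catch-all for promotional copy such as "no nasties").
#'
#' @param text Character vector of claim texts (non-empty).
#' @param lexicon Named vector of regex patterns to categories, in priority
#'   order; see [default_claim_lexicon()].
#' @return A tibble with one row per claim: `text`, `category`.
#' @examples
#' tag_claim(c("no nasties", "source of protein"))
#' @export
tag_claim <- function(text, lexicon = default_claim_lexicon()) {
  if (length(text) == 0 || any(is.na(text) | !nzchar(trimws(text)))) {
    abort("claim text must be non-empty", class = "nppm_validation_error")
  }
  category <- map_chr(text, function(s) {
    for (i in seq_along(lexicon)) {
      if (grepl(names(lexicon)[i], s, ignore.case = TRUE)) {
        return(unname(lexicon[i]))
      }
    }
    "marketing"
  })
  tibble(text = text, category = category)
}
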