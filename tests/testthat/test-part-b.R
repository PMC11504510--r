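bcheck <- function(p, id, rules = default_ruleset()) {
  res <- evaluate_part_b(p, rules)
  res[res$requirement_id == id, ]
}

test_that("any claim of any category fails the no-claims requirement", {
  p <- generate_fixture()[1, ]
  for (cat in c("compositional", "nutritional", "health", "marketing")) {
    p$claims <- list(tibble::tibble(text = "anything", category = cat))
    expect_false(bcheck(p, "no_claims")$passed)
  }
  p$claims <- list(nppm:::empty_claims())
  expect_true(bcheck(p, "no_claims")$passed)
})

test_that("claim order never affects verdicts", {
  p <- generate_fixture()[1, ]
  cl <- tibble::tibble(text = c("a", "b", "c"),
                       category = c("health", "marketing", "nutritional"))
  p$claims <- list(cl)
  r1 <- evaluate_part_b(p)
  p$claims <- list(cl[3:1, ])
  r2 <- evaluate_part_b(p)
  expect_equal(r1$passed, r2$passed)
})

test_that("pouch requirements apply exactly to spouted pouches", {
  fx <- generate_fixture()
  pouch_ids <- c("pouch_spoon_suggestion", "pouch_no_spout_instruction",
                 "pouch_upper_age_label", "no_on_the_go_claim")
  res <- evaluate_part_b(fx)
  res <- dplyr::left_join(res, fx[, c("product_id", "package_type")],
                          by = "product_id")
  pouch_rows <- res[res$requirement_id %in% pouch_ids, ]
  expect_true(all(pouch_rows$applicable[pouch_rows$package_type == "pouch"]))
  expect_false(any(pouch_rows$applicable[pouch_rows$package_type != "pouch"]))

  # a spoon suggestion does not satisfy the explicit no-spout instruction
  p <- fx[fx$product_id == "p09", ]  # spouted pouch, spoon suggestion only
  expect_true(bcheck(p, "pouch_spoon_suggestion")$passed)
  expect_false(bcheck(p, "pouch_no_spout_instruction")$passed)

  # a pouch without a spout is exempt
  p$has_spout <- FALSE
  expect_false(bcheck(p, "pouch_no_spout_instruction")$applicable)
})

test_that("age labelling below the recommended minimum fails", {
  p <- generate_fixture()[1, ]
  p$age_min_months <- 4
  expect_false(bcheck(p, "age_min_label")$passed)
  p$age_min_months <- 6
  expect_true(bcheck(p, "age_min_label")$passed)
  p$age_min_months <- NA_real_
  res <- bcheck(p, "age_min_label")
  expect_true(res$applicable && is.na(res$passed))

  # upper-age labelling is reported for every product
  expect_false(bcheck(p, "upper_age_label")$passed)
  p$age_max_months <- 36
  expect_true(bcheck(p, "upper_age_label")$passed)
})

test_that("preparation instructions are checked only where preparation is required", {
  fx <- generate_fixture()
  cereal <- fx[fx$product_id == "p01", ]
  expect_true(bcheck(cereal, "preparation_instructions")$passed)
  cereal$preparation_instructions_suitable <- FALSE
  expect_false(bcheck(cereal, "preparation_instructions")$passed)
  snack <- fx[fx$product_id == "p40", ]
  expect_false(bcheck(snack, "preparation_instructions")$applicable)
})

test_that("the promotion rollup is a conjunction with a vacuous-pass warning", {
  # a claim-free, fully labelled hypothetical product meets everything
  p <- generate_fixture()[1, ]
  p$claims <- list(nppm:::empty_claims())
  p$breastfeeding_statement_present <- TRUE
  p$age_max_months <- 36
  res <- evaluate_part_b(p)
  expect_true(meets_all_promotional_requirements(res))

  fx_res <- evaluate_part_b(generate_fixture())
  by_prod <- split(fx_res, fx_res$product_id)
  expect_true(all(!vapply(by_prod, meets_all_promotional_requirements,
                          logical(1))))

  empty <- fx_res[0, ]
  expect_warning(out <- meets_all_promotional_requirements(empty), "vacuous")
  expect_true(out)
})

test_that("part B applicability switches live in the ruleset", {
  rs <- default_ruleset()
  rs$options$pouch_rules <- FALSE
  p <- generate_fixture()[8, ]  # a spouted pouch
  res <- evaluate_part_b(p, rs)
  expect_false(any(res$applicable[res$requirement_id %in%
    c("pouch_spoon_suggestion", "pouch_no_spout_instruction")]))

  rs2 <- default_ruleset()
  rs2$options$age_min_label_months <- 4
  p$age_min_months <- 4
  expect_true(bcheck(p, "age_min_label", rs2)$passed)
})
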