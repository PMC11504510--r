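three_products <- function() {
  generate_fixture()[c(1, 23, 41), ]
}

test_that("product tables round-trip through CSV and JSON", {
  prods <- three_products()
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_products(prods, path)
    back <- read_products(path)
    expect_equal(nrow(back), 3)
    expect_equal(back$product_id, prods$product_id)
    num <- vapply(prods, is.numeric, logical(1))
    expect_equal(as.data.frame(back[, num]), as.data.frame(prods[, num]))
    expect_equal(back$claims, prods$claims)
    # read -> write -> read is the identity on the record set
    path2 <- withr::local_tempfile(fileext = ext)
    write_products(back, path2)
    expect_equal(as.data.frame(read_products(path2)), as.data.frame(back))
  }
})

test_that("validation rejects out-of-range values naming product and field", {
  prods <- three_products()

  bad <- prods
  bad$total_sugar_g_per_100g[2] <- 120
  expect_error(validate_products(bad), "total_sugar",
               class = "nppm_validation_error")
  expect_error(validate_products(bad), bad$product_id[2])

  bad <- prods
  bad$sodium_mg_per_100g[1] <- -1
  expect_error(validate_products(bad), "sodium",
               class = "nppm_validation_error")

  bad <- prods
  bad$fruit_pct[1] <- 130
  expect_error(validate_products(bad), "fruit_pct",
               class = "nppm_validation_error")

  bad <- prods
  bad$subcategory[1] <- "7.7"
  expect_error(validate_products(bad), class = "nppm_validation_error")

  bad <- prods
  bad$product_group[1] <- "confectionery"  # inconsistent with subcategory 1.1
  expect_error(validate_products(bad), "inconsistent",
               class = "nppm_validation_error")

  bad <- prods
  bad$age_min_months[1] <- 12
  bad$age_max_months[1] <- 6
  expect_error(validate_products(bad), "age_max",
               class = "nppm_validation_error")

  bad <- prods
  bad$package_type[1] <- "tin"
  expect_error(validate_products(bad), class = "nppm_validation_error")
})

test_that("a missing mandatory column is a schema error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  prods <- three_products()
  prods$claims <- nppm:::claims_to_string(prods$claims)
  readr::write_csv(prods[, setdiff(names(prods), "sodium_mg_per_100g")], path)
  expect_error(read_products(path), "sodium_mg_per_100g",
               class = "nppm_schema_error")
})

test_that("energy in kJ is converted when the kcal column is absent", {
  prods <- three_products()
  path <- withr::local_tempfile(fileext = ".csv")
  flat <- prods
  flat$claims <- nppm:::claims_to_string(prods$claims)
  flat$energy_kj_per_100g <- flat$energy_kcal_per_100g * 4.184
  flat$energy_kcal_per_100g <- NULL
  readr::write_csv(flat, path)
  back <- read_products(path)
  expect_equal(back$energy_kcal_per_100g, prods$energy_kcal_per_100g,
               tolerance = 1e-12)
})

test_that("the packaged fixture reads back in full with 16 pouches", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_products(generate_fixture(), path)
  back <- read_products(path)
  expect_equal(nrow(back), 45)
  expect_equal(sum(back$package_type == "pouch"), 16)
})

test_that("claim tagging follows lexicon priority with a marketing fallback", {
  expect_equal(tag_claim("no nasties")$category, "marketing")
  expect_equal(tag_claim("source of protein")$category, "nutritional")
  expect_equal(tag_claim("organic")$category, "compositional")
  expect_equal(tag_claim("supports brain development")$category, "health")
  expect_equal(tag_claim("zzzz-unmatched")$category, "marketing")
  expect_error(tag_claim(""), class = "nppm_validation_error")
  expect_error(tag_claim(character(0)), class = "nppm_validation_error")
  # curated annotations in the table are never overwritten by the lexicon
  prods <- three_products()
  expect_equal(prods$claims[[1]]$category, "marketing")
})

test_that("assessments serialise one long row per (product, requirement)", {
  a <- assess(three_products())
  path <- withr::local_tempfile(fileext = ".csv")
  write_assessments(a, path)
  back <- read_assessments(path)
  expect_equal(nrow(back), 3 * length(nppm_requirements()))
  expect_equal(as.data.frame(back), as.data.frame(a$checks))

  pj <- withr::local_tempfile(fileext = ".json")
  write_assessments(a, pj)
  bj <- read_assessments(pj)
  srt <- function(x) {
    dplyr::arrange(as.data.frame(x), product_id, part, requirement_id)
  }
  expect_equal(srt(bj), srt(a$checks))
})

test_that("an empty assessment refuses to write", {
  empty <- assess(generate_fixture()[0, ])
  expect_error(write_assessments(empty, withr::local_tempfile(fileext = ".csv")),
               class = "nppm_empty_input")
})
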