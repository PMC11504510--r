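test_that("the fixture is deterministic and structurally faithful", {
  f1 <- generate_fixture()
  f2 <- generate_fixture()
  expect_identical(f1, f2)
  spec <- fixture_spec()
  expect_equal(nrow(f1), spec$structure$n_products)
  expect_equal(sum(f1$package_type == "pouch"), spec$structure$n_pouches)
  pouches <- f1[f1$package_type == "pouch", ]
  expect_true(all(pouches$has_spout))
  expect_equal(table(pouches$product_group)[names(spec$structure$pouches_by_group)],
               table(factor(rep(names(spec$structure$pouches_by_group),
                                spec$structure$pouches_by_group)))[
                                  names(spec$structure$pouches_by_group)])
  alloc <- table(f1$subcategory)
  expect_true(all(alloc <= 5))
  nonzero <- spec$allocation[spec$allocation > 0]
  expect_equal(as.integer(alloc[names(nonzero)]), unname(nonzero))
  # three non-empty subcategories hold fewer than five products
  expect_equal(sum(nonzero < 5), 3L)
})

test_that("assessing the fixture reproduces every target marginal exactly", {
  spec <- fixture_spec()
  s <- summarize_compliance(assess(generate_fixture()))
  got <- s$requirements[, c("requirement_id", "numerator", "denominator")]
  merged <- merge(spec$requirements, got, by = "requirement_id",
                  suffixes = c("_want", "_got"))
  expect_equal(nrow(merged), nrow(spec$requirements))
  expect_equal(merged$numerator_got, merged$numerator_want,
               info = paste(merged$requirement_id, collapse = ","))
  expect_equal(merged$denominator_got, merged$denominator_want)
  expect_equal(s$overall$measure, spec$overall$measure)
  expect_equal(s$overall$numerator, spec$overall$numerator)
  expect_equal(s$overall$denominator, spec$overall$denominator)
})

test_that("fixture round-trip through CSV preserves the summary report", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_products(generate_fixture(), path)
  s1 <- summarize_compliance(assess(generate_fixture()))
  s2 <- summarize_compliance(assess(read_products(path)))
  expect_equal(s1$requirements, s2$requirements)
  expect_equal(s1$overall, s2$overall)
  expect_equal(s1$package_type, s2$package_type)
})

test_that("fixture engineering places the printed deviation extremes", {
  ck <- assess(generate_fixture())$checks
  dev <- function(id) {
    rows <- ck[ck$requirement_id == id & ck$applicable & !is.na(ck$passed) &
                 !ck$passed, ]
    sort(rows$deviation_pct)
  }
  expect_equal(dev("added_water"), 71)
  expect_equal(dev("sodium"), c(7, 38))
  expect_equal(range(dev("total_sugar")), c(16, 97))
  expect_equal(range(dev("protein_content")), c(-39, -17))
  expect_equal(range(dev("protein_weight")), c(-65, -13))
  expect_equal(dev("fat"), 16)
  expect_equal(min(dev("energy_density")), -48)
  fruit <- ck[ck$requirement_id == "fruit_content" & !is.na(ck$observed), ]
  expect_true(any(fruit$observed == 99.5))
  water <- ck[ck$requirement_id == "added_water" & ck$applicable, ]
  expect_equal(water$observed, 42.8)
})

test_that("an inconsistent spec/ruleset combination refuses to generate", {
  rs <- default_ruleset()
  rs$rules$sugar_max_pct_energy[] <- NA_real_  # no subcategory keeps a limit
  expect_error(generate_fixture(rs), class = "nppm_generation_error")

  spec <- fixture_spec()
  spec$requirements$numerator[1] <- 99
  expect_error(check_fixture_spec(spec), class = "nppm_generation_error")

  spec2 <- fixture_spec()
  spec2$allocation["1.1"] <- 10L
  expect_error(check_fixture_spec(spec2), class = "nppm_generation_error")
})

test_that("zero configured noncompliance yields full compliance everywhere", {
  prods <- generate_random(generator_config(200, seed = 9))
  a <- assess(prods)
  decided <- a$checks[a$checks$applicable & !is.na(a$checks$passed), ]
  expect_true(all(decided$passed))
  expect_true(all(a$rollups$meets_all_nutrient))
  expect_true(all(a$rollups$meets_all_promotion))
})

test_that("the random generator is seeded and respects its config", {
  cfg <- generator_config(50, list(sodium = 0.3), seed = 21)
  expect_identical(generate_random(cfg), generate_random(cfg))
  cfg2 <- generator_config(50, list(sodium = 0.3), seed = 22)
  expect_false(identical(generate_random(cfg), generate_random(cfg2)))

  expect_equal(nrow(generate_random(generator_config(0))), 0)
  expect_error(generator_config(10, list(sodium = 1.5)),
               class = "nppm_config_error")
  expect_error(generator_config(10, list(unheard_of = 0.1)),
               class = "nppm_config_error")
})

test_that("empirical noncompliance tracks the configured probability", {
  p <- 0.1
  prods <- generate_random(generator_config(600, list(total_sugar = p),
                                            seed = 5))
  a <- assess(prods)
  sugar <- a$checks[a$checks$requirement_id == "total_sugar" &
                      a$checks$applicable & !is.na(a$checks$passed), ]
  fails <- sum(!sugar$passed)
  bounds <- stats::qbinom(c(0.005, 0.995), nrow(sugar), p)
  expect_gte(fails, bounds[1])
  expect_lte(fails, bounds[2])
})
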