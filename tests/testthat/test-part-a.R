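test_that("per-energy normalisations follow their defining formulas", {
  expect_equal(pct_energy_from_sugar(3.75, 100, 4), 15)
  expect_equal(pct_energy_from_sugar(0, 80, 4), 0)
  # algebra oracle: 15 % limit exceeded by 97 % is 15 * 1.97 % of energy
  expect_equal(pct_energy_from_sugar(7.39, 100, 4), 29.56)
  expect_equal(15 * 1.97, 29.55)
  expect_error(pct_energy_from_sugar(5, 0), class = "nppm_undefined_input")

  expect_equal(sodium_per_100kcal(50, 100), 50)
  expect_equal(sodium_per_100kcal(100, 200), 50)
  expect_error(sodium_per_100kcal(50, 0), class = "nppm_undefined_input")

  expect_equal(energy_per_serve(250, 20), 50)
  expect_equal(energy_per_serve(400, 10), 40)
  expect_equal(energy_per_serve(500, 25), 125)
  expect_error(energy_per_serve(100, NA), class = "nppm_undefined_input")
})

test_that("deviation reporting matches the printed worked examples", {
  expect_equal(deviation_pct(42.8, 25), 71)
  expect_equal(deviation_pct(25, 25), 0)
  expect_equal(deviation_pct(13, 25), -48)
  expect_equal(deviation_pct(69, 50), 38)
  expect_error(deviation_pct(10, 0), class = "nppm_undefined_input")
})

# a single savoury product whose fields each boundary test perturbs
boundary_product <- function(...) {
  p <- generate_fixture()[generate_fixture()$product_id == "p35", ]
  overrides <- list(...)
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  p
}

check_of <- function(p, id, rules = default_ruleset()) {
  res <- evaluate_part_a(p, rules)
  res[res$requirement_id == id, ]
}

test_that("observed values exactly at inclusive limits pass; epsilon flips", {
  eps <- 1e-9
  # sodium base limit 50 mg/100 kcal at energy 100
  p <- boundary_product(energy_kcal_per_100g = 100, sodium_mg_per_100g = 50)
  expect_true(check_of(p, "sodium")$passed)
  p$sodium_mg_per_100g <- 50 * (1 + eps)
  expect_false(check_of(p, "sodium")$passed)

  # cheese-named products use the 100 mg/100 kcal limit
  p <- boundary_product(energy_kcal_per_100g = 100, sodium_mg_per_100g = 100,
                        cheese_named = TRUE)
  expect_true(check_of(p, "sodium")$passed)
  p$cheese_named <- FALSE
  expect_false(check_of(p, "sodium")$passed)
  p$cheese_named <- TRUE
  p$sodium_mg_per_100g <- 100 * (1 + eps)
  expect_false(check_of(p, "sodium")$passed)

  # sugar at exactly 15 % of energy
  p <- boundary_product(energy_kcal_per_100g = 100,
                        total_sugar_g_per_100g = 3.75)
  expect_true(check_of(p, "total_sugar")$passed)
  p$total_sugar_g_per_100g <- 3.75 * (1 + eps)
  expect_false(check_of(p, "total_sugar")$passed)

  # snack energy at exactly 50 kcal per serve
  s <- generate_fixture()[generate_fixture()$product_id == "p40", ]
  s$energy_kcal_per_100g <- 500; s$serve_size_g <- 10
  expect_true(check_of(s, "energy_density")$passed)
  s$serve_size_g <- 10 * (1 + eps)
  expect_false(check_of(s, "energy_density")$passed)

  # added water at exactly 25 %
  v <- generate_fixture()[generate_fixture()$product_id == "p23", ]
  v$added_water_pct <- 25
  expect_true(check_of(v, "added_water")$passed)
  v$added_water_pct <- 25 + 1e-9
  expect_false(check_of(v, "added_water")$passed)

  # minimum energy density at exactly 60 kcal/100 g
  p <- boundary_product(energy_kcal_per_100g = 60)
  expect_true(check_of(p, "energy_density")$passed)
  p$energy_kcal_per_100g <- 60 - 1e-6
  expect_false(check_of(p, "energy_density")$passed)
})

test_that("sodium density is invariant to joint rescaling of sodium and energy", {
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(sodium_per_100kcal(80 * k, 120 * k),
                 sodium_per_100kcal(80, 120))
  }
})

test_that("increasing total sugar never flips a failing sugar check to passing", {
  p <- boundary_product(energy_kcal_per_100g = 100,
                        total_sugar_g_per_100g = 4)  # 16 %E, failing
  expect_false(check_of(p, "total_sugar")$passed)
  for (sugar in seq(4, 20, by = 2)) {
    p$total_sugar_g_per_100g <- sugar
    expect_false(check_of(p, "total_sugar")$passed)
  }
})

test_that("part A returns a fixed-cardinality, deterministic result list", {
  prods <- generate_fixture()
  res1 <- evaluate_part_a(prods)
  res2 <- evaluate_part_a(prods)
  expect_identical(res1, res2)
  per_product <- table(res1$product_id)
  expect_true(all(per_product == length(nppm_requirements("A"))))
  expect_setequal(unique(res1$requirement_id), nppm_requirements("A"))
})

test_that("cheese naming selects the sodium limit", {
  fx <- generate_fixture()
  q5 <- fx[fx$product_id == "p30", ]  # 80 mg/100 kcal, cheese named
  res <- check_of(q5, "sodium")
  expect_equal(res$threshold, 100)
  expect_true(res$passed)
  q5$cheese_named <- FALSE
  res2 <- check_of(q5, "sodium")
  expect_equal(res2$threshold, 50)
  expect_false(res2$passed)
})

test_that("insufficient inputs yield missing verdicts with notes, not errors", {
  s <- generate_fixture()[generate_fixture()$product_id == "p40", ]
  s$serve_size_g <- NA_real_
  res <- check_of(s, "energy_density")
  expect_true(res$applicable)
  expect_true(is.na(res$passed))
  expect_match(res$note, "serve_size_g")

  v <- generate_fixture()[generate_fixture()$product_id == "p23", ]
  v$added_water_pct <- NA_real_
  res <- check_of(v, "added_water")
  expect_true(is.na(res$passed))

  z <- boundary_product(energy_kcal_per_100g = 0)
  res <- evaluate_part_a(z)
  sod <- res[res$requirement_id == "sodium", ]
  expect_true(sod$applicable && is.na(sod$passed))
})

test_that("the nutrient rollup is a conjunction excluding the sugar flag", {
  fx <- generate_fixture()
  all_pass <- evaluate_part_a(fx[fx$product_id == "p35", ])
  expect_true(meets_all_nutrient_requirements(all_pass))

  one_fail <- evaluate_part_a(fx[fx$product_id == "p30", ])  # energy only
  expect_false(meets_all_nutrient_requirements(one_fail))
  failing <- one_fail[one_fail$applicable & !is.na(one_fail$passed) &
                        !one_fail$passed, ]
  expect_equal(failing$requirement_id, "energy_density")

  # flag-required product otherwise compliant: the flag never fails it
  dairy <- fx[fx$product_id == "p12", ]
  dairy$total_sugar_g_per_100g <- 45 * dairy$energy_kcal_per_100g / 400
  res <- evaluate_part_a(dairy)
  expect_true(res$observed[res$requirement_id == "high_sugar_flag"] >
                res$threshold[res$requirement_id == "high_sugar_flag"])
  expect_true(meets_all_nutrient_requirements(res))

  # confectionery is subject to no nutrient-threshold checks
  conf <- evaluate_part_a(fx[fx$product_id == "p41", ])
  expect_true(is.na(meets_all_nutrient_requirements(conf)))
  expect_false(conf$passed[conf$requirement_id == "category_permitted"])
})

test_that("unknown subcategories error at evaluation", {
  p <- generate_fixture()[1, ]
  p$subcategory <- "8.1"
  expect_error(evaluate_part_a(p), class = "nppm_config_error")
})
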