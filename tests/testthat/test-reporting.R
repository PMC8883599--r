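# a minimal optimal result for report-level tests
mk_result <- function(cost = 1.42, energy = 2184, weight = 86,
                      grams = c("5502" = 86)) {
  foods <- toy_foods(toy_food_row("5502", "bar",
                                  calcium_mg = 322.9 / weight * 100,
                                  energy_kj = energy * 100 / weight,
                                  cost_usd_per_100g = cost * 100 / weight,
                                  racc_g = 55))
  solve_lp(build_lp(foods, toy_target(calcium = 322.9)))
}

test_that("scale_to_servings multiplies totals and grams exactly", {
  res <- mk_result()
  s18 <- scale_to_servings(res, 1.8)
  expect_equal(s18$daily_cost_usd, 1.42 * 1.8, tolerance = 1e-9)
  expect_equal(s18$daily_energy_kj, 2184 * 1.8, tolerance = 1e-9)
  expect_equal(unname(s18$grams_by_category["5502"]), 86 * 1.8,
               tolerance = 1e-9)
  s1 <- scale_to_servings(res, 1)
  expect_equal(s1$daily_cost_usd, unname(res$totals["cost"]))
  expect_equal(s1$daily_weight_g, unname(res$totals["weight"]))
  # exact linearity in s
  a <- scale_to_servings(res, 0.7); b <- scale_to_servings(res, 2.3)
  ab <- scale_to_servings(res, 3.0)
  expect_equal(a$daily_cost_usd + b$daily_cost_usd, ab$daily_cost_usd)
  expect_error(scale_to_servings(res, 0), class = "dairylp_validation_error")
  bad <- res; bad$status <- "infeasible"
  expect_error(scale_to_servings(bad, 1.8), class = "dairylp_state_error")
})

test_that("RACC servings are grams over RACC, one decimal", {
  expect_equal(to_racc_servings(90, 55), 1.6)
  expect_equal(to_racc_servings(0, 55), 0)
  expect_equal(to_racc_servings(55, 55), 1)
  expect_equal(to_racc_servings(c(100, 240), c(40, 240)), c(2.5, 1))
  expect_error(to_racc_servings(10, 0), class = "dairylp_validation_error")
})

test_that("ratios_vs_reference returns plain ratios and excesses", {
  res <- mk_result()
  ref <- dairy_fixture()$reference
  out <- ratios_vs_reference(res, ref)
  expect_equal(unname(out$ratios["cost"]), 1.42 / 0.41, tolerance = 1e-9)
  expect_equal(unname(out$ratios["energy"]), 2184 / 435, tolerance = 1e-9)
  expect_equal(unname(out$excesses["cost"]), 1.42 - 0.41, tolerance = 1e-9)
  # combination equal to the reference: ratios 1, excesses 0
  same <- mk_result(cost = ref$cost_per_serving, energy = 435,
                    weight = ref$weight_per_serving)
  out2 <- ratios_vs_reference(same, ref)
  expect_equal(unname(out2$ratios), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(out2$excesses), rep(0, 3), tolerance = 1e-9)
})

test_that("nutrients-to-limit summary totals, teaspoons and flags", {
  foods <- toy_foods(toy_food_row("2804", "cereal", calcium_mg = 100,
                                  sodium_mg = 903 / 3, added_sugars_g = 23.9 / 3,
                                  sat_fat_g = 1, energy_kj = 1500))
  res <- solve_lp(build_lp(foods, toy_target(calcium = 100)))  # x = 100 g
  # delivered at 300 g: Na 903 mg, added sugars 23.9 g
  res3 <- solve_lp(build_lp(foods, toy_target(calcium = 300)))
  ref <- dairy_fixture()$reference
  out <- nutrients_to_limit_summary(res3, ref)
  expect_equal(unname(out$amounts["sodium"]), 903, tolerance = 1e-9)
  expect_equal(unname(out$amounts["added_sugars_tsp"]), 23.9 / 4.2,
               tolerance = 1e-9)
  expect_equal(unname(out$ratios_vs_dairy["sodium"]), 903 / 133,
               tolerance = 1e-9)
  expect_null(out$flags)
  withf <- nutrients_to_limit_summary(res3, ref, daily_energy_kj = 8700)
  expect_named(withf$flags, c("sodium_over_2300mg", "added_sugars_over_10pct",
                              "sat_fat_over_10pct"))
  expect_false(withf$flags[["sodium_over_2300mg"]])  # 903 mg < 2300 mg
  # 23.9 g x 17 kJ/g = 406 kJ < 10 % of 8700 kJ
  expect_false(withf$flags[["added_sugars_over_10pct"]])
  # zero added sugar -> 0 tsp
  zero <- nutrients_to_limit_summary(res, ref)
  expect_equal(unname(zero$amounts["added_sugars"]) * 0, 0)
})

test_that("nutrient-matched comparison is exact and scale invariant", {
  ref <- dairy_fixture()$reference
  # identical profile: all differences 0 where the reference is positive
  out <- compare_to_reference(ref$per_serving, ref,
                              cost_per_profile = ref$cost_per_serving)
  pos <- unclass(ref$per_serving) > 0
  expect_equal(unname(out$percent_diff[pos]), rep(0, sum(pos)))
  expect_equal(out$cost_percent_diff, 0)

  # substitute built so Ca-matched protein is 34 % of dairy's -> 66 % lower
  p <- unclass(ref$per_serving)
  sub <- nutrient_vector(calcium = p[["calcium"]] * 2,
                         protein = 0.34 * p[["protein"]] * 2,
                         vit_d = p[["vit_d"]] * 0.78 * 2,
                         energy = p[["energy"]] * 0.78 * 2)
  res <- compare_to_reference(sub, ref)
  expect_equal(unname(res$percent_diff["protein"]), -66, tolerance = 1e-9)
  expect_equal(unname(res$percent_diff["vit_d"]), -22, tolerance = 1e-9)

  # doubling the profile before matching changes nothing
  res2 <- compare_to_reference(nutrient_vector(2 * unclass(sub)), ref)
  expect_equal(res2$percent_diff, res$percent_diff)
  expect_error(compare_to_reference(nutrient_vector(protein = 1), ref,
                                    match_on = "calcium"),
               class = "dairylp_validation_error")
})

test_that("grid_report summarises a scenario grid", {
  foods <- generate_food_db(25, seed = 91)
  intakes <- generate_intakes(foods, n_persons = 80, seed = 92)
  grid <- run_all(foods, intakes, dairy_fixture()$reference)
  rep <- grid_report(grid, foods)
  expect_equal(nrow(rep), 12)
  ok <- rep$status == "optimal"
  expect_true(any(ok))
  expect_equal(rep$cost_usd_1.8[ok], rep$cost_usd[ok] * 1.8)
  expect_equal(rep$energy_kj_3.0[ok], rep$energy_kj[ok] * 3.0)
})
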