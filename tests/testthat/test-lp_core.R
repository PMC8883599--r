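test_that("single-food single-nutrient LP has the closed-form solution", {
  foods <- toy_foods(toy_food_row(2804, "cereal", calcium_mg = 100,
                                  energy_kj = 1500, cost_usd_per_100g = 0.9))
  target <- toy_target(calcium = 300)
  for (obj in c("cost", "energy", "weight")) {
    res <- solve_lp(build_lp(foods, target, objective = obj))
    expect_equal(res$status, "optimal")
    expect_equal(unname(res$grams["2804"]), 300, tolerance = 1e-9)
    expect_equal(res$binding, "calcium")   # slack 0 at the optimum
  }
  res <- solve_lp(build_lp(foods, target, objective = "cost"))
  expect_equal(res$objective_value, 300 * 0.9 / 100, tolerance = 1e-9)
  expect_equal(unname(res$totals["energy"]), 300 * 15, tolerance = 1e-9)
  oracle <- brute_force_oracle(build_lp(foods, target))
  expect_equal(unname(oracle$x["2804"]), 300, tolerance = 1e-9)
})

test_that("build_lp wires objectives, caps and exclusions", {
  foods <- toy_foods(
    toy_food_row(2804, "cereal", calcium_mg = 100, energy_kj = 1600),
    toy_food_row(2204, "fish", calcium_mg = 20, protein_g = 22,
                 energy_kj = 600),
    toy_food_row(1006, "milk", calcium_mg = 120, energy_kj = 140)
  )
  target <- toy_target(calcium = 300)
  spec <- build_lp(foods, target, objective = "weight",
                   caps = data.frame(code = "2804", p90_g = 120),
                   exclusions = phase_exclusions(1))
  expect_equal(spec$obj_coef, rep(1, 3))
  expect_equal(spec$upper, c(120, Inf, Inf))
  expect_equal(spec$excluded, c(FALSE, FALSE, TRUE))
  res <- solve_lp(spec)
  expect_equal(unname(res$grams["1006"]), 0)   # excluded stays at zero
  expect_lte(unname(res$grams["2804"]), 120 + 1e-9)
  espec <- build_lp(foods, target, objective = "energy")
  expect_equal(espec$obj_coef, foods$energy_kj / 100)
  expect_error(build_lp(foods, target, exclusions = foods$code),
               class = "dairylp_spec_error")
})

test_that("infeasible caps are reported with the most-violated nutrient", {
  foods <- toy_foods(
    toy_food_row(2804, "cereal", calcium_mg = 100, vit_d_ug = 50))
  target <- toy_target(calcium = 300, vit_d = 10)
  spec <- build_lp(foods, target,
                   caps = data.frame(code = "2804", p90_g = 100))
  res <- solve_lp(spec)
  expect_equal(res$status, "infeasible")
  expect_equal(res$most_violated, "calcium")  # 100 g gives 100 of 300 mg
  expect_equal(brute_force_oracle(spec)$status, "infeasible")
  expect_error(binding_nutrients(res), class = "dairylp_state_error")
})

test_that("solve_lp agrees with the brute-force oracle on random instances", {
  n_feasible <- 0
  for (seed in 1:40) {
    spec <- rand_small_instance(seed)
    res <- solve_lp(spec)
    oracle <- brute_force_oracle(spec)
    expect_equal(res$status, oracle$status, info = paste("seed", seed))
    if (res$status == "optimal") {
      n_feasible <- n_feasible + 1
      expect_equal(res$objective_value, oracle$value,
                   tolerance = 1e-6, info = paste("seed", seed))
      # feasibility: every constrained nutrient met within tolerance
      expect_true(all(res$slack >= -1e-6 * pmax(res$target, 1)),
                  info = paste("seed", seed))
    }
  }
  expect_gt(n_feasible, 10)
})

test_that("some nutrient binds at any optimum with positive costs", {
  for (seed in 41:60) {
    spec <- rand_small_instance(seed)
    if (any(spec$obj_coef <= 0)) next
    res <- solve_lp(spec)
    if (res$status != "optimal" || res$objective_value <= 0) next
    expect_gt(length(res$binding), 0, label = paste("seed", seed))
  }
})

test_that("binding_nutrients orders by slack and handles all-slack optima", {
  inst <- planted_optimum_instance(4, binding = c("calcium", "vit_d"),
                                   seed = 7)
  res <- solve_lp(build_lp(inst$foods, inst$target, objective = "cost"))
  expect_setequal(binding_nutrients(res), c("calcium", "vit_d"))
  expect_equal(sort(res$slack[res$binding]), res$slack[res$binding])
  # constructed result where every slack is positive
  fake <- res
  fake$slack <- fake$slack + fake$target * 0.5 + 1
  expect_length(binding_nutrients(fake), 0)
})

test_that("oracle refuses oversized instances", {
  foods <- do.call(toy_foods, lapply(1:7, function(i)
    toy_food_row(1000 + i, calcium_mg = 50)))
  spec <- build_lp(foods, toy_target(calcium = 100))
  expect_error(brute_force_oracle(spec), class = "dairylp_size_error")
})

test_that("optimal results serialise to JSON", {
  foods <- toy_foods(toy_food_row(2804, "cereal", calcium_mg = 100))
  res <- solve_lp(build_lp(foods, toy_target(calcium = 300)))
  path <- withr::local_tempfile(fileext = ".json")
  write_lp_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$status, "optimal")
  expect_equal(back$grams$`2804`, 300, tolerance = 1e-9)
})
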