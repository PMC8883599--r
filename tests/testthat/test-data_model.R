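test_that("nutrient_vector validates names and nonnegativity", {
  nv <- nutrient_vector(protein = 8.3, calcium = 300)
  expect_s3_class(nv, "nutrient_vector")
  expect_equal(unclass(nv)[["calcium"]], 300)
  expect_equal(unclass(nv)[["vit_d"]], 0)
  expect_error(nutrient_vector(cholesterol = 1), class = "dairylp_validation_error")
  expect_error(nutrient_vector(protein = -1), class = "dairylp_validation_error")
  expect_setequal(nutrient_names(),
                  c(constrained_nutrients(), reported_nutrients()))
  expect_length(constrained_nutrients(), 11)
})

test_that("food table round-trips through text and preserves codes", {
  foods <- toy_foods(
    toy_food_row(7704, "bottled water", cost_usd_per_100g = 0.025,
                 calcium_mg = 2.4, is_beverage = TRUE),
    toy_food_row(2804, "cereal", calcium_mg = 450, vit_d_ug = 3.1),
    toy_food_row(2204, "fish", protein_g = 22, vit_d_ug = 9)
  )
  expect_equal(nrow(foods), 3)
  expect_equal(foods$code, c("7704", "2804", "2204"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_table(foods, path)
  back <- load_food_table(path)
  expect_equal(as.data.frame(back), as.data.frame(foods))
})

test_that("food table schema and integrity violations are caught", {
  df <- toy_food_row(7704)
  expect_error(food_table(df[, setdiff(names(df), "racc_g")]),
               regexp = "racc_g", class = "dairylp_schema_error")
  expect_error(food_table(rbind(toy_food_row(7704), toy_food_row(7704))),
               regexp = "7704", class = "dairylp_integrity_error")
  bad <- toy_food_row(1234)
  bad$calcium_mg <- -5
  expect_error(food_table(rbind(toy_food_row(7704), bad)),
               regexp = "2", class = "dairylp_validation_error")
})

test_that("intake table validates and round-trips", {
  df <- data.frame(person_id = c("a", "a", "b"),
                   sample_weight = c(1.5, 1.5, 2),
                   code = c("7704", "2804", "7704"),
                   grams = c(300, 50, 120))
  it <- intake_table(df)
  path <- withr::local_tempfile(fileext = ".csv")
  write_intake_table(it, path)
  expect_equal(as.data.frame(load_intake_table(path)), as.data.frame(it))
  df$sample_weight[2] <- 9
  expect_error(intake_table(df), class = "dairylp_integrity_error")
  df$sample_weight[2] <- 1.5
  df$grams[1] <- -1
  expect_error(intake_table(df), class = "dairylp_validation_error")
})

test_that("build_dairy_reference combines components by weight fraction", {
  fx <- dairy_fixture()
  # degenerate composite returns the milk profile unchanged
  ref <- build_dairy_reference(fx$milk, fx$cheese, fx$yogurt, c(1, 0, 0))
  expect_equal(unclass(ref$per_serving), unclass(fx$milk$nutrients))
  expect_equal(ref$cost_per_serving, fx$milk$cost_per_serving)
  # hand arithmetic: protein 8 and 12 at 50/50 -> 10
  a <- dairy_component(nutrient_vector(protein = 8, energy = 100), 0.2, 200)
  b <- dairy_component(nutrient_vector(protein = 12, energy = 300), 0.4, 100)
  ref2 <- build_dairy_reference(a, b, a, c(0.5, 0.5, 0))
  expect_equal(unclass(ref2$per_serving)[["protein"]], 10)
  expect_equal(ref2$cost_per_serving, 0.3)
  expect_error(build_dairy_reference(a, b, a, c(0.5, 0.6, 0)),
               class = "dairylp_validation_error")
})

test_that("composite blending is linear in the weights", {
  fx <- dairy_fixture()
  w1 <- c(0.6, 0.3, 0.1); w2 <- c(0.2, 0.5, 0.3)
  alpha <- 0.25
  blend <- alpha * w1 + (1 - alpha) * w2
  r1 <- build_dairy_reference(fx$milk, fx$cheese, fx$yogurt, w1)
  r2 <- build_dairy_reference(fx$milk, fx$cheese, fx$yogurt, w2)
  rb <- build_dairy_reference(fx$milk, fx$cheese, fx$yogurt, blend)
  expect_equal(unclass(rb$per_serving),
               alpha * unclass(r1$per_serving) +
                 (1 - alpha) * unclass(r2$per_serving))
  expect_equal(rb$cost_per_serving,
               alpha * r1$cost_per_serving + (1 - alpha) * r2$cost_per_serving)
})

test_that("dairy fixture composite matches the recoverable printed values", {
  fx <- dairy_fixture()
  per <- unclass(fx$reference$per_serving)
  expect_equal(per[["energy"]], 435)
  expect_equal(fx$reference$cost_per_serving, 0.41)
  expect_equal(per[["sodium"]], 133)
  expect_equal(sum(fx$reference$composite_weights), 1)
})

test_that("dairy reference survives a JSON round trip", {
  fx <- dairy_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  comp <- function(x) list(nutrients = as.list(unclass(x$nutrients)),
                           cost_per_serving = x$cost_per_serving,
                           weight_per_serving = x$weight_per_serving)
  jsonlite::write_json(list(milk = comp(fx$milk), cheese = comp(fx$cheese),
                            yogurt = comp(fx$yogurt),
                            weights = c(0.53, 0.45, 0.02)),
                       path, auto_unbox = TRUE, digits = NA)
  back <- read_dairy_reference(path)
  expect_equal(unclass(back$per_serving), unclass(fx$reference$per_serving))
  expect_equal(back$cost_per_serving, fx$reference$cost_per_serving)
})
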