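# Fixture builders used across the suite. Everything is constructed in code;
# no binary fixtures.

# one food-table row with all nutrients defaulting to zero (per 100 g)
toy_food_row <- function(code, name = paste("food", code),
                         cost_usd_per_100g = 1, racc_g = 100,
                         is_beverage = FALSE, ...) {
  nut <- list(...)
  df <- data.frame(code = as.character(code), name = name,
                   stringsAsFactors = FALSE)
  cols <- c(protein_g = 0, calcium_mg = 0, choline_mg = 0, fibre_g = 0,
            iron_mg = 0, magnesium_mg = 0, potassium_mg = 0,
            vit_a_ug_rae = 0, vit_c_mg = 0, vit_d_ug = 0, vit_e_mg = 0,
            energy_kj = 0, sodium_mg = 0, added_sugars_g = 0, sat_fat_g = 0)
  cols[names(nut)] <- unlist(nut)
  for (nm in names(cols)) df[[nm]] <- cols[[nm]]
  df$cost_usd_per_100g <- cost_usd_per_100g
  df$racc_g <- racc_g
  df$is_beverage <- is_beverage
  df
}

toy_foods <- function(...) food_table(do.call(rbind, list(...)))

# dairy_reference with arbitrary constrained targets (others zero)
toy_target <- function(..., energy = 435, cost = 0.41, weight = 153.65) {
  dairy_reference(nutrient_vector(..., energy = energy),
                  cost_per_serving = cost, weight_per_serving = weight)
}

# independent brute-force weighted-ECDF inverse (kept deliberately naive)
wq_oracle <- function(values, weights, q) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord] / sum(weights)
  acc <- 0
  for (i in seq_along(v)) {
    acc <- acc + w[i]
    if (acc >= q - 1e-12) return(v[i])
  }
  v[length(v)]
}

# random small LP instance for oracle-equivalence checks: <= 4 foods,
# <= 3 nutrients with positive targets, occasionally capped (sometimes
# infeasibly tight)
rand_small_instance <- function(seed) {
  set.seed(seed)
  n <- sample(1:4, 1)
  k <- sample(1:3, 1)
  nutr <- sample(constrained_nutrients(), k)
  rows <- lapply(seq_len(n), function(i) {
    args <- as.list(stats::runif(k, 5, 40))
    names(args) <- paste0(c(protein = "protein_g", calcium = "calcium_mg",
                            choline = "choline_mg", fibre = "fibre_g",
                            iron = "iron_mg", magnesium = "magnesium_mg",
                            potassium = "potassium_mg", vit_a = "vit_a_ug_rae",
                            vit_c = "vit_c_mg", vit_d = "vit_d_ug",
                            vit_e = "vit_e_mg")[nutr])
    do.call(toy_food_row, c(list(code = 100 + i,
                                 cost_usd_per_100g = stats::runif(1, 0.2, 3),
                                 energy_kj = stats::runif(1, 100, 1500)),
                            args))
  })
  foods <- food_table(do.call(rbind, rows))
  targs <- as.list(stats::runif(k, 20, 120))
  names(targs) <- nutr
  target <- do.call(toy_target, targs)
  caps <- NULL
  if (stats::runif(1) < 0.4) {
    caps <- data.frame(code = foods$code,
                       p90_g = stats::runif(n, 20, 400))
  }
  objective <- sample(c("cost", "energy", "weight"), 1)
  build_lp(foods, target, objective = objective, caps = caps)
}
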