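# Seeded generators that emulate the statistical structure of the real
# inputs -- a ~150-category food/nutrient/price table, zero-inflated
# single-day recall intakes with survey weights -- plus planted-optimum LP
# instances whose solutions are known by construction. All generators are
# pure functions of their seeds.

#' Archetype parameters for the synthetic food database
#'
#' The generator draws categories from eight archetypes (staples, fortified
#' cereals, fish, leafy greens, juices, nutrition bars, water-like
#' beverages, milk-substitute-like beverages). Per-archetype ranges for
#' nutrient densities (per 100 g), cost, RACC and consumption parameters
#' live in an editable delimited-text file shipped with the package, so
#' users can push the generated world toward other regimes.
#'
#' @param path Optional path to an alternative parameter file with the same
#'   columns as `system.file("extdata", "archetype_params.csv", package =
#'   "dairylp")`.
#' @return data.frame of archetype parameters.
#' @export
archetype_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "archetype_params.csv", package = "dairylp")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("archetype", "share", "is_beverage", "consume_prob",
            "amount_meanlog", "amount_sdlog", "cost_lo", "cost_hi",
            "racc_lo", "racc_hi",
            paste0(rep(.NUTRIENTS, each = 2), c("_lo", "_hi")))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_schema(sprintf("archetype params missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  df
}

# canonical code blocks per archetype; water-like beverages get the real
# category codes so phase-2 exclusions bite on generated data
.ARCHETYPE_CODES <- list(
  staple = function(k) as.character(4402 + 2 * (seq_len(k) - 1)),
  fortified_cereal = function(k) as.character(2804 + 2 * (seq_len(k) - 1)),
  fish = function(k) as.character(2204 + 2 * (seq_len(k) - 1)),
  leafy_green = function(k) as.character(6402 + 2 * (seq_len(k) - 1)),
  juice = function(k) as.character(7002 + 2 * (seq_len(k) - 1)),
  nutrition_bar = function(k) as.character(5502 + 2 * (seq_len(k) - 1)),
  water_like = function(k) {
    canon <- c("7702", "7704", "7302", "7102", "7106")
    if (k <= length(canon)) canon[seq_len(k)]
    else c(canon, as.character(7710 + 2 * (seq_len(k - length(canon)) - 1)))
  },
  milk_substitute = function(k) as.character(7220 + 2 * (seq_len(k) - 1))
)

# log-uniform draw on [lo, hi]; uniform when lo is at (or below) zero
draw_range <- function(n, lo, hi) {
  if (hi <= 0) return(rep(0, n))
  if (lo <= 0) stats::runif(n, max(lo, 0), hi)
  else exp(stats::runif(n, log(lo), log(hi)))
}

#' Generate a synthetic food-category database
#'
#' Archetype-based generation of a WWEIA-like table: nutrient densities are
#' drawn log-uniformly within archetype ranges (uniformly where a range
#' touches zero), costs are positive, and water-like categories have
#' near-zero energy, near-free cost and trace Ca/Mg -- making them, as in
#' real price data, the cheapest source of those minerals. Deterministic
#' given `seed`.
#'
#' @param n_categories Number of categories (>= 20); every archetype is
#'   represented at least once.
#' @param seed Integer seed.
#' @param params Archetype parameter table, see [archetype_params()].
#' @return A [food_table()] carrying a `synthetic_meta` attribute
#'   (archetype and consumption parameters per code) used by
#'   [generate_intakes()].
#' @export
generate_food_db <- function(n_categories = 150, seed = 1,
                             params = archetype_params()) {
  if (n_categories < 20) stop_validation("n_categories must be >= 20")
  set.seed(seed)
  counts <- pmax(1L, floor(params$share * n_categories))
  # water-like categories are limited to the five real near-zero-energy
  # beverage codes, so phase-2 exclusions remove all of them as in the
  # real database; the remainder goes to the first (staple) archetype
  wi <- which(params$archetype == "water_like")
  if (length(wi) && counts[wi] > 5L) {
    counts[1L] <- counts[1L] + counts[wi] - 5L
    counts[wi] <- 5L
  }
  counts[1L] <- counts[1L] + (n_categories - sum(counts))
  if (counts[1L] < 1L)
    stop_validation("n_categories too small for the archetype shares")
  rows <- list()
  meta <- list()
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    k <- counts[i]
    codes <- .ARCHETYPE_CODES[[p$archetype]](k)
    nut <- sapply(.NUTRIENTS, function(nm)
      draw_range(k, p[[paste0(nm, "_lo")]], p[[paste0(nm, "_hi")]]))
    nut <- matrix(nut, nrow = k, dimnames = list(NULL, .NUTRIENTS))
    df <- data.frame(code = codes,
                     name = sprintf("%s %02d", gsub("_", " ", p$archetype),
                                    seq_len(k)),
                     stringsAsFactors = FALSE)
    for (nm in .NUTRIENTS) df[[.NUTRIENT_COLS[[nm]]]] <- nut[, nm]
    df$cost_usd_per_100g <- draw_range(k, p$cost_lo, p$cost_hi)
    df$racc_g <- stats::runif(k, p$racc_lo, p$racc_hi)
    df$is_beverage <- p$is_beverage
    rows[[i]] <- df
    meta[[i]] <- data.frame(code = codes, archetype = p$archetype,
                            consume_prob = p$consume_prob,
                            amount_meanlog = p$amount_meanlog,
                            amount_sdlog = p$amount_sdlog,
                            stringsAsFactors = FALSE)
  }
  out <- food_table(do.call(rbind, rows))
  attr(out, "synthetic_meta") <- do.call(rbind, meta)
  out
}

#' Generate synthetic single-day intake samples
#'
#' Per category, consumption is zero-inflated: each person consumes it with
#' the archetype's probability, and consumed amounts are log-normal --
#' mimicking the sparsity of single-day 24-h recall data. Survey weights
#' are positive and dispersed (log-normal, sd 0.5). Deterministic given
#' `seed`.
#'
#' @param foods A food table from [generate_food_db()] (its
#'   `synthetic_meta` attribute supplies consumption parameters; tables
#'   from other sources fall back to a generic profile).
#' @param n_persons Number of persons (>= 10).
#' @param seed Integer seed.
#' @return An [intake_table()].
#' @export
generate_intakes <- function(foods, n_persons = 2000, seed = 1) {
  if (n_persons < 10) stop_validation("n_persons must be >= 10")
  meta <- attr(foods, "synthetic_meta")
  foods <- food_table(foods)
  if (is.null(meta)) {
    meta <- data.frame(code = foods$code, archetype = "generic",
                       consume_prob = 0.3,
                       amount_meanlog = log(pmax(foods$racc_g, 1) * 1.5),
                       amount_sdlog = 0.6, stringsAsFactors = FALSE)
  }
  set.seed(seed)
  persons <- sprintf("p%05d", seq_len(n_persons))
  weights <- stats::rlnorm(n_persons, meanlog = 0, sdlog = 0.5)
  recs <- list()
  for (i in seq_len(nrow(meta))) {
    eats <- stats::runif(n_persons) < meta$consume_prob[i]
    ne <- sum(eats)
    if (!ne) next
    recs[[length(recs) + 1L]] <- data.frame(
      person_id = persons[eats],
      sample_weight = weights[eats],
      code = meta$code[i],
      grams = stats::rlnorm(ne, meta$amount_meanlog[i], meta$amount_sdlog[i]),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  # persons who consumed nothing still appear (zero-gram anchor record)
  missing_p <- setdiff(persons, df$person_id)
  if (length(missing_p)) {
    df <- rbind(df, data.frame(
      person_id = missing_p,
      sample_weight = weights[match(missing_p, persons)],
      code = meta$code[1L], grams = 0, stringsAsFactors = FALSE))
  }
  df <- df[order(df$person_id, df$code), ]
  intake_table(df)
}

#' Construct an LP instance with a planted, verified optimum
#'
#' Builds a small nutrient-replacement instance whose unique optimum is
#' known by construction: a vertex is chosen (a subset of foods active, the
#' requested nutrients binding), targets are set from the vertex, and costs
#' are priced through strictly positive duals on the binding rows plus a
#' strict reduced-cost margin on inactive foods, which makes that vertex the
#' unique minimiser. The instance is verified against
#' [brute_force_oracle()] before being returned.
#'
#' @param n_foods Number of foods (2..6).
#' @param binding Character vector of nutrients (subset of
#'   [constrained_nutrients()], at most `n_foods` of them) designed to bind.
#' @param seed Integer seed.
#' @param max_tries Construction retries before giving up.
#' @return List with `foods` (a [food_table()]), `target` (a
#'   [dairy_reference()]), `x_opt` (planted grams, named by code),
#'   `objective_value`, and `binding`.
#' @export
planted_optimum_instance <- function(n_foods, binding = c("calcium", "vit_d"),
                                     seed = 1, max_tries = 20L) {
  if (n_foods < 2 || n_foods > 6)
    stop_validation("n_foods must be in 2..6")
  binding <- unique(as.character(binding))
  if (!length(binding) || !all(binding %in% .CONSTRAINED))
    stop_validation("binding must be a non-empty subset of constrained nutrients")
  k <- length(binding)
  if (k > n_foods)
    stop_validation("cannot bind more nutrients than foods")
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    # per-gram nutrient densities, strictly positive everywhere
    A <- matrix(stats::runif(11 * n_foods, 0.02, 0.2), 11, n_foods,
                dimnames = list(.CONSTRAINED, NULL))
    # binding rows x active foods: diagonally dominant, well conditioned
    M <- matrix(stats::runif(k * k, 0, 0.05), k, k) +
      diag(stats::runif(k, 0.5, 1), k)
    A[binding, seq_len(k)] <- M
    x_act <- stats::runif(k, 50, 300)
    b <- numeric(11); names(b) <- .CONSTRAINED
    b[binding] <- as.vector(M %*% x_act)
    delivered <- as.vector(A[, seq_len(k), drop = FALSE] %*% x_act)
    names(delivered) <- .CONSTRAINED
    nonbind <- setdiff(.CONSTRAINED, binding)
    b[nonbind] <- delivered[nonbind] * stats::runif(length(nonbind), 0.3, 0.7)
    # price through duals: c_active = A_B' y; inactive get a strict margin
    y <- stats::runif(k, 0.5, 2)
    cvec <- as.vector(t(A[binding, , drop = FALSE]) %*% y)
    if (n_foods > k) {
      idx <- (k + 1):n_foods
      cvec[idx] <- cvec[idx] * (1 + stats::runif(length(idx), 0.1, 0.5))
    }
    codes <- as.character(5000 + 2 * seq_len(n_foods))
    df <- data.frame(code = codes,
                     name = sprintf("planted food %d", seq_len(n_foods)),
                     stringsAsFactors = FALSE)
    for (nm in .CONSTRAINED) df[[.NUTRIENT_COLS[[nm]]]] <- A[nm, ] * 100
    df$energy_kj <- stats::runif(n_foods, 400, 900)
    df$sodium_mg <- stats::runif(n_foods, 50, 300)
    df$added_sugars_g <- 0
    df$sat_fat_g <- stats::runif(n_foods, 0, 2)
    df$cost_usd_per_100g <- cvec * 100
    df$racc_g <- 100
    df$is_beverage <- FALSE
    foods <- food_table(df)
    target <- dairy_reference(
      nutrient_vector(c(b, energy = 435, sodium = 0, added_sugars = 0,
                        sat_fat = 0)),
      cost_per_serving = 0.41, weight_per_serving = 153.65)
    spec <- build_lp(foods, target, objective = "cost")
    x_opt <- stats::setNames(c(x_act, rep(0, n_foods - k)), codes)
    planted_val <- sum(cvec * x_opt)
    oracle <- brute_force_oracle(spec)
    ok <- oracle$status == "optimal" &&
      abs(oracle$value - planted_val) <= 1e-7 * (1 + abs(planted_val)) &&
      max(abs(oracle$x - x_opt)) <= 1e-6 * (1 + max(x_opt))
    if (ok) {
      return(list(foods = foods, target = target, x_opt = x_opt,
                  objective_value = planted_val, binding = binding))
    }
  }
  stop_generation(sprintf(
    "could not construct a verified planted instance in %d tries", max_tries))
}

#' Dairy-reference fixture profiles
#'
#' Component per-serving profiles for fat-free milk (1 cup, 245 g), low-fat
#' cheese (42 g cup-equivalent) and low-fat yogurt (1 cup, 245 g) whose
#' 0.53/0.45/0.02 composite has energy 435 kJ, cost US$0.41 and sodium
#' 133 mg per cup-equivalent serving. Those three composite values are the
#' ones recoverable from published worked examples; every other field is a
#' plausible USDA-style stand-in, clearly a fixture, and fully replaceable
#' via [dairy_reference()] when real targets are available (the cheese
#' energy, cost and sodium are derived in code so the composite is exact).
#'
#' @return List with `milk`, `cheese`, `yogurt` ([dairy_component()]s) and
#'   `reference` (their [build_dairy_reference()] composite).
#' @export
#' @examples
#' fx <- dairy_fixture()
#' unclass(fx$reference$per_serving)[["energy"]]  # 435
dairy_fixture <- function() {
  w <- c(0.53, 0.45, 0.02)
  milk <- dairy_component(
    nutrient_vector(protein = 8.3, calcium = 300, choline = 38, fibre = 0,
                    iron = 0.07, magnesium = 27, potassium = 380,
                    vit_a = 149, vit_c = 0, vit_d = 2.9, vit_e = 0.03,
                    energy = 347, sodium = 103, added_sugars = 0,
                    sat_fat = 0.1),
    cost_per_serving = 0.25, weight_per_serving = 245)
  yogurt <- dairy_component(
    nutrient_vector(protein = 8.9, calcium = 320, choline = 37, fibre = 0,
                    iron = 0.2, magnesium = 40, potassium = 465,
                    vit_a = 60, vit_c = 1, vit_d = 1.2, vit_e = 0.05,
                    energy = 650, sodium = 140, added_sugars = 0,
                    sat_fat = 1.5),
    cost_per_serving = 0.30, weight_per_serving = 245)
  # cheese energy/cost/sodium derived so the composite hits 435 kJ,
  # US$0.41 and 133 mg exactly
  cheese <- dairy_component(
    nutrient_vector(protein = 10.3, calcium = 350, choline = 7, fibre = 0,
                    iron = 0.2, magnesium = 12, potassium = 40,
                    vit_a = 60, vit_c = 0, vit_d = 0.2, vit_e = 0.08,
                    energy = (435 - w[1] * 347 - w[3] * 650) / w[2],
                    sodium = (133 - w[1] * 103 - w[3] * 140) / w[2],
                    added_sugars = 0, sat_fat = 2.5),
    cost_per_serving = (0.41 - w[1] * 0.25 - w[3] * 0.30) / w[2],
    weight_per_serving = 42)
  list(milk = milk, cheese = cheese, yogurt = yogurt,
       reference = build_dairy_reference(milk, cheese, yogurt, weights = w))
}
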