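# Translate per-serving optimisation results into reported quantities:
# daily scaling (1.8 current / 3.0 recommended dairy servings), RACC
# servings, ratios versus the dairy reference, nutrients-to-limit summaries
# and nutrient-matched profile comparisons.

#' Scale a per-serving result to daily dairy servings
#'
#' Results are computed per one cup-equivalent of dairy; daily implications
#' follow by multiplying by the servings multiplier `s` -- 1.8 for the
#' current US average intake (ages 2+) or 3.0 for the recommended servings
#' (ages 9+). Scaling is exact because the LP is homogeneous in its targets.
#'
#' @param result An optimal `lp_result`.
#' @param s Servings multiplier (> 0).
#' @param racc_g Optional named vector of RACC grams by category code (e.g.
#'   `setNames(foods$racc_g, foods$code)`) to also report approximate
#'   servings per category.
#' @return A `scaled_report`: `s`, `daily_cost_usd`, `daily_energy_kj`,
#'   `daily_weight_g`, `grams_by_category`, and `racc_servings` when RACC
#'   grams are supplied.
#' @export
#' @examples
#' # the paper-style arithmetic: 1.42 US$/serving at 1.8 servings/d
#' r <- structure(list(status = "optimal",
#'                     totals = c(cost = 1.42, energy = 2184, weight = 86),
#'                     grams = c("5502" = 86)), class = "lp_result")
#' scale_to_servings(r, 1.8)$daily_cost_usd  # 2.556
scale_to_servings <- function(result, s, racc_g = NULL) {
  stopifnot(inherits(result, "lp_result"))
  if (result$status != "optimal")
    stop_state("scale_to_servings requires an optimal result")
  if (!is.finite(s) || s <= 0) stop_validation("s must be > 0")
  grams <- result$grams * s
  out <- list(s = s,
              daily_cost_usd = unname(result$totals["cost"]) * s,
              daily_energy_kj = unname(result$totals["energy"]) * s,
              daily_weight_g = unname(result$totals["weight"]) * s,
              grams_by_category = grams)
  if (!is.null(racc_g)) {
    sel <- grams[grams > 0]
    rg <- racc_g[names(sel)]
    out$racc_servings <- round(sel / rg, 1)
  }
  structure(out, class = "scaled_report")
}

#' @export
print.scaled_report <- function(x, ...) {
  cat(sprintf("<scaled_report> s = %.2g: %.2f US$/d, %.0f kJ/d, %.0f g/d\n",
              x$s, x$daily_cost_usd, x$daily_energy_kj, x$daily_weight_g))
  invisible(x)
}

#' Convert grams to approximate RACC servings
#'
#' Divides consumed grams by the category's Reference Amount Customarily
#' Consumed (21 CFR 101.12) and rounds to one decimal, the convention for
#' reporting "approximate servings".
#'
#' @param grams Gram amount(s).
#' @param racc_g RACC serving size(s) in g (> 0).
#' @return Approximate servings, one decimal place.
#' @export
#' @examples
#' to_racc_servings(90, 55)  # 1.6
to_racc_servings <- function(grams, racc_g) {
  if (any(!is.finite(racc_g)) || any(racc_g <= 0))
    stop_validation("racc_g must be > 0")
  round(grams / racc_g, 1)
}

#' Cost, energy and weight ratios versus the dairy reference
#'
#' Plain ratios (combination / reference) and absolute excesses
#' (combination - reference) for cost, energy and weight. Prose such as
#' "x times more" is deliberately left to the caller: the report carries
#' only unambiguous quantities.
#'
#' @param result An optimal `lp_result`.
#' @param reference A [dairy_reference()] with positive cost, energy and
#'   weight.
#' @return List with `ratios` and `excesses`, each a named numeric
#'   (cost, energy, weight).
#' @export
ratios_vs_reference <- function(result, reference) {
  stopifnot(inherits(result, "lp_result"))
  if (result$status != "optimal")
    stop_state("ratios_vs_reference requires an optimal result")
  ref <- c(cost = reference$cost_per_serving,
           energy = unclass(reference$per_serving)[["energy"]],
           weight = reference$weight_per_serving)
  if (any(ref <= 0))
    stop_validation("reference cost, energy and weight must be > 0")
  combo <- result$totals[c("cost", "energy", "weight")]
  list(ratios = combo / ref, excesses = combo - ref)
}

#' Nutrients-to-limit summary
#'
#' Totals of the reported-only nutrients the dietary guidelines flag as
#' nutrients to limit -- sodium (< 2300 mg/d), added sugars and saturated
#' fat (each < 10 % of daily energy) -- with ratios versus the dairy
#' reference and, when a daily energy intake is supplied, guideline
#' threshold flags. Added sugars are also expressed in teaspoons
#' (4.2 g/tsp, the labelling convention).
#'
#' @param result An optimal `lp_result`.
#' @param reference A [dairy_reference()].
#' @param daily_energy_kj Optional total daily energy intake (kJ) for the
#'   percent-of-energy thresholds.
#' @return List with `amounts` (sodium mg, added_sugars g, added_sugars_tsp,
#'   sat_fat g), `ratios_vs_dairy`, and `flags` (NULL without
#'   `daily_energy_kj`).
#' @export
nutrients_to_limit_summary <- function(result, reference,
                                       daily_energy_kj = NULL) {
  stopifnot(inherits(result, "lp_result"))
  if (result$status != "optimal")
    stop_state("nutrients_to_limit_summary requires an optimal result")
  d <- result$delivered
  ref <- unclass(reference$per_serving)
  amounts <- c(sodium = unname(d["sodium"]),
               added_sugars = unname(d["added_sugars"]),
               added_sugars_tsp = unname(d["added_sugars"]) / .G_ADDED_SUGAR_PER_TSP,
               sat_fat = unname(d["sat_fat"]))
  ratio <- function(nm) {
    if (ref[[nm]] > 0) unname(d[nm]) / ref[[nm]] else NA_real_
  }
  ratios <- c(sodium = ratio("sodium"), added_sugars = ratio("added_sugars"),
              sat_fat = ratio("sat_fat"))
  flags <- NULL
  if (!is.null(daily_energy_kj)) {
    # guideline limits: Na < 2300 mg/d; added sugars, sat fat < 10 % energy
    # (energy density: 17 kJ/g carbohydrate, 37 kJ/g fat)
    flags <- c(
      sodium_over_2300mg = unname(d["sodium"]) > 2300,
      added_sugars_over_10pct = unname(d["added_sugars"]) * 17 >
        0.10 * daily_energy_kj,
      sat_fat_over_10pct = unname(d["sat_fat"]) * 37 > 0.10 * daily_energy_kj
    )
  }
  list(amounts = amounts, ratios_vs_dairy = ratios, flags = flags)
}

#' Nutrient-matched comparison with the dairy reference
#'
#' Rescales a food profile so its `match_on` nutrient equals the dairy
#' reference amount (the paper-style "Ca-matched" comparison for milk
#' substitutes), then reports percent differences per nutrient and, when a
#' cost is supplied, for cost. Invariant to positive rescaling of the input
#' profile.
#'
#' @param profile A `nutrient_vector` (any serving basis).
#' @param reference A [dairy_reference()].
#' @param match_on Nutrient to match (default `"calcium"`); the profile must
#'   have a positive amount of it.
#' @param cost_per_profile Optional cost of the profile as given, US$.
#' @return List with `scale` (applied multiplier), `percent_diff` (named,
#'   100 x (scaled - reference)/reference; NA where the reference amount is
#'   0) and `cost_percent_diff` when a cost was supplied.
#' @export
compare_to_reference <- function(profile, reference, match_on = "calcium",
                                 cost_per_profile = NULL) {
  profile <- as_nutrient_vector(profile)
  if (!match_on %in% .NUTRIENTS)
    stop_validation(sprintf("unknown nutrient: %s", match_on))
  p <- unclass(profile)
  ref <- unclass(reference$per_serving)
  if (p[[match_on]] <= 0)
    stop_validation(sprintf("profile %s must be > 0 to match on it", match_on))
  k <- ref[[match_on]] / p[[match_on]]
  scaled <- p * k
  pd <- ifelse(ref > 0, 100 * (scaled - ref) / ref, NA_real_)
  names(pd) <- names(ref)
  out <- list(scale = k, percent_diff = pd)
  if (!is.null(cost_per_profile)) {
    if (reference$cost_per_serving <= 0)
      stop_validation("reference cost must be > 0")
    out$cost_percent_diff <-
      100 * (cost_per_profile * k - reference$cost_per_serving) /
      reference$cost_per_serving
  }
  out
}

#' Wide report over a scenario grid
#'
#' One row per scenario with cost/energy/weight totals at servings
#' multipliers 1, 1.8 and 3.0, binding nutrients, and the selected foods
#' with their approximate RACC servings.
#'
#' @param grid A `scenario_grid` from [run_all()].
#' @param foods The [food_table()] used (for RACC grams and names).
#' @return A data.frame, one row per scenario label.
#' @export
grid_report <- function(grid, foods) {
  stopifnot(inherits(grid, "scenario_grid"))
  foods <- food_table(foods)
  racc <- stats::setNames(foods$racc_g, foods$code)
  rows <- lapply(names(grid$results), function(lb) {
    r <- grid$results[[lb]]
    if (!inherits(r, "lp_result") || r$status != "optimal") {
      return(data.frame(label = lb,
                        status = if (inherits(r, "lp_result")) r$status else "error",
                        cost_usd = NA_real_, energy_kj = NA_real_,
                        weight_g = NA_real_, cost_usd_1.8 = NA_real_,
                        energy_kj_1.8 = NA_real_, cost_usd_3.0 = NA_real_,
                        energy_kj_3.0 = NA_real_, binding = NA,
                        foods_selected = NA, stringsAsFactors = FALSE))
    }
    s18 <- scale_to_servings(r, 1.8)
    s30 <- scale_to_servings(r, 3.0)
    sel <- r$grams[r$grams > 1e-6]
    sel_txt <- paste(sprintf("%s:%.0fg(%.1f srv)", names(sel), sel,
                             to_racc_servings(sel, racc[names(sel)])),
                     collapse = "; ")
    data.frame(label = lb, status = r$status,
               cost_usd = unname(r$totals["cost"]),
               energy_kj = unname(r$totals["energy"]),
               weight_g = unname(r$totals["weight"]),
               cost_usd_1.8 = s18$daily_cost_usd,
               energy_kj_1.8 = s18$daily_energy_kj,
               cost_usd_3.0 = s30$daily_cost_usd,
               energy_kj_3.0 = s30$daily_energy_kj,
               binding = paste(r$binding, collapse = "+"),
               foods_selected = sel_txt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
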