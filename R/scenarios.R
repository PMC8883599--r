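# The analysis grid: 2 exclusion phases x 3 objectives x 2 cap settings.
# Phase 1 excludes only dairy (incl. cheese sandwiches); phase 2 additionally
# excludes categories that are not reasonable population-level dairy
# substitutes (baby foods, infant formula, nutrition powders/beverages) and
# near-zero-energy beverages (coffee, tap/bottled water, diet drinks).

.PHASE1_CODES <- c("1006", "1008", "1206", "1208", "1804", "1404",  # low-fat milk/yogurt
                   "1002", "1004", "1202", "1204", "1402", "1802",  # higher-fat milk/yogurt
                   "1602", "1604",                                  # cheese
                   "3720")                                          # cheese sandwiches
.PHASE2_EXTRA <- c("9002", "9004", "9006", "9008", "9010", "9012", "9202",  # baby foods
                   "9402", "9404",                                  # infant formulas
                   "9802",                                          # protein/nutritional powders
                   "7208",                                          # nutritional beverages
                   "7302", "7702", "7704", "7102", "7106")          # coffee, waters, diet drinks

#' Phase exclusion sets
#'
#' Phase 1 excludes the 15 dairy category codes (milk, yogurt, cheese and
#' cheese sandwiches); phase 2 additionally excludes the 16 codes judged
#' unreasonable as population-level dairy substitutes (baby foods, infant
#' formulas, protein/nutritional powders and beverages, coffee, tap and
#' bottled water, diet drinks). Phase 2 is a strict superset of phase 1.
#'
#' @param phase 1 or 2.
#' @return Character vector of excluded category codes.
#' @export
#' @examples
#' length(phase_exclusions(1))  # 15
#' setdiff(phase_exclusions(2), phase_exclusions(1))
phase_exclusions <- function(phase) {
  if (length(phase) != 1L || !phase %in% c(1, 2))
    stop_validation("phase must be 1 or 2")
  if (phase == 1) .PHASE1_CODES else c(.PHASE1_CODES, .PHASE2_EXTRA)
}

#' Define one optimisation scenario
#'
#' @param phase Exclusion phase, 1 or 2 (see [phase_exclusions()]).
#' @param objective `"cost"`, `"energy"` or `"weight"`.
#' @param cap_mode `"none"` (amounts unconstrained above) or `"p90"`
#'   (each category capped at the survey-weighted 90th percentile of
#'   current intake).
#' @return A `scenario_spec` with a deterministic `label`
#'   (`"phase<p>/<objective>/<cap_mode>"`).
#' @export
scenario_spec <- function(phase, objective = c("cost", "energy", "weight"),
                          cap_mode = c("none", "p90")) {
  objective <- match.arg(objective)
  cap_mode <- match.arg(cap_mode)
  exclusions <- phase_exclusions(phase)   # validates phase
  structure(list(phase = as.integer(phase), objective = objective,
                 cap_mode = cap_mode, exclusions = exclusions,
                 label = sprintf("phase%d/%s/%s", phase, objective, cap_mode)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s (%d exclusions)\n", x$label,
              length(x$exclusions)))
  invisible(x)
}

#' Run one optimisation scenario
#'
#' Computes p90 caps from the intake table if requested, builds the LP with
#' the phase's exclusion set and solves it.
#'
#' @param foods A [food_table()].
#' @param intakes An [intake_table()] (needed when `cap_mode = "p90"`).
#' @param target A [dairy_reference()].
#' @param spec A [scenario_spec()].
#' @param consumers_only Passed to [intake_caps()].
#' @return An `lp_result` with the scenario label attached (`$label`) and
#'   the caps table used (`$caps`, NULL when uncapped).
#' @export
run_scenario <- function(foods, intakes, target, spec, consumers_only = TRUE) {
  if (!inherits(spec, "scenario_spec"))
    stop_validation("spec must be a scenario_spec")
  caps <- NULL
  if (spec$cap_mode == "p90") {
    if (is.null(intakes))
      stop_validation(sprintf("[%s] cap_mode p90 requires an intake table",
                              spec$label))
    caps <- intake_caps(intakes, codes = foods$code,
                        consumers_only = consumers_only)
  }
  res <- tryCatch(
    solve_lp(build_lp(foods, target, objective = spec$objective,
                      caps = caps, exclusions = spec$exclusions)),
    dairylp_error = function(e) {
      stop(errorCondition(sprintf("[%s] %s", spec$label, conditionMessage(e)),
                          class = class(e)))
    })
  res$label <- spec$label
  res$caps <- caps
  res
}

#' Run the full 2 x 3 x 2 scenario grid
#'
#' All twelve combinations of phase (1, 2), objective (cost, energy, weight)
#' and cap mode (none, p90) in deterministic order. A scenario that errors
#' is recorded under its label and the run continues.
#'
#' @inheritParams run_scenario
#' @return A `scenario_grid`: named list of `lp_result` (or error condition)
#'   objects plus a `summary` data.frame (label, status, objective value,
#'   cost, energy, weight, binding nutrients).
#' @export
run_all <- function(foods, intakes, target, consumers_only = TRUE) {
  specs <- list()
  for (phase in 1:2)
    for (objective in c("cost", "energy", "weight"))
      for (cap_mode in c("none", "p90"))
        specs[[length(specs) + 1L]] <-
          scenario_spec(phase, objective, cap_mode)
  results <- lapply(specs, function(sp) {
    tryCatch(run_scenario(foods, intakes, target, sp,
                          consumers_only = consumers_only),
             dairylp_error = function(e) e)
  })
  names(results) <- vapply(specs, `[[`, "", "label")
  summary <- do.call(rbind, lapply(names(results), function(lb) {
    r <- results[[lb]]
    if (inherits(r, "lp_result") && r$status == "optimal") {
      data.frame(label = lb, status = r$status,
                 objective = r$spec_objective,
                 objective_value = r$objective_value,
                 cost_usd = unname(r$totals["cost"]),
                 energy_kj = unname(r$totals["energy"]),
                 weight_g = unname(r$totals["weight"]),
                 binding = paste(r$binding, collapse = "+"),
                 stringsAsFactors = FALSE)
    } else {
      status <- if (inherits(r, "lp_result")) r$status else "error"
      data.frame(label = lb, status = status, objective = NA,
                 objective_value = NA_real_, cost_usd = NA_real_,
                 energy_kj = NA_real_, weight_g = NA_real_, binding = NA,
                 stringsAsFactors = FALSE)
    }
  }))
  structure(list(results = results, summary = summary), class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("<scenario_grid> 2 phases x 3 objectives x 2 cap modes\n")
  print(x$summary, digits = 4)
  invisible(x)
}
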