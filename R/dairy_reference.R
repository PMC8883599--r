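# The constraint right-hand side: nutrient content, cost and weight of one
# USDA cup-equivalent serving of the dairy group, a weighted composite of
# fat-free milk, low-fat cheese and yogurt.

#' Describe one dairy component serving
#'
#' Bundles a per-serving [nutrient_vector()] with its cost (US$) and edible
#' weight (g), for use in [build_dairy_reference()].
#'
#' @param nutrients A `nutrient_vector` (amounts per serving).
#' @param cost_per_serving Cost of one serving, US$.
#' @param weight_per_serving Weight of one serving, g.
#' @return A `dairy_component` object.
#' @export
dairy_component <- function(nutrients, cost_per_serving, weight_per_serving) {
  nutrients <- as_nutrient_vector(nutrients)
  cost_per_serving <- as.numeric(cost_per_serving)
  weight_per_serving <- as.numeric(weight_per_serving)
  if (!is.finite(cost_per_serving) || cost_per_serving < 0)
    stop_validation("cost_per_serving must be finite and >= 0")
  if (!is.finite(weight_per_serving) || weight_per_serving <= 0)
    stop_validation("weight_per_serving must be finite and > 0")
  structure(list(nutrients = nutrients,
                 cost_per_serving = cost_per_serving,
                 weight_per_serving = weight_per_serving),
            class = "dairy_component")
}

#' Build the dairy-reference composite
#'
#' Combines milk, cheese and yogurt per-serving profiles with composite
#' weight fractions (default 53 % fat-free milk, 45 % low-fat cheese, 2 %
#' yogurt) into the per-cup-equivalent constraint targets: every nutrient,
#' the cost and the weight are the fraction-weighted sums of the components.
#'
#' @param milk,cheese,yogurt `dairy_component` objects.
#' @param weights Numeric length-3 composite fractions; must be in \[0, 1\]
#'   and sum to 1 within 1e-9.
#' @return A `dairy_reference`: list with `per_serving` (nutrient_vector),
#'   `cost_per_serving`, `weight_per_serving`, `composite_weights`.
#' @export
#' @examples
#' fx <- dairy_fixture()
#' build_dairy_reference(fx$milk, fx$cheese, fx$yogurt)
build_dairy_reference <- function(milk, cheese, yogurt,
                                  weights = c(0.53, 0.45, 0.02)) {
  comps <- list(milk, cheese, yogurt)
  if (!all(vapply(comps, inherits, logical(1), "dairy_component")))
    stop_validation("milk, cheese and yogurt must be dairy_component objects")
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(!is.finite(weights)) ||
      any(weights < 0) || any(weights > 1))
    stop_validation("weights must be 3 fractions in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-9)
    stop_validation(sprintf("composite weights must sum to 1 (got %.12g)",
                            sum(weights)))
  per <- Reduce(`+`, Map(function(cmp, w) w * unclass(cmp$nutrients),
                         comps, weights))
  dairy_reference(
    per_serving = nutrient_vector(per),
    cost_per_serving = sum(weights * vapply(comps, `[[`, 0, "cost_per_serving")),
    weight_per_serving = sum(weights * vapply(comps, `[[`, 0, "weight_per_serving")),
    composite_weights = weights
  )
}

#' Construct a dairy reference directly from per-serving targets
#'
#' @param per_serving `nutrient_vector` of per-cup-equivalent targets.
#' @param cost_per_serving,weight_per_serving Cost (US$) and weight (g) of
#'   one serving.
#' @param composite_weights Optional length-3 milk/cheese/yogurt fractions.
#' @return A `dairy_reference` object.
#' @export
dairy_reference <- function(per_serving, cost_per_serving, weight_per_serving,
                            composite_weights = c(0.53, 0.45, 0.02)) {
  per_serving <- as_nutrient_vector(per_serving)
  if (!is.finite(cost_per_serving) || cost_per_serving < 0)
    stop_validation("cost_per_serving must be finite and >= 0")
  if (!is.finite(weight_per_serving) || weight_per_serving <= 0)
    stop_validation("weight_per_serving must be finite and > 0")
  structure(list(per_serving = per_serving,
                 cost_per_serving = as.numeric(cost_per_serving),
                 weight_per_serving = as.numeric(weight_per_serving),
                 composite_weights = as.numeric(composite_weights)),
            class = "dairy_reference")
}

#' @export
print.dairy_reference <- function(x, ...) {
  cat(sprintf(
    "<dairy_reference> one cup-equivalent: %.3f US$, %.1f kJ, %.1f g\n",
    x$cost_per_serving, unclass(x$per_serving)[["energy"]],
    x$weight_per_serving))
  cat(sprintf("composite weights (milk/cheese/yogurt): %s\n",
              paste(format(x$composite_weights), collapse = "/")))
  invisible(x)
}

#' Read a dairy reference from a JSON config
#'
#' The config either gives the three component profiles plus composite
#' weights (keys `milk`, `cheese`, `yogurt`, `weights`, each component a map
#' with `nutrients`, `cost_per_serving`, `weight_per_serving`) or a direct
#' target (`per_serving`, `cost_per_serving`, `weight_per_serving`).
#'
#' @param path Path to a JSON file.
#' @return A `dairy_reference`.
#' @export
read_dairy_reference <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$per_serving)) {
    return(dairy_reference(nutrient_vector(unlist(cfg$per_serving)),
                           cfg$cost_per_serving, cfg$weight_per_serving))
  }
  comp <- function(x)
    dairy_component(nutrient_vector(unlist(x$nutrients)),
                    x$cost_per_serving, x$weight_per_serving)
  build_dairy_reference(comp(cfg$milk), comp(cfg$cheese), comp(cfg$yogurt),
                        weights = unlist(cfg$weights))
}
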