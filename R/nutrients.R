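#' @keywords internal
"_PACKAGE"


#' Nutrient name sets
#'
#' The analysis distinguishes 11 *constrained* nutrients -- protein plus the
#' ten shortfall nutrients (calcium, choline, fibre, iron, magnesium,
#' potassium, vitamins A, C, D and E) -- whose amounts in the optimised food
#' combination must meet or exceed the dairy-reference targets, from 4
#' *reported-only* quantities (energy, sodium, added sugars, saturated fat)
#' that are tracked but not constrained.
#'
#' @return Character vector of canonical nutrient names.
#' @export
#' @examples
#' constrained_nutrients()
nutrient_names <- function() .NUTRIENTS

#' @rdname nutrient_names
#' @export
constrained_nutrients <- function() .CONSTRAINED

#' @rdname nutrient_names
#' @export
reported_nutrients <- function() .REPORTED

#' @rdname nutrient_names
#' @export
nutrient_units <- function() .NUTRIENT_UNITS

#' Construct a nutrient vector
#'
#' A `nutrient_vector` is a named numeric vector over the 15 canonical
#' nutrients (see [nutrient_names()]) in fixed units: g for protein, fibre,
#' added sugars and saturated fat; mg for calcium, choline, iron, magnesium,
#' potassium, vitamin C, vitamin E and sodium; ug RAE for vitamin A; ug for
#' vitamin D; kJ for energy. Unspecified nutrients default to 0.
#'
#' @param ... Named nutrient amounts, or a single named numeric vector/list.
#' @return A `nutrient_vector` object.
#' @export
#' @examples
#' nutrient_vector(protein = 8.3, calcium = 300, vit_d = 2.9)
nutrient_vector <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    args <- as.list(args[[1]])
  bad <- setdiff(names(args), .NUTRIENTS)
  if (length(bad))
    stop_validation(sprintf("unknown nutrient name(s): %s",
                            paste(bad, collapse = ", ")))
  out <- stats::setNames(numeric(length(.NUTRIENTS)), .NUTRIENTS)
  out[names(args)] <- vapply(args, as.numeric, numeric(1))
  if (any(!is.finite(out)) || any(out < 0))
    stop_validation("nutrient amounts must be finite and >= 0")
  structure(out, class = "nutrient_vector")
}

#' @export
print.nutrient_vector <- function(x, ...) {
  cat("<nutrient_vector>\n")
  df <- data.frame(amount = unclass(x), unit = .NUTRIENT_UNITS[names(x)])
  print(df, ...)
  invisible(x)
}

as_nutrient_vector <- function(x) {
  if (inherits(x, "nutrient_vector")) return(x)
  nutrient_vector(x)
}

#' Energy unit conversion
#'
#' Energy is carried in kJ throughout; these helpers convert for display
#' (1 kcal = 4.184 kJ).
#'
#' @param x Energy value(s).
#' @return Converted numeric value(s).
#' @export
kcal_to_kj <- function(x) x * .KJ_PER_KCAL

#' @rdname kcal_to_kj
#' @export
kj_to_kcal <- function(x) x / .KJ_PER_KCAL

# ---- condition helpers -------------------------------------------------

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("dairylp_validation_error", "dairylp_error")))
}

stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("dairylp_schema_error", "dairylp_error")))
}

stop_integrity <- function(msg) {
  stop(errorCondition(msg, class = c("dairylp_integrity_error", "dairylp_error")))
}

stop_state <- function(msg) {
  stop(errorCondition(msg, class = c("dairylp_state_error", "dairylp_error")))
}

stop_size <- function(msg) {
  stop(errorCondition(msg, class = c("dairylp_size_error", "dairylp_error")))
}

stop_estimation <- function(msg) {
  stop(errorCondition(msg, class = c("dairylp_estimation_error", "dairylp_error")))
}

stop_generation <- function(msg) {
  stop(errorCondition(msg, class = c("dairylp_generation_error", "dairylp_error")))
}
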