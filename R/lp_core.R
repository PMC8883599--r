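# Build and solve the nutrient-replacement LP:
#   min sum_i c_i x_i
#   s.t. sum_i a_ij x_i >= b_j   for the 11 constrained nutrients j
#        0 <= x_i <= u_i,  x_i = 0 for excluded categories
# with x_i grams of category i, a_ij nutrient per gram, b_j the
# dairy-reference per-serving amount, c_i cost/g, energy kJ/g or 1 g/g.

#' Build a nutrient-replacement LP specification
#'
#' @param foods A [food_table()].
#' @param target A [dairy_reference()]; its `per_serving` constrained-nutrient
#'   amounts are the right-hand side.
#' @param objective One of `"cost"` (US$/g), `"energy"` (kJ/g) or
#'   `"weight"` (coefficient 1 per g).
#' @param caps Optional caps table (`code`, `p90_g`), e.g. from
#'   [intake_caps()]; capped categories get `u_i = p90_g`, others are
#'   unbounded above. `NA` caps mean unbounded.
#' @param exclusions Character vector of category codes fixed to zero grams
#'   (e.g. [phase_exclusions()]).
#' @return An `lp_spec` object.
#' @export
build_lp <- function(foods, target,
                     objective = c("cost", "energy", "weight"),
                     caps = NULL, exclusions = character()) {
  foods <- food_table(foods)
  if (!inherits(target, "dairy_reference"))
    stop_validation("target must be a dairy_reference")
  objective <- match.arg(objective)
  exclusions <- as.character(exclusions)
  excluded <- foods$code %in% exclusions
  if (all(excluded))
    stop(errorCondition("all food categories are excluded",
                        class = c("dairylp_spec_error", "dairylp_error")))

  per_g <- t(food_nutrients_per_g(foods))           # 15 x n
  A <- per_g[.CONSTRAINED, , drop = FALSE]          # 11 x n
  b <- unclass(target$per_serving)[.CONSTRAINED]
  cost_g <- foods$cost_usd_per_100g / 100
  energy_g <- per_g["energy", ]
  obj <- switch(objective,
                cost = cost_g,
                energy = unname(energy_g),
                weight = rep(1, nrow(foods)))

  upper <- rep(Inf, nrow(foods))
  if (!is.null(caps)) {
    caps <- as.data.frame(caps)
    if (!all(c("code", "p90_g") %in% names(caps)))
      stop_schema("caps table needs columns code, p90_g")
    idx <- match(as.character(caps$code), foods$code)
    ok <- !is.na(idx) & !is.na(caps$p90_g)
    upper[idx[ok]] <- caps$p90_g[ok]
  }

  structure(list(
    objective = objective,
    obj_coef = obj,                 # per gram
    A = A, b = b,
    upper = upper,
    excluded = excluded,
    codes = foods$code,
    names = foods$name,
    cost_per_g = cost_g,
    nutrients_per_g = per_g,        # all 15, per gram
    racc_g = foods$racc_g,
    target = target
  ), class = "lp_spec")
}

#' @export
print.lp_spec <- function(x, ...) {
  cat(sprintf(
    "<lp_spec> objective=%s, %d categories (%d excluded, %d capped), 11 nutrient constraints\n",
    x$objective, length(x$codes), sum(x$excluded),
    sum(is.finite(x$upper))))
  invisible(x)
}

#' Solve a nutrient-replacement LP
#'
#' Solves the LP with the package's two-phase simplex backend. Constraint
#' rows are scaled by their targets (`b_j` where positive) so the
#' feasibility tolerance is comparable across mg/ug/g nutrient units.
#'
#' @param spec An `lp_spec` from [build_lp()].
#' @param tol Relative feasibility tolerance on scaled constraints.
#' @return An `lp_result`: `grams` (named by category code, zero for
#'   excluded), `objective_value`, `totals` (cost US$, energy kJ, weight g),
#'   `delivered` (all 15 nutrients), `slack` (delivered minus target for the
#'   11 constrained nutrients), `binding` nutrients, `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`) and solver metadata.
#'   Infeasible results name the most-violated nutrient in
#'   `most_violated`.
#' @export
solve_lp <- function(spec, tol = 1e-9) {
  stopifnot(inherits(spec, "lp_spec"))
  keep <- !spec$excluded
  A <- spec$A[, keep, drop = FALSE]
  obj <- spec$obj_coef[keep]
  upper <- spec$upper[keep]
  b <- spec$b
  row_scale <- ifelse(b > 0, b, 1)
  sol <- simplex_lp(obj, A / row_scale, b / row_scale, upper, tol = tol)

  grams <- stats::setNames(numeric(length(spec$codes)), spec$codes)
  res <- list(status = sol$status, spec_objective = spec$objective,
              solver = list(backend = "two-phase simplex (Bland)",
                            iterations = sol$iter, tol = tol))
  if (sol$status == "infeasible") {
    res$most_violated <- .CONSTRAINED[which.max(sol$residual_rows)]
    res$grams <- grams
    res$objective_value <- NA_real_
    class(res) <- "lp_result"
    return(res)
  }
  if (sol$status == "unbounded") {
    res$zero_cost_columns <- spec$codes[keep][spec$obj_coef[keep] <= 0]
    res$grams <- grams
    res$objective_value <- -Inf
    class(res) <- "lp_result"
    return(res)
  }
  grams[keep] <- sol$x
  delivered <- as.vector(spec$nutrients_per_g %*% grams)
  names(delivered) <- rownames(spec$nutrients_per_g)
  slack <- delivered[.CONSTRAINED] - spec$b
  res$grams <- grams
  res$objective_value <- sol$value
  res$totals <- c(cost = sum(spec$cost_per_g * grams),
                  energy = unname(delivered["energy"]),
                  weight = sum(grams))
  res$delivered <- delivered
  res$slack <- slack
  res$target <- spec$b
  class(res) <- "lp_result"
  res$binding <- binding_nutrients(res)
  res
}

#' @export
print.lp_result <- function(x, ...) {
  cat(sprintf("<lp_result> status=%s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", objective (%s) = %.4g\n", x$spec_objective,
                x$objective_value))
    cat(sprintf("totals: %.3f US$, %.1f kJ, %.1f g; binding: %s\n",
                x$totals["cost"], x$totals["energy"], x$totals["weight"],
                paste(x$binding, collapse = ", ")))
    sel <- x$grams[x$grams > 1e-9]
    if (length(sel)) {
      cat("selected grams:\n")
      print(round(sel, 2))
    }
  } else if (x$status == "infeasible") {
    cat(sprintf(" (most violated: %s)\n", x$most_violated))
  } else cat("\n")
  invisible(x)
}

#' Binding (limiting) nutrients at an optimum
#'
#' A nutrient constraint is *binding* (the nutrient is *limiting*) when its
#' slack -- delivered amount minus target -- is zero at the optimum, i.e.
#' the food combination supplies exactly the dairy-reference amount. Slack
#' is compared on the target-scaled basis so a single tolerance works across
#' mg/ug/g units.
#'
#' @param result An optimal `lp_result`.
#' @param tol Absolute tolerance on target-scaled slack.
#' @return Character vector of binding nutrient names, ordered by slack
#'   (tightest first).
#' @export
binding_nutrients <- function(result, tol = 1e-6) {
  stopifnot(inherits(result, "lp_result"))
  if (result$status != "optimal")
    stop_state(sprintf("binding_nutrients requires an optimal result (status %s)",
                       result$status))
  scaled <- result$slack / pmax(result$target, 1e-12)
  scaled[result$target <= 0] <- Inf   # zero targets can never bind
  bind <- which(scaled <= tol)
  names(sort(scaled[bind]))
}

#' Brute-force LP oracle by vertex enumeration
#'
#' Independent correctness anchor for [solve_lp()]: enumerates every basic
#' solution (each choice of `n` active constraints among nutrient rows,
#' lower bounds and caps), keeps the feasible ones and returns the
#' minimum-objective vertex. Because all decision variables are bounded
#' below by 0 the feasible region is pointed, so a nonempty region has a
#' vertex and "no feasible vertex" is equivalent to infeasibility; with the
#' nonnegative objectives used here the optimum is always attained at a
#' vertex. Limited to 6 decision variables.
#'
#' @param spec An `lp_spec` with at most 6 non-excluded categories.
#' @param feas_tol Feasibility tolerance, relative to `1 + |rhs|`.
#' @return List with `status`, `x` (grams, named), `value`.
#' @export
brute_force_oracle <- function(spec, feas_tol = 1e-7) {
  stopifnot(inherits(spec, "lp_spec"))
  keep <- !spec$excluded
  n <- sum(keep)
  if (n > 6L)
    stop_size(sprintf("brute_force_oracle supports <= 6 variables (got %d)", n))
  A <- spec$A[, keep, drop = FALSE]
  b <- spec$b
  upper <- spec$upper[keep]
  obj <- spec$obj_coef[keep]
  row_scale <- ifelse(b > 0, b, 1)

  # constraint stack G x >= h
  G <- rbind(A / row_scale, diag(n))
  h <- c(b / row_scale, numeric(n))
  fin <- which(is.finite(upper))
  if (length(fin)) {
    Gu <- matrix(0, length(fin), n)
    Gu[cbind(seq_along(fin), fin)] <- -1
    G <- rbind(G, Gu)
    h <- c(h, -upper[fin])
  }
  m <- nrow(G)
  best <- NULL
  best_val <- Inf
  feasible_found <- FALSE
  for (sel in utils::combn(m, n, simplify = FALSE)) {
    M <- G[sel, , drop = FALSE]
    x <- tryCatch(solve(M, h[sel]), error = function(e) NULL)
    if (is.null(x) || any(!is.finite(x))) next
    if (any(G %*% x < h - feas_tol * (1 + abs(h)))) next
    feasible_found <- TRUE
    val <- sum(obj * x)
    if (is.null(best) || val < best_val - 1e-12 * (1 + abs(val))) {
      best_val <- val
      best <- x
    }
  }
  grams <- stats::setNames(numeric(length(spec$codes)), spec$codes)
  if (!feasible_found)
    return(list(status = "infeasible", x = grams, value = NA_real_))
  grams[keep] <- pmax(best, 0)
  list(status = "optimal", x = grams, value = best_val)
}

#' Serialise an optimisation result to structured text (JSON)
#'
#' @param result An `lp_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp_result <- function(result, path) {
  stopifnot(inherits(result, "lp_result"))
  out <- unclass(result)
  out$grams <- as.list(result$grams)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
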