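# Price attachment and adjustment: CPI inflation across survey cycles,
# mixed-dish cost estimation from food-pattern components, and explicit
# per-category price overrides (e.g. bottled water at US$0.25/l).

#' Consumer Price Index series for a 2-year survey cycle
#'
#' @param month Character or integer month labels.
#' @param index_value Positive CPI values, one per month.
#' @param cycle Optional cycle label (e.g. `"2001-2004"`).
#' @return A `cpi_series` object.
#' @export
cpi_series <- function(month, index_value, cycle = NULL) {
  index_value <- as.numeric(index_value)
  if (length(index_value) < 1L) stop_validation("CPI series must be non-empty")
  if (length(month) != length(index_value))
    stop_validation("month and index_value lengths differ")
  if (any(!is.finite(index_value)) || any(index_value <= 0))
    stop_validation("CPI index values must be finite and > 0")
  structure(list(month = as.character(month), index_value = index_value,
                 cycle = cycle), class = "cpi_series")
}

#' @rdname cpi_series
#' @param path Delimited text file with columns `month,index_value`.
#' @export
load_cpi_series <- function(path, cycle = NULL) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("month", "index_value") %in% names(df)))
    stop_schema("CPI file needs columns month, index_value")
  cpi_series(df$month, df$index_value, cycle = cycle)
}

#' Inflation-adjust a price between survey cycles
#'
#' Multiplies `price` by the ratio of the arithmetic-mean CPI of the target
#' cycle to that of the base cycle (the CPI is averaged over each 2-year
#' cycle's available months). Scale-equivariant in the CPI: rebasing both
#' series leaves the result unchanged.
#'
#' @param price Price(s) in US$ (vectorised).
#' @param base `cpi_series` for the cycle the price was observed in.
#' @param target `cpi_series` for the cycle to express the price in.
#' @return Adjusted price(s), US$.
#' @export
#' @examples
#' b <- cpi_series(1:12, rep(200, 12))
#' t <- cpi_series(1:12, rep(220, 12))
#' adjust_for_inflation(2, b, t)  # 2.20
adjust_for_inflation <- function(price, base, target) {
  if (!inherits(base, "cpi_series") || !inherits(target, "cpi_series"))
    stop_validation("base and target must be cpi_series objects")
  price * mean(target$index_value) / mean(base$index_value)
}

#' Estimate component unit costs for mixed dishes
#'
#' Mixed dishes prepared from multiple ingredients have no single market
#' price; their costs are decomposed by regressing observed dish costs on
#' the amounts of food-pattern components per 100 g of dish. Unit costs are
#' estimated by least squares with a nonnegativity constraint (unit costs
#' are physically nonnegative and a dish containing nothing should cost
#' about nothing), solved as a quadratic programme. An unconstrained and/or
#' intercept/weighted variant is available behind switches since the exact
#' historical regression form is not fixed by convention.
#'
#' @param components Matrix (dishes x components) of component amounts per
#'   100 g of dish; entries >= 0, no all-zero row, at least as many dishes
#'   as components and full column rank.
#' @param dish_costs Observed dish costs, US$ per 100 g.
#' @param nonnegative Constrain unit costs >= 0 (default TRUE).
#' @param intercept Include an (unconstrained) intercept (default FALSE).
#' @param weights Optional observation weights.
#' @return A `component_cost_fit`: `unit_costs` (named), `intercept`,
#'   `fitted`, `residuals`.
#' @export
estimate_component_costs <- function(components, dish_costs,
                                     nonnegative = TRUE, intercept = FALSE,
                                     weights = NULL) {
  X <- as.matrix(components)
  y <- as.numeric(dish_costs)
  if (nrow(X) != length(y))
    stop_validation("components rows and dish_costs lengths differ")
  if (any(X < 0)) stop_validation("component amounts must be >= 0")
  if (any(rowSums(X) == 0)) stop_validation("component matrix has an all-zero row")
  if (is.null(colnames(X))) colnames(X) <- paste0("component_", seq_len(ncol(X)))
  p0 <- ncol(X)
  if (nrow(X) < p0 + intercept)
    stop_estimation("need at least as many dishes as components")
  Xf <- if (intercept) cbind(`(intercept)` = 1, X) else X
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    dep <- colnames(Xf)[qrX$pivot[(qrX$rank + 1L):ncol(Xf)]]
    stop_estimation(sprintf("component matrix is rank deficient; dependent column(s): %s",
                            paste(dep, collapse = ", ")))
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  sw <- sqrt(weights)
  Xw <- Xf * sw
  yw <- y * sw
  if (nonnegative) {
    # NNLS as a QP: min 1/2 b'(X'X)b - (X'y)'b  s.t. b_j >= 0 (components only)
    D <- crossprod(Xw)
    d <- crossprod(Xw, yw)
    ncons <- p0
    Amat <- matrix(0, ncol(Xf), ncons)
    Amat[(ncol(Xf) - p0 + 1L):ncol(Xf), ] <- diag(p0)
    fit <- quadprog::solve.QP(D, d, Amat, bvec = numeric(ncons))
    beta <- fit$solution
  } else {
    beta <- qr.coef(qr(Xw), yw)
  }
  names(beta) <- colnames(Xf)
  fitted <- as.vector(Xf %*% beta)
  structure(list(
    unit_costs = beta[colnames(X)],
    intercept = if (intercept) unname(beta["(intercept)"]) else 0,
    fitted = fitted,
    residuals = y - fitted,
    nonnegative = nonnegative
  ), class = "component_cost_fit")
}

#' @export
print.component_cost_fit <- function(x, ...) {
  cat("<component_cost_fit> unit costs (US$ per component unit):\n")
  print(round(x$unit_costs, 4))
  cat(sprintf("residual RMS: %.4g\n", sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Predict costs for new dishes from a component fit
#'
#' @param object A `component_cost_fit`.
#' @param newdata Matrix of component amounts per 100 g of dish (columns in
#'   the fit's component order).
#' @param ... Unused.
#' @return Predicted dish costs, US$ per 100 g.
#' @export
predict.component_cost_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  as.vector(X %*% object$unit_costs) + object$intercept
}

#' Apply explicit price overrides to a food table
#'
#' Overrides are rules `code -> (price, basis)` where basis is `per_100g`
#' (price used as-is) or `per_litre` (converted to per 100 g assuming
#' beverage density 1 g/ml, so price/10). Used e.g. to set bottled water
#' (code 7704) at US$0.25/l, i.e. US$0.025 per 100 g.
#'
#' @param foods A [food_table()].
#' @param overrides data.frame with columns `code`, `price`, `basis`.
#' @return The food table with overridden `cost_usd_per_100g`.
#' @export
apply_price_overrides <- function(foods, overrides) {
  foods <- food_table(foods)
  overrides <- as.data.frame(overrides)
  if (nrow(overrides) == 0L) return(foods)
  if (!all(c("code", "price", "basis") %in% names(overrides)))
    stop_schema("overrides need columns code, price, basis")
  overrides$code <- as.character(overrides$code)
  unknown <- setdiff(overrides$code, foods$code)
  if (length(unknown))
    stop_validation(sprintf("override for unknown code(s): %s",
                            paste(unknown, collapse = ", ")))
  bad <- setdiff(overrides$basis, c("per_100g", "per_litre"))
  if (length(bad))
    stop_validation(sprintf("unknown price basis: %s", paste(bad, collapse = ", ")))
  price100 <- ifelse(overrides$basis == "per_litre",
                     overrides$price / 10, overrides$price)
  foods$cost_usd_per_100g[match(overrides$code, foods$code)] <- price100
  foods
}

#' @rdname apply_price_overrides
#' @param path Delimited text file `code,price,basis`.
#' @export
load_price_overrides <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  if (!all(c("code", "price", "basis") %in% names(df)))
    stop_schema("override file needs columns code, price, basis")
  df
}

#' Apply a food-code crosswalk
#'
#' Maps category codes between database vintages using a user-supplied
#' two-column mapping (`from`, `to`), applied before costing. Codes without
#' a mapping are left unchanged and reported in the `unmapped` attribute,
#' never silently dropped.
#'
#' @param codes Character vector of codes.
#' @param crosswalk data.frame with columns `from`, `to`.
#' @return Mapped codes, with attribute `unmapped` listing inputs that had
#'   no mapping.
#' @export
apply_code_crosswalk <- function(codes, crosswalk) {
  crosswalk <- as.data.frame(crosswalk)
  if (!all(c("from", "to") %in% names(crosswalk)))
    stop_schema("crosswalk needs columns from, to")
  codes <- as.character(codes)
  idx <- match(codes, as.character(crosswalk$from))
  out <- ifelse(is.na(idx), codes, as.character(crosswalk$to)[idx])
  attr(out, "unmapped") <- unique(codes[is.na(idx)])
  out
}
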