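# Food-category tables: one row per WWEIA-like category, nutrient columns on a
# per-100 g edible-portion basis, cost in US$ per 100 g, RACC serving in g.

.FOOD_COLS <- c("code", "name", unname(.NUTRIENT_COLS),
                "cost_usd_per_100g", "racc_g", "is_beverage")

#' Validate and classify a food-category table
#'
#' A food table holds one row per food category: a unique 4-digit `code`, a
#' `name`, the 15 nutrient columns per 100 g (see [nutrient_names()] for
#' units), `cost_usd_per_100g`, the RACC reference serving `racc_g` and an
#' `is_beverage` flag.
#'
#' @param df A data.frame with the documented columns.
#' @return The validated table with class `food_table`.
#' @export
food_table <- function(df) {
  if (!is.data.frame(df)) stop_schema("food table must be a data.frame")
  missing_cols <- setdiff(.FOOD_COLS, names(df))
  if (length(missing_cols))
    stop_schema(sprintf("food table is missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  df <- df[, .FOOD_COLS]
  df$code <- as.character(df$code)
  df$is_beverage <- as.logical(df$is_beverage)
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup))
    stop_integrity(sprintf("duplicate food category code(s): %s",
                           paste(dup, collapse = ", ")))
  num_cols <- c(unname(.NUTRIENT_COLS), "cost_usd_per_100g", "racc_g")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  neg <- which(apply(df[num_cols] < 0, 1L, any) |
                 apply(!is.finite(as.matrix(df[num_cols])), 1L, any))
  if (length(neg))
    stop_validation(sprintf(
      "negative or non-finite amount(s) in food table row(s): %s",
      paste(neg, collapse = ", ")))
  if (any(df$racc_g <= 0))
    stop_validation(sprintf("racc_g must be > 0 (row %s)",
                            paste(which(df$racc_g <= 0), collapse = ", ")))
  rownames(df) <- NULL
  class(df) <- c("food_table", "data.frame")
  df
}

#' Read / write food-category tables
#'
#' Plain delimited text (CSV) with a header row matching the documented
#' schema; nutrient columns are per 100 g.
#'
#' @param path File path.
#' @param x A `food_table`.
#' @return `load_food_table` returns a validated `food_table`;
#'   `write_food_table` returns `path` invisibly.
#' @export
load_food_table <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(code = "character"))
  food_table(df)
}

#' @rdname load_food_table
#' @export
write_food_table <- function(x, path) {
  x <- food_table(x)
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.food_table <- function(x, ...) {
  cat(sprintf("<food_table> %d categories (%d beverages)\n",
              nrow(x), sum(x$is_beverage)))
  NextMethod()
}

# nutrient matrix per gram: categories x 15 nutrients
food_nutrients_per_g <- function(foods, nutrients = .NUTRIENTS) {
  m <- as.matrix(foods[, .NUTRIENT_COLS[nutrients], drop = FALSE]) / 100
  dimnames(m) <- list(foods$code, nutrients)
  m
}
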