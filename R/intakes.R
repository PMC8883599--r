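# Day-1 24-h recall intakes in long format: one row per (person, category)
# actually consumed; categories not listed are implicit zeros. sample_weight
# is the dietary day-1 survey weight. Optional strata/psu columns are accepted
# and carried along for documentation, but variance estimation is out of
# scope here.

.INTAKE_COLS <- c("person_id", "sample_weight", "code", "grams")

#' Validate an intake table
#'
#' Long-format single-day recall data: columns `person_id`, `sample_weight`
#' (positive survey weight, constant within person), `code` (food category)
#' and `grams` consumed. A person's categories not present are zeros.
#'
#' @param df A data.frame with the documented columns.
#' @return The validated table with class `intake_table`.
#' @export
intake_table <- function(df) {
  if (!is.data.frame(df)) stop_schema("intake table must be a data.frame")
  missing_cols <- setdiff(.INTAKE_COLS, names(df))
  if (length(missing_cols))
    stop_schema(sprintf("intake table is missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  extra <- intersect(c("strata", "psu"), names(df))
  df <- df[, c(.INTAKE_COLS, extra)]
  df$person_id <- as.character(df$person_id)
  df$code <- as.character(df$code)
  df$sample_weight <- as.numeric(df$sample_weight)
  df$grams <- as.numeric(df$grams)
  if (any(!is.finite(df$sample_weight)) || any(df$sample_weight <= 0))
    stop_validation("sample_weight must be finite and > 0")
  if (any(!is.finite(df$grams)) || any(df$grams < 0))
    stop_validation("grams must be finite and >= 0")
  w <- tapply(df$sample_weight, df$person_id, function(v) length(unique(v)))
  if (any(w > 1L))
    stop_integrity(sprintf(
      "sample_weight differs within person(s): %s",
      paste(names(w)[w > 1L], collapse = ", ")))
  rownames(df) <- NULL
  class(df) <- c("intake_table", "data.frame")
  df
}

#' Read / write intake tables
#'
#' @param path File path to delimited text (CSV) in the long intake schema.
#' @param x An `intake_table`.
#' @return `load_intake_table` returns a validated `intake_table`;
#'   `write_intake_table` returns `path` invisibly.
#' @export
load_intake_table <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character",
                                       code = "character"))
  intake_table(df)
}

#' @rdname load_intake_table
#' @export
write_intake_table <- function(x, path) {
  x <- intake_table(x)
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.intake_table <- function(x, ...) {
  cat(sprintf("<intake_table> %d persons, %d consumption records, %d categories\n",
              length(unique(x$person_id)), nrow(x), length(unique(x$code))))
  invisible(x)
}

# per-person view for one category: grams (0 for non-consumers) and weights
person_grams <- function(intakes, code) {
  first <- !duplicated(intakes$person_id)
  persons <- intakes$person_id[first]
  weights <- intakes$sample_weight[first]
  grams <- stats::setNames(numeric(length(persons)), persons)
  sel <- intakes$code == code
  if (any(sel)) {
    g <- tapply(intakes$grams[sel], intakes$person_id[sel], sum)
    grams[names(g)] <- g
  }
  list(persons = persons, grams = unname(grams), weights = weights)
}
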