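# Survey-weighted consumption summaries: the per-category 90th-percentile
# intake caps used to keep optimised amounts within observed eating habits.

#' Weighted quantile (left-continuous ECDF inverse)
#'
#' Returns the smallest observed value whose cumulative normalised weight
#' reaches `q`: the left-continuous inverse of the weighted empirical
#' distribution. No interpolation is done, so the result is always an
#' observed value -- an intake cap derived from it is an amount someone
#' actually consumed.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @param q Quantile fraction(s) in (0, 1].
#' @return Numeric vector, one quantile per element of `q`.
#' @export
#' @examples
#' weighted_quantile(1:10, rep(1, 10), 0.9)  # 9
weighted_quantile <- function(values, weights, q) {
  if (length(values) == 0L) stop_validation("empty values")
  if (length(weights) != length(values))
    stop_validation("values and weights must have equal length")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop_validation("weights must be finite and > 0")
  if (any(q <= 0 | q > 1)) stop_validation("q must be in (0, 1]")
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord]) / sum(weights)
  vapply(q, function(qi) v[which(cw >= qi - 1e-12)[1L]], numeric(1))
}

#' Per-category 90th-percentile intake cap
#'
#' Computes the survey-weighted 90th percentile of single-day consumed grams
#' for one food category. By default the percentile is taken among
#' *consumers* of the category (persons with positive grams): an all-persons
#' percentile would cap rarely consumed categories at 0 g and remove them
#' from the optimisation entirely. Set `consumers_only = FALSE` for the
#' all-persons definition.
#'
#' @param intakes An [intake_table()].
#' @param code Food category code.
#' @param consumers_only Restrict to persons with grams > 0 (default TRUE).
#' @param q Quantile fraction (default 0.9).
#' @return The gram cap, or `NA` (explicit "no cap") if `consumers_only` and
#'   nobody consumed the category.
#' @export
intake_p90 <- function(intakes, code, consumers_only = TRUE, q = 0.9) {
  intakes <- intake_table(intakes)
  code <- as.character(code)
  if (!code %in% intakes$code)
    stop_validation(sprintf("unknown food category code: %s", code))
  pg <- person_grams(intakes, code)
  g <- pg$grams; w <- pg$weights
  if (consumers_only) {
    sel <- g > 0
    if (!any(sel)) return(NA_real_)
    g <- g[sel]; w <- w[sel]
  }
  weighted_quantile(g, w, q)
}

#' Caps table for a set of categories
#'
#' @param intakes An [intake_table()].
#' @param codes Category codes to cap; defaults to all codes present in the
#'   intake table.
#' @param consumers_only See [intake_p90()].
#' @param q Quantile fraction.
#' @return data.frame `code`, `p90_g`, `n_consumers`. Categories in `codes`
#'   that nobody consumed get `p90_g = NA` (no cap) when `consumers_only`.
#' @export
intake_caps <- function(intakes, codes = NULL, consumers_only = TRUE, q = 0.9) {
  intakes <- intake_table(intakes)
  if (is.null(codes)) codes <- sort(unique(intakes$code))
  codes <- as.character(codes)
  known <- codes %in% intakes$code
  cap <- rep(NA_real_, length(codes))
  ncons <- integer(length(codes))
  for (i in which(known)) {
    pg <- person_grams(intakes, codes[i])
    ncons[i] <- sum(pg$grams > 0)
    cap[i] <- intake_p90(intakes, codes[i], consumers_only = consumers_only,
                         q = q)
  }
  data.frame(code = codes, p90_g = cap, n_consumers = ncons,
             stringsAsFactors = FALSE)
}
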