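#' Extremal quotient
#'
#' Ratio of the highest to the lowest area rate.
#'
#' @param rates Numeric vector of area rates (>= 2 areas, minimum > 0).
#' @return `max(rates) / min(rates)`.
#' @export
#' @examples
#' extremal_quotient(c(41.7, 144.4))  # 3.46 -> prints as 3.5
extremal_quotient <- function(rates) {
  if (length(rates) < 2)
    psy_stop("extremal quotient needs at least 2 areas", "psyvar_input_error")
  if (min(rates) <= 0)
    psy_stop(paste0("extremal quotient undefined: minimum area rate is 0; ",
                    "consider the persons/prescriptions numerator mode or a ",
                    "drug class without empty areas"),
             "psyvar_input_error")
  max(rates) / min(rates)
}

#' Population-weighted coefficient of variation (percent)
#'
#' `100 * sqrt(sum(w * (r - rbar)^2) / sum(w)) / rbar` with the
#' population-weighted mean `rbar = sum(w * r) / sum(w)`.
#'
#' @param rates Numeric vector of area rates.
#' @param weights Positive area populations.
#' @return Weighted CV in percent.
#' @export
#' @examples
#' weighted_cv(c(50, 150), c(3, 1))  # 57.735
weighted_cv <- function(rates, weights) {
  if (length(rates) < 2 || length(rates) != length(weights))
    psy_stop("need >= 2 areas with matching weights", "psyvar_input_error")
  if (any(weights <= 0))
    psy_stop("weights must be positive", "psyvar_input_error")
  m <- sum(weights * rates) / sum(weights)
  if (m <= 0)
    psy_stop("weighted mean rate must be positive", "psyvar_input_error")
  100 * sqrt(sum(weights * (rates - m)^2) / sum(weights)) / m
}

#' Systematic component of variation
#'
#' McPherson-type SCV over areas' observed (`O`) and indirectly expected
#' (`E`) event counts:
#' `SCV = (100 / k) * sum(((O - E) / E)^2 - 1 / E)`.
#' The `1/E` term removes the Poisson (random) variance component, so the
#' statistic estimates the non-random, systematic relative variation; under
#' a pure Poisson null its expectation is 0, and under multiplicative
#' area-level mixing with log-variance `v` its expectation approaches
#' `100 * (exp(v) - 1)` as counts grow.
#'
#' @param O Observed counts per area.
#' @param E Expected counts per area (all > 0).
#' @return The SCV (same percent-like scale as published values).
#' @export
#' @examples
#' scv(c(120, 80), c(100, 100))  # 3.0
scv <- function(O, E) {
  if (length(O) != length(E) || length(O) < 2)
    psy_stop("O and E must have equal length >= 2", "psyvar_input_error")
  bad <- which(E <= 0)
  if (length(bad))
    psy_stop(paste0("non-positive expected count at area index ",
                    paste(bad, collapse = ", ")),
             "psyvar_input_error")
  k <- length(O)
  (100 / k) * sum(((O - E) / E)^2 - 1 / E)
}

#' Interpretation band for an SCV value
#'
#' Below 3.0 is "low"; 3.0 up to (but excluding) 5.5 is "moderate"; 5.5 to
#' 10 inclusive is "high"; above 10 is "very high".
#'
#' @param scv_value Finite numeric SCV.
#' @return One of `"low"`, `"moderate"`, `"high"`, `"very high"`.
#' @export
#' @examples
#' classify_scv(167.5)  # "very high"
classify_scv <- function(scv_value) {
  if (!is.finite(scv_value))
    psy_stop("SCV must be finite", "psyvar_input_error")
  if (scv_value < 3) "low"
  else if (scv_value < 5.5) "moderate"
  else if (scv_value <= 10) "high"
  else "very high"
}

#' Variation summary for a set of areas
#'
#' Bundles the extremal quotient (on standardized rates), the
#' population-weighted CV, the SCV and its interpretation band.
#'
#' @param rates Standardized area rates (per 1000).
#' @param weights Area populations.
#' @param O,E Observed and expected counts per area.
#' @return List of class `"psy_variation"`: `k`, `EQ`, `CV`, `SCV`, `band`.
#' @export
variation_summary <- function(rates, weights, O, E) {
  s <- scv(O, E)
  structure(list(k = length(rates),
                 EQ = extremal_quotient(rates),
                 CV = weighted_cv(rates, weights),
                 SCV = s,
                 band = classify_scv(s)),
            class = "psy_variation")
}

#' @export
print.psy_variation <- function(x, ...) {
  cat(sprintf("Small-area variation over k = %d areas\n", x$k))
  cat(sprintf("  EQ  = %.1f\n  CV  = %.1f%%\n  SCV = %.1f (%s variation)\n",
              x$EQ, x$CV, x$SCV, x$band))
  invisible(x)
}

#' Chi-square test of one division against the provincial rate
#'
#' One-sample proportion chi-square with 1 df, treating the provincial rate
#' as fixed: `X2 = (O - E)^2 / E + ((N - O) - (N - E))^2 / (N - E)`; the
#' p-value is the upper chi-square(1) tail. Vectorized over divisions.
#'
#' @param O Observed events per division.
#' @param E Expected events per division (provincial rate applied to the
#'   division population; must lie strictly between 0 and `N`).
#' @param N Division population at risk.
#' @param alpha Per-comparison significance threshold (e.g. the familywise
#'   level divided by the number of areas, rounded to one significant
#'   figure).
#' @param division_id Optional identifiers carried into the result.
#' @return Data frame: `division_id`, `statistic`, `p_value`, `alpha`,
#'   `direction` (`"above"`, `"below"`, `"none"`), `significant`.
#' @export
#' @examples
#' division_vs_province_test(130, 100, 1000, alpha = 0.001)
division_vs_province_test <- function(O, E, N, alpha = 0.001,
                                      division_id = NULL) {
  if (any(E <= 0) || any(E >= N))
    psy_stop("expected counts must lie strictly between 0 and N",
             "psyvar_input_error")
  if (any(O < 0) || any(O > N))
    psy_stop("observed counts must lie in [0, N]", "psyvar_input_error")
  stat <- (O - E)^2 / E + ((N - O) - (N - E))^2 / (N - E)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  sig <- p < alpha
  dirn <- ifelse(O > E, "above", ifelse(O < E, "below", "none"))
  if (is.null(division_id)) division_id <- seq_along(O)
  data.frame(division_id = division_id, statistic = stat, p_value = p,
             alpha = alpha, direction = dirn, significant = sig,
             stringsAsFactors = FALSE)
}

#' Per-comparison alpha from a familywise level
#'
#' Divides the familywise Type 1 error level by the number of comparisons
#' and rounds to one significant figure (the convention that turns 0.05/49
#' into 0.001).
#'
#' @param alpha_familywise Familywise level in (0, 1).
#' @param k Number of comparisons.
#' @return List with `raw` (`alpha_familywise / k`) and `rounded` (one
#'   significant figure).
#' @export
per_comparison_alpha <- function(alpha_familywise, k) {
  if (alpha_familywise <= 0 || alpha_familywise >= 1)
    psy_stop("alpha_familywise must be in (0, 1)", "psyvar_input_error")
  raw <- alpha_familywise / k
  list(raw = raw, rounded = round_1sf(raw))
}
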