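#' Standardized difference between two proportions
#'
#' `|p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`, the scale-free
#' effect size used in baseline-characteristics tables.
#'
#' @param p1,p2 Proportions in \[0, 1\] with positive pooled variance.
#' @return The standardized difference (full precision; round at the
#'   reporting layer).
#' @export
#' @examples
#' std_diff_proportions(0.153, 0.041)  # ~0.39
std_diff_proportions <- function(p1, p2) {
  pooled <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (any(pooled <= 0))
    psy_stop("standardized difference undefined: pooled variance is zero",
             "psyvar_undefined")
  abs(p1 - p2) / sqrt(pooled)
}

#' Standardized difference between two means
#'
#' Pooled-SD convention: `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param m1,s1 Mean and SD of group 1.
#' @param m2,s2 Mean and SD of group 2.
#' @return The standardized difference.
#' @export
#' @examples
#' std_diff_continuous(5, 2, 3, 2)  # 1
std_diff_continuous <- function(m1, s1, m2, s2) {
  pooled <- (s1^2 + s2^2) / 2
  if (any(pooled <= 0))
    psy_stop("standardized difference undefined: pooled SD is zero",
             "psyvar_undefined")
  abs(m1 - m2) / sqrt(pooled)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Rank correlation with mid-ranks for ties; the 95% CI uses the Fisher z
#' transform with standard error `1 / sqrt(n - 3)`, back-transformed.
#'
#' @param x,y Numeric vectors (n >= 4, finite, not constant).
#' @return List of class `"psy_correlation"`: `rho`, `n`, `ci95`.
#' @export
#' @examples
#' spearman_with_ci(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
spearman_with_ci <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    psy_stop("need paired vectors of length >= 4", "psyvar_input_error")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    psy_stop("inputs must be finite", "psyvar_input_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    psy_stop("correlation undefined for a constant vector", "psyvar_undefined")
  n <- length(x)
  rho <- cor(x, y, method = "spearman")
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  half <- 1.959964 / sqrt(n - 3)
  structure(list(rho = rho, n = n,
                 ci95 = c(lower = tanh(z - half), upper = tanh(z + half))),
            class = "psy_correlation")
}

#' @export
print.psy_correlation <- function(x, ...) {
  cat(sprintf("Spearman rho %.2f (95%% CI %.2f to %.2f), n = %d\n",
              x$rho, x$ci95["lower"], x$ci95["upper"], x$n))
  invisible(x)
}

#' Baseline characteristics with standardized differences
#'
#' Compares psychotropic recipients with the sampled non-recipients on age
#' (median/IQR plus a mean/SD-based standardized difference), age band,
#' sex, neighbourhood income quintile, rurality, and ADG comorbidity band.
#' Counts and percentages are unweighted within group, matching how a
#' design with a fixed 10% comparison sample is tabulated.
#'
#' @param persons Person table.
#' @return Data frame with `variable`, `level`, `recipients`,
#'   `non_recipients` (formatted summaries) and `std_difference`.
#' @export
baseline_table <- function(persons) {
  g1 <- persons[persons$any_psychotropic == 1, , drop = FALSE]
  g0 <- persons[persons$any_psychotropic == 0, , drop = FALSE]
  if (!nrow(g1) || !nrow(g0))
    psy_stop("both recipient and non-recipient groups must be non-empty",
             "psyvar_input_error")
  rows <- list()
  add <- function(variable, level, s1, s0, sd_val) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, recipients = s1,
      non_recipients = s0, std_difference = round(sd_val, 2),
      stringsAsFactors = FALSE)
  }
  med_iqr <- function(x) sprintf("%d (%d-%d)", round(median(x)),
                                 round(quantile(x, 0.25)), round(quantile(x, 0.75)))
  add("Age (years)", "median (IQR)", med_iqr(g1$age_years), med_iqr(g0$age_years),
      std_diff_continuous(mean(g1$age_years), sd(g1$age_years),
                          mean(g0$age_years), sd(g0$age_years)))
  cat_rows <- function(variable, col, levels) {
    for (lev in levels) {
      p1 <- mean(g1[[col]] == lev)
      p0 <- mean(g0[[col]] == lev)
      add(variable, as.character(lev),
          sprintf("%d (%.1f%%)", sum(g1[[col]] == lev), 100 * p1),
          sprintf("%d (%.1f%%)", sum(g0[[col]] == lev), 100 * p0),
          std_diff_proportions(p1, p0))
    }
  }
  cat_rows("Age band", "age_band", psy_age_bands())
  cat_rows("Sex", "sex", "female")
  cat_rows("Income quintile", "income_quintile", 1:5)
  cat_rows("Residence", "rurality", c("urban", "rural"))
  cat_rows("ADG category", "adg_band", psy_adg_bands())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Division-level correlations of dispensing with service density
#'
#' Spearman correlations (with Fisher-z CIs) between each division's
#' standardized all-psychotropic dispensing rate and the division-level
#' service covariates: specialist density, mental-health agency density,
#' and the mental-health hospitalization/ED visit rate.
#'
#' @param rates Output of [standardize_rates()].
#' @param divisions Division table.
#' @param covariates Division columns to correlate against.
#' @return Named list of [spearman_with_ci()] results.
#' @export
division_correlations <- function(rates, divisions,
                                  covariates = c("agency_density",
                                                 "mh_admission_ed_rate",
                                                 "specialist_density")) {
  r <- rates[rates$class == "all", , drop = FALSE]
  m <- match(r$division_id, divisions$division_id)
  if (anyNA(m))
    psy_stop("rates reference divisions absent from the divisions table",
             "psyvar_input_error")
  out <- lapply(covariates, function(v)
    spearman_with_ci(r$standardized_per_1000, divisions[[v]][m]))
  setNames(out, covariates)
}
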