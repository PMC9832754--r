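#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults describe the stated study world: 49 census
#' divisions whose 0-24 population spans roughly 3,500 to 738,000
#' (log-uniform), provincial baseline dispensing rates per 1000 youths of
#' 47.8 (antidepressants), 28.4 (stimulants), 13.5 (antipsychotics) and 9.7
#' (benzodiazepines), and a multiplicative log-normal division-level rate
#' effect whose default standard deviation (0.99 on the log scale) places
#' the systematic component of variation in the "very high" regime
#' (expected SCV near 167).
#'
#' `log_rate_ratios` holds per-class individual-level covariate effects on
#' the log-rate scale and defaults to [table2_log_rate_ratios()], the
#' natural logs of the published adjusted rate ratios (age band, sex,
#' rurality, income quintile, ADG band; the cross-class "other
#' psychotropic" effect is not generable and is excluded). Pass an empty
#' list for a no-covariate-effects world, or a partial named list to set
#' selected effects. Validation rejects any configuration whose
#' most-exposed covariate pattern implies a dispensing probability above 1
#' (before the division effect; generation clamps at 1 with a warning when
#' an extreme division effect pushes a pattern over).
#'
#' @param n_divisions Number of census divisions (areas).
#' @param division_population_range Length-2 integer vector, min and max
#'   youth (0-24) population per division; populations are drawn
#'   log-uniformly between them.
#' @param age_group_shares Named numeric of length 5 (names
#'   [psy_age_bands()]) summing to 1.
#' @param sex_share_female Probability a person is female.
#' @param income_quintile_shares Numeric of length 5 summing to 1.
#' @param rural_share Probability of rural residence.
#' @param adg_distribution List with `mu` and `size`: negative-binomial
#'   parameters for the ADG comorbidity count, truncated to 0-32.
#' @param baseline_rates_per_1000 Named positive numeric, one entry per
#'   class in [psy_classes()]: the reference-pattern one-year dispensing
#'   rate per 1000.
#' @param log_rate_ratios Named list, one element per drug class, each a
#'   named numeric of log rate ratios over covariate levels (see
#'   [table2_log_rate_ratios()] for the recognised term names).
#' @param division_effect_sd Standard deviation (log scale) of the
#'   division-level multiplicative rate effect `u_d`; the effect is drawn
#'   as `exp(Normal(-sd^2/2, sd))` so that `E[u_d] = 1`.
#' @param division_covariate_params Named list of distribution specs for the
#'   nine division-level covariates (see Details in the package vignette).
#' @param rx_per_recipient List with `mu` and `size`: recipients receive
#'   `1 + NegBin(mu - 1, size)` prescriptions in the year.
#' @param nonrecipient_sample_fraction Fraction of non-recipients retained
#'   (weighted up by its reciprocal); the study design value is 0.10.
#' @param seed Integer seed; identical (config, seed) pairs reproduce
#'   byte-identical tables.
#'
#' @return A validated list of class `"generator_config"`.
#' @export
#' @examples
#' cfg <- generator_config(n_divisions = 5,
#'                         division_population_range = c(500, 2000),
#'                         seed = 1)
#' cfg$baseline_rates_per_1000
generator_config <- function(n_divisions = 49L,
                             division_population_range = c(3500L, 738000L),
                             age_group_shares = c("0-4" = 0.19, "5-9" = 0.20,
                                                  "10-14" = 0.20, "15-19" = 0.20,
                                                  "20-24" = 0.21),
                             sex_share_female = 0.49,
                             income_quintile_shares = rep(0.2, 5),
                             rural_share = 0.10,
                             adg_distribution = list(mu = 4, size = 2),
                             baseline_rates_per_1000 = c(antidepressant = 47.8,
                                                         stimulant = 28.4,
                                                         antipsychotic = 13.5,
                                                         benzodiazepine = 9.7),
                             log_rate_ratios = NULL,
                             division_effect_sd = 0.99,
                             division_covariate_params = default_division_covariate_params(),
                             rx_per_recipient = list(mu = 3, size = 2),
                             nonrecipient_sample_fraction = 0.10,
                             seed = 1L) {
  if (is.null(log_rate_ratios)) log_rate_ratios <- table2_log_rate_ratios()
  cfg <- structure(list(
    n_divisions = as.integer(n_divisions),
    division_population_range = as.numeric(division_population_range),
    age_group_shares = age_group_shares,
    sex_share_female = sex_share_female,
    income_quintile_shares = income_quintile_shares,
    rural_share = rural_share,
    adg_distribution = adg_distribution,
    baseline_rates_per_1000 = baseline_rates_per_1000,
    log_rate_ratios = log_rate_ratios,
    division_effect_sd = division_effect_sd,
    division_covariate_params = division_covariate_params,
    rx_per_recipient = rx_per_recipient,
    nonrecipient_sample_fraction = nonrecipient_sample_fraction,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
}

## Covariate term names accepted in log_rate_ratios, with the factor level
## each represents (references: age 5-9, female, urban, income quintile 1,
## ADG 0-5).
generator_terms <- function() {
  c("age_0_4", "age_10_14", "age_15_19", "age_20_24",
    "male", "rural",
    "income_2", "income_3", "income_4", "income_5",
    "adg_6_9", "adg_10plus")
}

#' Published adjusted rate ratios as generator truth
#'
#' Returns, per drug class, the natural logs of the published adjusted rate
#' ratios for the individual-level covariates (age band, sex, rurality,
#' neighbourhood income quintile, ADG comorbidity band). These are intended
#' the default `log_rate_ratios` of [generator_config()]. The "other
#' psychotropic class" effect is deliberately absent — the generator draws
#' the four classes independently given covariates, so a cross-class effect
#' is not generable (and with it included, the most-exposed pattern would
#' exceed probability 1).
#'
#' @return Named list (one element per class) of named numerics of log rate
#'   ratios; names follow `generator_terms()`.
#' @export
#' @examples
#' lrr <- table2_log_rate_ratios()
#' exp(lrr$stimulant["male"])   # 1.75
table2_log_rate_ratios <- function() {
  rr <- list(
    antidepressant = c(age_0_4 = 0.02, age_10_14 = 4.56, age_15_19 = 8.73,
                       age_20_24 = 9.32, male = 0.81, rural = 0.95,
                       income_2 = 1.01, income_3 = 0.98, income_4 = 0.98,
                       income_5 = 0.97, adg_6_9 = 1.53, adg_10plus = 1.73),
    stimulant = c(age_0_4 = 0.04, age_10_14 = 1.11, age_15_19 = 0.81,
                  age_20_24 = 0.61, male = 1.75, rural = 0.91,
                  income_2 = 0.97, income_3 = 0.95, income_4 = 0.95,
                  income_5 = 1.00, adg_6_9 = 1.50, adg_10plus = 1.71),
    antipsychotic = c(age_0_4 = 0.14, age_10_14 = 1.25, age_15_19 = 1.53,
                      age_20_24 = 1.80, male = 1.40, rural = 0.90,
                      income_2 = 0.88, income_3 = 0.81, income_4 = 0.75,
                      income_5 = 0.72, adg_6_9 = 1.77, adg_10plus = 2.33),
    benzodiazepine = c(age_0_4 = 0.46, age_10_14 = 2.89, age_15_19 = 8.60,
                       age_20_24 = 12.37, male = 0.85, rural = 0.94,
                       income_2 = 1.01, income_3 = 0.98, income_4 = 1.00,
                       income_5 = 1.01, adg_6_9 = 1.82, adg_10plus = 2.61)
  )
  lapply(rr, log)
}

## Default distributions for the nine division-level covariates. Values are
## chosen once as plausible for Ontario census divisions; they are noise
## covariates (no generative effect on rates) unless a user wires them in.
default_division_covariate_params <- function() {
  list(
    specialist_density   = list(dist = "lognormal", meanlog = log(3),    sdlog = 0.6),
    agency_density       = list(dist = "lognormal", meanlog = log(0.15), sdlog = 0.5),
    mh_admission_ed_rate = list(dist = "lognormal", meanlog = log(15),   sdlog = 0.4),
    pct_postsecondary    = list(dist = "normal", mean = 55, sd = 8,  min = 0, max = 100),
    pct_visible_minority = list(dist = "lognormal", meanlog = log(8), sdlog = 0.8, max = 100),
    pct_noncitizen       = list(dist = "lognormal", meanlog = log(4), sdlog = 0.7, max = 100),
    pct_employed         = list(dist = "normal", mean = 60, sd = 5, min = 0, max = 100),
    pct_neither_language = list(dist = "lognormal", meanlog = log(1.2), sdlog = 0.7, max = 100),
    mean_household_size  = list(dist = "normal", mean = 2.6, sd = 0.2, min = 1)
  )
}

#' Validate a generator configuration
#'
#' Checks structural invariants (probability vectors sum to 1 within 1e-9,
#' strictly positive baselines, non-negative division effect SD) and the
#' probability budget: for each drug class, the dispensing probability
#' implied by the most-exposed covariate pattern (division effect at its
#' mean of 1) must not exceed 1. Violations are reported with the offending
#' class and pattern.
#'
#' @param cfg A `generator_config`.
#' @return The config, invisibly classed, if valid; otherwise an error of
#'   class `"psyvar_config_error"`.
#' @export
validate_generator_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) psy_stop(msg, "psyvar_config_error")
  chk(length(cfg$n_divisions) == 1 && cfg$n_divisions >= 2,
      "n_divisions must be a single integer >= 2")
  rng <- cfg$division_population_range
  chk(length(rng) == 2 && all(rng > 0) && rng[1] <= rng[2],
      "division_population_range must be positive (min, max)")
  prob_sum1 <- function(p) abs(sum(p) - 1) <= 1e-9 && all(p >= 0)
  chk(length(cfg$age_group_shares) == 5 && prob_sum1(cfg$age_group_shares),
      "age_group_shares must be 5 probabilities summing to 1 (within 1e-9)")
  chk(length(cfg$income_quintile_shares) == 5 && prob_sum1(cfg$income_quintile_shares),
      "income_quintile_shares must be 5 probabilities summing to 1 (within 1e-9)")
  chk(cfg$sex_share_female >= 0 && cfg$sex_share_female <= 1,
      "sex_share_female must be in [0,1]")
  chk(cfg$rural_share >= 0 && cfg$rural_share <= 1,
      "rural_share must be in [0,1]")
  chk(all(psy_classes() %in% names(cfg$baseline_rates_per_1000)) &&
        all(cfg$baseline_rates_per_1000[psy_classes()] > 0),
      "baseline_rates_per_1000 must be strictly positive for every class")
  chk(cfg$division_effect_sd >= 0, "division_effect_sd must be >= 0")
  chk(cfg$nonrecipient_sample_fraction > 0 && cfg$nonrecipient_sample_fraction <= 1,
      "nonrecipient_sample_fraction must be in (0,1]")
  chk(is.list(cfg$log_rate_ratios) &&
        all(names(cfg$log_rate_ratios) %in% psy_classes()),
      "log_rate_ratios must be a list keyed by drug class")

  for (cls in names(cfg$log_rate_ratios)) {
    lrr <- cfg$log_rate_ratios[[cls]]
    if (!length(lrr)) next
    bad <- setdiff(names(lrr), generator_terms())
    if (length(bad)) {
      if (any(grepl("other", bad)))
        psy_stop(paste0("log_rate_ratios[", cls, "]: an 'other psychotropic class' ",
                        "effect is not generable (classes are drawn independently); ",
                        "remove term(s): ", paste(bad, collapse = ", ")),
                 "psyvar_config_error")
      psy_stop(paste0("log_rate_ratios[", cls, "]: unknown term(s) ",
                      paste(bad, collapse = ", "), "; valid terms: ",
                      paste(generator_terms(), collapse = ", ")),
               "psyvar_config_error")
    }
    ## most-exposed pattern: take the worst level within each covariate group
    grp <- list(age = c("age_0_4", "age_10_14", "age_15_19", "age_20_24"),
                sex = "male", rural = "rural",
                income = c("income_2", "income_3", "income_4", "income_5"),
                adg = c("adg_6_9", "adg_10plus"))
    worst <- vapply(grp, function(g) {
      v <- lrr[intersect(g, names(lrr))]
      if (!length(v)) 0 else max(0, v)
    }, numeric(1))
    p_max <- cfg$baseline_rates_per_1000[[cls]] / 1000 * exp(sum(worst))
    if (p_max > 1) {
      lev <- vapply(names(grp), function(gn) {
        v <- lrr[intersect(grp[[gn]], names(lrr))]
        if (!length(v) || max(v) <= 0) "(ref)" else names(v)[which.max(v)]
      }, character(1))
      psy_stop(sprintf(
        "class '%s': most-exposed pattern [%s] implies probability %.3f > 1",
        cls, paste(paste0(names(grp), "=", lev), collapse = ", "), p_max),
        "psyvar_config_error")
    }
  }
  invisible(cfg)
}
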