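#' Generate a synthetic provincial cohort
#'
#' Simulates a closed one-year cohort of 0-24 year olds across census
#' divisions, draws per-class psychotropic dispensing from a multiplicative
#' log-linear rate model, and applies the study sampling design: every
#' recipient of any class is retained with weight 1, and non-recipients are
#' down-sampled (10% by default) with weight equal to the reciprocal
#' fraction.
#'
#' The rate model for class `c` and person `i` in division `d` is
#' `p = min(1, baseline_c/1000 * u_d * exp(sum of covariate log rate ratios))`
#' where `u_d = exp(Normal(-sd^2/2, sd))` is a division-level effect with
#' mean 1. Draws flow from a single RNG stream seeded from `config$seed`,
#' in a fixed documented order (division populations, division covariates,
#' division effects, person covariates, dispensing by class, prescription
#' counts, the non-recipient sampling permutation), so identical configs
#' reproduce identical tables.
#'
#' The non-recipient sample is taken as every k-th element of a random
#' permutation (k = 1/fraction), so the sum of emitted weights equals the
#' simulated population up to the remainder `n_nonrecipients mod k`.
#'
#' @param config A [generator_config()].
#' @return An object of class `"psy_cohort"`: a list with `persons` (one row
#'   per retained person), `divisions` (one row per division, with
#'   population counts per age-band-by-sex stratum computed from the full
#'   simulated cohort before down-sampling), and the echoed `config`.
#' @export
#' @examples
#' cfg <- generator_config(n_divisions = 4,
#'                         division_population_range = c(300, 1200),
#'                         division_effect_sd = 0.3, seed = 7)
#' coh <- generate_cohort(cfg)
#' head(coh$persons)
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  nd <- config$n_divisions
  classes <- psy_classes()

  ## 1. division populations, log-uniform over the configured range
  rng <- config$division_population_range
  pop <- as.integer(round(exp(runif(nd, log(rng[1]), log(rng[2])))))
  div_ids <- sprintf("D%02d", seq_len(nd))

  ## 2. division-level covariates (fixed order)
  divcov <- lapply(config$division_covariate_params, draw_division_covariate, n = nd)

  ## 3. division multiplicative rate effects, E[u_d] = 1
  s <- config$division_effect_sd
  u <- if (s > 0) exp(rnorm(nd, -s^2 / 2, s)) else rep(1, nd)

  ## 4. person-level covariates
  n <- sum(pop)
  div_idx <- rep.int(seq_len(nd), pop)
  band_idx <- sample.int(5L, n, replace = TRUE, prob = config$age_group_shares)
  age <- (band_idx - 1L) * 5L + sample.int(5L, n, replace = TRUE) - 1L
  female <- rbinom(n, 1L, config$sex_share_female)
  income <- sample.int(5L, n, replace = TRUE, prob = config$income_quintile_shares)
  rural <- rbinom(n, 1L, config$rural_share)
  adg <- pmin(rnbinom(n, size = config$adg_distribution$size,
                      mu = config$adg_distribution$mu), 32L)

  ## 5. per-class dispensing draws (class order fixed)
  lp_covariates <- function(lrr) {
    eff <- setNames(numeric(length(generator_terms())), generator_terms())
    if (length(lrr)) eff[names(lrr)] <- lrr
    age_eff <- c(eff[["age_0_4"]], 0, eff[["age_10_14"]],
                 eff[["age_15_19"]], eff[["age_20_24"]])
    adg_eff <- c(0, eff[["adg_6_9"]], eff[["adg_10plus"]])
    inc_eff <- c(0, eff[["income_2"]], eff[["income_3"]],
                 eff[["income_4"]], eff[["income_5"]])
    adg_band <- findInterval(adg, c(0, 6, 10))
    age_eff[band_idx] + (1 - female) * eff[["male"]] + rural * eff[["rural"]] +
      inc_eff[income] + adg_eff[adg_band]
  }
  dispensed <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  clamped <- 0L
  for (cls in classes) {
    lp <- log(config$baseline_rates_per_1000[[cls]] / 1000) + log(u)[div_idx] +
      lp_covariates(config$log_rate_ratios[[cls]])
    p <- exp(lp)
    clamped <- clamped + sum(p > 1)
    dispensed[, cls] <- rbinom(n, 1L, pmin(p, 1))
  }
  if (clamped > 0)
    message(sprintf(
      "generate_cohort: %d person-class probabilities exceeded 1 and were clamped (%.3f%% of draws)",
      clamped, 100 * clamped / (n * length(classes))))
  any_psy <- as.integer(rowSums(dispensed) > 0)

  ## 6. prescription counts (>= 1 per dispensed person-class)
  rx <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  for (cls in classes) {
    idx <- which(dispensed[, cls] == 1L)
    if (length(idx))
      rx[idx, cls] <- 1L + rnbinom(length(idx),
                                   size = config$rx_per_recipient$size,
                                   mu = max(config$rx_per_recipient$mu - 1, 1e-8))
  }

  ## 7. down-sample non-recipients: every k-th of a random permutation
  k <- round(1 / config$nonrecipient_sample_fraction)
  nonrec <- which(any_psy == 0L)
  perm <- sample(nonrec)
  sampled <- if (length(perm) >= k) sort(perm[seq(k, length(perm), by = k)]) else integer(0)
  keep <- sort(c(which(any_psy == 1L), sampled))
  weight <- ifelse(any_psy[keep] == 1L, 1, k)

  bands <- psy_age_bands()
  sexes <- c("female", "male")
  persons <- data.table::data.table(
    person_id = sprintf("P%08d", keep),
    division_id = div_ids[div_idx[keep]],
    age_years = age[keep],
    age_band = bands[band_idx[keep]],
    sex = sexes[2L - female[keep]],
    income_quintile = income[keep],
    rurality = ifelse(rural[keep] == 1L, "rural", "urban"),
    adg_count = adg[keep],
    adg_band = as.character(adg_band_of(adg[keep]))
  )
  for (cls in classes) persons[[paste0("dispensed_", cls)]] <- dispensed[keep, cls]
  for (cls in classes) persons[[paste0("rx_", cls)]] <- rx[keep, cls]
  persons$any_psychotropic <- any_psy[keep]
  ## per-class indicator of receiving any *different* psychotropic class
  for (cls in classes) {
    other <- rowSums(dispensed[keep, setdiff(classes, cls), drop = FALSE])
    persons[[paste0("other_", cls)]] <- as.integer(other > 0)
  }
  persons$weight <- weight

  ## division table: stratum populations from the full pre-sampling cohort
  strat <- data.table::data.table(div = div_idx, band = band_idx, female = female)
  cnt <- strat[, .N, by = .(div, band, female)]
  divisions <- data.table::data.table(division_id = div_ids)
  for (b in seq_along(bands)) for (f in c(1L, 0L)) {
    col <- stratum_col(bands[b], sexes[2L - f])
    v <- integer(nd)
    sub <- cnt[cnt$band == b & cnt$female == f, ]
    v[sub$div] <- sub$N
    divisions[[col]] <- v
  }
  divisions$total_population <- pop
  for (nm in names(divcov)) divisions[[nm]] <- divcov[[nm]]

  structure(list(persons = as.data.frame(persons),
                 divisions = as.data.frame(divisions),
                 config = config),
            class = "psy_cohort")
}

## Column name for an (age band, sex) population stratum.
stratum_col <- function(band, sex) {
  paste0("pop_", gsub("-", "_", band), "_", sex)
}

draw_division_covariate <- function(param, n) {
  x <- switch(param$dist,
    lognormal = exp(rnorm(n, param$meanlog, param$sdlog)),
    normal = rnorm(n, param$mean, param$sd),
    psy_stop(paste0("unknown covariate distribution: ", param$dist),
             "psyvar_config_error"))
  if (!is.null(param$min)) x <- pmax(x, param$min)
  if (!is.null(param$max)) x <- pmin(x, param$max)
  x
}

#' @export
print.psy_cohort <- function(x, ...) {
  cat("Synthetic psychotropic dispensing cohort\n")
  cat(sprintf("  divisions: %d, simulated population: %s\n",
              nrow(x$divisions), format(sum(x$divisions$total_population), big.mark = ",")))
  cat(sprintf("  emitted persons: %s (sum of weights %s)\n",
              format(nrow(x$persons), big.mark = ","),
              format(sum(x$persons$weight), big.mark = ",")))
  for (cls in psy_classes()) {
    n_cls <- sum(x$persons[[paste0("dispensed_", cls)]])
    cat(sprintf("  %-15s recipients: %s\n", cls, format(n_cls, big.mark = ",")))
  }
  invisible(x)
}

#' Write a cohort to CSV with a metadata sidecar
#'
#' Writes `persons.csv`, `divisions.csv` (RFC-4180, UTF-8, header row, stable
#' column order) and `cohort_metadata.json` echoing the seed and config.
#'
#' @param cohort A `psy_cohort`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "persons.csv")
  dp <- file.path(dir, "divisions.csv")
  mp <- file.path(dir, "cohort_metadata.json")
  data.table::fwrite(cohort$persons, pp)
  data.table::fwrite(cohort$divisions, dp)
  jsonlite::write_json(list(seed = cohort$config$seed,
                            config = unclass(cohort$config)),
                       mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(persons = pp, divisions = dp, metadata = mp))
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory holding `persons.csv` and `divisions.csv`.
#' @return A list with `persons` and `divisions` data frames.
#' @export
read_cohort <- function(dir) {
  pp <- file.path(dir, "persons.csv")
  dp <- file.path(dir, "divisions.csv")
  for (p in c(pp, dp)) if (!file.exists(p))
    psy_stop(paste0("missing input table: ", p), "psyvar_io_error")
  list(persons = as.data.frame(data.table::fread(pp)),
       divisions = as.data.frame(data.table::fread(dp)))
}
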