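# Shared fixtures: small synthetic cohorts and hand-built tables.

## A small but non-trivial cohort config: keeps generation under a second
## while leaving every stratum populated.
small_config <- function(seed = 42, ...) {
  generator_config(n_divisions = 6,
                   division_population_range = c(2000, 8000),
                   division_effect_sd = 0.3,
                   seed = seed, ...)
}

## Minimal hand-built person table: one division, `n_rec` recipients of
## `class` (weight 1) and `n_nonrec_rows` sampled non-recipient rows
## (weight 10), all in one age-sex stratum unless spread = TRUE.
toy_persons <- function(n_rec = 10, n_nonrec_rows = 19,
                        class = "stimulant", division = "D01",
                        spread = FALSE) {
  n <- n_rec + n_nonrec_rows
  classes <- psy_classes()
  df <- data.frame(
    person_id = sprintf("P%03d", seq_len(n)),
    division_id = division,
    age_years = if (spread) rep(c(7L, 17L), length.out = n) else 7L,
    age_band = if (spread) rep(c("5-9", "15-19"), length.out = n) else "5-9",
    sex = if (spread) rep(c("female", "male"), length.out = n) else "female",
    income_quintile = 1L,
    rurality = "urban",
    adg_count = 2L,
    adg_band = "0-5",
    stringsAsFactors = FALSE)
  for (cl in classes) df[[paste0("dispensed_", cl)]] <- 0L
  df[[paste0("dispensed_", class)]][seq_len(n_rec)] <- 1L
  for (cl in classes) df[[paste0("rx_", cl)]] <- 3L * df[[paste0("dispensed_", cl)]]
  df$any_psychotropic <- as.integer(rowSums(
    df[paste0("dispensed_", classes)]) > 0)
  for (cl in classes) {
    other <- rowSums(df[paste0("dispensed_", setdiff(classes, cl))])
    df[[paste0("other_", cl)]] <- as.integer(other > 0)
  }
  df$weight <- ifelse(df$any_psychotropic == 1, 1, 10)
  df
}

toy_divisions <- function(ids = "D01", population = 200) {
  df <- data.frame(division_id = ids, stringsAsFactors = FALSE)
  for (b in psy_age_bands()) for (s in c("female", "male"))
    df[[psyvar:::stratum_col(b, s)]] <- round(population / 10)
  df$total_population <- population
  df$specialist_density <- 3
  df$agency_density <- 0.15
  df$mh_admission_ed_rate <- 15
  df$pct_postsecondary <- 55
  df$pct_visible_minority <- 8
  df$pct_noncitizen <- 4
  df$pct_employed <- 60
  df$pct_neither_language <- 1.2
  df$mean_household_size <- 2.6
  df
}

## Direct Poisson / log-normal mixing oracle for the expected SCV: draws
## `reps` provinces with O_i ~ Poisson(E_i * u_i), u_i log-normal with
## log-variance v and mean 1, and returns the Monte-Carlo mean SCV.
## With `estimate_E = TRUE` the expected counts are re-estimated from each
## replicate's pooled rate (E_i = N_i * sum(O)/sum(N)), mirroring how the
## pipeline derives them from the data; this shrinks the SCV slightly
## (the sum-to-zero constraint on O - E absorbs one degree of freedom).
oracle_scv_mean <- function(E, v, reps, seed = 1, estimate_E = FALSE) {
  set.seed(seed)
  k <- length(E)
  mean(vapply(seq_len(reps), function(i) {
    u <- if (v > 0) exp(rnorm(k, -v / 2, sqrt(v))) else rep(1, k)
    O <- rpois(k, E * u)
    Ei <- if (estimate_E) E * sum(O) / sum(E) else E
    scv(O, Ei)
  }, numeric(1)))
}
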