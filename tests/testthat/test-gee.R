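# Design construction and the GEE solver, cross-checked against
# independent oracles (quasi-Poisson GLM; frozen statsmodels GEE values).

## Small clustered Poisson dataset with a log-normal cluster effect. The
## exchangeable fit of this exact dataset was cross-checked against an
## independent GEE implementation (statsmodels 0.14, Poisson family,
## exchangeable covariance, offset): coefficients, alpha and robust SEs
## agreed to ~1e-8. Those values are frozen below as the oracle.
oracle_cluster_data <- function() {
  set.seed(9)
  ncl <- 12; percl <- 6
  cl <- rep(seq_len(ncl), each = percl)
  x1 <- round(rnorm(ncl * percl), 3)
  x2 <- rep(round(rnorm(ncl), 3), each = percl)
  off <- log(round(runif(ncl * percl, 50, 200)))
  u <- rep(exp(rnorm(ncl, 0, 0.4)), each = percl)
  y <- rpois(ncl * percl, exp(-3 + 0.3 * x1 + 0.1 * x2 + off) * u)
  list(X = cbind("(Intercept)" = 1, x1 = x1, x2 = x2),
       y = y, offset = off, cluster = cl)
}

test_that("cells aggregate outcome, weights and offset as specified", {
  ## 10 recipients + 19 non-recipient rows (weight 10) in one pattern:
  ## outcome 10, offset log(200)
  p <- rbind(toy_persons(n_rec = 10, n_nonrec_rows = 19),
             within(toy_persons(n_rec = 5, n_nonrec_rows = 10), {
               person_id <- paste0("B", person_id); sex <- "male"
             }))
  des <- build_design(p, toy_divisions(), "stimulant",
                      individual_covariates = "sex",
                      division_covariates = character(0),
                      include_other_class = FALSE)
  i <- which(des$X[, "sex=male"] == 0)
  expect_equal(des$y[i], 10)
  expect_equal(des$offset[i], log(200))
  expect_equal(des$y[-i], 5)
  expect_equal(des$offset[-i], log(105))
})

test_that("single-level covariates and unknown divisions are hard errors", {
  p <- toy_persons(spread = TRUE)
  expect_error(build_design(p, toy_divisions(), "stimulant",
                            individual_covariates = "rurality"),
               regexp = "rurality", class = "psyvar_design_error")
  expect_error(build_design(toy_persons(), toy_divisions(ids = "D99"), "all"),
               class = "psyvar_input_error")
})

test_that("independence GEE reproduces the quasi-Poisson GLM oracle", {
  coh <- generate_cohort(small_config(seed = 51))
  des <- build_design(coh$persons, coh$divisions, "stimulant",
                      division_covariates = c("specialist_density",
                                              "agency_density"))
  f <- fit_gee(des)
  g <- glm(des$y ~ des$X - 1 + offset(des$offset), family = quasipoisson())
  expect_true(f$converged)
  expect_lt(max(abs(coef(g) - f$beta)), 1e-6)
  ## Pearson dispersion agrees (phi is quadratic in residuals, so the
  ## 1e-6 coefficient agreement propagates to ~1e-4 here)
  expect_equal(f$phi, summary(g)$dispersion, tolerance = 1e-3)
})

test_that("intercept-only fit has the closed-form rate", {
  coh <- generate_cohort(small_config(seed = 52))
  des <- build_design(coh$persons, coh$divisions, "antidepressant",
                      division_covariates = character(0),
                      individual_covariates = "sex",
                      include_other_class = FALSE)
  d0 <- list(X = matrix(1, length(des$y), 1, dimnames = list(NULL, "(Intercept)")),
             y = des$y, offset = des$offset, cluster = des$cluster)
  f <- fit_gee(d0)
  expect_equal(exp(f$beta[[1]]), sum(des$y) / sum(exp(des$offset)),
               tolerance = 1e-10)
})

test_that("exchangeable fit matches the frozen independent-oracle values", {
  d <- oracle_cluster_data()
  f <- fit_gee(d, corstr = "exchangeable", tol = 1e-10)
  expect_true(f$converged)
  expect_equal(unname(f$beta),
               c(-2.81466735, 0.34484267, -0.26027676), tolerance = 1e-7)
  expect_equal(f$alpha_work, 0.11887435, tolerance = 1e-6)
  expect_equal(unname(f$robust_se),
               c(0.058285, 0.044093, 0.083613), tolerance = 1e-4)
})

test_that("sandwich equals the HC0 robust GLM covariance with singleton clusters", {
  d <- oracle_cluster_data()
  d$cluster <- seq_along(d$y)      # one cell per cluster
  f <- fit_gee(d)
  mu <- exp(drop(d$X %*% f$beta) + d$offset)
  bread <- solve(crossprod(d$X * sqrt(mu)))
  meat <- crossprod(d$X * (d$y - mu))
  expect_equal(f$robust_cov, bread %*% meat %*% bread,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("estimates are invariant to cell order and cell splitting", {
  d <- oracle_cluster_data()
  f1 <- fit_gee(d, corstr = "exchangeable", tol = 1e-10)
  set.seed(5)
  perm <- sample(length(d$y))
  d2 <- list(X = d$X[perm, ], y = d$y[perm], offset = d$offset[perm],
             cluster = d$cluster[perm])
  f2 <- fit_gee(d2, corstr = "exchangeable", tol = 1e-10)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$robust_cov, f2$robust_cov, tolerance = 1e-8)

  ## splitting a cell in two leaves the independence estimating equations
  ## unchanged (sufficiency of aggregation for log-link counts): split each
  ## observation into two half-population rows carrying split outcomes
  fi <- fit_gee(d)
  ys <- c(floor(d$y / 2), d$y - floor(d$y / 2))
  d3 <- list(X = rbind(d$X, d$X), y = ys,
             offset = c(d$offset + log(0.5), d$offset + log(0.5)),
             cluster = c(d$cluster, d$cluster))
  f3 <- fit_gee(d3)
  expect_equal(f3$beta, fi$beta, tolerance = 1e-6)
})

test_that("negative binomial variance yields a positive theta and close RRs", {
  coh <- generate_cohort(small_config(seed = 53))
  des <- build_design(coh$persons, coh$divisions, "antidepressant",
                      division_covariates = c("specialist_density"))
  fq <- fit_gee(des)
  fn <- fit_gee(des, family = "negbin")
  expect_true(fn$converged)
  expect_gt(fn$theta, 0)
  ## same mean model: point estimates agree loosely, not exactly
  expect_lt(max(abs(log(fn$rr) - log(fq$rr))), 0.2)
})

test_that("pathological exchangeable regimes report non-convergence honestly", {
  ## very large between-division heterogeneity + covariate-pattern cells:
  ## the cell-level exchangeable score may have no root; the solver must
  ## say so rather than return a silent answer
  cfg <- generator_config(n_divisions = 10,
                          division_population_range = c(2000, 6000),
                          division_effect_sd = 0.99, seed = 54)
  coh <- generate_cohort(cfg)
  des <- build_design(coh$persons, coh$divisions, "all",
                      division_covariates = c("specialist_density",
                                              "agency_density"))
  expect_warning(f <- fit_gee(des, corstr = "exchangeable", maxit = 30),
                 regexp = "did not converge")
  expect_false(f$converged)
  expect_true(is.finite(f$max_abs_update))
  expect_error(rr_table(list(all = f)), class = "psyvar_input_error")
})

test_that("rr_table formats rate ratios with reference rows", {
  ## hand-built result with known numbers
  fake <- structure(list(
    beta = c("(Intercept)" = -2, "sex=male" = log(1.40), "specialist_density" = 0),
    rr = c(exp(-2), 1.40, 1),
    ci95 = cbind(lower = c(0.1, 1.36, 0.98), upper = c(0.2, 1.44, 1.02)),
    converged = TRUE,
    terms = data.frame(
      term = c("(Intercept)", "sex=male", "specialist_density"),
      variable = c("(Intercept)", "sex", "specialist_density"),
      level = c(NA, "male", NA),
      type = c("intercept", "factor", "numeric"), stringsAsFactors = FALSE),
    refs = data.frame(variable = "sex", ref = "female", stringsAsFactors = FALSE)
  ), class = "gee_result")
  tab <- rr_table(list(stimulant = fake))
  expect_equal(tab$stimulant[which(tab$level == "female (ref)")], "1.00")
  expect_equal(tab$stimulant[which(tab$level == "male")], "1.40 (1.36 to 1.44)")
  expect_equal(tab$stimulant[which(tab$variable == "specialist_density")],
               "1.00 (0.98 to 1.02)")
})
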