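#' Build the aggregated model design for a dispensing GEE
#'
#' Persons are collapsed to covariate-pattern cells within census division:
#' the cell outcome is the count of recipients of the modelled class, and
#' the cell offset is the log of the summed person weights, which inflates
#' the 10% non-recipient sample back to population scale. For a log-link
#' count model this aggregation leaves the estimating equations identical
#' to a person-level fit. Division-level covariates are joined by
#' `division_id`.
#'
#' @param persons Person table (schema of [generate_cohort()]).
#' @param divisions Division table carrying the division-level covariates.
#' @param outcome_class `"all"` or one of [psy_classes()]. For a stratified
#'   class model the per-person indicator of receiving any *other*
#'   psychotropic class is included as a covariate (the pooled "all" model
#'   has no such term).
#' @param individual_covariates Individual-level factors to include (and to
#'   key the cells by); defaults to the full published set. A covariate with
#'   a single observed level is a hard error (inestimable).
#' @param division_covariates Character vector of division-table columns to
#'   include as continuous area-level terms; zero-variance columns are
#'   dropped with a warning.
#' @param include_other_class Include the other-psychotropic-class
#'   indicator; defaults to `TRUE` for stratified models.
#' @return Object of class `"gee_design"`: design matrix `X` (with
#'   intercept), outcome `y`, `offset`, `cluster` (division id per cell)
#'   and term metadata used by [rr_table()].
#' @export
build_design <- function(persons, divisions,
                         outcome_class = c("all", psy_classes()),
                         individual_covariates = c("age_band", "sex", "rurality",
                                                   "income_quintile", "adg_band"),
                         division_covariates = default_division_covariates(),
                         include_other_class = !identical(outcome_class[1], "all")) {
  outcome_class <- match.arg(outcome_class)
  check_divisions(persons, divisions)
  if (any(persons$weight <= 0))
    psy_stop("person weights must be positive", "psyvar_input_error")
  ycol <- if (outcome_class == "all") "any_psychotropic"
          else paste0("dispensed_", outcome_class)
  dt <- data.table::as.data.table(persons)
  keyvars <- c("division_id", individual_covariates)
  if (include_other_class) {
    dt$other_class <- dt[[paste0("other_", outcome_class)]]
    keyvars <- c(keyvars, "other_class")
  }
  cells <- dt[, .(y = sum(.SD[[1]]), pop = sum(weight)),
              by = keyvars, .SDcols = ycol]
  data.table::setorderv(cells, keyvars)

  fac <- list(
    age_band = list(levels = psy_age_bands(), ref = "5-9"),
    sex = list(levels = c("female", "male"), ref = "female"),
    rurality = list(levels = c("urban", "rural"), ref = "urban"),
    income_quintile = list(levels = as.character(1:5), ref = "1"),
    adg_band = list(levels = psy_adg_bands(), ref = "0-5")
  )
  bad_cov <- setdiff(individual_covariates, names(fac))
  if (length(bad_cov))
    psy_stop(paste0("unknown individual covariate(s): ",
                    paste(bad_cov, collapse = ", ")), "psyvar_design_error")
  fac <- fac[individual_covariates]
  n <- nrow(cells)
  cols <- list(`(Intercept)` = rep(1, n))
  terms <- data.frame(term = "(Intercept)", variable = "(Intercept)",
                      level = NA_character_, type = "intercept",
                      stringsAsFactors = FALSE)
  for (v in names(fac)) {
    obs <- as.character(cells[[v]])
    seen <- unique(obs)
    if (length(seen) < 2)
      psy_stop(paste0("covariate '", v, "' has a single observed level ('",
                      seen, "'): inestimable"), "psyvar_design_error")
    unknown <- setdiff(seen, fac[[v]]$levels)
    if (length(unknown))
      psy_stop(paste0("covariate '", v, "' has unexpected level(s): ",
                      paste(unknown, collapse = ", ")), "psyvar_design_error")
    for (lev in setdiff(fac[[v]]$levels, fac[[v]]$ref)) {
      if (!lev %in% seen) next   # unobserved non-reference level: no column
      nm <- paste0(v, "=", lev)
      cols[[nm]] <- as.numeric(obs == lev)
      terms <- rbind(terms, data.frame(term = nm, variable = v, level = lev,
                                       type = "factor", stringsAsFactors = FALSE))
    }
  }
  if (include_other_class) {
    if (length(unique(cells$other_class)) < 2)
      psy_stop("covariate 'other_class' has a single observed level: inestimable",
               "psyvar_design_error")
    cols[["other_class"]] <- as.numeric(cells$other_class)
    terms <- rbind(terms, data.frame(term = "other_class", variable = "other_class",
                                     level = NA, type = "numeric",
                                     stringsAsFactors = FALSE))
  }
  dv <- data.table::as.data.table(divisions)
  m <- match(cells$division_id, dv$division_id)
  for (v in division_covariates) {
    if (!v %in% names(dv))
      psy_stop(paste0("division covariate '", v, "' not in divisions table"),
               "psyvar_design_error")
    x <- dv[[v]][m]
    if (stats::var(x) < .Machine$double.eps) {
      warning("dropping zero-variance division covariate: ", v)
      next
    }
    cols[[v]] <- x
    terms <- rbind(terms, data.frame(term = v, variable = v, level = NA,
                                     type = "numeric", stringsAsFactors = FALSE))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  ## reference levels recorded for the reporting layer
  refs <- data.frame(variable = names(fac),
                     ref = vapply(fac, `[[`, "", "ref"),
                     stringsAsFactors = FALSE)
  structure(list(X = X, y = cells$y, offset = log(cells$pop),
                 cluster = cells$division_id, terms = terms, refs = refs,
                 outcome_class = outcome_class),
            class = "gee_design")
}

## Division-level covariates in the published model, in table order.
default_division_covariates <- function() {
  c("specialist_density", "agency_density", "mh_admission_ed_rate",
    "pct_postsecondary", "pct_visible_minority", "mean_household_size",
    "pct_noncitizen", "pct_employed", "pct_neither_language")
}

#' Fit a log-link GEE for clustered count data
#'
#' Solves the generalized estimating equations
#' `sum_c D_c' V_c^{-1} (y_c - mu_c) = 0` by Fisher scoring with
#' `mu = exp(X beta + offset)`. The variance function is `mu`
#' (quasi-Poisson, with Pearson dispersion `phi`) or `mu + mu^2 / theta`
#' (negative binomial, `theta` re-estimated by method of moments each
#' iteration). The working correlation is independence or exchangeable
#' (moment estimator over within-cluster residual cross-products; clusters
#' of size 1 contribute only to `phi`). The reported covariance is always
#' the cluster-robust sandwich; the model-based covariance is retained for
#' diagnostics.
#'
#' @param design A `gee_design` from [build_design()], or a list with
#'   elements `X`, `y`, `offset`, `cluster` (and optionally `terms`,
#'   `refs`).
#' @param corstr Working correlation: `"independence"` or `"exchangeable"`.
#' @param family Variance family: `"quasipoisson"` or `"negbin"`.
#' @param tol Convergence tolerance on `max(abs(delta beta))`.
#' @param maxit Maximum Fisher scoring iterations.
#' @return Object of class `"gee_result"`: `beta`, `robust_cov`,
#'   `naive_cov`, `rr`, `ci95`, `robust_se`, `alpha_work`, `phi`, `theta`,
#'   `n_clusters`, `n_obs`, `iterations`, `converged`, `max_abs_update`.
#'   Non-convergence is reported in the object (with the last iterate),
#'   never silently.
#' @export
fit_gee <- function(design,
                    corstr = c("independence", "exchangeable"),
                    family = c("quasipoisson", "negbin"),
                    tol = 1e-8, maxit = 100L) {
  corstr <- match.arg(corstr)
  family <- match.arg(family)
  X <- design$X
  y <- design$y
  off <- design$offset
  cl <- design$cluster
  n <- length(y)
  p <- ncol(X)
  if (length(unique(cl)) < 2)
    psy_stop("GEE needs at least 2 clusters", "psyvar_design_error")
  qrX <- qr(X)
  if (qrX$rank < p)
    psy_stop(paste0("design matrix is rank deficient; aliased column(s): ",
                    paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]],
                          collapse = ", ")),
             "psyvar_design_error")

  ## initial values from a plain Poisson GLM
  beta <- suppressWarnings(
    glm.fit(X, y, offset = off, family = poisson())$coefficients)
  idx <- split(seq_len(n), cl)
  sizes <- lengths(idx)
  npairs <- sum(sizes * (sizes - 1) / 2)

  ## working quantities at a given beta: residuals on the working scale
  resid_parts <- function(beta, theta) {
    mu <- exp(drop(X %*% beta) + off)
    v <- if (is.finite(theta)) mu + mu^2 / theta else mu
    list(mu = mu, v = v, r = (y - mu) / sqrt(v))
  }
  ## estimating function and (optionally) the working information, for a
  ## fixed working correlation alpha
  score_info <- function(parts, alpha, want_B = TRUE) {
    W <- (parts$mu / sqrt(parts$v)) * X      # A^{-1/2} D
    r <- parts$r
    B <- if (want_B) matrix(0, p, p) else NULL
    s <- numeric(p)
    for (ii in idx) {
      Wc <- W[ii, , drop = FALSE]
      ec <- r[ii]
      if (corstr == "independence" || length(ii) == 1L) {
        if (want_B) B <- B + crossprod(Wc)
        s <- s + drop(crossprod(Wc, ec))
      } else {
        nc <- length(ii)
        a1 <- 1 / (1 - alpha)
        a2 <- alpha / (1 + (nc - 1) * alpha)
        cw <- colSums(Wc)
        if (want_B) B <- B + a1 * (crossprod(Wc) - a2 * tcrossprod(cw))
        s <- s + a1 * (drop(crossprod(Wc, ec)) - a2 * cw * sum(ec))
      }
    }
    list(B = B, s = s)
  }

  alpha <- 0
  theta <- Inf
  phi <- 1
  iter <- 0L
  maxupd <- Inf
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    if (family == "negbin") {
      mu0 <- exp(drop(X %*% beta) + off)
      den <- sum((y - mu0)^2 - mu0)
      theta <- if (den > 0) sum(mu0^2) / den else Inf
    }
    parts <- resid_parts(beta, theta)
    r <- parts$r
    phi <- sum(r^2) / (n - p)
    if (corstr == "exchangeable") {
      cross <- sum(vapply(idx, function(ii) sum(r[ii])^2 - sum(r[ii]^2),
                          numeric(1))) / 2
      denom <- phi * (npairs - p)
      if (denom <= 0)
        psy_stop("too few within-cluster pairs to estimate exchangeable alpha",
                 "psyvar_fit_error")
      alpha <- cross / denom
      if (alpha >= 1 || any(1 + (sizes - 1) * alpha <= 0))
        psy_stop(sprintf("singular working covariance (alpha = %.4f)", alpha),
                 "psyvar_fit_error")
    }
    si <- score_info(parts, alpha)
    delta <- tryCatch(solve(si$B, si$s), error = function(e)
      psy_stop("singular working information matrix", "psyvar_fit_error"))
    ## step-halving on the score norm (at fixed alpha/theta) guards the
    ## Gauss-Newton step against overshoot with few, large clusters
    s_norm <- sum(si$s^2)
    step <- delta
    for (h in seq_len(20L)) {
      cand <- beta + step
      lp <- drop(X %*% cand)
      if (all(is.finite(lp)) && max(lp + off) < 700) {
        s_try <- score_info(resid_parts(cand, theta), alpha, want_B = FALSE)$s
        if (sum(s_try^2) <= s_norm || max(abs(step)) < tol) break
      }
      step <- step / 2
    }
    beta <- beta + step
    maxupd <- max(abs(step))
    if (maxupd < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }

  ## sandwich at the final iterate
  mu <- exp(drop(X %*% beta) + off)
  if (family == "negbin") {
    den <- sum((y - mu)^2 - mu)
    theta <- if (den > 0) sum(mu^2) / den else Inf
  }
  v <- if (is.finite(theta)) mu + mu^2 / theta else mu
  r <- (y - mu) / sqrt(v)
  phi <- sum(r^2) / (n - p)
  W <- (mu / sqrt(v)) * X
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    Wc <- W[ii, , drop = FALSE]
    ec <- r[ii]
    if (corstr == "independence" || length(ii) == 1L) {
      B <- B + crossprod(Wc)
      g <- drop(crossprod(Wc, ec))
    } else {
      nc <- length(ii)
      a1 <- 1 / (1 - alpha)
      a2 <- alpha / (1 + (nc - 1) * alpha)
      cw <- colSums(Wc)
      B <- B + a1 * (crossprod(Wc) - a2 * tcrossprod(cw))
      g <- a1 * (drop(crossprod(Wc, ec)) - a2 * cw * sum(ec))
    }
    M <- M + tcrossprod(g)
  }
  Binv <- solve(B)
  robust <- Binv %*% M %*% Binv
  robust <- (robust + t(robust)) / 2
  naive <- phi * Binv
  se <- sqrt(diag(robust))
  z <- 1.959964
  beta <- setNames(drop(beta), colnames(X))
  res <- structure(list(
    beta = beta,
    robust_cov = robust,
    naive_cov = naive,
    robust_se = setNames(se, colnames(X)),
    rr = exp(beta),
    ci95 = cbind(lower = exp(beta - z * se), upper = exp(beta + z * se)),
    alpha_work = if (corstr == "exchangeable") alpha else NA_real_,
    phi = phi,
    theta = if (family == "negbin") theta else NA_real_,
    corstr = corstr, family = family,
    n_clusters = length(idx), n_obs = n,
    iterations = iter, converged = converged, max_abs_update = maxupd,
    terms = design$terms, refs = design$refs,
    outcome_class = design$outcome_class
  ), class = "gee_result")
  if (!converged)
    warning(sprintf(
      "GEE did not converge in %d iterations (max |delta beta| = %.3g); last iterate returned",
      iter, maxupd))
  res
}

#' @export
print.gee_result <- function(x, ...) {
  cat(sprintf("Log-link GEE (%s variance, %s working correlation)\n",
              x$family, x$corstr))
  cat(sprintf("  %d observations in %d clusters; %s after %d iterations\n",
              x$n_obs, x$n_clusters,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf("  dispersion phi = %.4f", x$phi))
  if (!is.na(x$alpha_work)) cat(sprintf(", exchangeable alpha = %.4f", x$alpha_work))
  if (!is.na(x$theta)) cat(sprintf(", NB theta = %.2f", x$theta))
  cat("\n\nRate ratios (robust 95% CI):\n")
  tab <- data.frame(RR = sprintf("%.3f", x$rr),
                    lower = sprintf("%.3f", x$ci95[, "lower"]),
                    upper = sprintf("%.3f", x$ci95[, "upper"]),
                    row.names = names(x$beta))
  print(tab)
  invisible(x)
}

#' Formatted rate-ratio table across fitted models
#'
#' Renders one or several [fit_gee()] results into the familiar adjusted
#' rate-ratio layout: one row per covariate level (reference rows marked
#' `1.00`), one column per model, entries formatted
#' `"RR (lower to upper)"` at two decimals.
#'
#' @param results A single `gee_result` or a named list of them (names
#'   become columns, e.g. the drug classes).
#' @return Data frame with `variable`, `level`, and one character column
#'   per model.
#' @export
rr_table <- function(results) {
  if (inherits(results, "gee_result")) results <- list(model = results)
  stopifnot(length(results) >= 1)
  base <- results[[1]]
  if (is.null(base$terms))
    psy_stop("results lack term metadata (fit via build_design)", "psyvar_input_error")

  ## row scaffold from the union of term metadata, with reference rows
  rows <- list()
  seen_vars <- character(0)
  for (res in results) {
    tm <- res$terms[res$terms$type != "intercept", , drop = FALSE]
    for (v in unique(tm$variable)) {
      if (v %in% seen_vars) next
      seen_vars <- c(seen_vars, v)
      if (any(tm$type[tm$variable == v] == "factor")) {
        ref <- res$refs$ref[res$refs$variable == v]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = paste0(ref, " (ref)"), term = NA,
          stringsAsFactors = FALSE)
        for (lev in tm$level[tm$variable == v])
          rows[[length(rows) + 1L]] <- data.frame(
            variable = v, level = lev, term = paste0(v, "=", lev),
            stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = NA, term = v, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  for (nm in names(results)) {
    res <- results[[nm]]
    if (!res$converged)
      psy_stop(paste0("model '", nm, "' did not converge; refusing to format"),
               "psyvar_input_error")
    col <- character(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      trm <- tab$term[i]
      if (is.na(trm)) { col[i] <- "1.00"; next }
      j <- match(trm, names(res$beta))
      col[i] <- if (is.na(j)) NA_character_ else
        sprintf("%.2f (%.2f to %.2f)", res$rr[j],
                res$ci95[j, "lower"], res$ci95[j, "upper"])
    }
    if (anyNA(col))
      message("rr_table: model '", nm, "' lacks some terms; cells left NA")
    tab[[nm]] <- col
  }
  tab$term <- NULL
  rownames(tab) <- NULL
  tab
}
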