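#' Run the full small-area variation pipeline
#'
#' Orchestrates generate (or load) -> rates -> variation -> per-division
#' tests -> GEE models -> descriptives, writing every output as CSV/JSON
#' plus a run manifest. Any stage failure aborts with a stage-named error;
#' stages completed so far are recorded in the manifest.
#'
#' The config may be an R list, or a path to a JSON or YAML file with the
#' same structure. Recognised entries (all optional unless noted):
#' \describe{
#'   \item{input}{`"synthetic"` (default) or a list with `persons` and
#'     `divisions` CSV paths.}
#'   \item{generator}{List of [generator_config()] arguments for synthetic
#'     input.}
#'   \item{numerator_mode}{`"persons"` (default) or `"prescriptions"`.}
#'   \item{alpha_familywise}{Familywise Type 1 error level, default 0.05;
#'     the per-comparison threshold is `alpha_familywise / k` rounded to
#'     one significant figure, with both values recorded.}
#'   \item{gee}{List: `classes` (default `"all"` plus the four classes),
#'     `family` (`"quasipoisson"` default or `"negbin"`), `corstr_all`
#'     (default `"exchangeable"`), `corstr_stratified` (default
#'     `"independence"`).}
#'   \item{seed}{Integer; overrides `generator$seed`.}
#' }
#'
#' @param config R list or path to a JSON/YAML config file.
#' @param out_dir Output directory (created); default `"psyvar_results"`.
#' @param seed Optional seed overriding the config.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = "psyvar_results",
                         seed = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(cfg$seed)) cfg$generator$seed <- cfg$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- proc.time()[["elapsed"]]
  manifest <- list(package = "psyvar",
                   version = as.character(packageVersion("psyvar")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed, stages = list(), complete = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  res <- list()

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest_write(manifest, out_dir)
      psy_stop(paste0("stage '", name, "' failed: ", conditionMessage(e)),
               "psyvar_pipeline_error")
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  ## ---- input ----------------------------------------------------------
  inp <- stage("input", function() {
    if (identical(cfg$input, "synthetic")) {
      gcfg <- do.call(generator_config, cfg$generator)
      coh <- generate_cohort(gcfg)
      write_cohort(coh, out_dir)
      list(persons = coh$persons, divisions = coh$divisions)
    } else {
      for (p in c(cfg$input$persons, cfg$input$divisions))
        if (!file.exists(p))
          psy_stop(paste0("input file not found: ", p), "psyvar_io_error")
      list(persons = as.data.frame(data.table::fread(cfg$input$persons)),
           divisions = as.data.frame(data.table::fread(cfg$input$divisions)))
    }
  })
  manifest$stages$input$n_persons <- nrow(inp$persons)
  manifest$stages$input$n_divisions <- nrow(inp$divisions)

  ## ---- rates ----------------------------------------------------------
  res$rates <- stage("rates", function() {
    r <- standardize_rates(inp$persons, inp$divisions,
                           numerator_mode = cfg$numerator_mode)
    write.csv(r, file.path(out_dir, "rates.csv"), row.names = FALSE)
    r
  })

  ## ---- variation + per-division tests ---------------------------------
  res$variation <- stage("variation", function() {
    out <- lapply(c("all", psy_classes()), function(cls) {
      r <- res$rates[res$rates$class == cls, , drop = FALSE]
      vs <- variation_summary(r$standardized_per_1000, r$population, r$O, r$E)
      c(list(class = cls), unclass(vs))
    })
    names(out) <- c("all", psy_classes())
    jsonlite::write_json(out, file.path(out_dir, "variation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  })
  res$division_tests <- stage("division_tests", function() {
    r <- res$rates[res$rates$class == "all", , drop = FALSE]
    al <- per_comparison_alpha(cfg$alpha_familywise, nrow(r))
    tst <- division_vs_province_test(r$O, r$E, r$population,
                                     alpha = al$rounded,
                                     division_id = r$division_id)
    tst$alpha_raw <- al$raw
    write.csv(tst, file.path(out_dir, "division_tests.csv"), row.names = FALSE)
    tst
  })

  ## ---- GEE models ------------------------------------------------------
  res$gee <- stage("gee", function() {
    fits <- lapply(cfg$gee$classes, function(cls) {
      des <- build_design(inp$persons, inp$divisions, outcome_class = cls,
                          division_covariates = cfg$gee$division_covariates)
      corstr <- if (cls == "all") cfg$gee$corstr_all else cfg$gee$corstr_stratified
      suppressWarnings(fit_gee(des, corstr = corstr, family = cfg$gee$family))
    })
    names(fits) <- cfg$gee$classes
    dump <- lapply(fits, function(f)
      list(beta = as.list(f$beta), robust_se = as.list(f$robust_se),
           rr = as.list(f$rr),
           ci95 = list(lower = unname(f$ci95[, 1]), upper = unname(f$ci95[, 2])),
           alpha_work = f$alpha_work, phi = f$phi, theta = f$theta,
           corstr = f$corstr, family = f$family,
           n_clusters = f$n_clusters, n_obs = f$n_obs,
           iterations = f$iterations, converged = f$converged))
    jsonlite::write_json(dump, file.path(out_dir, "gee_results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ok <- vapply(fits, `[[`, TRUE, "converged")
    if (!all(ok))
      message("table2: omitting model(s) that did not converge: ",
              paste(names(fits)[!ok], collapse = ", "))
    if (!any(ok))
      psy_stop("no GEE model converged; table2.csv not written",
               "psyvar_fit_error")
    write.csv(rr_table(fits[ok]), file.path(out_dir, "table2.csv"),
              row.names = FALSE)
    fits
  })

  ## ---- descriptives ----------------------------------------------------
  res$table1 <- stage("table1", function() {
    t1 <- baseline_table(inp$persons)
    write.csv(t1, file.path(out_dir, "table1.csv"), row.names = FALSE)
    t1
  })
  res$correlations <- stage("correlations", function() {
    cr <- division_correlations(res$rates, inp$divisions)
    jsonlite::write_json(lapply(cr, unclass),
                         file.path(out_dir, "correlations.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cr
  })

  manifest$complete <- TRUE
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  manifest_write(manifest, out_dir)
  invisible(list(results = res, manifest = manifest))
}

manifest_write <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## Normalize a run config from a list or a JSON/YAML file, filling defaults.
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      psy_stop(paste0("config file not found: ", config), "psyvar_io_error")
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        psy_stop("YAML config requires the 'yaml' package", "psyvar_io_error")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config))
    psy_stop("config must be a list or a path to a JSON/YAML file",
             "psyvar_config_error")
  defaults <- list(input = "synthetic", generator = list(),
                   numerator_mode = "persons", alpha_familywise = 0.05,
                   gee = list(), seed = NULL)
  cfg <- modifyList(defaults, config)
  gee_defaults <- list(classes = c("all", psy_classes()),
                       family = "quasipoisson",
                       corstr_all = "exchangeable",
                       corstr_stratified = "independence",
                       division_covariates = default_division_covariates())
  cfg$gee <- modifyList(gee_defaults, cfg$gee)
  if (cfg$alpha_familywise <= 0 || cfg$alpha_familywise >= 1)
    psy_stop("alpha_familywise must be in (0, 1)", "psyvar_config_error")
  if (!identical(cfg$input, "synthetic") &&
      !(is.list(cfg$input) && all(c("persons", "divisions") %in% names(cfg$input))))
    psy_stop("config$input must be \"synthetic\" or list(persons=, divisions=)",
             "psyvar_config_error")
  cfg
}
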