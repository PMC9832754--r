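#' Provincial reference structure for direct standardization
#'
#' Pools the (weighted) person table into the 10 age-band-by-sex strata and
#' returns each stratum's provincial population share and provincial
#' dispensing rate per class (events per person). Used as the reference for
#' direct standardization and as the source of indirect expected counts.
#'
#' @param persons Person table (see [generate_cohort()] for the schema).
#' @param numerator_mode `"persons"` (individuals dispensed; default) or
#'   `"prescriptions"` (prescription counts).
#' @return Data frame with columns `age_band`, `sex`, `share`, and one
#'   `rate_<class>` column per class plus `rate_all`.
#' @export
reference_structure <- function(persons, numerator_mode = c("persons", "prescriptions")) {
  numerator_mode <- match.arg(numerator_mode)
  dt <- with_rx_total(data.table::as.data.table(persons))
  ev <- event_columns(numerator_mode)
  agg <- dt[, c(list(w = sum(weight)),
                lapply(.SD, function(x) sum(x * weight))),
            by = .(age_band, sex), .SDcols = unname(ev)]
  data.table::setnames(agg, unname(ev), paste0("rate_", names(ev)))
  for (nm in paste0("rate_", names(ev))) agg[[nm]] <- agg[[nm]] / agg$w
  agg$share <- agg$w / sum(agg$w)
  agg$w <- NULL
  out <- as.data.frame(agg)
  out[order(match(out$age_band, psy_age_bands()), out$sex), ,
      drop = FALSE]
}

## Event column per class for a numerator mode; names are the class labels
## (including "all"), values the person-table columns.
event_columns <- function(numerator_mode) {
  classes <- psy_classes()
  if (numerator_mode == "persons") {
    setNames(c("any_psychotropic", paste0("dispensed_", classes)),
             c("all", classes))
  } else {
    setNames(c("rx_total", paste0("rx_", classes)), c("all", classes))
  }
}

## Adds rx_total (all-classes prescription count) when needed.
with_rx_total <- function(dt) {
  if (!"rx_total" %in% names(dt))
    dt$rx_total <- rowSums(dt[, paste0("rx_", psy_classes()), drop = FALSE])
  dt
}

check_divisions <- function(persons, divisions) {
  if (is.null(divisions)) return(invisible())
  unknown <- setdiff(unique(persons$division_id), divisions$division_id)
  if (length(unknown))
    psy_stop(paste0("person rows reference unknown division_id(s): ",
                    paste(sort(unknown), collapse = ", ")),
             "psyvar_input_error")
  zero <- divisions$division_id[divisions$total_population <= 0]
  if (length(zero))
    psy_stop(paste0("division(s) with zero population: ",
                    paste(zero, collapse = ", ")),
             "psyvar_input_error")
  invisible()
}

#' Crude dispensing rates per division and drug class
#'
#' Weighted event counts over weighted population, scaled per 1000. The
#' `"all"` class counts a person dispensed several classes once (persons
#' mode) or sums prescriptions over classes (prescriptions mode).
#'
#' @inheritParams reference_structure
#' @param divisions Optional division table for referential-integrity
#'   checks (unknown or zero-population divisions are hard errors).
#' @return Data frame: `division_id`, `class`, `O` (weighted events),
#'   `population` (weighted persons), `crude_per_1000`.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_divisions = 3,
#'   division_population_range = c(500, 1500), seed = 2))
#' head(crude_rates(coh$persons, coh$divisions))
crude_rates <- function(persons, divisions = NULL,
                        numerator_mode = c("persons", "prescriptions")) {
  numerator_mode <- match.arg(numerator_mode)
  check_divisions(persons, divisions)
  if (any(persons$weight <= 0))
    psy_stop("person weights must be positive", "psyvar_input_error")
  dt <- with_rx_total(data.table::as.data.table(persons))
  ev <- event_columns(numerator_mode)
  agg <- dt[, c(list(population = sum(weight)),
                lapply(.SD, function(x) sum(x * weight))),
            by = division_id, .SDcols = unname(ev)]
  long <- data.table::melt(agg, id.vars = c("division_id", "population"),
                           variable.name = "col", value.name = "O")
  long$class <- names(ev)[match(long$col, unname(ev))]
  long$col <- NULL
  long$crude_per_1000 <- 1000 * long$O / long$population
  out <- as.data.frame(long[order(long$division_id,
                                  match(long$class, c("all", psy_classes())))])
  out[, c("division_id", "class", "O", "population", "crude_per_1000")]
}

#' Directly standardized rates with indirect expected counts
#'
#' Computes, per division and class, the crude rate, the direct age- and
#' sex-standardized rate (reference-share-weighted mean of the division's
#' stratum rates), and the indirect expected count `E` (provincial stratum
#' rates applied to the division's stratum populations) needed by the
#' systematic component of variation and the per-division chi-square tests.
#'
#' Strata with zero division population contribute nothing to the direct
#' sum; their reference shares are renormalized away (a message notes which
#' divisions were affected). When the reference is built from the pooled
#' input itself, `sum(E) == sum(O)` per class up to floating point.
#'
#' @inheritParams crude_rates
#' @param reference A reference structure from [reference_structure()];
#'   defaults to the pooled provincial structure of `persons` itself.
#' @return Data frame: `division_id`, `class`, `O`, `population`, `E`,
#'   `crude_per_1000`, `standardized_per_1000`.
#' @export
standardize_rates <- function(persons, divisions = NULL, reference = NULL,
                              numerator_mode = c("persons", "prescriptions")) {
  numerator_mode <- match.arg(numerator_mode)
  check_divisions(persons, divisions)
  if (!is.null(reference) && nrow(reference) == 0)
    psy_stop("empty reference structure", "psyvar_input_error")
  if (is.null(reference)) reference <- reference_structure(persons, numerator_mode)
  dt <- with_rx_total(data.table::as.data.table(persons))
  ev <- event_columns(numerator_mode)
  strat <- dt[, c(list(w = sum(weight)),
                  lapply(.SD, function(x) sum(x * weight))),
              by = .(division_id, age_band, sex), .SDcols = unname(ev)]
  ref <- data.table::as.data.table(reference)
  strat <- merge(strat, ref, by = c("age_band", "sex"), all.x = TRUE)
  if (anyNA(strat$share))
    psy_stop("reference structure lacks strata present in the data",
             "psyvar_input_error")

  crude <- crude_rates(persons, divisions = NULL, numerator_mode = numerator_mode)
  pieces <- lapply(names(ev), function(cls) {
    ocol <- unname(ev[[cls]])
    rcol <- paste0("rate_", cls)
    per <- strat[, {
      sh <- share / sum(share)           # renormalize over observed strata
      list(std = 1000 * sum(sh * get(ocol) / w),
           E = sum(get(rcol) * w))
    }, by = division_id]
    per$class <- cls
    per
  })
  std <- data.table::rbindlist(pieces)

  ## note divisions missing strata (renormalized shares)
  n_strata <- nrow(ref)
  miss <- strat[, .N, by = division_id][N < n_strata]
  if (nrow(miss))
    message("standardize_rates: reference shares renormalized for division(s) ",
            "with empty strata: ", paste(miss$division_id, collapse = ", "))

  out <- merge(data.table::as.data.table(crude), std,
               by = c("division_id", "class"))
  out <- as.data.frame(out[order(out$division_id,
                                 match(out$class, c("all", psy_classes())))])
  out <- out[, c("division_id", "class", "O", "population", "E",
                 "crude_per_1000", "std")]
  names(out)[names(out) == "std"] <- "standardized_per_1000"
  rownames(out) <- NULL
  out
}

#' Subgroup proportion with explicit numerator and denominator
#'
#' Computes the proportion of a flagged condition inside a subgroup, e.g.
#' the share of antipsychotic recipients in an income quintile carrying a
#' prior psychosis diagnosis. An empty denominator is a signalled condition
#' (`"psyvar_empty_subgroup"`), never silently 0/0.
#'
#' @param flag 0/1 (or logical) vector marking the condition.
#' @param subset Optional logical vector selecting the subgroup (default:
#'   all rows).
#' @param weights Optional positive weights (default 1).
#' @return List with `numerator`, `denominator`, and `percent` (one
#'   decimal).
#' @export
#' @examples
#' subgroup_proportion(c(rep(1, 2414), rep(0, 13963 - 2414)))$percent  # 17.3
subgroup_proportion <- function(flag, subset = NULL, weights = NULL) {
  flag <- as.numeric(flag)
  n <- length(flag)
  if (is.null(subset)) subset <- rep(TRUE, n)
  if (is.null(weights)) weights <- rep(1, n)
  keep <- which(subset)
  den <- sum(weights[keep])
  if (length(keep) == 0 || den <= 0)
    psy_stop("empty subgroup: denominator is zero", "psyvar_empty_subgroup")
  num <- sum(weights[keep] * flag[keep])
  list(numerator = num, denominator = den,
       percent = round(100 * num / den, 1))
}
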