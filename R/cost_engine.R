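#' Wage truncation bounds
#'
#' Hourly wages are truncated to a minimum of 6.72 and a maximum of 268.63
#' EUR per hour (DKK 50 and DKK 2000 at the implied fixed rate of 7.44
#' DKK/EUR), applied before price indexing.
#'
#' @return named numeric vector `c(low, high)` in EUR/hour.
#' @export
wage_truncation_bounds <- function() c(low = 6.72, high = 268.63)

#' Standardize a payment/hours pair to a truncated hourly wage
#'
#' Payments are standardized to hourly rates using the Danish norm of 7.4
#' working hours per day (37-hour week); the rate is the payment divided by
#' the recorded hours, clamped to the truncation bounds. Zero or missing
#' hours with a positive payment, or a missing payment, yield a missing rate
#' to be imputed.
#'
#' @param payment gross payment in EUR (vectorized).
#' @param hours recorded hours.
#' @param bounds truncation bounds, default [wage_truncation_bounds()].
#' @return data.frame with `rate` (EUR/hour, NA if missing) and `source`
#'   (observed / truncated_low / truncated_high / missing).
#' @export
standardize_hourly_wage <- function(payment, hours,
                                    bounds = wage_truncation_bounds()) {
  if (any(payment < 0, na.rm = TRUE)) stop("negative payment")
  if (any(hours < 0, na.rm = TRUE)) stop("negative hours")
  raw <- ifelse(!is.na(hours) & hours > 0, payment / hours, NA_real_)
  rate <- pmin(pmax(raw, bounds["low"]), bounds["high"])
  source <- ifelse(is.na(raw), "missing",
            ifelse(raw < bounds["low"], "truncated_low",
            ifelse(raw > bounds["high"], "truncated_high", "observed")))
  data.frame(rate = unname(rate), source = source, stringsAsFactors = FALSE)
}

#' Impute missing hourly wages by regression
#'
#' A linear regression of the log hourly rate on sex, age group, education
#' level, sector and industry group, fitted on the observed wages, replaces
#' missing rates by exponentiated predictions clamped to the truncation
#' bounds. Records whose covariate pattern contains a level unseen in the
#' observed wages fall back to the sex-by-age stratum geometric mean
#' (flagged with a warning).
#'
#' @param rate hourly rates with NA for missing.
#' @param covariates data.frame with sex, age_group, education, sector,
#'   industry_group (one row per rate).
#' @param bounds truncation bounds.
#' @return list with `rate` (completed) and `source` ("imputed" where
#'   filled, NA elsewhere — callers merge with the standardization source).
#' @export
impute_missing_wages <- function(rate, covariates,
                                 bounds = wage_truncation_bounds()) {
  stopifnot(nrow(covariates) == length(rate))
  miss <- is.na(rate)
  if (!any(miss)) return(list(rate = rate, source = rep(NA_character_,
                                                        length(rate))))
  obs <- which(!miss)
  if (!length(obs)) stop("no observed wages to fit the imputation model")
  preds <- c("sex", "age_group", "education", "sector", "industry_group")
  d <- covariates[, preds, drop = FALSE]
  d[] <- lapply(d, as.character)
  dat <- cbind(logw = log(rate), d)
  fit <- stats::lm(logw ~ sex + age_group + education + sector +
                     industry_group, data = dat[obs, , drop = FALSE])
  new <- dat[miss, , drop = FALSE]
  unseen <- rep(FALSE, nrow(new))
  for (p in preds) unseen <- unseen | !(new[[p]] %in% unique(d[[p]][obs]))
  pred <- rep(NA_real_, nrow(new))
  if (any(!unseen))
    pred[!unseen] <- stats::predict(fit, newdata = new[!unseen, , drop = FALSE])
  if (any(unseen)) {
    warning(sum(unseen), " record(s) with unseen covariate level; ",
            "falling back to the stratum mean wage")
    strat <- paste(d$sex, d$age_group)
    for (i in which(unseen)) {
      same <- obs[strat[obs] == strat[miss][i]]
      pred[i] <- if (length(same)) mean(log(rate[same])) else
        mean(log(rate[obs]))
    }
  }
  out <- rate
  out[miss] <- pmin(pmax(exp(pred), bounds["low"]), bounds["high"])
  src <- rep(NA_character_, length(rate))
  src[miss] <- "imputed"
  list(rate = out, source = src)
}

#' Express a wage at the 2022 price level
#'
#' Multiplies nominal rates by the sex- and age-specific consumer price
#' index factor for the wage year (2022 = 1).
#'
#' @param rate nominal hourly rate.
#' @param sex,age_group,year lookup keys (vectorized).
#' @param cpi_table data.frame sex, age_group, year, factor.
#' @return rate at 2022 price level.
#' @export
adjust_to_price_level <- function(rate, sex, age_group, year, cpi_table) {
  key <- paste(sex, age_group, year)
  tab <- stats::setNames(cpi_table$factor,
                         paste(cpi_table$sex, cpi_table$age_group,
                               cpi_table$year))
  f <- tab[key]
  if (anyNA(f))
    stop("missing CPI entry for: ",
         paste(unique(key[is.na(f)]), collapse = ", "))
  unname(rate * f)
}

#' Annual cost components from two-year duration differences
#'
#' Converts a two-year duration difference against the reference group into
#' an annual cost at the individual's standardized hourly wage: per state
#' k in sickness absence / unemployment / temporary out,
#' \eqn{C_k = rate \times 7.4 \times \Delta_k / 2}; work absenteeism is the
#' wage value of the shortfall in workdays,
#' \eqn{C_A = rate \times 7.4 \times (-\Delta_{work}) / 2}. Negative values
#' are cost savings (more workdays than the reference).
#'
#' @param delta named length-7 vector (or persons x 7 matrix) of two-year
#'   duration differences in days.
#' @param rate hourly wage(s), EUR at 2022 prices.
#' @param hours_per_day working-day norm (default 7.4).
#' @return data.frame with columns absenteeism, sickness_absence,
#'   unemployment, temporary_out (EUR/year).
#' @export
annual_cost_per_employee <- function(delta, rate, hours_per_day = 7.4) {
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1,
                                           dimnames = list(NULL, names(delta)))
  k <- hours_per_day / 2
  data.frame(
    absenteeism = -rate * k * delta[, "work"],
    sickness_absence = rate * k * delta[, "sickness_absence"],
    unemployment = rate * k * delta[, "unemployment"],
    temporary_out = rate * k * delta[, "temporary_out"])
}

#' Aggregate person-level costs into the cost table
#'
#' Per stratum x exposure level (exposed levels 1-3): the survey-weighted
#' mean cost per employee and the weighted total (mean times weighted
#' employee count). "Total" rows per sex average across that sex's exposed
#' cells with the exposed weights. Component shares divide each component
#' total by the absenteeism total; coverage divides the weighted sample
#' size (all follow-ups) by the national workforce count.
#'
#' @param person_costs data.frame with stratum, exposure_level, sex,
#'   survey_weight and the four cost components of
#'   [annual_cost_per_employee()].
#' @param national_workforce national full-time workforce count for the
#'   coverage denominator (NA to skip).
#' @return object of class `cost_table`: `cells` (per stratum x level),
#'   `totals` (per sex), `coverage_pct`, `weighted_n`.
#' @export
aggregate_costs <- function(person_costs, national_workforce = NA) {
  comp <- c("absenteeism", "sickness_absence", "unemployment",
            "temporary_out")
  pc <- person_costs
  exp_pc <- pc[pc$exposure_level > 0, , drop = FALSE]
  if (!nrow(exp_pc)) stop("no exposed follow-ups to aggregate")
  key <- interaction(exp_pc$stratum, exp_pc$exposure_level, drop = TRUE)
  wsum <- tapply(exp_pc$survey_weight, key, sum)
  cells <- data.frame(do.call(rbind, strsplit(names(wsum), ".",
                                              fixed = TRUE)),
                      stringsAsFactors = FALSE)
  names(cells) <- c("stratum", "exposure_level")
  cells$exposure_level <- as.integer(cells$exposure_level)
  cells$weighted_n <- as.numeric(wsum)
  for (cc in comp) {
    cells[[paste0(cc, "_avg")]] <-
      as.numeric(tapply(exp_pc$survey_weight * exp_pc[[cc]], key, sum)) /
      cells$weighted_n
    cells[[paste0(cc, "_total")]] <-
      cells[[paste0(cc, "_avg")]] * cells$weighted_n
  }
  cells$sex <- substr(cells$stratum, 1, 1)
  totals <- do.call(rbind, lapply(split(cells, cells$sex), function(d) {
    out <- data.frame(sex = d$sex[1], weighted_n = sum(d$weighted_n))
    for (cc in comp) {
      out[[paste0(cc, "_total")]] <- sum(d[[paste0(cc, "_total")]])
      out[[paste0(cc, "_avg")]] <- out[[paste0(cc, "_total")]] /
        out$weighted_n
      out[[paste0(cc, "_share_pct")]] <- 100 * out[[paste0(cc, "_total")]] /
        out$absenteeism_total
    }
    out
  }))
  rownames(totals) <- NULL
  wn_all <- sum(pc$survey_weight)
  structure(list(
    cells = cells[order(cells$stratum, cells$exposure_level), ],
    totals = totals,
    weighted_n = wn_all,
    coverage_pct = if (is.na(national_workforce)) NA_real_ else
      coverage_fraction(wn_all, national_workforce)),
    class = "cost_table")
}

#' Share of a cost component in the absenteeism total
#'
#' @param component_total,absenteeism_total totals in the same units.
#' @return share in percent.
#' @export
cost_share <- function(component_total, absenteeism_total) {
  100 * component_total / absenteeism_total
}

#' Coverage of the weighted sample
#'
#' @param weighted_n weighted sample size.
#' @param national_workforce national workforce count.
#' @return coverage in percent.
#' @export
coverage_fraction <- function(weighted_n, national_workforce) {
  100 * weighted_n / national_workforce
}

#' Hypothetical stress-reduction scenario
#'
#' Re-assigns a random fraction `f` of exposed follow-ups (drawn
#' proportionally within each exposure level) to the reference level — their
#' excess-duration costs become zero — and recomputes the weighted totals.
#'
#' @param person_costs as in [aggregate_costs()].
#' @param f fraction of exposed follow-ups re-assigned, in [0, 1].
#' @param seed RNG seed for the draw.
#' @return data.frame with the scenario totals and the percent reduction of
#'   the absenteeism and sickness-absence totals relative to `f = 0`.
#' @export
reduction_scenario <- function(person_costs, f, seed = 1L) {
  if (f < 0 || f > 1) stop("reduction fraction must lie in [0, 1]")
  base <- aggregate_costs(person_costs)
  base_abs <- sum(base$totals$absenteeism_total)
  base_sick <- sum(base$totals$sickness_absence_total)
  pc <- person_costs
  set.seed(seed)
  for (l in sort(unique(pc$exposure_level[pc$exposure_level > 0]))) {
    i <- which(pc$exposure_level == l)
    # a seeded permutation truncated at f keeps scenarios nested in f
    perm <- sample(i)
    k <- round(f * length(i))
    if (k > 0) {
      drop <- perm[seq_len(k)]
      pc$exposure_level[drop] <- 0L
      pc[drop, c("absenteeism", "sickness_absence", "unemployment",
                 "temporary_out")] <- 0
    }
  }
  if (!any(pc$exposure_level > 0)) {
    red <- data.frame(absenteeism_total = 0, sickness_absence_total = 0)
  } else {
    sc <- aggregate_costs(pc)
    red <- data.frame(absenteeism_total = sum(sc$totals$absenteeism_total),
                      sickness_absence_total =
                        sum(sc$totals$sickness_absence_total))
  }
  data.frame(
    f = f,
    absenteeism_total = red$absenteeism_total,
    sickness_absence_total = red$sickness_absence_total,
    absenteeism_reduction_pct = 100 * (1 - red$absenteeism_total / base_abs),
    sickness_reduction_pct = 100 * (1 - red$sickness_absence_total /
                                      base_sick))
}

#' @export
#' @method print cost_table
print.cost_table <- function(x, ...) {
  cat("Cost table:", nrow(x$cells), "stratum x exposure cells; weighted N =",
      format(round(x$weighted_n)), "\n")
  if (!is.na(x$coverage_pct))
    cat("Coverage:", round(x$coverage_pct, 1), "% of the national workforce\n")
  print(x$totals, digits = 5)
  invisible(x)
}
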