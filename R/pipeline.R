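#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the cohort source (a
#' [sim_config()] or paths to episode/baseline CSVs), horizon, resampling
#' effort, wage-layer inputs and reporting flags.
#'
#' @param sim a `sim_config` (synthetic run), or NULL when reading CSVs.
#' @param episodes_path,baseline_path CSV paths (ignored when `sim` given).
#' @param output_dir directory for result tables and the log.
#' @param horizon_days follow-up horizon (default 730).
#' @param n_resamples resampling draws for confidence intervals.
#' @param seed integer seed stamped on all outputs.
#' @param wage_bounds truncation bounds, EUR/hour.
#' @param cpi_table sex/age/year CPI data.frame (default: the synthetic
#'   series), or a CSV path.
#' @param national_workforce coverage denominator (default: the Danish
#'   full-time workforce in 2022).
#' @param part_time_included include part-time employees in the cost table
#'   (default FALSE: full-time, >= 95 percent arrangement, only).
#' @param crude_comparison also compute the crude comparator table.
#' @param reduction_fractions stress-reduction scenario fractions.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = NULL, episodes_path = NULL, baseline_path = NULL,
                       output_dir = "results", horizon_days = 730L,
                       n_resamples = 1000L, seed = 1L,
                       wage_bounds = wage_truncation_bounds(),
                       cpi_table = synthetic_cpi_table(),
                       national_workforce = 2275785,
                       part_time_included = FALSE,
                       crude_comparison = TRUE,
                       reduction_fractions = c(0.1, 0.5, 1.0)) {
  if (is.null(sim) && (is.null(episodes_path) || is.null(baseline_path)))
    stop("either a sim_config or both episodes_path and baseline_path ",
         "must be supplied")
  if (is.character(cpi_table)) {
    if (!file.exists(cpi_table))
      stop("configuration error: cpi_table file not found: ", cpi_table)
    cpi_table <- utils::read.csv(cpi_table, stringsAsFactors = FALSE)
  }
  if (!all(c("sex", "age_group", "year", "factor") %in% names(cpi_table)))
    stop("configuration error: cpi_table needs sex, age_group, year, factor")
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  structure(list(sim = sim, episodes_path = episodes_path,
                 baseline_path = baseline_path, output_dir = output_dir,
                 horizon_days = as.integer(horizon_days),
                 n_resamples = as.integer(n_resamples), seed = as.integer(seed),
                 wage_bounds = wage_bounds, cpi_table = cpi_table,
                 national_workforce = national_workforce,
                 part_time_included = isTRUE(part_time_included),
                 crude_comparison = isTRUE(crude_comparison),
                 reduction_fractions = reduction_fractions),
            class = "run_config")
}

#' Prepare the analysis-ready event history
#'
#' Censors episodes (horizon / age 65 / next follow-up / employer change),
#' builds the stabilized IPW-combined analysis weights and expands the
#' censored episodes into per-transition risk-set records.
#'
#' @param episodes tiled episode table.
#' @param baseline baseline table.
#' @param horizon_days censoring horizon.
#' @param log a function taking message strings (default `message`).
#' @return list with censored `episodes`, weighted `baseline` and
#'   `transition_records`.
#' @export
prepare_cohort <- function(episodes, baseline, horizon_days = 730L,
                           log = message) {
  if (!"stratum" %in% names(baseline))
    baseline$stratum <- assign_stratum(baseline$sex, baseline$age_at_start)
  log(sprintf("episodes in: %d (%d follow-ups)", nrow(episodes),
              nrow(baseline)))
  cens <- apply_censoring(episodes, baseline, horizon_days)
  log(sprintf("episodes after censoring: %d", nrow(cens)))
  baseline <- estimate_ipw(baseline)
  tr <- to_transition_records(cens, baseline)
  log(sprintf("transition records: %d (%d events)", nrow(tr),
              sum(tr$event_flag)))
  ev <- stats::aggregate(event_flag ~ from_state + to_state, tr, sum)
  for (i in seq_len(nrow(ev)))
    log(sprintf("  events %s->%s: %d", ev$from_state[i], ev$to_state[i],
                ev$event_flag[i]))
  list(episodes = cens, baseline = baseline, transition_records = tr)
}

#' Person-level standardized hourly wages at 2022 prices
#'
#' Aggregates each follow-up's work-episode payments and hours,
#' standardizes to a truncated hourly rate, imputes missing rates by
#' regression on sex, age group, education, sector and industry group, and
#' expresses everything at the 2022 price level.
#'
#' @param episodes censored episode table.
#' @param baseline baseline table (needs wage_year for the CPI lookup;
#'   missing column means already at 2022 prices).
#' @param cpi_table sex/age/year CPI factors.
#' @param bounds truncation bounds.
#' @return baseline with `hourly_rate` (EUR/h, 2022) and `wage_source`.
#' @export
person_wages <- function(episodes, baseline,
                         cpi_table = synthetic_cpi_table(),
                         bounds = wage_truncation_bounds()) {
  wk <- episodes[episodes$state == "work", , drop = FALSE]
  pay <- tapply(wk$payment, wk$follow_up_id, sum)
  hrs <- tapply(wk$hours, wk$follow_up_id, sum)
  i <- match(baseline$follow_up_id, names(pay))
  w <- standardize_hourly_wage(as.numeric(pay)[i], as.numeric(hrs)[i],
                               bounds)
  imp <- impute_missing_wages(w$rate, baseline, bounds)
  baseline$wage_source <- ifelse(is.na(imp$source), w$source, imp$source)
  rate <- imp$rate
  if ("wage_year" %in% names(baseline))
    rate <- adjust_to_price_level(rate, baseline$sex, baseline$age_group,
                                  baseline$wage_year, cpi_table)
  baseline$hourly_rate <- rate
  baseline
}

#' Cost table with resampling intervals from an ELMA fit
#'
#' Combines the fitted two-year duration differences with each exposed
#' individual's own hourly wage into annual per-employee cost components,
#' aggregates with survey weights, and propagates the duration resamples
#' into 95% intervals for the per-cell averages and per-sex totals.
#'
#' @param fit an `elma_fit`.
#' @param baseline output of [person_wages()] (needs stratum,
#'   exposure_level, sex, survey_weight, hourly_rate, arrangement).
#' @param national_workforce coverage denominator.
#' @param part_time_included if FALSE (default) only full-time employees
#'   enter the cost table.
#' @return list: `table` (a `cost_table`), `cells_ci`, `totals_ci`,
#'   `person_costs`.
#' @export
compute_costs <- function(fit, baseline, national_workforce = NA,
                          part_time_included = FALSE) {
  b <- baseline
  if (!part_time_included && "arrangement" %in% names(b))
    b <- b[b$arrangement == "full_time", , drop = FALSE]
  key <- paste(b$stratum, b$exposure_level)
  tab <- fit$table
  dk <- paste(tab$stratum, tab$exposure_level)
  delta <- matrix(0, nrow(b), 7, dimnames = list(NULL, elma_states()))
  for (st in elma_states()) {
    v <- stats::setNames(tab$delta[tab$state == st],
                         dk[tab$state == st])[key]
    delta[, st] <- ifelse(is.na(v), 0, v)
  }
  pc <- cbind(b[, c("follow_up_id", "stratum", "exposure_level", "sex",
                    "survey_weight")],
              annual_cost_per_employee(delta, b$hourly_rate))
  ct <- aggregate_costs(pc, national_workforce)
  ci <- cost_intervals(fit, b)
  list(table = ct, cells_ci = ci$cells, totals_ci = ci$totals,
       person_costs = pc)
}

# propagate per-stratum delta draws into cost CIs; within a cell the draw
# cost average is (7.4/2) * weighted-mean rate * delta draw, so draws are
# aggregated at cell level and combined linearly into sex totals
cost_intervals <- function(fit, b, hours_per_day = 7.4) {
  comp <- c(absenteeism = "work", sickness_absence = "sickness_absence",
            unemployment = "unemployment", temporary_out = "temporary_out")
  sgn <- c(absenteeism = -1, sickness_absence = 1, unemployment = 1,
           temporary_out = 1)
  k <- hours_per_day / 2
  cells <- list(); draws_by_cell <- list()
  for (s in names(fit$draws)) {
    dr <- fit$draws[[s]] # draws x level x state
    for (l in 1:3) {
      i <- which(b$stratum == s & b$exposure_level == l)
      if (!length(i)) next
      wsum <- sum(b$survey_weight[i])
      wrate <- sum(b$survey_weight[i] * b$hourly_rate[i]) / wsum
      cd <- sapply(names(comp), function(cc)
        sgn[cc] * k * wrate * dr[, l + 1, comp[cc]])
      id <- paste(s, l)
      draws_by_cell[[id]] <- list(sex = substr(s, 1, 1), wsum = wsum,
                                  draws = cd)
      qs <- apply(cd, 2, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE)
      cells[[id]] <- data.frame(
        stratum = s, exposure_level = l,
        t(stats::setNames(qs[1, ], paste0(names(comp), "_avg_lo"))),
        t(stats::setNames(qs[2, ], paste0(names(comp), "_avg_hi"))))
    }
  }
  totals <- lapply(c("M", "F"), function(sx) {
    sel <- Filter(function(d) d$sex == sx, draws_by_cell)
    if (!length(sel)) return(NULL)
    wtot <- sum(vapply(sel, `[[`, 1.0, "wsum"))
    avg <- Reduce(`+`, lapply(sel, function(d) d$wsum * d$draws)) / wtot
    qs <- apply(avg, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    data.frame(sex = sx,
               t(stats::setNames(qs[1, ], paste0(names(comp), "_avg_lo"))),
               t(stats::setNames(qs[2, ], paste0(names(comp), "_avg_hi"))))
  })
  list(cells = do.call(rbind, c(cells, make.row.names = FALSE)),
       totals = do.call(rbind, c(totals, make.row.names = FALSE)))
}

#' Run the full pipeline
#'
#' simulate (or load) -> prepare -> estimate -> cost -> report, writing all
#' tables as CSV plus a plain-text formatted report and a log, every file
#' stamped with the seed and a configuration hash. Deterministic given the
#' configuration.
#'
#' @param config a [run_config()].
#' @return list with the duration table, cost tables, crude comparison,
#'   scenario report and file paths, invisibly also written to
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  stamp <- sprintf("seed=%d config=%s", config$seed, config_hash(config))

  cohort <- if (!is.null(config$sim)) {
    simulate_cohort(config$sim)
  } else {
    list(episodes = utils::read.csv(config$episodes_path,
                                    stringsAsFactors = FALSE),
         baseline = utils::read.csv(config$baseline_path,
                                    stringsAsFactors = FALSE),
         truth = NULL)
  }
  prep <- prepare_cohort(cohort$episodes, cohort$baseline,
                         config$horizon_days, log = log)
  fit <- elma(prep$transition_records, prep$baseline,
              horizon_days = config$horizon_days,
              n_resamples = config$n_resamples, seed = config$seed)
  wages <- person_wages(prep$episodes, prep$baseline,
                        cpi_table = config$cpi_table,
                        bounds = config$wage_bounds)
  costs <- compute_costs(fit, wages,
                         national_workforce = config$national_workforce,
                         part_time_included = config$part_time_included)
  crude <- if (config$crude_comparison)
    crude_durations(prep$episodes, prep$baseline)
  scenarios <- if (length(config$reduction_fractions))
    do.call(rbind, lapply(config$reduction_fractions, function(f)
      reduction_scenario(costs$person_costs, f, seed = config$seed)))

  paths <- list(
    durations = file.path(config$output_dir, "state_durations.csv"),
    costs_cells = file.path(config$output_dir, "costs_cells.csv"),
    costs_totals = file.path(config$output_dir, "costs_totals.csv"),
    report = file.path(config$output_dir, "report.txt"),
    log = file.path(config$output_dir, "run.log"))
  write_stamped_csv(fit$table, paths$durations, stamp)
  write_stamped_csv(merge(costs$table$cells, costs$cells_ci,
                          by = c("stratum", "exposure_level"),
                          all.x = TRUE, sort = TRUE),
                    paths$costs_cells, stamp)
  write_stamped_csv(merge(costs$table$totals, costs$totals_ci, by = "sex"),
                    paths$costs_totals, stamp)
  if (!is.null(crude)) {
    paths$crude <- file.path(config$output_dir, "crude_durations.csv")
    write_stamped_csv(crude, paths$crude, stamp)
  }
  if (!is.null(scenarios)) {
    paths$scenarios <- file.path(config$output_dir, "reduction_scenarios.csv")
    write_stamped_csv(scenarios, paths$scenarios, stamp)
  }
  writeLines(c(paste("#", stamp),
               format_duration_table(fit$table, crude),
               "", format_cost_report(costs$table)), paths$report)
  writeLines(c(paste("#", stamp), log_lines), paths$log)

  invisible(list(fit = fit, costs = costs, crude = crude,
                 scenarios = scenarios, paths = paths, stamp = stamp))
}

config_hash <- function(config) {
  cfg <- config
  cfg$output_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste("#", stamp), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Format the state-duration table as plain text
#'
#' One reference row (expected days, 95% CI) per stratum and signed
#' difference rows for 1-3 indicators, with the crude comparator alongside
#' when supplied.
#'
#' @param tab the duration table of an `elma_fit`.
#' @param crude optional [crude_durations()] table.
#' @return character vector of report lines.
#' @export
format_duration_table <- function(tab, crude = NULL) {
  states <- recurrent_states()
  lines <- c("Expected days per state over the two-year follow-up",
             paste(" (ELMA: days and 95% CI; signed rows are differences",
                   "against the 0-indicator reference)"))
  fmt <- function(x, ref) {
    s <- sprintf(if (ref) "%.1f" else "%+.1f", x)
    s
  }
  for (s in unique(tab$stratum)) {
    lines <- c(lines, "", paste0("Stratum ", s))
    for (l in 0:3) {
      d <- tab[tab$stratum == s & tab$exposure_level == l, ]
      d <- d[match(states, d$state), ]
      ref <- l == 0
      vals <- if (ref) d$days else d$delta
      lo <- if (ref) d$ci_low else d$delta_ci_low
      hi <- if (ref) d$ci_high else d$delta_ci_high
      cr <- if (!is.null(crude)) {
        cd <- crude[crude$stratum == s & crude$exposure_level == l, ]
        cd <- cd[match(states, cd$state), ]
        if (ref) cd$crude_days else
          cd$crude_days - crude$crude_days[crude$stratum == s &
                                             crude$exposure_level == 0][
            match(states, crude$state[crude$stratum == s &
                                        crude$exposure_level == 0])]
      }
      cells <- vapply(seq_along(states), function(k) {
        base <- sprintf("%s %s (%s-%s)", states[k], fmt(vals[k], ref),
                        sprintf("%.1f", lo[k]), sprintf("%.1f", hi[k]))
        if (!is.null(cr) && !is.na(cr[k]))
          base <- paste0(base, sprintf(" [crude %s]", fmt(cr[k], ref)))
        base
      }, "")
      lines <- c(lines, sprintf("  %s: %s",
                                if (ref) "Ref 0 of 3" else
                                  sprintf("%d of 3", l),
                                paste(cells, collapse = "; ")))
    }
  }
  lines
}

#' Format the cost table as plain text
#'
#' @param ct a `cost_table`.
#' @return character vector of report lines.
#' @export
format_cost_report <- function(ct) {
  lines <- c("Annual standardized costs of work absenteeism per full-time",
             "employee (EUR, 2022 prices) and weighted totals")
  for (i in seq_len(nrow(ct$cells))) {
    d <- ct$cells[i, ]
    lines <- c(lines, sprintf(
      "  %s, %d of 3: absenteeism %.1f; sickness %.1f; unemployment %.1f; temporary out %.1f",
      d$stratum, d$exposure_level, d$absenteeism_avg,
      d$sickness_absence_avg, d$unemployment_avg, d$temporary_out_avg))
  }
  for (i in seq_len(nrow(ct$totals))) {
    d <- ct$totals[i, ]
    lines <- c(lines, sprintf(
      "  Total %s: avg %.1f EUR/employee/year; total %.1f MEUR/year; sickness share %.0f%%",
      d$sex, d$absenteeism_avg, d$absenteeism_total / 1e6,
      d$sickness_absence_share_pct))
  }
  if (!is.na(ct$coverage_pct))
    lines <- c(lines, sprintf("  Coverage: %.0f%% of the national workforce",
                              ct$coverage_pct))
  lines
}
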