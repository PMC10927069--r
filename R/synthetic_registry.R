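#' Simulation configuration for a synthetic register cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' defaults emulate a Danish-style employee cohort followed for two years
#' (730 days) across six sex-by-age strata, with per-stratum work-stress
#' indicator counts, exposure-dependent transition intensities, log-normal
#' hourly wages and survey/register weights. All rates are per day.
#'
#' The default generator matrices are calibrated so that reference-group
#' state occupancies are of realistic register magnitude (roughly 700 of 730
#' days in work for men aged 35-49, with sickness absence around 16 days and
#' rare absorbing events); exposure multiplies the work-to-sickness intensity
#' by hazard ratios 1.5, 1.75 and 2.0 at indicator counts 1, 2 and 3 and the
#' work-to-unemployment intensity by 1.2, 1.4 and 1.6.
#'
#' @param n_persons number of persons to simulate.
#' @param horizon_days follow-up length in days (default 730).
#' @param strata character vector of stratum labels, `"sex:lo-hi"`.
#' @param stratum_prob sampling probability per stratum (defaults to the
#'   composition of a large Danish employee sample).
#' @param level_prob 6 x 4 matrix of exposure-count probabilities
#'   (rows = strata, columns = 0..3 indicators).
#' @param indicator_margins per-stratum length-3 marginal prevalences of the
#'   three indicators (self-perceived stress, Cohen-4 work stress, job
#'   strain), used to pick which indicators are positive given the count.
#' @param stress_model `"count"` (default) draws the indicator count from
#'   `level_prob`; `"independent"` draws the three indicators independently
#'   at `indicator_margins`.
#' @param q_list list of four 7x7 generator matrices (exposure levels 0..3),
#'   or `NULL` to build them from `base_q`/`exposure_hr`.
#' @param base_q reference-level generator matrix (level 0).
#' @param exposure_hr named list mapping `"from->to"` to a length-4 vector of
#'   hazard ratios by exposure level (level 0 must be 1).
#' @param stratum_multipliers named list per stratum of named intensity
#'   multipliers (`"from->to"` = factor) applied on top of `base_q`.
#' @param start_prob start-state distribution over the four recurrent states.
#' @param wage_meanlog,wage_sdlog log-normal hourly wage parameters (EUR/h),
#'   per stratum (named vector) or scalar.
#' @param missing_wage_fraction fraction of persons with no observed wage.
#' @param target_population total the survey weights are calibrated to sum
#'   to (the weighted number of employees the sample represents).
#' @param confounding list with `or_smoking` (multiplicative tilt of the
#'   exposure-count distribution per level for smokers) and `hr_smoking`
#'   (multiplier on the work-to-sickness intensity for smokers); both 1 by
#'   default, i.e. no unmeasured structure beyond exposure.
#' @param seed integer RNG seed; the cohort is a deterministic function of
#'   the configuration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_persons,
                       horizon_days = 730L,
                       strata = default_strata(),
                       stratum_prob = default_stratum_prob(),
                       level_prob = default_level_prob(),
                       indicator_margins = default_indicator_margins(),
                       stress_model = c("count", "independent"),
                       q_list = NULL,
                       base_q = default_base_q(),
                       exposure_hr = default_exposure_hr(),
                       stratum_multipliers = default_stratum_multipliers(),
                       start_prob = c(work = 0.93, sickness_absence = 0.02,
                                      unemployment = 0.01, temporary_out = 0.04),
                       wage_meanlog = default_wage_meanlog(),
                       wage_sdlog = 0.35,
                       missing_wage_fraction = 0.05,
                       target_population = 1230754,
                       confounding = list(or_smoking = 1, hr_smoking = 1),
                       seed = 1L) {
  stress_model <- match.arg(stress_model)
  stopifnot(n_persons >= 1, horizon_days >= 1,
            abs(sum(start_prob) - 1) < 1e-8,
            missing_wage_fraction >= 0, missing_wage_fraction <= 1)
  if (any(level_prob < 0) || any(abs(rowSums(level_prob) - 1) > 1e-6))
    stop("level_prob rows must be probability vectors")
  if (any(indicator_margins < 0) || any(indicator_margins > 1))
    stop("indicator prevalences must lie in [0, 1]")
  if (is.null(q_list)) {
    q_list <- lapply(strata, function(s) {
      q_s <- apply_intensity_multipliers(base_q, stratum_multipliers[[s]])
      build_generator_matrices(q_s, exposure_hr)
    })
    names(q_list) <- strata
  } else {
    # a flat list of 4 applies to every stratum
    if (!is.null(dim(q_list[[1]]))) q_list <- stats::setNames(
      rep(list(q_list), length(strata)), strata)
  }
  for (s in names(q_list)) for (Q in q_list[[s]]) validate_generator(Q)
  structure(list(
    n_persons = as.integer(n_persons), horizon_days = as.integer(horizon_days),
    strata = strata, stratum_prob = stratum_prob, level_prob = level_prob,
    indicator_margins = indicator_margins, stress_model = stress_model,
    q_list = q_list, start_prob = start_prob,
    wage_meanlog = wage_meanlog, wage_sdlog = wage_sdlog,
    missing_wage_fraction = missing_wage_fraction,
    target_population = target_population,
    confounding = confounding, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_strata <- function() {
  c("M:18-34", "M:35-49", "M:50-64", "F:18-34", "F:35-49", "F:50-64")
}

#' @rdname sim_config
#' @export
default_stratum_prob <- function() {
  n <- c(3730, 8593, 9797, 5226, 12437, 12980)
  stats::setNames(n / sum(n), default_strata())
}

#' @rdname sim_config
#' @export
default_level_prob <- function() {
  m <- rbind(
    "M:18-34" = c(71, 20, 7, 2),
    "M:35-49" = c(70, 19, 7, 3),
    "M:50-64" = c(74, 17, 6, 3),
    "F:18-34" = c(63, 21, 11, 5),
    "F:35-49" = c(66, 20, 10, 4),
    "F:50-64" = c(69, 18, 9, 4))
  sweep(m, 1, rowSums(m), "/")
}

#' @rdname sim_config
#' @export
default_indicator_margins <- function() {
  m <- rbind(
    "M:18-34" = c(0.11, 0.18, 0.13),
    "M:35-49" = c(0.12, 0.17, 0.15),
    "M:50-64" = c(0.10, 0.15, 0.13),
    "F:18-34" = c(0.17, 0.23, 0.17),
    "F:35-49" = c(0.16, 0.20, 0.15),
    "F:50-64" = c(0.15, 0.18, 0.15))
  colnames(m) <- c("self_perceived", "cohen4", "job_strain")
  m
}

#' Default reference-level generator matrix
#'
#' Per-day transition intensities for the reference group (no work-stress
#' indicators), calibrated to realistic register occupancies: frequent short
#' sickness-absence spells, rare long unemployment spells, occasional
#' temporary-out spells and rare absorbing events.
#'
#' @return 7x7 intensity matrix, rows summing to zero, absorbing rows zero.
#' @export
default_base_q <- function() {
  st <- elma_states()
  Q <- matrix(0, 7, 7, dimnames = list(st, st))
  Q["work", "sickness_absence"] <- 2.8e-3
  Q["work", "unemployment"] <- 8.0e-5
  Q["work", "temporary_out"] <- 4.5e-4
  Q["work", "retirement"] <- 4e-6
  Q["work", "disability_pension"] <- 1e-6
  Q["work", "death"] <- 1e-6
  Q["sickness_absence", "work"] <- 0.12
  Q["sickness_absence", "unemployment"] <- 5e-4
  Q["sickness_absence", "temporary_out"] <- 3e-4
  Q["sickness_absence", "retirement"] <- 1e-5
  Q["sickness_absence", "disability_pension"] <- 2e-5
  Q["sickness_absence", "death"] <- 1e-5
  Q["unemployment", "work"] <- 0.015
  Q["unemployment", "sickness_absence"] <- 1e-3
  Q["unemployment", "temporary_out"] <- 1e-3
  Q["unemployment", "retirement"] <- 5e-6
  Q["unemployment", "disability_pension"] <- 2e-6
  Q["unemployment", "death"] <- 2e-6
  Q["temporary_out", "work"] <- 0.04
  Q["temporary_out", "sickness_absence"] <- 5e-4
  Q["temporary_out", "unemployment"] <- 1e-3
  Q["temporary_out", "retirement"] <- 5e-6
  Q["temporary_out", "disability_pension"] <- 2e-6
  Q["temporary_out", "death"] <- 2e-6
  diag(Q) <- -rowSums(Q)
  Q
}

#' @rdname default_base_q
#' @export
default_exposure_hr <- function() {
  list("work->sickness_absence" = c(1, 1.5, 1.75, 2.0),
       "work->unemployment" = c(1, 1.2, 1.4, 1.6))
}

#' @rdname default_base_q
#' @export
default_stratum_multipliers <- function() {
  list(
    "M:18-34" = c("work->unemployment" = 1.9, "work->temporary_out" = 9),
    "M:35-49" = c(),
    "M:50-64" = c("work->sickness_absence" = 1.35,
                  "work->unemployment" = 1.2,
                  "work->temporary_out" = 0.33, "work->retirement" = 30,
                  "sickness_absence->retirement" = 10),
    "F:18-34" = c("work->sickness_absence" = 1.6, "work->unemployment" = 2.1,
                  "work->temporary_out" = 12, "temporary_out->work" = 0.65),
    "F:35-49" = c("work->sickness_absence" = 1.9, "work->unemployment" = 1.7,
                  "work->temporary_out" = 2.1),
    "F:50-64" = c("work->sickness_absence" = 1.85,
                  "work->unemployment" = 1.95,
                  "work->temporary_out" = 0.33, "work->retirement" = 25,
                  "sickness_absence->retirement" = 8))
}

#' @rdname sim_config
#' @export
default_wage_meanlog <- function() {
  stats::setNames(log(c(24, 30, 31, 20, 23, 24)), default_strata())
}

apply_intensity_multipliers <- function(Q, mult) {
  if (is.null(mult) || length(mult) == 0) return(Q)
  for (nm in names(mult)) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
    Q[ft[1], ft[2]] <- Q[ft[1], ft[2]] * mult[[nm]]
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Build exposure-level generator matrices from a reference matrix
#'
#' @param base_q reference (level 0) intensity matrix.
#' @param exposure_hr named list `"from->to"` -> hazard ratios for levels 0..3.
#' @return list of four intensity matrices.
#' @export
build_generator_matrices <- function(base_q, exposure_hr = default_exposure_hr()) {
  lapply(0:3, function(l) {
    Q <- base_q
    for (nm in names(exposure_hr)) {
      ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
      Q[ft[1], ft[2]] <- Q[ft[1], ft[2]] * exposure_hr[[nm]][l + 1]
    }
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    Q
  })
}

#' Validate a 7-state generator matrix
#'
#' Checks nonnegative off-diagonals, zero row sums, zero out-rows for the
#' three absorbing states and zeros on all non-permitted transitions.
#'
#' @param Q 7x7 matrix with rows/columns in [elma_states()] order.
#' @return `Q`, invisibly; stops on violation.
#' @export
validate_generator <- function(Q) {
  st <- elma_states()
  if (!is.matrix(Q) || !all(dim(Q) == c(7, 7)))
    stop("Q must be a 7x7 matrix")
  dimnames(Q) <- list(st, st)
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("negative off-diagonal intensity in Q")
  if (any(abs(rowSums(Q)) > 1e-10)) stop("rows of Q must sum to zero")
  if (any(off[absorbing_states(), ] != 0))
    stop("absorbing states must have zero out-rows")
  allowed <- matrix(FALSE, 7, 7, dimnames = list(st, st))
  pt <- permitted_transitions()
  allowed[cbind(pt$from, pt$to)] <- TRUE
  if (any(off[!allowed] != 0))
    stop("Q has intensity on a non-permitted transition")
  invisible(Q)
}

#' Closed-form expected state durations for a homogeneous Markov chain
#'
#' For a continuous-time Markov chain with generator `Q` and initial
#' distribution `pi`, the expected time in state k over `[0, horizon]` is the
#' k-th component of \eqn{\pi^T \int_0^T e^{Qt} dt}. The integral is computed
#' exactly (to matrix-exponential accuracy) via the augmented-matrix identity
#' \eqn{\exp\left(\begin{smallmatrix}Q & I\\ 0 & 0\end{smallmatrix}\right)T}
#' whose upper-right block is \eqn{\int_0^T e^{Qt} dt}.
#'
#' @param Q 7x7 (or d x d) generator matrix.
#' @param pi initial state distribution (sums to 1).
#' @param horizon integration horizon in days.
#' @return named vector of expected days per state; sums to `horizon`.
#' @export
true_expected_durations <- function(Q, pi, horizon) {
  d <- nrow(Q)
  if (length(pi) != d) stop("pi must have one entry per state")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (d == 7) validate_generator(Q) else {
    off <- Q; diag(off) <- 0
    if (any(off < 0) || any(abs(rowSums(Q)) > 1e-10))
      stop("invalid generator matrix")
  }
  M <- rbind(cbind(Q, diag(d)), matrix(0, d, 2 * d))
  E <- as.vector(pi %*% as.matrix(Matrix::expm(M * horizon))[1:d, (d + 1):(2 * d)])
  names(E) <- if (!is.null(rownames(Q))) rownames(Q) else NULL
  E
}

# one continuous-time trajectory, day-rounded to half-open episodes.
# Day d is labelled with the state occupied at its start (time d), so a jump
# at continuous time t takes effect from day ceiling(t); the last of several
# sub-day jumps wins. Absorbing states occupy the remaining days.
simulate_person_path <- function(Q, start_state, horizon) {
  t <- 0; cur <- start_state
  times <- 0; states <- cur
  repeat {
    r <- -Q[cur, cur]
    if (r <= 0) break
    t <- t + stats::rexp(1, r)
    if (t >= horizon) break
    p <- Q[cur, ]; p[cur] <- 0
    cur <- sample.int(7L, 1L, prob = p)
    times <- c(times, t); states <- c(states, cur)
  }
  eff_day <- as.integer(ceiling(times))
  keep <- !duplicated(eff_day, fromLast = TRUE) & eff_day < horizon
  starts <- eff_day[keep]; st <- states[keep]
  if (length(st) > 1) { # merge runs of identical day-states
    same <- c(FALSE, st[-1] == st[-length(st)])
    starts <- starts[!same]; st <- st[!same]
  }
  list(start = starts, end = c(starts[-1], as.integer(horizon)),
       state = as.integer(st))
}

#' Simulate a synthetic survey + register cohort
#'
#' Draws per-person stratum, work-stress indicators, baseline covariates,
#' wages and weights, then simulates each labor-market trajectory as an exact
#' sample from the continuous-time Markov chain with the person's
#' exposure-specific generator matrix, discretized to whole days (each day is
#' labelled with the state occupied at the start of the day). Episodes tile
#' `[0, horizon)` without gaps or overlaps.
#'
#' @param config a [sim_config()] object.
#' @return object of class `synthetic_cohort`: list with `episodes`
#'   (person_id, follow_up_id, start_day, end_day, state, hours, payment),
#'   `baseline` (one row per follow-up with stratum, indicators, covariates,
#'   weights, wage and start state) and `truth` (per stratum x exposure level,
#'   the closed-form expected days per state).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  H <- config$horizon_days
  strata <- config$strata
  st_names <- elma_states()

  stratum <- sample(strata, n, replace = TRUE, prob = config$stratum_prob)
  sex <- substr(stratum, 1, 1)
  age_band <- substr(stratum, 3, 7)
  age_lo <- as.numeric(substr(age_band, 1, 2))
  age_hi <- as.numeric(substr(age_band, 4, 5))
  age_at_start <- floor(stats::runif(n, age_lo, age_hi + 1))
  age_at_start <- pmin(age_at_start, 64)

  covs <- simulate_covariates(n)

  # exposure level and indicator triple
  level <- integer(n)
  ind <- matrix(0L, n, 3,
                dimnames = list(NULL, c("self_perceived", "cohen4", "job_strain")))
  for (s in strata) {
    i <- which(stratum == s)
    if (!length(i)) next
    if (config$stress_model == "independent") {
      for (k in 1:3) ind[i, k] <- stats::rbinom(length(i), 1L,
                                                config$indicator_margins[s, k])
      level[i] <- rowSums(ind[i, , drop = FALSE])
    } else {
      pl <- config$level_prob[s, ]
      or <- config$confounding$or_smoking
      if (!is.null(or) && or != 1) {
        smoker <- covs$smoking[i] == "smoker"
        lv <- integer(length(i))
        tilt <- pl * or^(0:3); tilt <- tilt / sum(tilt)
        ns <- sum(!smoker)
        if (ns) lv[!smoker] <- sample(0:3, ns, TRUE, prob = pl)
        if (any(smoker)) lv[smoker] <- sample(0:3, sum(smoker), TRUE, prob = tilt)
        level[i] <- lv
      } else {
        level[i] <- sample(0:3, length(i), TRUE, prob = pl)
      }
      m <- config$indicator_margins[s, ]
      for (j in i[level[i] > 0]) {
        k <- level[j]
        pick <- if (k == 3) 1:3 else sample.int(3L, k, prob = m)
        ind[j, pick] <- 1L
      }
    }
  }

  start_state <- sample.int(4L, n, TRUE, prob = config$start_prob)

  # trajectories
  ep_list <- vector("list", n)
  hrs <- config$confounding$hr_smoking
  for (p in seq_len(n)) {
    Q <- config$q_list[[stratum[p]]][[level[p] + 1]]
    if (!is.null(hrs) && hrs != 1 && covs$smoking[p] == "smoker") {
      Q["work", "sickness_absence"] <- Q["work", "sickness_absence"] * hrs
      diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    }
    ep_list[[p]] <- simulate_person_path(Q, start_state[p], H)
  }
  n_ep <- vapply(ep_list, function(e) length(e$state), 1L)
  episodes <- data.frame(
    person_id = rep(seq_len(n), n_ep),
    follow_up_id = rep(seq_len(n), n_ep),
    start_day = unlist(lapply(ep_list, `[[`, "start")),
    end_day = unlist(lapply(ep_list, `[[`, "end")),
    state = st_names[unlist(lapply(ep_list, `[[`, "state"))],
    stringsAsFactors = FALSE)

  # wages, hours and payments
  meanlog <- config$wage_meanlog
  if (length(meanlog) == 1) meanlog <- stats::setNames(rep(meanlog, length(strata)), strata)
  wage <- stats::rlnorm(n, meanlog[stratum], config$wage_sdlog)
  arrangement_frac <- c("full_time" = 1, "medium" = 0.8, "low" = 0.4)[covs$arrangement]
  days <- episodes$end_day - episodes$start_day
  frac <- arrangement_frac[episodes$person_id]
  episodes$hours <- ifelse(episodes$state == "work", 7.4 * days * frac,
                    ifelse(episodes$state %in% recurrent_states(),
                           7.4 * days * frac * 0.9, 0))
  episodes$payment <- ifelse(episodes$state == "work",
                             wage[episodes$person_id] * episodes$hours,
                      ifelse(episodes$state %in% recurrent_states(),
                             0.6 * wage[episodes$person_id] * episodes$hours, 0))

  wage_missing <- stats::runif(n) < config$missing_wage_fraction
  # a missing wage observation: the register carries hours but no usable
  # payment for the person's work episodes
  episodes$payment[episodes$state == "work" &
                     wage_missing[episodes$person_id]] <- NA_real_
  sw <- stats::rlnorm(n, 0, 0.3)
  sw <- sw * config$target_population / sum(sw)
  rw <- stats::rlnorm(n, 0, 0.2)

  baseline <- data.frame(
    person_id = seq_len(n), follow_up_id = seq_len(n),
    sex = sex, age_group = age_band, age_at_start = age_at_start,
    self_perceived = ind[, 1], cohen4 = ind[, 2], job_strain = ind[, 3],
    exposure_level = level,
    covs,
    survey_weight = sw, register_weight = rw,
    start_state = st_names[start_state],
    employer_id = sprintf("emp%04d", sample.int(2600L, n, TRUE)),
    hourly_wage = ifelse(wage_missing, NA_real_, wage),
    wage_year = sample(2012:2020, n, TRUE),
    stringsAsFactors = FALSE)

  truth <- do.call(rbind, lapply(strata, function(s) {
    do.call(rbind, lapply(0:3, function(l) {
      E <- true_expected_durations(config$q_list[[s]][[l + 1]],
                                   c(config$start_prob, 0, 0, 0), H)
      data.frame(stratum = s, exposure_level = l, state = st_names,
                 expected_days = unname(E), stringsAsFactors = FALSE)
    }))
  }))

  structure(list(episodes = episodes, baseline = baseline, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

# nine baseline covariates with explicit "not_available" levels where the
# source questionnaires leave gaps, plus industry group (wage imputation)
simulate_covariates <- function(n) {
  samp <- function(lev, p) sample(lev, n, TRUE, prob = p)
  data.frame(
    bmi = samp(c("underweight", "normal", "overweight", "obese", "not_available"),
               c(0.01, 0.48, 0.30, 0.13, 0.08)),
    smoking = samp(c("nonsmoker", "smoker", "not_available"),
                   c(0.77, 0.19, 0.04)),
    alcohol = samp(c("none", "moderate", "high", "not_available"),
                   c(0.19, 0.39, 0.37, 0.05)),
    physical_activity = samp(c("no", "yes"), c(0.58, 0.42)),
    disease_treatment = samp(c("no", "yes", "not_available"),
                             c(0.34, 0.15, 0.51)),
    arrangement = samp(c("full_time", "medium", "low"), c(0.76, 0.21, 0.03)),
    sector = samp(c("private", "public"), c(0.45, 0.55)),
    education = samp(c("low", "middle", "high", "not_available"),
                     c(0.10, 0.40, 0.49, 0.01)),
    n_waves = samp(c("1of4", "2of4", "3of4", "4of4"),
                   c(0.73, 0.17, 0.05, 0.05)),
    industry_group = samp(paste0("ind", 1:8),
                          c(0.2, 0.17, 0.15, 0.13, 0.12, 0.1, 0.08, 0.05)),
    stringsAsFactors = FALSE)
}

#' Write / read a synthetic cohort as plain-text files
#'
#' Episodes and baseline tables are written as UTF-8 CSVs with a header row
#' and ISO day indices; the closed-form truth vector as a JSON sidecar.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` the re-read
#'   list (without the config).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$episodes, file.path(dir, "episodes.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(
    episodes = utils::read.csv(file.path(dir, "episodes.csv"),
                               stringsAsFactors = FALSE),
    baseline = utils::read.csv(file.path(dir, "baseline.csv"),
                               stringsAsFactors = FALSE),
    truth = as.data.frame(jsonlite::read_json(file.path(dir, "truth.json"),
                                              simplifyVector = TRUE)))
}

#' Synthetic sex- and age-specific consumer price index table
#'
#' Deterministic stand-in for a national sex/age-specific CPI series
#' (2022 = 1): roughly 1.8 percent yearly inflation with small sex and age
#' offsets. Factors multiply a nominal wage to express it at the 2022 price
#' level.
#'
#' @param years integer vector of wage years.
#' @return data.frame with sex, age_group, year, factor.
#' @export
synthetic_cpi_table <- function(years = 2010:2022) {
  g <- expand.grid(sex = c("M", "F"),
                   age_group = c("18-34", "35-49", "50-64"),
                   year = years, stringsAsFactors = FALSE)
  drift <- 0.018 + 0.001 * (g$sex == "F") +
    0.0005 * match(g$age_group, c("18-34", "35-49", "50-64"))
  g$factor <- (1 + drift)^(2022 - g$year)
  g
}
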