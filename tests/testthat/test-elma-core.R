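trec <- function(entry, exit, event, level = 0, w = 1) {
  data.frame(follow_up_id = seq_along(entry), from_state = "work",
             to_state = "sickness_absence", entry_day = entry,
             exit_day = exit, event_flag = event, exposure_level = level,
             weight = w, stringsAsFactors = FALSE)
}

test_that("reference baseline increments are the Nelson-Aalen estimator", {
  # risk sets Y = (5, 4, 3), one event at each of days 1, 2, 3
  r <- trec(entry = rep(0, 5), exit = c(1, 2, 3, 4, 4),
            event = c(1, 1, 1, 0, 0))
  m <- fit_transition_hazard(r, "work", "sickness_absence")
  expect_equal(m$baseline$time, c(1, 2, 3))
  expect_equal(m$baseline$dA0, c(1 / 5, 1 / 4, 1 / 3))
  expect_equal(sum(m$baseline$dA0), 0.7833, tolerance = 1e-4)
  expect_equal(unname(m$beta), c(0, 0, 0))
})

test_that("zero events degenerate to a zero hazard with a warning", {
  r <- trec(entry = c(0, 0), exit = c(100, 200), event = c(0, 0))
  expect_warning(m <- fit_transition_hazard(r, "work", "sickness_absence"),
                 "no events")
  expect_equal(nrow(m$baseline), 0)
  expect_equal(unname(m$beta), c(0, 0, 0))
  expect_true("no_events" %in% m$flags)
})

test_that("two-group toy coefficient matches a partial-likelihood grid search", {
  # reference subjects with events at days 2 and 6, a level-1 subject with
  # an event at day 4 and one censored; no ties
  r <- trec(entry = rep(0, 4), exit = c(2, 6, 4, 8),
            event = c(1, 1, 1, 0), level = c(0, 0, 1, 1))
  m <- fit_transition_hazard(r, "work", "sickness_absence")
  # independent oracle: brute-force Breslow partial likelihood over a grid
  loglik <- function(b) {
    eta <- ifelse(r$exposure_level == 1, b, 0)
    ll <- 0
    for (i in which(r$event_flag == 1)) {
      at_risk <- r$exit_day >= r$exit_day[i]
      ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
    }
    ll
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, loglik, 1.0))]
  expect_equal(unname(m$beta["level1"]), b_grid, tolerance = 1e-3)
})

test_that("planted hazard ratios are recovered within 2 SE at n = 5000", {
  mods <- planted_fit()
  m <- mods[["work->sickness_absence"]]
  se <- sqrt(diag(m$vcov))
  expect_lt(abs(m$beta["level1"] - log(1.5)), 2 * se[1])
  expect_lt(abs(m$beta["level3"] - log(2.0)), 2 * se[3])
})

test_that("product integral is the identity at time zero and with no hazard", {
  mods <- fake_model_set()
  p <- transition_probability(mods, 0, point_mass("work"), 730,
                              return_P = TRUE)
  expect_equal(unname(p$occupation[1, ]), unname(point_mass("work")))
  E <- expected_durations(p)
  expect_equal(unname(E["work"]), 730)
  expect_equal(sum(E), 730)
})

test_that("dense constant hazard reproduces the exponential distribution", {
  lam <- 0.005
  times <- seq(0.1, 730, by = 0.1)
  mods <- fake_model_set(list("work->death" = fake_model(
    "work", "death", times, rep(lam * 0.1, length(times)))))
  p <- transition_probability(mods, 0, point_mass("work"), 730,
                              return_P = TRUE)
  for (t in c(100, 400, 730)) {
    i <- max(which(p$grid <= t)) + 1L
    P_wd <- p$P[1, 7, i]
    expect_equal(P_wd, 1 - exp(-lam * t), tolerance = 0.01)
  }
  # rows of P remain stochastic at every grid point
  m <- dim(p$P)[3]
  rs <- apply(p$P, 3, rowSums)
  expect_true(all(abs(rs - 1) < 1e-8))
  expect_true(all(p$P >= 0 & p$P <= 1 + 1e-12))
})

test_that("compiled product integral agrees with the dense R reference", {
  mods <- planted_fit()
  pg <- elma:::pooled_grid(mods)
  for (lev in c(0, 2)) {
    inc <- elma:::sweep_cols(pg$inc0, elma:::exp_beta(mods, lev))
    pi0 <- c(0.9, 0.03, 0.02, 0.05, 0, 0, 0)
    cpp <- aj_path_cpp(inc, pg$from, pg$to, pi0, pg$grid, 730)
    ref <- aj_reference(inc, pg$from, pg$to, pi0, pg$grid, 730)
    expect_equal(as.numeric(cpp$durations), ref$durations, tolerance = 1e-10)
    expect_equal(unname(cpp$occupation[nrow(cpp$occupation), ]),
                 ref$occupation, tolerance = 1e-10)
  }
})

test_that("occupation probabilities conserve mass and durations sum to 730", {
  mods <- planted_fit()
  for (lev in 0:3) {
    p <- transition_probability(mods, lev, point_mass("work"), 730)
    expect_true(all(abs(rowSums(p$occupation) - 1) < 1e-8))
    E <- expected_durations(p)
    expect_equal(sum(E), 730, tolerance = 1e-6)
    expect_equal(unname(E), as.numeric(p$durations_cpp), tolerance = 1e-10)
  }
})

test_that("raising the work-to-sickness hazard shifts days from work to sickness", {
  lam <- 0.003
  times <- 1:730
  base_inc <- rep(lam, 730)
  mk <- function(mult) fake_model_set(list(
    "work->sickness_absence" = fake_model("work", "sickness_absence",
                                          times, base_inc * mult),
    "sickness_absence->work" = fake_model("sickness_absence", "work",
                                          times, rep(0.08, 730))))
  E1 <- expected_durations(transition_probability(mk(1), 0,
                                                  point_mass("work"), 730))
  E2 <- expected_durations(transition_probability(mk(2), 0,
                                                  point_mass("work"), 730))
  expect_lt(E2["work"], E1["work"])
  expect_gt(E2["sickness_absence"], E1["sickness_absence"])
})

test_that("duration differences are zero at reference and conserve days", {
  mods <- planted_fit()
  E <- t(vapply(0:3, function(l) expected_durations(
    transition_probability(mods, l, point_mass("work"), 730)), numeric(7)))
  d <- duration_differences(E)
  expect_true(all(d[1, ] == 0))
  expect_true(all(abs(rowSums(d)) < 1e-8))
  # planted positive work->sickness hazard ratios force the sign pattern
  expect_lt(d[4, "work"], 0)
  expect_gt(d[4, "sickness_absence"], 0)
})

test_that("resampling intervals contain the point estimate and shrink to zero width", {
  mods <- planted_fit()
  pi0 <- point_mass("work")
  ci <- confidence_intervals(mods, pi0, n_resamples = 200, seed = 9)
  E <- t(vapply(0:3, function(l) expected_durations(
    transition_probability(mods, l, pi0, 730)), numeric(7)))
  # point estimates inside the envelope for the four recurrent states
  for (l in 1:4) for (st in recurrent_states()) {
    expect_lte(ci$E_ci_low[l, st], E[l, st] + 1e-6)
    expect_gte(ci$E_ci_high[l, st], E[l, st] - 1e-6)
  }
  # no-noise limit: zero coefficient variance and fixed baseline
  mods0 <- lapply(mods, function(m) { m$vcov <- matrix(0, 3, 3); m })
  class(mods0) <- "transition_models"
  ci0 <- confidence_intervals(mods0, pi0, n_resamples = 50, seed = 2,
                              include_baseline = FALSE)
  expect_equal(ci0$E_ci_low, ci0$E_ci_high, tolerance = 1e-10)
  expect_equal(ci0$E_ci_low[1, "work"], unname(E[1, "work"]),
               tolerance = 1e-6)
})

test_that("crude durations average observed days per employee", {
  ep <- data.frame(person_id = c(1, 2), follow_up_id = c(1, 2),
                   start_day = c(0, 0), end_day = c(730, 730),
                   state = c("work", "sickness_absence"),
                   hours = 0, payment = 0)
  b <- data.frame(follow_up_id = c(1, 2), stratum = "M:35-49",
                  exposure_level = 0)
  cr <- crude_durations(ep, b)
  expect_equal(cr$crude_days[cr$state == "work"], 365)
  expect_equal(cr$crude_days[cr$state == "sickness_absence"], 365)
  # degenerate cohort: identical trajectories make crude exact
  expect_equal(sum(cr$crude_days), 730)
})

test_that("ELMA and crude agree on uncensored homogeneous data", {
  co <- homog_cohort()
  pr <- records_of(co)
  fit <- suppressWarnings(
    elma(pr$records, pr$baseline, n_resamples = 20, seed = 4))
  cr <- crude_durations(pr$episodes, pr$baseline)
  # pooled over levels (homogeneous generator): compare reference cell
  for (st in c("work", "sickness_absence", "temporary_out")) {
    e <- fit$table$days[fit$table$state == st &
                          fit$table$exposure_level == 0]
    c0 <- cr$crude_days[cr$state == st & cr$exposure_level == 0]
    expect_equal(e, c0, tolerance = 0.05)
  }
})
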