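# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

# single-stratum homogeneous cohort: every exposure level shares the
# reference generator, so the closed-form oracle applies marginally
homog_config <- function(n = 5000, seed = 101) {
  sim_config(n_persons = n, strata = "M:35-49",
             stratum_prob = c("M:35-49" = 1),
             exposure_hr = list(), missing_wage_fraction = 0, seed = seed)
}

# single-stratum cohort with the planted work->sickness hazard ratios
planted_config <- function(n = 5000, seed = 2) {
  sim_config(n_persons = n, strata = "M:35-49",
             stratum_prob = c("M:35-49" = 1), seed = seed)
}

homog_cohort <- function() fixture("homog_cohort", function()
  simulate_cohort(homog_config()))

planted_cohort <- function() fixture("planted_cohort", function()
  simulate_cohort(planted_config()))

# censored records with unit weights (no confounding in these cohorts)
records_of <- function(cohort, horizon = 730L) {
  cens <- apply_censoring(cohort$episodes, cohort$baseline, horizon)
  b <- cohort$baseline
  b$weight <- 1
  list(episodes = cens, baseline = b,
       records = to_transition_records(cens, b))
}

homog_fit <- function() fixture("homog_fit", function() {
  pr <- records_of(homog_cohort())
  suppressWarnings(fit_transition_hazards(pr$records))
})

planted_fit <- function() fixture("planted_fit", function() {
  pr <- records_of(planted_cohort())
  suppressWarnings(fit_transition_hazards(pr$records))
})

# independent pure-R product-integral reference (dense matrix products)
aj_reference <- function(inc, from, to, pi, grid, horizon) {
  S <- length(pi)
  P <- diag(S)
  E <- numeric(S)
  tprev <- 0
  p <- pi
  for (i in seq_along(grid)) {
    E <- E + p * (grid[i] - tprev)
    tprev <- grid[i]
    dA <- matrix(0, S, S)
    for (k in seq_along(from)) dA[from[k], to[k]] <- dA[from[k], to[k]] + inc[i, k]
    rs <- rowSums(dA)
    for (s in which(rs > 1)) dA[s, ] <- dA[s, ] / rs[s]
    diag(dA) <- diag(dA) - pmin(rowSums(dA), 1)
    P <- P %*% (diag(S) + dA)
    p <- as.numeric(pi %*% P)
  }
  E <- E + p * (horizon - tprev)
  list(P = P, occupation = p, durations = E)
}

# hand-built transition model (for synthetic hazard scenarios)
fake_model <- function(from, to, times, dA0, beta = c(0, 0, 0),
                       denom = rep(1e12, length(times))) {
  structure(list(from = from, to = to,
                 beta = stats::setNames(beta, paste0("level", 1:3)),
                 vcov = matrix(0, 3, 3),
                 baseline = data.frame(time = times, dA0 = dA0,
                                       denom = denom),
                 n_events = length(times), flags = character(0)),
            class = "transition_model")
}

# a full 24-arrow model set with zero hazards everywhere except overrides
fake_model_set <- function(overrides = list()) {
  pt <- permitted_transitions()
  models <- lapply(seq_len(nrow(pt)), function(k) {
    key <- paste0(pt$from[k], "->", pt$to[k])
    if (!is.null(overrides[[key]])) overrides[[key]] else
      fake_model(pt$from[k], pt$to[k], numeric(0), numeric(0))
  })
  names(models) <- paste0(pt$from, "->", pt$to)
  structure(models, class = "transition_models")
}

point_mass <- function(state) {
  p <- stats::setNames(numeric(7), elma_states())
  p[state] <- 1
  p
}
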