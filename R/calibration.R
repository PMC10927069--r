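#' Coverage experiment for the resampling confidence intervals
#'
#' Repeatedly simulates a single-stratum cohort from a known generator,
#' runs the estimation pipeline (censoring, transition records, Cox fits,
#' product-integral durations, resampling intervals) and records whether
#' the 95% intervals cover the closed-form expected durations. Used to
#' check the calibration of the interval construction at reduced scale.
#'
#' @param n_persons cohort size per replicate.
#' @param n_replicates number of simulation replicates.
#' @param n_resamples resampling draws per replicate.
#' @param levels exposure levels monitored (reference must come first).
#' @param states state names monitored.
#' @param stratum single stratum simulated.
#' @param seed master seed; per-replicate seeds are drawn from it.
#' @param config_args extra arguments passed to [sim_config()].
#' @return list with `coverage` (levels x states, fraction of replicates
#'   covering the oracle), `truth`, `n_replicates` and the per-replicate
#'   interval bounds.
#' @export
ci_coverage_experiment <- function(n_persons = 1000, n_replicates = 200,
                                   n_resamples = 200, levels = c(0, 1),
                                   states = c("work", "sickness_absence"),
                                   stratum = "M:35-49", seed = 1L,
                                   config_args = list()) {
  set.seed(seed)
  seeds_sim <- sample.int(2147483646L - 1L, n_replicates)
  seeds_ci <- sample.int(2147483646L - 1L, n_replicates)
  cfg0 <- do.call(sim_config, c(list(
    n_persons = n_persons, strata = stratum,
    stratum_prob = stats::setNames(1, stratum), seed = 1L), config_args))
  truth <- vapply(levels, function(l) true_expected_durations(
    cfg0$q_list[[stratum]][[l + 1]], c(cfg0$start_prob, 0, 0, 0),
    cfg0$horizon_days), numeric(7))
  rownames(truth) <- elma_states()
  lo <- hi <- array(NA_real_,
                    c(n_replicates, length(levels), length(states)),
                    dimnames = list(NULL, paste0("level", levels), states))
  for (r in seq_len(n_replicates)) {
    cfg <- cfg0
    cfg$seed <- seeds_sim[r]
    co <- simulate_cohort(cfg)
    cens <- apply_censoring(co$episodes, co$baseline, cfg$horizon_days)
    b <- co$baseline
    b$weight <- 1
    recs <- to_transition_records(cens, b)
    mods <- suppressWarnings(fit_transition_hazards(recs))
    pi_by_level <- t(vapply(levels, function(l) {
      ss <- b$start_state[b$exposure_level == l]
      if (!length(ss)) ss <- b$start_state
      as.numeric(table(factor(ss, levels = elma_states()))) / length(ss)
    }, numeric(7)))
    pi_n <- vapply(levels, function(l)
      sum(b$exposure_level == l), integer(1))
    ci <- confidence_intervals(mods, pi_by_level,
                               n_resamples = n_resamples,
                               seed = seeds_ci[r],
                               horizon_days = cfg$horizon_days,
                               levels = levels, pi_n = pi_n)
    lo[r, , ] <- ci$E_ci_low[, states]
    hi[r, , ] <- ci$E_ci_high[, states]
  }
  cov <- matrix(NA_real_, length(levels), length(states),
                dimnames = list(paste0("level", levels), states))
  for (li in seq_along(levels)) for (si in seq_along(states))
    cov[li, si] <- mean(lo[, li, si] <= truth[states[si], li] &
                          truth[states[si], li] <= hi[, li, si])
  list(coverage = cov, truth = truth[states, , drop = FALSE],
       n_replicates = n_replicates, lower = lo, upper = hi)
}
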