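test_that("hourly standardization truncates at the published bounds", {
  w <- standardize_hourly_wage(c(1000, 30, 3000), c(100, 10, 10))
  expect_equal(w$rate, c(10, 6.72, 268.63))
  expect_equal(w$source, c("observed", "truncated_low", "truncated_high"))
  # zero hours with positive payment is a missing rate, to be imputed
  w0 <- standardize_hourly_wage(500, 0)
  expect_true(is.na(w0$rate))
  expect_equal(w0$source, "missing")
  expect_error(standardize_hourly_wage(-1, 10), "negative payment")
})

test_that("truncation never leaves the published interval", {
  set.seed(1)
  w <- standardize_hourly_wage(stats::rlnorm(500, 5, 3),
                               stats::rlnorm(500, 2, 1))
  b <- wage_truncation_bounds()
  expect_true(all(w$rate >= b["low"] & w$rate <= b["high"]))
})

make_wage_covs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sex = sample(c("M", "F"), n, TRUE),
    age_group = sample(c("18-34", "35-49", "50-64"), n, TRUE),
    education = sample(c("low", "middle", "high"), n, TRUE),
    sector = sample(c("private", "public"), n, TRUE),
    industry_group = sample(paste0("ind", 1:4), n, TRUE),
    stringsAsFactors = FALSE)
}

test_that("wage imputation recovers exactly under a noiseless model", {
  n <- 300
  cv <- make_wage_covs(n)
  logw <- 3 + 0.1 * (cv$sex == "F") + 0.05 * (cv$age_group == "50-64") +
    0.2 * (cv$education == "high") - 0.1 * (cv$sector == "public") +
    0.03 * as.integer(sub("ind", "", cv$industry_group))
  rate <- exp(logw)
  miss <- seq(1, n, by = 5)
  r_in <- rate; r_in[miss] <- NA
  out <- impute_missing_wages(r_in, cv)
  expect_equal(out$rate[miss], rate[miss], tolerance = 1e-8)
  expect_true(all(out$source[miss] == "imputed"))
  # with nothing missing the input is returned untouched
  out2 <- impute_missing_wages(rate, cv)
  expect_identical(out2$rate, rate)
})

test_that("imputation error scales with the wage noise", {
  n <- 2000
  cv <- make_wage_covs(n, seed = 4)
  set.seed(9)
  sigma <- 0.3
  logw <- 3 + 0.2 * (cv$education == "high") + stats::rnorm(n, 0, sigma)
  rate <- exp(logw)
  miss <- sample(n, 500)
  r_in <- rate; r_in[miss] <- NA
  out <- impute_missing_wages(r_in, cv)
  rmse <- sqrt(mean((out$rate[miss] - rate[miss])^2))
  expect_lt(abs(rmse - sigma * mean(rate)) / (sigma * mean(rate)), 0.2)
})

test_that("unseen covariate levels fall back to the stratum mean", {
  cv <- make_wage_covs(50)
  rate <- rep(20, 50)
  rate[1] <- NA
  cv$industry_group[1] <- "ind99"
  expect_warning(out <- impute_missing_wages(rate, cv), "unseen")
  expect_equal(out$rate[1], 20, tolerance = 1e-8)
})

test_that("price indexing multiplies by the CPI factor", {
  cpi <- data.frame(sex = "M", age_group = "35-49", year = c(2012, 2022),
                    factor = c(1.10, 1.00))
  expect_equal(adjust_to_price_level(10, "M", "35-49", 2022, cpi), 10)
  expect_equal(adjust_to_price_level(10, "M", "35-49", 2012, cpi), 11)
  expect_error(adjust_to_price_level(10, "F", "35-49", 2012, cpi),
               "missing CPI")
  # a chained index equals the product of yearly factors
  yearly <- 1 + c(0.02, 0.03, 0.01)
  chained <- rev(cumprod(rev(yearly)))
  cpi2 <- data.frame(sex = "M", age_group = "35-49", year = 2019:2022,
                     factor = c(chained, 1))
  expect_equal(adjust_to_price_level(10, "M", "35-49", 2019, cpi2),
               10 * prod(yearly))
})

test_that("annual costs follow the 7.4-hour, half-delta arithmetic", {
  d <- stats::setNames(numeric(7), elma_states())
  d["work"] <- -10; d["sickness_absence"] <- 10
  cc <- annual_cost_per_employee(d, 20)
  expect_equal(cc$absenteeism, 20 * 7.4 * 5)
  expect_equal(cc$sickness_absence, 740)
  expect_equal(cc$unemployment, 0)
  # zero differences cost nothing
  cc0 <- annual_cost_per_employee(stats::setNames(numeric(7), elma_states()),
                                  35)
  expect_true(all(as.numeric(cc0) == 0))
  # more workdays than the reference appear as negative cost (savings)
  d2 <- stats::setNames(numeric(7), elma_states()); d2["work"] <- 10
  expect_equal(annual_cost_per_employee(d2, 20)$absenteeism, -740)
})

test_that("cost components obey the absorbing-remainder accounting identity", {
  set.seed(3)
  d <- matrix(stats::rnorm(7 * 20, 0, 5), 20, 7,
              dimnames = list(NULL, elma_states()))
  d[, "work"] <- -rowSums(d[, -1]) # days conserved
  rate <- stats::runif(20, 10, 40)
  cc <- annual_cost_per_employee(d, rate)
  remainder <- rate * 3.7 * (d[, "retirement"] + d[, "disability_pension"] +
                               d[, "death"])
  expect_equal(cc$absenteeism,
               cc$sickness_absence + cc$unemployment + cc$temporary_out +
                 remainder, tolerance = 1e-10)
})

person_costs_toy <- function() {
  data.frame(
    follow_up_id = 1:6,
    stratum = rep(c("M:35-49", "F:35-49"), each = 3),
    exposure_level = rep(c(0, 1, 2), 2),
    sex = rep(c("M", "F"), each = 3),
    survey_weight = c(10, 20, 30, 10, 40, 20),
    absenteeism = c(0, 100, 200, 0, 300, 400),
    sickness_absence = c(0, 60, 120, 0, 200, 280),
    unemployment = c(0, 30, 60, 0, 80, 100),
    temporary_out = c(0, 10, 20, 0, 20, 20))
}

test_that("aggregation weights averages and reproduces the published shares", {
  ct <- aggregate_costs(person_costs_toy(), national_workforce = 260)
  m <- ct$totals[ct$totals$sex == "M", ]
  expect_equal(m$absenteeism_total, 20 * 100 + 30 * 200)
  expect_equal(m$absenteeism_avg, 8000 / 50)
  # single employee with weight one: total equals the per-employee cost
  single <- person_costs_toy()[2, ]; single$survey_weight <- 1
  ct1 <- aggregate_costs(single)
  expect_equal(ct1$totals$absenteeism_total, 100)
  expect_equal(ct1$totals$absenteeism_avg, 100)
  # published-totals identities recomputed by the aggregation operations
  expect_equal(round(cost_share(1141.9, 1903.0)), 60)
  expect_equal(round(cost_share(580.7, 868.5)), 67)
  expect_equal(round(coverage_fraction(1230754, 2275785)), 54)
  expect_equal(ct$coverage_pct, 100 * 130 / 260)
})

test_that("weighted totals are invariant to proportional stratum splits", {
  pc <- person_costs_toy()
  ct <- aggregate_costs(pc)
  split_pc <- rbind(pc, pc)
  split_pc$survey_weight <- split_pc$survey_weight / 2
  split_pc$stratum <- paste0(split_pc$stratum,
                             rep(c("a", "b"), each = nrow(pc)))
  # keep the sex prefix intact for the totals grouping
  split_pc$follow_up_id <- seq_len(nrow(split_pc))
  ct2 <- aggregate_costs(split_pc)
  expect_equal(sum(ct2$totals$absenteeism_total),
               sum(ct$totals$absenteeism_total), tolerance = 1e-10)
  expect_equal(ct2$totals$absenteeism_avg[ct2$totals$sex == "M"],
               ct$totals$absenteeism_avg[ct$totals$sex == "M"],
               tolerance = 1e-10)
})

test_that("reduction scenarios are monotone with f = 0 a no-op and f = 1 total", {
  set.seed(8)
  n <- 400
  pc <- data.frame(
    follow_up_id = 1:n,
    stratum = sample(c("M:35-49", "F:35-49"), n, TRUE),
    exposure_level = sample(0:3, n, TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
    survey_weight = stats::runif(n, 1, 3))
  pc$sex <- substr(pc$stratum, 1, 1)
  pc$absenteeism <- ifelse(pc$exposure_level > 0,
                           100 * pc$exposure_level, 0)
  pc$sickness_absence <- 0.6 * pc$absenteeism
  pc$unemployment <- 0.3 * pc$absenteeism
  pc$temporary_out <- 0.1 * pc$absenteeism
  r0 <- reduction_scenario(pc, 0, seed = 2)
  expect_equal(r0$absenteeism_reduction_pct, 0)
  r1 <- reduction_scenario(pc, 1, seed = 2)
  expect_equal(r1$absenteeism_reduction_pct, 100)
  expect_equal(r1$sickness_reduction_pct, 100)
  red <- vapply(c(0, 0.1, 0.5, 1),
                function(f) reduction_scenario(pc, f,
                                               seed = 2)$absenteeism_reduction_pct,
                1.0)
  expect_true(all(diff(red) >= -1e-9))
  expect_error(reduction_scenario(pc, 1.5), "0, 1")
})
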