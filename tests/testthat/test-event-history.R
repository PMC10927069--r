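raw_row <- function(fu, a, b, state, hours = 0, pay = 0, person = fu) {
  data.frame(person_id = person, follow_up_id = fu, start_day = a,
             end_day = b, state = state, hours = hours, payment = pay,
             stringsAsFactors = FALSE)
}

test_that("simultaneous payments resolve by most recorded hours", {
  raw <- rbind(raw_row(1, 0, 10, "work", hours = 5, pay = 100),
               raw_row(1, 0, 10, "sickness_absence", hours = 3, pay = 50))
  ep <- build_episodes(raw)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$state, "work")
  expect_equal(ep$hours, 5)
})

test_that("absorbing states are prioritized over recurrent payments", {
  raw <- rbind(raw_row(1, 0, 10, "work", hours = 5, pay = 100),
               raw_row(1, 5, 10, "death"))
  ep <- build_episodes(raw)
  expect_equal(ep$state, c("work", "death"))
  expect_equal(ep$start_day, c(0L, 5L))
})

test_that("a single wage record becomes a single work episode", {
  ep <- build_episodes(raw_row(1, 0, 730, "work", hours = 5402, pay = 1e5))
  expect_equal(nrow(ep), 1)
  expect_equal(c(ep$start_day, ep$end_day), c(0L, 730L))
  expect_equal(ep$state, "work")
})

test_that("records dated after an absorbing onset are rejected", {
  raw <- rbind(raw_row(1, 0, 100, "work", hours = 10),
               raw_row(1, 100, 730, "death"),
               raw_row(1, 200, 210, "work", hours = 5))
  expect_error(build_episodes(raw), "absorbing state onset")
})

test_that("unpaid gap days inherit the preceding state", {
  raw <- rbind(raw_row(1, 0, 100, "work", hours = 10, pay = 100),
               raw_row(1, 150, 300, "sickness_absence", hours = 8, pay = 50))
  ep <- build_episodes(raw)
  expect_equal(ep$state, c("work", "sickness_absence"))
  expect_equal(ep$start_day, c(0L, 150L)) # vacation days stay with work
  expect_equal(ep$end_day, c(150L, 300L))
  expect_equal(sum(ep$hours), 18)
})

test_that("censoring stops at the first competing event", {
  ep <- raw_row(1, 0, 730, "work", hours = 100, pay = 1000)
  fu <- data.frame(follow_up_id = 1, age_at_start = 40)
  # no competing events: horizon
  expect_equal(apply_censoring(ep, fu)$end_day, 730L)
  # age 65 reached around day 400
  fu65 <- data.frame(follow_up_id = 1,
                     age_at_start = 65 - 400 / 365.25)
  out <- apply_censoring(ep, fu65)
  expect_equal(out$end_day, 400L)
  expect_equal(out$hours, 100 * 400 / 730)
  # new employer id registered day 200
  fu_emp <- data.frame(follow_up_id = 1, age_at_start = 40,
                       employer_change_day = 200)
  expect_equal(apply_censoring(ep, fu_emp)$end_day, 200L)
  # next follow-up starts day 300
  fu_next <- data.frame(follow_up_id = 1, age_at_start = 40,
                        next_followup_day = 300)
  expect_equal(apply_censoring(ep, fu_next)$end_day, 300L)
})

test_that("day accounting is conserved under censoring", {
  co <- simulate_cohort(sim_config(n_persons = 200, seed = 77))
  b <- co$baseline
  b$employer_change_day <- ifelse(seq_len(nrow(b)) %% 3 == 0, 250, NA)
  cens <- apply_censoring(co$episodes, b)
  len <- tapply(cens$end_day - cens$start_day, cens$follow_up_id, sum)
  age65 <- ceiling((65 - b$age_at_start) * 365.25)
  expected <- pmin(730, age65, ifelse(is.na(b$employer_change_day), Inf,
                                      b$employer_change_day))
  expect_equal(as.numeric(len),
               as.numeric(expected[match(names(len), b$follow_up_id)]))
})

test_that("transition records enumerate the six destinations per episode", {
  ep <- rbind(raw_row(1, 0, 100, "work"),
              raw_row(1, 100, 200, "sickness_absence"))
  fu <- data.frame(follow_up_id = 1, exposure_level = 2, weight = 1.5)
  tr <- to_transition_records(ep, fu)
  w <- tr[tr$from_state == "work", ]
  expect_equal(nrow(w), 6)
  expect_equal(sum(w$event_flag), 1)
  expect_equal(w$to_state[w$event_flag == 1], "sickness_absence")
  expect_true(all(w$entry_day == 0 & w$exit_day == 100))
  expect_true(all(tr$exposure_level == 2 & tr$weight == 1.5))
  # final episode is censored: all flags zero
  s <- tr[tr$from_state == "sickness_absence", ]
  expect_equal(nrow(s), 6)
  expect_equal(sum(s$event_flag), 0)
})

test_that("a work-sickness-work-retirement path yields 18 records, 3 events", {
  # each recurrent state has six out-arrows, so three recurrent episodes
  # expand to 3 x 6 records; the absorbing retirement episode emits none
  ep <- rbind(raw_row(1, 0, 100, "work"),
              raw_row(1, 100, 150, "sickness_absence"),
              raw_row(1, 150, 400, "work"),
              raw_row(1, 400, 730, "retirement"))
  fu <- data.frame(follow_up_id = 1, exposure_level = 0)
  tr <- to_transition_records(ep, fu)
  expect_equal(nrow(tr), 18)
  expect_equal(sum(tr$event_flag), 3)
  expect_true(all(paste(tr$from_state, tr$to_state) %in%
                    paste(permitted_transitions()$from,
                          permitted_transitions()$to)))
})

test_that("an absorbing episode with a successor is rejected", {
  ep <- rbind(raw_row(1, 0, 100, "death"),
              raw_row(1, 100, 200, "work"))
  fu <- data.frame(follow_up_id = 1, exposure_level = 0)
  expect_error(to_transition_records(ep, fu), "absorbing")
})

test_that("event count equals the number of state changes on simulated data", {
  co <- simulate_cohort(sim_config(n_persons = 150, seed = 13))
  pr <- records_of(co)
  changes <- sum(tapply(pr$episodes$state, pr$episodes$follow_up_id,
                        length) - 1)
  expect_equal(sum(pr$records$event_flag), changes)
  expect_true(all(pr$records$entry_day < pr$records$exit_day))
})
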