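#' Resolve raw dated payment records into one-state-per-day episodes
#'
#' Register extracts carry overlapping dated payment/benefit records. This
#' resolves them to a single labor-market state per day: absorbing states are
#' prioritized over recurrent states (death over disability pension over
#' retirement when several absorbing records coincide); among simultaneous
#' recurrent payments the one with the most recorded hours (per day) wins;
#' days with no payment record inherit the preceding state (registers contain
#' no leisure-time records, so vacation days are carried by the prior state);
#' a leading gap inherits the first observed state. Contiguous same-state
#' days are merged into maximal half-open episodes `[start_day, end_day)`.
#'
#' @param raw_records data.frame with columns person_id, follow_up_id,
#'   start_day, end_day (half-open integer days), state, hours, payment.
#' @return episode data.frame tiling `[0, max end_day)` per follow-up.
#' @section Errors: a recurrent record starting at or after the onset of an
#'   absorbing state for the same follow-up is rejected with a diagnostic
#'   (absorbing states are terminal).
#' @export
build_episodes <- function(raw_records) {
  req <- c("person_id", "follow_up_id", "start_day", "end_day",
           "state", "hours", "payment")
  if (!all(req %in% names(raw_records)))
    stop("raw_records must have columns: ", paste(req, collapse = ", "))
  if (any(raw_records$start_day >= raw_records$end_day))
    stop("records must satisfy start_day < end_day")
  state_code(raw_records$state) # validates names
  out <- lapply(split(raw_records, raw_records$follow_up_id),
                resolve_one_followup)
  ep <- do.call(rbind, out)
  rownames(ep) <- NULL
  ep
}

resolve_one_followup <- function(rr) {
  abs_pr <- absorbing_priority()
  is_abs <- rr$state %in% names(abs_pr)
  if (any(is_abs)) {
    onset <- min(rr$start_day[is_abs])
    bad <- !is_abs & rr$start_day >= onset
    if (any(bad))
      stop("follow-up ", rr$follow_up_id[1], ": ", sum(bad),
           " record(s) dated after an absorbing state onset at day ", onset)
  }
  brk <- sort(unique(c(0L, rr$start_day, rr$end_day)))
  ns <- length(brk) - 1L
  seg_state <- character(ns); seg_hours <- numeric(ns); seg_pay <- numeric(ns)
  per_day_hours <- rr$hours / (rr$end_day - rr$start_day)
  per_day_pay <- rr$payment / (rr$end_day - rr$start_day)
  for (i in seq_len(ns)) {
    a <- brk[i]; b <- brk[i + 1L]
    act <- which(rr$start_day <= a & rr$end_day >= b)
    if (!length(act)) { seg_state[i] <- NA_character_; next }
    aa <- act[rr$state[act] %in% names(abs_pr)]
    win <- if (length(aa)) {
      aa[which.max(abs_pr[rr$state[aa]])]
    } else {
      act[which.max(per_day_hours[act])]
    }
    seg_state[i] <- rr$state[win]
    seg_hours[i] <- per_day_hours[win] * (b - a)
    seg_pay[i] <- per_day_pay[win] * (b - a)
  }
  # gap segments inherit the preceding state; a leading gap the following one
  if (anyNA(seg_state)) {
    filled <- seg_state
    for (i in seq_len(ns)) if (is.na(filled[i]) && i > 1) filled[i] <- filled[i - 1]
    for (i in rev(seq_len(ns))) if (is.na(filled[i]) && i < ns) filled[i] <- filled[i + 1]
    if (anyNA(filled)) stop("follow-up ", rr$follow_up_id[1],
                            ": no payment record at all")
    seg_state <- filled
  }
  run <- cumsum(c(TRUE, seg_state[-1] != seg_state[-ns]))
  data.frame(
    person_id = rr$person_id[1], follow_up_id = rr$follow_up_id[1],
    start_day = as.integer(brk[-(ns + 1)][!duplicated(run)]),
    end_day = as.integer(tapply(brk[-1], run, max)),
    state = seg_state[!duplicated(run)],
    hours = as.numeric(tapply(seg_hours, run, sum)),
    payment = as.numeric(tapply(seg_pay, run, sum)),
    stringsAsFactors = FALSE)
}

#' Censor episodes at the first competing event
#'
#' Follow-up ends at the first of: the two-year horizon, the day the person
#' turns 65, the start of the person's next follow-up period, or the day a
#' new employer id is registered.
#'
#' @param episodes episode table for one or more follow-ups.
#' @param followup baseline table with follow_up_id and age_at_start, and
#'   optionally next_followup_day and employer_change_day (NA = absent).
#' @param horizon_days administrative horizon (default 730).
#' @return truncated episode table; follow-ups with censor day 0 vanish.
#' @export
apply_censoring <- function(episodes, followup, horizon_days = 730L) {
  i <- match(episodes$follow_up_id, followup$follow_up_id)
  if (anyNA(i)) stop("episodes reference unknown follow_up_id")
  age65_day <- ceiling(round((65 - followup$age_at_start) * 365.25, 6))
  cens <- pmin(horizon_days, age65_day[i],
               get_or_inf(followup, "next_followup_day")[i],
               get_or_inf(followup, "employer_change_day")[i])
  keep <- episodes$start_day < cens
  out <- episodes[keep, , drop = FALSE]
  cens <- cens[keep]
  clip <- out$end_day > cens
  if (any(clip)) {
    frac <- (pmin(out$end_day, cens) - out$start_day) /
      (out$end_day - out$start_day)
    out$hours <- out$hours * frac
    out$payment <- out$payment * frac
    out$end_day <- as.integer(pmin(out$end_day, cens))
  }
  rownames(out) <- NULL
  out
}

get_or_inf <- function(df, col) {
  if (col %in% names(df)) {
    v <- df[[col]]
    v[is.na(v)] <- Inf
    v
  } else rep(Inf, nrow(df))
}

#' Expand censored episodes into per-transition risk-set records
#'
#' For each recurrent episode `[a, b)` in state h, one record is emitted for
#' each of the six permitted destinations j, with `entry_day = a`,
#' `exit_day = b` and `event_flag = 1` only for the destination actually
#' entered at day b (all zero when the episode ends by censoring). Time is
#' days since follow-up start (clock-forward), shared across recurrent
#' visits. Episodes in absorbing states emit no records; an absorbing episode
#' with a successor is rejected.
#'
#' @param episodes censored, tiled episode table.
#' @param followup baseline table with follow_up_id, exposure_level and
#'   optionally weight (combined analysis weight, default 1).
#' @return data.frame with follow_up_id, from_state, to_state, entry_day,
#'   exit_day, event_flag, exposure_level, weight.
#' @export
to_transition_records <- function(episodes, followup) {
  ep <- episodes[order(episodes$follow_up_id, episodes$start_day), ,
                 drop = FALSE]
  n <- nrow(ep)
  same_fu <- c(ep$follow_up_id[-1] == ep$follow_up_id[-n], FALSE)
  nxt <- c(ep$state[-1], NA_character_)
  nxt[!same_fu] <- NA_character_
  if (any(ep$state %in% absorbing_states() & !is.na(nxt)))
    stop("absorbing-state episode with a successor")
  rec <- ep$state %in% recurrent_states()
  ep <- ep[rec, , drop = FALSE]; nxt <- nxt[rec]
  if (!nrow(ep)) return(empty_transition_records())
  dest <- lapply(ep$state, function(h) setdiff(elma_states(), h))
  out <- data.frame(
    follow_up_id = rep(ep$follow_up_id, each = 6L),
    from_state = rep(ep$state, each = 6L),
    to_state = unlist(dest, use.names = FALSE),
    entry_day = rep(ep$start_day, each = 6L),
    exit_day = rep(ep$end_day, each = 6L),
    event_flag = 0L, stringsAsFactors = FALSE)
  out$event_flag <- as.integer(!is.na(rep(nxt, each = 6L)) &
                                 out$to_state == rep(nxt, each = 6L))
  i <- match(out$follow_up_id, followup$follow_up_id)
  if (anyNA(i)) stop("episodes reference unknown follow_up_id")
  out$exposure_level <- followup$exposure_level[i]
  out$weight <- if ("weight" %in% names(followup)) followup$weight[i] else 1
  out
}

empty_transition_records <- function() {
  data.frame(follow_up_id = integer(0), from_state = character(0),
             to_state = character(0), entry_day = integer(0),
             exit_day = integer(0), event_flag = integer(0),
             exposure_level = integer(0), weight = numeric(0),
             stringsAsFactors = FALSE)
}

#' Check the episode tiling invariant
#'
#' Episodes of each follow-up must tile `[0, censor_day)` without gaps or
#' overlaps, with absorbing states terminal.
#'
#' @param episodes episode table.
#' @return TRUE invisibly; stops with a diagnostic otherwise.
#' @export
validate_episodes <- function(episodes) {
  sp <- split(episodes, episodes$follow_up_id)
  for (e in sp) {
    e <- e[order(e$start_day), ]
    if (any(e$start_day >= e$end_day))
      stop("follow-up ", e$follow_up_id[1], ": empty or inverted episode")
    if (nrow(e) > 1 && any(e$end_day[-nrow(e)] != e$start_day[-1]))
      stop("follow-up ", e$follow_up_id[1], ": episodes do not tile")
    ia <- which(e$state %in% absorbing_states())
    if (length(ia) && any(ia < nrow(e)))
      stop("follow-up ", e$follow_up_id[1], ": absorbing state not terminal")
  }
  invisible(TRUE)
}
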