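#' Count positive work-stress indicators
#'
#' The exposure is the number of positive indicators among self-perceived
#' work stress, the Cohen four-item work-stress scale and job strain:
#' 0 (reference), 1, 2 or 3.
#'
#' @param indicators matrix/data.frame with three 0/1 columns, or a length-3
#'   vector for a single follow-up.
#' @return integer vector of exposure levels 0..3. Follow-ups with a missing
#'   indicator are returned as NA with a warning; the caller excludes them.
#' @export
count_stress_indicators <- function(indicators) {
  m <- as.matrix(indicators)
  if (is.null(dim(indicators)) && length(indicators) == 3) m <- t(m)
  if (ncol(m) != 3) stop("exactly three indicators are required")
  ok <- is.na(m) | m == 0 | m == 1
  if (!all(ok)) stop("indicators must be 0, 1 or NA")
  lev <- as.integer(rowSums(m))
  if (anyNA(lev))
    warning(sum(is.na(lev)), " follow-up(s) with missing indicators ",
            "flagged for exclusion")
  lev
}

#' Assign the sex-by-age stratum
#'
#' Six subsamples by sex and age at follow-up start: 18-34, 35-49 and 50-64
#' years, boundaries inclusive.
#'
#' @param sex "M" or "F" (vectorized).
#' @param age_at_start age in whole years, within 18..64.
#' @return character vector of stratum labels, e.g. `"F:35-49"`.
#' @export
assign_stratum <- function(sex, age_at_start) {
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(age_at_start < 18 | age_at_start > 64))
    stop("age_at_start must lie in [18, 64]")
  band <- c("18-34", "35-49", "50-64")[
    findInterval(age_at_start, c(18, 35, 50))]
  paste0(sex, ":", band)
}

#' Stabilized inverse-probability exposure weights
#'
#' Per stratum, a multinomial logistic model of the exposure level (0..3) on
#' the nine baseline covariates gives propensities \eqn{\hat p(\ell | x)};
#' the stabilized weight is the marginal level frequency divided by the
#' propensity of the observed level. Propensities below `floor` are raised to
#' it (with a warning counting affected records) to avoid non-overlap blow-up.
#' The combined analysis weight multiplies the IPW with the register weight.
#'
#' @param followups baseline table with exposure_level, the nine covariates
#'   (bmi, smoking, alcohol, physical_activity, disease_treatment,
#'   arrangement, sector, education, n_waves), register_weight, and sex /
#'   age_group (or a stratum column).
#' @param floor propensity floor (default 0.001).
#' @return `followups` with columns ipw, register_weight and weight
#'   (= ipw x register_weight) appended/updated.
#' @export
estimate_ipw <- function(followups, floor = 0.001) {
  covars <- c("bmi", "smoking", "alcohol", "physical_activity",
              "disease_treatment", "arrangement", "sector", "education",
              "n_waves")
  miss <- setdiff(c(covars, "exposure_level"), names(followups))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"stratum" %in% names(followups))
    followups$stratum <- assign_stratum(followups$sex,
                                        followups$age_at_start)
  stratum <- followups$stratum
  ipw <- rep(NA_real_, nrow(followups))
  n_floored <- 0L
  for (s in unique(stratum)) {
    i <- which(stratum == s)
    d <- followups[i, c("exposure_level", covars)]
    d$exposure_level <- factor(d$exposure_level, levels = 0:3)
    # drop covariates that are constant within the stratum
    use <- covars[vapply(d[covars], function(x) length(unique(x)) > 1, TRUE)]
    marg <- as.numeric(prop.table(table(d$exposure_level)))
    if (sum(marg > 0) < 2 || length(use) == 0) {
      p_obs <- marg[followups$exposure_level[i] + 1]
    } else {
      fit <- nnet::multinom(
        stats::as.formula(paste("exposure_level ~", paste(use, collapse = "+"))),
        data = droplevels(d), trace = FALSE, maxit = 200)
      pr <- stats::predict(fit, newdata = droplevels(d), type = "probs")
      if (is.null(dim(pr))) { # two observed levels: vector of P(level 2)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- levels(droplevels(d$exposure_level))
      }
      lev_obs <- match(as.character(d$exposure_level), colnames(pr))
      if (anyNA(lev_obs)) stop("propensity prediction lost a level")
      p_obs <- pr[cbind(seq_len(nrow(pr)), lev_obs)]
      marg <- as.numeric(prop.table(table(droplevels(d$exposure_level))))[
        match(as.character(d$exposure_level), levels(droplevels(d$exposure_level)))]
      n_floored <- n_floored + sum(p_obs < floor)
      p_obs <- pmax(p_obs, floor)
      ipw[i] <- marg / p_obs
      next
    }
    n_floored <- n_floored + sum(p_obs < floor, na.rm = TRUE)
    p_obs <- pmax(p_obs, floor)
    ipw[i] <- marg[followups$exposure_level[i] + 1] / p_obs
  }
  if (n_floored > 0)
    warning(n_floored, " propensity value(s) truncated at the ", floor,
            " floor")
  followups$ipw <- ipw
  if (!"register_weight" %in% names(followups)) followups$register_weight <- 1
  followups$weight <- followups$ipw * followups$register_weight
  attr(followups, "n_floored") <- n_floored
  followups
}

#' Weighted standardized differences of a covariate across exposure groups
#'
#' Balance diagnostic for the IPW construction: for a categorical covariate,
#' the maximum absolute standardized difference of level prevalences between
#' the exposed (level > 0) and reference groups, under the supplied weights.
#'
#' @param x categorical covariate vector.
#' @param exposed logical: exposure level > 0.
#' @param w weights.
#' @return maximum absolute standardized difference over covariate levels.
#' @export
weighted_std_diff <- function(x, exposed, w) {
  lv <- unique(x)
  sdiff <- vapply(lv, function(l) {
    p1 <- sum(w[exposed] * (x[exposed] == l)) / sum(w[exposed])
    p0 <- sum(w[!exposed] * (x[!exposed] == l)) / sum(w[!exposed])
    v <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
    if (v <= 0) 0 else (p1 - p0) / sqrt(v)
  }, 1.0)
  max(abs(sdiff))
}
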