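# Discrete-time simulation engine shared by the observational cohort
# generator and the counterfactual oracle.
#
# Time convention: ICU day t indexes the interval [t, t+1) from admission
# (day 0).  Within a day the order is fixed: covariate update -> KDIGO
# staging -> treatment decision -> competing event draw.  A patient is
# "included" on the first day the combined KDIGO stage reaches 2; from
# that day on, follow-up intervals are f = t - inclusion_day = 0..29 and
# an event during interval f contributes to the cumulative incidence at
# grid time f + 1 (so 30-day mortality accumulates exactly 30 daily
# hazards).

# Absolute indication for RRT used by the death-hazard interaction:
# persisting oliguria, severe hyperkalaemia, oliguric acidosis, or
# profound acidosis.  This is what makes "early, unindicated" starts
# harmful and indicated starts beneficial in the default scenario.
rrt_indicated <- function(potassium, ph, uo_stage3, oliguric_stage2) {
  uo_stage3 | potassium >= 7.0 | (ph < 7.2 & oliguric_stage2) | ph < 7.0
}

# mode: "observational" draws RRT initiation from the logistic model;
#       "regime" forces initiation to follow `regime` exactly;
#       "never" never initiates.
# record: "person_day" returns full tables, "summary" one row per patient.
simulate_engine <- function(params, n, mode = c("observational", "regime", "never"),
                            regime = NULL, seed = NULL,
                            record = c("person_day", "summary")) {
  mode <- match.arg(mode)
  record <- match.arg(record)
  if (mode == "regime") {
    if (is.null(regime)) stop_param("regime", "required in regime mode")
    regime <- as.list(regime)
  }
  validate_scenario_params(params)
  if (n < 1) stop_param("n", "must be >= 1")
  with_seed(seed, {
    b <- params$baseline
    horizon <- params$horizon_days
    n <- as.integer(n)

    age <- pmin(pmax(rnorm(n, b$age_mean, b$age_sd), 18), 95)
    if (b$minor_rate > 0) {
      minors <- runif(n) < b$minor_rate
      age[minors] <- runif(sum(minors), 10, 17.9)
    }
    sex <- ifelse(runif(n) < b$prop_male, "M", "F")
    weight <- pmin(pmax(rnorm(n, b$weight_mean, b$weight_sd), 35), 180)
    weight[runif(n) < b$missing_weight_rate] <- NA_real_
    adm_sofa <- round(pmin(pmax(rnorm(n, b$sofa_mean, b$sofa_sd), 0), 24))
    adm_cat <- sample(c("medical", "surgical", "cardiac"), n,
                      replace = TRUE, prob = c(0.5, 0.35, 0.15))
    ckd <- runif(n) < b$ckd_rate
    rrt_hist <- runif(n) < b$rrt_history_rate
    dnr <- runif(n) < b$dnr_rate

    baseline <- data.table(
      patient_id = seq_len(n), age = age, sex = sex, weight = weight,
      admission_category = adm_cat, admission_sofa = adm_sofa,
      ckd_flag = ckd, rrt_history_flag = rrt_hist,
      dnr_restriction_flag = dnr)

    # day-0 covariates
    cr0 <- exp(rnorm(n, b$creat_log_mean, b$creat_log_sd))
    sev <- log(cr0) + rnorm(n, params$severity$log_ratio_mean,
                            params$severity$log_ratio_sd)
    st <- list(
      creat = cr0,
      potassium = rnorm(n, params$potassium$mu, params$potassium$sd),
      ph = rnorm(n, params$ph$mu, params$ph$sd),
      urine = pmax(rnorm(n, params$urine$mu, 0.25), 0),
      sofa = as.numeric(adm_sofa))
    st <- clamp_covariates(st)
    st$sofa <- round(st$sofa)

    incl_day <- rep(NA_integer_, n)
    crcrit <- rep(FALSE, n)   # creatinine criterion (stage >= 2) ever met
    olig2 <- rep(FALSE, n)    # urine-output stage-2 criterion ever met
    prev_uo_low <- rep(FALSE, n)  # yesterday's rate < 0.3
    rrt <- rep(FALSE, n)
    rrt_start_day <- rep(NA_integer_, n)
    event <- rep(0L, n)       # 0 none, 1 death, 2 discharge
    event_day <- rep(NA_integer_, n)
    active <- rep(TRUE, n)

    ini <- params$initiation; dth <- params$death; dis <- params$discharge
    rows <- if (record == "person_day") vector("list", horizon + 30L) else NULL

    max_day <- horizon + 29L
    for (t in 0:max_day) {
      idx <- which(active)
      if (!length(idx)) break
      if (t > 0) {
        ratio <- st$creat[idx] / cr0[idx]
        m <- length(idx)
        lcr <- log(st$creat[idx])
        lcr <- lcr + params$creatinine$revert * (sev[idx] - lcr) +
          rnorm(m, 0, params$creatinine$sd)
        st$creat[idx] <- exp(lcr)
        mu_u <- pmax(0.05, params$urine$mu + params$urine$per_ratio * (ratio - 1))
        st$urine[idx] <- st$urine[idx] +
          params$urine$revert * (mu_u - st$urine[idx]) +
          rnorm(m, 0, params$urine$sd)
        oligur <- st$urine[idx] < 0.3
        mu_k <- params$potassium$mu + params$potassium$per_ratio * (ratio - 1) +
          params$potassium$oliguria * oligur + params$potassium$rrt * rrt[idx]
        st$potassium[idx] <- st$potassium[idx] +
          params$potassium$revert * (mu_k - st$potassium[idx]) +
          rnorm(m, 0, params$potassium$sd)
        mu_p <- params$ph$mu + params$ph$per_ratio * (ratio - 1) +
          params$ph$oliguria * oligur + params$ph$rrt * rrt[idx]
        st$ph[idx] <- st$ph[idx] +
          params$ph$revert * (mu_p - st$ph[idx]) +
          rnorm(m, 0, params$ph$sd)
        mu_s <- params$sofa$mu + params$sofa$per_ratio * (ratio - 1)
        st$sofa[idx] <- st$sofa[idx] +
          params$sofa$revert * (mu_s - st$sofa[idx]) +
          rnorm(m, 0, params$sofa$sd)
        st <- clamp_covariates(st)
        st$sofa <- round(st$sofa)
      }

      # KDIGO staging on today's values
      k <- st$potassium[idx]; phv <- st$ph[idx]
      uo <- st$urine[idx]; sf <- st$sofa[idx]; cr <- st$creat[idx]
      ratio <- cr / cr0[idx]
      cstage <- ifelse(cr >= 4.0, 3L,
                       (ratio >= 1.5) + (ratio >= 2.0) + (ratio >= 3.0))
      uo2_today <- uo < 0.5
      uo3_today <- (uo < 0.3) & prev_uo_low[idx] & t >= 1
      ustage <- ifelse(uo3_today, 3L, ifelse(uo2_today, 2L, 0L))
      crcrit[idx] <- crcrit[idx] | cstage >= 2L
      olig2[idx] <- olig2[idx] | ustage >= 2L
      combined <- pmax(cstage, ustage)
      newly <- is.na(incl_day[idx]) & combined >= 2L & t <= horizon - 1L
      incl_day[idx[newly]] <- t
      included <- !is.na(incl_day[idx])
      fup <- t - incl_day[idx]  # follow-up interval index (NA if not included)

      # treatment decision (only pre-initiation, from inclusion)
      can_decide <- included & !rrt[idx]
      start <- rep(FALSE, length(idx))
      if (mode == "observational") {
        lp <- ini$intercept + ini$potassium * k + ini$ph * phv +
          ini$urine * uo + ini$uo_stage3 * uo3_today + ini$sofa * sf
        start <- can_decide & (runif(length(idx)) < plogis(lp))
      } else if (mode == "regime") {
        olig_sel <- olig2[idx]
        xph <- ifelse(olig_sel, regime$x_ph_olig, regime$x_ph_nonolig)
        xk <- ifelse(olig_sel, regime$x_k_olig, regime$x_k_nonolig)
        start <- can_decide & crcrit[idx] &
          (phv < xph | k >= xk | uo3_today)
      }
      rrt[idx[start]] <- TRUE
      rrt_start_day[idx[start]] <- t

      # competing event draw for interval [t, t+1)
      ind <- rrt_indicated(k, phv, uo3_today, olig2[idx])
      lp_d <- dth$intercept + dth$potassium * k + dth$ph * phv +
        dth$sofa * sf + dth$urine * uo + dth$creatinine * cr +
        dth$rrt * rrt[idx] + dth$rrt_indicated * (rrt[idx] & ind)
      lp_c <- dis$intercept + dis$sofa * sf + dis$urine * uo +
        dis$potassium * k + dis$ph * phv + dis$rrt * rrt[idx]
      u_death <- runif(length(idx)) < plogis(lp_d)
      u_disch <- !u_death & (runif(length(idx)) < plogis(lp_c))
      ev <- ifelse(u_death, 1L, ifelse(u_disch, 2L, 0L))
      event[idx[ev > 0L]] <- ev[ev > 0L]
      event_day[idx[ev > 0L]] <- t

      if (record == "person_day") {
        rows[[t + 1L]] <- data.table(
          patient_id = idx, day = t,
          creatinine = round(cr, 3), potassium = round(k, 2),
          ph = round(phv, 3), urine_output_rate = round(pmax(uo, 0), 3),
          sofa = as.integer(sf),
          rrt_active = rrt[idx],
          rrt_started_today = start,
          event_today = c("none", "death", "discharge")[ev + 1L])
      }

      done <- ev > 0L |
        (!included & t >= horizon - 1L) |
        (included & fup >= 29L)
      active[idx[done]] <- FALSE
      prev_uo_low[idx] <- uo < 0.3
    }

    if (record == "summary") {
      out <- data.table(
        patient_id = seq_len(n),
        eligible = age > 18 & !rrt_hist & !is.na(weight) & !dnr,
        inclusion_day = incl_day,
        event = c("none", "death", "discharge")[event + 1L],
        event_day = event_day,
        rrt_start_day = rrt_start_day)
      out[, event_f := event_day - inclusion_day]
      out[, rrt_start_f := rrt_start_day - inclusion_day]
      return(out)
    }
    person_day <- rbindlist(rows)
    setkey(person_day, patient_id, day)
    structure(list(baseline = baseline, person_day = person_day,
                   params = params),
              class = "cohort_bundle")
  })
}

#' Generate a synthetic ICU cohort
#'
#' Simulates `params$n_patients` ICU admissions day by day under the
#' observational (confounded) RRT-initiation process and returns a
#' baseline table and a long person-day table.  Trajectories end at the
#' first of death, live ICU discharge, the inclusion horizon (for
#' patients who never reach KDIGO-AKI stage 2), or 30 follow-up days
#' after inclusion.
#'
#' @param params a [scenario_params()] object.
#' @param seed optional integer overriding `params$seed`.
#' @return A `cohort_bundle`: list with `baseline`, `person_day`
#'   (both `data.table`) and `params`.
#' @examples
#' coh <- generate_cohort(scenario_params(n_patients = 50), seed = 7)
#' names(coh)
#' @export
generate_cohort <- function(params = scenario_params(), seed = NULL) {
  simulate_engine(params, n = params$n_patients, mode = "observational",
                  seed = seed %||% params$seed, record = "person_day")
}

#' Counterfactual cumulative incidence by direct simulation (oracle)
#'
#' Simulates `n_mc` patients with RRT initiation forced to follow a
#' regime's prescription exactly (overriding the observational
#' initiation model) and returns the empirical cumulative incidence of
#' ICU death and discharge among eligible, included patients on the
#' daily grid 0..30, together with Monte Carlo standard errors and the
#' proportion initiated on RRT within follow-up.
#'
#' @param params a [scenario_params()] object.
#' @param regime one row of [enumerate_regimes()] (or a list with the
#'   four thresholds), the string `"never"` for the never-initiate
#'   regime, or `"natural"` for the observational natural course.
#' @param n_mc number of Monte Carlo patients.
#' @param seed integer seed.
#' @return An object of class `oracle_cif`: `data.table` with columns
#'   `day` (0..30), `cif_death`, `cif_discharge`, `surv`, `se_death`,
#'   `se_discharge`; attributes `n_included` and `p_initiated`.
#' @export
simulate_counterfactual_cif <- function(params, regime, n_mc = 10000L,
                                        seed = NULL) {
  if (n_mc < 1) stop_param("n_mc", "must be >= 1")
  if (is.character(regime) && length(regime) == 1L) {
    mode <- switch(regime, never = "never", natural = "observational",
                   stop_param("regime", "unknown keyword"))
    regime <- NULL
  } else {
    mode <- "regime"
    regime <- as.list(regime)
    needed <- c("x_ph_olig", "x_ph_nonolig", "x_k_olig", "x_k_nonolig")
    if (!all(needed %in% names(regime)))
      stop_param("regime", "must contain the four threshold fields")
  }
  s <- simulate_engine(params, n = n_mc, mode = mode, regime = regime,
                       seed = seed %||% params$seed, record = "summary")
  s <- s[eligible & !is.na(inclusion_day)]
  n <- nrow(s)
  if (n == 0L) stop("no eligible included patients in oracle simulation")
  grid <- 0:30
  cif_d <- vapply(grid, function(t) mean(s$event == "death" & s$event_f < t),
                  numeric(1))
  cif_c <- vapply(grid, function(t) mean(s$event == "discharge" & s$event_f < t),
                  numeric(1))
  out <- data.table(
    day = grid, cif_death = cif_d, cif_discharge = cif_c,
    surv = 1 - cif_d - cif_c,
    se_death = sqrt(cif_d * (1 - cif_d) / n),
    se_discharge = sqrt(cif_c * (1 - cif_c) / n))
  setattr(out, "n_included", n)
  setattr(out, "p_initiated", s[, mean(!is.na(rrt_start_f) & rrt_start_f <= 29)])
  setattr(out, "class", c("oracle_cif", class(out)))
  out[]
}
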