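#' Scenario parameters for the synthetic ICU cohort generator
#'
#' Bundles every constant of the discrete-time data-generating process:
#' baseline distributions, autoregressive covariate dynamics, the
#' observational RRT-initiation model and the competing death/discharge
#' hazards.  All hazard and initiation models are logistic on the daily
#' grid; coefficients are on the logit scale and multiply the *raw*
#' covariate values (potassium mEq/l, pH units, urine output ml/kg/h,
#' SOFA points, creatinine mg/dl).
#'
#' The default scenario is the package's "stated world": it is calibrated
#' once so that, among patients reaching KDIGO-AKI stage >= 2, 30-day ICU
#' mortality is roughly 12-13% and 8-9% start RRT within 30 days of
#' inclusion, and so that starting RRT without an absolute indication
#' (severe hyperkalaemia, oliguric acidosis, pH < 7.0, or persisting
#' oliguria) increases the death hazard while an indicated start reduces
#' it.  Under those dynamics an interior regime of the threshold grid is
#' optimal.
#'
#' @param n_patients number of ICU admissions to simulate.
#' @param horizon_days last ICU day (from admission, day 0) on which a
#'   patient can still become included; included patients are followed
#'   for 30 further days.
#' @param seed integer seed stored with the scenario; individual
#'   operations may override it.
#' @param baseline,severity,creatinine,potassium,ph,urine,sofa,initiation,death,discharge
#'   named lists overriding individual defaults of the corresponding
#'   component (partial lists are merged into the defaults).
#' @return An object of class `scenario_params` (a named list).
#' @export
scenario_params <- function(n_patients = 2000L,
                            horizon_days = 30L,
                            seed = 1L,
                            baseline = list(),
                            severity = list(),
                            creatinine = list(),
                            potassium = list(),
                            ph = list(),
                            urine = list(),
                            sofa = list(),
                            initiation = list(),
                            death = list(),
                            discharge = list()) {
  defaults <- list(
    n_patients = as.integer(n_patients),
    horizon_days = as.integer(horizon_days),
    seed = as.integer(seed),
    baseline = list(
      age_mean = 63, age_sd = 15,
      weight_mean = 78, weight_sd = 14,
      prop_male = 0.65,
      sofa_mean = 8, sofa_sd = 4,
      creat_log_mean = log(1.0), creat_log_sd = 0.30,
      missing_weight_rate = 0.01,
      rrt_history_rate = 0.02,
      dnr_rate = 0.03,
      ckd_rate = 0.08,
      minor_rate = 0.00
    ),
    # latent AKI severity: attractor of log creatinine is
    # log(creat0) + log_ratio, per patient
    severity = list(log_ratio_mean = log(3.0), log_ratio_sd = 0.65),
    creatinine = list(revert = 0.30, sd = 0.13),
    potassium = list(revert = 0.35, mu = 4.15, per_ratio = 0.40,
                     oliguria = 0.70, rrt = -0.90, sd = 0.38),
    ph = list(revert = 0.35, mu = 7.40, per_ratio = -0.030,
              oliguria = -0.060, rrt = 0.050, sd = 0.038),
    urine = list(revert = 0.40, mu = 1.15, per_ratio = -0.22, sd = 0.16),
    sofa = list(revert = 0.20, mu = 5.0, per_ratio = 1.3, sd = 1.2),
    initiation = list(intercept = 48.0, potassium = 0.90, ph = -8.0,
                      urine = -1.2, uo_stage3 = 1.0, sofa = 0.06),
    death = list(intercept = 30.25, potassium = 0.25, ph = -5.0,
                 sofa = 0.10, urine = -0.30, creatinine = 0.0,
                 rrt = 0.80, rrt_indicated = -1.50),
    discharge = list(intercept = -13.0, sofa = -0.22, urine = 0.30,
                     potassium = -0.10, ph = 1.80, rrt = -1.50)
  )
  p <- defaults
  for (comp in c("baseline", "severity", "creatinine", "potassium", "ph",
                 "urine", "sofa", "initiation", "death", "discharge")) {
    ov <- get(comp)
    if (length(ov)) {
      bad <- setdiff(names(ov), names(defaults[[comp]]))
      if (length(bad))
        stop_param(paste0(comp, "$", bad[1]), "unknown field")
      p[[comp]] <- modifyList(defaults[[comp]], ov)
    }
  }
  class(p) <- "scenario_params"
  validate_scenario_params(p)
  p
}

#' @rdname scenario_params
#' @export
default_scenario <- function(seed = 1L, n_patients = 2000L) {
  scenario_params(n_patients = n_patients, seed = seed)
}

validate_scenario_params <- function(p) {
  if (!is.numeric(p$n_patients) || is.na(p$n_patients) || p$n_patients < 1)
    stop_param("n_patients", "must be a positive integer")
  if (!is.numeric(p$horizon_days) || is.na(p$horizon_days) || p$horizon_days < 1)
    stop_param("horizon_days", "must be >= 1")
  b <- p$baseline
  for (f in c("age_sd", "weight_sd", "sofa_sd", "creat_log_sd"))
    if (!is.numeric(b[[f]]) || b[[f]] <= 0)
      stop_param(paste0("baseline$", f), "scale must be strictly positive")
  for (f in c("prop_male", "missing_weight_rate", "rrt_history_rate",
              "dnr_rate", "ckd_rate", "minor_rate"))
    if (!is.numeric(b[[f]]) || b[[f]] < 0 || b[[f]] > 1)
      stop_param(paste0("baseline$", f), "proportion must lie in [0, 1]")
  for (comp in c("creatinine", "potassium", "ph", "urine", "sofa")) {
    if (p[[comp]]$sd <= 0)
      stop_param(paste0(comp, "$sd"), "scale must be strictly positive")
    if (p[[comp]]$revert < 0 || p[[comp]]$revert > 1)
      stop_param(paste0(comp, "$revert"), "mean-reversion rate must lie in [0, 1]")
  }
  if (p$severity$log_ratio_sd <= 0)
    stop_param("severity$log_ratio_sd", "scale must be strictly positive")
  invisible(p)
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("<scenario_params>\n")
  cat(sprintf("  n_patients: %d, horizon_days: %d, seed: %d\n",
              x$n_patients, x$horizon_days, x$seed))
  cat(sprintf("  initiation intercept %.2f; death intercept %.2f; discharge intercept %.2f\n",
              x$initiation$intercept, x$death$intercept, x$discharge$intercept))
  invisible(x)
}

# physiological clamps applied after every covariate update
clamp_covariates <- function(s) {
  s$potassium <- pmin(pmax(s$potassium, 2.0), 9.0)
  s$ph        <- pmin(pmax(s$ph, 6.6), 7.7)
  s$urine     <- pmax(s$urine, 0)
  s$creat     <- pmax(s$creat, 0.2)
  s$sofa      <- pmin(pmax(s$sofa, 0), 24)
  s
}
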