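# Per-regime evaluation, standard-of-care reference, optimal-regime
# selection, risk difference, and the k-fold cross-validation benchmark.

#' Control options for regime evaluation
#'
#' @param covariates covariate specification for the initiation model
#'   (see [fit_initiation_model()]).
#' @param time_form,time_df follow-up time effect in the pooled model.
#' @param truncate_percentile weight-truncation percentile; 1 (default)
#'   leaves the weights exactly at 1/probability.
#' @param same_day event-vs-censoring precedence on a deviation day
#'   (see [apply_censoring()]).
#' @param grace concordance grace window in days (default 0).
#' @param var_method variance method for per-regime mortality CIs.
#' @param boot_init bootstrap resamples for the expected-initiations CI
#'   (default 500; set 0 to skip).
#' @param boot_rd bootstrap resamples for the risk-difference CI.
#' @param level confidence level.
#' @param seed RNG seed for all bootstraps.
#' @export
eval_control <- function(covariates = default_covariates(),
                         time_form = "ns", time_df = 4L,
                         truncate_percentile = 1,
                         same_day = "event", grace = 0L,
                         var_method = "infinitesimal-jackknife",
                         boot_init = 500L, boot_rd = 500L,
                         level = 0.95, seed = NULL) {
  list(covariates = covariates, time_form = time_form, time_df = time_df,
       truncate_percentile = truncate_percentile, same_day = same_day,
       grace = grace, var_method = var_method,
       boot_init = as.integer(boot_init), boot_rd = as.integer(boot_rd),
       level = level, seed = seed)
}

as_followup <- function(cohort) {
  if (inherits(cohort, "followup_cohort")) return(cohort)
  if (is.list(cohort) && all(c("baseline", "person_day") %in% names(cohort)))
    return(build_followup(cohort))
  stop("cohort must be a followup_cohort or a cohort bundle", call. = FALSE)
}

# One regime, full machinery.  `variance = FALSE` and `boot_init = 0`
# give the fast point-estimate path used inside cross-validation.
evaluate_regime <- function(followup, regime, model, control = eval_control(),
                            variance = TRUE, init = TRUE) {
  cl <- as.data.table(copy(followup))
  cl[, regime_index := regime$regime_index %||% 1L]
  cl <- apply_censoring(cl, as.data.table(as.list(regime)),
                        same_day = control$same_day, grace = control$grace)
  cl <- compute_ipc_weights(model, cl)
  if (control$truncate_percentile < 1)
    cl <- truncate_weights(cl, control$truncate_percentile)
  curve <- weighted_aalen_johansen(cl)
  m30 <- curve$cif_death[nrow(curve)]
  res <- list(curve = curve, clones = cl, mortality_30d = m30,
              ci_low = NA_real_, ci_high = NA_real_,
              expected_rrt = NA_real_, rrt_ci_low = NA_real_,
              rrt_ci_high = NA_real_)
  if (variance) {
    curve <- estimate_variance(curve, method = control$var_method,
                               B = max(control$boot_rd, 2L),
                               level = control$level, seed = control$seed)
    res$curve <- curve
    res$ci_low <- curve$ci_low_death[nrow(curve)]
    res$ci_high <- curve$ci_high_death[nrow(curve)]
    ei <- expected_initiations(cl, cohort_size = length(unique(followup$patient_id)),
                               B = control$boot_init, level = control$level,
                               seed = control$seed)
    res$expected_rrt <- ei$expected
    res$rrt_ci_low <- ei$ci_low
    res$rrt_ci_high <- ei$ci_high
  } else if (init) {
    ei <- expected_initiations(cl, cohort_size = length(unique(followup$patient_id)),
                               B = 0L)
    res$expected_rrt <- ei$expected
  }
  w <- cl[at_risk == TRUE, .(wmax = max(ipcw)), by = patient_id]$wmax
  res$ess <- sum(w)^2 / sum(w^2)
  res
}

#' Standard-of-care reference estimate
#'
#' Unweighted Aalen-Johansen on the observed data from inclusion (no
#' cloning, no artificial censoring), plus the raw count of patients
#' starting RRT within follow-up.
#'
#' @param cohort a `cohort_bundle` or `followup_cohort`.
#' @param control an [eval_control()].
#' @return list with `curve` (with CIs), `mortality_30d`, `ci_low`,
#'   `ci_high`, `rrt_count`, `rrt_ci_low`, `rrt_ci_high`, `n_patients`.
#' @export
observed_care_estimate <- function(cohort, control = eval_control()) {
  fu <- as_followup(cohort)
  if (nrow(fu) == 0L) stop("empty cohort", call. = FALSE)
  cl <- observed_pseudo_clones(fu)
  curve <- weighted_aalen_johansen(cl)
  curve <- estimate_variance(curve, method = control$var_method,
                             B = max(control$boot_rd, 2L),
                             level = control$level, seed = control$seed)
  ei <- expected_initiations(cl, cohort_size = length(unique(fu$patient_id)),
                             B = control$boot_init, level = control$level,
                             seed = control$seed)
  list(curve = curve,
       mortality_30d = curve$cif_death[nrow(curve)],
       ci_low = curve$ci_low_death[nrow(curve)],
       ci_high = curve$ci_high_death[nrow(curve)],
       rrt_count = ei$expected, rrt_ci_low = ei$ci_low,
       rrt_ci_high = ei$ci_high,
       n_patients = length(unique(fu$patient_id)))
}

#' Evaluate every regime of a grid
#'
#' Runs clone -> censor -> weight -> estimate for each regime, computes
#' the standard-of-care reference, selects the mortality-minimising
#' regime (ties broken by lowest index) and the risk difference
#' (observed minus optimal) with a joint patient-bootstrap CI.
#'
#' @param cohort a `cohort_bundle` or `followup_cohort`.
#' @param regimes regime grid (default [enumerate_regimes()]).
#' @param control an [eval_control()].
#' @param model optional pre-fitted `initiation_model` (fitted on the
#'   cohort's person-days when `NULL`).
#' @param variance compute per-regime CIs (default TRUE; FALSE is the
#'   fast path used in cross-validation).
#' @return object of class `evaluation_report`.
#' @export
evaluate_all_regimes <- function(cohort, regimes = enumerate_regimes(),
                                 control = eval_control(), model = NULL,
                                 variance = TRUE, init = TRUE,
                                 observed = TRUE) {
  fu <- as_followup(cohort)
  has_p <- "p_init" %in% names(fu)  # pre-supplied probabilities
  if (is.null(model) && !has_p)
    model <- fit_initiation_model(fu, covariates = control$covariates,
                                  time_form = control$time_form,
                                  time_df = control$time_df)
  regimes <- as.data.table(regimes)
  if (!variance && !init && !observed)
    return(grid_point_estimates(fu, regimes, model, control))
  if (!has_p) {
    fu <- copy(fu)
    fu[, p_init := predict(model, fu)]  # shared across regimes
  }
  rows <- vector("list", nrow(regimes))
  curves <- vector("list", nrow(regimes))
  for (i in seq_len(nrow(regimes))) {
    rg <- as.list(regimes[i])
    ev <- tryCatch(
      evaluate_regime(fu, rg, NULL, control, variance = variance,
                      init = init),
      error = function(e) stop(sprintf("regime %s: %s", rg$regime_index,
                                       conditionMessage(e)), call. = FALSE))
    rows[[i]] <- data.table(
      regime_index = rg$regime_index,
      x_ph_olig = rg$x_ph_olig, x_ph_nonolig = rg$x_ph_nonolig,
      x_k_olig = rg$x_k_olig, x_k_nonolig = rg$x_k_nonolig,
      mortality_30d = ev$mortality_30d,
      ci_low = ev$ci_low, ci_high = ev$ci_high,
      expected_rrt = ev$expected_rrt,
      rrt_ci_low = ev$rrt_ci_low, rrt_ci_high = ev$rrt_ci_high,
      ess = ev$ess)
    cv <- copy(ev$curve)
    setattr(cv, "components", NULL)  # keep the report light
    curves[[i]] <- cv
  }
  tab <- rbindlist(rows)
  opt_i <- tab$regime_index[which.min(tab$mortality_30d)]
  ties <- sum(tab$mortality_30d == min(tab$mortality_30d))
  if (!observed) {
    return(structure(list(
      regimes = tab, observed = NULL, optimal_index = opt_i,
      optimal_ties = ties, risk_difference = NA_real_,
      rd_ci = c(NA_real_, NA_real_), model = model, control = control,
      curves = curves,
      n_patients = length(unique(fu$patient_id))),
      class = "evaluation_report"))
  }
  obs <- observed_care_estimate(fu, control)
  rd <- obs$mortality_30d - tab[regime_index == opt_i, mortality_30d]

  # joint patient bootstrap for the risk difference (patients shared
  # between arms; weights treated as fixed)
  comp_obs <- attr(obs$curve, "components")
  opt_ev <- evaluate_regime(fu, as.list(regimes[regime_index == opt_i]),
                            NULL, control, variance = FALSE, init = FALSE)
  comp_opt <- attr(opt_ev$curve, "components")
  rd_ci <- c(NA_real_, NA_real_)
  if (control$boot_rd >= 2 &&
      identical(comp_obs$patient_ids, comp_opt$patient_ids)) {
    n <- nrow(comp_obs$Y)
    rd_b <- with_seed(control$seed, {
      cnt <- rmultinom(control$boot_rd, n, rep(1 / n, n))
      o <- crossprod(comp_obs$Y, cnt)
      oD <- lapply(comp_obs$D, function(M) crossprod(M, cnt))
      p <- crossprod(comp_opt$Y, cnt)
      pD <- lapply(comp_opt$D, function(M) crossprod(M, cnt))
      sapply(seq_len(control$boot_rd), function(b) {
        aj_from_totals(o[, b], lapply(oD, function(M) M[, b]))$cif$death[31L] -
          aj_from_totals(p[, b], lapply(pD, function(M) M[, b]))$cif$death[31L]
      })
    })
    rd_ci <- quantile(rd_b, c((1 - control$level) / 2,
                              1 - (1 - control$level) / 2), names = FALSE)
  }

  structure(list(
    regimes = tab, observed = obs, optimal_index = opt_i,
    optimal_ties = ties, risk_difference = rd, rd_ci = rd_ci,
    model = model, control = control, curves = curves,
    n_patients = obs$n_patients),
    class = "evaluation_report")
}

# Vectorised point-estimate path: censor and weight every regime's
# clones in one long table and aggregate the discrete-time AJ by
# regime.  Identical estimates to the per-regime path, used where only
# the mortality ranking is needed (cross-validation selection).
grid_point_estimates <- function(fu, regimes, model, control) {
  fu2 <- as.data.table(copy(fu))
  if (!"p_init" %in% names(fu2)) fu2[, p_init := predict(model, fu2)]
  cl <- expand_clones(fu2, regimes)
  cl <- apply_censoring(cl, regimes, same_day = control$same_day,
                        grace = control$grace)
  cl <- compute_ipc_weights(NULL, cl)
  if (control$truncate_percentile < 1)
    cl <- truncate_weights(cl, control$truncate_percentile)
  agg <- cl[f <= N_INTERVALS - 1L & at_risk == TRUE,
            .(Y = sum(ipcw),
              Dd = sum(ipcw * (event_today == "death")),
              Dc = sum(ipcw * (event_today == "discharge"))),
            by = .(regime_index, f)]
  full <- CJ(regime_index = regimes$regime_index, f = 0:(N_INTERVALS - 1L))
  agg <- agg[full, on = c("regime_index", "f")]
  for (cn in c("Y", "Dd", "Dc")) set(agg, which(is.na(agg[[cn]])), cn, 0)
  setorder(agg, regime_index, f)
  tab <- agg[, {
    aj <- aj_from_totals(Y, list(death = Dd, discharge = Dc))
    .(mortality_30d = aj$cif$death[N_INTERVALS + 1L])
  }, by = regime_index]
  tab <- regimes[tab, on = "regime_index"]
  tab[, `:=`(ci_low = NA_real_, ci_high = NA_real_,
             expected_rrt = NA_real_, rrt_ci_low = NA_real_,
             rrt_ci_high = NA_real_, ess = NA_real_)]
  opt_i <- tab$regime_index[which.min(tab$mortality_30d)]
  structure(list(
    regimes = tab[],
    observed = NULL, optimal_index = opt_i,
    optimal_ties = sum(tab$mortality_30d == min(tab$mortality_30d)),
    risk_difference = NA_real_, rd_ci = c(NA_real_, NA_real_),
    model = model, control = control, curves = NULL,
    n_patients = length(unique(fu$patient_id))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d regimes, %d patients\n",
              nrow(x$regimes), x$n_patients))
  cat(sprintf("  observed 30-day ICU mortality: %.3f [%.3f, %.3f]; RRT count %.0f\n",
              x$observed$mortality_30d, x$observed$ci_low,
              x$observed$ci_high, x$observed$rrt_count))
  opt <- x$regimes[regime_index == x$optimal_index]
  cat(sprintf("  optimal regime %d (pH %.1f/%.1f, K %.1f/%.1f): mortality %.3f [%.3f, %.3f]\n",
              x$optimal_index, opt$x_ph_olig, opt$x_ph_nonolig,
              opt$x_k_olig, opt$x_k_nonolig, opt$mortality_30d,
              opt$ci_low, opt$ci_high))
  cat(sprintf("  risk difference (observed - optimal): %.3f [%.3f, %.3f]\n",
              x$risk_difference, x$rd_ci[1], x$rd_ci[2]))
  invisible(x)
}

#' Fivefold cross-validation benchmark for the optimal regime
#'
#' Splits patients into `k_folds` folds; for each fold the
#' mortality-minimising regime is selected on the training folds
#' (initiation model refitted on training data) and that regime's
#' mortality is estimated on the held-out fold (model refitted on the
#' held-out data by default).  The benchmark is the
#' patient-count-weighted average of the held-out estimates.
#'
#' @param cohort a `cohort_bundle` or `followup_cohort`.
#' @param regimes regime grid.
#' @param k_folds number of folds (default 5; must be >= 2).
#' @param seed seed for the fold assignment.
#' @param control an [eval_control()].
#' @param refit_test refit the initiation model on the held-out fold
#'   (default TRUE); otherwise the training-fold model is reused.
#' @return list with `benchmark`, per-fold table `folds`
#'   (`fold`, `selected_regime`, `estimate`, `n_test`, `valid`) and the
#'   fold assignment.
#' @export
cross_validated_benchmark <- function(cohort, regimes = enumerate_regimes(),
                                      k_folds = 5L, seed = NULL,
                                      control = eval_control(),
                                      refit_test = TRUE) {
  if (k_folds < 2) stop_param("k_folds", "must be >= 2")
  fu <- as_followup(cohort)
  pats <- unique(fu$patient_id)
  if (k_folds > length(pats))
    stop_param("k_folds", "more folds than patients")
  fold_of <- with_seed(seed, {
    sample(rep_len(seq_len(k_folds), length(pats)))
  })
  assign_dt <- data.table(patient_id = pats, fold = fold_of)
  res <- vector("list", k_folds)
  for (k in seq_len(k_folds)) {
    test_ids <- assign_dt[fold == k, patient_id]
    train <- fu[!patient_id %in% test_ids]
    test <- fu[patient_id %in% test_ids]
    res[[k]] <- tryCatch({
      rep_train <- evaluate_all_regimes(train, regimes, control,
                                        variance = FALSE, init = FALSE,
                                        observed = FALSE)
      sel <- rep_train$optimal_index
      model_test <- if ("p_init" %in% names(test)) NULL
      else if (refit_test) {
        fit_initiation_model(test, covariates = control$covariates,
                             time_form = control$time_form,
                             time_df = control$time_df)
      } else rep_train$model
      ev <- evaluate_regime(test, as.list(regimes[regime_index == sel]),
                            model_test, control, variance = FALSE,
                            init = FALSE)
      data.table(fold = k, selected_regime = sel,
                 estimate = ev$mortality_30d,
                 n_test = length(test_ids), valid = TRUE)
    }, error = function(e) {
      warning(sprintf("fold %d failed and is excluded from the benchmark: %s",
                      k, conditionMessage(e)))
      data.table(fold = k, selected_regime = NA_integer_,
                 estimate = NA_real_, n_test = length(test_ids),
                 valid = FALSE)
    })
  }
  folds <- rbindlist(res)
  valid <- folds[valid == TRUE]
  if (nrow(valid) == 0L) stop("all folds failed", call. = FALSE)
  list(benchmark = valid[, sum(estimate * n_test) / sum(n_test)],
       folds = folds, assignment = assign_dt)
}
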