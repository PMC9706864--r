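# Pooled (discrete-time) logistic model for daily RRT initiation and the
# inverse-probability-of-censoring weights it implies.
#
# One model is fitted on the original (un-cloned) person-days at risk of
# initiation and shared across all regimes: every regime's censoring
# mechanism is fully determined by the single observed initiation
# process.

default_covariates <- function() {
  list(baseline = c("age", "sex", "weight", "admission_sofa"),
       timevarying = c("creatinine", "potassium", "ph",
                       "urine_output_rate", "sofa", "uo_stage3"))
}

#' Fit the pooled logistic RRT-initiation model
#'
#' Logistic regression of daily RRT initiation on main effects of the
#' baseline and time-varying covariates and a flexible effect of
#' follow-up time, fitted on person-days at risk (from inclusion, not
#' yet on RRT).
#'
#' @param followup a [build_followup()] table.
#' @param covariates list with character vectors `baseline` and
#'   `timevarying`; defaults to age, sex, weight, admission SOFA,
#'   creatinine, potassium, pH, urine output, SOFA and the
#'   persisting-oliguria indicator.
#' @param time_form `"ns"` (natural spline, default), `"factor"` (one
#'   indicator per day) or `"none"` (no time effect) for follow-up time.
#' @param time_df spline degrees of freedom (default 4).
#' @param ridge_on_separation refit with a small ridge penalty (via
#'   glmnet, if installed) when the ML fit shows signs of separation.
#' @return object of class `initiation_model`.
#' @export
fit_initiation_model <- function(followup,
                                 covariates = default_covariates(),
                                 time_form = c("ns", "factor", "none"),
                                 time_df = 4L,
                                 ridge_on_separation = TRUE) {
  time_form <- match.arg(time_form)
  fu <- as.data.table(followup)
  risk <- fu[(!rrt_active | rrt_started_today) & f <= 29L]
  if (nrow(risk) == 0L) stop("no at-risk person-days", call. = FALSE)
  if (sum(risk$rrt_started_today) == 0L)
    stop("degenerate outcome: no RRT initiations in the cohort",
         call. = FALSE)
  covs <- intersect(c(covariates$baseline, covariates$timevarying),
                    names(risk))
  time_term <- switch(time_form,
    ns = if (length(unique(risk$f)) > time_df) {
      sprintf("splines::ns(f, df = %d)", as.integer(time_df))
    } else "f",
    factor = "factor(f)",
    none = NULL)
  rhs <- c(covs, time_term)
  if (!length(rhs)) rhs <- "1"
  fml <- stats::as.formula(paste(
    "rrt_started_today ~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = risk, family = binomial(),
                                     control = stats::glm.control(maxit = 100L)))
  separated <- !fit$converged || isTRUE(fit$boundary) || anyNA(coef(fit))
  ridge <- NULL
  if (separated && ridge_on_separation &&
      requireNamespace("glmnet", quietly = TRUE)) {
    warning("possible separation in initiation model; refitting with a small ridge penalty")
    X <- stats::model.matrix(fml, risk)[, -1L, drop = FALSE]
    ridge <- glmnet::glmnet(X, risk$rrt_started_today, family = "binomial",
                            alpha = 0, lambda = 1e-3)
  } else if (separated) {
    warning("possible separation in initiation model (glmnet not available for ridge refit)")
  }
  structure(list(fit = fit, ridge = ridge, formula = fml,
                 covariates = covs, time_form = time_form,
                 time_df = time_df, converged = fit$converged,
                 n_rows = nrow(risk),
                 n_events = sum(risk$rrt_started_today)),
            class = "initiation_model")
}

#' @export
print.initiation_model <- function(x, ...) {
  cat("<initiation_model> pooled logistic, ",
      x$n_events, " initiations / ", x$n_rows, " person-days at risk\n",
      sep = "")
  print(coef(x$fit))
  invisible(x)
}

#' Predicted daily initiation probabilities
#'
#' @param object an `initiation_model`.
#' @param newdata rows with the model covariates and `f`.
#' @param clip probabilities are clipped to `[clip, 1 - clip]` as a
#'   positivity guard (count of clipped rows attached as attribute).
#' @param ... unused.
#' @export
predict.initiation_model <- function(object, newdata, clip = 1e-6, ...) {
  nd <- as.data.frame(newdata)
  if (!is.null(object$ridge)) {
    X <- stats::model.matrix(object$formula[-2L], nd)[, -1L, drop = FALSE]
    p <- as.numeric(predict(object$ridge, X, type = "response"))
  } else {
    p <- as.numeric(predict(object$fit, nd, type = "response"))
  }
  n_clip <- sum(p < clip | p > 1 - clip)
  p <- pmin(pmax(p, clip), 1 - clip)
  attr(p, "n_clipped") <- n_clip
  p
}

#' Inverse-probability-of-censoring weights per clone-day
#'
#' For every uncensored clone decision-day the probability of remaining
#' uncensored is the probability that observed care agrees with the
#' regime: `1 - p_init` when the regime prescribes no initiation,
#' `p_init` when it prescribes initiation.  Days after a concordant
#' initiation contribute 1 (concordance is then automatic), as does a
#' kept event day whose decision deviated.  The cumulative weight is the
#' running product of reciprocals within each clone.
#'
#' @param model an `initiation_model` (or `NULL` to use a `p_init`
#'   column already present on `clones`).
#' @param clones censored clone table from [apply_censoring()].
#' @return the clone table with columns `p_init`, `p_uncensored` and
#'   `ipcw` (cumulative weight) filled in.
#' @export
compute_ipc_weights <- function(model, clones) {
  cl <- as.data.table(clones)
  if (!is.null(model)) {
    cl[, p_init := predict(model, .SD)]
  } else if (!"p_init" %in% names(cl)) {
    stop("either a model or a p_init column is required", call. = FALSE)
  }
  cl[, p_uncensored := 1.0]
  live <- cl[, decision & at_risk & !dev_on_event]
  cl[live, p_uncensored := ifelse(prescribed, p_init, 1 - p_init)]
  if (any(cl$p_uncensored <= 0)) {
    bad <- cl[p_uncensored <= 0][1L]
    stop(sprintf(
      "positivity violation: p_uncensored = 0 for patient %s, regime %s, day %d",
      bad$patient_id, bad$regime_index, bad$f), call. = FALSE)
  }
  cl[, ipcw := cumprod(1 / p_uncensored), by = .(regime_index, patient_id)]
  cl[]
}

#' Truncate IPC weights at a percentile of their pooled distribution
#'
#' @param clones weighted clone table from [compute_ipc_weights()].
#' @param upper_percentile in (0.5, 1]; 1 is the identity.
#' @return the table with `ipcw` capped; the untruncated weights are
#'   kept in `ipcw_raw` and the cap value is attached as attribute
#'   `truncation_cap`.
#' @export
truncate_weights <- function(clones, upper_percentile = 0.995) {
  if (upper_percentile <= 0.5 || upper_percentile > 1)
    stop_param("upper_percentile", "must lie in (0.5, 1]")
  cl <- as.data.table(clones)
  cl[, ipcw_raw := ipcw]
  cap <- stats::quantile(cl$ipcw, upper_percentile, names = FALSE, type = 1)
  if (upper_percentile < 1) cl[, ipcw := pmin(ipcw, cap)]
  setattr(cl, "truncation_cap", cap)
  cl[]
}

#' IPC-weight calibration diagnostic
#'
#' For correctly specified weights,
#' `E[W(t) x 1(concordant through t)] = 1` at every follow-up day: the
#' re-weighted pseudo-population keeps the original cohort size.  Clones
#' censored by day `t` contribute 0; clones whose event occurred before
#' `t` carry their final weight forward (their later decisions are
#' vacuous).  A clone kept under event precedence despite a same-day
#' deviation counts as censored here, matching the identity.
#'
#' @param clones weighted clone table (one regime).
#' @return `data.table` with `f`, `mean_w` (should be near 1) and its
#'   naive standard error `se_w` across patients.
#' @export
weight_calibration <- function(clones) {
  cl <- as.data.table(clones)
  if (length(unique(cl$regime_index)) > 1L)
    stop("clone table must contain a single regime", call. = FALSE)
  per <- cl[, {
    cens <- if (any(censored) || any(dev_on_event)) {
      suppressWarnings(min(censor_day[censored], f[dev_on_event], na.rm = TRUE))
    } else NA_integer_
    .(last_f = max(f), last_w = ipcw[.N], cens_f = as.integer(cens))
  }, by = patient_id]
  # per-day weight path per clone, carried forward after the last row
  wpath <- cl[, .(patient_id, f, ipcw)]
  grid <- 0:(N_INTERVALS - 1L)
  out <- rbindlist(lapply(grid, function(t) {
    cur <- wpath[f <= t, .(w = ipcw[.N]), by = patient_id]
    cur <- per[cur, on = "patient_id"]
    cur[, w := fifelse(!is.na(cens_f) & cens_f <= t, 0, w)]
    data.table(f = t, mean_w = mean(cur$w), se_w = sd(cur$w) / sqrt(nrow(cur)))
  }))
  out[]
}

# Weight diagnostics used in reports/logs.
weight_diagnostics <- function(clones) {
  cl <- as.data.table(clones)
  cl[at_risk == TRUE,
     .(mean_w = mean(ipcw), max_w = max(ipcw),
       n_clone_days = .N),
     by = regime_index]
}
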