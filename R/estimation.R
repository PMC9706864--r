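# IPC-weighted discrete-time Aalen-Johansen estimation with ICU
# discharge as competing event, infinitesimal-jackknife and
# patient-bootstrap variance, and the expected-initiations estimator.
#
# Hazard intervals are follow-up days f = 0..29; the cumulative
# incidence is reported on the grid t = 0..30 where CIF(t) accumulates
# intervals f < t.  With unit weights and a single event type the
# estimator reduces exactly to 1 - Kaplan-Meier.

N_INTERVALS <- 30L

# Per-patient weighted component matrices (n x 30): at-risk mass and
# event mass per interval, for a clone table restricted to ONE regime.
aj_components <- function(clones, events = c("death", "discharge"),
                          weight_col = "ipcw") {
  cl <- as.data.table(clones)
  if (length(unique(cl$regime_index)) > 1L)
    stop("clone table must contain a single regime", call. = FALSE)
  w <- cl[[weight_col]]
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  pid <- factor(cl$patient_id)
  n <- nlevels(pid)
  ri <- as.integer(pid)
  ci <- cl$f + 1L
  keep <- cl$f <= N_INTERVALS - 1L
  idx <- cbind(ri, ci)[keep, , drop = FALSE]
  at <- cl$at_risk[keep]; wk <- w[keep]; evk <- cl$event_today[keep]
  Y <- matrix(0, n, N_INTERVALS)
  Y[idx] <- wk * at
  D <- lapply(events, function(e) {
    M <- matrix(0, n, N_INTERVALS)
    M[idx] <- wk * at * (evk == e)
    M
  })
  names(D) <- events
  list(Y = Y, D = D, patient_ids = levels(pid))
}

aj_from_totals <- function(Ytot, Dtot) {
  K <- length(Dtot)
  hz <- lapply(Dtot, function(d) ifelse(Ytot > 0, d / Ytot, 0))
  htot <- Reduce(`+`, hz)
  htot <- pmin(htot, 1)
  S <- c(1, cumprod(1 - htot))           # grid 0..30
  cif <- lapply(hz, function(h) c(0, cumsum(S[seq_len(N_INTERVALS)] * h)))
  list(S = S, cif = cif, hazard = hz, htot = htot)
}

#' IPC-weighted Aalen-Johansen cumulative incidence
#'
#' Discrete-time product-limit estimator: at each follow-up interval the
#' weighted hazard of each event type is the weighted number of events
#' divided by the weighted number at risk; cumulative incidences
#' accumulate `S(t) x hazard`.
#'
#' @param clones weighted clone-day table (one regime) from
#'   [compute_ipc_weights()] or [observed_pseudo_clones()].
#' @param events event types to track (default death and discharge).
#' @param weight_col column holding the clone-day weights.
#' @return An `incidence_curve` `data.table` with columns `day` (0..30),
#'   one `cif_<event>` per event type, `surv`, `n_risk` and `w_risk`.
#'   The per-patient components are attached for variance estimation.
#' @export
weighted_aalen_johansen <- function(clones,
                                    events = c("death", "discharge"),
                                    weight_col = "ipcw") {
  comp <- aj_components(clones, events, weight_col)
  Ytot <- colSums(comp$Y)
  Dtot <- lapply(comp$D, colSums)
  # empty risk set before later events is not estimable
  anyev <- Reduce(`+`, Dtot)
  if (any(Ytot == 0 & rev(cumsum(rev(anyev))) > 0))
    stop("empty risk set at an interval with later events", call. = FALSE)
  aj <- aj_from_totals(Ytot, Dtot)
  out <- data.table(day = 0:N_INTERVALS)
  for (e in events) out[, paste0("cif_", e) := aj$cif[[e]]]
  out[, surv := aj$S]
  out[, n_risk := c(colSums(comp$Y > 0), 0)]
  out[, w_risk := c(Ytot, 0)]
  setattr(out, "components", comp)
  setattr(out, "events", events)
  setattr(out, "class", c("incidence_curve", class(out)))
  out[]
}

# row-wise cumulative sum over columns of a matrix
row_cumsum <- function(M) {
  for (j in seq_len(ncol(M))[-1L]) M[, j] <- M[, j] + M[, j - 1L]
  M
}

# Infinitesimal-jackknife influence of each patient on CIF_e(t), t=0..30.
# Case-weight derivative of the discrete-time weighted AJ, IPC weights
# treated as fixed; clones of one patient aggregate into one influence.
ij_influence <- function(comp, aj, event) {
  Y <- comp$Y
  Ytot <- colSums(Y)
  h_e <- aj$hazard[[event]]
  htot <- aj$htot
  S <- aj$S                      # length 31, grid 0..30
  inv_Y <- ifelse(Ytot > 0, 1 / Ytot, 0)
  # dh_e,i(f) = (d_ei(f) - h_e(f) y_i(f)) / Y(f)
  dh_list <- lapply(names(comp$D), function(e) {
    he <- aj$hazard[[e]]
    sweep(comp$D[[e]] - sweep(Y, 2, he, `*`), 2, inv_Y, `*`)
  })
  names(dh_list) <- names(comp$D)
  dh_tot <- Reduce(`+`, dh_list)
  om <- pmax(1 - htot, 1e-12)
  A <- sweep(dh_tot, 2, 1 / om, `*`)             # n x 30
  cumA <- cbind(0, row_cumsum(A))                # n x 31, grid 0..30
  dS <- -sweep(cumA, 2, S, `*`)                  # dS_i(t), grid 0..30
  # dF_e,i(t) = sum_{f < t} [ dS_i(f) h_e(f) + S(f) dh_e,i(f) ]
  incr <- sweep(dS[, seq_len(N_INTERVALS), drop = FALSE], 2, h_e, `*`) +
    sweep(dh_list[[event]], 2, S[seq_len(N_INTERVALS)], `*`)
  cbind(0, row_cumsum(incr))                     # n x 31
}

#' Pointwise variance and confidence intervals for an incidence curve
#'
#' @param curve an `incidence_curve` from [weighted_aalen_johansen()].
#' @param method `"infinitesimal-jackknife"` (default; per-patient
#'   influence contributions, variance = sum of squared influences) or
#'   `"patient-bootstrap"` (patients resampled with replacement, all of
#'   a patient's clone-days move together, percentile intervals).
#' @param B bootstrap resamples (default 500).
#' @param level confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return the curve with `var_<event>`, `ci_low_<event>` and
#'   `ci_high_<event>` columns (intervals clipped to `[0, 1]`).
#' @export
estimate_variance <- function(curve,
                              method = c("infinitesimal-jackknife",
                                         "patient-bootstrap"),
                              B = 500L, level = 0.95, seed = NULL) {
  method <- match.arg(method)
  comp <- attr(curve, "components")
  events <- attr(curve, "events")
  if (is.null(comp)) stop("curve lacks stored components", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  out <- copy(curve)
  if (method == "infinitesimal-jackknife") {
    aj <- aj_from_totals(colSums(comp$Y), lapply(comp$D, colSums))
    for (e in events) {
      IF <- ij_influence(comp, aj, e)
      v <- colSums(IF^2)
      est <- out[[paste0("cif_", e)]]
      out[, paste0("var_", e) := v]
      out[, paste0("ci_low_", e) := pmax(est - z * sqrt(v), 0)]
      out[, paste0("ci_high_", e) := pmin(est + z * sqrt(v), 1)]
    }
  } else {
    if (B < 2) stop_param("B", "must be >= 2")
    n <- nrow(comp$Y)
    boot <- with_seed(seed, {
      cnt <- rmultinom(B, n, rep(1 / n, n))     # n x B
      Yb <- crossprod(comp$Y, cnt)              # 30 x B
      Db <- lapply(comp$D, function(M) crossprod(M, cnt))
      lapply(events, function(e) {
        sapply(seq_len(B), function(b) {
          aj_from_totals(Yb[, b], lapply(Db, function(M) M[, b]))$cif[[e]]
        })                                      # 31 x B
      })
    })
    names(boot) <- events
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    for (e in events) {
      qs <- apply(boot[[e]], 1L, quantile, probs = probs, names = FALSE)
      out[, paste0("var_", e) := apply(boot[[e]], 1L, var)]
      out[, paste0("ci_low_", e) := pmax(qs[1L, ], 0)]
      out[, paste0("ci_high_", e) := pmin(qs[2L, ], 1)]
    }
  }
  for (a in c("components", "events"))
    setattr(out, a, attr(curve, a))
  setattr(out, "class", class(curve))
  out[]
}

#' Expected number of RRT initiations under a regime
#'
#' IPC-weighted cumulative incidence of RRT initiation by day 30
#' (death and discharge as competing events), scaled to the cohort
#' size, with a patient-level bootstrap percentile interval.
#'
#' @param clones weighted clone-day table (one regime).
#' @param cohort_size number of patients the count is scaled to
#'   (default: patients in the table).
#' @param B bootstrap resamples (default 500); 0 skips the interval.
#' @param level confidence level.
#' @param seed RNG seed.
#' @param weight_col weight column.
#' @return list with `expected`, `ci_low`, `ci_high`, `cif_init`.
#' @export
expected_initiations <- function(clones, cohort_size = NULL, B = 500L,
                                 level = 0.95, seed = NULL,
                                 weight_col = "ipcw") {
  cl <- as.data.table(clones)
  if (length(unique(cl$regime_index)) > 1L)
    stop("clone table must contain a single regime", call. = FALSE)
  cl <- copy(cl)
  # initiation endpoint: event = observed (concordant) start; rows after
  # the start leave the risk set
  cl[, init_today := rrt_started_today & at_risk]
  starts <- cl[init_today == TRUE, .(start_f = f[1L]), by = patient_id]
  cl[, start_f := NA_integer_]
  cl[starts, start_f := i.start_f, on = "patient_id"]
  cl <- cl[is.na(start_f) | f <= start_f]
  # initiation precedes the competing event within the day
  cl[, event_init := ifelse(init_today, "init", event_today)]
  cl2 <- cl[, .(regime_index, patient_id, f, at_risk,
                event_today = event_init)]
  cl2[, (weight_col) := cl[[weight_col]]]
  comp <- aj_components(cl2, events = c("init", "death", "discharge"),
                        weight_col = weight_col)
  n <- nrow(comp$Y)
  if (is.null(cohort_size)) cohort_size <- n
  aj <- aj_from_totals(colSums(comp$Y), lapply(comp$D, colSums))
  cif30 <- aj$cif[["init"]][N_INTERVALS + 1L]
  res <- list(expected = cif30 * cohort_size, cif_init = cif30,
              ci_low = NA_real_, ci_high = NA_real_)
  if (B >= 2) {
    bt <- with_seed(seed, {
      cnt <- rmultinom(B, n, rep(1 / n, n))
      Yb <- crossprod(comp$Y, cnt)
      Db <- lapply(comp$D, function(M) crossprod(M, cnt))
      sapply(seq_len(B), function(b) {
        aj_from_totals(Yb[, b],
                       lapply(Db, function(M) M[, b]))$cif[["init"]][N_INTERVALS + 1L]
      })
    })
    qs <- quantile(bt, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    res$ci_low <- max(qs[1L] * cohort_size, 0)
    res$ci_high <- min(qs[2L] * cohort_size, cohort_size)
  }
  res
}
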