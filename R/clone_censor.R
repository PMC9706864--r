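# Follow-up cohort construction and the cloning / artificial-censoring
# steps of the target-trial emulation.
#
# Follow-up time convention: the inclusion day is relabelled f = 0; row
# f covers the interval [f, f+1) so decisions happen at f = 0..29 and an
# event recorded on row f contributes to cumulative incidence at grid
# time f + 1.

#' Build the follow-up analysis table
#'
#' Stages the person-day table, applies the exclusion criteria and
#' returns one row per (eligible, included) patient and follow-up day,
#' with the decision-state columns needed by the regimes.
#'
#' @param bundle a `cohort_bundle` (or list with `baseline` and
#'   `person_day` tables).
#' @return A `followup_cohort` `data.table` keyed by (`patient_id`, `f`).
#' @export
build_followup <- function(bundle) {
  bl <- as.data.table(bundle$baseline)
  stg <- compute_kdigo_stages(bundle$person_day)
  elig <- apply_exclusion_criteria(bl)
  keep <- elig[eligible == TRUE, patient_id]
  pd <- stg$stages[stg$inclusion, on = "patient_id", nomatch = NULL]
  pd <- pd[!is.na(inclusion_day) & patient_id %in% keep]
  pd[, f := day - inclusion_day]
  pd <- pd[f >= 0L & f <= 29L]
  bcols <- intersect(c("patient_id", "age", "sex", "weight",
                       "admission_sofa"), names(bl))
  fu <- bl[, ..bcols][pd, on = "patient_id"]
  keep_cols <- c("patient_id", "f", "day", "inclusion_day",
                 setdiff(bcols, "patient_id"),
                 "creatinine", "potassium", "ph", "urine_output_rate",
                 "sofa", "uo_stage3", "creat_crit", "olig2_met",
                 "rrt_active", "rrt_started_today", "event_today")
  keep_cols <- intersect(keep_cols, names(fu))
  fu <- fu[, ..keep_cols]
  setkey(fu, patient_id, f)
  setattr(fu, "class", c("followup_cohort", class(fu)))
  fu[]
}

#' Expand a follow-up cohort into per-regime clones
#'
#' Creates one copy ("clone") of every patient's follow-up trajectory
#' per regime.  Censoring is applied separately by [apply_censoring()].
#'
#' @param followup a [build_followup()] table.
#' @param regimes a regime table from [enumerate_regimes()].
#' @return clone-day `data.table` with an added `regime_index` column.
#' @export
expand_clones <- function(followup, regimes = enumerate_regimes()) {
  fu <- as.data.table(followup)
  cl <- fu[rep(seq_len(nrow(fu)), times = nrow(regimes))]
  cl[, regime_index := rep(regimes$regime_index, each = nrow(fu))]
  setkey(cl, regime_index, patient_id, f)
  cl[]
}

#' Censor clones at the first deviation from their regime
#'
#' Walks each clone's decision days in order and censors it on the first
#' day the regime's prescription disagrees with the observed initiation
#' behaviour: either the regime prescribes initiation and the patient
#' did not start that day, or the patient started without prescription.
#' Once a prescribed start coincides with the observed start, all later
#' days are concordant (RRT is absorbing).
#'
#' @param clones output of [expand_clones()] (any subset of regimes).
#' @param regimes regime table supplying thresholds per `regime_index`.
#' @param same_day what to do when an event falls on the deviation day:
#'   `"event"` (default) keeps the event, `"censor"` censors first and
#'   drops the event.
#' @param grace non-negative integer: a prescribed initiation may be
#'   honoured up to `grace` days late before the clone is censored, and
#'   an observed start is concordant if the regime prescribed initiation
#'   on any of the `grace + 1` days up to the start.  Default 0
#'   (same-day concordance).
#' @return clone-day table with rows after the censoring day dropped and
#'   added columns `prescribed`, `decision`, `censored`, `censor_day`,
#'   `at_risk`, `dev_on_event`, plus a unit `ipcw` weight placeholder.
#' @export
apply_censoring <- function(clones, regimes = enumerate_regimes(),
                            same_day = c("event", "censor"),
                            grace = 0L) {
  same_day <- match.arg(same_day)
  if (grace < 0) stop_param("grace", "must be >= 0")
  cl <- as.data.table(clones)
  rg <- as.data.table(regimes)
  cl <- rg[cl, on = "regime_index"]
  setkey(cl, regime_index, patient_id, f)
  cl[, decision := (!rrt_active | rrt_started_today)]
  cl[, prescribed := decision & prescribes_vec(
    creat_crit, olig2_met, ph, potassium, uo_stage3,
    x_ph_olig, x_ph_nonolig, x_k_olig, x_k_nonolig)]

  g <- as.integer(grace)
  cl[, dev := {
    if (g == 0L) {
      decision & (prescribed != rrt_started_today)
    } else {
      # run length of consecutive unmet prescriptions; start concordant
      # if prescribed on any of the last g+1 decision days
      run <- Reduce(function(acc, p) if (p) acc + 1L else 0L,
                    prescribed & decision, accumulate = TRUE)
      recent <- frollsum(as.integer(prescribed & decision), g + 1L,
                         align = "right", fill = 0)
      devA <- decision & prescribed & !rrt_started_today & run >= g + 1L
      devB <- decision & rrt_started_today & recent == 0
      devA | devB
    }
  }, by = .(regime_index, patient_id)]

  cl[, `:=`(censored = FALSE, censor_day = NA_integer_,
            at_risk = TRUE, dev_on_event = FALSE)]
  devs <- cl[dev == TRUE, .(dev_f = f[1L]), by = .(regime_index, patient_id)]
  evs <- cl[event_today != "none", .(ev_f = f[1L]),
            by = .(regime_index, patient_id)]
  cl[, dev_f := NA_integer_][, ev_f := NA_integer_]
  cl[devs, dev_f := i.dev_f, on = c("regime_index", "patient_id")]
  cl[evs, ev_f := i.ev_f, on = c("regime_index", "patient_id")]

  cl[!is.na(dev_f) & !is.na(ev_f) & dev_f == ev_f & same_day == "event",
     dev_on_event := f == dev_f]
  censor_here <- cl[, !is.na(dev_f) &
                      (is.na(ev_f) | dev_f < ev_f |
                         (dev_f == ev_f & same_day == "censor"))]
  cl[censor_here, `:=`(censored = TRUE, censor_day = dev_f)]
  cl <- cl[censor_here == FALSE | f <= dev_f]
  cl[censored & f == censor_day,
     `:=`(at_risk = FALSE, event_today = "none")]
  cl[, dev := NULL]
  cl[, ipcw := 1.0]
  setkey(cl, regime_index, patient_id, f)
  cl[]
}

# The observed standard-of-care pseudo-regime: prescription is defined
# as whatever was observed, so no clone is ever censored and weights
# are 1.  Used for the reference estimate.
observed_pseudo_clones <- function(followup) {
  cl <- as.data.table(copy(followup))
  cl[, regime_index := 0L]
  cl[, decision := (!rrt_active | rrt_started_today)]
  cl[, prescribed := decision & rrt_started_today]
  cl[, `:=`(censored = FALSE, censor_day = NA_integer_,
            at_risk = TRUE, dev_on_event = FALSE, ipcw = 1.0)]
  setkey(cl, patient_id, f)
  cl[]
}
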