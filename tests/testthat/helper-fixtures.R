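library(data.table)

# Build a hand-specified follow-up table (one regime's worth of state
# per patient-day).  `days` is a list of per-patient data.frames/lists
# with columns f, ph, k, uo, uo3, crcrit, olig2, started, active, event.
make_followup <- function(days) {
  rows <- rbindlist(lapply(seq_along(days), function(i) {
    d <- as.data.table(days[[i]])
    data.table(patient_id = i, f = d$f, day = d$f, inclusion_day = 0L,
               age = 60, sex = "M", weight = 80, admission_sofa = 8L,
               creatinine = 2.0, potassium = d$k, ph = d$ph,
               urine_output_rate = d$uo, sofa = 8L,
               uo_stage3 = d$uo3, creat_crit = d$crcrit,
               olig2_met = d$olig2, rrt_active = d$active,
               rrt_started_today = d$started, event_today = d$event)
  }))
  setkey(rows, patient_id, f)
  setattr(rows, "class", c("followup_cohort", class(rows)))
  rows[]
}

# quiet patient trajectory: no thresholds crossed, no RRT
quiet_days <- function(n_days, event_last = "none") {
  list(f = 0:(n_days - 1), ph = 7.4, k = 4.0, uo = 1.0, uo3 = FALSE,
       crcrit = TRUE, olig2 = FALSE, started = FALSE, active = FALSE,
       event = c(rep("none", n_days - 1), event_last))
}

# unit-weight clone table for estimator tests: one subject per element,
# tf = last interval index, ev = event type on that interval
make_clones <- function(tf, ev, w = rep(1, length(tf))) {
  rbindlist(lapply(seq_along(tf), function(i) {
    L <- tf[i]
    data.table(regime_index = 1L, patient_id = i, f = 0:L,
               at_risk = TRUE,
               event_today = c(rep("none", L), ev[i]),
               rrt_started_today = FALSE,
               ipcw = w[i])
  }))
}

# default decision state for prescribes_initiation tests
dec_state <- function(crcrit = TRUE, olig2 = FALSE, ph = 7.35, k = 4.5,
                      uo3 = FALSE) {
  list(creatinine_criterion_met = crcrit, oliguric_stage2_met = olig2,
       min_ph_last_24h = ph, max_k_last_24h = k,
       oliguric_stage3_last_24h = uo3)
}

# scenario with covariate-independent initiation at constant daily rate
flat_initiation_scenario <- function(rate = 0.1, n = 2000L) {
  scenario_params(n_patients = n,
                  initiation = list(intercept = qlogis(rate), potassium = 0,
                                    ph = 0, urine = 0, uo_stage3 = 0,
                                    sofa = 0))
}
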