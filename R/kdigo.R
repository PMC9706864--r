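# KDIGO-AKI staging on the daily grid and exclusion screening.
#
# Daily-mean urine output cannot resolve sub-day windows, so the
# sustained-duration criteria are approximated as:
#   stage 2: one day with mean rate < 0.5 ml/kg/h,
#   stage 3: two consecutive days with mean rate < 0.3 ml/kg/h (the
#            "24 h below 0.3" criterion is confirmed on the second day,
#            i.e. 24-36 h after oliguria onset).
# Creatinine staging uses the ratio to the baseline (first recorded ICU
# value): stage 1 at >= 1.5x, stage 2 at >= 2.0x, stage 3 at >= 3.0x or
# an absolute creatinine >= 4.0 mg/dl.

#' Daily KDIGO-AKI stages and inclusion day
#'
#' Computes per-day creatinine and urine-output stages, the combined
#' stage (their maximum), and each patient's inclusion day: the first
#' day on which the combined stage reaches 2.
#'
#' @param person_day long person-day table with columns `patient_id`,
#'   `day`, `creatinine` (mg/dl), `urine_output_rate` (ml/kg/h).
#' @param baseline_creatinine optional named vector or two-column
#'   data.frame (`patient_id`, `baseline_creatinine`); defaults to each
#'   patient's first recorded creatinine.
#' @return A list with `stages` (person-day table plus `creat_stage`,
#'   `uo_stage`, `combined_stage`, `creat_crit`, `olig2_met`,
#'   `uo_stage3`) and `inclusion` (one row per patient:
#'   `patient_id`, `inclusion_day`, `NA` when never included).
#' @export
compute_kdigo_stages <- function(person_day, baseline_creatinine = NULL) {
  pd <- as.data.table(person_day)
  req <- c("patient_id", "day", "creatinine", "urine_output_rate")
  miss <- setdiff(req, names(pd))
  if (length(miss))
    stop(sprintf("person-day table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  pd <- copy(pd)
  setkey(pd, patient_id, day)
  if (is.null(baseline_creatinine)) {
    base_cr <- pd[, .(base_creat = creatinine[1L]), by = patient_id]
  } else if (is.data.frame(baseline_creatinine)) {
    base_cr <- as.data.table(baseline_creatinine)
    setnames(base_cr, 1:2, c("patient_id", "base_creat"))
  } else {
    base_cr <- data.table(patient_id = as.integer(names(baseline_creatinine)),
                          base_creat = as.numeric(baseline_creatinine))
  }
  pd <- base_cr[pd, on = "patient_id"]
  bad <- pd[is.na(base_creat) | base_creat <= 0, unique(patient_id)]
  if (length(bad))
    stop(sprintf("missing or non-positive baseline creatinine for patient(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)

  pd[, ratio := creatinine / base_creat]
  pd[, creat_stage := ifelse(creatinine >= 4.0, 3L,
                             (ratio >= 1.5) + (ratio >= 2.0) + (ratio >= 3.0))]
  pd[, uo_low3 := urine_output_rate < 0.3]
  pd[, uo_stage := {
    prev <- shift(uo_low3, fill = FALSE)
    s3 <- uo_low3 & prev
    ifelse(s3, 3L, ifelse(urine_output_rate < 0.5, 2L, 0L))
  }, by = patient_id]
  pd[, uo_stage3 := uo_stage == 3L]
  pd[, combined_stage := pmax(creat_stage, uo_stage)]
  pd[, creat_crit := cummax(creat_stage >= 2L) > 0L, by = patient_id]
  pd[, olig2_met := cummax(uo_stage >= 2L) > 0L, by = patient_id]
  pd[, uo_low3 := NULL]

  inclusion <- pd[, {
    w <- which(combined_stage >= 2L)
    .(inclusion_day = if (length(w)) day[w[1L]] else NA_integer_)
  }, by = patient_id]
  list(stages = pd[], inclusion = inclusion[])
}

#' Screen baseline exclusion criteria
#'
#' A patient is eligible iff age > 18 years, no recorded RRT history,
#' baseline weight present, and no registered DNR restriction to start
#' RRT.  Missing flags are treated conservatively as exclusions.
#'
#' @param baseline baseline table with columns `patient_id`, `age`,
#'   `weight`, `rrt_history_flag`, `dnr_restriction_flag`.
#' @return `data.table` with `patient_id`, `eligible` and a
#'   semicolon-separated `reason` column listing every failed criterion
#'   (empty string when eligible).
#' @export
apply_exclusion_criteria <- function(baseline) {
  bl <- as.data.table(baseline)
  req <- c("patient_id", "age", "weight", "rrt_history_flag",
           "dnr_restriction_flag")
  miss <- setdiff(req, names(bl))
  if (length(miss))
    stop(sprintf("baseline table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  fail <- function(cond) {
    cond[is.na(cond)] <- TRUE
    cond
  }
  crit <- list(
    age = fail(!(bl$age > 18)),
    `rrt-history` = fail(bl$rrt_history_flag),
    `missing baseline weight` = is.na(bl$weight),
    `dnr-restriction` = fail(bl$dnr_restriction_flag))
  # missing flag fields themselves
  crit[["missing-field"]] <- is.na(bl$age) | is.na(bl$rrt_history_flag) |
    is.na(bl$dnr_restriction_flag)
  mat <- do.call(cbind, crit)
  reason <- apply(mat, 1L, function(r)
    paste(colnames(mat)[r], collapse = ";"))
  data.table(patient_id = bl$patient_id,
             eligible = !rowSums(mat) > 0,
             reason = reason)
}
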