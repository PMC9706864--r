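# Delimited-text readers/writers and validation shared by all modules.
# CSV (UTF-8, header row, RFC-4180 quoting) is the canonical
# interchange; units are fixed by the schema (creatinine mg/dl,
# potassium mEq/l, pH unitless, urine output ml/kg/h).

baseline_schema <- c("patient_id", "age", "sex", "weight",
                     "admission_category", "admission_sofa", "ckd_flag",
                     "rrt_history_flag", "dnr_restriction_flag")
person_day_schema <- c("patient_id", "day", "creatinine", "potassium",
                       "ph", "urine_output_rate", "sofa", "rrt_active",
                       "rrt_started_today", "event_today")

#' Write a cohort bundle as CSV files
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pb <- file.path(dir, "baseline.csv")
  pp <- file.path(dir, "person_day.csv")
  fwrite(as.data.table(bundle$baseline), pb)
  fwrite(as.data.table(bundle$person_day), pp)
  invisible(c(baseline = pb, person_day = pp))
}

#' Read and validate a cohort bundle from CSV files
#'
#' Extra columns are accepted (and kept, so additional covariates are
#' available to the weight model); missing required columns are a
#' schema error.
#'
#' @param baseline_path,person_day_path CSV paths.
#' @return a validated `cohort_bundle`.
#' @export
read_cohort <- function(baseline_path, person_day_path) {
  for (p in c(baseline_path, person_day_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  bl <- fread(baseline_path)
  pd <- fread(person_day_path)
  bundle <- structure(list(baseline = bl, person_day = pd,
                           provenance = c(baseline = baseline_path,
                                          person_day = person_day_path)),
                      class = "cohort_bundle")
  validate_cohort(bundle)
  bundle
}

#' Validate a cohort bundle
#'
#' Checks the schema, that every person-day `patient_id` exists in the
#' baseline table, that days are contiguous from each patient's first
#' day, and that event rows are terminal.
#'
#' @param bundle a `cohort_bundle` (or list of two tables).
#' @return the bundle, invisibly; errors describe the violation.
#' @export
validate_cohort <- function(bundle) {
  bl <- as.data.table(bundle$baseline)
  pd <- as.data.table(bundle$person_day)
  miss_b <- setdiff(baseline_schema, names(bl))
  if (length(miss_b))
    stop(sprintf("baseline schema error: missing column(s) %s",
                 paste(miss_b, collapse = ", ")), call. = FALSE)
  miss_p <- setdiff(person_day_schema, names(pd))
  if (length(miss_p))
    stop(sprintf("person-day schema error: missing column(s) %s",
                 paste(miss_p, collapse = ", ")), call. = FALSE)
  orphan <- setdiff(pd$patient_id, bl$patient_id)
  if (length(orphan))
    stop(sprintf("validation error: person-day rows with unknown patient_id: %s",
                 paste(head(orphan, 5), collapse = ", ")), call. = FALSE)
  chk <- pd[order(patient_id, day),
            .(contiguous = all(diff(day) == 1L) || .N == 1L,
              terminal = {
                ev <- which(event_today != "none")
                length(ev) == 0L || (length(ev) == 1L && ev == .N)
              }), by = patient_id]
  bad_c <- chk[contiguous == FALSE, patient_id]
  if (length(bad_c))
    stop(sprintf("validation error: non-contiguous days for patient(s): %s",
                 paste(head(bad_c, 5), collapse = ", ")), call. = FALSE)
  bad_t <- chk[terminal == FALSE, patient_id]
  if (length(bad_t))
    stop(sprintf("validation error: non-terminal event rows for patient(s): %s",
                 paste(head(bad_t, 5), collapse = ", ")), call. = FALSE)
  invisible(bundle)
}

#' Forward-fill missing laboratory values
#'
#' Fills `NA` lab values from the previous day up to `max_gap`
#' consecutive days and adds a `<column>_missing` indicator usable by
#' the weight model.
#'
#' @param person_day person-day table.
#' @param cols columns to fill.
#' @param max_gap maximum gap length to fill (default 1).
#' @return a filled copy of the table.
#' @export
fill_missing_labs <- function(person_day,
                              cols = c("creatinine", "potassium", "ph",
                                       "urine_output_rate"),
                              max_gap = 1L) {
  pd <- copy(as.data.table(person_day))
  setkey(pd, patient_id, day)
  for (cn in intersect(cols, names(pd))) {
    pd[, paste0(cn, "_missing") := as.integer(is.na(get(cn)))]
    pd[, (cn) := {
      x <- get(cn)
      gap <- 0L
      for (i in seq_along(x)) {
        if (is.na(x[i]) && i > 1L && gap < max_gap && !is.na(x[i - 1L])) {
          x[i] <- x[i - 1L]; gap <- gap + 1L
        } else if (!is.na(x[i])) gap <- 0L
      }
      x
    }, by = patient_id]
  }
  pd[]
}

#' Read a JSON run configuration
#'
#' Sections: `scenario` (passed to [scenario_params()]), `regimes`
#' (`ph_grid`, `k_grid`), `weights`, `estimation`, `cv`.  Every section
#' is optional.
#'
#' @param path JSON file.
#' @return named list of sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
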