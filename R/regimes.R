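# The threshold grid of dynamic treatment regimes: initiate RRT once the
# KDIGO stage >= 2 creatinine criterion is met and, within the last 24 h,
# pH fell below x_pH, potassium reached x_K, or the oliguric KDIGO
# stage-3 criterion was met.  Separate pH/K thresholds apply depending on
# whether the oliguric stage-2 criterion had been met by the decision
# day.  pH in {7.0, 7.1, 7.2}, K in {6.0, 6.5, 7.0} mEq/l for each of
# the two oliguria states: 3^4 = 81 regimes.

.ph_grid <- c(7.0, 7.1, 7.2)
.k_grid <- c(6.0, 6.5, 7.0)

#' Enumerate the 81 threshold regimes
#'
#' The canonical ordering advances `x_k_olig` fastest, then
#' `x_k_nonolig`, then `x_ph_olig`, with `x_ph_nonolig` slowest, so that
#' regime 1 is (7.0, 7.0, 6.0, 6.0), regime 27 is (7.2, 7.0, 7.0, 7.0)
#' and regime 81 is (7.2, 7.2, 7.0, 7.0).
#'
#' @param ph_grid,k_grid threshold grids (defaults above).
#' @return `data.table` with columns `regime_index`, `x_ph_olig`,
#'   `x_ph_nonolig`, `x_k_olig`, `x_k_nonolig`.
#' @export
enumerate_regimes <- function(ph_grid = .ph_grid, k_grid = .k_grid) {
  g <- expand.grid(x_k_olig = k_grid, x_k_nonolig = k_grid,
                   x_ph_olig = ph_grid, x_ph_nonolig = ph_grid,
                   KEEP.OUT.ATTRS = FALSE)
  out <- as.data.table(g)[, .(x_ph_olig, x_ph_nonolig, x_k_olig, x_k_nonolig)]
  out[, regime_index := .I]
  setcolorder(out, "regime_index")
  out[]
}

#' Does a regime prescribe RRT initiation in a given decision state?
#'
#' @param regime one row of [enumerate_regimes()] (or list with the four
#'   thresholds).
#' @param state list or data.frame row with logical
#'   `creatinine_criterion_met`, `oliguric_stage2_met`,
#'   `oliguric_stage3_last_24h` and numeric `min_ph_last_24h`,
#'   `max_k_last_24h`.  Vectors are accepted and recycled against the
#'   single regime.
#' @return logical: `TRUE` iff the creatinine criterion is met and at
#'   least one of the pH, potassium or persisting-oliguria triggers
#'   fired (pH strictly below, potassium at or above its threshold).
#' @export
prescribes_initiation <- function(regime, state) {
  regime <- as.list(regime)
  st <- as.list(state)
  need <- c("creatinine_criterion_met", "oliguric_stage2_met",
            "min_ph_last_24h", "max_k_last_24h", "oliguric_stage3_last_24h")
  miss <- setdiff(need, names(st))
  if (length(miss))
    stop(sprintf("decision state lacks field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyNA(st$min_ph_last_24h) || anyNA(st$max_k_last_24h))
    stop("decision error: missing lab window (pH/potassium)", call. = FALSE)
  xph <- ifelse(st$oliguric_stage2_met, regime$x_ph_olig, regime$x_ph_nonolig)
  xk <- ifelse(st$oliguric_stage2_met, regime$x_k_olig, regime$x_k_nonolig)
  st$creatinine_criterion_met &
    (st$min_ph_last_24h < xph |
       st$max_k_last_24h >= xk |
       st$oliguric_stage3_last_24h)
}

# Vectorised internal form used on the follow-up table: thresholds are
# scalars, state columns are vectors.
prescribes_vec <- function(creat_crit, olig2, ph, k, uo3,
                           x_ph_olig, x_ph_nonolig, x_k_olig, x_k_nonolig) {
  xph <- ifelse(olig2, x_ph_olig, x_ph_nonolig)
  xk <- ifelse(olig2, x_k_olig, x_k_nonolig)
  creat_crit & (ph < xph | k >= xk | uo3)
}
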