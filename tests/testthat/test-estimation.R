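# Weighted Aalen-Johansen estimator, variance, expected initiations.
# Convention: an event on clone row f is counted in the CIF at grid
# time f + 1, so "death on day 1" is an event on row f = 0.

test_that("the four-subject hand example matches the product-limit arithmetic", {
  cl <- make_clones(tf = c(0, 1, 2, 29),
                    ev = c("death", "discharge", "death", "none"))
  cv <- weighted_aalen_johansen(cl)
  expect_equal(cv$cif_death[2], 0.25)        # day 1
  expect_equal(cv$cif_death[3], 0.25)        # day 2
  expect_equal(cv$cif_death[4], 0.50)        # day 3
  expect_equal(cv$cif_death[31], 0.50)       # day 30
  expect_equal(cv$cif_discharge[31], 0.25)
  expect_equal(cv$surv[31], 0.25)
})

test_that("with unit weights and one event type the estimator is 1 - KM", {
  skip_if_not_installed("survival")
  set.seed(77)
  for (r in 1:50) {
    n <- sample(15:50, 1)
    tf <- sample(0:29, n, replace = TRUE)
    died <- runif(n) < runif(1, 0.3, 0.9)
    cl <- make_clones(tf = ifelse(died, tf, 29L),
                      ev = ifelse(died, "death", "none"))
    cv <- weighted_aalen_johansen(cl, events = "death")
    sf <- survival::survfit(
      survival::Surv(ifelse(died, tf + 1, 30), died) ~ 1)
    km <- summary(sf, times = 0:30, extend = TRUE)$surv
    expect_equal(cv$cif_death, 1 - km, tolerance = 1e-12)
  }
})

test_that("rescaling all weights leaves every CIF value unchanged", {
  set.seed(5)
  cl <- make_clones(tf = sample(0:29, 40, TRUE),
                    ev = sample(c("death", "discharge", "none"), 40, TRUE),
                    w = runif(40, 0.5, 3))
  a <- weighted_aalen_johansen(cl)
  cl2 <- copy(cl)[, ipcw := ipcw * 2]
  b <- weighted_aalen_johansen(cl2)
  expect_equal(a$cif_death, b$cif_death)
  expect_equal(a$cif_discharge, b$cif_discharge)
})

test_that("curve invariants hold on weighted clone data", {
  set.seed(8)
  cl <- make_clones(tf = sample(0:29, 60, TRUE),
                    ev = sample(c("death", "discharge", "none"), 60, TRUE),
                    w = runif(60, 0.2, 5))
  cv <- weighted_aalen_johansen(cl)
  expect_true(all(abs(cv$cif_death + cv$cif_discharge + cv$surv - 1) < 1e-9))
  expect_true(all(diff(cv$cif_death) >= 0))
  expect_true(all(diff(cv$cif_discharge) >= 0))
})

test_that("degenerate inputs raise the documented errors", {
  cl <- make_clones(tf = c(2, 4), ev = c("death", "death"))
  cl[, ipcw := c(rep(1, 3), rep(-1, 5))]
  expect_error(weighted_aalen_johansen(cl), "finite and non-negative")
  # empty risk set before a later event
  cl2 <- rbindlist(list(
    data.table(regime_index = 1L, patient_id = 1L, f = 0:0, at_risk = TRUE,
               event_today = "death", rrt_started_today = FALSE, ipcw = 1),
    data.table(regime_index = 1L, patient_id = 2L, f = c(3L, 4L),
               at_risk = TRUE, event_today = c("none", "death"),
               rrt_started_today = FALSE, ipcw = 1)))
  expect_error(weighted_aalen_johansen(cl2), "empty risk set")
  cl3 <- make_clones(tf = 3, ev = "death")
  cv3 <- weighted_aalen_johansen(cl3)
  expect_error(estimate_variance(cv3, "patient-bootstrap", B = 1), "B")
})

test_that("IJ variance is zero for one patient and Greenwood for KM", {
  cv1 <- estimate_variance(weighted_aalen_johansen(
    make_clones(tf = 5, ev = "death")), "infinitesimal-jackknife")
  expect_true(all(cv1$var_death == 0))

  skip_if_not_installed("survival")
  set.seed(11)
  for (r in 1:50) {
    n <- sample(20:60, 1)
    tf <- sample(0:29, n, replace = TRUE)
    died <- runif(n) < 0.6
    cl <- make_clones(tf = ifelse(died, tf, 29L),
                      ev = ifelse(died, "death", "none"))
    cv <- estimate_variance(weighted_aalen_johansen(cl, events = "death"),
                            "infinitesimal-jackknife")
    sf <- summary(survival::survfit(
      survival::Surv(ifelse(died, tf + 1, 30), died) ~ 1),
      times = 30, extend = TRUE)
    gw <- sf$std.err^2  # Greenwood variance of S = variance of 1 - KM
    if (gw > 0)
      expect_lt(abs(cv$var_death[31] / gw - 1), 0.10)
  }
})

test_that("bootstrap intervals bracket the point estimate", {
  set.seed(21)
  cl <- make_clones(tf = sample(0:29, 80, TRUE),
                    ev = sample(c("death", "discharge", "none"), 80, TRUE,
                                prob = c(0.3, 0.5, 0.2)))
  cv <- estimate_variance(weighted_aalen_johansen(cl), "patient-bootstrap",
                          B = 300, seed = 1)
  expect_true(cv$ci_low_death[31] <= cv$cif_death[31])
  expect_true(cv$ci_high_death[31] >= cv$cif_death[31])
  expect_true(all(cv$ci_low_death >= 0 & cv$ci_high_death <= 1))
  # reproducible given the seed
  cv2 <- estimate_variance(weighted_aalen_johansen(cl), "patient-bootstrap",
                           B = 300, seed = 1)
  expect_equal(cv$ci_low_death, cv2$ci_low_death)
})

test_that("expected initiations reduce to the raw count under observed care", {
  coh <- generate_cohort(scenario_params(n_patients = 400), seed = 19)
  fu <- build_followup(coh)
  cl <- icudtr:::observed_pseudo_clones(fu)
  ei <- expected_initiations(cl, B = 100, seed = 2)
  raw <- fu[, any(rrt_started_today), by = patient_id][, sum(V1)]
  expect_equal(ei$expected, raw)
  expect_true(ei$ci_low <= ei$expected && ei$expected <= ei$ci_high)
})

test_that("a never-initiating regime in a no-initiation cohort expects zero", {
  fu <- make_followup(list(quiet_days(10), quiet_days(8, "discharge")))
  r9 <- enumerate_regimes()[9]
  cl <- apply_censoring(expand_clones(fu, r9), r9)
  cl[, p_init := 0.05]
  cl <- compute_ipc_weights(NULL, cl)
  ei <- expected_initiations(cl, B = 0)
  expect_equal(ei$expected, 0)
})
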