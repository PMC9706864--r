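# Pooled logistic initiation model and IPC weights.

r9 <- enumerate_regimes()[9]

test_that("a cohort without initiations is a degenerate outcome", {
  coh <- generate_cohort(scenario_params(
    n_patients = 150, initiation = list(intercept = -30)), seed = 3)
  fu <- build_followup(coh)
  expect_error(fit_initiation_model(fu), "degenerate outcome")
})

test_that("an intercept-only model recovers logit of the constant rate", {
  p <- flat_initiation_scenario(rate = 0.1, n = 4000L)
  fu <- build_followup(generate_cohort(p, seed = 18))
  m <- fit_initiation_model(
    fu, covariates = list(baseline = character(0), timevarying = character(0)),
    time_form = "none")
  a <- coef(m$fit)[["(Intercept)"]]
  se <- sqrt(diag(vcov(m$fit)))[["(Intercept)"]]
  expect_lt(abs(a - qlogis(0.1)), max(3 * se, 0.05))
})

test_that("estimated coefficients cover the truth at the nominal rate", {
  # scaled-down Monte Carlo coverage study: 40 replicates, Wald 95% CIs
  # for the potassium coefficient (truth 0.9); pass bound 0.85 chosen a
  # priori from binomial noise at R = 40
  R <- 40L; hits <- 0L
  p <- scenario_params(n_patients = 1200)
  for (r in seq_len(R)) {
    fu <- build_followup(generate_cohort(p, seed = 900 + r))
    m <- suppressWarnings(fit_initiation_model(fu, time_form = "none"))
    if (!is.null(m$ridge)) { hits <- hits + 1L; next }  # rare fallback
    est <- coef(m$fit)[["potassium"]]
    se <- sqrt(diag(vcov(m$fit)))[["potassium"]]
    hits <- hits + (abs(est - 0.9) <= qnorm(0.975) * se)
  }
  expect_gte(hits / R, 0.85)
})

test_that("weights follow the closed-form product", {
  # p_uncensored = 0.8 on three consecutive days -> W = 1/0.8^3
  fu <- make_followup(list(quiet_days(3)))
  cl <- apply_censoring(expand_clones(fu, r9), r9)
  cl[, p_init := 0.2]
  cl <- compute_ipc_weights(NULL, cl)
  expect_equal(cl$p_uncensored, rep(0.8, 3))
  expect_equal(cl$ipcw[3], 1.953125)
})

test_that("zero initiation risk gives unit weights everywhere", {
  fu <- make_followup(list(quiet_days(5), quiet_days(4)))
  cl <- apply_censoring(expand_clones(fu, r9), r9)
  cl[, p_init := 0]
  cl <- compute_ipc_weights(NULL, cl)
  expect_true(all(cl$ipcw == 1))
})

test_that("weights are 1 after a concordant initiation", {
  k <- c(4, 4, 7.2, 4, 4)
  fu <- make_followup(list(list(f = 0:4, ph = 7.4, k = k, uo = 1, uo3 = FALSE,
                                crcrit = TRUE, olig2 = FALSE,
                                started = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                                active = c(FALSE, FALSE, TRUE, TRUE, TRUE),
                                event = rep("none", 5))))
  cl <- apply_censoring(expand_clones(fu, r9), r9)
  cl[, p_init := 0.25]
  cl <- compute_ipc_weights(NULL, cl)
  # two non-prescribed days at 1/0.75, the start day at 1/0.25, then flat
  w_expect <- c(1 / 0.75, 1 / 0.75^2, 1 / 0.75^2 / 0.25,
                1 / 0.75^2 / 0.25, 1 / 0.75^2 / 0.25)
  expect_equal(cl$ipcw, w_expect)
  expect_equal(cl$p_uncensored[4:5], c(1, 1))
})

test_that("truncation caps at the pooled order statistic", {
  fu <- make_followup(list(quiet_days(1), quiet_days(1),
                           quiet_days(1), quiet_days(1)))
  cl <- apply_censoring(expand_clones(fu, r9), r9)
  cl[, ipcw := c(1, 1, 1, 100)]
  tr <- truncate_weights(cl, 0.75)
  expect_equal(sort(tr$ipcw), c(1, 1, 1, 1))
  expect_equal(tr$ipcw_raw[4], 100)
  id <- truncate_weights(cl, 1)
  expect_equal(id$ipcw, cl$ipcw)
  expect_error(truncate_weights(cl, 0.4), "upper_percentile")
})

test_that("the re-weighted pseudo-population keeps the cohort size", {
  p <- flat_initiation_scenario(rate = 0.1, n = 1500L)
  fu <- build_followup(generate_cohort(p, seed = 31))
  m <- fit_initiation_model(fu)
  fu2 <- copy(fu)
  fu2[, p_init := predict(m, fu2)]
  cl <- apply_censoring(expand_clones(fu2, r9), r9)
  cl <- compute_ipc_weights(NULL, cl)
  wc <- weight_calibration(cl)
  for (t in c(0L, 3L, 8L, 15L)) {
    row <- wc[f == t]
    expect_lt(abs(row$mean_w - 1), max(3 * row$se_w, 0.02))
  }
})

test_that("weights are robust to an extra zero-effect covariate", {
  p <- default_scenario(n_patients = 1500)
  fu <- build_followup(generate_cohort(p, seed = 41))
  set.seed(1); fu[, noise_cov := rnorm(.N)]
  m0 <- fit_initiation_model(fu)
  covs <- default_covariates()
  covs$timevarying <- c(covs$timevarying, "noise_cov")
  m1 <- fit_initiation_model(fu, covariates = covs)
  p0 <- predict(m0, fu); p1 <- predict(m1, fu)
  expect_gt(cor(p0, p1), 0.99)
})

test_that("positivity violations are reported with the offending day", {
  fu <- make_followup(list(quiet_days(2)))
  cl <- apply_censoring(expand_clones(fu, r9), r9)
  cl[, p_init := c(1, 0.5)]  # p_uncensored = 0 on a non-prescribed day
  expect_error(compute_ipc_weights(NULL, cl), "positivity")
})
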