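# Closed-form equivalences on hand-laid covariate-free data, matching each
# estimator's defining arithmetic, plus behavioural checks on simulated data.

test_that("the IV estimate on covariate-free binary data reduces to the Wald ratio", {
  # E[Y1|Z=1]=0.6, E[Y1|Z=0]=0.4, E[X|Z=1]=0.8, E[X|Z=0]=0.3 -> ratio 0.4
  z <- rep(c(1L, 0L), each = 10)
  d <- make_manual_dataset(
    z = z,
    x = c(binary_vec(10, 8), binary_vec(10, 3)),
    y0 = rep(0:1, 10),
    y1 = c(binary_vec(10, 6), binary_vec(10, 4))
  )
  est <- suppressWarnings(
    fit_iv(d, covariates = character(0), second_stage = "linear"))
  wald <- (0.6 - 0.4) / (0.8 - 0.3)
  expect_equal(est$beta_hat, wald, tolerance = 1e-10)
})

test_that("the linear DiD estimate on covariate-free data is the four-mean plug-in", {
  d <- make_manual_dataset(
    z = rep(c(0L, 1L), each = 20),
    x = rep(c(0L, 1L), each = 20),
    y0 = c(binary_vec(20, 2), binary_vec(20, 6)),   # prior rates 0.1 / 0.3
    y1 = c(binary_vec(20, 4), binary_vec(20, 10))   # study rates 0.2 / 0.5
  )
  est <- fit_did(d, family = "linear", adjust = FALSE)
  oracle <- (0.5 - 0.2) - (0.3 - 0.1)
  expect_equal(est$beta_hat, oracle, tolerance = 1e-10)

  # parallel arm-wise gaps across periods cancel exactly
  dpar <- make_manual_dataset(
    z = rep(c(0L, 1L), each = 20),
    x = rep(c(0L, 1L), each = 20),
    y0 = c(binary_vec(20, 2), binary_vec(20, 8)),
    y1 = c(binary_vec(20, 4), binary_vec(20, 10))   # both gaps 0.3
  )
  est0 <- fit_did(dpar, family = "linear", adjust = FALSE)
  expect_equal(est0$beta_hat, 0, tolerance = 1e-10)
})

test_that("linear-family CaT equals the raw difference in event proportions", {
  d <- make_manual_dataset(
    z = rep(0L, 30),
    x = rep(c(1L, 0L), c(12, 18)),
    y0 = rep(0L, 30),
    y1 = c(binary_vec(12, 6), binary_vec(18, 3))
  )
  est <- fit_cat(d, covariates = character(0), family = "linear")
  expect_equal(est$beta_hat, 6 / 12 - 3 / 18, tolerance = 1e-12)
})

test_that("stacking the two periods follows the definition", {
  d <- make_manual_dataset(z = 0L, x = 1L, y0 = 0L, y1 = 1L,
                           w0 = 0.3, w1 = -0.2)
  st <- stack_periods(d)
  expect_equal(nrow(st), 2L)
  expect_equal(st$y_star, c(0L, 1L))
  expect_equal(st$p_star, c(0L, 1L))
  expect_equal(st$x_star, c(1L, 1L))
  expect_equal(st$w_star, c(0.3, -0.2))

  dd <- simulate_dataset(small_config(n = 400L), 3)
  st <- stack_periods(dd)
  expect_equal(nrow(st), 800L)
  expect_equal(sum(table(st$patient_id) == 2L), 400L)
  # group means of y* by (period, arm) equal directly tabulated event rates
  for (p in 0:1) {
    for (a in 0:1) {
      direct <- mean(if (p == 1) dd$y1[dd$x == a] else dd$y0[dd$x == a])
      stacked <- mean(st$y_star[st$p_star == p & st$x_star == a])
      expect_equal(stacked, direct)
    }
  }
})

test_that("greedy propensity matching reproduces the brute-force pairing", {
  ps <- c(0.10, 0.50, 0.90, 0.12, 0.48, 0.88, 0.30, 0.70)
  treated <- c(rep(TRUE, 3), rep(FALSE, 5))
  m <- causaltri:::greedy_match(ps, treated, patient_id = 1:8, seed = 1)
  # unambiguous nearest neighbours: 1-4, 2-5, 3-6 whatever the order
  pairing <- m$control[order(m$treated)]
  expect_equal(m$treated[order(m$treated)], 1:3)
  expect_equal(pairing, 4:6)

  # exact distance ties resolve to the lowest patient id
  mt <- causaltri:::greedy_match(c(0.5, 0.4, 0.6), c(TRUE, FALSE, FALSE),
                                 patient_id = 1:3, seed = 1)
  expect_equal(mt$control, 2L)

  # caliper excludes distant pairs entirely
  mc <- causaltri:::greedy_match(c(0.9, 0.1, 0.15), c(TRUE, FALSE, FALSE),
                                 patient_id = 1:3, seed = 1, caliper = 0.2)
  expect_length(mc$treated, 0L)
})

test_that("PSM with a constant propensity score equals the unadjusted contrast", {
  d <- make_manual_dataset(
    z = rep(0L, 40),
    x = rep(c(1L, 0L), each = 20),
    y0 = rep(0L, 40),
    y1 = c(binary_vec(20, 9), binary_vec(20, 4))
  )
  est <- fit_psm(d, covariates = character(0), seed = 2)
  expect_equal(est$diagnostics$matched_fraction, 1)
  expect_equal(est$beta_hat, 9 / 20 - 4 / 20, tolerance = 1e-10)
})

test_that("PSM and CaT agree when measured confounding is fully adjusted", {
  d <- simulate_dataset(small_config(n = 4000L), 17)
  e_cat <- fit_cat(d)
  e_psm <- fit_psm(d, seed = 3)
  expect_gt(e_psm$diagnostics$matched_fraction, 0.5)
  expect_lt(abs(e_psm$beta_hat - e_cat$beta_hat),
            3 * sqrt(e_cat$se^2 + e_psm$se^2))
  # matching improves or retains covariate balance
  expect_lte(abs(e_psm$diagnostics$smd_post["w1"]),
             abs(e_psm$diagnostics$smd_pre["w1"]) + 0.05)
})

test_that("an irrelevant instrument yields a small F and a weak-instrument warning", {
  set.seed(51)
  n <- 2000L
  d <- make_manual_dataset(
    z = rep(c(0L, 1L), each = n / 2),
    x = rbinom(n, 1, 0.5),
    y0 = rbinom(n, 1, 0.2),
    y1 = rbinom(n, 1, 0.2),
    w0 = rnorm(n), w1 = rnorm(n)
  )
  expect_lt(first_stage_f(d, "z"), 10)
  expect_warning(fit_iv(d), "weak instrument")

  # an augmented instrument with a null interaction coefficient is weak too
  cfg <- make_scenario_config("poa1", list(coef = list(x_y0z = 0)))
  dp <- simulate_dataset(cfg, 5)
  expect_lt(first_stage_f(dp, "y0z"), 10)
  expect_warning(e <- fit_poa_iv(dp), "weak instrument")
  expect_gt(e$se, fit_iv(dp)$se)  # inflated uncertainty
})

test_that("CF agrees with CaT when there is no unmeasured confounding", {
  d <- simulate_dataset(small_config(n = 20000L), 23)
  e_cf <- fit_cf(d)
  e_cat <- fit_cat(d)
  expect_lt(abs(e_cf$beta_hat - e_cat$beta_hat), 3 * e_cf$se)
  # POA variants are also consistent here and agree with CaT
  dp <- simulate_dataset(
    make_scenario_config("custom",
      list(n = 20000L, flags = list(poa_relevance = TRUE, did1_violated = TRUE))),
    23)
  e_pcf <- fit_poa_cf(dp)
  expect_lt(abs(e_pcf$beta_hat - fit_cat(dp, include_y0 = TRUE)$beta_hat),
            3 * e_pcf$se)
})

test_that("perfect separation is reported with the offending term", {
  d <- make_manual_dataset(
    z = rep(0L, 40),
    x = rep(c(1L, 0L), each = 20),
    y0 = rep(0L, 40),
    y1 = rep(c(1L, 0L), each = 20),
    w0 = rnorm(40), w1 = rnorm(40)
  )
  expect_error(fit_cat(d), "separation")
})

test_that("degenerate periods are rejected by the DiD estimator", {
  d <- make_manual_dataset(
    z = rep(0L, 20),
    x = rep(c(1L, 0L), each = 10),
    y0 = rep(0L, 20),
    y1 = rbinom(20, 1, 0.5)
  )
  expect_error(fit_did(d), "degenerate period")
})

test_that("effect estimates carry coherent inference fields", {
  d <- simulate_dataset(small_config(n = 2000L), 29)
  for (m in c("cat", "iv", "cf", "did")) {
    e <- fit_method(d, m)
    expect_s3_class(e, "effect_estimate")
    expect_lte(e$ci_low, e$beta_hat)
    expect_gte(e$ci_high, e$beta_hat)
    expect_gt(e$se, 0)
    expect_gte(e$p_value, 0)
    expect_lte(e$p_value, 1)
    expect_equal(e$n_used, 2000L)
  }
  expect_error(fit_method(d, "nonsense"), "unknown method")
})

test_that("estimators never consume the oracle-only columns", {
  d <- simulate_dataset(small_config(n = 2000L), 37)
  d_corrupt <- d
  d_corrupt$u <- 99
  d_corrupt$y1_po_1 <- 1L
  d_corrupt$y1_po_0 <- 0L
  for (m in c("cat", "psm", "iv", "cf", "did", "poa_iv", "poa_cf")) {
    e1 <- suppressWarnings(fit_method(d, m))
    e2 <- suppressWarnings(fit_method(d_corrupt, m))
    expect_identical(e1$beta_hat, e2$beta_hat)
  }
})

test_that("delta-method SEs agree with patient-level bootstrap SEs", {
  d <- simulate_dataset(make_scenario_config("base1"), 43)
  cv <- bootstrap_covariance(d, c("cat", "did"), B = 300, seed = 44)
  boot_se <- sqrt(diag(cv))
  model_se <- c(fit_cat(d)$se, fit_did(d)$se)
  expect_lt(max(abs(boot_se - model_se) / model_se), 0.15)
})
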