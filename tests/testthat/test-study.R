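test_that("performance metrics follow their defining arithmetic", {
  # replicates equal to the truth: zero bias and MSE, full coverage
  m <- performance_metrics(rep(0.1, 4), rep(0.01, 4), rep(0.05, 4),
                           rep(0.15, 4), rep(0.001, 4), truth = 0.1)
  expect_equal(m$bias, 0)
  expect_equal(m$mse, 0)
  expect_equal(m$coverage, 1)

  # hand-computed two-replicate case
  m2 <- performance_metrics(c(0.0, 0.2), c(0.01, 0.01), c(-0.1, 0.1),
                            c(0.1, 0.3), c(0.5, 0.01), truth = 0.1)
  expect_equal(m2$bias, 0)
  expect_equal(m2$emp_se, sd(c(0.0, 0.2)))
  expect_equal(m2$mse, 0.01)
  expect_equal(m2$coverage, 1)
  expect_equal(m2$t1e, 0.5)

  # closed-form coverage MCSE at p = 0.95, R = 1000
  p <- 0.95
  m3 <- performance_metrics(rep(0.1, 1000), rep(0.01, 1000),
                            rep(c(0.05, 0.15), c(950, 50)),
                            rep(0.15, 1000), rep(0.5, 1000), truth = 0.1)
  expect_equal(m3$coverage, p)
  expect_equal(m3$coverage_mcse, sqrt(p * (1 - p) / 1000), tolerance = 1e-12)

  expect_error(performance_metrics(1:3, 1:2, 1:3, 1:3, 1:3, 0), "length")
})

test_that("MSE decomposes into squared bias plus scaled variance", {
  set.seed(91)
  est <- rnorm(200, 0.12, 0.03)
  m <- performance_metrics(est, rep(0.03, 200), est - 0.06, est + 0.06,
                           runif(200), truth = 0.1)
  expect_equal(m$mse, m$bias^2 + m$emp_se^2 * 199 / 200, tolerance = 1e-12)
})

test_that("simulation studies are byte-reproducible under a fixed master seed", {
  s1 <- run_simulation_study("base1", methods = "cat", n_reps = 2,
                             master_seed = 5, overrides = list(n = 500),
                             n_mc_truth = 1e4)
  s2 <- run_simulation_study("base1", methods = "cat", n_reps = 2,
                             master_seed = 5, overrides = list(n = 500),
                             n_mc_truth = 1e4)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- run_simulation_study("base1", methods = "cat", n_reps = 2,
                             master_seed = 6, overrides = list(n = 500),
                             n_mc_truth = 1e4)
  expect_false(identical(s1$bias, s3$bias))
})

test_that("scenario-driven adjustment sets are applied automatically", {
  # under an exclusion-restriction violation CaT is reported with Z included
  s <- run_simulation_study("base3", methods = c("cat", "did"), n_reps = 2,
                            master_seed = 7, overrides = list(n = 500),
                            n_mc_truth = 1e4)
  expect_setequal(s$method, c("CaT+Z", "DiD+Z"))
  s0 <- run_simulation_study("base3", methods = "cat", n_reps = 2,
                             master_seed = 7, overrides = list(n = 500),
                             auto_adjust = FALSE, n_mc_truth = 1e4)
  expect_equal(s0$method, "CaT")
})

test_that("the preference instrument is the provider's previous prescription", {
  recs <- data.frame(provider_id = 1L, patient_id = 1:4,
                     order_index = 1:4, treatment = c(1L, 0L, 0L, 1L))
  z <- build_preference_iv(recs)
  expect_equal(z$patient_id, 2:4)
  expect_equal(z$z, c(1L, 0L, 0L))

  # a single-patient provider contributes nothing
  solo <- data.frame(provider_id = 2L, patient_id = 9L,
                     order_index = 1L, treatment = 1L)
  expect_equal(nrow(build_preference_iv(solo)), 0L)
  both <- build_preference_iv(rbind(recs, solo))
  expect_equal(both$patient_id, 2:4)

  # duplicate time ranks within a provider are invalid
  dup <- recs; dup$order_index <- c(1L, 2L, 2L, 3L)
  expect_error(build_preference_iv(dup), "duplicate order_index")

  # a wider window takes the majority of recent prescriptions
  recs5 <- data.frame(provider_id = 1L, patient_id = 1:5,
                      order_index = 1:5, treatment = c(1L, 1L, 0L, 0L, 0L))
  z2 <- build_preference_iv(recs5, window = 2)
  expect_equal(z2$patient_id, 3:5)
  # rank 4 sees (1, 0): the tie resolves to the most recent prescription (0)
  expect_equal(z2$z, c(1L, 0L, 0L))
})

test_that("a sticky-preference prescribing stream yields a strong instrument", {
  set.seed(95)
  n_prov <- 30L; per <- 40L
  recs <- do.call(rbind, lapply(seq_len(n_prov), function(g) {
    pref <- sample(c(0.15, 0.85), 1)
    data.frame(provider_id = g,
               patient_id = (g - 1L) * per + seq_len(per),
               order_index = seq_len(per),
               treatment = rbinom(per, 1L, pref))
  }))
  zmap <- build_preference_iv(recs)
  d <- merge(recs, zmap, by = "patient_id")
  dat <- data.frame(patient_id = d$patient_id, cluster_id = d$provider_id,
                    z = d$z, x = d$treatment,
                    y0 = 0L, y1 = 0L, w0 = rnorm(nrow(d)), w1 = rnorm(nrow(d)))
  expect_gt(first_stage_f(dat, "z"), 10)
})

test_that("rejection is certain at a degenerate test level", {
  res <- run_qtest_study("base1", list(c("cat", "did")), n_reps = 50, B = 100,
                         master_seed = 9, alpha = 1,
                         overrides = list(n = 200))
  expect_equal(res$rejection_rate, 1)
  expect_equal(res$ci_high, 1)
})

test_that("study preconditions are enforced", {
  expect_error(run_qtest_study("base1", list("cat"), n_reps = 50, B = 100),
               "at least 2 methods")
  expect_error(run_qtest_study("base1", list(c("cat", "did")), n_reps = 10,
                               B = 100), "at least 50")
  expect_error(run_qtest_study("base1", list(c("cat", "did")), n_reps = 50,
                               B = 50), "at least 100")
  expect_error(run_simulation_study("base1", n_reps = 1), "at least 2")
})
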