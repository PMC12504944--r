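# Clamp a probability-scale linear predictor to [floor, 1 - floor]; a clamped
# fraction above tol signals miscalibrated coefficients and is a hard error.
clamp_probs <- function(p, floor, tol, what) {
  clamped <- p < floor | p > 1 - floor
  frac <- mean(clamped)
  if (frac > tol) {
    stop("probability model for ", what, " clamped for ",
         sprintf("%.1f%%", 100 * frac), " of patients (tolerance ",
         sprintf("%.1f%%", 100 * tol), "); coefficients are miscalibrated")
  }
  pmin(pmax(p, floor), 1 - floor)
}

#' Simulate one two-period observational dataset
#'
#' Generates patient-level data under the scenario's data-generating process:
#' a binary cluster-level instrument Z (provider preference), continuous
#' measured confounders W0/W1, a standard-normal unmeasured confounder U,
#' binary prior and study outcomes Y0/Y1, a binary treatment X, and both
#' potential study outcomes. The study outcome is linear on the probability
#' scale with an additive treatment effect, so the ground-truth estimand is
#' the configured risk difference (up to rare clamping at the probability
#' floor).
#'
#' The columns `u`, `y1_po_1` and `y1_po_0` are oracle-only: they exist so
#' that simulation studies can compute the truth, and no estimator in this
#' package reads them.
#'
#' @param config A [make_scenario_config()] object.
#' @param seed Integer seed; the same (config, seed) pair always yields an
#'   identical dataset, and the caller's RNG state is left untouched.
#' @return A data.frame with columns `patient_id`, `cluster_id`, `z`, `x`,
#'   `y0`, `y1`, `w0`, `w1`, `u`, `y1_po_1`, `y1_po_0`.
#' @examples
#' dat <- simulate_dataset(make_scenario_config("base1", list(n = 500)), seed = 1)
#' head(dat)
#' @export
simulate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  n <- config$n; n_g <- config$n_g
  cf <- config$coef; fl <- config$flags
  eps <- config$prob_floor; tol <- config$clamp_tol

  with_seed(seed, {
    cluster_id <- rep(seq_len(n_g), each = n %/% n_g)
    z_cluster <- rbinom(n_g, 1L, cf$z_prev)
    z <- z_cluster[cluster_id]

    u  <- rnorm(n)
    w0 <- rnorm(n)
    w1 <- cf$rho_w * w0 + sqrt(1 - cf$rho_w^2) * rnorm(n)

    p0 <- cf$y0_int + cf$y0_w0 * w0 +
      (if (fl$y0_confounded) cf$y0_u * u else 0)
    p0 <- clamp_probs(p0, eps, tol, "y0")
    y0 <- rbinom(n, 1L, p0)

    lin_x <- cf$x_int + cf$x_z * z + cf$x_w1 * w1 +
      (if (fl$did1_violated) cf$x_y0 * y0 else 0) +
      (if (fl$nuc_violated) cf$x_u * u else 0) +
      (if (fl$poa_relevance) cf$x_y0z * y0 * z else 0)
    x <- rbinom(n, 1L, plogis(lin_x))

    q_base <- cf$y1_int + cf$y1_w1 * w1 +
      (if (fl$nuc_violated) cf$y1_u * u else 0) +
      (if (fl$iv2_violated) cf$y1_z * z else 0) +
      (if (fl$y0_direct) cf$y1_y0 * y0 else 0)
    q0 <- clamp_probs(q_base, eps, tol, "y1 under x = 0")
    q1 <- clamp_probs(q_base + config$beta, eps, tol, "y1 under x = 1")
    y1_po_0 <- rbinom(n, 1L, q0)
    y1_po_1 <- rbinom(n, 1L, q1)
    y1 <- ifelse(x == 1L, y1_po_1, y1_po_0)

    data.frame(
      patient_id = seq_len(n), cluster_id = cluster_id,
      z = z, x = x, y0 = y0, y1 = y1, w0 = w0, w1 = w1,
      u = u, y1_po_1 = y1_po_1, y1_po_0 = y1_po_0
    )
  })
}

#' Monte-Carlo ground-truth risk difference of a scenario
#'
#' Simulates a fresh sample and averages the difference of the two stored
#' potential outcomes. Equals the configured `beta` in expectation whenever
#' no clamping at the probability floor occurs.
#'
#' @param config A `scenario_config`.
#' @param n_mc Monte-Carlo sample size (at least 1e4); rounded up to a
#'   multiple of the cluster count.
#' @param seed Integer seed.
#' @return The Monte-Carlo mean of `y1_po_1 - y1_po_0`.
#' @export
true_effect <- function(config, n_mc = 2e5, seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_mc < 1e4) validation_error("n_mc must be at least 1e4")
  cfg <- config
  cfg$n <- as.integer(ceiling(n_mc / cfg$n_g) * cfg$n_g)
  dat <- simulate_dataset(cfg, seed)
  mean(dat$y1_po_1 - dat$y1_po_0)
}
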