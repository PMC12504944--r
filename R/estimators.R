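# The seven effect estimators. Every estimator reports the treatment effect
# as an average marginal effect on the risk-difference scale with a
# delta-method standard error, a Wald confidence interval and a two-sided
# p-value, packed into an `effect_estimate`.

require_columns <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    validation_error("dataset lacks required column(s): ",
                     paste(miss, collapse = ", "))
  }
  invisible(data)
}

cov_matrix <- function(data, covariates) {
  if (!length(covariates)) return(NULL)
  m <- as.matrix(data[covariates])
  colnames(m) <- covariates
  m
}

#' Confounder-adjusted outcome regression ('Corrected as Treated')
#'
#' Logistic regression of the study outcome on treatment and measured
#' confounders; the treatment effect is the AME of the treatment indicator.
#' `include_z` adds the instrument as a measured confounder (appropriate when
#' the instrument has a direct outcome effect), `include_y0` adds the prior
#' outcome.
#'
#' @param data Dataset with columns `x`, `y1`, and the covariates.
#' @param include_z,include_y0 Add `z` / `y0` to the adjustment set.
#' @param covariates Character vector of confounder columns (default `"w1"`).
#' @param family `"logistic"` (default) or `"linear"` outcome model.
#' @param level Confidence level.
#' @return An `effect_estimate`.
#' @export
fit_cat <- function(data, include_z = FALSE, include_y0 = FALSE,
                    covariates = "w1", family = c("logistic", "linear"),
                    level = 0.95) {
  family <- match.arg(family)
  require_columns(data, c("x", "y1", covariates,
                          if (include_z) "z", if (include_y0) "y0"))
  X <- cbind(`(Intercept)` = 1, x = data$x, cov_matrix(data, covariates),
             if (include_z) cbind(z = data$z),
             if (include_y0) cbind(y0 = data$y0))
  fit <- if (family == "logistic") logit_fit(X, data$y1) else linear_fit(X, data$y1)
  X1 <- X; X1[, "x"] <- 1
  X0 <- X; X0[, "x"] <- 0
  a <- ame_contrast(fit, X1, X0)
  new_effect_estimate(
    method = if (include_z) "CaT+Z" else "CaT",
    beta_hat = a["est"], se = a["se"], n_used = nrow(data),
    diagnostics = list(converged = fit$converged, family = family),
    level = level
  )
}

# Greedy 1-1 nearest-neighbour matching on the propensity score without
# replacement: treated processed in a seeded random order, distance ties
# broken by the lowest patient id, optional caliper on the score scale.
greedy_match <- function(ps, treated, patient_id, seed = 1L, caliper = NULL) {
  t_idx <- which(treated)
  c_idx <- which(!treated)
  if (!length(t_idx) || !length(c_idx)) {
    validation_error("matching needs patients in both arms")
  }
  t_ord <- with_seed(seed, t_idx[sample.int(length(t_idx))])
  o <- order(ps[c_idx], patient_id[c_idx])
  co <- c_idx[o]
  cps <- ps[co]
  used <- rep(FALSE, length(co))
  pt <- integer(0); pc <- integer(0)
  for (ti in t_ord) {
    lo <- findInterval(ps[ti], cps)
    hi <- lo + 1L
    while (lo >= 1L && used[lo]) lo <- lo - 1L
    while (hi <= length(co) && used[hi]) hi <- hi + 1L
    dl <- if (lo >= 1L) abs(ps[ti] - cps[lo]) else Inf
    dh <- if (hi <= length(co)) abs(ps[ti] - cps[hi]) else Inf
    if (!is.finite(dl) && !is.finite(dh)) break
    pick <- if (dl < dh) lo
            else if (dh < dl) hi
            else if (patient_id[co[lo]] <= patient_id[co[hi]]) lo else hi
    if (!is.null(caliper) && abs(ps[ti] - cps[pick]) > caliper) next
    used[pick] <- TRUE
    pt <- c(pt, ti); pc <- c(pc, co[pick])
  }
  list(treated = pt, control = pc)
}

smd <- function(v, treated) {
  s <- sqrt((var(v[treated]) + var(v[!treated])) / 2)
  if (s == 0) return(0)
  (mean(v[treated]) - mean(v[!treated])) / s
}

#' Propensity-score-matched treatment-effect estimate
#'
#' Fits a logistic propensity model, performs greedy 1-1 nearest-neighbour
#' matching without replacement, and applies the confounder-adjusted outcome
#' regression of [fit_cat()] to the matched subset. Diagnostics record the
#' matched fraction and standardized mean differences before and after
#' matching.
#'
#' @inheritParams fit_cat
#' @param caliper Optional maximum propensity-score distance for a match.
#' @param seed Seed for the order in which treated patients are matched.
#' @return An `effect_estimate` with matching diagnostics.
#' @export
fit_psm <- function(data, include_y0 = FALSE, caliper = NULL,
                    covariates = "w1", seed = 1L, level = 0.95) {
  require_columns(data, c("x", "y1", "patient_id", covariates,
                          if (include_y0) "y0"))
  if (sum(data$x == 1L) < 2L || sum(data$x == 0L) < 2L) {
    validation_error("matching needs at least 2 patients per arm")
  }
  Xp <- cbind(`(Intercept)` = rep(1, nrow(data)),
              cov_matrix(data, covariates),
              if (include_y0) cbind(y0 = data$y0))
  ps_fit <- logit_fit(Xp, data$x)
  ps <- ps_fit$fitted
  treated <- data$x == 1L
  m <- greedy_match(ps, treated, data$patient_id, seed = seed, caliper = caliper)
  if (!length(m$treated)) validation_error("matching produced an empty matched set")
  idx <- c(m$treated, m$control)
  matched <- data[idx, , drop = FALSE]
  bal_vars <- c(covariates, if (include_y0) "y0")
  smd_pre <- vapply(bal_vars, function(v) smd(data[[v]], treated), numeric(1))
  smd_post <- vapply(bal_vars, function(v) smd(matched[[v]], matched$x == 1L),
                     numeric(1))
  est <- fit_cat(matched, include_y0 = include_y0, covariates = covariates,
                 level = level)
  new_effect_estimate(
    method = "PSM", beta_hat = est$beta_hat, se = est$se, n_used = nrow(matched),
    diagnostics = list(
      matched_fraction = nrow(matched) / nrow(data),
      n_pairs = length(m$treated),
      smd_pre = smd_pre, smd_post = smd_post,
      converged = TRUE
    ),
    level = level
  )
}

first_stage_design <- function(data, covariates, poa) {
  cbind(`(Intercept)` = 1, z = data$z, cov_matrix(data, covariates),
        if (poa) cbind(y0 = data$y0, `y0:z` = data$y0 * data$z))
}

wald_f <- function(fit, term) {
  unname((fit$coef[term] / sqrt(fit$vcov[term, term]))^2)
}

#' First-stage F-statistic of an instrument
#'
#' The squared Wald z-statistic of the instrument's coefficient in the
#' treatment model (the single-instrument F). `instrument = "z"` tests the
#' provider-preference instrument in the plain first stage; `"y0z"` tests the
#' prior-outcome-by-instrument interaction in the augmented first stage.
#' Values below 10 conventionally flag a weak instrument.
#'
#' @param data Dataset with columns `x`, `z`, the covariates, and `y0` for the
#'   augmented first stage.
#' @param instrument `"z"` or `"y0z"`.
#' @param covariates Confounder columns for the first-stage model.
#' @return The F-statistic (a single number).
#' @export
first_stage_f <- function(data, instrument = c("z", "y0z"), covariates = "w1") {
  instrument <- match.arg(instrument)
  poa <- instrument == "y0z"
  require_columns(data, c("x", "z", covariates, if (poa) "y0"))
  fit <- logit_fit(first_stage_design(data, covariates, poa), data$x)
  wald_f(fit, if (poa) "y0:z" else "z")
}

warn_weak <- function(f, what) {
  if (f < 10) {
    warning("weak instrument: first-stage F of ", what, " is ",
            sprintf("%.2f", f), " (< 10); the estimate may be unreliable",
            call. = FALSE)
  }
}

#' Two-stage instrumental-variable estimate
#'
#' Stage one is a logistic regression of treatment on the instrument and
#' measured confounders; its fitted probabilities replace the observed
#' treatment in the second-stage outcome model. With the default linear
#' second stage the treatment effect is the coefficient of the predicted
#' treatment (already a risk difference, HC0 robust SE); with a logistic
#' second stage it is the AME of moving the predicted treatment from 0 to 1.
#' A first-stage F below 10 raises a weak-instrument warning.
#'
#' @inheritParams fit_cat
#' @param second_stage `"linear"` (default) or `"logistic"` second-stage
#'   outcome model.
#' @return An `effect_estimate` with the first-stage F in the diagnostics.
#' @export
fit_iv <- function(data, include_y0 = FALSE, covariates = "w1",
                   second_stage = c("linear", "logistic"), level = 0.95) {
  second_stage <- match.arg(second_stage)
  require_columns(data, c("x", "y1", "z", covariates, if (include_y0) "y0"))
  s1 <- logit_fit(first_stage_design(data, covariates, poa = FALSE), data$x)
  f_z <- wald_f(s1, "z")
  warn_weak(f_z, "z")
  xhat <- s1$fitted
  X2 <- cbind(`(Intercept)` = 1, xhat = xhat, cov_matrix(data, covariates),
              if (include_y0) cbind(y0 = data$y0))
  fit2 <- if (second_stage == "logistic") logit_fit(X2, data$y1)
          else linear_fit(X2, data$y1)
  X1m <- X2; X1m[, "xhat"] <- 1
  X0m <- X2; X0m[, "xhat"] <- 0
  a <- ame_contrast(fit2, X1m, X0m)
  new_effect_estimate(
    method = "IV", beta_hat = a["est"], se = a["se"], n_used = nrow(data),
    diagnostics = list(first_stage_f_z = f_z, second_stage = second_stage,
                       converged = TRUE),
    level = level
  )
}

#' Control-function estimate for binary outcomes
#'
#' Uses the same first stage as [fit_iv()]; the first-stage residual (and its
#' interaction with the instrument) enters a logistic outcome model alongside
#' the observed treatment, absorbing the unmeasured confounding signal. The
#' treatment effect is the AME of the treatment indicator.
#'
#' @inheritParams fit_iv
#' @return An `effect_estimate` with the first-stage F in the diagnostics.
#' @export
fit_cf <- function(data, include_y0 = FALSE, covariates = "w1", level = 0.95) {
  require_columns(data, c("x", "y1", "z", covariates, if (include_y0) "y0"))
  s1 <- logit_fit(first_stage_design(data, covariates, poa = FALSE), data$x)
  f_z <- wald_f(s1, "z")
  warn_weak(f_z, "z")
  dhat <- data$x - s1$fitted
  X2 <- cbind(`(Intercept)` = 1, x = data$x, cov_matrix(data, covariates),
              if (include_y0) cbind(y0 = data$y0),
              dhat = dhat, `dhat:z` = dhat * data$z)
  fit2 <- logit_fit(X2, data$y1)
  X1m <- X2; X1m[, "x"] <- 1
  X0m <- X2; X0m[, "x"] <- 0
  a <- ame_contrast(fit2, X1m, X0m)
  new_effect_estimate(
    method = "CF", beta_hat = a["est"], se = a["se"], n_used = nrow(data),
    diagnostics = list(first_stage_f_z = f_z, converged = TRUE),
    level = level
  )
}

#' Stack the two periods of a dataset into long format
#'
#' Returns the 2n-row representation used by the difference-in-difference
#' regression: one row per patient and period, with the period indicator
#' `p_star`, the period's outcome `y_star` and confounder `w_star`, and the
#' (period-constant) treatment indicator `x_star`.
#'
#' @param data Dataset with columns `y0`, `y1`, `w0`, `w1`, `x`.
#' @return Data frame with 2n rows.
#' @export
stack_periods <- function(data) {
  require_columns(data, c("patient_id", "x", "y0", "y1", "w0", "w1"))
  n <- nrow(data)
  data.frame(
    patient_id = rep(data$patient_id, 2L),
    p_star = rep(c(0L, 1L), each = n),
    y_star = c(data$y0, data$y1),
    x_star = rep(data$x, 2L),
    w_star = c(data$w0, data$w1),
    z = if ("z" %in% names(data)) rep(data$z, 2L) else NA_integer_
  )
}

#' Difference-in-difference estimate from stacked two-period data
#'
#' Fits a single regression of the stacked outcome on period, treatment,
#' their interaction, and the period-specific confounder (plus its period
#' interaction); optionally the instrument and its period interaction. For
#' the logistic family the reported effect is the difference-in-AME: the
#' study-period treatment contrast in average predicted probability minus the
#' prior-period contrast, each patient evaluated with the period-appropriate
#' confounder; for the linear family this reduces to the interaction
#' coefficient.
#'
#' @inheritParams fit_cat
#' @param adjust Include the confounder terms `w_star` and `w_star:p_star`
#'   (disable only for closed-form checks on covariate-free data).
#' @return An `effect_estimate`.
#' @export
fit_did <- function(data, include_z = FALSE, family = c("logistic", "linear"),
                    adjust = TRUE, level = 0.95) {
  family <- match.arg(family)
  require_columns(data, c("x", "y0", "y1", "w0", "w1", if (include_z) "z"))
  st <- stack_periods(data)
  for (p in 0:1) {
    if (length(unique(st$y_star[st$p_star == p])) < 2L) {
      validation_error("degenerate period: all outcomes equal in period ", p)
    }
  }
  X <- cbind(`(Intercept)` = 1, p_star = st$p_star, x_star = st$x_star,
             `p_star:x_star` = st$p_star * st$x_star,
             if (adjust) cbind(w_star = st$w_star,
                               `w_star:p_star` = st$w_star * st$p_star),
             if (include_z) cbind(z = st$z, `z:p_star` = st$z * st$p_star))
  fit <- if (family == "logistic") logit_fit(X, st$y_star)
         else linear_fit(X, st$y_star)
  n <- nrow(data)
  mk <- function(p, x) {
    w <- if (p == 1) data$w1 else data$w0
    cbind(`(Intercept)` = 1, p_star = p, x_star = x, `p_star:x_star` = p * x,
          if (adjust) cbind(w_star = w, `w_star:p_star` = w * p),
          if (include_z) cbind(z = data$z, `z:p_star` = data$z * p))
  }
  a <- did_contrast(fit, mk(1, 1), mk(1, 0), mk(0, 1), mk(0, 0))
  new_effect_estimate(
    method = if (include_z) "DiD+Z" else "DiD",
    beta_hat = a["est"], se = a["se"], n_used = n,
    diagnostics = list(converged = TRUE, family = family),
    level = level
  )
}

#' Prior-outcome-augmented IV estimate
#'
#' Extends the two-stage IV: the first-stage treatment model additionally
#' includes the prior outcome and its interaction with the instrument, and
#' the interaction serves as the new instrument. The second stage controls
#' for any direct effects of the instrument and of the prior outcome on the
#' study outcome. Valid when the interaction is a strong predictor of
#' treatment and the prior outcome is itself unconfounded, even if the
#' exclusion restriction and the prior-outcome-to-treatment assumption both
#' fail.
#'
#' @inheritParams fit_iv
#' @return An `effect_estimate` with the F-statistics of both the instrument
#'   and the interaction instrument in the diagnostics.
#' @export
fit_poa_iv <- function(data, covariates = "w1",
                       second_stage = c("linear", "logistic"), level = 0.95) {
  second_stage <- match.arg(second_stage)
  require_columns(data, c("x", "y1", "z", "y0", covariates))
  s1 <- logit_fit(first_stage_design(data, covariates, poa = TRUE), data$x)
  f_z <- wald_f(s1, "z")
  f_y0z <- wald_f(s1, "y0:z")
  warn_weak(f_y0z, "y0:z")
  xhat <- s1$fitted
  X2 <- cbind(`(Intercept)` = 1, xhat = xhat, cov_matrix(data, covariates),
              z = data$z, y0 = data$y0)
  fit2 <- if (second_stage == "logistic") logit_fit(X2, data$y1)
          else linear_fit(X2, data$y1)
  X1m <- X2; X1m[, "xhat"] <- 1
  X0m <- X2; X0m[, "xhat"] <- 0
  a <- ame_contrast(fit2, X1m, X0m)
  new_effect_estimate(
    method = "POA-IV", beta_hat = a["est"], se = a["se"], n_used = nrow(data),
    diagnostics = list(first_stage_f_z = f_z, first_stage_f_y0z = f_y0z,
                       second_stage = second_stage, converged = TRUE),
    level = level
  )
}

#' Prior-outcome-augmented control-function estimate
#'
#' The control-function counterpart of [fit_poa_iv()]: the augmented
#' first-stage residual and its interaction with the instrument enter a
#' logistic outcome model that also controls for the instrument and the prior
#' outcome; the effect is the AME of the treatment indicator.
#'
#' @inheritParams fit_poa_iv
#' @return An `effect_estimate`.
#' @export
fit_poa_cf <- function(data, covariates = "w1", level = 0.95) {
  require_columns(data, c("x", "y1", "z", "y0", covariates))
  s1 <- logit_fit(first_stage_design(data, covariates, poa = TRUE), data$x)
  f_z <- wald_f(s1, "z")
  f_y0z <- wald_f(s1, "y0:z")
  warn_weak(f_y0z, "y0:z")
  dhat <- data$x - s1$fitted
  X2 <- cbind(`(Intercept)` = 1, x = data$x, cov_matrix(data, covariates),
              z = data$z, y0 = data$y0,
              dhat = dhat, `dhat:z` = dhat * data$z)
  fit2 <- logit_fit(X2, data$y1)
  X1m <- X2; X1m[, "x"] <- 1
  X0m <- X2; X0m[, "x"] <- 0
  a <- ame_contrast(fit2, X1m, X0m)
  new_effect_estimate(
    method = "POA-CF", beta_hat = a["est"], se = a["se"], n_used = nrow(data),
    diagnostics = list(first_stage_f_z = f_z, first_stage_f_y0z = f_y0z,
                       converged = TRUE),
    level = level
  )
}

.method_labels <- c(
  cat = "CaT", cat_z = "CaT+Z", psm = "PSM", iv = "IV", cf = "CF",
  did = "DiD", did_z = "DiD+Z", poa_iv = "POA-IV", poa_cf = "POA-CF"
)

normalize_method <- function(method) {
  key <- gsub("[+-]", "_", tolower(method))
  bad <- !key %in% names(.method_labels)
  if (any(bad)) {
    validation_error("unknown method(s): ", paste(method[bad], collapse = ", "))
  }
  key
}

#' Fit an estimator selected by name
#'
#' Dispatcher over the estimator functions; `method` may use the display
#' labels (`"CaT"`, `"CaT+Z"`, `"PSM"`, `"IV"`, `"CF"`, `"DiD"`, `"DiD+Z"`,
#' `"POA-IV"`, `"POA-CF"`) or lower-case keys.
#'
#' @param data Dataset.
#' @param method Method label.
#' @param include_z,include_y0 Adjustment-set flags forwarded to the methods
#'   that accept them.
#' @param ... Further arguments for the selected estimator.
#' @return An `effect_estimate`.
#' @export
fit_method <- function(data, method, include_z = FALSE, include_y0 = FALSE, ...) {
  key <- normalize_method(method)
  switch(key,
    cat    = fit_cat(data, include_z = include_z, include_y0 = include_y0, ...),
    cat_z  = fit_cat(data, include_z = TRUE, include_y0 = include_y0, ...),
    psm    = fit_psm(data, include_y0 = include_y0, ...),
    iv     = fit_iv(data, include_y0 = include_y0, ...),
    cf     = fit_cf(data, include_y0 = include_y0, ...),
    did    = fit_did(data, include_z = include_z, ...),
    did_z  = fit_did(data, include_z = TRUE, ...),
    poa_iv = fit_poa_iv(data, ...),
    poa_cf = fit_poa_cf(data, ...)
  )
}
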