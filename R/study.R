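# Monte-Carlo study orchestration: estimator performance metrics with
# Monte-Carlo standard errors, rejection-rate studies for the dissimilarity
# statistic, and the provider-preference instrument builder.

#' Performance metrics of a set of replicate estimates
#'
#' Computes bias, empirical SE, MSE, 95% CI coverage and type-1-error rate,
#' each with its Monte-Carlo standard error: bias MCSE = empSE/sqrt(R),
#' empSE MCSE = empSE/sqrt(2(R-1)), MSE MCSE = SD(squared errors)/sqrt(R),
#' proportions MCSE = sqrt(p(1-p)/R).
#'
#' @param estimates,ses Replicate point estimates and standard errors.
#' @param ci_low,ci_high Replicate confidence bounds.
#' @param pvals Replicate two-sided p-values.
#' @param truth True effect the replicates target.
#' @return One-row data.frame of metrics and MCSEs.
#' @export
performance_metrics <- function(estimates, ses, ci_low, ci_high, pvals, truth) {
  R <- length(estimates)
  lens <- c(length(ses), length(ci_low), length(ci_high), length(pvals))
  if (any(lens != R)) validation_error("metric input vectors differ in length")
  if (R < 2L) validation_error("at least 2 replicates are required")
  err <- estimates - truth
  emp_se <- sd(estimates)
  cover <- mean(ci_low <= truth & truth <= ci_high)
  t1e <- mean(pvals < 0.05)
  data.frame(
    bias = mean(err), bias_mcse = emp_se / sqrt(R),
    emp_se = emp_se, emp_se_mcse = emp_se / sqrt(2 * (R - 1)),
    mean_model_se = mean(ses),
    mse = mean(err^2), mse_mcse = sd(err^2) / sqrt(R),
    coverage = cover, coverage_mcse = sqrt(cover * (1 - cover) / R),
    t1e = t1e, t1e_mcse = sqrt(t1e * (1 - t1e) / R),
    n_reps = R
  )
}

resolve_config <- function(scenario, overrides = list()) {
  if (inherits(scenario, "scenario_config")) {
    if (length(overrides)) {
      validation_error("overrides are only accepted with a scenario id, not ",
                       "a ready config")
    }
    scenario
  } else {
    make_scenario_config(scenario, overrides)
  }
}

# Scenario-driven adjustment sets: when the instrument has a direct outcome
# effect it is a measured confounder and enters the CaT/DiD models; when the
# prior outcome affects the study outcome it enters all outcome models.
adjustment_for <- function(cfg, auto_adjust) {
  list(
    include_z = isTRUE(auto_adjust) && isTRUE(cfg$flags$iv2_violated),
    include_y0 = isTRUE(auto_adjust) && isTRUE(cfg$flags$y0_direct)
  )
}

#' Monte-Carlo simulation study of estimator performance
#'
#' For each scenario and replicate, simulates a dataset, fits every requested
#' method, and aggregates bias / empirical SE / MSE / coverage / type-1-error
#' against the scenario's Monte-Carlo ground truth. When a scenario violates
#' the exclusion restriction the instrument is automatically added to the
#' CaT and DiD adjustment sets, and when the prior outcome affects the study
#' outcome it is added to all outcome models (`auto_adjust = FALSE` disables
#' both for ablation). Failed fits are dropped for that method only and
#' counted.
#'
#' @param scenarios Character vector of scenario ids, or a list of
#'   `scenario_config` objects.
#' @param methods Method labels (see [fit_method()]).
#' @param n_reps Number of replicates per scenario.
#' @param master_seed Master seed; per-replicate seeds are derived from it.
#' @param null_truth Re-simulate with a zero treatment effect (for
#'   type-1-error studies); the truth is then 0.
#' @param overrides Overrides applied to every scenario id.
#' @param auto_adjust Apply the scenario-driven adjustment sets.
#' @param n_mc_truth Monte-Carlo size for the ground-truth computation.
#' @return A `performance_summary` data.frame with one row per scenario and
#'   method; the full replicate draws are kept in attribute `"details"`.
#' @export
run_simulation_study <- function(scenarios, methods = c("cat", "iv", "cf", "did"),
                                 n_reps = 500L, master_seed = 1L,
                                 null_truth = FALSE, overrides = list(),
                                 auto_adjust = TRUE, n_mc_truth = 2e5) {
  if (n_reps < 2L) validation_error("n_reps must be at least 2")
  if (!is.list(scenarios)) scenarios <- as.list(scenarios)
  keys <- normalize_method(if (is.list(methods)) names(methods) else methods)
  n_s <- length(scenarios)
  seeds <- matrix(derive_seeds(master_seed, n_s * (n_reps + 1L)),
                  nrow = n_s)
  out <- list()
  details <- list()
  for (si in seq_len(n_s)) {
    cfg <- resolve_config(scenarios[[si]], overrides)
    if (null_truth) cfg$beta <- 0
    scen_name <- cfg$scenario_id
    truth <- if (null_truth) 0 else true_effect(cfg, n_mc_truth, seeds[si, 1L])
    adj <- adjustment_for(cfg, auto_adjust)
    res <- array(NA_real_, dim = c(n_reps, length(keys), 5L),
                 dimnames = list(NULL, keys,
                                 c("est", "se", "ci_low", "ci_high", "p")))
    for (r in seq_len(n_reps)) {
      dat <- simulate_dataset(cfg, seeds[si, r + 1L])
      for (m in keys) {
        e <- tryCatch(
          suppressWarnings(fit_method(dat, m, include_z = adj$include_z,
                                      include_y0 = adj$include_y0)),
          error = function(err) NULL
        )
        if (!is.null(e)) {
          res[r, m, ] <- c(e$beta_hat, e$se, e$ci_low, e$ci_high, e$p_value)
        }
      }
    }
    for (m in keys) {
      ok <- !is.na(res[, m, "est"])
      n_failed <- sum(!ok)
      cell <- if (sum(ok) >= 2L) {
        performance_metrics(res[ok, m, "est"], res[ok, m, "se"],
                            res[ok, m, "ci_low"], res[ok, m, "ci_high"],
                            res[ok, m, "p"], truth)
      } else {
        data.frame(bias = NA_real_, bias_mcse = NA_real_, emp_se = NA_real_,
                   emp_se_mcse = NA_real_, mean_model_se = NA_real_,
                   mse = NA_real_, mse_mcse = NA_real_, coverage = NA_real_,
                   coverage_mcse = NA_real_, t1e = NA_real_,
                   t1e_mcse = NA_real_, n_reps = sum(ok))
      }
      cell$failed <- n_failed > 0.05 * n_reps
      if (cell$failed[1]) {
        warning("method ", .method_labels[m], " failed on ", n_failed, " of ",
                n_reps, " replicates in scenario ", scen_name, call. = FALSE)
      }
      label <- unname(.method_labels[m])
      if (adj$include_z && m %in% c("cat", "did")) label <- paste0(label, "+Z")
      out[[length(out) + 1L]] <- cbind(
        data.frame(scenario = scen_name, method = label,
                   truth = truth, n_failed = n_failed),
        cell
      )
    }
    details[[scen_name]] <- res
  }
  summary <- do.call(rbind, out)
  rownames(summary) <- NULL
  class(summary) <- c("performance_summary", "data.frame")
  attr(summary, "details") <- details
  attr(summary, "master_seed") <- master_seed
  summary
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("Monte-Carlo performance summary (risk-difference scale)\n")
  df <- as.data.frame(x)
  df$bias <- sprintf("%+.4f", df$bias)
  df$emp_se <- sprintf("%.4f", df$emp_se)
  df$mse <- sprintf("%.5f", df$mse)
  df$coverage <- sprintf("%.1f%%", 100 * df$coverage)
  df$t1e <- sprintf("%.1f%%", 100 * df$t1e)
  print(df[, c("scenario", "method", "n_reps", "bias", "emp_se", "mse",
               "coverage", "t1e", "n_failed")], row.names = FALSE)
  invisible(x)
}

#' Rejection-rate study for the dissimilarity statistic
#'
#' Repeatedly simulates a scenario; in each replicate the requested method
#' pairs are fit, their joint covariance is estimated from a nonparametric
#' bootstrap (one bootstrap over the union of methods, sliced per pair), and
#' the share of replicates in which the heterogeneity test rejects at `alpha`
#' is reported with a Wald binomial confidence interval.
#'
#' @param scenario Scenario id or `scenario_config`.
#' @param method_pairs List of character vectors (usually pairs) of method
#'   labels.
#' @param n_reps Number of simulation replicates (at least 50).
#' @param B Bootstrap resamples per replicate (at least 100).
#' @param master_seed Master seed.
#' @param alpha Test level.
#' @param overrides Scenario overrides.
#' @param auto_adjust Apply scenario-driven adjustment sets.
#' @return Data.frame with one row per method set: rejection rate and Wald
#'   95% CI (proportions).
#' @export
run_qtest_study <- function(scenario, method_pairs, n_reps = 500L, B = 500L,
                            master_seed = 1L, alpha = 0.05,
                            overrides = list(), auto_adjust = TRUE) {
  if (n_reps < 50L) validation_error("n_reps must be at least 50")
  if (B < 100L) validation_error("B must be at least 100")
  if (!is.list(method_pairs)) method_pairs <- list(method_pairs)
  for (p in method_pairs) {
    if (length(p) < 2L) validation_error("each method set needs at least 2 methods")
  }
  cfg <- resolve_config(scenario, overrides)
  adj <- adjustment_for(cfg, auto_adjust)
  pair_keys <- lapply(method_pairs, normalize_method)
  union_keys <- unique(unlist(pair_keys))
  union_labels <- unname(.method_labels[union_keys])
  seeds <- matrix(derive_seeds(master_seed, 2L * n_reps), ncol = 2L)
  rejects <- matrix(NA, nrow = n_reps, ncol = length(pair_keys))
  for (r in seq_len(n_reps)) {
    dat <- simulate_dataset(cfg, seeds[r, 1L])
    beta <- vapply(union_keys, function(m) {
      suppressWarnings(fit_method(dat, m, include_z = adj$include_z,
                                  include_y0 = adj$include_y0))$beta_hat
    }, numeric(1))
    names(beta) <- union_labels
    cv <- suppressWarnings(bootstrap_covariance(
      dat, union_keys, B = B, seed = seeds[r, 2L],
      include_z = adj$include_z, include_y0 = adj$include_y0))
    for (j in seq_along(pair_keys)) {
      lab <- unname(.method_labels[pair_keys[[j]]])
      res <- q_statistic(beta[lab], cv[lab, lab], alpha = alpha)
      rejects[r, j] <- res$reject
    }
  }
  rate <- colMeans(rejects)
  half <- qnorm(0.975) * sqrt(rate * (1 - rate) / n_reps)
  data.frame(
    scenario = cfg$scenario_id,
    methods = vapply(pair_keys, function(k)
      paste(.method_labels[k], collapse = ", "), character(1)),
    n_reps = n_reps, B = B, alpha = alpha,
    rejection_rate = rate,
    ci_low = pmax(0, rate - half), ci_high = pmin(1, rate + half)
  )
}

#' Provider-preference instrument from prescribing records
#'
#' For each patient, the binary instrument is the provider's most recent
#' previous prescription choice (with `window > 1`, the majority of the last
#' `window` choices, ties resolved by the most recent one). The first
#' `window` patients of each provider have no history and are excluded from
#' the returned map.
#'
#' @param records Data.frame with columns `provider_id`, `patient_id`,
#'   `order_index` (within-provider time rank, unique per provider) and
#'   binary `treatment`.
#' @param window Number of past prescriptions the preference proxy looks at.
#' @return Data.frame `patient_id`, `z`, one row per patient with enough
#'   history.
#' @examples
#' recs <- data.frame(provider_id = 1, patient_id = 1:4,
#'                    order_index = 1:4, treatment = c(1, 0, 0, 1))
#' build_preference_iv(recs)   # patients 2:4 get z = 1, 0, 0
#' @export
build_preference_iv <- function(records, window = 1L) {
  require_columns(records, c("provider_id", "patient_id", "order_index",
                             "treatment"))
  if (!all(records$treatment %in% c(0L, 1L))) {
    validation_error("treatment must be binary 0/1")
  }
  if (window < 1L) validation_error("window must be at least 1")
  parts <- split(records, records$provider_id)
  out <- lapply(parts, function(p) {
    if (anyDuplicated(p$order_index)) {
      validation_error("duplicate order_index within provider ",
                       p$provider_id[1])
    }
    p <- p[order(p$order_index), , drop = FALSE]
    k <- nrow(p)
    if (k <= window) return(NULL)
    z <- vapply((window + 1L):k, function(i) {
      recent <- p$treatment[(i - window):(i - 1L)]
      m <- mean(recent)
      if (m == 0.5) recent[length(recent)] else as.integer(m > 0.5)
    }, numeric(1))
    data.frame(patient_id = p$patient_id[(window + 1L):k], z = as.integer(z))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(patient_id = integer(0), z = integer(0)))
  }
  rownames(out) <- NULL
  out[order(out$patient_id), , drop = FALSE]
}
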