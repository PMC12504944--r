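# Dissimilarity testing: a generalized Cochran's Q over a set of correlated
# effect estimates, with the covariance of the estimates approximated by a
# nonparametric bootstrap in which every estimator is refit on each resample.

#' Inverse-variance-weighted average of a set of estimates
#'
#' @param beta Numeric vector of estimates.
#' @param variances Positive variances of the estimates.
#' @return The pooled estimate \eqn{\sum_j w_j \beta_j / \sum_j w_j} with
#'   \eqn{w_j = 1/\mathrm{var}_j}.
#' @export
ivw_average <- function(beta, variances) {
  if (length(beta) != length(variances)) {
    validation_error("beta and variances must have equal length")
  }
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    validation_error("variances must be finite and strictly positive")
  }
  w <- 1 / variances
  sum(w * beta) / sum(w)
}

#' Generalized heterogeneity statistic for correlated estimates
#'
#' Computes \eqn{Q_e = (\hat\beta_e - \hat\beta_{IVW,e}) \hat\Sigma_e^{-1}
#' (\hat\beta_e - \hat\beta_{IVW,e})^T}, where the pooled estimate uses
#' inverse-variance weights taken from the diagonal of the supplied
#' covariance. Under the null hypothesis that all estimates target the same
#' quantity, \eqn{Q_e} is asymptotically chi-square with (set size - 1)
#' degrees of freedom. A near-singular covariance (condition number above
#' `cond_cap`) is an error: the statistic is unstable there and no
#' pseudo-inverse is substituted.
#'
#' @param beta Named numeric vector of estimates (at least 2).
#' @param cov Covariance matrix of the estimates (e.g. from
#'   [bootstrap_covariance()]).
#' @param alpha Test level for the reject flag.
#' @param methods Method labels (defaults to `names(beta)`).
#' @param B,seed,failed_resamples Optional bookkeeping copied into the result.
#' @param cond_cap Maximum tolerated condition number of `cov`.
#' @return Object of class `dissimilarity_result` with the estimate vector,
#'   weights, pooled estimate, `q_stat`, `df`, `p_value` and reject flag.
#' @export
q_statistic <- function(beta, cov, alpha = 0.05, methods = names(beta),
                        B = NA_integer_, seed = NA_integer_,
                        failed_resamples = NA_integer_, cond_cap = 1e10) {
  k <- length(beta)
  if (k < 2L) validation_error("at least 2 estimates are required")
  cov <- as.matrix(cov)
  if (!all(dim(cov) == k)) validation_error("cov must be ", k, "x", k)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    validation_error("cov must be symmetric")
  }
  if (any(diag(cov) <= 0)) validation_error("cov must have positive diagonal")
  if (is.null(methods)) methods <- paste0("estimate", seq_len(k))
  kap <- kappa(cov, exact = TRUE)
  if (!is.finite(kap) || kap > cond_cap) {
    validation_error(
      "covariance matrix is singular or ill-conditioned (condition number ",
      format(kap, digits = 3), "); drop one of a pair of nearly collinear ",
      "methods rather than relying on a pseudo-inverse")
  }
  ivw <- ivw_average(beta, diag(cov))
  d <- beta - ivw
  q <- drop(t(d) %*% solve(cov, d))
  df <- k - 1L
  p <- pchisq(q, df = df, lower.tail = FALSE)
  structure(list(
    methods = methods,
    beta_vec = stats::setNames(as.numeric(beta), methods),
    weights = stats::setNames(1 / diag(cov), methods),
    ivw = ivw,
    cov = cov,
    q_stat = q, df = df, p_value = p,
    alpha = alpha, reject = p < alpha,
    B = B, seed = seed, failed_resamples = failed_resamples
  ), class = "dissimilarity_result")
}

#' @export
print.dissimilarity_result <- function(x, ...) {
  cat("Dissimilarity test over {", paste(x$methods, collapse = ", "), "}\n",
      sep = "")
  cat(sprintf("  Q = %.3f on %d df, p = %.4g (alpha = %g): %s\n",
              x$q_stat, x$df, x$p_value, x$alpha,
              if (x$reject) "estimates are dissimilar"
              else "no evidence of dissimilarity"))
  cat(sprintf("  IVW pooled estimate %.4f; estimates: %s\n", x$ivw,
              paste(sprintf("%s=%.4f", x$methods, x$beta_vec), collapse = ", ")))
  if (!is.na(x$B)) {
    cat(sprintf("  bootstrap: B = %d, failed resamples = %d\n",
                x$B, x$failed_resamples))
  }
  invisible(x)
}

#' Bootstrap covariance of a set of effect estimates
#'
#' Resamples the dataset with replacement `B` times, refits every method on
#' each resample, and returns the empirical covariance of the estimate
#' vectors. Resamples on which any method fails are dropped and counted; more
#' than 10% failures is an error. Resampling is by patient by default; the
#' cluster option resamples whole providers, respecting the cluster-constant
#' instrument.
#'
#' @param data Dataset.
#' @param methods Character vector of method labels (see [fit_method()]), or
#'   a named list of functions `function(data) -> effect_estimate`-like
#'   objects with a `beta_hat` field.
#' @param B Number of bootstrap resamples (at least 100).
#' @param seed Integer seed.
#' @param unit `"patient"` (default) or `"cluster"` resampling unit.
#' @param include_z,include_y0 Adjustment flags forwarded to the estimators.
#' @param keep_replicates Attach the B-by-k replicate matrix as attribute
#'   `"replicates"` (for audit export).
#' @return Covariance matrix with attributes `B`, `failed` and optionally
#'   `replicates`.
#' @export
bootstrap_covariance <- function(data, methods, B = 500L, seed = 1L,
                                 unit = c("patient", "cluster"),
                                 include_z = FALSE, include_y0 = FALSE,
                                 keep_replicates = FALSE) {
  unit <- match.arg(unit)
  if (B < 100L) validation_error("B must be at least 100")
  fns <- method_functions(methods, include_z, include_y0)
  k <- length(fns)
  n <- nrow(data)
  idx_list <- with_seed(seed, {
    if (unit == "patient") {
      lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
    } else {
      cl <- unique(data$cluster_id)
      rows <- split(seq_len(n), data$cluster_id)
      lapply(seq_len(B), function(b) {
        unlist(rows[as.character(sample(cl, length(cl), replace = TRUE))],
               use.names = FALSE)
      })
    }
  })
  reps <- matrix(NA_real_, nrow = B, ncol = k,
                 dimnames = list(NULL, names(fns)))
  for (b in seq_len(B)) {
    d <- data[idx_list[[b]], , drop = FALSE]
    est <- tryCatch(
      vapply(fns, function(f) suppressWarnings(f(d))$beta_hat, numeric(1)),
      error = function(e) rep(NA_real_, k)
    )
    reps[b, ] <- est
  }
  ok <- stats::complete.cases(reps)
  failed <- sum(!ok)
  if (failed > 0.10 * B) {
    stop("bootstrap failed on ", failed, " of ", B,
         " resamples (> 10%); estimates are too unstable for a reliable ",
         "covariance")
  }
  if (failed > 0) {
    warning(failed, " of ", B, " bootstrap resamples failed to converge and ",
            "were dropped", call. = FALSE)
  }
  cv <- cov(reps[ok, , drop = FALSE])
  attr(cv, "B") <- B
  attr(cv, "failed") <- failed
  if (keep_replicates) attr(cv, "replicates") <- reps
  cv
}

method_functions <- function(methods, include_z = FALSE, include_y0 = FALSE) {
  if (is.list(methods)) {
    if (is.null(names(methods)) || any(names(methods) == "")) {
      validation_error("a list of method functions must be fully named")
    }
    return(methods)
  }
  keys <- normalize_method(methods)
  fns <- lapply(keys, function(key) {
    force(key)
    function(d) fit_method(d, key, include_z = include_z,
                           include_y0 = include_y0)
  })
  stats::setNames(fns, .method_labels[keys])
}

#' Dissimilarity test of several estimators on one dataset
#'
#' Convenience wrapper: fits each method on the full data, estimates the
#' joint covariance of the estimates by nonparametric bootstrap, and applies
#' the heterogeneity statistic [q_statistic()].
#'
#' @inheritParams bootstrap_covariance
#' @param alpha Test level.
#' @return A `dissimilarity_result`.
#' @examples
#' \donttest{
#' dat <- simulate_dataset(make_scenario_config("base1", list(n = 1000)), 1)
#' dissimilarity_test(dat, c("cat", "did"), B = 100, seed = 2)
#' }
#' @export
dissimilarity_test <- function(data, methods, B = 500L, seed = 1L,
                               alpha = 0.05, unit = "patient",
                               include_z = FALSE, include_y0 = FALSE,
                               keep_replicates = FALSE) {
  fns <- method_functions(methods, include_z, include_y0)
  if (length(fns) < 2L) validation_error("at least 2 methods are required")
  beta <- vapply(fns, function(f) suppressWarnings(f(data))$beta_hat, numeric(1))
  cv <- bootstrap_covariance(data, fns, B = B, seed = seed, unit = unit,
                             keep_replicates = keep_replicates)
  res <- q_statistic(beta, cv, alpha = alpha, methods = names(fns),
                     B = attr(cv, "B"), seed = seed,
                     failed_resamples = attr(cv, "failed"))
  if (keep_replicates) attr(res, "replicates") <- attr(cv, "replicates")
  res
}
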