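# Internal fitting machinery: thin, fast wrappers around glm.fit / lm.fit on
# explicit design matrices, plus closed-form average-marginal-effect (AME)
# contrasts with delta-method standard errors. Estimator fronts in
# estimators.R assemble design matrices and call into these.

# Newton-Raphson IRLS for the logistic likelihood with step-halving; falls
# back to glm.fit when it fails to converge. Convergence tolerance 1e-8 on
# the relative deviance change, 100 iterations maximum.
logit_irls <- function(X, y, maxit = 100L, tol = 1e-8) {
  b <- numeric(ncol(X))
  pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  if (all(X[, 1L] == 1)) b[1L] <- log(pbar / (1 - pbar))
  devfun <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -2 * sum(ifelse(y == 1, log(p), log1p(-p)))
  }
  p <- plogis(drop(X %*% b))
  dev <- devfun(p)
  for (it in seq_len(maxit)) {
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w)
    score <- crossprod(X, y - p)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      b_new <- b + lambda * drop(step)
      p_new <- plogis(drop(X %*% b_new))
      dev_new <- devfun(p_new)
      if (is.finite(dev_new) && dev_new <= dev + 1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-8) return(NULL)
    }
    done <- abs(dev - dev_new) / (abs(dev_new) + 0.1) < tol
    b <- b_new; p <- p_new; dev <- dev_new
    if (done) {
      return(list(coefficients = b, fitted.values = p,
                  weights = p * (1 - p), converged = TRUE))
    }
  }
  NULL
}

logit_fit <- function(X, y, term_names = colnames(X)) {
  fit <- logit_irls(X, y)
  if (is.null(fit)) {
    fit <- suppressWarnings(glm.fit(
      X, y, family = binomial(),
      control = glm.control(epsilon = 1e-8, maxit = 100)
    ))
    if (!fit$converged) {
      stop("logistic regression did not converge (terms: ",
           paste(term_names, collapse = ", "), ")")
    }
  }
  b <- fit$coefficients
  bad <- !is.finite(b) | abs(b) > 15
  if (any(bad)) {
    stop("perfect or quasi-perfect separation suspected for term(s): ",
         paste(term_names[bad], collapse = ", "))
  }
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
    stop("singular information matrix (terms: ",
         paste(term_names, collapse = ", "), ")")
  })
  dimnames(V) <- list(term_names, term_names)
  names(b) <- term_names
  list(family = "logistic", coef = b, vcov = V,
       fitted = fit$fitted.values, converged = TRUE)
}

# OLS with HC0 heteroscedasticity-robust covariance (binary outcomes make the
# classical homoscedastic variance a poor default).
linear_fit <- function(X, y, term_names = colnames(X), robust = TRUE) {
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    stop("rank-deficient linear model (terms: ",
         paste(term_names, collapse = ", "), ")")
  }
  b <- fit$coefficients
  XtX_inv <- chol2inv(chol(crossprod(X)))
  e <- fit$residuals
  V <- if (robust) {
    XtX_inv %*% crossprod(X * e) %*% XtX_inv
  } else {
    XtX_inv * sum(e^2) / (length(y) - ncol(X))
  }
  dimnames(V) <- list(term_names, term_names)
  names(b) <- term_names
  list(family = "linear", coef = b, vcov = V,
       fitted = fit$fitted.values, converged = TRUE)
}

# AME of a term toggled between two design matrices. For the logistic family
# this is mean(expit(X1 b) - expit(X0 b)) with the delta-method gradient
# colMeans(p(1-p) X) evaluated at each arm; for the linear family it reduces
# to the toggled coefficient.
ame_contrast <- function(fit, X1, X0) {
  b <- fit$coef
  if (fit$family == "logistic") {
    p1 <- plogis(drop(X1 %*% b)); p0 <- plogis(drop(X0 %*% b))
    est <- mean(p1 - p0)
    g <- colMeans(X1 * (p1 * (1 - p1))) - colMeans(X0 * (p0 * (1 - p0)))
  } else {
    est <- mean(drop((X1 - X0) %*% b))
    g <- colMeans(X1 - X0)
  }
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  c(est = est, se = se)
}

# Difference-in-AME across periods for the stacked DiD model: the four-way
# predicted-probability contrast [p(1,1)-p(1,0)] - [p(0,1)-p(0,0)], one
# prediction per patient with the period-appropriate confounder.
did_contrast <- function(fit, A11, A10, A01, A00) {
  b <- fit$coef
  if (fit$family == "logistic") {
    p <- lapply(list(A11, A10, A01, A00), function(A) plogis(drop(A %*% b)))
    est <- mean(p[[1]] - p[[2]]) - mean(p[[3]] - p[[4]])
    d <- lapply(p, function(pp) pp * (1 - pp))
    g <- colMeans(A11 * d[[1]]) - colMeans(A10 * d[[2]]) -
         colMeans(A01 * d[[3]]) + colMeans(A00 * d[[4]])
  } else {
    est <- mean(drop((A11 - A10 - A01 + A00) %*% b))
    g <- colMeans(A11 - A10 - A01 + A00)
  }
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  c(est = est, se = se)
}

new_effect_estimate <- function(method, beta_hat, se, n_used,
                                diagnostics = list(), level = 0.95) {
  zq <- qnorm(1 - (1 - level) / 2)
  structure(list(
    method = method,
    beta_hat = unname(beta_hat),
    se = unname(se),
    ci_low = unname(beta_hat - zq * se),
    ci_high = unname(beta_hat + zq * se),
    p_value = unname(2 * pnorm(-abs(beta_hat / se))),
    n_used = n_used,
    level = level,
    diagnostics = diagnostics
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, percent = FALSE, ...) {
  s <- if (percent) 100 else 1
  unit <- if (percent) "%" else ""
  cat(sprintf("%s estimate: risk difference %.4f%s (SE %.4f%s)\n",
              x$method, s * x$beta_hat, unit, s * x$se, unit))
  cat(sprintf("  %d%% CI [%.4f%s, %.4f%s], p = %.3g, n = %d\n",
              round(100 * x$level), s * x$ci_low, unit, s * x$ci_high, unit,
              x$p_value, x$n_used))
  fk <- grep("^first_stage_f", names(x$diagnostics), value = TRUE)
  for (k in fk) {
    cat(sprintf("  %s = %.2f\n", k, x$diagnostics[[k]]))
  }
  invisible(x)
}

#' Average marginal effect of a binary term in a fitted model
#'
#' The difference in average predicted outcomes when `target_term` is fixed at
#' 1 and 0 for every observation, holding all other covariates at their
#' observed values; the standard error follows from the delta method through
#' the coefficient covariance. For a linear model this equals the raw
#' coefficient of the term.
#'
#' @param fit A fitted `glm` (binomial) or `lm` object.
#' @param data Data frame on which to average (usually the estimation data).
#' @param target_term Name of a column of `data` used as a main effect.
#' @return Named vector `c(ame = ..., se = ...)`.
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.3), x = rbinom(200, 1, 0.5))
#' fit <- glm(y ~ x, family = binomial(), data = d)
#' ame(fit, d, "x")
#' @export
ame <- function(fit, data, target_term) {
  if (!target_term %in% names(data)) {
    stop("target_term '", target_term, "' is not a column of data")
  }
  tt <- delete.response(terms(fit))
  d1 <- data; d1[[target_term]] <- 1
  d0 <- data; d0[[target_term]] <- 0
  X1 <- model.matrix(tt, d1)
  X0 <- model.matrix(tt, d0)
  b <- coef(fit)
  V <- vcov(fit)
  fam <- if (inherits(fit, "glm")) family(fit)$family else "gaussian"
  internal <- list(
    family = if (fam == "binomial") "logistic" else "linear",
    coef = b, vcov = V
  )
  r <- ame_contrast(internal, X1[, names(b), drop = FALSE],
                    X0[, names(b), drop = FALSE])
  c(ame = unname(r["est"]), se = unname(r["se"]))
}
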