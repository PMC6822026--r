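#' Fit a richness GLM
#'
#' Log-link Poisson or negative-binomial regression of per-cell overall
#' richness on per-cell predictors (typically rare- or common-species
#' richness). Poisson fits use iteratively reweighted least squares; the
#' negative binomial alternates IRLS for the coefficients with maximum
#' likelihood updates of the dispersion parameter theta until joint
#' convergence (MASS machinery). The negative binomial is the usual remedy
#' when richness counts are overdispersed relative to Poisson.
#'
#' @param y nonnegative integer response (per-cell richness).
#' @param x predictor matrix/data.frame (an intercept is always added), or
#'   `NULL` for an intercept-only model.
#' @param family `"poisson"` or `"negative_binomial"`.
#' @return object of class `srp_glm`: list with `fit` (the underlying glm),
#'   `family`, `coefficients`, `theta` (NB only), `log_likelihood`,
#'   `null_deviance`, `residual_deviance`, `pseudo_r2`, `aicc`, `residuals`
#'   (response scale), `n_params` (including theta for the NB), `n`.
#' @export
fit_glm <- function(y, x = NULL, family = c("poisson", "negative_binomial")) {
  family <- match.arg(family)
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("`y` must be nonnegative and finite", call. = FALSE)
  }
  if (is.null(x)) {
    dat <- data.frame(y = y)
    fml <- y ~ 1
  } else {
    x <- as.data.frame(x)
    if (nrow(x) != length(y)) stop("`x` rows must match length of `y`", call. = FALSE)
    dat <- cbind(data.frame(y = y), x)
    fml <- y ~ .
  }
  if (family == "poisson") {
    fit <- stats::glm(fml, data = dat, family = stats::poisson(link = "log"))
  } else {
    fit <- tryCatch(
      MASS::glm.nb(fml, data = dat, link = log,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      error = function(e) NULL
    )
    # The ML estimate of theta diverges when the counts carry no
    # overdispersion; beyond ~1e5 the NB log-likelihood also degrades
    # numerically (lgamma cancellation). Represent the Poisson limit by a
    # fixed large theta instead.
    theta_cap <- 1e5
    if (is.null(fit) || fit$theta > theta_cap || fit$deviance < 0) {
      fit <- stats::glm(fml, data = dat,
                        family = MASS::negative.binomial(theta_cap))
      fit$theta <- theta_cap
    }
  }
  if (!fit$converged) warning("GLM did not converge in 100 iterations")
  theta <- if (family == "negative_binomial") fit$theta else NULL
  k <- length(stats::coef(fit)) + if (is.null(theta)) 0L else 1L
  ll <- as.numeric(stats::logLik(fit))
  n <- length(y)
  out <- structure(
    list(
      fit = fit,
      family = family,
      coefficients = stats::coef(fit),
      theta = theta,
      log_likelihood = ll,
      null_deviance = fit$null.deviance,
      residual_deviance = fit$deviance,
      residuals = stats::residuals(fit, type = "response"),
      fitted = stats::fitted(fit),
      n_params = k,
      n = n
    ),
    class = "srp_glm"
  )
  out$pseudo_r2 <- pseudo_r2(out)
  out$aicc <- if (n > k + 1) aicc(out) else NA_real_
  out
}

#' @export
print.srp_glm <- function(x, ...) {
  cat(sprintf("%s richness GLM (log link), n = %d\n",
              if (x$family == "poisson") "Poisson" else "Negative-binomial", x$n))
  print(round(x$coefficients, 4))
  if (!is.null(x$theta)) cat(sprintf("  theta = %.3f\n", x$theta))
  cat(sprintf("  pseudo R2 = %.3f, AICc = %.1f\n", x$pseudo_r2, x$aicc))
  invisible(x)
}

#' Explained-deviance pseudo R-squared
#'
#' \deqn{R^2 = (D_{null} - D_{resid}) / D_{null}} -- the share of the null
#' deviance explained by the model. 0 for an intercept-only model, 1 for a
#' saturated (perfectly predicting) fit. A Nagelkerke variant is available.
#'
#' @param fit an [fit_glm()] result.
#' @param type `"deviance"` (default) or `"nagelkerke"`.
#' @return fraction in \[0, 1\], or `NA` (with a warning) for a constant
#'   response.
#' @export
pseudo_r2 <- function(fit, type = c("deviance", "nagelkerke")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "srp_glm"))
  if (fit$null_deviance <= .Machine$double.eps^0.5 &&
      type == "deviance") {
    warning("null deviance is zero (constant response); pseudo R2 undefined")
    return(NA_real_)
  }
  if (type == "deviance") {
    r2 <- (fit$null_deviance - fit$residual_deviance) / fit$null_deviance
    min(max(r2, 0), 1) # guard against rounding just outside [0, 1]
  } else {
    n <- fit$n
    ll0 <- fit$log_likelihood + (fit$residual_deviance - fit$null_deviance) / 2
    r2 <- 1 - exp(-2 * (fit$log_likelihood - ll0) / n)
    r2 / (1 - exp(2 * ll0 / n))
  }
}

#' Small-sample corrected Akaike information criterion
#'
#' \deqn{AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)} with `k` counting every
#' estimated parameter, including the negative-binomial dispersion theta.
#'
#' @param fit an [fit_glm()] result (or a list with `log_likelihood`,
#'   `n_params`, `n`).
#' @param n sample size; defaults to the fitted `n`.
#' @return scalar AICc.
#' @export
aicc <- function(fit, n = fit$n) {
  k <- fit$n_params
  if (n <= k + 1) stop("AICc requires n > k + 1", call. = FALSE)
  -2 * fit$log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
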