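#' Kendall tau-b rank correlation
#'
#' Tie-corrected Kendall correlation
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' with \eqn{n_0 = n(n-1)/2} and \eqn{n_1, n_2} the within-tie pair counts of
#' `x` and `y`. Appropriate for integer richness vectors with many repeated
#' values. When all values of `x` or of `y` are tied the coefficient is
#' undefined and `NA` is returned (never a silent 0).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return scalar in \[-1, 1\], or `NA` if undefined.
#' @examples
#' kendall_tau_b(1:5, c(2, 2, 3, 5, 5))
#' @export
kendall_tau_b <- function(x, y) {
  .check_tau_input(x, y)
  .tau_b_fixed(x, .tau_prep(y))
}

#' Kendall tau-b test
#'
#' As [kendall_tau_b()], plus a two-sided p-value from the tie-corrected
#' normal approximation for the statistic \eqn{S = C - D} (the standard
#' large-sample test used for tied data).
#'
#' @inheritParams kendall_tau_b
#' @return list with `tau_b`, `S`, `z`, `p_value`, `n`, and `undefined`
#'   (TRUE when all of `x` or `y` are tied).
#' @export
kendall_test <- function(x, y) {
  .check_tau_input(x, y)
  n <- length(x)
  prep <- .tau_prep(y)
  sx <- sign(outer(x, x, "-"))
  S <- sum(sx * prep$sy) / 2
  n0 <- n * (n - 1) / 2
  n1 <- (sum(sx == 0) - n) / 2
  n2 <- prep$n2
  if (n0 == n1 || n0 == n2) {
    return(list(tau_b = NA_real_, S = S, z = NA_real_, p_value = NA_real_,
                n = n, undefined = TRUE))
  }
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  tx <- table(x)
  ty <- table(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(var_s)
  list(tau_b = tau, S = S, z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       n = n, undefined = FALSE)
}

.check_tau_input <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  invisible(NULL)
}

# Precompute the parts of tau-b that depend only on y; the stepwise curves
# correlate many subset vectors against one fixed overall richness vector.
.tau_prep <- function(y) {
  n <- length(y)
  sy <- sign(outer(y, y, "-"))
  list(sy = sy, n = n, n0 = n * (n - 1) / 2, n2 = (sum(sy == 0) - n) / 2)
}

.tau_b_fixed <- function(x, prep) {
  sx <- sign(outer(x, x, "-"))
  S <- sum(sx * prep$sy) / 2
  n1 <- (sum(sx == 0) - prep$n) / 2
  denom <- (prep$n0 - n1) * (prep$n0 - prep$n2)
  if (denom <= 0) return(NA_real_)
  S / sqrt(denom)
}
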