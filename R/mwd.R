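# Distribution kernel for the three-parameter modified Weibull law.
# All evaluation goes through the log scale: (x/beta)^alpha is computed as
# exp(alpha * log(x/beta)) and the density as exp(logpdf), so that large
# t/beta overflows to -Inf log-density rather than NaN.

check_mwd_params <- function(alpha, beta, lambda) {
  if (!is.numeric(alpha) || !is.numeric(beta) || !is.numeric(lambda))
    stop("'alpha', 'beta' and 'lambda' must be numeric", call. = FALSE)
  if (any(!is.finite(c(alpha, beta, lambda))) ||
      any(c(alpha, beta, lambda) <= 0))
    stop("'alpha', 'beta' and 'lambda' must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

# (x/beta)^alpha in log space; x may be 0 (-> 0 when alpha > 0)
.mwd_z <- function(x, alpha, beta) {
  z <- rep(0, length(x))
  pos <- x > 0
  z[pos] <- exp(alpha * (log(x[pos]) - log(beta)))
  z
}

#' The modified Weibull distribution
#'
#' Density, distribution function, survival function, quantile function,
#' hazard rate, reversed (inverse) hazard rate and random generation for the
#' three-parameter modified Weibull distribution with shape parameters
#' `alpha` and `beta` and scale parameter `lambda`:
#' \deqn{f(x) = \lambda\alpha (x/\beta)^{\alpha-1}
#'   \exp\{(x/\beta)^\alpha + \lambda\beta(1 - e^{(x/\beta)^\alpha})\}.}
#'
#' At `x = 0` the density is 0 for `alpha > 1`, `lambda` for `alpha = 1`, and
#' `Inf` (the true limit, returned as a sentinel rather than an error) for
#' `alpha < 1`.  Setting `lambda = 1` recovers the exponential power
#' distribution EPD(`alpha`, `beta`).
#'
#' The hazard rate \eqn{h(t) = f(t)/S(t)} is increasing whenever
#' \eqn{\alpha \ge 1}; for \eqn{\alpha < 1} it is bathtub-shaped with interior
#' minimum at \eqn{t^* = \beta((1-\alpha)/\alpha)^{1/\alpha}}
#' (see [mwd_hazard_min()]).
#'
#' @param x,q,t vector of nonnegative times (`t` strictly positive for the
#'   hazard functions).
#' @param p vector of probabilities in `[0, 1)`.
#' @param n number of draws.
#' @param alpha,beta,lambda distribution parameters, all strictly positive.
#' @param log,log.p logical; if `TRUE`, densities/probabilities are returned
#'   on the log scale.
#' @param lower.tail logical; if `FALSE`, `pmwd` returns the survival
#'   function \eqn{S(q) = 1 - F(q)}.
#' @return `dmwd` the density, `pmwd` the distribution (or survival)
#'   function, `qmwd` the quantile function
#'   \eqn{\beta[\log(1 - \log(1-p)/(\lambda\beta))]^{1/\alpha}},
#'   `hmwd` the hazard rate, `rhmwd` the reversed hazard rate
#'   \eqn{f/F}, and `rmwd` a vector of `n` random deviates
#'   (inverse-CDF sampling, reproducible under `set.seed`).
#' @examples
#' pmwd(1, 1, 1, 1)                    # 1 - exp(1 - e)
#' qmwd(pmwd(0.7, 2, 1, 0.5), 2, 1, 0.5)
#' hmwd(2, 0.5, 1, 1) * pmwd(2, 0.5, 1, 1, lower.tail = FALSE)  # = dmwd(2, ...)
#' @name mwd
NULL

#' @rdname mwd
#' @export
dmwd <- function(x, alpha, beta, lambda, log = FALSE) {
  check_mwd_params(alpha, beta, lambda)
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  lp <- numeric(length(x))
  pos <- x > 0
  z <- .mwd_z(x[pos], alpha, beta)
  lp[pos] <- log(lambda * alpha) + (alpha - 1) * (log(x[pos]) - log(beta)) +
    z + lambda * beta * (1 - exp(z))
  # limits at the origin
  lp[!pos] <- if (alpha > 1) -Inf else if (alpha == 1) log(lambda) else Inf
  if (log) lp else exp(lp)
}

#' @rdname mwd
#' @export
pmwd <- function(q, alpha, beta, lambda, lower.tail = TRUE, log.p = FALSE) {
  check_mwd_params(alpha, beta, lambda)
  if (any(q < 0)) stop("'q' must be >= 0", call. = FALSE)
  z <- .mwd_z(q, alpha, beta)
  lsurv <- lambda * beta * (1 - exp(z))   # log S(q), always <= 0
  if (lower.tail) {
    if (log.p) log(-expm1(lsurv)) else -expm1(lsurv)
  } else {
    if (log.p) lsurv else exp(lsurv)
  }
}

#' @rdname mwd
#' @export
qmwd <- function(p, alpha, beta, lambda) {
  check_mwd_params(alpha, beta, lambda)
  if (any(p < 0 | p >= 1)) stop("'p' must lie in [0, 1)", call. = FALSE)
  # F(x) = p  <=>  x = beta * [log(1 - log(1-p)/(lambda beta))]^(1/alpha)
  beta * (log1p(-log1p(-p) / (lambda * beta)))^(1 / alpha)
}

#' @rdname mwd
#' @export
rmwd <- function(n, alpha, beta, lambda) {
  qmwd(runif(n), alpha, beta, lambda)
}

#' @rdname mwd
#' @export
hmwd <- function(t, alpha, beta, lambda) {
  check_mwd_params(alpha, beta, lambda)
  if (any(t <= 0)) stop("'t' must be > 0", call. = FALSE)
  z <- .mwd_z(t, alpha, beta)
  lambda * alpha * exp((alpha - 1) * (log(t) - log(beta))) * exp(z)
}

#' @rdname mwd
#' @export
rhmwd <- function(t, alpha, beta, lambda) {
  check_mwd_params(alpha, beta, lambda)
  if (any(t <= 0)) stop("'t' must be > 0", call. = FALSE)
  dmwd(t, alpha, beta, lambda) / pmwd(t, alpha, beta, lambda)
}

#' Location of the hazard-rate minimum
#'
#' For `alpha < 1` the modified Weibull hazard is bathtub-shaped: decreasing
#' up to \eqn{t^* = \beta((1-\alpha)/\alpha)^{1/\alpha}} and increasing
#' beyond it (obtained by solving \eqn{d \log h/dt = 0}).  For
#' `alpha >= 1` the hazard is monotone increasing and `NA` is returned.
#'
#' @inheritParams mwd
#' @return the turning point \eqn{t^*}, or `NA_real_` when the hazard is
#'   monotone.
#' @export
mwd_hazard_min <- function(alpha, beta, lambda = 1) {
  check_mwd_params(alpha, beta, lambda)
  if (alpha >= 1) return(NA_real_)
  beta * ((1 - alpha) / alpha)^(1 / alpha)
}
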