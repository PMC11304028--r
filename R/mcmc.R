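# Metropolis-within-Gibbs sampler for the joint posterior of
# (alpha, beta, lambda) under independent gamma priors.
#
# lambda has a conjugate gamma full conditional; alpha and beta are updated
# by normal random-walk Metropolis-Hastings steps whose proposal sds default
# to the Wald standard errors of the MLE.  Proposals <= 0 have zero target
# density and are rejected automatically.

# joint log posterior (unnormalized)
.log_posterior <- function(params, sample, priors) {
  if (any(params <= 0)) return(-Inf)
  a <- params[1]; b <- params[2]; l <- params[3]
  x <- sample$x; sch <- sample$scheme
  z <- exp(a * (log(x) - log(b)))
  v <- (sch$m + priors$a1 - 1) * log(a) + (priors$a2 - 1) * log(b) +
    (sch$m + priors$a3 - 1) * log(l) -
    priors$b1 * a - priors$b2 * b - priors$b3 * l +
    (a - 1) * sum(log(x) - log(b)) + sum(z) +
    l * b * sch$k * sum((sch$R + 1) * (1 - exp(z)))
  if (is.na(v)) -Inf else v
}

#' Full conditional distributions of the PFFC posterior
#'
#' `lambda_conditional` returns the shape and rate of lambda's conjugate
#' gamma full conditional,
#' \eqn{\lambda \mid \alpha,\beta \sim \mathrm{Gamma}(m + a_3,\;
#' b_3 + k\beta\sum(R_i+1)(e^{(x_i/\beta)^\alpha} - 1))}.
#' `log_cond_alpha` and `log_cond_beta` return the unnormalized log full
#' conditionals of `alpha` and `beta` (equal to the joint log posterior up
#' to terms constant in the argument; nonpositive arguments give `-Inf`).
#'
#' @param alpha,beta,lambda current parameter values.
#' @param sample a [pffc_sample()].
#' @param priors a [gamma_priors()].
#' @return `lambda_conditional` a list with `shape` and `rate`; the two
#'   `log_cond_*` functions a scalar log density.
#' @export
lambda_conditional <- function(alpha, beta, sample, priors = gamma_priors()) {
  if (alpha <= 0 || beta <= 0) stop("'alpha' and 'beta' must be > 0")
  x <- sample$x; sch <- sample$scheme
  z <- exp(alpha * (log(x) - log(beta)))
  rate <- priors$b3 + sch$k * beta * sum((sch$R + 1) * expm1(z))
  if (!is.finite(rate) || rate <= 0)
    stop("lambda conditional rate is not finite and positive ",
         "(overflow in exp((x/beta)^alpha))")
  list(shape = sch$m + priors$a3, rate = rate)
}

#' @rdname lambda_conditional
#' @export
log_cond_alpha <- function(alpha, beta, lambda, sample,
                           priors = gamma_priors()) {
  if (alpha <= 0) return(-Inf)
  .log_posterior(c(alpha, beta, lambda), sample, priors)
}

#' @rdname lambda_conditional
#' @export
log_cond_beta <- function(beta, alpha, lambda, sample,
                          priors = gamma_priors()) {
  if (beta <= 0) return(-Inf)
  .log_posterior(c(alpha, beta, lambda), sample, priors)
}

#' Metropolis-within-Gibbs sampling of the PFFC posterior
#'
#' Runs the hybrid sampler: each sweep draws `lambda` exactly from its gamma
#' full conditional, then updates `alpha` and `beta` by normal random-walk
#' Metropolis-Hastings steps.  The chain starts at the MLE and the default
#' proposal standard deviations are the Wald standard errors (falling back
#' to 10% of the current value, with a warning, when the information matrix
#' was not positive definite).  The survival, hazard and reversed-hazard
#' functions at `t` are recorded at every iteration.
#'
#' @param fit a converged [mwd_fit()] (supplies data, initial state and
#'   proposal scales).
#' @param priors a [gamma_priors()].
#' @param n_iter total number of sweeps `N`.
#' @param burn_in number of initial sweeps `M` discarded by the summary
#'   functions (`0 <= M < N`).
#' @param proposal_sd optional length-2 vector of proposal sds for
#'   `(alpha, beta)`.
#' @param t evaluation time for the reliability functions.
#' @return an object of class `"mwd_mcmc"`: a list with `draws` (an
#'   `n_iter` x 6 matrix with columns `alpha`, `beta`, `lambda`, `S`, `h`,
#'   `r`), `accept` (acceptance fractions for `alpha` and `beta`),
#'   `burn_in`, `t`, and the call configuration.  A fixed seed gives an
#'   identical chain.
#' @seealso [posterior_estimate()], [credible_interval()]
#' @examples
#' sch <- pffc_scheme(30, 20, k = 2, kind = "SC1")
#' set.seed(11)
#' fit <- mwd_fit(rpffc(sch, 2, 1, 1))
#' ch <- mwd_mcmc(fit, gamma_priors(1, 2, 1, 2, 1, 2),
#'                n_iter = 500, burn_in = 100)
#' posterior_estimate(ch, "alpha")
#' @export
mwd_mcmc <- function(fit, priors = gamma_priors(), n_iter = 12000,
                     burn_in = 2000, proposal_sd = NULL, t = 1) {
  if (!inherits(fit, "mwd_fit")) stop("'fit' must be an mwd_fit")
  if (burn_in < 0 || burn_in >= n_iter) stop("need 0 <= burn_in < n_iter")
  sample <- fit$sample
  cur <- unname(fit$coefficients)
  if (any(!is.finite(cur))) stop("fit has no usable estimates")
  if (is.null(proposal_sd)) {
    v <- diag(fit$vcov)[1:2]
    if (fit$vcov_ok && all(is.finite(v)) && all(v > 0)) {
      proposal_sd <- sqrt(v)
    } else {
      warning("information matrix not positive definite; ",
              "falling back to 10% random-walk proposals")
      proposal_sd <- 0.1 * cur[1:2]
    }
  }
  if (any(proposal_sd <= 0)) stop("proposal sds must be > 0")

  draws <- matrix(NA_real_, n_iter, 6,
                  dimnames = list(NULL, c("alpha", "beta", "lambda",
                                          "S", "h", "r")))
  acc <- c(alpha = 0L, beta = 0L)
  lp_cur <- .log_posterior(cur, sample, priors)
  if (!is.finite(lp_cur)) stop("log posterior not finite at the MLE")
  for (j in seq_len(n_iter)) {
    gc_ <- lambda_conditional(cur[1], cur[2], sample, priors)
    cur[3] <- rgamma(1, shape = gc_$shape, rate = gc_$rate)
    lp_cur <- .log_posterior(cur, sample, priors)

    ap <- rnorm(1, cur[1], proposal_sd[1])
    lp_prop <- .log_posterior(c(ap, cur[2], cur[3]), sample, priors)
    if (log(runif(1)) < lp_prop - lp_cur) {
      cur[1] <- ap; lp_cur <- lp_prop; acc[1] <- acc[1] + 1L
    }
    bp <- rnorm(1, cur[2], proposal_sd[2])
    lp_prop <- .log_posterior(c(cur[1], bp, cur[3]), sample, priors)
    if (log(runif(1)) < lp_prop - lp_cur) {
      cur[2] <- bp; lp_cur <- lp_prop; acc[2] <- acc[2] + 1L
    }
    draws[j, 1:3] <- cur
    draws[j, 4] <- pmwd(t, cur[1], cur[2], cur[3], lower.tail = FALSE)
    draws[j, 5] <- hmwd(t, cur[1], cur[2], cur[3])
    draws[j, 6] <- rhmwd(t, cur[1], cur[2], cur[3])
  }
  accept <- acc / n_iter
  if (any(accept < 0.01))
    warning("Metropolis acceptance rate below 1%; consider smaller ",
            "proposal sds or re-parameterization")
  structure(list(draws = draws, accept = accept, n_iter = n_iter,
                 burn_in = burn_in, t = t, priors = priors,
                 proposal_sd = proposal_sd),
            class = "mwd_mcmc")
}

.post_burn <- function(chain, quantity) {
  d <- chain$draws[(chain$burn_in + 1):chain$n_iter, quantity]
  if (length(d) == 0L) stop("empty post-burn-in chain")
  d
}

#' Posterior point estimates from an MCMC chain
#'
#' Squared-error loss (`"self"`) gives the post-burn-in mean; general
#' entropy loss (`"gelf"`) gives
#' \eqn{[\frac{1}{N-M}\sum \psi_i^{-\epsilon}]^{-1/\epsilon}}.  The two
#' coincide exactly at \eqn{\epsilon = -1}.
#'
#' @param chain an [mwd_mcmc()].
#' @param quantity one of `"alpha"`, `"beta"`, `"lambda"`, `"S"`, `"h"`,
#'   `"r"`.
#' @param loss `"self"` or `"gelf"`.
#' @param epsilon nonzero GELF parameter.
#' @return a scalar estimate.
#' @export
posterior_estimate <- function(chain, quantity = "alpha",
                               loss = c("self", "gelf"), epsilon = NULL) {
  loss <- match.arg(loss)
  d <- .post_burn(chain, quantity)
  if (loss == "self") return(mean(d))
  if (is.null(epsilon) || epsilon == 0)
    stop("GELF requires a nonzero 'epsilon'")
  mean(d^(-epsilon))^(-1 / epsilon)
}

#' Credible interval from sorted posterior draws
#'
#' The default is the equal-tail percentile construction on the sorted
#' post-burn-in draws, taking order statistics `floor(gamma * (N - M))` and
#' `ceiling((1 - gamma) * (N - M))` (clamped to the valid range), i.e. a
#' `100 * (1 - 2 * gamma)`% interval.  `method = "hpd"` instead returns the
#' shortest interval spanning a `1 - 2 * gamma` fraction of the sorted
#' draws.
#'
#' @inheritParams posterior_estimate
#' @param gamma tail probability per side (`gamma = 0.025` gives 95%).
#' @param method `"percentile"` (default) or `"hpd"`.
#' @return length-2 vector `c(lower, upper)`.
#' @export
credible_interval <- function(chain, quantity = "alpha", gamma = 0.025,
                              method = c("percentile", "hpd")) {
  method <- match.arg(method)
  d <- sort(.post_burn(chain, quantity))
  nd <- length(d)
  if (method == "percentile") {
    lo <- min(max(floor(gamma * nd), 1L), nd)
    hi <- min(max(ceiling((1 - gamma) * nd), 1L), nd)
    c(lower = d[lo], upper = d[hi])
  } else {
    width <- max(1L, floor((1 - 2 * gamma) * nd))
    if (width >= nd) return(c(lower = d[1], upper = d[nd]))
    lens <- d[(width + 1):nd] - d[1:(nd - width)]
    i <- which.min(lens)
    c(lower = d[i], upper = d[i + width])
  }
}

#' @export
print.mwd_mcmc <- function(x, ...) {
  cat("Metropolis-within-Gibbs chain:", x$n_iter, "sweeps,",
      x$burn_in, "burn-in\n")
  cat("acceptance rates: alpha", round(x$accept[1], 3),
      " beta", round(x$accept[2], 3), "\n")
  invisible(x)
}

#' @export
summary.mwd_mcmc <- function(object, gamma = 0.025, epsilons = c(-1, 1), ...) {
  qs <- colnames(object$draws)
  tab <- t(vapply(qs, function(q) {
    ests <- c(SELF = posterior_estimate(object, q),
              vapply(epsilons, function(e)
                posterior_estimate(object, q, "gelf", e), numeric(1)))
    ci <- credible_interval(object, q, gamma)
    c(ests, ci)
  }, numeric(3 + length(epsilons))))
  colnames(tab) <- c("SELF", paste0("GELF(eps=", epsilons, ")"),
                     "lower", "upper")
  structure(list(table = tab, gamma = gamma, chain = object),
            class = "summary.mwd_mcmc")
}

#' @export
print.summary.mwd_mcmc <- function(x, digits = 5, ...) {
  print(x$chain)
  cat("\nPosterior estimates and ", 100 * (1 - 2 * x$gamma),
      "% percentile credible intervals:\n", sep = "")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
plot.mwd_mcmc <- function(x, quantities = c("alpha", "beta", "lambda"), ...) {
  op <- par(mfrow = c(length(quantities), 2), mar = c(3, 4, 2, 1))
  on.exit(par(op))
  for (q in quantities) {
    d <- .post_burn(x, q)
    plot(d, type = "l", ylab = q, xlab = "", main = paste("trace:", q))
    abline(h = mean(d), lty = 2)
    hist(d, breaks = 40, main = paste("posterior:", q), xlab = q)
    abline(v = credible_interval(x, q), lty = 1)
  }
  invisible(x)
}
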