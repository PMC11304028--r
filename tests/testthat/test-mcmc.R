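# Metropolis-within-Gibbs sampler: conditional/joint consistency (the
# anti-typo guard), the conjugate lambda step, estimators under both losses,
# and credible-interval mechanics.

test_that("printed conditional kernels equal the joint posterior up to constants", {
  s <- toy_sample(); pr <- toy_priors()
  lp <- function(p) mwpffc:::.log_posterior(p, s, pr)
  set.seed(77)
  for (i in 1:10) {
    p <- exp(runif(3, -1, 1))
    a2 <- p[1] * exp(runif(1, -0.5, 0.5))
    expect_equal(log_cond_alpha(a2, p[2], p[3], s, pr) -
                 log_cond_alpha(p[1], p[2], p[3], s, pr),
                 lp(c(a2, p[2], p[3])) - lp(p), tolerance = 1e-10)
    b2 <- p[2] * exp(runif(1, -0.5, 0.5))
    expect_equal(log_cond_beta(b2, p[1], p[3], s, pr) -
                 log_cond_beta(p[2], p[1], p[3], s, pr),
                 lp(c(p[1], b2, p[3])) - lp(p), tolerance = 1e-10)
    # lambda's gamma conditional is the joint in lambda up to a constant
    gc_ <- lambda_conditional(p[1], p[2], s, pr)
    l2 <- p[3] * exp(runif(1, -0.5, 0.5))
    expect_equal(dgamma(l2, gc_$shape, rate = gc_$rate, log = TRUE) -
                 dgamma(p[3], gc_$shape, rate = gc_$rate, log = TRUE),
                 lp(c(p[1], p[2], l2)) - lp(p), tolerance = 1e-10)
  }
  expect_identical(log_cond_alpha(-1, 1, 1, s, pr), -Inf)
  expect_identical(log_cond_beta(0, 1, 1, s, pr), -Inf)
})

test_that("the lambda conditional has the conjugate gamma form", {
  # Jeffreys case with k = 1, R = 0: shape is exactly m
  cs <- pffc_sample(c(0.2, 0.5, 0.9, 1.4), pffc_scheme(4, 4, 1, kind = "SC3"))
  gc0 <- lambda_conditional(1, 1, cs, gamma_priors())
  expect_identical(gc0$shape, 4)
  # frozen hand-summation on the renal subsample at the printed estimates
  gc1 <- lambda_conditional(0.65122, 1.77911, renal_pffc_sample(),
                            gamma_priors(1e-4, 1e-4, 1e-4, 1e-4, 1e-4, 1e-4))
  expect_equal(gc1$rate, 108.1194, tolerance = 1e-4)
  expect_equal(gc1$shape / gc1$rate, 0.0925, tolerance = 1e-3)
  # moment check on draws from the returned law
  set.seed(3)
  d <- rgamma(1e5, gc1$shape, rate = gc1$rate)
  mu <- gc1$shape / gc1$rate; v <- gc1$shape / gc1$rate^2
  expect_lt(abs(mean(d) - mu), 3 * sqrt(v / 1e5))
  expect_lt(abs(var(d) - v), 3 * v * sqrt(2 / 1e5) * 1.5)
  # mode of the beta conditional matches a 1-D maximization of the joint
  s <- toy_sample(); pr <- toy_priors()
  ob <- optimize(function(b) -log_cond_beta(b, 1.2, 0.4, s, pr), c(0.05, 10))
  oj <- optimize(function(b) -mwpffc:::.log_posterior(c(1.2, b, 0.4), s, pr),
                 c(0.05, 10))
  expect_equal(ob$minimum, oj$minimum, tolerance = 1e-6)
})

test_that("chains are reproducible, positive, and track the reliability functions", {
  s <- toy_sample()
  fit <- mwd_fit(s)
  pr <- toy_priors()
  set.seed(5); ch1 <- mwd_mcmc(fit, pr, n_iter = 400, burn_in = 100, t = 1)
  set.seed(5); ch2 <- mwd_mcmc(fit, pr, n_iter = 400, burn_in = 100, t = 1)
  expect_identical(ch1$draws, ch2$draws)
  expect_equal(nrow(ch1$draws), 400)
  expect_true(all(ch1$draws[, 1:3] > 0))
  expect_true(all(ch1$draws[, "S"] > 0 & ch1$draws[, "S"] <= 1))
  # recorded reliability columns are the deterministic transforms
  i <- 57
  p <- ch1$draws[i, 1:3]
  expect_equal(unname(ch1$draws[i, "h"]), unname(hmwd(1, p[1], p[2], p[3])))
  expect_error(mwd_mcmc(fit, pr, n_iter = 100, burn_in = 100), "burn_in")
})

test_that("posterior sampling reproduces grid-quadrature posterior means on the toy problem", {
  s <- toy_sample(); pr <- toy_priors()
  q <- quad_posterior(s, pr, c(0.02, 6, 0.02, 6, 0.01, 4), np = 70)
  expect_lt(q["edge"], 1e-3)   # the grid box contains the mass
  fit <- mwd_fit(s)
  set.seed(5)
  ch <- mwd_mcmc(fit, pr, n_iter = 12000, burn_in = 2000, t = 1)
  for (nm in c("alpha", "beta", "lambda")) {
    d <- ch$draws[2001:12000, nm]
    mc_se <- 3 * sd(d) / sqrt(length(d) / 20)   # generous autocorrelation factor
    expect_lt(abs(posterior_estimate(ch, nm) - q[nm]), max(mc_se, 0.02 * q[nm]))
  }
  # mixing across independent seeds: split-free Gelman-Rubin below 1.05
  lam <- vapply(1:4, function(sd_) {
    set.seed(sd_)
    mwd_mcmc(fit, pr, n_iter = 3000, burn_in = 500)$draws[501:3000, "lambda"]
  }, numeric(2500))
  N <- nrow(lam)
  B <- N * var(colMeans(lam)); W <- mean(apply(lam, 2, var))
  rhat <- sqrt(((N - 1) / N * W + B / N) / W)
  expect_lt(rhat, 1.05)
})

test_that("loss functionals on chains: SELF mean, GELF power mean, and their identities", {
  s <- toy_sample()
  fit <- mwd_fit(s)
  set.seed(6)
  ch <- mwd_mcmc(fit, toy_priors(), n_iter = 2000, burn_in = 500)
  expect_identical(posterior_estimate(ch, "alpha"),
                   posterior_estimate(ch, "alpha", "gelf", epsilon = -1))
  # harmonic-type mean under epsilon = 1 is below the arithmetic mean
  expect_lt(posterior_estimate(ch, "lambda", "gelf", epsilon = 1),
            posterior_estimate(ch, "lambda"))
  expect_error(posterior_estimate(ch, "alpha", "gelf", epsilon = 0), "nonzero")
  # a constant chain gives that constant under every loss
  chc <- ch
  chc$draws[, "alpha"] <- 2.5
  expect_equal(posterior_estimate(chc, "alpha"), 2.5)
  expect_equal(posterior_estimate(chc, "alpha", "gelf", 1), 2.5)
  expect_equal(posterior_estimate(chc, "alpha", "gelf", -2.3), 2.5)
})

test_that("percentile credible intervals use the printed order-statistic convention", {
  fake <- structure(list(draws = cbind(alpha = c(rep(0, 500), 1:10000)),
                         n_iter = 10500, burn_in = 500, accept = c(1, 1)),
                    class = "mwd_mcmc")
  ci <- credible_interval(fake, "alpha", gamma = 0.025)
  expect_equal(unname(ci), c(250, 9750))
  # hpd on a skewed chain is no wider than the percentile interval
  s <- toy_sample()
  fit <- mwd_fit(s)
  set.seed(9)
  ch <- mwd_mcmc(fit, toy_priors(), n_iter = 3000, burn_in = 500)
  pc <- credible_interval(ch, "lambda")
  hp <- credible_interval(ch, "lambda", method = "hpd")
  expect_lte(hp[2] - hp[1], pc[2] - pc[1])
  # interval brackets the posterior mean for these unimodal chains
  for (nm in c("alpha", "beta", "lambda")) {
    ci <- credible_interval(ch, nm)
    est <- posterior_estimate(ch, nm)
    expect_true(ci[1] < est && est < ci[2])
  }
})
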