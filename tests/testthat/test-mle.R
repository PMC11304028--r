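# Corrected PFFC log-likelihood, analytic score, observed information,
# the fitter, and Wald/delta intervals.

test_that("log-likelihood matches the joint PFFC density and the frozen reference value", {
  s <- renal_pffc_sample()
  k <- s$scheme$k; R <- s$scheme$R; m <- s$scheme$m
  # independent oracle: sum log f + sum (k(R_i+1)-1) log S + m log k
  joint <- function(p) {
    sum(dmwd(s$x, p[1], p[2], p[3], log = TRUE)) +
      sum((k * (R + 1) - 1) *
            pmwd(s$x, p[1], p[2], p[3], lower.tail = FALSE, log.p = TRUE)) +
      m * log(k)
  }
  for (p in list(printed_renal_mle, c(0.4, 3.9, 0.06), c(1.2, 0.8, 0.5)))
    expect_equal(pffc_loglik(p, s) + m * log(k), joint(p), tolerance = 1e-12)
  # hand-evaluated value at the printed estimates
  expect_equal(pffc_loglik(printed_renal_mle, s), -22.9782, tolerance = 1e-4)
  # complete-sample reduction: k = 1, R = 0, m = n
  x <- sort(rmwd(8, 1.5, 1, 1))
  cs <- pffc_sample(x, pffc_scheme(8, 8, 1, kind = "SC3"))
  expect_equal(pffc_loglik(c(1.5, 1, 1), cs),
               sum(dmwd(x, 1.5, 1, 1, log = TRUE)), tolerance = 1e-12)
})

test_that("analytic score equals the numeric gradient on random parameter/sample pairs", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(8:20, 1); m <- sample(4:n, 1)
    R <- as.numeric(rmultinom(1, n - m, rep(1, m)))
    sch <- pffc_scheme(n, m, sample(1:4, 1), R = R)
    truth <- exp(runif(3, -0.7, 0.7))
    s <- rpffc(sch, truth[1], truth[2], truth[3])
    p <- truth * exp(runif(3, -0.3, 0.3))
    g <- pffc_score(p, s)
    gn <- num_grad3(function(q) pffc_loglik(q, s), p)
    expect_equal(unname(g), gn, tolerance = 1e-6)
  }
})

test_that("the closed-form lambda profile is the root of the lambda score", {
  s <- renal_pffc_sample()
  for (ab in list(c(0.65122, 1.77911), c(0.4, 3.9), c(1.1, 1))) {
    lam <- pffc_profile_lambda(ab[1], ab[2], s)
    expect_equal(unname(pffc_score(c(ab, lam), s)["lambda"]), 0,
                 tolerance = 1e-8 * s$scheme$m / lam)
  }
  # frozen hand-summation at the printed estimates:
  # m / (k beta sum (R_i+1)(e^z - 1)) = 10 / (5 * 1.77911 * 12.15431)
  expect_equal(pffc_profile_lambda(0.65122, 1.77911, s), 0.0924904,
               tolerance = 1e-6)
})

test_that("the fitter finds a stationary interior optimum, robust to the starting point", {
  s <- renal_pffc_sample()
  fit <- mwd_fit(s)
  expect_true(fit$converged)
  # first-order condition, scaled by the parameters
  expect_lt(max(abs(pffc_score(coef(fit), s) * coef(fit))), 1e-5)
  # joint optimum consistent with the lambda profile
  expect_lt(abs(coef(fit)[3] -
                pffc_profile_lambda(coef(fit)[1], coef(fit)[2], s)) /
            coef(fit)[3], 1e-6)
  # five random starting points agree to 1e-4
  set.seed(99)
  ests <- t(vapply(1:5, function(i) {
    coef(mwd_fit(s, init = c(runif(1, 0.3, 3), runif(1, 0.5, 5),
                             runif(1, 0.02, 1))))
  }, numeric(3)))
  expect_lt(max(apply(ests, 2, function(v) diff(range(v)) / median(v))), 1e-4)
  # degenerate data are flagged, not silently fitted
  dg <- pffc_sample(rep(1, 5), pffc_scheme(5, 5, 1, kind = "SC3"))
  expect_warning(fd <- mwd_fit(dg), "degenerate")
  expect_false(fd$converged)
})

test_that("observed information matches curvature of the log-likelihood, with -m/lambda^2 in the corner", {
  s <- renal_pffc_sample()
  p <- c(0.7, 1.5, 0.1)
  I <- pffc_info(p, s)
  expect_equal(I, t(I))
  # second finite differences of the log-likelihood itself
  h <- 1e-4 * p
  for (i in 1:3) for (j in 1:3) {
    ei <- numeric(3); ei[i] <- h[i]
    ej <- numeric(3); ej[j] <- h[j]
    d2 <- (pffc_loglik(p + ei + ej, s) - pffc_loglik(p + ei - ej, s) -
           pffc_loglik(p - ei + ej, s) + pffc_loglik(p - ei - ej, s)) /
      (4 * h[i] * h[j])
    expect_equal(I[i, j], -d2, tolerance = 1e-4)
  }
  # d2l/dlambda2 = -m/lambda^2 exactly (up to rounding of the difference)
  expect_equal(I["lambda", "lambda"], s$scheme$m / p[3]^2, tolerance = 1e-9)
  # positive definite at the optimum
  fit <- mwd_fit(s)
  expect_true(all(eigen(pffc_info(coef(fit), s))$values > 0))
})

test_that("Wald intervals use the exact normal quantile and handle degenerate covariance", {
  s <- renal_pffc_sample()
  fit <- mwd_fit(s)
  ci <- confint(fit, level = 0.95)
  se <- sqrt(diag(vcov(fit)))
  expect_equal(unname(ci[, 2] - ci[, 1]), unname(2 * 1.959963985 * se),
               tolerance = 1e-9)
  # zero covariance -> intervals collapse onto the estimates
  fit0 <- fit
  fit0$vcov <- matrix(0, 3, 3, dimnames = dimnames(fit$vcov))
  ci0 <- confint(fit0)
  expect_equal(unname(ci0[, 1]), unname(coef(fit)))
  expect_equal(unname(ci0[, 2]), unname(coef(fit)))
  # negative variance is an error, not a NaN interval
  fitn <- fit
  fitn$vcov[1, 1] <- -1
  expect_error(confint(fitn), "positive definite")
  # optional truncation at zero
  expect_true(all(confint(fit, truncate = TRUE)[, 1] >= 0))
})

test_that("delta-method reliability intervals behave and match a parametric bootstrap", {
  s <- renal_pffc_sample()
  fit <- mwd_fit(s)
  pr <- predict(fit, times = 1)
  p <- coef(fit)
  expect_equal(pr$S, unname(pmwd(1, p[1], p[2], p[3], lower.tail = FALSE)))
  expect_equal(pr$h, unname(hmwd(1, p[1], p[2], p[3])))
  expect_equal(pr$r, unname(rhmwd(1, p[1], p[2], p[3])))
  # plug-in value at the printed estimates (frozen direct evaluation)
  expect_equal(unname(pmwd(1, 0.65122, 1.77911, 0.09011, lower.tail = FALSE)),
               0.8535047, tolerance = 1e-6)
  # zero covariance -> zero-width intervals
  fit0 <- fit
  fit0$vcov <- matrix(0, 3, 3, dimnames = dimnames(fit$vcov))
  pr0 <- predict(fit0, times = 1)
  expect_equal(pr0$lower_S, pr0$upper_S)
  expect_error(predict(fit, times = -1), "> 0")

  # delta variance of S(t) vs a parametric-bootstrap cloud at (90, 75)
  sch <- pffc_scheme(90, 75, k = 2, kind = "SC1")
  set.seed(31)
  sb <- rpffc(sch, 1, 0.1, 2)
  fb <- mwd_fit(sb)
  t0 <- 0.15
  tau2 <- predict(fb, times = t0)$se_S^2
  set.seed(32)
  pb <- coef(fb)
  Sb <- vapply(1:300, function(b) {
    f2 <- tryCatch(suppressWarnings(mwd_fit(rpffc(sch, pb[1], pb[2], pb[3]))),
                   error = function(e) NULL)
    if (is.null(f2) || !f2$converged) return(NA_real_)
    q <- coef(f2)
    pmwd(t0, q[1], q[2], q[3], lower.tail = FALSE)
  }, numeric(1))
  expect_gt(tau2 / var(Sb, na.rm = TRUE), 0.75)
  expect_lt(tau2 / var(Sb, na.rm = TRUE), 1 / 0.75)
})

test_that("rescaling the time unit maps the fit to (alpha, c beta, lambda/c)", {
  s <- renal_pffc_sample()
  fit <- mwd_fit(s)
  cc <- 3.7
  fit2 <- mwd_fit(pffc_sample(s$x * cc, s$scheme))
  expect_equal(unname(coef(fit2)),
               unname(c(coef(fit)[1], cc * coef(fit)[2], coef(fit)[3] / cc)),
               tolerance = 1e-4)
})

test_that("fit methods: logLik, residuals, simulate, summary", {
  s <- renal_pffc_sample()
  fit <- mwd_fit(s)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(attr(logLik(fit), "df"), 3L)
  r <- residuals(fit)
  p <- coef(fit)
  expect_equal(r, -log(pmwd(s$x, p[1], p[2], p[3], lower.tail = FALSE)))
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "pffc_sample")
  expect_output(print(summary(fit)), "Wald")
})
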