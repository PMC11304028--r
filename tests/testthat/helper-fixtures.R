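# Shared fixtures and small oracles used across the suite.

# the published PFFC subsample of the kidney-graft data and its MLE column
# as printed in the source analysis
printed_renal_mle <- c(alpha = 0.65122, beta = 1.77911, lambda = 0.09011)

# fixed m = 3 toy world with proper gamma priors: small enough for 3-D grid
# quadrature of the posterior
toy_sample <- function() {
  pffc_sample(c(0.3, 0.7, 1.2), pffc_scheme(5, 3, k = 2, R = c(1, 1, 0)))
}
toy_priors <- function() gamma_priors(2, 2, 2, 2, 2, 2)

# vectorized 3-D grid quadrature of the joint posterior; returns posterior
# means of (alpha, beta, lambda) plus the largest edge weight as a mass
# containment diagnostic
quad_posterior <- function(s, pr, lims, np = 80) {
  ga <- seq(lims[1], lims[2], length.out = np)
  gb <- seq(lims[3], lims[4], length.out = np)
  gl <- seq(lims[5], lims[6], length.out = np)
  G <- as.matrix(expand.grid(a = ga, b = gb, l = gl))
  m <- s$scheme$m; k <- s$scheme$k; R <- s$scheme$R; x <- s$x
  lp <- (m + pr$a1 - 1) * log(G[, 1]) + (pr$a2 - 1) * log(G[, 2]) +
    (m + pr$a3 - 1) * log(G[, 3]) -
    pr$b1 * G[, 1] - pr$b2 * G[, 2] - pr$b3 * G[, 3]
  for (i in seq_along(x)) {
    z <- exp(G[, 1] * (log(x[i]) - log(G[, 2])))
    lp <- lp + (G[, 1] - 1) * (log(x[i]) - log(G[, 2])) + z +
      G[, 3] * G[, 2] * k * (R[i] + 1) * (1 - exp(z))
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  edge <- G[, 1] %in% range(ga) | G[, 2] %in% range(gb) | G[, 3] %in% range(gl)
  c(alpha = sum(G[, 1] * w), beta = sum(G[, 2] * w), lambda = sum(G[, 3] * w),
    edge = max(w[edge]))
}

# central finite-difference gradient for score cross-checks
num_grad3 <- function(f, p, h = 1e-6) {
  vapply(1:3, function(i) {
    hi <- h * p[i]
    e <- numeric(3); e[i] <- hi
    (f(p + e) - f(p - e)) / (2 * hi)
  }, numeric(1))
}
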