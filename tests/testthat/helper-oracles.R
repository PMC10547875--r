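# Independent brute-force oracles. Everything here uses dense trapezoid
# quadrature or closed forms, deliberately sharing no code with the package's
# Gauss-Legendre implementation.

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# BLS posterior mean by dense trapezoid quadrature on the prior support.
oracle_bls <- function(t_m, params, n = 1e6 + 1) {
  ts <- seq(params$prior_lo, params$prior_hi, length.out = n)
  vapply(t_m, function(m) {
    lik <- dnorm(m, ts, params$w_m * ts)
    trapz(ts, ts * lik) / trapz(ts, lik)
  }, 0)
}

# BLS posterior mean at one measurement, by brute-force trapezoid on a grid
# uniform in the standardized measurement z = (m - ts)/(wm ts); this places
# nodes where the likelihood lives (crucial when m sits far outside the
# prior support and the likelihood collapses to a boundary layer).
oracle_bls_point <- function(m, params, n) {
  wm <- params$w_m
  z_at <- function(ts) (m - ts) / (wm * ts)
  a <- max(z_at(params$prior_hi), -38)
  b <- min(z_at(params$prior_lo), 38)
  if (a >= b) {   # likelihood range entirely in one far tail
    a <- z_at(params$prior_hi)
    b <- min(z_at(params$prior_lo), a + 2)
  }
  ts <- sort(m / (1 + wm * seq(a, b, length.out = n)))
  L <- dnorm(m, ts, wm * ts, log = TRUE)
  w <- exp(L - max(L))
  trapz(ts, ts * w) / trapz(ts, w)
}

# Marginal response density by nested trapezoid quadrature: outer integral
# over the measurement on the same +/- 6 sd window as the implementation
# (plus the floor-clamp atom), inner BLS integral per measurement node.
oracle_response_raw <- function(t_r, t_s, params, n_m, n_s) {
  lo <- max(1e-4, t_s * (1 - 6 * params$w_m))
  hi <- t_s * (1 + 6 * params$w_m)
  tm <- seq(lo, hi, length.out = n_m)
  te <- vapply(tm, oracle_bls_point, 0, params = params, n = n_s)
  meas <- dnorm(tm, t_s, params$w_m * t_s)
  out <- vapply(t_r, function(r)
    trapz(tm, meas * dnorm(r, te, params$w_r * te)), 0)
  p_clamp <- pnorm(1e-4, t_s, params$w_m * t_s)
  if (p_clamp > 1e-12) {
    te0 <- oracle_bls_point(1e-4, params, n = n_s)
    out <- out + p_clamp * dnorm(t_r, te0, params$w_r * te0)
  }
  out
}

# One Richardson (Romberg) step on the nested trapezoid: halving both grids
# and extrapolating removes the h^2 term, leaving errors ~1e-9 where the
# prior boundary truncates the likelihood mid-mass and plain trapezoid
# converges slowly.
oracle_response_pdf <- function(t_r, t_s, params, n_m = 4001, n_s = 2001) {
  i1 <- oracle_response_raw(t_r, t_s, params, n_m, n_s)
  i2 <- oracle_response_raw(t_r, t_s, params, 2L * n_m - 1L, 2L * n_s - 1L)
  (4 * i2 - i1) / 3
}

# Predicted probability of a "long" choice under the remembered-standard
# rule: only the first (remembered) interval is shrunk toward the prior, the
# comparison measurement is used raw, so
#   P(long) = E_{t_m1 ~ N(ts1, wm ts1)} [ P( t_m2 > f(t_m1) ) ]
# marginalized by trapezoid quadrature over the first measurement.
oracle_p_long <- function(ts1, ts2, params, n_m = 4001, n_s = 1001) {
  lo <- max(1e-4, ts1 * (1 - 6 * params$w_m))
  hi <- ts1 * (1 + 6 * params$w_m)
  tm1 <- seq(lo, hi, length.out = n_m)
  te1 <- vapply(tm1, oracle_bls_point, 0, params = params, n = n_s)
  f1 <- dnorm(tm1, ts1, params$w_m * ts1)
  vapply(ts2, function(x)
    trapz(tm1, f1 * pnorm((x - te1) / (params$w_m * x))), 0)
}

# Fully-within 2x2 repeated-measures ANOVA from explicit sums of squares.
oracle_rm_anova <- function(d) {
  # d: subject_id, effector, task, value
  Y <- tapply(d$value, list(d$subject_id, d$effector, d$task), mean)
  n <- dim(Y)[1]
  grand <- mean(Y)
  m_s <- apply(Y, 1, mean); m_e <- apply(Y, 2, mean); m_t <- apply(Y, 3, mean)
  m_se <- apply(Y, c(1, 2), mean); m_st <- apply(Y, c(1, 3), mean)
  m_et <- apply(Y, c(2, 3), mean)
  ss_e <- 2 * n * sum((m_e - grand)^2)
  ss_t <- 2 * n * sum((m_t - grand)^2)
  ss_et <- n * sum((m_et - outer(m_e, rep(1, 2)) -
                      outer(rep(1, 2), m_t) + grand)^2)
  ss_se <- 2 * sum((m_se - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_e) + grand)^2)
  ss_st <- 2 * sum((m_st - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_t) + grand)^2)
  resid <- Y
  for (i in 1:n) for (j in 1:2) for (k in 1:2)
    resid[i, j, k] <- Y[i, j, k] - m_se[i, j] - m_st[i, k] - m_et[j, k] +
      m_s[i] + m_e[j] + m_t[k] - grand
  ss_set <- sum(resid^2)
  data.frame(
    effect = c("effector", "task", "interaction"),
    F = c((ss_e / 1) / (ss_se / (n - 1)),
          (ss_t / 1) / (ss_st / (n - 1)),
          (ss_et / 1) / (ss_set / (n - 1))),
    partial_eta_sq = c(ss_e / (ss_e + ss_se),
                       ss_t / (ss_t + ss_st),
                       ss_et / (ss_et + ss_set)))
}

# Jeffreys' closed-form approximation to the correlation Bayes factor
# (BF01), used as an order-of-magnitude cross-check of the exact integral.
jeffreys_bf01_approx <- function(r, n)
  sqrt((2 * n - 3) / pi) * (1 - r^2)^((n - 4) / 2)

# Simple deterministic reproduction trial set for fitting tests.
make_fit_trials <- function(params, n_per = 48L, seed = 1L) {
  ts <- rep(design_intervals(), each = n_per)
  data.frame(t_s = ts, t_r = simulate_reproduction(params, ts, seed = seed))
}
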