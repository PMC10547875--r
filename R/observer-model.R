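#' Observer parameters for the three-stage Bayesian timing model
#'
#' Bundles the two Weber-fraction noise parameters of the observer with the
#' support of its uniform prior over sample intervals. The observer measures a
#' sample interval \eqn{t_s} with scalar Gaussian noise (sd \eqn{w_m t_s}),
#' maps the measurement to a Bayes least-squares estimate \eqn{t_e} (posterior
#' mean under a uniform prior on \code{[prior_lo, prior_hi]}), and produces a
#' response with scalar Gaussian motor noise (sd \eqn{w_r t_e}).
#'
#' @param w_m Measurement Weber fraction (> 0): the sd of the internal
#'   measurement grows as \code{w_m * t_s}.
#' @param w_r Motor Weber fraction (> 0): the sd of the produced interval
#'   grows as \code{w_r * t_e}.
#' @param prior_lo,prior_hi Support of the uniform prior, in seconds.
#'   Defaults span the experimental interval range 0.4--1.9 s.
#' @return An object of class \code{observer_params}.
#' @export
observer_params <- function(w_m, w_r, prior_lo = 0.4, prior_hi = 1.9) {
  if (!is.numeric(w_m) || length(w_m) != 1L || !is.finite(w_m) || w_m <= 0)
    stop("'w_m' must be a single positive number", call. = FALSE)
  if (!is.numeric(w_r) || length(w_r) != 1L || !is.finite(w_r) || w_r <= 0)
    stop("'w_r' must be a single positive number", call. = FALSE)
  if (!is.numeric(prior_lo) || !is.numeric(prior_hi) ||
      prior_lo <= 0 || prior_hi <= prior_lo)
    stop("prior support must satisfy 0 < prior_lo < prior_hi", call. = FALSE)
  structure(list(w_m = unname(w_m), w_r = unname(w_r),
                 prior_lo = prior_lo, prior_hi = prior_hi),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "Bayesian observer: w_m = %.4g, w_r = %.4g, prior U(%.3g, %.3g) s\n",
    x$w_m, x$w_r, x$prior_lo, x$prior_hi))
  invisible(x)
}

stopifnot_params <- function(params) {
  if (!inherits(params, "observer_params"))
    stop("'params' must be an observer_params object", call. = FALSE)
  invisible(params)
}

#' Measurement-stage density (likelihood of a noisy measurement)
#'
#' Density of the internal measurement \code{t_m} given the sample interval
#' \code{t_s}: Gaussian with mean \code{t_s} and scalar standard deviation
#' \code{w_m * t_s}.
#'
#' @param t_m Measurement value(s), seconds.
#' @param t_s Sample interval, seconds (> 0).
#' @param w_m Measurement Weber fraction (> 0).
#' @return Density values, same length as \code{t_m}.
#' @export
measurement_pdf <- function(t_m, t_s, w_m) {
  if (!is.numeric(t_s) || any(t_s <= 0)) stop("'t_s' must be positive", call. = FALSE)
  if (!is.numeric(w_m) || any(w_m <= 0)) stop("'w_m' must be positive", call. = FALSE)
  stats::dnorm(t_m, mean = t_s, sd = w_m * t_s)
}

#' Motor-stage density
#'
#' Density of the produced interval \code{t_r} given the internal estimate
#' \code{t_e}: Gaussian with mean \code{t_e} and standard deviation
#' \code{w_r * t_e}. The Gaussian is not truncated at zero.
#'
#' @param t_r Produced interval(s), seconds.
#' @param t_e Internal estimate, seconds (> 0).
#' @param w_r Motor Weber fraction (> 0).
#' @return Density values.
#' @export
motor_pdf <- function(t_r, t_e, w_r) {
  if (!is.numeric(t_e) || any(t_e <= 0)) stop("'t_e' must be positive", call. = FALSE)
  if (!is.numeric(w_r) || any(w_r <= 0)) stop("'w_r' must be positive", call. = FALSE)
  stats::dnorm(t_r, mean = t_e, sd = w_r * t_e)
}

# Gauss-Legendre nodes/weights on [a, b]. Reference nodes on [-1, 1] are
# cached per order (computing them involves an eigendecomposition) and
# affine-mapped to the requested interval.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n, a, b) {
  key <- as.character(n)
  std <- .gl_cache[[key]]
  if (is.null(std)) {
    std <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- std
  }
  list(x = (a + b) / 2 + (b - a) / 2 * std$x,
       w = std$w * (b - a) / 2)
}

#' Bayes least-squares estimate from a noisy measurement
#'
#' Posterior-mean mapping \eqn{f(t_m)} of the estimation stage: the mean of
#' the posterior over \eqn{t_s} under a continuous uniform prior on
#' \code{[prior_lo, prior_hi]},
#' \deqn{f(t_m) = \frac{\int t_s\, p(t_m \mid t_s)\, dt_s}{\int p(t_m \mid t_s)\, dt_s},}
#' with both integrals over the prior support. The estimate always lies
#' strictly inside the support and is nondecreasing in \code{t_m}; values of
#' \code{t_m} outside the support are legal inputs (measurement noise can
#' carry the measurement past the extreme intervals).
#'
#' @param t_m Noisy measurement(s), seconds (> 0).
#' @param params An \code{\link{observer_params}} object.
#' @param n_nodes Gauss--Legendre quadrature order on the prior support.
#' @return Estimates \code{t_e}, same length as \code{t_m}.
#' @export
bls_estimate <- function(t_m, params, n_nodes = 513L) {
  stopifnot_params(params)
  if (!is.numeric(t_m) || any(!is.finite(t_m)) || any(t_m <= 0))
    stop("'t_m' must be positive and finite", call. = FALSE)
  gl <- gauss_legendre(n_nodes, params$prior_lo, params$prior_hi)
  # rows: t_s nodes, cols: t_m values; log densities for stability far
  # outside the support, where the raw likelihood underflows.
  logl <- outer(gl$x, t_m,
                function(ts, m) stats::dnorm(m, ts, params$w_m * ts, log = TRUE))
  mx <- apply(logl, 2, max)
  lik <- exp(sweep(logl, 2, mx))
  num <- colSums(lik * gl$w * gl$x)
  den <- colSums(lik * gl$w)
  num / den
}

#' Marginal response density of the observer
#'
#' Density of the produced interval \code{t_r} given the sample interval
#' \code{t_s}, marginalising over the internal measurement:
#' \deqn{p(t_r \mid t_s) = \int p(t_r \mid f(t_m), w_r)\, p(t_m \mid t_s, w_m)\, dt_m.}
#' The measurement integral runs over \code{t_s} +/- 6 measurement sds,
#' truncated below at a small positive floor, with Gauss--Legendre quadrature;
#' the BLS mapping is evaluated directly at the quadrature nodes. Measurements
#' are clamped at the floor in the generative process, so the clamped
#' Gaussian mass contributes an atom at the floor's BLS estimate; including
#' it keeps the density normalised and exactly consistent with
#' \code{\link{simulate_reproduction}}.
#'
#' @param t_r Produced interval(s), seconds.
#' @param t_s Sample interval, seconds (> 0).
#' @param params An \code{\link{observer_params}} object.
#' @param n_nodes Quadrature order for the measurement integral.
#' @return Density values, same length as \code{t_r}.
#' @export
response_pdf <- function(t_r, t_s, params, n_nodes = 257L) {
  stopifnot_params(params)
  if (!is.numeric(t_s) || length(t_s) != 1L || t_s <= 0)
    stop("'t_s' must be a single positive number", call. = FALSE)
  lo <- max(1e-4, t_s * (1 - 6 * params$w_m))
  hi <- t_s * (1 + 6 * params$w_m)
  gl <- gauss_legendre(n_nodes, lo, hi)
  t_e <- bls_estimate(gl$x, params)
  w_meas <- gl$w * stats::dnorm(gl$x, t_s, params$w_m * t_s)
  # mot[i, j] = p(t_r[j] | t_e at node i)
  mot <- outer(t_e, t_r,
               function(e, r) stats::dnorm(r, e, params$w_r * e))
  dens <- as.numeric(crossprod(mot, w_meas))
  # measurements are clamped at the floor in the generative process; the
  # clamped mass is an atom at the floor's BLS estimate
  p_clamp <- stats::pnorm(1e-4, t_s, params$w_m * t_s)
  if (p_clamp > 0) {
    te0 <- bls_estimate(1e-4, params)
    dens <- dens + p_clamp * stats::dnorm(t_r, te0, params$w_r * te0)
  }
  dens
}

#' Predicted mean and standard deviation of the response
#'
#' Moments of \code{t_r} given \code{t_s} under the observer, computed by
#' quadrature over the measurement stage using the laws of total expectation
#' and variance: given \code{t_m}, \code{t_r} is Gaussian with mean
#' \code{f(t_m)} and sd \code{w_r f(t_m)}.
#'
#' @inheritParams response_pdf
#' @return A data frame with columns \code{t_s}, \code{mean_tr}, \code{sd_tr}
#'   (one row per element of \code{t_s}; here \code{t_s} may be a vector).
#' @export
predicted_moments <- function(t_s, params, n_nodes = 257L) {
  stopifnot_params(params)
  if (!is.numeric(t_s) || any(t_s <= 0)) stop("'t_s' must be positive", call. = FALSE)
  one <- function(ts) {
    lo <- max(1e-4, ts * (1 - 6 * params$w_m))
    hi <- ts * (1 + 6 * params$w_m)
    gl <- gauss_legendre(n_nodes, lo, hi)
    t_e <- bls_estimate(gl$x, params)
    w <- gl$w * stats::dnorm(gl$x, ts, params$w_m * ts)
    p_clamp <- stats::pnorm(1e-4, ts, params$w_m * ts)
    if (p_clamp > 0) {                    # atom of floor-clamped measurements
      w <- c(w, p_clamp)
      t_e <- c(t_e, bls_estimate(1e-4, params))
    }
    w <- w / sum(w)                       # renormalise truncation remainder
    m1 <- sum(w * t_e)
    m2 <- sum(w * t_e^2 * (1 + params$w_r^2))
    c(mean_tr = m1, sd_tr = sqrt(max(m2 - m1^2, 0)))
  }
  mom <- t(vapply(t_s, one, c(mean_tr = 0, sd_tr = 0)))
  data.frame(t_s = t_s, mean_tr = mom[, "mean_tr"], sd_tr = mom[, "sd_tr"])
}

#' Simulate reproduction responses from the observer
#'
#' For each sample interval, draws a measurement
#' \code{t_m ~ N(t_s, w_m t_s)}, maps it through the BLS estimator, and draws
#' the response \code{t_r ~ N(t_e, w_r t_e)}. Deterministic given \code{seed}.
#'
#' @param params An \code{\link{observer_params}} object.
#' @param t_s_list Vector of sample intervals, seconds.
#' @param seed Integer seed; the function restores the caller's RNG state.
#' @return Numeric vector of responses \code{t_r}, one per sample interval.
#' @export
simulate_reproduction <- function(params, t_s_list, seed) {
  stopifnot_params(params)
  if (length(t_s_list) == 0L) stop("'t_s_list' must be nonempty", call. = FALSE)
  if (any(t_s_list <= 0)) stop("sample intervals must be positive", call. = FALSE)
  with_seed(seed, {
    t_m <- stats::rnorm(length(t_s_list), t_s_list, params$w_m * t_s_list)
    t_m <- pmax(t_m, 1e-4)             # measurement durations cannot be <= 0
    t_e <- bls_estimate(t_m, params)
    stats::rnorm(length(t_e), t_e, params$w_r * t_e)
  })
}

# Run an expression under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit child seed from a base seed, kept inside 32-bit range.
child_seed <- function(seed, index, stride = 1000L) {
  as.integer((as.numeric(seed) * stride + index) %% .Machine$integer.max)
}
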