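#' Negative log-likelihood of reproduction data under the observer model
#'
#' Sums \code{-log p(t_r | t_s, w_m, w_r)} over trials, where the marginal
#' response density is that of \code{\link{response_pdf}}. Trials are grouped
#' by distinct sample interval; the BLS mapping is evaluated exactly at every
#' measurement-quadrature node. The default engine runs the dense loops in
#' compiled code; \code{engine = "R"} uses \code{\link{response_pdf}}
#' directly and is the reference path the compiled one is tested against.
#'
#' Log-densities below \code{log_floor} (default -745, near the smallest
#' representable double) are clamped so a single outlier trial cannot make
#' the objective infinite; the number of clamped trials is returned as an
#' attribute \code{"n_clamped"}.
#'
#' @param trials Data frame with columns \code{t_s} and \code{t_r} (seconds).
#' @param params An \code{\link{observer_params}} object.
#' @param n_nodes Measurement-quadrature order per interval.
#' @param log_floor Clamp value for underflowing log-densities.
#' @param engine \code{"cpp"} (default) or \code{"R"}.
#' @return The negative log-likelihood in nats (a single number), with
#'   attribute \code{n_clamped}.
#' @export
negative_log_likelihood <- function(trials, params, n_nodes = 257L,
                                    log_floor = -745, engine = c("cpp", "R")) {
  stopifnot_params(params)
  engine <- match.arg(engine)
  if (!is.data.frame(trials) || nrow(trials) == 0L ||
      !all(c("t_s", "t_r") %in% names(trials)))
    stop("'trials' must be a nonempty data frame with columns t_s, t_r",
         call. = FALSE)
  ts_vals <- sort(unique(trials$t_s))
  if (engine == "cpp") {
    glp <- gauss_legendre(513L, params$prior_lo, params$prior_hi)
    glm <- gauss_legendre(n_nodes, -1, 1)
    res <- nll_observer_cpp(
      lapply(ts_vals, function(ts) trials$t_r[trials$t_s == ts]),
      ts_vals, params$w_m, params$w_r,
      glp$x, glp$w, glm$x, glm$w,
      params$prior_lo, params$prior_hi, 1e-4, log_floor)
    return(structure(res$nll, n_clamped = res$n_clamped))
  }
  total <- 0
  n_clamped <- 0L
  for (ts in ts_vals) {
    tr <- trials$t_r[trials$t_s == ts]
    dens <- response_pdf(tr, ts, params, n_nodes = n_nodes)
    ld <- log(pmax(dens, 0))
    clamped <- !is.finite(ld) | ld < log_floor
    ld[clamped] <- log_floor
    n_clamped <- n_clamped + sum(clamped)
    total <- total - sum(ld)
  }
  structure(total, n_clamped = n_clamped)
}

default_start_grid <- function() {
  as.matrix(expand.grid(w_m = c(0.05, 0.1, 0.2, 0.3),
                        w_r = c(0.05, 0.1, 0.2, 0.3)))
}

#' Maximum-likelihood fit of the observer's noise parameters
#'
#' Minimises \code{\link{negative_log_likelihood}} over \code{(w_m, w_r)}
#' with Nelder--Mead simplex search restarted from a grid of initial values.
#' The search runs in log-parameter space, so positivity of both Weber
#' fractions is structural rather than enforced by penalties. Parameters are
#' additionally clamped to \code{[1e-5, 10]} inside the objective: for
#' degenerate data (e.g. noise-free responses) the likelihood is unbounded as
#' a Weber fraction tends to zero, and the fit then returns the floor with
#' \code{converged} reporting the optimizer's status. The best restart is
#' returned even when no restart formally converged; an error is raised only
#' if the objective is non-finite at every start.
#'
#' @param trials Data frame with columns \code{t_s}, \code{t_r}; at least 20
#'   trials spanning at least two distinct sample intervals.
#' @param init_grid Matrix or data frame of starting values with columns
#'   \code{w_m}, \code{w_r}. Defaults to the 4 x 4 grid
#'   \{0.05, 0.1, 0.2, 0.3\}^2, bracketing plausible human Weber fractions.
#' @param prior_lo,prior_hi Prior support passed to the observer.
#' @param reltol Convergence tolerance of the simplex (on parameters and
#'   objective).
#' @param agree_tol Restarts whose final objective is within this of the best
#'   are counted as agreeing.
#' @return A list of class \code{observer_fit}: \code{params} (the fitted
#'   \code{\link{observer_params}}), \code{nll}, \code{n_trials},
#'   \code{converged}, \code{n_restarts_agreeing}, \code{n_clamped} and the
#'   per-restart table \code{restarts}.
#' @export
fit_observer <- function(trials, init_grid = default_start_grid(),
                         prior_lo = 0.4, prior_hi = 1.9,
                         reltol = 1e-6, agree_tol = 1e-3) {
  if (!is.data.frame(trials) || nrow(trials) < 20L)
    stop("need at least 20 trials", call. = FALSE)
  if (length(unique(trials$t_s)) < 2L)
    stop("trials must span at least two distinct sample intervals",
         call. = FALSE)
  init_grid <- as.matrix(init_grid)
  clamp_w <- function(theta) pmin(pmax(exp(theta), 1e-5), 10)
  obj <- function(theta) {
    w <- clamp_w(theta)
    p <- observer_params(w[1], w[2], prior_lo, prior_hi)
    as.numeric(negative_log_likelihood(trials, p))
  }
  res <- vector("list", nrow(init_grid))
  for (i in seq_len(nrow(init_grid))) {
    start <- log(init_grid[i, c("w_m", "w_r")])
    o <- tryCatch(
      stats::optim(start, obj, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 500L)),
      error = function(e) NULL)
    res[[i]] <- o
  }
  ok <- vapply(res, function(o) !is.null(o) && is.finite(o$value), logical(1))
  if (!any(ok))
    stop("observer fit failed: objective non-finite at every start (",
         nrow(init_grid), " starts attempted)", call. = FALSE)
  nlls <- vapply(res[ok], function(o) o$value, 0)
  best <- res[ok][[which.min(nlls)]]
  w_best <- clamp_w(best$par)
  params <- observer_params(w_best[1], w_best[2], prior_lo, prior_hi)
  nll_best <- negative_log_likelihood(trials, params)
  restarts <- data.frame(
    w_m_start = init_grid[ok, "w_m"], w_r_start = init_grid[ok, "w_r"],
    nll = nlls,
    converged = vapply(res[ok], function(o) o$convergence == 0L, TRUE))
  structure(list(
    params = params,
    nll = as.numeric(nll_best),
    n_trials = nrow(trials),
    converged = best$convergence == 0L,
    n_restarts_agreeing = sum(nlls <= min(nlls) + agree_tol),
    n_clamped = attr(nll_best, "n_clamped"),
    restarts = restarts), class = "observer_fit")
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf(
    "Observer ML fit: w_m = %.4f, w_r = %.4f (NLL %.3f over %d trials; %d/%d restarts agree)\n",
    x$params$w_m, x$params$w_r, x$nll, x$n_trials,
    x$n_restarts_agreeing, nrow(x$restarts)))
  invisible(x)
}

#' Pseudo-responses from psychometric fits (discrimination-route fitting)
#'
#' The discrimination task yields, per standard interval, a cumulative-Gaussian
#' psychometric function with mean \code{mu} (the PSE) and spread
#' \code{sigma}. To fit the observer model to discrimination data, each
#' psychometric function is transformed into a Gaussian response distribution
#' with the same parameters and pseudo-responses are drawn from it, paired
#' with their standard interval; the resulting pairs feed
#' \code{\link{fit_observer}} unchanged.
#'
#' @param psych_fits Data frame with columns \code{t_s1}, \code{mu},
#'   \code{sigma} and (optionally) \code{excluded}; one non-excluded row per
#'   standard-interval condition.
#' @param n_per_condition Draws per condition (default 48, the per-condition
#'   trial count of the discrimination design).
#' @param seed Integer seed.
#' @return Data frame with columns \code{t_s} (the standard interval) and
#'   \code{t_r} (the pseudo-response).
#' @export
fit_psychometric_contexts <- function(psych_fits, n_per_condition = 48L, seed) {
  if (!is.data.frame(psych_fits) ||
      !all(c("t_s1", "mu", "sigma") %in% names(psych_fits)))
    stop("'psych_fits' needs columns t_s1, mu, sigma", call. = FALSE)
  if ("excluded" %in% names(psych_fits) && any(psych_fits$excluded))
    stop("excluded psychometric conditions must be removed before sampling",
         call. = FALSE)
  if (anyDuplicated(psych_fits$t_s1))
    stop("one psychometric fit per condition expected", call. = FALSE)
  if (any(!is.finite(psych_fits$mu)) || any(!is.finite(psych_fits$sigma)) ||
      any(psych_fits$sigma <= 0))
    stop("psychometric parameters must be finite with sigma > 0", call. = FALSE)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(psych_fits)), function(i) {
      data.frame(
        t_s = psych_fits$t_s1[i],
        t_r = stats::rnorm(n_per_condition, psych_fits$mu[i],
                           psych_fits$sigma[i]))
    })
    do.call(rbind, out)
  })
}
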