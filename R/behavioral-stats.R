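#' Interquartile-range outlier mask
#'
#' Flags values outside the Tukey fences
#' \code{[Q1 - mult*IQR, Q3 + mult*IQR]}, with quartiles computed by the
#' linear-interpolation convention (\code{stats::quantile} type 7). When the
#' IQR is zero nothing is flagged.
#'
#' @param values Numeric vector (at least 4 values).
#' @param mult Fence multiplier (default 1.5).
#' @return Logical mask, \code{TRUE} for outliers.
#' @export
iqr_filter <- function(values, mult = 1.5) {
  if (!is.numeric(values) || length(values) < 4L)
    stop("need at least 4 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(rep(FALSE, length(values)))
  values < q[1] - mult * iqr | values > q[2] + mult * iqr
}

#' Central-tendency (compression-bias) regression
#'
#' Ordinary least squares of the per-interval mean response on the sample
#' interval. The compression bias is \code{C = 1 - slope}; the indifference
#' point \code{IP = intercept / (1 - slope)} is the interval at which the
#' regression line crosses the unity diagonal (no bias). With a slope within
#' 1e-9 of 1 the IP is undefined and flagged rather than raising an error.
#'
#' @param condition_means Data frame with columns \code{t_s} and
#'   \code{mean_tr}: per-interval mean responses (reproduction) or PSEs
#'   (discrimination). Normally all 5 design intervals; at least 3 distinct
#'   intervals are required (condition exclusions can remove up to two).
#' @return A list with \code{slope}, \code{intercept}, \code{C}, \code{IP},
#'   \code{ip_defined}, \code{n_points}.
#' @export
central_tendency_fit <- function(condition_means) {
  if (!is.data.frame(condition_means) ||
      !all(c("t_s", "mean_tr") %in% names(condition_means)))
    stop("'condition_means' needs columns t_s, mean_tr", call. = FALSE)
  x <- condition_means$t_s
  y <- condition_means$mean_tr
  if (length(unique(x)) < 3L || any(!is.finite(y)))
    stop("need finite means at >= 3 distinct intervals", call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  ip_defined <- abs(1 - slope) > 1e-9
  list(slope = slope, intercept = intercept,
       C = 1 - slope,
       IP = if (ip_defined) intercept / (1 - slope) else NA_real_,
       ip_defined = ip_defined, n_points = length(x))
}

#' Weber's-law regression of timing variance on squared interval
#'
#' OLS of response variance on the squared sample interval. The slope is the
#' time-dependent (Weber) component \code{web_s}; the intercept is the
#' time-independent component \code{web_i} (seconds squared).
#'
#' @param condition_stats Data frame with columns \code{t_s} and
#'   \code{var_tr} (per-interval response variance, or squared psychometric
#'   spread for discrimination).
#' @return A list with \code{web_s}, \code{web_i}, \code{negative_slope}
#'   (flag: a negative slope is possible under sampling noise).
#' @export
weber_fit <- function(condition_stats) {
  if (!is.data.frame(condition_stats) ||
      !all(c("t_s", "var_tr") %in% names(condition_stats)))
    stop("'condition_stats' needs columns t_s, var_tr", call. = FALSE)
  x <- condition_stats$t_s^2
  y <- condition_stats$var_tr
  if (length(unique(x)) < 3L || any(!is.finite(y)))
    stop("need finite variances at >= 3 distinct intervals", call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  list(web_s = slope, web_i = intercept, negative_slope = slope < 0)
}

#' Cumulative-Gaussian psychometric fit
#'
#' Least-squares fit of \eqn{\Phi((t_{s2} - \mu)/\sigma)} to the proportion
#' of "long" choices across comparison intervals for one standard interval.
#' The fit is unweighted, with no lapse or guess parameters. Goodness of fit
#' \code{R} is the Pearson correlation between observed and fitted
#' proportions; conditions with \code{R <= 0.50} are flagged excluded, as are
#' degenerate fits (flat data, non-finite or runaway spread).
#'
#' Starting values come from a probit-linearised regression, refined by
#' Nelder--Mead with multistart.
#'
#' @param condition_props Data frame with columns \code{t_s2} and
#'   \code{p_long} (proportions in \code{[0, 1]}); normally the 8 comparison
#'   intervals of one standard.
#' @param t_s1 The standard interval (seconds), carried into the result.
#' @param r_threshold Exclusion threshold on \code{R} (default 0.50).
#' @return A list with \code{t_s1}, \code{mu}, \code{sigma}, \code{R},
#'   \code{excluded}.
#' @export
psychometric_fit <- function(condition_props, t_s1, r_threshold = 0.50) {
  if (!is.data.frame(condition_props) ||
      !all(c("t_s2", "p_long") %in% names(condition_props)))
    stop("'condition_props' needs columns t_s2, p_long", call. = FALSE)
  x <- condition_props$t_s2
  p <- condition_props$p_long
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]", call. = FALSE)
  sigma_cap <- 10 * (max(x) - min(x))

  bad <- function() list(t_s1 = t_s1, mu = NA_real_, sigma = NA_real_,
                         R = NA_real_, excluded = TRUE)
  if (stats::var(p) == 0) return(bad())

  sse <- function(theta) {
    mu <- theta[1]; sig <- exp(theta[2])
    sum((p - stats::pnorm((x - mu) / sig))^2)
  }
  # probit-linearised start
  z <- stats::qnorm(pmin(pmax(p, 0.01), 0.99))
  b <- stats::cov(x, z) / stats::var(x)
  starts <- list()
  if (is.finite(b) && b > 0)
    starts[[1]] <- c(mean(x) - mean(z) / b, log(1 / b))
  sig0 <- (max(x) - min(x)) / 4
  for (m in stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
    starts[[length(starts) + 1]] <- c(m, log(sig0))
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, sse, method = "Nelder-Mead",
                          control = list(reltol = 1e-10, maxit = 2000L)),
             error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) stop("psychometric fit failed to converge",
                               call. = FALSE)
  best <- fits[[which.min(vapply(fits, function(f) f$value, 0))]]
  mu <- best$par[1]; sigma <- exp(best$par[2])
  fitted <- stats::pnorm((x - mu) / sigma)
  R <- if (stats::sd(fitted) == 0) 0 else stats::cor(p, fitted)
  degenerate <- !is.finite(sigma) || sigma > sigma_cap || !is.finite(R)
  list(t_s1 = t_s1, mu = mu, sigma = sigma,
       R = if (degenerate) NA_real_ else R,
       excluded = degenerate || !is.finite(R) || R <= r_threshold)
}

#' Proportion of "long" choices per comparison interval
#'
#' Aggregates discrimination trials of one standard interval into the
#' psychometric points consumed by \code{\link{psychometric_fit}}.
#'
#' @param trials Data frame with columns \code{t_s2} and \code{choice}
#'   (\code{"long"} / \code{"short"}).
#' @return Data frame with columns \code{t_s2}, \code{p_long}, \code{n}.
#' @export
choice_proportions <- function(trials) {
  ag <- stats::aggregate(list(p_long = trials$choice == "long"),
                         by = list(t_s2 = trials$t_s2), FUN = mean)
  n <- stats::aggregate(list(n = trials$choice),
                        by = list(t_s2 = trials$t_s2), FUN = length)
  merge(ag, n, by = "t_s2")
}

#' Bootstrap confidence interval for the group indifference point
#'
#' Resamples subjects with replacement, recomputes the group indifference
#' point for each resample (central-tendency regression on the across-subject
#' mean of the per-interval means), and returns percentile bounds.
#' Resamples with an undefined IP (group slope equal to 1) are redrawn and
#' counted.
#'
#' @param subject_condition_means Data frame with columns \code{subject_id},
#'   \code{t_s}, \code{mean_tr}; at least 5 subjects, complete intervals.
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return A list with \code{ip_ci_lo}, \code{ip_ci_hi}, \code{ip_hat} (the
#'   full-sample group IP), \code{n_redrawn}.
#' @export
bootstrap_ip_ci <- function(subject_condition_means, B = 2000L, seed,
                            level = 0.95) {
  d <- subject_condition_means
  if (!all(c("subject_id", "t_s", "mean_tr") %in% names(d)))
    stop("need columns subject_id, t_s, mean_tr", call. = FALSE)
  subjects <- unique(d$subject_id)
  n <- length(subjects)
  if (n < 5L) stop("need at least 5 subjects", call. = FALSE)
  ts_vals <- sort(unique(d$t_s))
  # matrix n_subjects x n_intervals of per-subject condition means
  M <- matrix(NA_real_, n, length(ts_vals),
              dimnames = list(subjects, ts_vals))
  for (i in seq_len(nrow(d)))
    M[as.character(d$subject_id[i]), as.character(d$t_s[i])] <- d$mean_tr[i]
  if (anyNA(M)) stop("every subject needs a mean for every interval",
                     call. = FALSE)
  x <- ts_vals
  sxx <- sum((x - mean(x))^2)
  ip_of <- function(ybar) {
    slope <- sum((x - mean(x)) * (ybar - mean(ybar))) / sxx
    if (abs(1 - slope) <= 1e-9) return(NA_real_)
    (mean(ybar) - slope * mean(x)) / (1 - slope)
  }
  ip_hat <- ip_of(colMeans(M))
  n_redrawn <- 0L
  ips <- with_seed(seed, {
    out <- numeric(B)
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        ip <- ip_of(colMeans(M[idx, , drop = FALSE]))
        if (is.finite(ip)) break
        n_redrawn <<- n_redrawn + 1L
      }
      out[b] <- ip
    }
    out
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(ips, c(alpha, 1 - alpha), type = 7, names = FALSE)
  list(ip_ci_lo = ci[1], ip_ci_hi = ci[2], ip_hat = ip_hat,
       n_redrawn = n_redrawn)
}

#' Subject and condition exclusion cascade
#'
#' Applies the exclusion rules, in order: (1) psychometric conditions with
#' goodness of fit \code{R <= 0.50} are excluded; (2) subjects with more than
#' two excluded conditions are removed entirely; (3) subjects whose
#' indifference point falls outside the presented range (below
#' \code{ip_range[1]} or above \code{ip_range[2]} seconds) in either task and
#' either effector are removed. The cascade is idempotent.
#'
#' @param psych_fits Data frame of psychometric fits with columns
#'   \code{subject_id}, \code{effector}, \code{t_s1}, \code{mu},
#'   \code{sigma}, \code{R}, \code{excluded}.
#' @param ip_table Data frame with columns \code{subject_id}, \code{task},
#'   \code{effector}, \code{IP} (one row per subject x task x effector).
#' @param r_threshold Goodness-of-fit threshold (default 0.50).
#' @param max_bad_conditions Conditions beyond which a subject is removed
#'   (default 2).
#' @param ip_range Allowed indifference-point range in seconds
#'   (default \code{c(0.4, 1.9)}).
#' @return A list: \code{psych_fits} (with the exclusion flag finalised),
#'   \code{excluded_subjects} (character vector), and \code{report}, a data
#'   frame of counts per rule (\code{conditions_excluded},
#'   \code{subjects_by_conditions}, \code{subjects_by_ip}, \code{subjects_total}).
#' @export
apply_exclusions <- function(psych_fits, ip_table, r_threshold = 0.50,
                             max_bad_conditions = 2L, ip_range = c(0.4, 1.9)) {
  pf <- psych_fits
  pf$excluded <- !is.finite(pf$R) | pf$R <= r_threshold
  bad_by_subj <- tapply(pf$excluded, pf$subject_id, sum)
  subj_cond <- names(bad_by_subj)[bad_by_subj > max_bad_conditions]
  ip_bad <- !is.finite(ip_table$IP) |
    ip_table$IP < ip_range[1] | ip_table$IP > ip_range[2]
  subj_ip <- unique(as.character(ip_table$subject_id[ip_bad]))
  excluded_subjects <- union(subj_cond, subj_ip)
  report <- data.frame(
    conditions_excluded = sum(pf$excluded),
    subjects_by_conditions = length(subj_cond),
    subjects_by_ip = length(subj_ip),
    subjects_total = length(excluded_subjects))
  list(psych_fits = pf, excluded_subjects = excluded_subjects,
       report = report)
}

#' Per-context summary of one subject's timing behaviour
#'
#' Assembles the derived scalars for one subject in one task x effector
#' context: per-interval response mean and sd, compression bias \code{C},
#' indifference point \code{IP}, Weber components \code{web_s} and
#' \code{web_i}, and the fitted observer parameters.
#'
#' For reproduction the per-interval statistics are the mean and sd of
#' \code{t_r}; for discrimination they are the PSE and psychometric spread
#' per standard interval.
#'
#' @param condition_stats Data frame with columns \code{t_s}, \code{mean_tr},
#'   \code{sd_tr} (one row per surviving interval).
#' @param fit An \code{observer_fit} (or \code{NULL} to omit parameters).
#' @param subject_id,task,effector Identifiers carried into the row.
#' @return A one-row data frame (the per-interval statistics are attached as
#'   the attribute \code{"per_interval"}).
#' @export
summarize_context <- function(condition_stats, fit = NULL,
                              subject_id = NA, task = NA, effector = NA) {
  if (!all(c("t_s", "mean_tr", "sd_tr") %in% names(condition_stats)))
    stop("'condition_stats' needs columns t_s, mean_tr, sd_tr", call. = FALSE)
  ct <- central_tendency_fit(condition_stats[, c("t_s", "mean_tr")])
  wb <- weber_fit(data.frame(t_s = condition_stats$t_s,
                             var_tr = condition_stats$sd_tr^2))
  out <- data.frame(
    subject_id = subject_id, task = task, effector = effector,
    C = ct$C, IP = ct$IP, web_s = wb$web_s, web_i = wb$web_i,
    mean_sd = mean(condition_stats$sd_tr),
    w_m = if (is.null(fit)) NA_real_ else fit$params$w_m,
    w_r = if (is.null(fit)) NA_real_ else fit$params$w_r)
  attr(out, "per_interval") <- condition_stats
  out
}
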