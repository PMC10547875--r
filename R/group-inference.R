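#' Two-way repeated-measures ANOVA on a 2 x 2 within-subject design
#'
#' Decomposes one measure per subject in the four task x effector cells into
#' main effects and interaction, testing each effect against its own
#' subject-by-effect error stratum (the standard fully-within decomposition).
#' Effect size is partial eta squared,
#' \code{SS_effect / (SS_effect + SS_error_effect)}. With two levels per
#' factor, sphericity is moot and no correction is applied.
#'
#' @param cell_table Data frame with columns \code{subject_id},
#'   \code{effector} (\code{"hand"}/\code{"eye"}), \code{task}
#'   (\code{"reproduction"}/\code{"discrimination"}) and \code{value}; every
#'   subject must have all four cells.
#' @return Data frame with one row per effect (\code{effector}, \code{task},
#'   \code{interaction}): \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{partial_eta_sq}.
#' @export
rm_anova_2x2 <- function(cell_table) {
  d <- check_cell_table(cell_table)
  d$subject_id <- factor(d$subject_id)
  d$effector <- factor(d$effector, levels = c("hand", "eye"))
  d$task <- factor(d$task, levels = c("reproduction", "discrimination"))
  fit <- stats::aov(value ~ effector * task +
                      Error(subject_id / (effector * task)), data = d)
  s <- summary(fit)
  ss_scale <- sum((d$value - mean(d$value))^2)
  pull <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    er <- match("Residuals", trimws(rownames(tab)))
    out <- data.frame(
      F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = tab[er, "Df"],
      p = tab[i, "Pr(>F)"],
      partial_eta_sq = tab[i, "Sum Sq"] /
        (tab[i, "Sum Sq"] + tab[er, "Sum Sq"]))
    # no between-cell variation for this effect (up to float noise relative
    # to the table's overall variation): report a null result rather than
    # the 0/0 the ratio would otherwise produce
    if (tab[i, "Sum Sq"] <= 1e-10 * max(ss_scale, .Machine$double.xmin)) {
      out$F <- 0; out$p <- 1; out$partial_eta_sq <- 0
    }
    out
  }
  out <- rbind(
    cbind(effect = "effector",
          pull("Error: subject_id:effector", "effector")),
    cbind(effect = "task", pull("Error: subject_id:task", "task")),
    cbind(effect = "interaction",
          pull("Error: subject_id:effector:task", "effector:task")))
  rownames(out) <- NULL
  out
}

check_cell_table <- function(cell_table) {
  need <- c("subject_id", "effector", "task", "value")
  if (!is.data.frame(cell_table) || !all(need %in% names(cell_table)))
    stop("'cell_table' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  counts <- table(cell_table$subject_id)
  if (any(counts != 4L) || anyNA(cell_table$value))
    stop("incomplete design: every subject needs all 4 cells", call. = FALSE)
  cell_table
}

#' Tukey HSD comparisons of the four within-subject cells
#'
#' All six pairwise comparisons between the task x effector cell means, with
#' studentized-range adjustment. The error term is the pooled within-subject
#' residual (total within-subject variation minus the cell effect), with
#' \code{(n - 1) * 3} degrees of freedom.
#'
#' @inheritParams rm_anova_2x2
#' @return Data frame with columns \code{cell_a}, \code{cell_b},
#'   \code{diff}, \code{p_adj}.
#' @export
tukey_hsd <- function(cell_table) {
  d <- check_cell_table(cell_table)
  d$cell <- paste(d$task, d$effector, sep = "_")
  cells <- sort(unique(d$cell))
  n <- length(unique(d$subject_id))
  means <- tapply(d$value, d$cell, mean)
  subj_means <- tapply(d$value, d$subject_id, mean)
  grand <- mean(d$value)
  ss_total <- sum((d$value - grand)^2)
  ss_cells <- n * sum((means - grand)^2)
  ss_subj <- 4 * sum((subj_means - grand)^2)
  df_err <- (n - 1L) * 3L
  ms_err <- (ss_total - ss_cells - ss_subj) / df_err
  se <- sqrt(ms_err / n)
  pairs <- utils::combn(cells, 2)
  out <- data.frame(cell_a = pairs[1, ], cell_b = pairs[2, ])
  out$diff <- as.numeric(means[out$cell_a] - means[out$cell_b])
  q <- abs(out$diff) / se
  out$p_adj <- if (ms_err <= 0) rep(1, nrow(out)) else
    stats::ptukey(q, nmeans = 4, df = df_err, lower.tail = FALSE)
  rownames(out) <- NULL
  out
}

#' JZS Bayes factor for a Pearson correlation
#'
#' Default two-sided Jeffreys--Zellner--Siow Bayes factor for the presence of
#' a correlation, using the exact expression with a stretched-beta prior on
#' the correlation (shape \code{kappa = 1}, i.e. uniform on (-1, 1)):
#' \deqn{BF_{10} = \frac{\sqrt{\pi}}{2}\,
#'   \frac{\Gamma((n+1)/2)}{\Gamma((n+2)/2)}\,
#'   {}_2F_1\!\left(\tfrac{n-1}{2}, \tfrac{n-1}{2}; \tfrac{n+2}{2}; r^2\right).}
#' The Gauss hypergeometric term is evaluated by numerical integration of its
#' Euler representation.
#'
#' @param r Observed Pearson correlation.
#' @param n Number of paired observations (>= 4).
#' @param kappa Stretched-beta prior shape (default 1, the default two-sided
#'   analysis).
#' @return The Bayes factor \code{BF10} (a single positive number).
#' @export
jzs_correlation_bf <- function(r, n, kappa = 1) {
  if (!is.finite(r) || abs(r) > 1) stop("need |r| <= 1", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  # at (or numerically at) |r| = 1 the evidence integral diverges
  if (abs(r) >= 1 - 1e-12) return(Inf)
  a <- (n - 1) / 2
  b <- (n - 1) / 2
  cc <- (n + 2 / kappa) / 2
  x <- r^2
  # 2F1(a, b; c; x) = int_0^1 t^(b-1) (1-t)^(c-b-1) (1-xt)^(-a) dt / B(b, c-b)
  h <- stats::integrate(function(t)
    exp((b - 1) * log(t) + (cc - b - 1) * log1p(-t) - a * log1p(-x * t)),
    0, 1, rel.tol = 1e-12)$value / beta(b, cc - b)
  exp((1 - 2 / kappa) * log(2) + 0.5 * log(pi) - lbeta(1 / kappa, 1 / kappa) +
        lgamma((n + 2 / kappa - 1) / 2) - lgamma((n + 2 / kappa) / 2)) * h
}

#' Pearson correlation with two-sided p-value and JZS Bayes factor
#'
#' @param x,y Paired numeric vectors (n >= 4, finite, non-constant).
#' @return A list with \code{r}, \code{p_unc}, \code{bf10}, \code{n}.
#' @export
pearson_with_bf <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_unc = ct$p.value,
       bf10 = jzs_correlation_bf(unname(ct$estimate), length(x)),
       n = length(x))
}

#' Bonferroni-corrected p-value
#'
#' @param p_unc Uncorrected p-value in \code{[0, 1]}.
#' @param m Family size (>= 1).
#' @return \code{min(1, m * p_unc)}.
#' @export
bonferroni <- function(p_unc, m) {
  if (any(p_unc < 0 | p_unc > 1)) stop("p-values must lie in [0, 1]",
                                       call. = FALSE)
  if (any(m < 1)) stop("family size must be >= 1", call. = FALSE)
  pmin(1, m * p_unc)
}

# The model x data context pairings reported per measure: the four pairings
# within each task (Bonferroni family of 4) plus the two cross-task
# same-effector pairings per effector (family of 2).
correlation_pairings <- function() {
  rbind(
    data.frame(data_context = c("R_H", "R_H", "R_E", "R_E"),
               model_context = c("R_H", "R_E", "R_H", "R_E"),
               family = "within_reproduction", m = 4),
    data.frame(data_context = c("D_H", "D_H", "D_E", "D_E"),
               model_context = c("D_H", "D_E", "D_H", "D_E"),
               family = "within_discrimination", m = 4),
    data.frame(data_context = c("R_H", "D_H"),
               model_context = c("D_H", "R_H"),
               family = "cross_task_hand", m = 2),
    data.frame(data_context = c("R_E", "D_E"),
               model_context = c("D_E", "R_E"),
               family = "cross_task_eye", m = 2))
}

#' Correlations between subject-derived and model-predicted summaries
#'
#' For each measure (compression bias \code{C} and mean per-interval response
#' sd) computes the Pearson correlation, across subjects, between the
#' data-derived value in one context and the model-predicted value in another
#' context, for the twelve context pairings reported per measure: all four
#' model x data pairings within each task plus the two cross-task pairings
#' for each effector. Bonferroni correction is applied within each family
#' (size 4 within task, size 2 cross-task).
#'
#' @param summaries Data frame of data-derived per-subject context summaries
#'   with columns \code{subject_id}, \code{task}, \code{effector}, \code{C},
#'   \code{mean_sd}.
#' @param model_predictions Same structure, derived from model simulations.
#' @return Data frame with 24 rows and columns \code{measure},
#'   \code{data_context}, \code{model_context}, \code{r}, \code{p_unc},
#'   \code{p_corr}, \code{m}, \code{bf10}, \code{n}.
#' @export
build_correlation_matrix <- function(summaries, model_predictions) {
  ctx <- function(task, effector)
    paste0(ifelse(task == "reproduction", "R", "D"),
           "_", ifelse(effector == "hand", "H", "E"))
  summaries$context <- ctx(summaries$task, summaries$effector)
  model_predictions$context <- ctx(model_predictions$task,
                                   model_predictions$effector)
  pairings <- correlation_pairings()
  rows <- list()
  for (measure in c("bias", "sd")) {
    col <- if (measure == "bias") "C" else "mean_sd"
    for (i in seq_len(nrow(pairings))) {
      dsub <- summaries[summaries$context == pairings$data_context[i], ]
      msub <- model_predictions[
        model_predictions$context == pairings$model_context[i], ]
      merged <- merge(dsub[, c("subject_id", col)],
                      msub[, c("subject_id", col)],
                      by = "subject_id", suffixes = c("_data", "_model"))
      if (nrow(merged) < length(unique(dsub$subject_id)))
        stop("subject mismatch between data and model tables", call. = FALSE)
      pr <- pearson_with_bf(merged[[paste0(col, "_data")]],
                            merged[[paste0(col, "_model")]])
      rows[[length(rows) + 1]] <- data.frame(
        measure = measure,
        data_context = pairings$data_context[i],
        model_context = pairings$model_context[i],
        r = pr$r, p_unc = pr$p_unc,
        p_corr = bonferroni(pr$p_unc, pairings$m[i]),
        m = pairings$m[i], bf10 = pr$bf10, n = pr$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
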