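#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles every tunable of the simulate -> exclude -> fit -> summarise ->
#' group-infer pipeline. Thresholds default to the values the behavioural
#' analyses prescribe: IQR fence multiplier 1.5, psychometric goodness
#' threshold R <= 0.50, indifference-point range 0.4--1.9 s.
#'
#' @param seed Master seed; all randomness in the run derives from it.
#' @param cohort A \code{\link{cohort_spec}} used when trials are simulated.
#' @param n_per_condition Pseudo-responses per standard interval in the
#'   discrimination-route observer fit.
#' @param init_grid Restart grid for \code{\link{fit_observer}}.
#' @param iqr_mult IQR fence multiplier for reproduction outliers.
#' @param r_threshold Psychometric goodness-of-fit exclusion threshold.
#' @param ip_range Allowed indifference-point range (seconds).
#' @param bootstrap_B Bootstrap resamples for group IP confidence intervals.
#' @param out_dir Output directory for CSVs and logs, or \code{NULL} to skip
#'   writing files.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, cohort = cohort_spec(seed = seed),
                            n_per_condition = 48L,
                            init_grid = default_start_grid(),
                            iqr_mult = 1.5, r_threshold = 0.50,
                            ip_range = c(0.4, 1.9), bootstrap_B = 2000L,
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), cohort = cohort,
                 n_per_condition = as.integer(n_per_condition),
                 init_grid = init_grid, iqr_mult = iqr_mult,
                 r_threshold = r_threshold, ip_range = ip_range,
                 bootstrap_B = as.integer(bootstrap_B), out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate a trial table against its schema
#'
#' Checks column presence, types, the design interval set, the response
#' range, and (discrimination) the comparison-ratio and correctness
#' invariants. Violations are collected with row indices and reported
#' together.
#'
#' @param path Path to a CSV file (header row required).
#' @param task \code{"reproduction"} or \code{"discrimination"}.
#' @return The parsed data frame, invisibly annotated; errors on violations.
#' @export
validate_trial_table <- function(path,
                                 task = c("reproduction", "discrimination")) {
  task <- match.arg(task)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- character()
  need <- if (task == "reproduction")
    c("subject_id", "effector", "block", "t_s", "t_r")
  else c("subject_id", "effector", "block", "t_s1", "t_s2", "choice")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_eff <- which(!d$effector %in% c("hand", "eye"))
  if (length(bad_eff))
    problems <- c(problems, paste0("row ", bad_eff[1], ": effector '",
                                   d$effector[bad_eff[1]],
                                   "' not in {hand, eye} (",
                                   length(bad_eff), " rows)"))
  ts_col <- if (task == "reproduction") d$t_s else d$t_s1
  bad_ts <- which(!vapply(ts_col, function(v)
    any(abs(v - design_intervals()) < 1e-9), TRUE))
  if (length(bad_ts))
    problems <- c(problems, paste0("row ", bad_ts[1], ": sample interval ",
                                   ts_col[bad_ts[1]],
                                   " not a design value (",
                                   length(bad_ts), " rows)"))
  if (task == "reproduction") {
    bad_tr <- which(!is.finite(d$t_r) | d$t_r <= 0 | d$t_r >= 10)
    if (length(bad_tr))
      problems <- c(problems, paste0("row ", bad_tr[1],
                                     ": t_r outside (0, 10) s (",
                                     length(bad_tr), " rows)"))
  } else {
    ratio <- d$t_s2 / d$t_s1 - 1
    bad_rt <- which(!vapply(ratio, function(v)
      any(abs(abs(v) - c(0.06, 0.12, 0.24, 0.48)) < 1e-9), TRUE))
    if (length(bad_rt))
      problems <- c(problems, paste0("row ", bad_rt[1],
                                     ": t_s2/t_s1 ratio off the design (",
                                     length(bad_rt), " rows)"))
    bad_ch <- which(!d$choice %in% c("long", "short"))
    if (length(bad_ch))
      problems <- c(problems, paste0("row ", bad_ch[1], ": choice '",
                                     d$choice[bad_ch[1]],
                                     "' not in {long, short} (",
                                     length(bad_ch), " rows)"))
  }
  if (length(problems))
    stop("schema error in ", basename(path), ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  d
}

# Per-interval means/sds of IQR-filtered reproduction trials for one
# subject x effector. Returns list(stats =, n_excluded =, trials =).
reproduction_condition_stats <- function(trials, iqr_mult = 1.5) {
  excluded <- rep(FALSE, nrow(trials))
  for (ts in unique(trials$t_s)) {
    i <- which(trials$t_s == ts)
    if (length(i) >= 4L) excluded[i] <- iqr_filter(trials$t_r[i], iqr_mult)
  }
  keep <- trials[!excluded, ]
  stats <- do.call(rbind, lapply(sort(unique(keep$t_s)), function(ts) {
    tr <- keep$t_r[keep$t_s == ts]
    data.frame(t_s = ts, mean_tr = mean(tr), sd_tr = stats::sd(tr))
  }))
  list(stats = stats, n_excluded = sum(excluded), trials = keep)
}

# Psychometric fits for one subject x effector of discrimination data.
discrimination_psych_fits <- function(trials, r_threshold = 0.50) {
  do.call(rbind, lapply(sort(unique(trials$t_s1)), function(ts1) {
    sub <- trials[trials$t_s1 == ts1, ]
    props <- choice_proportions(sub)
    pf <- psychometric_fit(
      data.frame(t_s2 = props$t_s2, p_long = props$p_long), ts1,
      r_threshold = r_threshold)
    data.frame(t_s1 = pf$t_s1, mu = pf$mu, sigma = pf$sigma, R = pf$R,
               excluded = pf$excluded)
  }))
}

#' Run the full analysis pipeline on a simulated or supplied cohort
#'
#' Orchestrates the complete workflow: simulate (or accept) trial tables for
#' both tasks and effectors; exclude reproduction outliers per subject x
#' effector x interval; fit psychometric functions and apply the exclusion
#' cascade; fit the Bayesian observer to every surviving subject x context
#' (directly for reproduction, via pseudo-responses for discrimination);
#' assemble per-context summaries; simulate model predictions from the
#' fitted parameters and recompute the same summaries; and run the
#' group-level inference (repeated-measures ANOVAs with Tukey follow-ups,
#' model-vs-data correlations with Bonferroni correction and Bayes factors,
#' bootstrap indifference-point intervals).
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param reproduction,discrimination Optional trial tables (see
#'   \code{\link{simulate_subject}} for the schemas); simulated from
#'   \code{config$cohort} when \code{NULL}.
#' @param verbose Print progress.
#' @return A list with elements \code{summaries} (per-subject data-derived
#'   context summaries), \code{model_summaries} (same, from model
#'   simulations), \code{anova} (per-variable effects), \code{tukey},
#'   \code{correlations} (24-row model-vs-data table), \code{ip_ci},
#'   \code{exclusions}, \code{truth} (generating parameters when simulated),
#'   and \code{config}. Files are written under \code{config$out_dir} when
#'   set.
#' @export
run_pipeline <- function(config = pipeline_config(), reproduction = NULL,
                         discrimination = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  truth <- NULL
  if (is.null(reproduction) || is.null(discrimination)) {
    say("simulating cohort of %d subjects", config$cohort$n_subjects)
    sim <- simulate_cohort(config$cohort)
    reproduction <- sim$reproduction
    discrimination <- sim$discrimination
    truth <- sim$truth
  }
  subjects <- sort(unique(reproduction$subject_id))
  effs <- c("hand", "eye")

  # --- per-context descriptive stage -------------------------------------
  rep_stats <- list(); rep_excluded <- 0L
  psych <- list()
  for (s in subjects) for (e in effs) {
    rt <- reproduction[reproduction$subject_id == s &
                         reproduction$effector == e, ]
    rs <- reproduction_condition_stats(rt, config$iqr_mult)
    rep_excluded <- rep_excluded + rs$n_excluded
    rep_stats[[paste(s, e)]] <- rs
    dt <- discrimination[discrimination$subject_id == s &
                           discrimination$effector == e, ]
    pf <- discrimination_psych_fits(dt, config$r_threshold)
    psych[[paste(s, e)]] <- data.frame(subject_id = s, effector = e, pf)
  }
  psych <- do.call(rbind, psych); rownames(psych) <- NULL

  # --- indifference points for the exclusion cascade ---------------------
  ip_rows <- list()
  for (s in subjects) for (e in effs) {
    ct_r <- central_tendency_fit(rep_stats[[paste(s, e)]]$stats)
    pf <- psych[psych$subject_id == s & psych$effector == e & !psych$excluded, ]
    ct_d <- if (nrow(pf) >= 3L)
      central_tendency_fit(data.frame(t_s = pf$t_s1, mean_tr = pf$mu))
    else list(IP = NA_real_)
    ip_rows[[paste(s, e)]] <- data.frame(
      subject_id = rep(s, 2), task = c("reproduction", "discrimination"),
      effector = e, IP = c(ct_r$IP, ct_d$IP))
  }
  ip_table <- do.call(rbind, ip_rows); rownames(ip_table) <- NULL

  excl <- apply_exclusions(psych, ip_table, config$r_threshold,
                           ip_range = config$ip_range)
  keep_subjects <- setdiff(subjects, excl$excluded_subjects)
  say("exclusions: %d conditions, %d subjects removed, %d remain",
      excl$report$conditions_excluded, excl$report$subjects_total,
      length(keep_subjects))

  # --- observer fits and context summaries -------------------------------
  summaries <- list(); model_summaries <- list()
  for (s in keep_subjects) {
    si <- match(s, subjects)
    for (e in effs) {
      key <- paste(s, e)
      say("fitting %s / %s", s, e)
      # reproduction context
      rs <- rep_stats[[key]]
      fit_r <- fit_observer(rs$trials[, c("t_s", "t_r")],
                            init_grid = config$init_grid,
                            prior_lo = config$ip_range[1],
                            prior_hi = config$ip_range[2])
      summaries[[paste(key, "R")]] <- summarize_context(
        rs$stats, fit_r, subject_id = s, task = "reproduction", effector = e)
      # discrimination context via pseudo-responses
      pf <- excl$psych_fits
      pf <- pf[pf$subject_id == s & pf$effector == e & !pf$excluded, ]
      pseudo <- fit_psychometric_contexts(
        pf[, c("t_s1", "mu", "sigma")], config$n_per_condition,
        seed = child_seed(config$seed, 500L + 10L * si + match(e, effs)))
      fit_d <- fit_observer(pseudo, init_grid = config$init_grid,
                            prior_lo = config$ip_range[1],
                            prior_hi = config$ip_range[2])
      summaries[[paste(key, "D")]] <- summarize_context(
        data.frame(t_s = pf$t_s1, mean_tr = pf$mu, sd_tr = pf$sigma),
        fit_d, subject_id = s, task = "discrimination", effector = e)
      # model predictions: simulate from the fitted observers and push the
      # simulated responses through the identical statistics
      model_summaries[[paste(key, "R")]] <- model_context_summary(
        fit_r$params, task = "reproduction", subject_id = s, effector = e,
        n_rep = nrow(rs$trials),
        seed = child_seed(config$seed, 700L + 10L * si + match(e, effs)),
        r_threshold = config$r_threshold)
      model_summaries[[paste(key, "D")]] <- model_context_summary(
        fit_d$params, task = "discrimination", subject_id = s, effector = e,
        n_rep = 6L,
        seed = child_seed(config$seed, 900L + 10L * si + match(e, effs)),
        r_threshold = config$r_threshold)
    }
  }
  summaries <- do.call(rbind, summaries)
  model_summaries <- do.call(rbind, model_summaries)
  rownames(summaries) <- rownames(model_summaries) <- NULL

  # --- group inference ----------------------------------------------------
  anova_tab <- list(); tukey_tab <- list()
  for (v in c("C", "IP", "web_s", "web_i", "w_m", "w_r")) {
    cells <- data.frame(subject_id = summaries$subject_id,
                        effector = summaries$effector,
                        task = summaries$task, value = summaries[[v]])
    if (length(keep_subjects) >= 2L && !anyNA(cells$value)) {
      a <- rm_anova_2x2(cells)
      anova_tab[[v]] <- cbind(variable = v, a)
      tukey_tab[[v]] <- cbind(variable = v, tukey_hsd(cells))
    }
  }
  anova_tab <- do.call(rbind, anova_tab)
  tukey_tab <- do.call(rbind, tukey_tab)
  rownames(anova_tab) <- rownames(tukey_tab) <- NULL

  correlations <- if (length(keep_subjects) >= 4L)
    build_correlation_matrix(summaries, model_summaries) else NULL

  ip_ci <- NULL
  if (length(keep_subjects) >= 5L) {
    ip_ci <- do.call(rbind, lapply(effs, function(e) {
      scm <- do.call(rbind, lapply(keep_subjects, function(s) {
        st <- rep_stats[[paste(s, e)]]$stats
        data.frame(subject_id = s, t_s = st$t_s, mean_tr = st$mean_tr)
      }))
      ci <- bootstrap_ip_ci(scm, B = config$bootstrap_B,
                            seed = child_seed(config$seed, 40L + match(e, effs)))
      data.frame(task = "reproduction", effector = e, ip = ci$ip_hat,
                 ci_lo = ci$ip_ci_lo, ci_hi = ci$ip_ci_hi)
    }))
  }

  result <- list(summaries = summaries, model_summaries = model_summaries,
                 anova = anova_tab, tukey = tukey_tab,
                 correlations = correlations, ip_ci = ip_ci,
                 exclusions = excl$report,
                 n_trials_excluded = rep_excluded,
                 excluded_subjects = excl$excluded_subjects,
                 truth = truth, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

# Simulate one context from fitted parameters and summarise it with the
# same statistics applied to the data.
model_context_summary <- function(params, task, subject_id, effector,
                                  n_rep, seed, r_threshold = 0.50) {
  if (task == "reproduction") {
    per <- max(4L, round(n_rep / length(design_intervals())))
    ts <- rep(design_intervals(), each = per)
    tr <- simulate_reproduction(params, ts, seed = seed)
    stats <- do.call(rbind, lapply(design_intervals(), function(s) {
      data.frame(t_s = s, mean_tr = mean(tr[ts == s]),
                 sd_tr = stats::sd(tr[ts == s]))
    }))
  } else {
    design <- make_design("discrimination", n_blocks = n_rep,
                          seed = child_seed(seed, 1L))
    design$choice <- simulate_discrimination_choice(
      params, design$t_s1, design$t_s2, seed = child_seed(seed, 2L))
    pf <- discrimination_psych_fits(
      data.frame(t_s1 = design$t_s1, t_s2 = design$t_s2,
                 choice = design$choice), r_threshold)
    pf <- pf[!pf$excluded, ]
    if (nrow(pf) < 3L)
      return(data.frame(subject_id = subject_id, task = task,
                        effector = effector, C = NA_real_, IP = NA_real_,
                        web_s = NA_real_, web_i = NA_real_,
                        mean_sd = NA_real_, w_m = params$w_m,
                        w_r = params$w_r))
    stats <- data.frame(t_s = pf$t_s1, mean_tr = pf$mu, sd_tr = pf$sigma)
  }
  out <- summarize_context(stats, fit = NULL, subject_id = subject_id,
                           task = task, effector = effector)
  out$w_m <- params$w_m
  out$w_r <- params$w_r
  out
}

write_pipeline_outputs <- function(result) {
  dir.create(result$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(result$config$out_dir, f)
  utils::write.csv(result$summaries, p("context_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(result$model_summaries, p("model_summaries.csv"),
                   row.names = FALSE)
  if (!is.null(result$anova))
    utils::write.csv(result$anova, p("group_anova.csv"), row.names = FALSE)
  if (!is.null(result$tukey))
    utils::write.csv(result$tukey, p("tukey_hsd.csv"), row.names = FALSE)
  if (!is.null(result$correlations))
    utils::write.csv(result$correlations, p("model_data_correlations.csv"),
                     row.names = FALSE)
  if (!is.null(result$ip_ci))
    utils::write.csv(result$ip_ci, p("ip_bootstrap_ci.csv"),
                     row.names = FALSE)
  writeLines(c(
    sprintf("seed: %d", result$config$seed),
    sprintf("R version: %s", as.character(getRversion())),
    sprintf("subjects simulated: %s",
            if (is.null(result$truth)) "external data"
            else length(unique(result$truth$subject_id))),
    sprintf("reproduction trials excluded by IQR rule: %d",
            result$n_trials_excluded),
    sprintf("psychometric conditions excluded (R <= %.2f): %d",
            result$config$r_threshold,
            result$exclusions$conditions_excluded),
    sprintf("subjects excluded by condition rule (> 2): %d",
            result$exclusions$subjects_by_conditions),
    sprintf("subjects excluded by IP range [%.1f, %.1f] s: %d",
            result$config$ip_range[1], result$config$ip_range[2],
            result$exclusions$subjects_by_ip),
    sprintf("subjects excluded total: %d (%s)",
            result$exclusions$subjects_total,
            paste(result$excluded_subjects, collapse = ", ")),
    sprintf("IQR multiplier: %.2f; bootstrap B: %d; pseudo-responses per condition: %d",
            result$config$iqr_mult, result$config$bootstrap_B,
            result$config$n_per_condition)),
    p("run_log.txt"))
  invisible(result)
}
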