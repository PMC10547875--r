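#' Sample intervals and comparison steps of the task designs
#'
#' @return For \code{design_intervals}, the five sample intervals in seconds;
#'   for \code{design_deltas}, the signed fractional comparison steps of the
#'   discrimination task.
#' @export
design_intervals <- function() c(0.4, 0.5, 0.7, 1.1, 1.9)

#' @rdname design_intervals
#' @export
design_deltas <- function() c(-0.48, -0.24, -0.12, -0.06,
                              0.06, 0.12, 0.24, 0.48)

#' Trial schedule for one task
#'
#' Builds the block-balanced pseudorandom schedule of the experiments: in
#' reproduction each block presents each of the five sample intervals eight
#' times in shuffled order (40 trials/block, 6 blocks by default); in
#' discrimination each block presents each (standard, step) pair once (5 x 8
#' = 40 trials/block, 12 blocks by default). Deterministic given the seed.
#'
#' @param task \code{"reproduction"} or \code{"discrimination"}.
#' @param n_blocks Number of blocks (defaults: 6 reproduction,
#'   12 discrimination).
#' @param seed Integer seed.
#' @return Data frame with columns \code{block}, \code{trial}, and either
#'   \code{t_s} (reproduction) or \code{t_s1}, \code{t_s2}, \code{delta}
#'   (discrimination).
#' @export
make_design <- function(task = c("reproduction", "discrimination"),
                        n_blocks = NULL, seed) {
  task <- match.arg(task)
  if (is.null(n_blocks))
    n_blocks <- if (task == "reproduction") 6L else 12L
  with_seed(seed, {
    blocks <- lapply(seq_len(n_blocks), function(b) {
      if (task == "reproduction") {
        ts <- sample(rep(design_intervals(), each = 8L))
        data.frame(block = b, trial = seq_along(ts), t_s = ts)
      } else {
        grid <- expand.grid(t_s1 = design_intervals(),
                            delta = design_deltas())
        grid <- grid[sample.int(nrow(grid)), ]
        data.frame(block = b, trial = seq_len(nrow(grid)),
                   t_s1 = grid$t_s1, delta = grid$delta,
                   t_s2 = grid$t_s1 * (1 + grid$delta))
      }
    })
    do.call(rbind, blocks)
  })
}

#' Simulate forced-choice duration comparisons
#'
#' Generative choice rule for the discrimination task: the observer measures
#' both intervals with scalar noise, but only the first interval -- held in
#' memory across the second presentation -- is regularised toward the prior,
#' \code{t_e1 = f(t_m1)}; the fresh second measurement is compared raw. The
#' choice is "long" iff \code{t_m2 > t_e1}. Shrinking only the remembered
#' standard gives the point of subjective equality the same regression toward
#' the prior mean that the data show; shrinking both intervals equally would
#' leave choices identical to comparing raw measurements (the BLS map is
#' monotone) and produce no such bias.
#'
#' @param params An \code{\link{observer_params}} object.
#' @param t_s1,t_s2 Standard and comparison intervals (vectors, seconds).
#' @param seed Integer seed.
#' @return Character vector of choices, \code{"long"} or \code{"short"}.
#' @export
simulate_discrimination_choice <- function(params, t_s1, t_s2, seed) {
  stopifnot_params(params)
  n <- length(t_s1)
  if (length(t_s2) != n) stop("'t_s1' and 't_s2' must match", call. = FALSE)
  with_seed(seed, {
    t_m1 <- pmax(stats::rnorm(n, t_s1, params$w_m * t_s1), 1e-4)
    t_m2 <- pmax(stats::rnorm(n, t_s2, params$w_m * t_s2), 1e-4)
    t_e1 <- bls_estimate(t_m1, params)
    ifelse(t_m2 > t_e1, "long", "short")
  })
}

#' Simulate one subject in all four contexts
#'
#' Simulates reproduction and discrimination trials for both effectors.
#' Blocks alternate between hand and eye (the experiments counterbalanced
#' response order across subjects; the alternation offset can be flipped via
#' \code{effector_offset}).
#'
#' @param params_by_context Named list with elements \code{R_H}, \code{R_E},
#'   \code{D_H}, \code{D_E}, each an \code{\link{observer_params}}.
#' @param subject_id Identifier stamped into the tables.
#' @param seed Integer seed (child seeds are derived per task).
#' @param n_blocks_repro,n_blocks_disc Total blocks per task, split evenly
#'   between effectors.
#' @param effector_offset 0 or 1: which effector takes the odd blocks.
#' @return A list with data frames \code{reproduction} (columns
#'   \code{subject_id}, \code{effector}, \code{block}, \code{t_s},
#'   \code{t_r}) and \code{discrimination} (\code{subject_id},
#'   \code{effector}, \code{block}, \code{t_s1}, \code{t_s2}, \code{choice},
#'   \code{correct}).
#' @export
simulate_subject <- function(params_by_context, subject_id, seed,
                             n_blocks_repro = 6L, n_blocks_disc = 12L,
                             effector_offset = 0L) {
  need <- c("R_H", "R_E", "D_H", "D_E")
  if (!all(need %in% names(params_by_context)))
    stop("'params_by_context' needs elements ", paste(need, collapse = ", "),
         call. = FALSE)
  effs <- c("hand", "eye")
  block_eff <- function(blocks)
    effs[1L + (blocks + effector_offset) %% 2L]

  rep_design <- make_design("reproduction", n_blocks_repro,
                            seed = child_seed(seed, 1L))
  rep_design$effector <- block_eff(rep_design$block)
  rep_rows <- lapply(effs, function(e) {
    d <- rep_design[rep_design$effector == e, ]
    p <- params_by_context[[paste0("R_", if (e == "hand") "H" else "E")]]
    d$t_r <- simulate_reproduction(p, d$t_s,
                                   seed = child_seed(seed, 2L + match(e, effs)))
    d
  })
  reproduction <- do.call(rbind, rep_rows)
  reproduction <- data.frame(subject_id = subject_id,
                             reproduction[, c("effector", "block", "t_s", "t_r")])

  disc_design <- make_design("discrimination", n_blocks_disc,
                             seed = child_seed(seed, 5L))
  disc_design$effector <- block_eff(disc_design$block)
  disc_rows <- lapply(effs, function(e) {
    d <- disc_design[disc_design$effector == e, ]
    p <- params_by_context[[paste0("D_", if (e == "hand") "H" else "E")]]
    d$choice <- simulate_discrimination_choice(
      p, d$t_s1, d$t_s2, seed = child_seed(seed, 6L + match(e, effs)))
    d
  })
  discrimination <- do.call(rbind, disc_rows)
  discrimination$correct <-
    (discrimination$choice == "long") == (discrimination$t_s2 > discrimination$t_s1)
  discrimination <- data.frame(
    subject_id = subject_id,
    discrimination[, c("effector", "block", "t_s1", "t_s2", "choice", "correct")])
  rownames(reproduction) <- rownames(discrimination) <- NULL
  list(reproduction = reproduction, discrimination = discrimination)
}

#' Default parameter population for simulated cohorts
#'
#' Per-context uniform ranges for the two Weber fractions, centred on the
#' group means reported for human subjects in each context (mean +/- one
#' between-subject sd): measurement noise around 0.18--0.21 and motor noise
#' around 0.16--0.24 depending on task and effector.
#'
#' @return Named list of per-context lists with elements \code{w_m_range},
#'   \code{w_r_range}.
#' @export
default_param_population <- function() {
  list(
    R_H = list(w_m_range = c(0.16, 0.26), w_r_range = c(0.11, 0.21)),
    R_E = list(w_m_range = c(0.16, 0.22), w_r_range = c(0.19, 0.29)),
    D_H = list(w_m_range = c(0.15, 0.21), w_r_range = c(0.13, 0.35)),
    D_E = list(w_m_range = c(0.16, 0.22), w_r_range = c(0.14, 0.34)))
}

#' Cohort specification for simulation studies
#'
#' @param n_subjects Number of subjects (default 30, the post-exclusion
#'   sample size the analyses assume).
#' @param population Per-context parameter ranges
#'   (see \code{\link{default_param_population}}).
#' @param context_coupling Correlation, per subject, of the latent parameter
#'   quantiles across contexts, in \code{[0, 1]}: 0 draws each context
#'   independently, 1 gives every context the same quantile (identical
#'   parameters when the context ranges coincide).
#' @param seed Integer seed.
#' @param n_blocks_repro,n_blocks_disc Design sizes passed to
#'   \code{\link{simulate_subject}}.
#' @return A list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 30L,
                        population = default_param_population(),
                        context_coupling = 0.7, seed = 1L,
                        n_blocks_repro = 6L, n_blocks_disc = 12L) {
  if (context_coupling < 0 || context_coupling > 1)
    stop("'context_coupling' must lie in [0, 1]", call. = FALSE)
  for (ctx in population)
    if (any(c(ctx$w_m_range, ctx$w_r_range) <= 0) ||
        any(c(ctx$w_m_range, ctx$w_r_range) >= 1))
      stop("parameter ranges must lie inside (0, 1)", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), population = population,
                 context_coupling = context_coupling, seed = as.integer(seed),
                 n_blocks_repro = n_blocks_repro,
                 n_blocks_disc = n_blocks_disc),
            class = "cohort_spec")
}

#' Simulate a cohort of Bayesian observers
#'
#' Draws per-subject, per-context parameters from the population (a Gaussian
#' copula couples each subject's quantiles across contexts with correlation
#' \code{context_coupling}; marginals are uniform on the context ranges),
#' simulates every subject in all four contexts, and returns the trial tables
#' together with the generating parameters for recovery studies. All
#' randomness derives from the spec seed via per-subject child seeds.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A list with data frames \code{reproduction},
#'   \code{discrimination}, and \code{truth} (columns \code{subject_id},
#'   \code{task}, \code{effector}, \code{context}, \code{w_m}, \code{w_r}).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec",
                                           call. = FALSE)
  contexts <- names(spec$population)
  rho <- spec$context_coupling
  draws <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      z_shared <- stats::rnorm(2)              # one latent per parameter
      lapply(stats::setNames(contexts, contexts), function(ctx) {
        z_ctx <- stats::rnorm(2)
        z <- rho * z_shared + sqrt(1 - rho^2) * z_ctx
        u <- stats::pnorm(z)
        pop <- spec$population[[ctx]]
        observer_params(
          w_m = pop$w_m_range[1] + u[1] * diff(pop$w_m_range),
          w_r = pop$w_r_range[1] + u[2] * diff(pop$w_r_range))
      })
    })
  })
  rep_list <- list(); disc_list <- list(); truth <- list()
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", i)
    sim <- simulate_subject(draws[[i]], subject_id = sid,
                            seed = child_seed(spec$seed, 100L + i),
                            n_blocks_repro = spec$n_blocks_repro,
                            n_blocks_disc = spec$n_blocks_disc,
                            effector_offset = i %% 2L)
    rep_list[[i]] <- sim$reproduction
    disc_list[[i]] <- sim$discrimination
    truth[[i]] <- data.frame(
      subject_id = sid,
      context = contexts,
      task = ifelse(substr(contexts, 1, 1) == "R",
                    "reproduction", "discrimination"),
      effector = ifelse(substr(contexts, 3, 3) == "H", "hand", "eye"),
      w_m = vapply(draws[[i]], function(p) p$w_m, 0),
      w_r = vapply(draws[[i]], function(p) p$w_r, 0))
  }
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(reproduction = do.call(rbind, rep_list),
       discrimination = do.call(rbind, disc_list),
       truth = truth)
}
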