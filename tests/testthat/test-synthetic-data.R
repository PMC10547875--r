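test_that("design constants match the study layout", {
  expect_equal(design_intervals(), c(0.4, 0.5, 0.7, 1.1, 1.9))
  expect_setequal(design_deltas(),
                  c(-0.48, -0.24, -0.12, -0.06, 0.06, 0.12, 0.24, 0.48))
  expect_equal(length(design_deltas()), 8)
})

test_that("reproduction design balances intervals within every block", {
  d <- make_design("reproduction", seed = 1)
  expect_equal(nrow(d), 240)                      # 6 blocks x 40 trials
  expect_equal(max(d$block), 6)
  for (b in 1:6) {
    blk <- d[d$block == b, ]
    expect_equal(nrow(blk), 40)
    expect_equal(as.vector(table(blk$t_s)), rep(8L, 5))
  }
  # seeded shuffles are reproducible and seed-sensitive
  expect_identical(make_design("reproduction", seed = 4),
                   make_design("reproduction", seed = 4))
  expect_false(identical(make_design("reproduction", seed = 4)$t_s,
                         make_design("reproduction", seed = 5)$t_s))
})

test_that("discrimination design crosses intervals with all eight ratios", {
  d <- make_design("discrimination", seed = 2)
  expect_equal(nrow(d), 480)                      # 12 blocks x 40 trials
  for (b in unique(d$block)) {
    blk <- d[d$block == b, ]
    expect_equal(nrow(blk), 40)
    # each standard appears with each signed step exactly once per block
    expect_equal(as.vector(table(blk$t_s1, blk$delta)), rep(1L, 40))
  }
  expect_true(all(abs(d$t_s2 - d$t_s1 * (1 + d$delta)) < 1e-12))
})

test_that("choice simulator follows the remembered-standard rule", {
  p <- observer_params(0.15, 0.15)
  # near-noiseless observer always calls a 48% longer comparison 'long'
  p0 <- observer_params(1e-4, 0.1)
  ch <- simulate_discrimination_choice(p0, rep(1.1, 200), rep(1.1 * 1.48, 200),
                                       seed = 1)
  expect_true(all(ch == "long"))
  ch2 <- simulate_discrimination_choice(p0, rep(1.1, 200), rep(1.1 * 0.52, 200),
                                        seed = 1)
  expect_true(all(ch2 == "short"))
  # determinism
  expect_identical(
    simulate_discrimination_choice(p, rep(0.7, 50), rep(0.8, 50), seed = 3),
    simulate_discrimination_choice(p, rep(0.7, 50), rep(0.8, 50), seed = 3))
})

test_that("choice simulator inherits central tendency from the first interval", {
  p <- observer_params(0.2, 0.15)
  mu_from <- function(ts1, props) {
    x <- ts1 * (1 + design_deltas())
    psychometric_fit(data.frame(t_s2 = x, p_long = props), t_s1 = ts1)$mu
  }
  # Monte-Carlo PSE from simulated choices
  pse_mc <- function(ts1, seed) {
    x <- ts1 * (1 + design_deltas())
    props <- vapply(x, function(ts2) {
      ch <- simulate_discrimination_choice(p, rep(ts1, 1500), rep(ts2, 1500),
                                           seed = seed + round(1e4 * ts2))
      mean(ch == "long")
    }, 0)
    mu_from(ts1, props)
  }
  # semi-analytic PSE: the same psychometric fit applied to the quadrature
  # choice probabilities of the remembered-standard rule
  pse_pred <- function(ts1)
    mu_from(ts1, oracle_p_long(ts1, ts1 * (1 + design_deltas()), p))
  # the simulated PSEs match the rule's prediction within Monte-Carlo noise
  expect_lt(abs(pse_mc(1.1, seed = 60) - pse_pred(1.1)), 0.03)
  expect_lt(abs(pse_mc(1.9, seed = 50) - pse_pred(1.9)), 0.05)
  # central tendency: a long standard is remembered compressed (PSE well
  # below the standard), a short one dilated (PSE above it)
  expect_lt(pse_pred(1.9), 1.8)
  expect_gt(pse_pred(0.4), 0.42)
})

test_that("subject simulator produces complete, reproducible sessions", {
  pars <- list(R_H = observer_params(0.2, 0.15),
               R_E = observer_params(0.18, 0.24),
               D_H = observer_params(0.19, 0.22),
               D_E = observer_params(0.2, 0.23))
  s <- simulate_subject(pars, subject_id = "S01", seed = 7)
  expect_equal(nrow(s$reproduction), 240)
  expect_equal(nrow(s$discrimination), 480)
  expect_setequal(unique(s$reproduction$effector), c("hand", "eye"))
  expect_equal(sum(s$reproduction$effector == "hand"), 120)
  expect_equal(sum(s$discrimination$effector == "eye"), 240)
  expect_true(all(s$reproduction$t_r > 0))
  expect_true(all(s$discrimination$choice %in% c("short", "long")))
  # correctness flag consistent with the stimuli
  longer <- s$discrimination$t_s2 > s$discrimination$t_s1
  expect_identical(s$discrimination$correct,
                   (s$discrimination$choice == "long") == longer)
  expect_identical(simulate_subject(pars, "S01", seed = 7),
                   simulate_subject(pars, "S01", seed = 7))
  expect_false(identical(simulate_subject(pars, "S01", seed = 7)$reproduction$t_r,
                         simulate_subject(pars, "S01", seed = 8)$reproduction$t_r))
})

test_that("simulated reproduction shows compression and scalar variability", {
  pars <- list(R_H = observer_params(0.21, 0.16),
               R_E = observer_params(0.19, 0.24),
               D_H = observer_params(0.18, 0.24),
               D_E = observer_params(0.19, 0.24))
  s <- simulate_subject(pars, "S01", seed = 21)
  rh <- s$reproduction[s$reproduction$effector == "hand", ]
  cs <- do.call(rbind, lapply(design_intervals(), function(t) data.frame(
    t_s = t, mean_tr = mean(rh$t_r[rh$t_s == t]),
    sd_tr = sd(rh$t_r[rh$t_s == t]))))
  ct <- central_tendency_fit(data.frame(t_s = cs$t_s, mean_tr = cs$mean_tr))
  expect_gt(ct$C, 0)
  expect_lt(ct$C, 1)
  expect_gt(cs$sd_tr[5], cs$sd_tr[1])   # sd grows with the interval
})

test_that("cohort simulator honours its specification", {
  spec <- cohort_spec(n_subjects = 4, seed = 3)
  coh <- simulate_cohort(spec)
  expect_equal(nrow(coh$truth), 16)               # 4 subjects x 4 contexts
  expect_setequal(unique(coh$truth$context), c("R_H", "R_E", "D_H", "D_E"))
  expect_equal(length(unique(coh$reproduction$subject_id)), 4)
  expect_equal(nrow(coh$reproduction), 4 * 240)
  expect_equal(nrow(coh$discrimination), 4 * 480)
  # parameters fall inside the population ranges
  pop <- default_param_population()
  for (ctx in names(pop)) {
    tr <- coh$truth[coh$truth$context == ctx, ]
    expect_true(all(tr$w_m >= pop[[ctx]]$w_m_range[1] &
                      tr$w_m <= pop[[ctx]]$w_m_range[2]))
    expect_true(all(tr$w_r >= pop[[ctx]]$w_r_range[1] &
                      tr$w_r <= pop[[ctx]]$w_r_range[2]))
  }
  # determinism
  coh2 <- simulate_cohort(cohort_spec(n_subjects = 4, seed = 3))
  expect_identical(coh, coh2)
})

test_that("context coupling controls cross-context parameter correlation", {
  pop <- default_param_population()
  # with full coupling and identical context distributions the same subject
  # gets the same w_m everywhere
  pop_same <- lapply(pop, function(z) pop$R_H)
  coh <- simulate_cohort(cohort_spec(n_subjects = 6, population = pop_same,
                                     context_coupling = 1, seed = 5))
  wm <- tapply(coh$truth$w_m, coh$truth$subject_id, function(v) diff(range(v)))
  expect_true(all(wm < 1e-12))
  # with zero coupling, contexts decorrelate across a larger cohort
  coh0 <- simulate_cohort(cohort_spec(n_subjects = 40, population = pop_same,
                                      context_coupling = 0, seed = 6))
  w <- reshape(coh0$truth[, c("subject_id", "context", "w_m")],
               idvar = "subject_id", timevar = "context", direction = "wide")
  r0 <- cor(w$w_m.R_H, w$w_m.D_E)
  expect_lt(abs(r0), 0.45)
})
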