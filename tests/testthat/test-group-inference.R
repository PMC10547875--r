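make_cell_table <- function(n, seed = 1, shift = list()) {
  set.seed(seed)
  d <- expand.grid(subject_id = sprintf("S%02d", 1:n),
                   effector = c("hand", "eye"),
                   task = c("reproduction", "discrimination"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), 0.3, 0.1)
  for (nm in names(shift)) {
    parts <- strsplit(nm, "\\.")[[1]]
    sel <- d$task == parts[1] & d$effector == parts[2]
    d$value[sel] <- d$value[sel] + shift[[nm]]
  }
  d
}

test_that("repeated-measures ANOVA matches the explicit sums-of-squares oracle", {
  for (seed in 1:4) {
    d <- make_cell_table(12, seed = seed,
                         shift = list(reproduction.hand = 0.05 * seed))
    got <- rm_anova_2x2(d)
    want <- oracle_rm_anova(d)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$partial_eta_sq, want$partial_eta_sq, tolerance = 1e-10)
    expect_equal(got$df1, rep(1L, 3))
    expect_equal(got$df2, rep(11L, 3))
    expect_equal(got$p, pf(want$F, 1, 11, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA is invariant to location shifts of the whole table", {
  d <- make_cell_table(10, seed = 7, shift = list(discrimination.eye = 0.08))
  d2 <- d; d2$value <- d2$value + 100
  expect_equal(rm_anova_2x2(d)$F, rm_anova_2x2(d2)$F, tolerance = 1e-8)
})

test_that("ANOVA reports null effects when all cells are identical", {
  d <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                   effector = c("hand", "eye"),
                   task = c("reproduction", "discrimination"),
                   stringsAsFactors = FALSE)
  set.seed(3)
  # each subject has one value repeated in all four cells
  sv <- rnorm(8, 0.3, 0.1)
  d$value <- sv[match(d$subject_id, sprintf("S%02d", 1:8))]
  got <- rm_anova_2x2(d)
  expect_equal(got$F, rep(0, 3))
  expect_equal(got$p, rep(1, 3))
  expect_equal(got$partial_eta_sq, rep(0, 3))
})

test_that("ANOVA rejects malformed cell tables", {
  d <- make_cell_table(6)
  expect_error(rm_anova_2x2(d[-1, ]), "4 cells")
  d2 <- d; d2$value[3] <- NA
  expect_error(rm_anova_2x2(d2), "4 cells")
  expect_error(rm_anova_2x2(d[, -4]), "columns")
})

test_that("Tukey comparisons behave at both extremes", {
  # identical cells: no differences, all p = 1
  d0 <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                    effector = c("hand", "eye"),
                    task = c("reproduction", "discrimination"),
                    stringsAsFactors = FALSE)
  d0$value <- 0.5
  t0 <- tukey_hsd(d0)
  expect_equal(nrow(t0), 6)
  expect_equal(t0$diff, rep(0, 6), tolerance = 1e-12)
  expect_equal(t0$p_adj, rep(1, 6))
  # one strongly shifted cell in a 30-subject table is detected
  d1 <- make_cell_table(30, seed = 9, shift = list(reproduction.hand = 0.3))
  t1 <- tukey_hsd(d1)
  hits <- t1$cell_a == "reproduction_hand" | t1$cell_b == "reproduction_hand"
  expect_true(all(t1$p_adj[hits] < 0.01))
  expect_true(all(t1$p_adj >= 0 & t1$p_adj <= 1))
})

test_that("studentized-range adjustment is conservative relative to 2 means", {
  d <- make_cell_table(15, seed = 11, shift = list(discrimination.hand = 0.06))
  tk <- tukey_hsd(d)
  # recover q from the reported p, then compare against the 2-mean range:
  # with 4 means in the family each adjusted p must be >= the 2-mean p
  for (i in seq_len(nrow(tk))) {
    q <- qtukey(tk$p_adj[i], nmeans = 4, df = 14 * 3, lower.tail = FALSE)
    p2 <- ptukey(q, nmeans = 2, df = 14 * 3, lower.tail = FALSE)
    expect_gte(tk$p_adj[i], p2 - 1e-12)
  }
})

test_that("correlation Bayes factor has the right monotonicities and limits", {
  # monotone increasing in |r| at fixed n
  rs <- seq(0, 0.9, by = 0.1)
  bfs <- vapply(rs, jzs_correlation_bf, 0, n = 30)
  expect_true(all(diff(bfs) > 0))
  # symmetric in the sign of r
  expect_equal(jzs_correlation_bf(0.5, 30), jzs_correlation_bf(-0.5, 30),
               tolerance = 1e-10)
  # for a clearly nonzero correlation, more data means more evidence
  ns <- c(10, 20, 40, 80)
  bfn <- vapply(ns, function(n) jzs_correlation_bf(0.5, n), 0)
  expect_true(all(diff(bfn) > 0))
  # r near 0 with decent n favours the null (BF10 < 1)
  expect_lt(jzs_correlation_bf(0.05, 30), 1)
  # perfect correlation gives unbounded evidence
  expect_identical(jzs_correlation_bf(1, 30), Inf)
  expect_error(jzs_correlation_bf(1.2, 30), "<= 1")
  expect_error(jzs_correlation_bf(0.3, 3), "n >= 4")
})

test_that("exact Bayes factor agrees with Jeffreys' closed-form approximation", {
  for (r in c(0.1, 0.3, 0.5)) {
    exact01 <- 1 / jzs_correlation_bf(r, 30)
    approx01 <- jeffreys_bf01_approx(r, 30)
    expect_equal(exact01, approx01, tolerance = 0.10)
  }
})

test_that("pearson_with_bf matches cor.test and handles edge input", {
  set.seed(15)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25, 0, 0.8)
  pr <- pearson_with_bf(x, y)
  ct <- cor.test(x, y)
  expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pr$p_unc, ct$p.value, tolerance = 1e-12)
  expect_equal(pr$n, 25)
  # perfectly correlated data
  pid <- pearson_with_bf(x, x)
  expect_equal(pid$r, 1)
  expect_identical(pid$bf10, Inf)
  # non-finite pairs are dropped before correlating
  x2 <- c(x, NA); y2 <- c(y, 5)
  expect_equal(pearson_with_bf(x2, y2)$n, 25)
  expect_error(pearson_with_bf(1:3, 1:3), "4 paired")
  expect_error(pearson_with_bf(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.089, 4), 0.356)
  expect_equal(bonferroni(0.4, 4), 1)
  expect_equal(bonferroni(0.02, 2), 0.04)
  expect_equal(bonferroni(c(0.01, 0.3), 4), c(0.04, 1))
  expect_error(bonferroni(-0.1, 4), "\\[0, 1\\]")
  expect_error(bonferroni(0.1, 0), ">= 1")
})

test_that("correlation matrix covers the reported pairings exactly once", {
  set.seed(20)
  mk <- function(noise) {
    d <- expand.grid(subject_id = sprintf("S%02d", 1:20),
                     task = c("reproduction", "discrimination"),
                     effector = c("hand", "eye"),
                     stringsAsFactors = FALSE)
    d$C <- runif(nrow(d), 0.1, 0.5) + rnorm(nrow(d), 0, noise)
    d$mean_sd <- runif(nrow(d), 0.05, 0.25) + rnorm(nrow(d), 0, noise)
    d
  }
  data_tab <- mk(0)
  out <- build_correlation_matrix(data_tab, data_tab)
  expect_equal(nrow(out), 24)
  expect_equal(sum(out$measure == "bias"), 12)
  expect_equal(sum(out$measure == "sd"), 12)
  # identical tables: the four matched-context pairings correlate perfectly
  matched <- out$data_context == out$model_context
  expect_equal(sum(matched), 8)   # 4 contexts x 2 measures
  expect_equal(out$r[matched], rep(1, 8), tolerance = 1e-12)
  # family sizes: 4 within-task, 2 cross-task
  expect_equal(sort(unique(out$m)), c(2, 4))
  expect_equal(sum(out$m == 4), 16)
  expect_equal(sum(out$m == 2), 8)
  expect_true(all(out$p_corr >= out$p_unc - 1e-15))
  expect_true(all(out$p_corr <= 1))
  expect_true(all(out$n == 20))
})

test_that("uncorrected correlation p-values are calibrated under the null", {
  # the |r| threshold at p = 0.05, n = 30 corresponds to t(28) critical value
  tcrit <- qt(0.975, 28)
  rcrit <- tcrit / sqrt(28 + tcrit^2)
  set.seed(33)
  hits <- mean(replicate(10000, {
    abs(cor(rnorm(30), rnorm(30))) > rcrit
  }))
  expect_equal(hits, 0.05, tolerance = 0.01)
})
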