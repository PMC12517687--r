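test_that("resampled AUC matches the brute-force oracle", {
  expect_equal(auc_between(c(0, 1, 2), c(1, 2, 3), n_sample = 3, n_iter = 1, seed = 1),
    7 / 9,
    tolerance = 1e-12
  )
  expect_equal(auc_between(1:5, 1:5, n_sample = 5, n_iter = 1, seed = 1), 0.5)
  expect_equal(auc_between(1:5, 11:15, n_sample = 5, n_iter = 1, seed = 1), 1)

  # full-class resampling equals the exact AUC; subsampling converges to it
  set.seed(7)
  for (i in 1:10) {
    a <- rpois(40, 5)
    b <- rpois(40, 7)
    exact <- auc_bruteforce(a, b)
    expect_equal(
      auc_between(a, b, n_sample = 40, n_iter = 1, seed = i), exact,
      tolerance = 1e-12
    )
    expect_lt(abs(auc_between(a, b, n_sample = 20, n_iter = 100, seed = i) - exact), 0.02)
  }
})

test_that("AUC is antisymmetric under label exchange", {
  set.seed(3)
  for (i in 1:10) {
    a <- rpois(25, 4)
    b <- rpois(25, 6)
    ab <- auc_between(a, b, n_sample = 25, n_iter = 1, seed = 1)
    ba <- auc_between(b, a, n_sample = 25, n_iter = 1, seed = 1)
    expect_equal(ab + ba, 1, tolerance = 1e-12)
  }
})

test_that("classes below the sample size are a named fatal error", {
  expect_error(auc_between(1:5, 1:30), "5")
})

test_that("null traces stay near 0.5 and planted choice onsets are recovered", {
  b <- simulate_behavior(
    behavior_params(d_easy = 1, d_hard = 1, c_bias = -0.5, n_trials = 360, p_probe = 0),
    seed = 21
  )
  pair <- contrast_builder(b$trials, "choice")[[1]]

  # a unit with no class difference: all adjusted bins inside the null band
  u_null <- poisson_unit(8, max(b$trials$t_onset) + 3, seed = 31)
  tr0 <- auc_timecourse(u_null, pair$a, pair$b, seed = 5)
  expect_true(all(abs(tr0$auc - 0.5) <= 3 * tr0$null_sd + 1e-9))
  expect_true(all(tr0$null_mean > 0.45 & tr0$null_mean < 0.55))
  expect_true(all(tr0$null_sd > 0))

  # planted choice gain at 0.15 s: onset within one step
  spk <- simulate_units(
    b$trials,
    unit_params(
      n_units = 5, baseline_rate = 5, evoked_gain = 0,
      choice_gain = 25, choice_onset = 0.15
    ),
    seed = 41
  )
  onsets <- vapply(spk$units, function(u) {
    tr <- auc_timecourse(u, pair$a, pair$b, seed = 6, contrast = "choice")
    discrimination_metrics(tr)$onset_latency
  }, 0)
  expect_lt(abs(median(onsets) - 0.15), 0.025 + 1e-9)

  # determinism
  u <- spk$units[[1]]
  t1 <- auc_timecourse(u, pair$a, pair$b, seed = 9)
  t2 <- auc_timecourse(u, pair$a, pair$b, seed = 9)
  expect_identical(t1$auc, t2$auc)
  expect_identical(t1$null_sd, t2$null_sd)
})

test_that("shuffle of constant-count trials collapses to a degenerate null", {
  tr <- make_trials(50)
  # one spike exactly 10 ms after every onset: identical counts everywhere
  u <- unit("const", sort(tr$t_onset + 0.01))
  nul <- shuffle_null(u, tr[1:25, ], tr[26:50, ], n_sample = 20, n_iter = 50, seed = 2)
  expect_true(all(nul$sd == 0))
  expect_true(all(nul$mean == 0.5))
})

test_that("discrimination metrics follow the stated conventions on a constructed trace", {
  t_centers <- seq(-0.175, 0.575, by = 0.025)
  trace <- structure(
    list(
      t = t_centers,
      auc = ifelse(t_centers >= 0.125 - 1e-9 & t_centers <= 0.3 + 1e-9, 0.9, 0.5),
      auc_raw = NULL,
      null_mean = rep(0.5, length(t_centers)),
      null_sd = rep(0.01, length(t_centers)),
      window = 0.05, step = 0.025, contrast = "choice", n_a = 20, n_b = 20
    ),
    class = "auc_trace"
  )
  m <- discrimination_metrics(trace)
  # bins covering [0.1, 0.3): first center at 0.1 + window/2, 8 bins
  expect_equal(m$onset_latency, 0.125)
  expect_equal(m$duration, 8 * 0.025)
  expect_equal(m$max_auc, 0.9)
  expect_true(m$significant)

  # nothing significant
  trace$auc <- rep(0.5, length(t_centers))
  m0 <- discrimination_metrics(trace)
  expect_true(is.na(m0$onset_latency))
  expect_equal(m0$duration, 0)
  expect_false(m0$significant)

  # a single significant bin counts one step of duration
  trace$auc[which(t_centers >= 0)[3]] <- 0.9
  expect_equal(discrimination_metrics(trace)$duration, 0.025)
})

test_that("contrast builder partitions trials per the task design", {
  b <- simulate_behavior(
    behavior_params(d_easy = 1.5, c_bias = -0.5, n_trials = 400),
    seed = 3
  )
  ce <- contrast_builder(b$trials, "stim_easy")
  expect_length(ce, 1)
  expect_true(all(ce[[1]]$a$outcome == "fa" & ce[[1]]$a$task == "easy"))
  expect_true(all(ce[[1]]$b$outcome == "hit" & ce[[1]]$b$task == "easy"))

  ch <- contrast_builder(b$trials, "choice")
  expect_length(ch, 2)
  for (pr in ch) {
    expect_true(all(pr$a$outcome == "cr"))
    expect_true(all(pr$b$outcome == "fa"))
    expect_false(any(c(pr$a$outcome, pr$b$outcome) %in% c("miss", "probe")))
  }

  gn <- contrast_builder(b$trials, "go_vs_nogo")
  expect_length(gn, 2)
  expect_true(all(gn[[1]]$b$category == "go"))

  # no FA trials: stimulus contrast is fatal with counts
  perfect <- b$trials
  perfect$outcome[perfect$outcome == "fa"] <- "cr"
  expect_error(contrast_builder(perfect, "stim_easy"), "empty class")
})

test_that("AUC-behavior correlation behaves across constructions", {
  d <- c(0.5, 1, 1.5, 2, 3)
  auc <- 0.5 + 0.08 * d # deterministic construction
  r <- auc_vs_behavior(auc, d)
  expect_gt(r$r, 0.95)
  r2 <- auc_vs_behavior(rev(auc), d)
  expect_lt(r2$r, 0)
  r3 <- auc_vs_behavior(auc, rep(1, 5))
  expect_identical(r3$flag, "constant_behavior")
  expect_error(auc_vs_behavior(auc[1:2], d[1:2]), "3 sessions")
})
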