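test_that("planted sensitivity is recovered by the behavioral estimator", {
  b <- simulate_behavior(
    behavior_params(d_easy = 4, d_hard = 2, c_bias = 0, n_trials = 2000),
    seed = 101
  )
  bs <- behavior_summary(b$trials, last_k = Inf)
  expect_lt(abs(bs$d_easy - 4), 0.3)
  expect_lt(abs(bs$d_hard - 2), 0.3)
})

test_that("zero planted sensitivity gives chance-level rates", {
  b <- simulate_behavior(
    behavior_params(d_easy = 0, d_hard = 0, c_bias = 0, n_trials = 2000),
    seed = 55
  )
  bs <- behavior_summary(b$trials, last_k = Inf)
  expect_gt(bs$hit_easy, 0.45)
  expect_lt(bs$hit_easy, 0.55)
  expect_gt(bs$fa_easy, 0.45)
  expect_lt(bs$fa_easy, 0.55)
})

test_that("the behavior generator is deterministic given the seed", {
  p <- behavior_params(n_trials = 150)
  b1 <- simulate_behavior(p, seed = 9)
  b2 <- simulate_behavior(p, seed = 9)
  expect_identical(b1$trials, b2$trials)
  expect_identical(b1$licks, b2$licks)
  b3 <- simulate_behavior(p, seed = 10)
  expect_false(identical(b1$trials$outcome, b3$trials$outcome))
})

test_that("invalid parameters fail with the offending field named", {
  expect_error(behavior_params(p_nogo = 0.8, p_probe = 0.5), "p_nogo/p_probe")
  expect_error(behavior_params(n_trials = 0), "n_trials")
  expect_error(behavior_params(lick_latency_mean = -1), "lick_latency_mean")
  expect_error(unit_params(tuning_sd_oct = 0), "tuning_sd_oct")
  expect_error(unit_params(choice_onset = 0.9), "choice_onset")
})

test_that("with no evoked or choice signal, counts are baseline Poisson", {
  trials <- make_trials(500, iti = 3)
  spk <- simulate_units(
    trials,
    unit_params(n_units = 1, baseline_rate = 10, evoked_gain = 0, choice_gain = 0),
    seed = 7
  )
  counts <- vapply(
    trials$t_onset,
    function(on) sum(spk$units[[1]]$spike_times >= on & spk$units[[1]]$spike_times < on + 0.2),
    0
  )
  mu <- 10 * 0.2 # expected Poisson mean in [0, 200 ms)
  se <- sqrt(mu / 500)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # Poisson variance matches the mean within sampling error
  expect_lt(abs(var(counts) - mu), 0.5)
})

test_that("strongly driven units at the Go frequency pass the responsiveness test", {
  trials <- make_trials(100)
  spk <- simulate_units(
    trials,
    unit_params(
      n_units = 50, baseline_rate = 4, evoked_gain = 60,
      bf_log2 = log2(7.07), tuning_sd_oct = 0.5
    ),
    seed = 13
  )
  excited <- vapply(
    spk$units,
    function(u) responsiveness_test(u, trials)$is_excited, TRUE
  )
  expect_gt(mean(excited), 0.95)
})

test_that("spike simulation is deterministic given the seed", {
  trials <- make_trials(30)
  p <- unit_params(n_units = 2, choice_gain = 8)
  s1 <- simulate_units(trials, p, seed = 4)
  s2 <- simulate_units(trials, p, seed = 4)
  expect_identical(s1$units[[1]]$spike_times, s2$units[[1]]$spike_times)
  expect_identical(s1$units[[2]]$spike_times, s2$units[[2]]$spike_times)
})

test_that("PSTH peak sits near the planted evoked latency plus kernel peak", {
  trials <- make_trials(200)
  spk <- simulate_units(
    trials,
    unit_params(
      n_units = 1, baseline_rate = 2, evoked_gain = 80,
      evoked_latency = 0.03, evoked_decay = 0.02, gain_noise_cv = 0
    ),
    seed = 3
  )
  fp <- firing_properties(spk$units[[1]], trials)
  # alpha kernel peaks one time constant after the latency
  expect_lt(abs(fp$latency_to_peak - (0.03 + 0.02)), 0.01)
})

test_that("the pure-tone protocol has the exact published structure", {
  s <- simulate_fra_protocol(unit_params(n_units = 1, baseline_rate = 1), seed = 5)
  expect_identical(nrow(s$trials), 1600L)
  cells <- table(s$trials$freq, s$trials$level)
  expect_true(all(cells == 16))
  expect_identical(dim(cells), c(20L, 5L))
  steps <- diff(log2(sort(unique(s$trials$freq))))
  expect_true(all(abs(steps - 0.1661) < 1e-3))
  s2 <- simulate_fra_protocol(unit_params(n_units = 1, baseline_rate = 1), seed = 5)
  expect_identical(s$trials, s2$trials)
  expect_identical(s$units[[1]]$spike_times, s2$units[[1]]$spike_times)
})

test_that("generated sessions pass validation and regenerate from their seed", {
  s <- small_session(seed = 31)
  expect_no_violations(s)
  s2 <- small_session(seed = 31)
  expect_identical(s$trials, s2$trials)
  expect_identical(
    lapply(s$units, function(u) u$spike_times),
    lapply(s2$units, function(u) u$spike_times)
  )
})
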