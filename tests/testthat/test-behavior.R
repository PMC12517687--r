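test_that("d-prime and criterion match their closed forms", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.99, 0.01), 2 * qnorm(0.99), tolerance = 1e-12)
  # extreme rates are clipped to [0.01, 0.99] before the probit
  expect_equal(dprime(1, 0), dprime(0.99, 0.01), tolerance = 1e-12)
  expect_equal(criterion_bias(0.5, 0.5), 0)
  expect_equal(criterion_bias(0.99, 0.01), 0)
  expect_equal(criterion_bias(0.9, 0.5), -0.5 * qnorm(0.9), tolerance = 1e-12)
  expect_error(dprime(NaN, 0.5), "NaN")
  expect_error(criterion_bias(0.5, NA), "NaN")
})

test_that("d-prime identities hold across the rate grid", {
  h <- seq(0.02, 0.98, by = 0.08)
  for (hr in h) {
    for (fr in h) {
      expect_equal(dprime(hr, fr), -dprime(fr, hr), tolerance = 1e-12)
      expect_equal(criterion_bias(hr, fr), -criterion_bias(1 - fr, 1 - hr),
        tolerance = 1e-12
      )
    }
  }
  # monotone increasing in hit rate, decreasing in FA rate
  expect_true(all(diff(dprime(h, 0.5)) > 0))
  expect_true(all(diff(dprime(0.5, h)) < 0))
})

test_that("outcome classification follows threshold and window rules", {
  tr <- make_trials(3, category = c("go", "nogo", "go"), tone_dur = 0.3)
  # trial 1: five licks 0.35-0.55 s after offset; trial 2: none; trial 3: four licks
  off1 <- tr$t_onset[1] + 0.3
  off3 <- tr$t_onset[3] + 0.3
  licks <- sort(c(off1 + seq(0.35, 0.55, length.out = 5), off3 + seq(0.3, 0.6, length.out = 4)))
  out <- classify_outcomes(tr, licks, lick_threshold = 5, response_window = 2)
  expect_identical(out$outcome, c("hit", "cr", "miss"))
  expect_identical(out$lick_count, c(5L, 0L, 4L))
  expect_equal(out$first_lick_latency[1], 0.3 + 0.35, tolerance = 1e-9)

  # outcomes partition non-probe trials
  b <- simulate_behavior(behavior_params(n_trials = 400), seed = 3)
  non_probe <- b$trials$category != "probe"
  expect_true(all(b$trials$outcome[non_probe] %in% c("hit", "miss", "fa", "cr")))
  expect_true(all(b$trials$outcome[!non_probe] == "probe"))
})

test_that("overlapping response windows are truncated with a warning", {
  tr <- make_trials(2, iti = 1.5) # window (2 s) overlaps the next onset
  expect_warning(classify_outcomes(tr, numeric()), "truncated")
})

test_that("running d-prime reduces to the whole-session value and handles gaps", {
  # alternating perfect hit/cr: every bin at the clipped ceiling
  tr <- make_trials(100,
    category = rep(c("go", "nogo"), 50),
    task = rep("easy", 100)
  )
  tr$outcome <- rep(c("hit", "cr"), 50)
  rd <- running_dprime(tr, window = 25, step = 25)
  expect_true(all(abs(rd$dprime - 2 * qnorm(0.99)) < 1e-12))

  # a bin with go trials only gives NA
  tr2 <- make_trials(30, category = rep("go", 30))
  tr2$outcome <- rep("hit", 30)
  rd2 <- running_dprime(tr2, window = 25, step = 25)
  expect_true(all(is.na(rd2$dprime)))

  # window = n, step = n equals the endpoint estimate
  b <- simulate_behavior(behavior_params(n_trials = 200), seed = 12)
  rd3 <- running_dprime(b$trials, window = 200, step = 200)
  bs <- behavior_summary(b$trials, last_k = Inf)
  expect_equal(rd3$dprime[rd3$task == "easy"], bs$d_easy, tolerance = 1e-12)
  expect_equal(rd3$dprime[rd3$task == "hard"], bs$d_hard, tolerance = 1e-12)
})

test_that("psychometric fit recovers noiseless parameters and flags degeneracy", {
  freqs <- 1000 * 2^seq(2.3, 4.1, length.out = 7)
  t <- log2(freqs / 1000)
  y <- 1 / (1 + exp(-(t - log2(10)) / 0.2))
  fit <- fit_psychometric(freqs, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$a - 1), 1e-6)
  expect_lt(abs(fit$b - log2(10)), 1e-6)
  expect_lt(abs(fit$c - 0.2), 1e-6)

  # falling curve: mirrored fit, inflection still within the data range
  y_fall <- 1 / (1 + exp((t - log2(10)) / 0.2))
  fit2 <- fit_psychometric(freqs, y_fall)
  expect_true(fit2$converged)
  expect_identical(fit2$direction, -1)
  expect_gt(fit2$b, min(t))
  expect_lt(fit2$b, max(t))
  expect_lt(abs(abs(fit2$b) - log2(10)), 1e-6)

  # flat rates: degenerate, no silent fallback
  fit3 <- fit_psychometric(freqs, rep(0.5, 7))
  expect_false(fit3$converged)
  expect_true(fit3$degenerate)
  expect_error(fit_psychometric(c(7070, 14140), c(0.9, 0.1)), "4 distinct")
})

test_that("behavior summary recovers planted parameters and degenerate statistics", {
  b <- simulate_behavior(
    behavior_params(d_easy = 2, d_hard = 1, c_bias = 0.2, n_trials = 1000),
    seed = 77
  )
  bs <- behavior_summary(b$trials, last_k = Inf)
  expect_lt(abs(bs$d_easy - 2), 0.35)
  expect_lt(abs(bs$criterion - 0.2), 0.2)
  expect_true(bs$cv_d >= 0)
  expect_named(
    bs$iti_by_prev_outcome,
    sort(unique(b$trials$outcome[-nrow(b$trials)])),
    ignore.order = TRUE
  )
})

test_that("criterion grid recovery stays within binomial error", {
  # planted (d, c) grid; 3 SE at n = 2000 per cell
  for (d in c(0, 2)) {
    for (cb in c(-0.5, 0.5)) {
      b <- simulate_behavior(
        behavior_params(
          d_easy = d, d_hard = d, c_bias = cb, n_trials = 1000,
          p_probe = 0
        ),
        seed = 1000 + round(10 * d + cb * 4)
      )
      bs <- behavior_summary(b$trials, last_k = Inf)
      # generous 3-SE style bound at this n
      expect_lt(abs(bs$d_easy - d), 0.45)
      expect_lt(abs(bs$criterion - cb), 0.3)
    }
  }
})
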