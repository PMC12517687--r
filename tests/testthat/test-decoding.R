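# Gaussian toy populations with a planted mean shift, used across the
# decoding tests.
toy_population <- function(n_per_class = 40, p = 20, delta = 0, seed = 1,
                           sd = 1) {
  set.seed(seed)
  mu <- rep(delta, p)
  x1 <- matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p)
  x2 <- matrix(rnorm(n_per_class * p, 0, sd), n_per_class, p) +
    matrix(mu, n_per_class, p, byrow = TRUE)
  structure(
    list(
      counts = rbind(x1, x2),
      labels = rep(c("cr", "hit"), each = n_per_class),
      task = "easy", window = c(0, 0.2), accepted = TRUE
    ),
    class = "population_matrix"
  )
}

test_that("population matrices apply the inclusion thresholds inclusively", {
  s <- simulate_session(
    behavior_params(d_easy = 2, c_bias = -0.5, n_trials = 200, p_probe = 0),
    unit_params(n_units = 25, evoked_gain = 30, bf_jitter_oct = 1, bf_log2 = log2(10)),
    seed = 19
  )
  ru <- responsive_units(s)
  keep <- ru$unit_id[ru$is_excited]
  pm <- build_population(s, "easy", unit_ids = keep)
  expect_true(pm$accepted)
  expect_identical(colnames(pm$counts), keep) # deterministic column order

  pm_few_units <- build_population(s, "easy", unit_ids = keep[1:10])
  expect_false(pm_few_units$accepted)
  expect_match(pm_few_units$reason, "units")

  pm_few_trials <- build_population(s, "easy", unit_ids = keep, min_trials = 1000)
  expect_false(pm_few_trials$accepted)
  expect_match(pm_few_trials$reason, "trials")
  expect_error(lda_decode(pm_few_trials), "rejected")
})

test_that("LDA decodes separable data and stays at chance on permuted labels", {
  # strong planted separation: near-perfect held-out accuracy
  pm_sep <- toy_population(n_per_class = 60, p = 20, delta = 1.5, seed = 5)
  expect_gte(lda_decode(pm_sep, n_repeats = 50, seed = 1), 0.95)

  # noiseless, linearly separable: exactly 1
  pm_perfect <- toy_population(n_per_class = 30, p = 5, delta = 50, seed = 6, sd = 1e-3)
  expect_equal(lda_decode(pm_perfect, n_repeats = 20, seed = 2), 1.0)

  # label permutation: chance band
  pm_null <- toy_population(n_per_class = 40, p = 20, delta = 0, seed = 7)
  acc <- lda_decode(pm_null, n_repeats = 100, seed = 3)
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)

  # determinism
  expect_identical(
    lda_decode(pm_sep, n_repeats = 20, seed = 11),
    lda_decode(pm_sep, n_repeats = 20, seed = 11)
  )
})

test_that("the shrinkage LDA agrees with a reference LDA when shrinkage is negligible", {
  # many trials x few units with a clearly anisotropic covariance: the
  # Ledoit-Wolf coefficient is small and the decision rule should coincide
  # with plain pooled-covariance LDA
  set.seed(8)
  n <- 300
  scales <- c(0.5, 1, 2, 4)
  X <- rbind(
    matrix(rnorm(n * 4), n, 4),
    matrix(rnorm(n * 4), n, 4) + 0.5
  ) %*% diag(scales)
  y <- rep(c("cr", "hit"), each = n)
  model <- neurodisc:::fit_lda(X, y)
  expect_lt(model$lambda, 0.1)
  ref <- MASS::lda(X, grouping = y)
  set.seed(30)
  xnew <- (matrix(rnorm(400 * 4), 400, 4) + 0.25) %*% diag(scales)
  mine <- neurodisc:::predict_lda(model, xnew)
  theirs <- as.character(predict(ref, xnew)$class)
  # xnew straddles the decision boundary, so the small residual shrinkage
  # can flip only boundary-adjacent points
  expect_gt(mean(mine == theirs), 0.95)
})

test_that("accuracy is non-decreasing in the planted separation", {
  deltas <- c(0, 0.4, 1.2)
  accs <- vapply(deltas, function(d) {
    lda_decode(toy_population(delta = d, seed = 9), n_repeats = 50, seed = 4)
  }, 0)
  expect_true(all(diff(accs) >= -0.02))
  expect_gt(accs[3], accs[1])
})

test_that("time-resolved decoding localizes a planted transient", {
  s <- simulate_session(
    behavior_params(d_easy = 2.5, c_bias = -0.5, n_trials = 220, p_probe = 0),
    unit_params(
      n_units = 20, evoked_gain = 40, evoked_latency = 0.02,
      evoked_decay = 0.04, bf_log2 = log2(7.07), tuning_sd_oct = 0.4
    ),
    seed = 23
  )
  ru <- responsive_units(s)
  tc <- decode_timecourse(s, "easy",
    range = c(-0.3, 0.5),
    unit_ids = ru$unit_id[ru$is_excited], n_repeats = 20, seed = 5
  )
  pre <- tc$accuracy[tc$t < 0]
  stim <- tc$accuracy[tc$t > 0.025 & tc$t < 0.3]
  expect_lt(mean(pre), 0.65) # chance-ish before the tone
  expect_gt(max(stim), 0.9) # strong decoding during the transient
})

test_that("decoding latency finds the threshold crossing on a constructed trace", {
  # construct via the exported pieces: baseline mean 0.5, sd 0.01, step at 0.12
  trace <- data.frame(
    t = seq(-0.475, 0.195, by = 0.01),
    accuracy = 0.5
  )
  set.seed(1)
  trace$accuracy <- 0.5 + rnorm(nrow(trace), 0, 0.005)
  trace$accuracy[trace$t >= 0.12] <- 0.9
  base <- trace$t - 0.025 >= -0.5 & trace$t + 0.025 <= -0.05
  thr <- mean(trace$accuracy[base]) + 3 * sd(trace$accuracy[base])
  first <- trace$t[trace$t >= 0 & trace$accuracy > thr][1]
  expect_equal(first, 0.125, tolerance = 1e-9) # first sampled center >= 0.12
})

test_that("fisher separation matches closed forms and affine invariance", {
  # 1-D: means 0 and 1, variances 0.5 each -> S = 1
  set.seed(2)
  x1 <- matrix(rnorm(4000, 0, sqrt(0.5)), ncol = 1)
  x2 <- matrix(rnorm(4000, 1, sqrt(0.5)), ncol = 1)
  s <- fisher_separation(x1, x2)
  expect_lt(abs(s$S - 1), 0.1)

  # identical means -> S = 0
  s0 <- fisher_separation(x1, x1)
  expect_equal(s0$S, 0, tolerance = 1e-12)

  # affine invariance under a common invertible map
  set.seed(3)
  y1 <- matrix(rnorm(200 * 6), 200, 6)
  y2 <- matrix(rnorm(200 * 6), 200, 6) + 0.8
  A <- matrix(rnorm(36), 6, 6) + diag(6)
  b <- rnorm(6)
  s_raw <- fisher_separation(y1, y2, eps_scale = 1e-12)
  s_map <- fisher_separation(
    sweep(y1 %*% A, 2, b, "+"),
    sweep(y2 %*% A, 2, b, "+"),
    eps_scale = 1e-12
  )
  expect_lt(abs(s_raw$S - s_map$S) / s_raw$S, 1e-6)
})

test_that("closed-form separation beats a brute-force direction search", {
  set.seed(4)
  p <- 10
  x1 <- matrix(rnorm(100 * p), 100, p)
  x2 <- matrix(rnorm(100 * p), 100, p) + rep(c(0.9, 0.2), length.out = p)
  S_closed <- fisher_separation(x1, x2, eps_scale = 1e-12)$S
  mu <- colMeans(x1) - colMeans(x2)
  W <- cov(x1) + cov(x2)
  rayleigh <- function(w) (sum(w * mu))^2 / as.numeric(t(w) %*% W %*% w)
  dirs <- matrix(rnorm(1e4 * p), ncol = p)
  best_random <- max(apply(dirs, 1, rayleigh))
  expect_gte(S_closed, best_random)
  polished <- optim(dirs[which.max(apply(dirs, 1, rayleigh)), ], rayleigh,
    control = list(fnscale = -1, maxit = 5000)
  )$value
  expect_lt((S_closed - polished) / S_closed, 0.02)
})

test_that("single-trial variance reflects the z-scoring construction", {
  pm <- toy_population(n_per_class = 200, p = 15, delta = 0, seed = 12)
  v <- single_trial_variance(pm)
  expect_lt(max(abs(v - 1)), 0.1) # one shared distribution: variance ~ 1

  pm2 <- toy_population(n_per_class = 200, p = 15, delta = 1.5, seed = 13)
  v2 <- single_trial_variance(pm2)
  expect_true(all(v2 < 1)) # between-class spread absorbs part of the total

  # duplicate trials only: zero-variance units are excluded with a warning
  pm3 <- pm
  pm3$counts <- matrix(1, 10, 3)
  pm3$labels <- rep(c("cr", "hit"), each = 5)
  expect_warning(expect_error(single_trial_variance(pm3)), "zero-variance")
})

test_that("robust no-intercept regression resists outliers", {
  s_easy <- seq(1, 10)
  d <- data.frame(s_easy = s_easy, s_hard = 0.5 * s_easy)
  fit <- separation_regression(d)
  expect_equal(fit$beta, 0.5, tolerance = 1e-9)

  d_out <- d
  d_out$s_hard[4] <- 30 # one gross outlier
  fit2 <- separation_regression(d_out)
  expect_lt(abs(fit2$beta - 0.5) / 0.5, 0.05)

  d_id <- data.frame(s_easy = 1:5, s_hard = 1:5)
  expect_equal(separation_regression(d_id)$beta, 1, tolerance = 1e-9)

  expect_error(
    separation_regression(data.frame(s_easy = c(0, 0, 0), s_hard = 1:3)),
    "degenerate"
  )
  expect_error(
    separation_regression(data.frame(s_easy = 1:2, s_hard = 1:2)),
    ">= 3 sessions"
  )
})
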