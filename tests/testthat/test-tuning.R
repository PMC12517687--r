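# One strongly tuned FRA session shared across the tuning tests.
fra_fixture <- function() {
  simulate_fra_protocol(
    unit_params(
      n_units = 4, baseline_rate = 2, evoked_gain = 60,
      bf_log2 = log2(10), tuning_sd_oct = 0.35
    ),
    seed = 61
  )
}

test_that("FRA recovers planted tuning and rejects malformed protocols", {
  s <- fra_fixture()
  f <- compute_fra(s$units[[1]], s$trials)
  expect_true(f$responsive)
  expect_lt(abs(log2(f$best_frequency / 10000)), 2 * 0.1661 + 1e-9)
  expect_true(all(f$rate >= 0))
  # level-dependent gain is monotone by construction: column means increase
  col_means <- colMeans(f$rate)
  expect_true(all(diff(col_means) > -0.5))

  # untuned unit: nothing significant, flagged unresponsive
  quiet <- unit("quiet", sort(runif(50, 0, max(s$trials$t_onset))))
  f0 <- compute_fra(quiet, s$trials)
  expect_false(f0$responsive)
  expect_true(is.na(f0$best_frequency))
  expect_equal(bandwidth(f0), 0)

  expect_error(
    compute_fra(s$units[[1]], s$trials[s$trials$level != 62, ]),
    "analysis level"
  )
  expect_error(
    compute_fra(s$units[[1]], s$trials[1:300, ]),
    "empty"
  )
})

test_that("bandwidth applies the false-positive correction exactly", {
  s <- fra_fixture()
  f <- compute_fra(s$units[[1]], s$trials)
  # overwrite the mask with constructed cases
  f$sig <- rep(FALSE, 20)
  f$sig[8:12] <- TRUE # 5 adjacent significant frequencies
  f$best_frequency <- f$freqs[10]
  expect_equal(bandwidth(f, alpha = 0.05, octave_step = 0.1661), (5 - 1) * 0.1661,
    tolerance = 1e-12
  )
  f$sig <- rep(TRUE, 20)
  expect_equal(bandwidth(f, alpha = 0.05, octave_step = 0.1661), 19 * 0.1661,
    tolerance = 1e-12
  )
  # bandwidth is monotone in the size of the significant run
  widths <- vapply(1:8, function(k) {
    f$sig <- rep(FALSE, 20)
    f$sig[10 + seq_len(k) - 1] <- TRUE
    f$best_frequency <- f$freqs[10]
    bandwidth(f, alpha = 0.05, octave_step = 0.1661)
  }, 0)
  expect_true(all(diff(widths) >= 0))
  expect_lte(max(widths), 19 * 0.1661)
})

test_that("population sparseness counts significant cells", {
  s <- fra_fixture()
  fras <- lapply(s$units, compute_fra, fra_trials = s$trials)
  ps <- population_sparseness(fras)
  expect_gt(ps, 0)
  expect_lt(ps, 1)
  expect_equal(ps, sum(vapply(fras, function(f) sum(f$sig), 0L)) / (4 * 20))
  # permutation invariance over units
  expect_equal(population_sparseness(rev(fras)), ps)
  # constructed extremes
  f_all <- fras[[1]]
  f_all$sig <- rep(TRUE, 20)
  f_none <- fras[[1]]
  f_none$sig <- rep(FALSE, 20)
  expect_equal(population_sparseness(list(f_all)), 1)
  expect_equal(population_sparseness(list(f_none)), 0)
  expect_error(population_sparseness(list()), "empty")
})

test_that("best-frequency distance to the Go tone is in octaves", {
  s <- fra_fixture()
  f <- compute_fra(s$units[[1]], s$trials)
  f$best_frequency <- 7070
  expect_equal(bf_distance_to_go(f), 0)
  f$best_frequency <- 14140
  expect_equal(bf_distance_to_go(f), 1)
  f$best_frequency <- 10000
  expect_equal(bf_distance_to_go(f), log2(10000 / 7070), tolerance = 1e-9)
  f$best_frequency <- NA_real_
  expect_true(is.na(bf_distance_to_go(f)))
})

test_that("pairwise d-prime matches hand-computable cases and invariances", {
  # two frequencies, two trials each: rates [1,1] vs [3,3] -> d' = 1
  tt <- data.frame(
    trial_id = 1:4, t_onset = c(1, 3, 5, 7), freq = c(8000, 8000, 12000, 12000),
    level = 62, category = "probe", task = "probe", tone_dur = 0.1,
    outcome = "unclassified", lick_count = 0L, first_lick_latency = NA_real_
  )
  mk_unit <- function(rates) {
    # `rates` per trial over the 0.15 s window -> rates * 0.15 spikes, evenly placed
    spikes <- unlist(lapply(seq_len(4), function(i) {
      n <- round(rates[i] * 0.15)
      tt$t_onset[i] + seq(0.01, 0.14, length.out = n)
    }))
    unit("u", sort(spikes))
  }
  u <- mk_unit(c(1, 1, 3, 3) / 0.15)
  pd <- pairwise_dprime(u, tt, learned_range = c(7000, 15000))
  expect_equal(pd$d[1, 2], 1, tolerance = 1e-9)
  expect_equal(diag(pd$d), c(0, 0))
  expect_equal(pd$d, t(pd$d))
  expect_equal(pd$mean_learned, 1, tolerance = 1e-9)

  # identical trial sets: zero numerator and denominator -> 0 with warning
  u_same <- mk_unit(c(2, 2, 2, 2) / 0.15)
  expect_warning(pd0 <- pairwise_dprime(u_same, tt, learned_range = c(7000, 15000)), "zero")
  expect_equal(pd0$d[1, 2], 0)

  # scale invariance: spike trains scaled by an integer factor
  u3 <- mk_unit(3 * c(1, 1, 3, 3) / 0.15)
  pd3 <- pairwise_dprime(u3, tt, learned_range = c(7000, 15000))
  expect_equal(pd3$d[1, 2], pd$d[1, 2], tolerance = 1e-9)
})

test_that("pairwise d-prime grows with the planted rate separation", {
  gains <- c(5, 20, 60)
  vals <- vapply(gains, function(g) {
    s <- simulate_fra_protocol(
      unit_params(
        n_units = 1, baseline_rate = 4, evoked_gain = g,
        bf_log2 = log2(10), tuning_sd_oct = 0.35, gain_noise_cv = 0
      ),
      seed = 71 # matched seed across the gain grid
    )
    suppressWarnings(pairwise_dprime(s$units[[1]], s$trials)$mean_learned)
  }, 0)
  expect_true(all(diff(vals) > 0))
})
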