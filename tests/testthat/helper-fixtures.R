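# Shared fixtures, all built in code at test time.

# Minimal hand-built trial table with evenly spaced onsets.
make_trials <- function(n, category = rep("go", n), task = rep("easy", n),
                        freq = NULL, iti = 8, tone_dur = 0.1, level = 72) {
  if (is.null(freq)) {
    freq <- ifelse(category == "go", 7070, 14140)
  }
  data.frame(
    trial_id = seq_len(n),
    t_onset = 1 + (seq_len(n) - 1) * iti,
    freq = freq, level = level, category = category, task = task,
    tone_dur = tone_dur, outcome = "unclassified", lick_count = 0L,
    first_lick_latency = NA_real_, stringsAsFactors = FALSE
  )
}

# Homogeneous-Poisson unit over [0, t_end] at `rate` Hz.
poisson_unit <- function(rate, t_end, seed, id = "u001") {
  set.seed(seed)
  n <- rpois(1, rate * t_end)
  unit(unit_id = id, spike_times = sort(runif(n, 0, t_end)))
}

# Brute-force Mann-Whitney AUC oracle: all ordered pairs, ties credited 0.5.
auc_bruteforce <- function(a, b) {
  tot <- 0
  for (x in a) {
    for (y in b) {
      tot <- tot + (y > x) + 0.5 * (y == x)
    }
  }
  tot / (length(a) * length(b))
}

# A small valid synthetic session reused across io/pipeline tests.
small_session <- function(seed = 2) {
  simulate_session(
    behavior_params(n_trials = 40, d_easy = 2, c_bias = -0.3),
    unit_params(n_units = 3, evoked_gain = 25, choice_gain = 5),
    seed = seed,
    meta = list(name = "fixture")
  )
}

expect_no_violations <- function(session) {
  expect_length(validate_session(session), 0)
}

# The protocol pure-tone frequency grid, rebuilt independently for
# constructed FRA objects.
FRA_FREQS_TEST <- 4000 * 2^(0.1661 * (0:19))
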