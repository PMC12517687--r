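# Synthetic Go/No-Go sessions with planted, recoverable structure.
#
# Behavior follows the equal-variance signal-detection model with the
# convention P(lick | go) = Phi(d/2 - c) and P(lick | nogo) = Phi(-d/2 - c),
# so the planted (d, c) are exactly the quantities the behavioral estimators
# recover. Spiking is an inhomogeneous Poisson process per unit:
#   rate(t) = baseline
#           + g_trial * evoked_gain * G(freq) * kernel(t)   (tuned transient)
#           + choice_gain * 1[lick trial] * 1[t in choice window]
# with G Gaussian in log2 frequency (peak 1), an alpha-shaped kernel
# (t/tau) exp(1 - t/tau) shifted by the evoked latency, a level-dependent
# gain monotone in dB SPL, and per-trial multiplicative gain noise (gamma,
# mean 1, CV = gain_noise_cv) on the evoked term only, so the planted choice
# step stays exact. Evoked and choice spikes are drawn by thinning with the
# analytic rate maximum as ceiling; all randomness flows from one seeded
# generator per call.

#' Behavioral simulation parameters
#'
#' Defaults emulate an expert head-fixed session: 100 ms tones, a 2 s
#' response window anchored at tone offset, 6-8 s inter-trial intervals,
#' no-go probability 0.45 and probe probability 0.10 (five probe tones at 2%
#' each), with planted sensitivities typical of learned performance.
#'
#' @param d_easy,d_hard planted sensitivities (unitless).
#' @param c_bias planted criterion (negative = liberal).
#' @param n_trials trial count.
#' @param p_nogo,p_probe category probabilities (`p_nogo + p_probe <= 1`).
#' @param lick_latency_mean,lick_latency_sd first-lick latency from the
#'   window anchor (s).
#' @param licks_per_response_mean mean lick count on response trials; must
#'   be at least `lick_threshold`.
#' @param iti_range inter-trial onset interval (s), length 2.
#' @param tone_dur tone duration (s).
#' @param response_window response-window length (s).
#' @param window_anchor `"offset"` or `"onset"`.
#' @param lick_threshold licks required to count as a response.
#' @return list of class `behavior_params`.
#' @export
behavior_params <- function(d_easy = 2.5, d_hard = 1.2, c_bias = 0,
                            n_trials = 300, p_nogo = 0.45, p_probe = 0.10,
                            lick_latency_mean = 0.35, lick_latency_sd = 0.12,
                            licks_per_response_mean = 6, iti_range = c(6, 8),
                            tone_dur = 0.1, response_window = 2,
                            window_anchor = "offset", lick_threshold = 1) {
  p <- list(
    d_easy = d_easy, d_hard = d_hard, c_bias = c_bias, n_trials = n_trials,
    p_nogo = p_nogo, p_probe = p_probe, lick_latency_mean = lick_latency_mean,
    lick_latency_sd = lick_latency_sd,
    licks_per_response_mean = licks_per_response_mean, iti_range = iti_range,
    tone_dur = tone_dur, response_window = response_window,
    window_anchor = window_anchor, lick_threshold = lick_threshold
  )
  for (f in c("p_nogo", "p_probe")) {
    if (p[[f]] < 0 || p[[f]] > 1) stop("invalid ", f, ": must be in [0, 1]", call. = FALSE)
  }
  if (p$p_nogo + p$p_probe > 1) stop("invalid p_nogo/p_probe: sum > 1", call. = FALSE)
  if (p$n_trials < 1) stop("invalid n_trials: must be >= 1", call. = FALSE)
  for (f in c("lick_latency_mean", "lick_latency_sd", "tone_dur", "response_window")) {
    if (p[[f]] <= 0) stop("invalid ", f, ": must be > 0", call. = FALSE)
  }
  if (p$licks_per_response_mean < p$lick_threshold) {
    stop("invalid licks_per_response_mean: below lick_threshold", call. = FALSE)
  }
  structure(p, class = "behavior_params")
}

#' Unit simulation parameters
#'
#' @param n_units number of units.
#' @param baseline_rate spontaneous rate (Hz).
#' @param evoked_gain peak evoked rate above baseline at the best frequency
#'   (Hz).
#' @param bf_log2 tuning center, log2(kHz); default centered on the easy Go
#'   tone.
#' @param bf_jitter_oct half-width (octaves) of uniform per-unit jitter on
#'   `bf_log2` (0 = identical tuning).
#' @param tuning_sd_oct Gaussian tuning width (octaves).
#' @param evoked_latency transient onset latency (s).
#' @param evoked_decay alpha-kernel time constant tau (s); the kernel peaks
#'   at `evoked_latency + tau`.
#' @param choice_gain firing-rate step on lick trials (Hz).
#' @param choice_onset step onset (s after tone onset), in `[0, 0.6]`.
#' @param choice_dur step duration (s).
#' @param gain_noise_cv CV of the per-trial multiplicative gain on the
#'   evoked term.
#' @return list of class `unit_params`.
#' @export
unit_params <- function(n_units = 30, baseline_rate = 5, evoked_gain = 30,
                        bf_log2 = log2(7.07), bf_jitter_oct = 0,
                        tuning_sd_oct = 0.5, evoked_latency = 0.02,
                        evoked_decay = 0.03, choice_gain = 0,
                        choice_onset = 0.2, choice_dur = 1.0,
                        gain_noise_cv = 0.3) {
  p <- list(
    n_units = n_units, baseline_rate = baseline_rate,
    evoked_gain = evoked_gain, bf_log2 = bf_log2,
    bf_jitter_oct = bf_jitter_oct, tuning_sd_oct = tuning_sd_oct,
    evoked_latency = evoked_latency, evoked_decay = evoked_decay,
    choice_gain = choice_gain, choice_onset = choice_onset,
    choice_dur = choice_dur, gain_noise_cv = gain_noise_cv
  )
  for (f in c("baseline_rate", "evoked_gain", "choice_gain", "gain_noise_cv")) {
    if (p[[f]] < 0) stop("invalid ", f, ": must be >= 0", call. = FALSE)
  }
  if (p$tuning_sd_oct <= 0) stop("invalid tuning_sd_oct: must be > 0", call. = FALSE)
  if (p$choice_onset < 0 || p$choice_onset > 0.6) {
    stop("invalid choice_onset: must be in [0, 0.6]", call. = FALSE)
  }
  if (p$n_units < 1) stop("invalid n_units: must be >= 1", call. = FALSE)
  structure(p, class = "unit_params")
}

level_gain <- function(level_db) {
  clip01((level_db - 22) / 50) # 0.2 at 32 dB ... 1.0 at 72 dB, monotone
}

#' Simulate Go/No-Go behavior
#'
#' Draws trial categories, stimulus frequencies (easy pair 7.07/14.14 kHz,
#' hard pair the exact quarter-octave pair around 10 kHz), lick responses
#' from the equal-variance signal-detection model, and lick trains inside the
#' response window. Outcomes are assigned by [classify_outcomes()] on the
#' generated lick stream, so generator and classifier can never disagree.
#' Probe-trial lick probabilities follow a sigmoid in octave distance from
#' the 10 kHz boundary, scaled by `d_easy`.
#'
#' @param params a [behavior_params()] object.
#' @param seed integer seed; the same seed and parameters reproduce the
#'   identical output.
#' @return list with `trials` (classified trial table), `licks` (sorted
#'   times), and `truth` (planted parameters, realized outcome counts,
#'   seed).
#' @export
simulate_behavior <- function(params, seed = 1) {
  stopifnot(inherits(params, "behavior_params"))
  p <- params
  with_seed(seed, {
    n <- p$n_trials
    u <- stats::runif(n)
    category <- ifelse(u < p$p_nogo, "nogo",
      ifelse(u < p$p_nogo + p$p_probe, "probe", "go")
    )
    task <- ifelse(category == "probe", "probe",
      ifelse(stats::runif(n) < 0.5, "easy", "hard")
    )
    freq <- numeric(n)
    freq[task == "easy" & category == "go"] <- FREQ_GO_EASY_HZ
    freq[task == "easy" & category == "nogo"] <- FREQ_NOGO_EASY_HZ
    freq[task == "hard" & category == "go"] <- FREQ_GO_HARD_HZ
    freq[task == "hard" & category == "nogo"] <- FREQ_NOGO_HARD_HZ
    n_probe <- sum(category == "probe")
    freq[category == "probe"] <- sample(FREQ_PROBES_HZ, n_probe, replace = TRUE)
    d_of <- c(easy = p$d_easy, hard = p$d_hard)
    p_lick <- numeric(n)
    for (tk in c("easy", "hard")) {
      is_go <- task == tk & category == "go"
      is_ng <- task == tk & category == "nogo"
      p_lick[is_go] <- stats::pnorm(d_of[[tk]] / 2 - p$c_bias)
      p_lick[is_ng] <- stats::pnorm(-d_of[[tk]] / 2 - p$c_bias)
    }
    probe_idx <- category == "probe"
    if (any(probe_idx)) {
      x <- log2(freq[probe_idx] / FREQ_BOUNDARY_HZ) # octaves above boundary
      p_lick[probe_idx] <- stats::pnorm(-x * p$d_easy - p$c_bias)
    }
    respond <- stats::runif(n) < p_lick
    onsets <- 1 + cumsum(stats::runif(n, p$iti_range[1], p$iti_range[2]))
    anchor <- onsets + if (p$window_anchor == "offset") p$tone_dur else 0
    licks <- list()
    for (i in which(respond)) {
      first <- clip01(
        stats::rnorm(1, p$lick_latency_mean, p$lick_latency_sd),
        0.03, p$response_window * 0.4
      )
      extra_mean <- p$licks_per_response_mean - p$lick_threshold
      n_licks <- p$lick_threshold + stats::rpois(1, extra_mean)
      gaps <- stats::runif(max(n_licks - 1, 0), 0.08, 0.15)
      t_rel <- first + c(0, cumsum(gaps))
      t_rel <- t_rel[t_rel < p$response_window - 1e-3]
      # the response must stay classifiable: keep at least threshold licks
      while (length(t_rel) < p$lick_threshold) {
        t_rel <- seq(first, by = 0.08, length.out = p$lick_threshold)
      }
      licks[[length(licks) + 1]] <- anchor[i] + t_rel
    }
    licks <- sort(unlist(licks, use.names = FALSE) %||% numeric())
    trials <- data.frame(
      trial_id = seq_len(n), t_onset = onsets, freq = freq,
      level = 72, category = category, task = task, tone_dur = p$tone_dur,
      outcome = "unclassified", lick_count = 0L,
      first_lick_latency = NA_real_, stringsAsFactors = FALSE
    )
    trials <- classify_outcomes(trials, licks,
      lick_threshold = p$lick_threshold,
      response_window = p$response_window, window_anchor = p$window_anchor
    )
    truth <- list(
      behavior_params = unclass(p), seed = seed,
      outcome_counts = as.list(table(trials$outcome)),
      planted = list(d_easy = p$d_easy, d_hard = p$d_hard, c_bias = p$c_bias)
    )
    list(trials = trials, licks = licks, truth = truth)
  })
}

# Thinned inhomogeneous Poisson draw of an alpha-kernel transient of peak
# rate `peak` starting at `t0` (absolute time), time constant tau.
draw_alpha_spikes <- function(t0, peak, tau, span = 10) {
  if (peak <= 0) {
    return(numeric())
  }
  len <- span * tau
  n_cand <- stats::rpois(1, peak * len)
  if (n_cand == 0) {
    return(numeric())
  }
  tc <- stats::runif(n_cand, 0, len)
  r <- (tc / tau) * exp(1 - tc / tau) # alpha kernel, peak 1 at tc = tau
  keep <- stats::runif(n_cand) < r
  t0 + tc[keep]
}

#' Simulate unit spike trains for a trial table
#'
#' See the module header for the rate model. Spike times are global (seconds
#' on the session clock); trials carry the stimulus frequency and level that
#' set the tuned gain, and trials with at least one lick carry the choice
#' step.
#'
#' @param trials trial table (non-empty; uses `t_onset`, `freq`, `level`,
#'   `lick_count`).
#' @param params a [unit_params()] object.
#' @param seed integer seed.
#' @return list with `units` (list of [unit()]) and `truth` (per-unit
#'   realized parameters and the seed).
#' @export
simulate_units <- function(trials, params, seed = 1) {
  stopifnot(inherits(params, "unit_params"))
  if (!nrow(trials)) {
    stop("empty trial table", call. = FALSE)
  }
  p <- params
  with_seed(seed, {
    t_end <- max(trials$t_onset) + 3
    lick_trial <- (trials$lick_count %||% rep(0L, nrow(trials))) >= 1
    x_oct <- log2(trials$freq / 1000) # log2 kHz
    lvl <- level_gain(trials$level %||% rep(72, nrow(trials)))
    units <- vector("list", p$n_units)
    truth_units <- vector("list", p$n_units)
    shape <- if (p$gain_noise_cv > 0) 1 / p$gain_noise_cv^2 else Inf
    for (k in seq_len(p$n_units)) {
      bf_k <- p$bf_log2 + if (p$bf_jitter_oct > 0) {
        stats::runif(1, -p$bf_jitter_oct, p$bf_jitter_oct)
      } else {
        0
      }
      tuning <- exp(-(x_oct - bf_k)^2 / (2 * p$tuning_sd_oct^2))
      n_base <- stats::rpois(1, p$baseline_rate * t_end)
      spikes <- sort(stats::runif(n_base, 0, t_end))
      ev <- list()
      for (i in seq_len(nrow(trials))) {
        g <- if (is.finite(shape)) stats::rgamma(1, shape = shape, rate = shape) else 1
        peak <- p$evoked_gain * tuning[i] * lvl[i] * g
        ev[[i]] <- draw_alpha_spikes(
          trials$t_onset[i] + p$evoked_latency, peak, p$evoked_decay
        )
        if (p$choice_gain > 0 && lick_trial[i]) {
          n_ch <- stats::rpois(1, p$choice_gain * p$choice_dur)
          ev[[i]] <- c(ev[[i]], trials$t_onset[i] + p$choice_onset +
            stats::runif(n_ch, 0, p$choice_dur))
        }
      }
      spikes <- sort(c(spikes, unlist(ev, use.names = FALSE)))
      units[[k]] <- unit(
        unit_id = sprintf("u%03d", k), spike_times = spikes,
        depth = 600 + 20 * k, region = "AUDp", layer = "L5/6"
      )
      truth_units[[k]] <- list(unit_id = sprintf("u%03d", k), bf_log2 = bf_k)
    }
    list(
      units = units,
      truth = list(unit_params = unclass(p), seed = seed, units = truth_units)
    )
  })
}

#' Simulate a complete engaged session
#'
#' Behavior plus spiking in one call; the ground truth of both stages is
#' stored in `meta$truth`.
#'
#' @param bparams a [behavior_params()] object.
#' @param uparams a [unit_params()] object.
#' @param seed integer seed (behavior and units draw from sub-seeds derived
#'   from it).
#' @param meta extra metadata merged into the session's `meta`.
#' @return a [gng_session()].
#' @export
simulate_session <- function(bparams = behavior_params(),
                             uparams = unit_params(), seed = 1,
                             meta = list()) {
  beh <- simulate_behavior(bparams, seed = derive_seed(seed, 1))
  spk <- simulate_units(beh$trials, uparams, seed = derive_seed(seed, 2))
  gng_session(
    trials = beh$trials, licks = beh$licks, units = spk$units,
    meta = c(
      list(
        protocol = "headfixed", seed = seed,
        truth = list(behavior = beh$truth, units = spk$truth)
      ),
      meta
    )
  )
}

#' Simulate a passive pure-tone (frequency-response area) session
#'
#' 20 frequencies (4 kHz upward in 0.1661-octave steps) x 5 sound levels
#' (32-72 dB SPL) x 16 repetitions in randomized order, 100 ms tones, 1 s
#' inter-onset interval, no licking. Spiking uses the same rate model as
#' [simulate_units()] with the level-dependent gain (monotone in dB).
#'
#' @param params a [unit_params()] object.
#' @param seed integer seed.
#' @return a [gng_session()] with `meta$protocol = "fra"`.
#' @export
simulate_fra_protocol <- function(params = unit_params(), seed = 1) {
  stopifnot(inherits(params, "unit_params"))
  grid <- expand.grid(
    freq = FRA_FREQS_HZ, level = FRA_LEVELS_DB,
    rep = seq_len(FRA_N_REPS), KEEP.OUT.ATTRS = FALSE
  )
  order_idx <- with_seed(derive_seed(seed, 1), sample.int(nrow(grid)))
  grid <- grid[order_idx, , drop = FALSE]
  n <- nrow(grid)
  trials <- data.frame(
    trial_id = seq_len(n),
    t_onset = 1 + (seq_len(n) - 1) * 1.0,
    freq = grid$freq, level = grid$level,
    category = "probe", task = "probe", tone_dur = 0.1,
    outcome = "unclassified", lick_count = 0L,
    first_lick_latency = NA_real_, stringsAsFactors = FALSE
  )
  spk <- simulate_units(trials, params, seed = derive_seed(seed, 2))
  gng_session(
    trials = trials, licks = numeric(), units = spk$units,
    meta = list(
      protocol = "fra", seed = seed,
      truth = list(units = spk$truth)
    )
  )
}
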