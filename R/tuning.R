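# Passive-listening frequency-response-area analysis. All tuning metrics are
# evaluated at a single analysis level (62 dB SPL by default -- close to the
# 72 dB task level while avoiding ceiling effects).

#' Compute a frequency-response area
#'
#' Mean firing rate per (frequency, level) cell over the response window
#' (tone onset to 50 ms after tone offset, i.e. `[0, 0.15)` s for 100 ms
#' tones), with per-frequency significance at the analysis level from a
#' one-sided signed-rank test of per-trial evoked vs baseline rates. The best
#' frequency is the significant frequency with the maximal rate at the
#' analysis level.
#'
#' @param unit a [unit()].
#' @param fra_trials trial table of the pure-tone protocol (columns `freq`,
#'   `level`, `t_onset`, `tone_dur`).
#' @param response_window evoked window (s), default `c(0, 0.15)`.
#' @param baseline_window baseline window (s), default `c(-0.2, -0.05)`.
#' @param analysis_level level (dB SPL) at which significance and BF are
#'   evaluated, default 62.
#' @param alpha per-frequency significance level, default 0.05.
#' @return object of class `fra`: list with `rate` (freq x level matrix,
#'   Hz), `freqs`, `levels`, `sig` (logical per frequency at the analysis
#'   level), `best_frequency` (Hz, `NA` if nothing significant),
#'   `analysis_level`, `alpha`, `responsive` (any significant frequency).
#' @export
compute_fra <- function(unit, fra_trials, response_window = c(0, 0.15),
                        baseline_window = c(-0.2, -0.05),
                        analysis_level = 62, alpha = 0.05) {
  freqs <- sort(unique(fra_trials$freq))
  levels <- sort(unique(fra_trials$level))
  if (!analysis_level %in% levels) {
    stop(sprintf("analysis level %g dB not in protocol levels", analysis_level),
      call. = FALSE
    )
  }
  cells <- table(factor(fra_trials$freq, levels = freqs),
    factor(fra_trials$level, levels = levels)
  )
  if (any(cells == 0)) {
    stop("malformed protocol: empty (freq, level) cell(s)", call. = FALSE)
  }
  rate_of <- function(tt) {
    mean(count_spikes(unit$spike_times, tt$t_onset, response_window)) /
      diff(response_window)
  }
  rate <- matrix(0, length(freqs), length(levels),
    dimnames = list(sprintf("%.1f", freqs), sprintf("%g", levels))
  )
  for (i in seq_along(freqs)) {
    for (j in seq_along(levels)) {
      tt <- fra_trials[fra_trials$freq == freqs[i] & fra_trials$level == levels[j], ]
      rate[i, j] <- rate_of(tt)
    }
  }
  sig <- logical(length(freqs))
  for (i in seq_along(freqs)) {
    tt <- fra_trials[fra_trials$freq == freqs[i] &
      fra_trials$level == analysis_level, ]
    ev <- count_spikes(unit$spike_times, tt$t_onset, response_window) /
      diff(response_window)
    ba <- count_spikes(unit$spike_times, tt$t_onset, baseline_window) /
      diff(baseline_window)
    sig[i] <- signed_rank_greater(ev - ba) < alpha
  }
  lvl_idx <- which(levels == analysis_level)
  bf <- NA_real_
  if (any(sig)) {
    r_an <- rate[, lvl_idx]
    r_an[!sig] <- -Inf
    bf <- freqs[which.max(r_an)]
  }
  structure(
    list(
      rate = rate, freqs = freqs, levels = levels, sig = sig,
      best_frequency = bf, analysis_level = analysis_level, alpha = alpha,
      responsive = any(sig)
    ),
    class = "fra"
  )
}

#' @export
print.fra <- function(x, ...) {
  cat(sprintf(
    "<fra> %d freqs x %d levels, BF = %s Hz, %d significant freq(s) at %g dB\n",
    length(x$freqs), length(x$levels),
    if (is.na(x$best_frequency)) "NA" else sprintf("%.0f", x$best_frequency),
    sum(x$sig), x$analysis_level
  ))
  invisible(x)
}

#' Tuning bandwidth in octaves
#'
#' Counts the significant adjacent frequencies at the analysis level (the
#' largest contiguous significant run containing the best frequency),
#' subtracts the expected number of false positives (`alpha x n_freqs`,
#' floored at zero), and multiplies by the octave step between neighboring
#' frequencies.
#'
#' @param fra an [compute_fra()] object.
#' @param alpha false-positive rate used for the correction (defaults to the
#'   FRA's own alpha).
#' @param octave_step octave distance between adjacent frequencies; by
#'   default the median log2 spacing of the FRA's frequency grid.
#' @return bandwidth in octaves.
#' @export
bandwidth <- function(fra, alpha = NULL, octave_step = NULL) {
  stopifnot(inherits(fra, "fra"))
  alpha <- alpha %||% fra$alpha
  octave_step <- octave_step %||% stats::median(diff(log2(fra$freqs)))
  if (!any(fra$sig) || is.na(fra$best_frequency)) {
    return(0)
  }
  runs <- rle(fra$sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  bf_idx <- which(fra$freqs == fra$best_frequency)
  in_run <- which(runs$values & starts <= bf_idx & ends >= bf_idx)
  n_adj <- if (length(in_run)) runs$lengths[in_run] else 0
  expected_fp <- alpha * length(fra$freqs)
  max(n_adj - expected_fp, 0) * octave_step
}

#' Population sparseness of significant responses
#'
#' Fraction of significant excited (unit x frequency) responses at the
#' analysis level over all units and frequencies.
#'
#' @param fras list of [compute_fra()] objects (>= 1 unit).
#' @return fraction in `[0, 1]`.
#' @export
population_sparseness <- function(fras) {
  if (!length(fras)) {
    stop("empty population", call. = FALSE)
  }
  n_sig <- sum(vapply(fras, function(f) sum(f$sig), 0L))
  n_tot <- sum(vapply(fras, function(f) length(f$sig), 0L))
  n_sig / n_tot
}

#' Octave distance from best frequency to the easy Go tone
#'
#' @param fra an [compute_fra()] object.
#' @param go_freq reference frequency (Hz), default the 7.07 kHz easy Go
#'   tone.
#' @return `|log2(BF / go_freq)|` in octaves; `NA` when the BF is undefined.
#' @export
bf_distance_to_go <- function(fra, go_freq = 7070) {
  if (is.na(fra$best_frequency)) {
    return(NA_real_)
  }
  abs(log2(fra$best_frequency / go_freq))
}

#' Pairwise neural d-prime across pure-tone frequencies
#'
#' For every frequency pair (p, q) at the analysis level, the discriminability
#' is the distance between the mean per-trial firing rates,
#' `|mean(p) - mean(q)|`, divided by the mean cross-trial distance
#' `mean_{i,j} |p_i - q_j|` over all trial pairs. The matrix is symmetric
#' with a zero diagonal and is invariant to rescaling all rates. The summary
#' value is the mean over frequency pairs inside the learned spectrum.
#'
#' @param unit a [unit()].
#' @param fra_trials pure-tone protocol trial table.
#' @param level analysis level (dB SPL), default 62.
#' @param response_window evoked window (s), default `c(0, 0.15)`.
#' @param learned_range frequency span (Hz) whose pairs enter the summary
#'   mean, default `c(7070, 14140)`.
#' @return object of class `pairwise_dprime`: list with `d` (matrix),
#'   `freqs`, `mean_learned`.
#' @export
pairwise_dprime <- function(unit, fra_trials, level = 62,
                            response_window = c(0, 0.15),
                            learned_range = c(7070, 14140)) {
  tt <- fra_trials[fra_trials$level == level, , drop = FALSE]
  freqs <- sort(unique(tt$freq))
  rates <- lapply(freqs, function(f) {
    on <- tt$t_onset[tt$freq == f]
    if (length(on) < 2) {
      stop(sprintf("need >= 2 trials per frequency at %g dB", level), call. = FALSE)
    }
    count_spikes(unit$spike_times, on, response_window) / diff(response_window)
  })
  n <- length(freqs)
  d <- matrix(0, n, n)
  n_degenerate <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- abs(mean(rates[[i]]) - mean(rates[[j]]))
      den <- mean(abs(outer(rates[[i]], rates[[j]], "-")))
      if (den == 0) {
        d[i, j] <- d[j, i] <- 0 # identical trial sets: d' = 0 by convention
        n_degenerate <- n_degenerate + 1L
      } else {
        d[i, j] <- d[j, i] <- num / den
      }
    }
  }
  if (n_degenerate > 0) {
    warning(sprintf(
      "%d frequency pair(s) with zero cross-trial distance set to d' = 0",
      n_degenerate
    ), call. = FALSE)
  }
  in_learned <- freqs >= learned_range[1] & freqs <= learned_range[2]
  mean_learned <- if (sum(in_learned) >= 2) {
    sub <- d[in_learned, in_learned, drop = FALSE]
    mean(sub[upper.tri(sub)])
  } else {
    NA_real_
  }
  structure(
    list(d = d, freqs = freqs, mean_learned = mean_learned, level = level),
    class = "pairwise_dprime"
  )
}
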