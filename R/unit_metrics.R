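# Single-unit selection and firing properties.
#
# Two baseline definitions coexist on purpose: the responsiveness test
# compares against [-0.2, -0.05) s before onset (guard gap against
# anticipatory licking artifacts), while the spontaneous rate uses [-0.2, 0) s.

signed_rank_greater <- function(d, exact_below = 25) {
  d <- d[d != 0] # standard zero-difference exclusion
  if (!length(d)) {
    return(1)
  }
  exact <- length(d) < exact_below && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "greater", exact = exact,
      correct = TRUE
    )$p.value
  )
}

#' Test whether a unit is excited by the tone
#'
#' One-sided (right-tailed) Wilcoxon signed-rank test of per-trial evoked
#' firing rate against per-trial baseline rate. Baseline spans
#' `[-0.2, -0.05)` s before tone onset; the evoked window spans tone onset to
#' 50 ms after tone offset. Units that fail (including suppressed units,
#' which the one-sided direction never flags) are excluded from downstream
#' analyses.
#'
#' @param unit a [unit()].
#' @param trials trial table (uses `t_onset` and `tone_dur`).
#' @param baseline_window,evoked_window length-2 windows (s, relative to
#'   onset); `evoked_window = NULL` uses `[0, tone_dur + 0.05)` per trial.
#' @param alpha significance level (default 0.05).
#' @return list with `is_excited`, `p`, `n_trials`, and the mean
#'   baseline/evoked rates.
#' @export
responsiveness_test <- function(unit, trials, baseline_window = c(-0.2, -0.05),
                                evoked_window = NULL, alpha = 0.05) {
  stopifnot(nrow(trials) >= 10)
  on <- trials$t_onset
  base_rate <- count_spikes(unit$spike_times, on, baseline_window) /
    diff(baseline_window)
  if (is.null(evoked_window)) {
    ev_len <- trials$tone_dur + 0.05
    lo <- findInterval(on, unit$spike_times, left.open = TRUE)
    hi <- findInterval(on + ev_len, unit$spike_times, left.open = TRUE)
    ev_rate <- (hi - lo) / ev_len
  } else {
    ev_rate <- count_spikes(unit$spike_times, on, evoked_window) /
      diff(evoked_window)
  }
  p <- signed_rank_greater(ev_rate - base_rate)
  list(
    is_excited = is.finite(p) && p < alpha, p = p, n_trials = nrow(trials),
    baseline_rate = mean(base_rate), evoked_rate = mean(ev_rate)
  )
}

#' Select auditory-responsive excited units of a session
#'
#' @param session a [gng_session()].
#' @param alpha significance level per unit.
#' @param trials optional trial subset (defaults to all session trials).
#' @return data.frame with `unit_id`, `p`, `is_excited`.
#' @export
responsive_units <- function(session, alpha = 0.05, trials = NULL) {
  trials <- trials %||% session$trials
  res <- lapply(session$units, responsiveness_test, trials = trials, alpha = alpha)
  data.frame(
    unit_id = vapply(session$units, function(u) u$unit_id, ""),
    p = vapply(res, function(r) r$p, 0),
    is_excited = vapply(res, function(r) r$is_excited, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Peri-stimulus time histogram
#'
#' Trial-aligned spike histogram in Hz, optionally smoothed with a Gaussian
#' kernel (sd 5 ms by default). The kernel is normalized to unit mass, so
#' smoothing preserves total spike mass to within edge effects.
#'
#' @param unit a [unit()].
#' @param trials trial table.
#' @param range length-2 window (s, relative to onset), default
#'   `c(-0.2, 0.6)`.
#' @param binsize histogram bin (s), default 0.001.
#' @param smoothing_sd Gaussian smoothing sd (s), default 0.005; `0` disables
#'   smoothing.
#' @return object of class `psth`: list with `t` (bin centers), `rate` (Hz),
#'   `binsize`, `smoothing_sd`, `n_trials`.
#' @export
compute_psth <- function(unit, trials, range = c(-0.2, 0.6), binsize = 0.001,
                         smoothing_sd = 0.005) {
  stopifnot(binsize > 0, nrow(trials) > 0)
  edges <- seq(range[1], range[2], by = binsize)
  if (abs(edges[length(edges)] - range[2]) > 1e-12) {
    edges <- c(edges, edges[length(edges)] + binsize)
  }
  rel <- relative_spikes(unit$spike_times, trials$t_onset, range)
  counts <- if (length(rel)) {
    tabulate(findInterval(rel, edges, left.open = FALSE),
      nbins = length(edges) - 1
    )
  } else {
    integer(length(edges) - 1)
  }
  rate <- counts / (nrow(trials) * binsize)
  if (smoothing_sd > 0) {
    half <- ceiling(4 * smoothing_sd / binsize)
    kt <- (-half:half) * binsize
    kern <- exp(-kt^2 / (2 * smoothing_sd^2))
    kern <- kern / sum(kern)
    padded <- c(rep(0, half), rate, rep(0, half))
    sm <- stats::filter(padded, kern, sides = 2)
    rate <- as.numeric(sm[(half + 1):(half + length(rate))])
  }
  structure(
    list(
      t = edges[-length(edges)] + binsize / 2, rate = rate,
      binsize = binsize, smoothing_sd = smoothing_sd, n_trials = nrow(trials)
    ),
    class = "psth"
  )
}

#' Lifetime sparseness of a response vector
#'
#' `S = (1 - (mean(r)^2 / mean(r^2))) / (1 - 1/n)` over the per-stimulus mean
#' rates `r`; 0 for a dense (uniform) code, 1 for a one-hot response.
#' Invariant to rescaling `r -> k r`.
#'
#' @param r non-negative per-stimulus mean rates (length >= 2).
#' @return sparseness in `[0, 1]`; `NA` if `r` is all zero.
#' @examples
#' lifetime_sparseness(c(1, 3)) # 0.4
#' @export
lifetime_sparseness <- function(r) {
  stopifnot(length(r) >= 2, all(r >= 0))
  if (all(r == 0)) {
    return(NA_real_)
  }
  n <- length(r)
  (1 - mean(r)^2 / mean(r^2)) / (1 - 1 / n)
}

#' Firing properties of an excited unit
#'
#' Spontaneous rate over `[-0.2, 0)` s, evoked rate over
#' `[0, tone_dur + 0.05)` s, fraction of trials whose evoked count strictly
#' exceeds the baseline count, coefficient of variation of per-trial evoked
#' rates, latency to the PSTH peak, minimal latency (median first spike after
#' onset across trials), full width at half maximum of the smoothed PSTH
#' measured above the spontaneous-rate floor, and lifetime sparseness over
#' the learned tones.
#'
#' @param unit a [unit()].
#' @param trials trial table (learned tones identified by `task` in
#'   `easy`/`hard`).
#' @param psth_range,binsize,smoothing_sd passed to [compute_psth()].
#' @return list of class `firing_properties`.
#' @export
firing_properties <- function(unit, trials, psth_range = c(-0.2, 0.6),
                              binsize = 0.001, smoothing_sd = 0.005) {
  on <- trials$t_onset
  tone_dur <- trials$tone_dur
  spont <- count_spikes(unit$spike_times, on, c(-0.2, 0)) / 0.2
  ev_len <- tone_dur + 0.05
  lo <- findInterval(on, unit$spike_times, left.open = TRUE)
  hi <- findInterval(on + ev_len, unit$spike_times, left.open = TRUE)
  ev_counts <- hi - lo
  ev_rate <- ev_counts / ev_len
  base_counts <- count_spikes(unit$spike_times, on, c(-0.2, 0))
  if (sum(ev_counts) == 0) {
    return(structure(list(
      spont_rate = mean(spont), evoked_rate = 0, frac_responsive_trials = 0,
      evoked_cv = NA_real_, latency_to_peak = NA_real_, min_latency = NA_real_,
      fwhm = NA_real_, lifetime_sparseness = NA_real_, absent = TRUE
    ), class = "firing_properties"))
  }
  psth <- compute_psth(unit, trials,
    range = psth_range, binsize = binsize,
    smoothing_sd = smoothing_sd
  )
  ev_mask <- psth$t >= 0 & psth$t < max(ev_len)
  pk <- which.max(ifelse(ev_mask, psth$rate, -Inf))
  latency_to_peak <- psth$t[pk]
  # median across trials of the first spike time after tone onset
  first_spike <- rep(NA_real_, length(on))
  for (i in seq_along(on)) {
    j <- findInterval(on[i], unit$spike_times, left.open = TRUE) + 1
    if (j <= length(unit$spike_times)) {
      fs <- unit$spike_times[j] - on[i]
      if (fs < (if (i < length(on)) on[i + 1] - on[i] else Inf)) {
        first_spike[i] <- fs
      }
    }
  }
  min_latency <- stats::median(first_spike, na.rm = TRUE)
  spont_rate <- mean(spont)
  half_level <- spont_rate + (psth$rate[pk] - spont_rate) / 2
  above <- psth$rate >= half_level
  fwhm <- NA_real_
  if (psth$rate[pk] > spont_rate) {
    left <- pk
    while (left > 1 && above[left - 1]) left <- left - 1
    right <- pk
    while (right < length(above) && above[right + 1]) right <- right + 1
    fwhm <- (right - left + 1) * psth$binsize
  }
  learned <- trials$task %in% c("easy", "hard")
  S <- NA_real_
  if (any(learned)) {
    fr_by_freq <- tapply(ev_rate[learned], trials$freq[learned], mean)
    if (length(fr_by_freq) >= 2 && any(fr_by_freq > 0)) {
      S <- lifetime_sparseness(as.numeric(fr_by_freq))
    }
  }
  structure(list(
    spont_rate = spont_rate,
    evoked_rate = mean(ev_rate),
    frac_responsive_trials = mean(ev_counts > base_counts),
    evoked_cv = stats::sd(ev_rate) / mean(ev_rate),
    latency_to_peak = latency_to_peak,
    min_latency = min_latency,
    fwhm = fwhm,
    lifetime_sparseness = S,
    absent = FALSE
  ), class = "firing_properties")
}
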