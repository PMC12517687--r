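# Time-resolved single-neuron ROC discriminability.
#
# The AUC convention throughout: auc(a, b) = P(B > A) + 0.5 * P(B = A), i.e.
# values above 0.5 mean class b tends to fire more. Traces use 50 ms windows
# advanced in 25 ms steps (a 25 ms-resolution running window), timestamped at
# the window center, then are baseline-adjusted:
# adjusted = (AUC - mean pre-onset AUC) + 0.5, clipped to [0, 1].

# Exact Mann-Whitney AUC with 0.5 tie credit, via midranks.
auc_exact <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  (sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2) / (na * nb)
}

#' Resampled ROC/AUC between two trial classes
#'
#' Mean over `n_iter` resamples (without replacement, `n_sample` trials per
#' class) of the exact Mann-Whitney AUC with ties credited 0.5. With
#' `n_sample` equal to the class sizes and `n_iter = 1` this reduces to the
#' exact AUC.
#'
#' @param counts_a,counts_b per-trial spike counts for the two classes.
#' @param n_sample trials drawn per class per iteration (default 20).
#' @param n_iter resampling iterations (default 100).
#' @param seed integer seed (RNG state is restored afterwards).
#' @return mean AUC in `[0, 1]`.
#' @export
auc_between <- function(counts_a, counts_b, n_sample = 20, n_iter = 100,
                        seed = NULL) {
  if (length(counts_a) < n_sample || length(counts_b) < n_sample) {
    stop(sprintf(
      "each class needs >= %d trials (got a: %d, b: %d)",
      n_sample, length(counts_a), length(counts_b)
    ), call. = FALSE)
  }
  with_seed(seed, {
    vals <- vapply(seq_len(n_iter), function(i) {
      ia <- sample.int(length(counts_a), n_sample)
      ib <- sample.int(length(counts_b), n_sample)
      auc_exact(counts_a[ia], counts_b[ib])
    }, 0)
    mean(vals)
  })
}

# Window-count matrix: trials x bins, half-open windows of length `window`
# advanced by `step` over `range`. Bin timestamps are window centers.
window_counts <- function(spike_times, onsets, range, window, step) {
  starts <- seq(range[1], range[2] - window + 1e-12, by = step)
  centers <- starts + window / 2
  m <- vapply(
    starts,
    function(s0) count_spikes(spike_times, onsets, c(s0, s0 + window)),
    numeric(length(onsets))
  )
  if (length(onsets) == 1) m <- matrix(m, nrow = 1)
  list(counts = m, starts = starts, centers = centers)
}

# AUC per column for one resample: rows 1..n_sample are class a, the rest b.
auc_columns <- function(sub, n_a) {
  n_b <- nrow(sub) - n_a
  r <- apply(sub, 2, rank)
  (colSums(r[(n_a + 1):nrow(sub), , drop = FALSE]) - n_b * (n_b + 1) / 2) /
    (n_a * n_b)
}

baseline_bins <- function(starts, window) {
  starts >= -0.2 - 1e-12 & (starts + window) <= 1e-12
}

adjust_trace <- function(auc, base_mask) {
  if (!any(base_mask)) {
    return(auc)
  }
  clip01((auc - mean(auc[base_mask])) + 0.5)
}

#' Time-resolved AUC trace for one unit
#'
#' Computes the resampled AUC per running window between the two trial
#' classes, baseline-adjusts the trace (mean raw AUC over windows fully
#' inside `[-0.2, 0)` mapped to 0.5, clipped to `[0, 1]`), and (by default)
#' attaches the shuffle null from [shuffle_null()] computed with the same
#' parameters.
#'
#' @param unit a [unit()].
#' @param trials_a,trials_b trial tables of the two classes (class b is the
#'   putatively more active one; AUC > 0.5 means b fires more).
#' @param range analysis window (s, relative to onset), default
#'   `c(-0.2, 0.6)`.
#' @param window,step running-window length and step (s), defaults 0.05 and
#'   0.025.
#' @param n_sample,n_iter resampling parameters as in [auc_between()].
#' @param seed integer seed.
#' @param compute_null attach the shuffle null (default `TRUE`).
#' @param contrast label stored on the trace.
#' @return object of class `auc_trace`: list with `t` (window centers),
#'   `auc` (adjusted), `auc_raw`, `null_mean`, `null_sd`, `window`, `step`,
#'   `contrast`, `n_a`, `n_b`.
#' @export
auc_timecourse <- function(unit, trials_a, trials_b, range = c(-0.2, 0.6),
                           window = 0.05, step = 0.025, n_sample = 20,
                           n_iter = 100, seed = NULL, compute_null = TRUE,
                           contrast = NA_character_) {
  if (nrow(trials_a) < n_sample || nrow(trials_b) < n_sample) {
    stop(sprintf(
      "each class needs >= %d trials (got a: %d, b: %d)",
      n_sample, nrow(trials_a), nrow(trials_b)
    ), call. = FALSE)
  }
  wa <- window_counts(unit$spike_times, trials_a$t_onset, range, window, step)
  wb <- window_counts(unit$spike_times, trials_b$t_onset, range, window, step)
  nbin <- length(wa$starts)
  base_mask <- baseline_bins(wa$starts, window)
  raw <- with_seed(seed, {
    acc <- numeric(nbin)
    for (it in seq_len(n_iter)) {
      ia <- sample.int(nrow(wa$counts), n_sample)
      ib <- sample.int(nrow(wb$counts), n_sample)
      sub <- rbind(wa$counts[ia, , drop = FALSE], wb$counts[ib, , drop = FALSE])
      acc <- acc + auc_columns(sub, n_sample)
    }
    acc / n_iter
  })
  nul <- if (compute_null) {
    shuffle_null(unit, trials_a, trials_b,
      range = range, window = window,
      step = step, n_sample = n_sample, n_iter = n_iter,
      seed = if (is.null(seed)) NULL else derive_seed(seed, 1)
    )
  } else {
    list(mean = rep(NA_real_, nbin), sd = rep(NA_real_, nbin))
  }
  structure(
    list(
      t = wa$centers, auc = adjust_trace(raw, base_mask), auc_raw = raw,
      null_mean = nul$mean, null_sd = nul$sd, window = window, step = step,
      contrast = contrast, n_a = nrow(trials_a), n_b = nrow(trials_b)
    ),
    class = "auc_trace"
  )
}

#' Shuffle null distribution for an AUC trace
#'
#' Repeats the resampled-AUC pipeline with class labels permuted over the
#' union of the two sampled trial sets on every iteration. Each iteration's
#' trace is baseline-adjusted exactly like the real trace; the per-bin mean
#' and standard deviation over iterations define the null band.
#'
#' @inheritParams auc_timecourse
#' @return list with per-bin `mean`, `sd`, and `t` (window centers).
#' @export
shuffle_null <- function(unit, trials_a, trials_b, range = c(-0.2, 0.6),
                         window = 0.05, step = 0.025, n_sample = 20,
                         n_iter = 100, seed = NULL) {
  if (nrow(trials_a) < n_sample || nrow(trials_b) < n_sample) {
    stop(sprintf(
      "each class needs >= %d trials (got a: %d, b: %d)",
      n_sample, nrow(trials_a), nrow(trials_b)
    ), call. = FALSE)
  }
  wa <- window_counts(unit$spike_times, trials_a$t_onset, range, window, step)
  wb <- window_counts(unit$spike_times, trials_b$t_onset, range, window, step)
  base_mask <- baseline_bins(wa$starts, window)
  traces <- with_seed(seed, {
    t(vapply(seq_len(n_iter), function(it) {
      ia <- sample.int(nrow(wa$counts), n_sample)
      ib <- sample.int(nrow(wb$counts), n_sample)
      pool <- rbind(wa$counts[ia, , drop = FALSE], wb$counts[ib, , drop = FALSE])
      perm <- sample.int(2 * n_sample)
      adjust_trace(auc_columns(pool[perm, , drop = FALSE], n_sample), base_mask)
    }, numeric(length(wa$starts))))
  })
  list(
    mean = colMeans(traces),
    sd = apply(traces, 2, stats::sd),
    t = wa$centers
  )
}

#' Discrimination metrics from an AUC trace
#'
#' A bin is significant when its adjusted AUC exceeds `null_mean +
#' 3 * null_sd` (one-sided; baseline adjustment centers the null at 0.5 and
#' the contrasts are directional). Restricted to bins with center `t >= 0`:
#' onset latency is the first significant bin center, duration is
#' `step x (number of significant bins)`, and `max_auc` is the maximal
#' adjusted AUC.
#'
#' @param trace an `auc_trace` (with null attached) from [auc_timecourse()].
#' @param n_sd null threshold in standard deviations (default 3).
#' @return list with `onset_latency` (s, `NA` if never significant),
#'   `max_auc`, `duration` (s), `significant` (any significant bin), and the
#'   per-bin logical `sig_bins`.
#' @export
discrimination_metrics <- function(trace, n_sd = 3) {
  stopifnot(inherits(trace, "auc_trace"))
  if (all(is.na(trace$null_mean))) {
    stop("trace has no shuffle null attached", call. = FALSE)
  }
  sig <- trace$auc > trace$null_mean + n_sd * trace$null_sd
  post <- trace$t >= 0
  sig_post <- sig & post
  onset <- if (any(sig_post)) trace$t[which(sig_post)[1]] else NA_real_
  list(
    onset_latency = onset,
    max_auc = max(trace$auc[post]),
    duration = trace$step * sum(sig_post),
    significant = any(sig_post),
    sig_bins = sig
  )
}

#' Build the trial-class pair(s) for a discriminability contrast
#'
#' `stim_easy` / `stim_hard`: hits vs false alarms within that task.
#' `choice`: false alarms vs correct rejects, one pair per task (metrics are
#' averaged across tasks downstream). `go_vs_nogo` (novice mode): all go vs
#' all no-go trials, one pair per task. Miss and probe trials are never used.
#'
#' @param trials classified trial table.
#' @param contrast one of `stim_easy`, `stim_hard`, `choice`, `go_vs_nogo`.
#' @return list of pairs; each pair is `list(a = trials_a, b = trials_b,
#'   task = label)`. For stimulus contrasts `a` = false alarms, `b` = hits;
#'   for choice `a` = correct rejects, `b` = false alarms; for go_vs_nogo
#'   `a` = no-go, `b` = go.
#' @export
contrast_builder <- function(trials,
                             contrast = c("stim_easy", "stim_hard", "choice", "go_vs_nogo")) {
  contrast <- match.arg(contrast)
  pick <- function(task, outcomes) {
    trials[trials$task == task & trials$outcome %in% outcomes, , drop = FALSE]
  }
  make_pair <- function(a, b, task) {
    if (!nrow(a) || !nrow(b)) {
      stop(sprintf(
        "contrast '%s' (%s task): empty class (a: %d, b: %d trials)",
        contrast, task, nrow(a), nrow(b)
      ), call. = FALSE)
    }
    list(a = a, b = b, task = task)
  }
  switch(contrast,
    stim_easy = list(make_pair(pick("easy", "fa"), pick("easy", "hit"), "easy")),
    stim_hard = list(make_pair(pick("hard", "fa"), pick("hard", "hit"), "hard")),
    choice = lapply(
      c("easy", "hard"),
      function(tk) make_pair(pick(tk, "cr"), pick(tk, "fa"), tk)
    ),
    go_vs_nogo = lapply(c("easy", "hard"), function(tk) {
      make_pair(
        trials[trials$task == tk & trials$category == "nogo", , drop = FALSE],
        trials[trials$task == tk & trials$category == "go", , drop = FALSE],
        tk
      )
    })
  )
}

#' Correlate neurometric AUC with behavioral sensitivity across sessions
#'
#' Pearson correlation between the per-session mean of the units' maximal
#' adjusted AUC and the per-session behavioral d-prime.
#'
#' @param max_auc_by_session numeric vector, one value per session.
#' @param dprime_by_session matching behavioral d-prime values.
#' @return list with `r`, `p`, `n`, and `flag` (`"ok"`, or
#'   `"constant_behavior"` when d-prime does not vary and the correlation is
#'   undefined).
#' @export
auc_vs_behavior <- function(max_auc_by_session, dprime_by_session) {
  stopifnot(length(max_auc_by_session) == length(dprime_by_session))
  if (length(max_auc_by_session) < 3) {
    stop("need at least 3 sessions", call. = FALSE)
  }
  if (stats::sd(dprime_by_session) < 1e-12 || stats::sd(max_auc_by_session) < 1e-12) {
    return(list(r = NA_real_, p = NA_real_, n = length(max_auc_by_session),
      flag = "constant_behavior"
    ))
  }
  ct <- stats::cor.test(max_auc_by_session, dprime_by_session, method = "pearson")
  list(
    r = unname(ct$estimate), p = ct$p.value,
    n = length(max_auc_by_session), flag = "ok"
  )
}
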