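# Behavioral signal-detection analysis for the Go/No-Go task.
#
# Sensitivity and bias follow the equal-variance Gaussian model:
#   d' = z(hit rate) - z(false-alarm rate)
#   c  = -0.5 * (z(hit rate) + z(false-alarm rate))
# with rates clipped to [0.01, 0.99] before the probit transform so d' stays
# finite (the clipping is symmetric, which keeps d'(h,f) = -d'(f,h)).

clip_rate <- function(p) clip01(p, 0.01, 0.99)

#' Signal-detection sensitivity (d-prime)
#'
#' @param hit_rate,fa_rate probabilities in `[0, 1]`; clipped to
#'   `[0.01, 0.99]` before the probit transform. Vectorized.
#' @return d-prime, `qnorm(hit) - qnorm(fa)` on the clipped rates.
#' @examples
#' dprime(0.99, 0.01) # 2 * qnorm(0.99) = 4.6527
#' @export
dprime <- function(hit_rate, fa_rate) {
  stop_if_nan(hit_rate, "hit rate")
  stop_if_nan(fa_rate, "false-alarm rate")
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1), all(fa_rate >= 0 & fa_rate <= 1))
  stats::qnorm(clip_rate(hit_rate)) - stats::qnorm(clip_rate(fa_rate))
}

#' Signal-detection criterion (response bias)
#'
#' Negative values indicate a liberal criterion (over-licking).
#'
#' @inheritParams dprime
#' @return criterion `c = -0.5 * (qnorm(hit) + qnorm(fa))` on clipped rates.
#' @export
criterion_bias <- function(hit_rate, fa_rate) {
  stop_if_nan(hit_rate, "hit rate")
  stop_if_nan(fa_rate, "false-alarm rate")
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1), all(fa_rate >= 0 & fa_rate <= 1))
  -0.5 * (stats::qnorm(clip_rate(hit_rate)) + stats::qnorm(clip_rate(fa_rate)))
}

#' Classify trial outcomes from the lick stream
#'
#' Counts licks in the half-open response window anchored at tone onset or
#' offset and labels each trial: go trials reaching `lick_threshold` licks are
#' hits (else misses), no-go trials false alarms (else correct rejects), and
#' probe trials keep the label `probe` (their lick flag is `probe_lick`).
#' Response windows overlapping the next trial onset are truncated there with
#' a warning. `first_lick_latency` is measured from tone onset.
#'
#' @param trials trial table (see [gng_session()]).
#' @param licks numeric lick times (s).
#' @param lick_threshold minimum lick count that counts as a response
#'   (1 for the head-fixed protocol, 5 for the home-cage protocol).
#' @param response_window response-window length (s), default 2.
#' @param window_anchor `"offset"` (default) or `"onset"`.
#' @return the trial table with `outcome`, `lick_count`,
#'   `first_lick_latency`, and logical `probe_lick` filled in.
#' @export
classify_outcomes <- function(trials, licks, lick_threshold = 1,
                              response_window = 2,
                              window_anchor = c("offset", "onset")) {
  window_anchor <- match.arg(window_anchor)
  stopifnot(response_window > 0, lick_threshold >= 1)
  tr <- trials
  n <- nrow(tr)
  anchor <- tr$t_onset + if (window_anchor == "offset") tr$tone_dur else 0
  win_end <- anchor + response_window
  next_onset <- c(tr$t_onset[-1], Inf)
  truncated <- win_end > next_onset
  if (any(truncated)) {
    warning(sprintf(
      "%d response window(s) truncated at the next trial onset", sum(truncated)
    ), call. = FALSE)
    win_end <- pmin(win_end, next_onset)
  }
  licks <- sort(licks)
  lo <- findInterval(anchor, licks, left.open = TRUE)
  hi <- findInterval(win_end, licks, left.open = TRUE)
  tr$lick_count <- as.integer(hi - lo)
  first <- rep(NA_real_, n)
  has <- tr$lick_count > 0
  first[has] <- licks[lo[has] + 1] - tr$t_onset[has]
  tr$first_lick_latency <- first
  responded <- tr$lick_count >= lick_threshold
  tr$outcome <- ifelse(tr$category == "go", ifelse(responded, "hit", "miss"),
    ifelse(tr$category == "nogo", ifelse(responded, "fa", "cr"), "probe")
  )
  tr$probe_lick <- ifelse(tr$category == "probe", responded, NA)
  tr
}

rates_from_outcomes <- function(outcomes) {
  n_go <- sum(outcomes %in% c("hit", "miss"))
  n_nogo <- sum(outcomes %in% c("fa", "cr"))
  list(
    hit = if (n_go) sum(outcomes == "hit") / n_go else NA_real_,
    fa = if (n_nogo) sum(outcomes == "fa") / n_nogo else NA_real_,
    n_go = n_go, n_nogo = n_nogo
  )
}

#' Running d-prime over trial bins
#'
#' Slides a window of `window` trials in steps of `step` over the trial
#' sequence; within each bin, hit and false-alarm rates are computed per task
#' from that bin's go/no-go trials and converted to d-prime. Bins lacking
#' either category for a task give `NA` for that task.
#'
#' @param trials classified trial table.
#' @param window bin size in trials (default 25).
#' @param step step in trials (default 25).
#' @return data.frame with `trial_index` (bin center, in trials), `task`,
#'   `n_go`, `n_nogo`, `dprime`.
#' @export
running_dprime <- function(trials, window = 25, step = 25) {
  stopifnot(window >= 10, step >= 1)
  n <- nrow(trials)
  starts <- seq(1, max(1, n - window + 1), by = step)
  tasks <- intersect(c("easy", "hard"), unique(trials$task))
  out <- list()
  for (s0 in starts) {
    idx <- s0:min(n, s0 + window - 1)
    for (tk in tasks) {
      oc <- trials$outcome[idx][trials$task[idx] == tk]
      r <- rates_from_outcomes(oc)
      d <- if (r$n_go > 0 && r$n_nogo > 0) dprime(r$hit, r$fa) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        trial_index = mean(idx), task = tk,
        n_go = r$n_go, n_nogo = r$n_nogo, dprime = d,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Fit a sigmoid psychometric function
#'
#' Least-squares fit of `S(t) = a / (1 + exp(-(t - b) / c))` to
#' unity-normalized lick rates, with `t = log2(freq / 1 kHz)`. The response
#' direction is auto-detected from the rank correlation between `t` and the
#' lick rates; falling curves are fitted on the mirrored axis (`t -> -t`) and
#' the inflection `b` is mapped back to the original axis. Initialization is
#' deterministic (a = max rate, b = abscissa nearest half-max, c = span/10),
#' so identical inputs give identical fits.
#'
#' @param freqs tone frequencies (Hz), at least 4 distinct values.
#' @param lick_rates lick rate per frequency, normalized to peak 1.
#' @return an object of class `psychometric_fit`: list with `a`, `b`
#'   (log2 kHz, original axis), `c` (steepness, log2 kHz), `direction`
#'   (`+1` rising, `-1` falling), `residual_sse`, `n_points`, `converged`,
#'   `degenerate`, and `fitted`.
#' @export
fit_psychometric <- function(freqs, lick_rates) {
  stopifnot(length(freqs) == length(lick_rates))
  if (length(unique(freqs)) < 4) {
    stop("need at least 4 distinct frequencies", call. = FALSE)
  }
  t_raw <- log2(freqs / 1000)
  rho <- suppressWarnings(stats::cor(t_raw, lick_rates, method = "spearman"))
  degenerate <- !is.finite(rho) || stats::sd(lick_rates) < 1e-12
  direction <- if (!degenerate && rho < 0) -1 else 1
  t <- direction * t_raw
  o <- order(t)
  t <- t[o]
  y <- lick_rates[o]
  a0 <- max(y)
  b0 <- t[which.min(abs(y - a0 / 2))]
  c0 <- max(diff(range(t)) / 10, 1e-3)
  fit <- NULL
  converged <- FALSE
  if (!degenerate) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a / (1 + exp(-(t - b) / c)),
        start = list(a = a0, b = b0, c = c0),
        lower = c(a = 1e-6, b = min(t) - 2, c = 1e-6),
        upper = c(a = 1.5, b = max(t) + 2, c = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    converged <- !is.null(fit)
  }
  if (!converged) {
    return(structure(
      list(
        a = NA_real_, b = NA_real_, c = NA_real_, direction = direction,
        residual_sse = NA_real_, n_points = length(t), converged = FALSE,
        degenerate = degenerate, fitted = rep(NA_real_, length(t))
      ),
      class = "psychometric_fit"
    ))
  }
  cf <- stats::coef(fit)
  structure(
    list(
      a = unname(cf["a"]),
      b = unname(direction * cf["b"]), # back on the original log2-frequency axis
      c = unname(cf["c"]),
      direction = direction,
      residual_sse = sum(stats::resid(fit)^2),
      n_points = length(t),
      converged = TRUE,
      degenerate = FALSE,
      fitted = stats::fitted(fit)[order(o)]
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<psychometric_fit> not converged",
      if (x$degenerate) "(degenerate input)" else "", "\n"
    )
  } else {
    cat(sprintf(
      "<psychometric_fit> a=%.4f b=%.4f c=%.4f (dir %+d, sse %.3g, n=%d)\n",
      x$a, x$b, x$c, x$direction, x$residual_sse, x$n_points
    ))
  }
  invisible(x)
}

#' Session-level behavioral summary
#'
#' Computes per-task d-prime and pooled criterion on the last `last_k` trials
#' of each task, the coefficient of variation of the running d-prime series,
#' per-trial lick latency and count, and the inter-trial onset interval
#' grouped by the previous trial's outcome. Probe trials never enter the
#' rates.
#'
#' @param trials classified trial table.
#' @param last_k how many final trials per task define the endpoint rates
#'   (default 100; use `Inf` for the whole session).
#' @param run_window,run_step passed to [running_dprime()].
#' @return list of class `behavior_summary`.
#' @export
behavior_summary <- function(trials, last_k = 100, run_window = 25,
                             run_step = 25) {
  stopifnot("outcome" %in% names(trials))
  endpoint <- function(tk) {
    tt <- trials[trials$task == tk & trials$category %in% c("go", "nogo"), ]
    if (!nrow(tt)) {
      return(list(d = NA_real_, c = NA_real_, hit = NA_real_, fa = NA_real_))
    }
    k <- min(nrow(tt), last_k)
    tt <- tt[(nrow(tt) - k + 1):nrow(tt), ]
    r <- rates_from_outcomes(tt$outcome)
    if (r$n_go == 0 || r$n_nogo == 0) {
      return(list(d = NA_real_, c = NA_real_, hit = r$hit, fa = r$fa))
    }
    list(d = dprime(r$hit, r$fa), c = criterion_bias(r$hit, r$fa), hit = r$hit, fa = r$fa)
  }
  easy <- endpoint("easy")
  hard <- endpoint("hard")
  crit <- mean(c(easy$c, hard$c), na.rm = TRUE)
  run <- if (nrow(trials) >= run_window) {
    running_dprime(trials, window = run_window, step = run_step)
  } else {
    NULL
  }
  cv_d <- NA_real_
  if (!is.null(run)) {
    dd <- run$dprime[is.finite(run$dprime)]
    if (length(dd) >= 2 && abs(mean(dd)) > 1e-12) {
      cv_d <- stats::sd(dd) / abs(mean(dd))
    } else if (length(dd) >= 2) {
      cv_d <- 0
    }
  }
  prev <- c(NA, trials$outcome[-nrow(trials)])
  iti <- c(NA, diff(trials$t_onset))
  iti_by_prev <- tapply(iti, prev, mean, na.rm = TRUE)
  structure(
    list(
      d_easy = easy$d, d_hard = hard$d,
      hit_easy = easy$hit, fa_easy = easy$fa,
      hit_hard = hard$hit, fa_hard = hard$fa,
      criterion = crit, cv_d = cv_d,
      running = run,
      lick_latency = trials$first_lick_latency,
      lick_count = trials$lick_count,
      iti_by_prev_outcome = iti_by_prev,
      last_k = last_k
    ),
    class = "behavior_summary"
  )
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf(
    "<behavior_summary> d'(easy)=%.3f d'(hard)=%.3f criterion=%.3f CV(d')=%.3f\n",
    x$d_easy, x$d_hard, x$criterion, x$cv_d
  ))
  invisible(x)
}
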