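# Population decoding of hit vs correct-reject activity.
#
# The decoder is a shared-covariance Gaussian (linear discriminant)
# classifier with Ledoit-Wolf shrinkage of the pooled covariance toward
# scaled identity -- stable at the 20-40 trials x >= 20 units regime these
# sessions live in. Equal class priors are used throughout.

# Ledoit-Wolf (2004) shrinkage of a covariance toward (tr(S)/p) * I.
# X: n x p matrix of observations (already class-centered for pooling).
lw_shrink_cov <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  S <- crossprod(X) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2)
  b2bar <- 0
  for (k in seq_len(n)) {
    xk <- X[k, ]
    b2bar <- b2bar + sum((tcrossprod(xk) - S)^2)
  }
  b2bar <- b2bar / n^2
  b2 <- min(b2bar, d2)
  lambda <- if (d2 > 0) b2 / d2 else 1
  list(sigma = (1 - lambda) * S + lambda * diag(m, p), lambda = lambda)
}

fit_lda <- function(X, y) {
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2)
  mu1 <- colMeans(X[y == classes[1], , drop = FALSE])
  mu2 <- colMeans(X[y == classes[2], , drop = FALSE])
  Xc <- X
  Xc[y == classes[1], ] <- sweep(X[y == classes[1], , drop = FALSE], 2, mu1)
  Xc[y == classes[2], ] <- sweep(X[y == classes[2], , drop = FALSE], 2, mu2)
  sh <- lw_shrink_cov(Xc)
  w <- solve(sh$sigma, mu2 - mu1)
  list(w = w, threshold = sum(w * (mu1 + mu2)) / 2, classes = classes,
    lambda = sh$lambda
  )
}

predict_lda <- function(model, X) {
  score <- as.numeric(X %*% model$w)
  ifelse(score > model$threshold, model$classes[2], model$classes[1])
}

#' Build a population count matrix for decoding
#'
#' Spike counts of the auditory-responsive units over a fixed post-onset
#' window (default the first 200 ms), for hit and correct-reject trials of
#' one task. Sessions with fewer than `min_units` responsive units or fewer
#' than `min_trials` trials in either class are rejected with a reason code
#' rather than an error.
#'
#' @param session a [gng_session()] with classified outcomes.
#' @param task `"easy"` or `"hard"`.
#' @param window count window (s, relative to onset), default `c(0, 0.2)`.
#' @param min_units,min_trials inclusion thresholds (both default 20,
#'   boundary inclusive).
#' @param unit_ids optional character vector of responsive unit ids; by
#'   default units are selected with [responsive_units()].
#' @param alpha responsiveness alpha when `unit_ids` is `NULL`.
#' @return object of class `population_matrix`: list with `counts`
#'   (trials x units), `labels` (`hit`/`cr`), `task`, `window`, `unit_ids`,
#'   `trial_id`, `accepted`, `reason`.
#' @export
build_population <- function(session, task = c("easy", "hard"),
                             window = c(0, 0.2), min_units = 20,
                             min_trials = 20, unit_ids = NULL, alpha = 0.05) {
  task <- match.arg(task)
  if (is.null(unit_ids)) {
    ru <- responsive_units(session, alpha = alpha)
    unit_ids <- ru$unit_id[ru$is_excited]
  }
  units <- Filter(function(u) u$unit_id %in% unit_ids, session$units)
  tr <- session$trials
  keep <- tr$task == task & tr$outcome %in% c("hit", "cr")
  tr <- tr[keep, , drop = FALSE]
  n_hit <- sum(tr$outcome == "hit")
  n_cr <- sum(tr$outcome == "cr")
  reject <- function(reason) {
    structure(
      list(
        counts = NULL, labels = NULL, task = task, window = window,
        unit_ids = vapply(units, function(u) u$unit_id, ""),
        trial_id = tr$trial_id, accepted = FALSE, reason = reason
      ),
      class = "population_matrix"
    )
  }
  if (length(units) < min_units) {
    return(reject(sprintf("units %d < %d", length(units), min_units)))
  }
  if (n_hit < min_trials) {
    return(reject(sprintf("hit trials %d < %d", n_hit, min_trials)))
  }
  if (n_cr < min_trials) {
    return(reject(sprintf("cr trials %d < %d", n_cr, min_trials)))
  }
  counts <- vapply(
    units,
    function(u) count_spikes(u$spike_times, tr$t_onset, window),
    numeric(nrow(tr))
  )
  colnames(counts) <- vapply(units, function(u) u$unit_id, "")
  structure(
    list(
      counts = counts, labels = tr$outcome, task = task, window = window,
      unit_ids = colnames(counts), trial_id = tr$trial_id, accepted = TRUE,
      reason = NA_character_
    ),
    class = "population_matrix"
  )
}

#' @export
print.population_matrix <- function(x, ...) {
  if (!x$accepted) {
    cat("<population_matrix> rejected:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<population_matrix> %s task, %d trials (%d hit / %d cr) x %d units\n",
      x$task, nrow(x$counts), sum(x$labels == "hit"), sum(x$labels == "cr"),
      ncol(x$counts)
    ))
  }
  invisible(x)
}

#' Held-out LDA decoding accuracy
#'
#' Per repeat: hold out `n_holdout_per_class` random trials per class, fit
#' the shrinkage LDA on the remainder, and score the held-out trials.
#' Accuracy is the mean over repeats.
#'
#' @param pm an accepted [build_population()] matrix, or any list with
#'   `counts` and `labels`.
#' @param n_holdout_per_class held-out trials per class (default 10).
#' @param n_repeats random splits (default 100).
#' @param seed integer seed.
#' @return mean held-out accuracy in `[0, 1]`.
#' @export
lda_decode <- function(pm, n_holdout_per_class = 10, n_repeats = 100,
                       seed = NULL) {
  if (isFALSE(pm$accepted)) {
    stop("population matrix was rejected: ", pm$reason, call. = FALSE)
  }
  X <- pm$counts
  y <- pm$labels
  classes <- sort(unique(y))
  stopifnot(length(classes) == 2)
  idx1 <- which(y == classes[1])
  idx2 <- which(y == classes[2])
  if (length(idx1) <= n_holdout_per_class || length(idx2) <= n_holdout_per_class) {
    stop(sprintf(
      "need > %d trials per class (got %d and %d)",
      n_holdout_per_class, length(idx1), length(idx2)
    ), call. = FALSE)
  }
  with_seed(seed, {
    acc <- vapply(seq_len(n_repeats), function(rep) {
      hold <- c(
        sample(idx1, n_holdout_per_class),
        sample(idx2, n_holdout_per_class)
      )
      model <- fit_lda(X[-hold, , drop = FALSE], y[-hold])
      mean(predict_lda(model, X[hold, , drop = FALSE]) == y[hold])
    }, 0)
    mean(acc)
  })
}

#' Time-resolved decoding accuracy
#'
#' Fits an independent LDA decoder on the spike counts of each `bin`-wide
#' window across the trace range (non-overlapping bins by default; pass
#' `step < bin` for a running window).
#'
#' @inheritParams build_population
#' @inheritParams lda_decode
#' @param bin window width (s), default 0.05.
#' @param range trace range (s, relative to onset), default `c(-0.5, 10)`.
#' @param step bin step (s); defaults to `bin`.
#' @return data.frame with `t` (window center) and `accuracy`.
#' @export
decode_timecourse <- function(session, task, bin = 0.05, range = c(-0.5, 10),
                              step = bin, min_units = 20, min_trials = 20,
                              unit_ids = NULL, n_holdout_per_class = 10,
                              n_repeats = 100, seed = NULL) {
  starts <- seq(range[1], range[2] - bin + 1e-12, by = step)
  if (is.null(unit_ids)) {
    ru <- responsive_units(session)
    unit_ids <- ru$unit_id[ru$is_excited]
  }
  acc <- vapply(seq_along(starts), function(i) {
    pm <- build_population(session, task,
      window = c(starts[i], starts[i] + bin),
      min_units = min_units, min_trials = min_trials, unit_ids = unit_ids
    )
    if (!pm$accepted) {
      return(NA_real_)
    }
    lda_decode(pm,
      n_holdout_per_class = n_holdout_per_class,
      n_repeats = n_repeats,
      seed = if (is.null(seed)) NULL else derive_seed(seed, i)
    )
  }, 0)
  data.frame(t = starts + bin / 2, accuracy = acc)
}

#' Decoding latency from a 100 Hz accuracy trace
#'
#' Builds a decoding-accuracy trace sampled at 100 Hz (window of `window` s
#' advanced in 10 ms steps, timestamped at the window center), computes the
#' baseline mean and SD over windows fully inside `baseline_window`, and
#' returns the first post-onset time at which accuracy exceeds
#' `baseline mean + 3 SD`. Sessions that never cross within `search_window`
#' get `NA` (and are excluded from latency summaries).
#'
#' @inheritParams decode_timecourse
#' @param window decoder count-window width (s), default 0.05.
#' @param sample_rate trace sampling rate (Hz), default 100.
#' @param baseline_window baseline span (s), default `c(-0.5, -0.05)`.
#' @param search_window post-onset span searched for the crossing (s),
#'   default `c(0, 0.2)`.
#' @param n_sd threshold in baseline SDs (default 3).
#' @return list with `latency` (s or `NA`), `threshold`, `baseline_mean`,
#'   `baseline_sd`, and the `trace` data.frame.
#' @export
decoding_latency <- function(session, task, window = 0.05, sample_rate = 100,
                             baseline_window = c(-0.5, -0.05),
                             search_window = c(0, 0.2), n_sd = 3,
                             min_units = 20, min_trials = 20, unit_ids = NULL,
                             n_holdout_per_class = 10, n_repeats = 50,
                             seed = NULL) {
  step <- 1 / sample_rate
  range <- c(baseline_window[1], search_window[2] + window)
  trace <- decode_timecourse(session, task,
    bin = window, range = range,
    step = step, min_units = min_units, min_trials = min_trials,
    unit_ids = unit_ids, n_holdout_per_class = n_holdout_per_class,
    n_repeats = n_repeats, seed = seed
  )
  starts <- trace$t - window / 2
  base <- starts >= baseline_window[1] - 1e-12 &
    (starts + window) <= baseline_window[2] + 1e-12
  b_mean <- mean(trace$accuracy[base], na.rm = TRUE)
  b_sd <- stats::sd(trace$accuracy[base], na.rm = TRUE)
  thr <- b_mean + n_sd * b_sd
  post <- trace$t >= search_window[1] & trace$t <= search_window[2] &
    is.finite(trace$accuracy)
  cross <- post & trace$accuracy > thr
  list(
    latency = if (any(cross)) trace$t[which(cross)[1]] else NA_real_,
    threshold = thr, baseline_mean = b_mean, baseline_sd = b_sd,
    trace = trace
  )
}

#' Fisher separation between two trial classes
#'
#' Closed-form maximizer of the between-class / within-class variance ratio
#' over linear projections: `S = (mu1 - mu2)' (Sigma1 + Sigma2 + eps I)^-1
#' (mu1 - mu2)` with direction `w = (Sigma1 + Sigma2 + eps I)^-1
#' (mu1 - mu2)`. The ridge `eps = 1e-6 x mean diagonal` keeps rank-deficient
#' class covariances invertible while leaving well-conditioned problems
#' untouched (S is invariant to common invertible affine maps of both
#' classes in the `eps -> 0` limit).
#'
#' @param x1,x2 trials x units count matrices of the two classes, or pass an
#'   accepted `population_matrix` as `x1` alone.
#' @param eps_scale ridge scale (default 1e-6).
#' @return object of class `separation_result`: list with `S`, `w`, `mu1`,
#'   `mu2`.
#' @export
fisher_separation <- function(x1, x2 = NULL, eps_scale = 1e-6) {
  if (inherits(x1, "population_matrix")) {
    pm <- x1
    if (!pm$accepted) {
      stop("population matrix was rejected: ", pm$reason, call. = FALSE)
    }
    cls <- sort(unique(pm$labels))
    x2 <- pm$counts[pm$labels == cls[2], , drop = FALSE]
    x1 <- pm$counts[pm$labels == cls[1], , drop = FALSE]
  }
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  stopifnot(ncol(x1) == ncol(x2), nrow(x1) >= 2, nrow(x2) >= 2)
  mu1 <- colMeans(x1)
  mu2 <- colMeans(x2)
  W <- stats::cov(x1) + stats::cov(x2)
  eps <- eps_scale * mean(diag(W))
  if (!is.finite(eps) || eps <= 0) eps <- eps_scale
  Wr <- W + diag(eps, ncol(x1))
  dmu <- mu1 - mu2
  w <- solve(Wr, dmu)
  structure(
    list(S = sum(dmu * w), w = w, mu1 = mu1, mu2 = mu2),
    class = "separation_result"
  )
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> S = %.4f (%d units)\n", x$S, length(x$w)))
  invisible(x)
}

#' Single-trial variance per class
#'
#' Each unit's counts are z-scored across all trials of the session; the
#' variance across trials is then computed per unit within each class and
#' averaged over units (equal weight). Units with zero variance across all
#' trials are excluded with a warning.
#'
#' @param pm an accepted [build_population()] matrix.
#' @return named numeric vector, one variance per class.
#' @export
single_trial_variance <- function(pm) {
  if (isFALSE(pm$accepted)) {
    stop("population matrix was rejected: ", pm$reason, call. = FALSE)
  }
  X <- pm$counts
  sds <- apply(X, 2, stats::sd)
  zero <- sds < 1e-12
  if (any(zero)) {
    warning(sprintf("%d zero-variance unit(s) excluded", sum(zero)), call. = FALSE)
    X <- X[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  if (!ncol(X)) {
    stop("all units have zero variance across trials", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  classes <- sort(unique(pm$labels))
  out <- vapply(classes, function(cl) {
    v <- apply(Z[pm$labels == cl, , drop = FALSE], 2, stats::var)
    mean(v)
  }, 0)
  names(out) <- classes
  out
}

#' Robust no-intercept regression of hard-task on easy-task separation
#'
#' Fits `S_hard = beta * S_easy` per group with Huber loss and no intercept.
#'
#' @param separations data.frame with columns `s_easy`, `s_hard`, and
#'   optionally `group`.
#' @return data.frame with `group`, `beta`, `n`; residuals attached as the
#'   `"residuals"` attribute (a list by group).
#' @export
separation_regression <- function(separations) {
  stopifnot(all(c("s_easy", "s_hard") %in% names(separations)))
  if (is.null(separations$group)) separations$group <- "all"
  out <- list()
  resids <- list()
  for (g in unique(separations$group)) {
    d <- separations[separations$group == g, , drop = FALSE]
    if (nrow(d) < 3) {
      stop(sprintf("group '%s': need >= 3 sessions (got %d)", g, nrow(d)),
        call. = FALSE
      )
    }
    if (all(abs(d$s_easy) < 1e-12)) {
      stop(sprintf("group '%s': degenerate all-zero easy separations", g),
        call. = FALSE
      )
    }
    fit <- MASS::rlm(s_hard ~ 0 + s_easy,
      data = d, psi = MASS::psi.huber,
      maxit = 100
    )
    out[[g]] <- data.frame(
      group = g, beta = unname(stats::coef(fit)["s_easy"]),
      n = nrow(d), stringsAsFactors = FALSE
    )
    resids[[g]] <- unname(stats::resid(fit))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "residuals") <- resids
  res
}
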