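#' @keywords internal
"_PACKAGE"

# Protocol constants. The learned Go/No-Go tones sit symmetrically around the
# 10 kHz category boundary: +/-0.5 octaves (easy) and +/-0.125 octaves (hard).
FREQ_BOUNDARY_HZ <- 10000
FREQ_GO_EASY_HZ <- 7070
FREQ_NOGO_EASY_HZ <- 14140
FREQ_GO_HARD_HZ <- FREQ_BOUNDARY_HZ * 2^-0.125 # 9170.04 Hz
FREQ_NOGO_HARD_HZ <- FREQ_BOUNDARY_HZ * 2^0.125 # 10905.08 Hz
FREQ_PROBES_HZ <- c(8490, 9567, 10000, 10440, 11890)

# Passive pure-tone protocol: 20 frequencies from 4 kHz in 0.1661-octave
# steps, five sound levels, 16 repetitions per cell.
FRA_FREQS_HZ <- 4000 * 2^(0.1661 * (0:19))
FRA_LEVELS_DB <- c(32, 42, 52, 62, 72)
FRA_N_REPS <- 16L

OUTCOME_LEVELS <- c("hit", "miss", "fa", "cr", "probe", "unclassified")
REGION_LEVELS <- c("AUDd", "AUDp", "AUDv", "TEa", "other")
LAYER_LEVELS <- c("L5/6", "other")

#' Run code with a locally-seeded RNG
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' seeded operations never perturb surrounding randomness. `seed = NULL` runs
#' `expr` under the ambient RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed (stage/session scoped) from a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k)) %% 2147483647
  }
  as.integer(s)
}

# Count spikes of a sorted spike train in per-trial half-open windows
# [onset + w[1], onset + w[2]). Vectorized over trials.
count_spikes <- function(spike_times, onsets, window) {
  stopifnot(window[2] > window[1])
  lo <- findInterval(onsets + window[1], spike_times, left.open = TRUE)
  hi <- findInterval(onsets + window[2], spike_times, left.open = TRUE)
  hi - lo
}

# Spike times (relative to onset) falling in [w1, w2) per trial; returns one
# concatenated vector of relative times.
relative_spikes <- function(spike_times, onsets, window) {
  out <- vector("list", length(onsets))
  for (i in seq_along(onsets)) {
    lo <- onsets[i] + window[1]
    hi <- onsets[i] + window[2]
    s <- spike_times[spike_times >= lo & spike_times < hi]
    out[[i]] <- s - onsets[i]
  }
  unlist(out, use.names = FALSE)
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_nan <- function(x, what) {
  if (any(is.nan(x) | is.na(x))) {
    stop(sprintf("NaN/NA %s not allowed", what), call. = FALSE)
  }
  invisible(x)
}
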