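#' Construct a recording session
#'
#' A session bundles the per-trial stimulus/outcome table, the lick event
#' stream, the sorted units, and free-form metadata, all on a common time base
#' (seconds; tone onset defines time zero for every trial-aligned analysis,
#' and all analysis windows are half-open `[start, end)`).
#'
#' @param trials data.frame with columns `trial_id`, `t_onset`, `freq`,
#'   `level`, `category` (`go`/`nogo`/`probe`), `task` (`easy`/`hard`/`probe`),
#'   `tone_dur`, `outcome`, `lick_count`, `first_lick_latency`.
#' @param licks numeric vector of lick times (s), sorted ascending.
#' @param units list of units from [unit()].
#' @param meta named list of session-level metadata (e.g. `protocol`, `group`).
#' @return an object of class `gng_session`.
#' @seealso [validate_session()], [save_session()], [load_session()]
#' @export
gng_session <- function(trials, licks = numeric(), units = list(), meta = list()) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  s <- structure(
    list(
      trials = trials,
      licks = as.numeric(licks),
      units = units,
      meta = meta
    ),
    class = "gng_session"
  )
  s
}

#' Construct a single sorted unit
#'
#' @param unit_id identifier (coerced to character).
#' @param spike_times numeric spike times (s), sorted ascending.
#' @param depth recording depth in micrometers.
#' @param region anatomical label; one of `AUDd`, `AUDp`, `AUDv`, `TEa`,
#'   `other`.
#' @param layer `"L5/6"` or `"other"`.
#' @param quality sorter quality label (free text, e.g. `"good"`).
#' @return an object of class `gng_unit`.
#' @export
unit <- function(unit_id, spike_times, depth = NA_real_, region = "other",
                 layer = "L5/6", quality = "good") {
  structure(
    list(
      unit_id = as.character(unit_id),
      spike_times = as.numeric(spike_times),
      depth = as.numeric(depth),
      region = as.character(region),
      layer = as.character(layer),
      quality = as.character(quality)
    ),
    class = "gng_unit"
  )
}

#' @export
print.gng_session <- function(x, ...) {
  cat(sprintf(
    "<gng_session> %d trials, %d licks, %d units\n",
    nrow(x$trials), length(x$licks), length(x$units)
  ))
  scalar <- Filter(function(v) is.atomic(v) && length(v) == 1, x$meta)
  if (length(scalar)) {
    cat("  meta:", paste(names(scalar), unlist(lapply(scalar, format)),
      sep = "=", collapse = ", "
    ), "\n")
  }
  invisible(x)
}

#' @export
print.gng_unit <- function(x, ...) {
  cat(sprintf(
    "<gng_unit %s> %d spikes, region=%s, layer=%s\n",
    x$unit_id, length(x$spike_times), x$region, x$layer
  ))
  invisible(x)
}

TRIAL_COLUMNS <- c(
  "trial_id", "t_onset", "freq", "level", "category", "task",
  "tone_dur", "outcome", "lick_count", "first_lick_latency"
)

#' Validate a session against its structural invariants
#'
#' Pure reporting operation: returns a character vector of violations (empty
#' means valid) and never mutates its input. Checked invariants: required
#' trial columns; finite, non-negative event times; strictly increasing trial
#' onsets; positive frequencies and tone durations; levels within
#' `[0, 120]` dB SPL; outcome/category/region/layer labels from their closed
#' vocabularies; sorted, NaN-free spike trains; and (for
#' `protocol = "strict"`) learned tone frequencies at the protocol values
#' (easy pair 7.07/14.14 kHz, hard pair 0.25 octaves around 10 kHz, within
#' 1 Hz).
#'
#' @param session a [gng_session()].
#' @param protocol `"strict"` enforces the learned-tone frequency values;
#'   `"any"` skips that check.
#' @return character vector of violation messages (length 0 if valid).
#' @export
validate_session <- function(session, protocol = c("any", "strict")) {
  protocol <- match.arg(protocol)
  v <- character()
  tr <- session$trials
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing_cols)) {
    return(sprintf("trials: missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tr)) {
    if (any(!is.finite(tr$t_onset)) || any(tr$t_onset < 0)) {
      v <- c(v, "trials: onsets must be finite and non-negative")
    }
    if (nrow(tr) > 1 && any(diff(tr$t_onset) <= 0)) {
      bad <- which(diff(tr$t_onset) <= 0)[1] + 1
      v <- c(v, sprintf("trials: onsets not strictly increasing at trial_id %s", tr$trial_id[bad]))
    }
    bad_freq <- which(!is.finite(tr$freq) | tr$freq <= 0)
    for (i in bad_freq) {
      v <- c(v, sprintf("trials: non-positive freq at trial_id %s", tr$trial_id[i]))
    }
    if (any(tr$level < 0 | tr$level > 120, na.rm = TRUE)) {
      v <- c(v, "trials: level outside [0, 120] dB SPL")
    }
    if (any(tr$tone_dur <= 0)) {
      v <- c(v, "trials: tone_dur must be positive")
    }
    if (!all(tr$outcome %in% OUTCOME_LEVELS)) {
      v <- c(v, sprintf(
        "trials: unknown outcome label(s): %s",
        paste(setdiff(unique(tr$outcome), OUTCOME_LEVELS), collapse = ", ")
      ))
    }
    if (!all(tr$category %in% c("go", "nogo", "probe"))) {
      v <- c(v, "trials: unknown category label")
    }
    if (!all(tr$task %in% c("easy", "hard", "probe"))) {
      v <- c(v, "trials: unknown task label")
    }
    if (protocol == "strict") {
      learned <- tr[tr$task %in% c("easy", "hard") & tr$category %in% c("go", "nogo"), ]
      expect <- list(
        easy = c(FREQ_GO_EASY_HZ, FREQ_NOGO_EASY_HZ),
        hard = c(FREQ_GO_HARD_HZ, FREQ_NOGO_HARD_HZ)
      )
      for (tk in c("easy", "hard")) {
        f <- unique(learned$freq[learned$task == tk])
        if (length(f) && any(vapply(f, function(x) min(abs(x - expect[[tk]])), 0) > 1)) {
          v <- c(v, sprintf("trials: %s-task frequency off protocol values", tk))
        }
      }
    }
  }
  if (length(session$licks)) {
    if (any(!is.finite(session$licks)) || any(session$licks < 0)) {
      v <- c(v, "licks: times must be finite and non-negative")
    }
    if (is.unsorted(session$licks)) {
      v <- c(v, "licks: times must be sorted ascending")
    }
  }
  for (k in seq_along(session$units)) {
    u <- session$units[[k]]
    st <- u$spike_times
    if (any(is.na(st))) {
      v <- c(v, sprintf("unit %s: NaN spike time at index %d", u$unit_id, which(is.na(st))[1]))
    } else {
      if (length(st) && (any(!is.finite(st)) || any(st < 0))) {
        v <- c(v, sprintf(
          "unit %s: negative/non-finite spike time at index %d",
          u$unit_id, which(!is.finite(st) | st < 0)[1]
        ))
      }
      if (is.unsorted(st)) {
        v <- c(v, sprintf("unit %s: spike times not sorted", u$unit_id))
      }
    }
    if (!u$region %in% REGION_LEVELS) {
      v <- c(v, sprintf("unit %s: unknown region '%s'", u$unit_id, u$region))
    }
    if (!u$layer %in% LAYER_LEVELS) {
      v <- c(v, sprintf("unit %s: unknown layer '%s'", u$unit_id, u$layer))
    }
  }
  ids <- vapply(session$units, function(u) u$unit_id, "")
  if (anyDuplicated(ids)) {
    v <- c(v, "units: duplicated unit_id")
  }
  v
}

#' Assert that a session is valid
#'
#' @param session a [gng_session()].
#' @param protocol passed to [validate_session()].
#' @return the session, invisibly; errors with all violations otherwise.
#' @export
assert_valid_session <- function(session, protocol = "any") {
  v <- validate_session(session, protocol)
  if (length(v)) {
    stop("invalid session:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(session)
}
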