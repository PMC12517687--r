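# End-to-end orchestration: behavior -> units -> auc -> decode -> tuning on
# session directories, with per-stage sub-seeds derived from one master seed
# (stage x session scoped, so reruns of any stage are reproducible in
# isolation). All numeric outputs are written as TSV/JSON with fixed
# formatting; two runs with the same config and seed are byte-identical.

PIPELINE_STAGES <- c("behavior", "units", "auc", "decode", "tuning")

CONFIG_DEFAULTS <- list(
  protocol = "headfixed", # or "educage"
  lick_threshold = NA_real_, # NA: 1 for headfixed, 5 for educage
  response_window = 2,
  window_anchor = "offset",
  last_k = 100,
  run_window = 25,
  run_step = 25,
  alpha = 0.05,
  psth_binsize = 0.001,
  psth_smoothing_sd = 0.005,
  auc_range = c(-0.2, 0.6),
  auc_window = 0.05,
  auc_step = 0.025,
  auc_n_sample = 20,
  auc_n_iter = 100,
  contrasts = c("stim_easy", "stim_hard", "choice"),
  decode_window = c(0, 0.2),
  decode_min_units = 20,
  decode_min_trials = 20,
  decode_holdout = 10,
  decode_repeats = 100,
  latency_sample_rate = 100,
  latency_repeats = 50,
  latency_search = c(0, 0.2),
  tuning_level = 62,
  fra_response_window = c(0, 0.15),
  seed = 1
)

#' Build a resolved pipeline configuration
#'
#' Flat key-value namespace with defaults equal to the protocol values used
#' throughout the package; unknown keys are rejected before any compute.
#'
#' @param ... overrides of the defaults (see `neurodisc:::CONFIG_DEFAULTS`).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS, over)
  if (is.na(cfg$lick_threshold)) {
    cfg$lick_threshold <- if (cfg$protocol == "educage") 5 else 1
  }
  structure(cfg, class = "run_config")
}

fmt_num <- function(x) {
  x <- as.numeric(x)
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- "NA"
  out
}

write_stage_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (cc in names(df)[num]) df[[cc]] <- fmt_num(df[[cc]])
  write_tsv_raw(df, path)
}

write_stage_json <- function(x, path) {
  writeLines(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"),
    path,
    useBytes = TRUE
  )
}

log_msg <- function(..., logfile = NULL) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE, sep = "")
}

stage_behavior <- function(session, cfg, out_dir, seed) {
  tr <- classify_outcomes(session$trials, session$licks,
    lick_threshold = cfg$lick_threshold, response_window = cfg$response_window,
    window_anchor = cfg$window_anchor
  )
  bs <- behavior_summary(tr,
    last_k = cfg$last_k, run_window = cfg$run_window,
    run_step = cfg$run_step
  )
  write_stage_tsv(tr[setdiff(names(tr), "probe_lick")], file.path(out_dir, "trial_outcomes.tsv"))
  write_stage_json(
    list(
      d_easy = bs$d_easy, d_hard = bs$d_hard, criterion = bs$criterion,
      cv_d = bs$cv_d, hit_easy = bs$hit_easy, fa_easy = bs$fa_easy,
      hit_hard = bs$hit_hard, fa_hard = bs$fa_hard,
      mean_lick_latency = mean(bs$lick_latency, na.rm = TRUE),
      iti_by_prev_outcome = as.list(bs$iti_by_prev_outcome)
    ),
    file.path(out_dir, "behavior_summary.json")
  )
  list(trials = tr, summary = bs)
}

stage_units <- function(session, trials, cfg, out_dir, seed) {
  ru <- responsive_units(session, alpha = cfg$alpha, trials = trials)
  rows <- lapply(seq_along(session$units), function(k) {
    u <- session$units[[k]]
    base <- data.frame(
      unit_id = u$unit_id, region = u$region, layer = u$layer,
      p_responsive = ru$p[k], is_excited = ru$is_excited[k],
      stringsAsFactors = FALSE
    )
    if (ru$is_excited[k]) {
      fp <- firing_properties(u, trials,
        binsize = cfg$psth_binsize,
        smoothing_sd = cfg$psth_smoothing_sd
      )
      cbind(base, data.frame(
        spont_rate = fp$spont_rate, evoked_rate = fp$evoked_rate,
        frac_responsive_trials = fp$frac_responsive_trials,
        evoked_cv = fp$evoked_cv, latency_to_peak = fp$latency_to_peak,
        min_latency = fp$min_latency, fwhm = fp$fwhm,
        lifetime_sparseness = fp$lifetime_sparseness
      ))
    } else {
      cbind(base, data.frame(
        spont_rate = NA_real_, evoked_rate = NA_real_,
        frac_responsive_trials = NA_real_, evoked_cv = NA_real_,
        latency_to_peak = NA_real_, min_latency = NA_real_, fwhm = NA_real_,
        lifetime_sparseness = NA_real_
      ))
    }
  })
  props <- do.call(rbind, rows)
  write_stage_tsv(props, file.path(out_dir, "unit_properties.tsv"))
  props
}

stage_auc <- function(session, trials, responsive, cfg, out_dir, seed) {
  keep <- responsive$unit_id[responsive$is_excited]
  units <- Filter(function(u) u$unit_id %in% keep, session$units)
  traces <- list()
  metrics <- list()
  skipped <- character()
  for (ct in cfg$contrasts) {
    pairs <- tryCatch(contrast_builder(trials, ct), error = function(e) NULL)
    if (!is.null(pairs)) {
      pairs <- Filter(
        function(pr) nrow(pr$a) >= cfg$auc_n_sample && nrow(pr$b) >= cfg$auc_n_sample,
        pairs
      )
    }
    if (!length(pairs)) {
      skipped <- c(skipped, ct)
      next
    }
    for (u in units) {
      per_pair <- lapply(seq_along(pairs), function(pi) {
        pr <- pairs[[pi]]
        tr <- auc_timecourse(u, pr$a, pr$b,
          range = cfg$auc_range,
          window = cfg$auc_window, step = cfg$auc_step,
          n_sample = cfg$auc_n_sample, n_iter = cfg$auc_n_iter,
          seed = derive_seed(seed, match(ct, cfg$contrasts), match(
            u$unit_id,
            keep
          ), pi),
          contrast = ct
        )
        list(trace = tr, metrics = discrimination_metrics(tr))
      })
      # choice & novice contrasts: metrics averaged across the task pairs
      m <- list(
        onset_latency = mean(vapply(per_pair, function(x) x$metrics$onset_latency, 0), na.rm = TRUE),
        max_auc = mean(vapply(per_pair, function(x) x$metrics$max_auc, 0)),
        duration = mean(vapply(per_pair, function(x) x$metrics$duration, 0)),
        significant = any(vapply(per_pair, function(x) x$metrics$significant, TRUE))
      )
      metrics[[length(metrics) + 1]] <- data.frame(
        unit_id = u$unit_id, contrast = ct,
        onset_latency = ifelse(is.nan(m$onset_latency), NA_real_, m$onset_latency),
        max_auc = m$max_auc, duration = m$duration, significant = m$significant,
        stringsAsFactors = FALSE
      )
      for (x in per_pair) {
        tr <- x$trace
        traces[[length(traces) + 1]] <- data.frame(
          unit_id = u$unit_id, contrast = ct, t = tr$t, auc = tr$auc,
          null_mean = tr$null_mean, null_sd = tr$null_sd,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(skipped)) {
    message(sprintf(
      "auc: contrast(s) %s skipped (fewer than %d trials in a class)",
      paste(skipped, collapse = ", "), cfg$auc_n_sample
    ))
  }
  if (!length(metrics)) {
    stop("no contrast had enough trials per class", call. = FALSE)
  }
  traces <- do.call(rbind, traces)
  metrics <- do.call(rbind, metrics)
  write_stage_tsv(traces, file.path(out_dir, "auc_traces.tsv"))
  write_stage_tsv(metrics, file.path(out_dir, "auc_metrics.tsv"))
  metrics
}

stage_decode <- function(session, trials, responsive, cfg, out_dir, seed) {
  keep <- responsive$unit_id[responsive$is_excited]
  s2 <- session
  s2$trials <- trials
  out <- list()
  tcs <- list()
  for (tk in c("easy", "hard")) {
    pm <- build_population(s2, tk,
      window = cfg$decode_window,
      min_units = cfg$decode_min_units, min_trials = cfg$decode_min_trials,
      unit_ids = keep
    )
    if (!pm$accepted) {
      out[[tk]] <- list(accepted = FALSE, reason = pm$reason)
      next
    }
    acc <- lda_decode(pm,
      n_holdout_per_class = cfg$decode_holdout,
      n_repeats = cfg$decode_repeats, seed = derive_seed(seed, match(tk, c("easy", "hard")), 1)
    )
    sep <- fisher_separation(pm)
    stv <- suppressWarnings(single_trial_variance(pm))
    lat <- decoding_latency(s2, tk,
      window = cfg$auc_window,
      sample_rate = cfg$latency_sample_rate, search_window = cfg$latency_search,
      min_units = cfg$decode_min_units, min_trials = cfg$decode_min_trials,
      unit_ids = keep, n_holdout_per_class = cfg$decode_holdout,
      n_repeats = cfg$latency_repeats,
      seed = derive_seed(seed, match(tk, c("easy", "hard")), 2)
    )
    out[[tk]] <- list(
      accepted = TRUE, accuracy = acc, separation = sep$S,
      latency = lat$latency,
      single_trial_variance = as.list(stv)
    )
    tcs[[tk]] <- cbind(task = tk, lat$trace)
  }
  write_stage_json(out, file.path(out_dir, "decoding.json"))
  if (length(tcs)) {
    write_stage_tsv(do.call(rbind, tcs), file.path(out_dir, "accuracy_timecourse.tsv"))
  }
  out
}

stage_tuning <- function(session, cfg, out_dir, seed) {
  at_level <- session$trials[session$trials$level == cfg$tuning_level, ]
  ru <- responsive_units(session, alpha = cfg$alpha, trials = at_level)
  keep_units <- Filter(
    function(u) u$unit_id %in% ru$unit_id[ru$is_excited],
    session$units
  )
  if (!length(keep_units)) {
    write_stage_json(
      list(n_units = 0, population_sparseness = NA),
      file.path(out_dir, "population_sparseness.json")
    )
    return(NULL)
  }
  fras <- lapply(keep_units, compute_fra, fra_trials = session$trials,
    response_window = cfg$fra_response_window,
    analysis_level = cfg$tuning_level, alpha = cfg$alpha
  )
  rows <- lapply(seq_along(keep_units), function(k) {
    pd <- suppressWarnings(pairwise_dprime(keep_units[[k]], session$trials,
      level = cfg$tuning_level, response_window = cfg$fra_response_window
    ))
    data.frame(
      unit_id = keep_units[[k]]$unit_id,
      best_frequency = fras[[k]]$best_frequency,
      bandwidth_oct = bandwidth(fras[[k]]),
      bf_to_go_oct = bf_distance_to_go(fras[[k]]),
      mean_pairwise_dprime = pd$mean_learned,
      stringsAsFactors = FALSE
    )
  })
  tbl <- do.call(rbind, rows)
  write_stage_tsv(tbl, file.path(out_dir, "fra_metrics.tsv"))
  write_stage_json(
    list(
      n_units = length(keep_units),
      population_sparseness = population_sparseness(fras)
    ),
    file.path(out_dir, "population_sparseness.json")
  )
  tbl
}

#' Run the full analysis pipeline on one or more sessions
#'
#' Stages: behavior, units, auc, decode (engaged sessions) and tuning
#' (pure-tone sessions, `meta$protocol == "fra"`). Stage failures are caught
#' and recorded per session; later independent stages still run. Every run
#' writes its resolved config and a manifest (package version, seeds,
#' per-stage status) next to the outputs.
#'
#' @param sessions list of [gng_session()] objects and/or session directory
#'   paths; a single session may be passed bare.
#' @param config a [run_config()].
#' @param out_dir output root; one subdirectory per session.
#' @param logfile optional path for the run log (also echoed via
#'   `message()`).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(sessions, config = run_config(), out_dir,
                         logfile = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(sessions, "gng_session") || is.character(sessions) && length(sessions) == 1) {
    sessions <- list(sessions)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stage_json(unclass(config), file.path(out_dir, "config.json"))
  manifest <- list(
    package = "neurodisc",
    version = as.character(utils::packageVersion("neurodisc")),
    seed = config$seed, sessions = list()
  )
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    if (is.character(s)) s <- load_session(s)
    name <- s$meta$name %||% sprintf("session%02d", si)
    sdir <- file.path(out_dir, name)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    is_fra <- identical(s$meta$protocol, "fra")
    status <- list()
    trials <- NULL
    responsive <- NULL
    run_stage <- function(stage, fn) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(fn(), error = function(e) e)
      dt <- proc.time()[["elapsed"]] - t0
      ok <- !inherits(res, "error")
      log_msg(
        "[%s] %s: %s (%.1fs)", name, stage,
        if (ok) "ok" else paste("failed:", conditionMessage(res)),
        dt,
        logfile = logfile
      )
      status[[stage]] <<- list(
        status = if (ok) "ok" else "failed",
        error = if (ok) NULL else conditionMessage(res),
        seed = derive_seed(config$seed, match(stage, PIPELINE_STAGES), si)
      )
      if (ok) res else NULL
    }
    if (!is_fra) {
      beh <- run_stage("behavior", function() {
        stage_behavior(s, config, sdir, derive_seed(config$seed, 1, si))
      })
      trials <- if (!is.null(beh)) beh$trials else s$trials
      responsive <- run_stage("units", function() {
        stage_units(s, trials, config, sdir, derive_seed(config$seed, 2, si))
      })
      if (!is.null(responsive)) {
        run_stage("auc", function() {
          stage_auc(s, trials, responsive, config, sdir, derive_seed(config$seed, 3, si))
        })
        run_stage("decode", function() {
          stage_decode(s, trials, responsive, config, sdir, derive_seed(config$seed, 4, si))
        })
      }
    } else {
      run_stage("tuning", function() {
        stage_tuning(s, config, sdir, derive_seed(config$seed, 5, si))
      })
    }
    manifest$sessions[[name]] <- status
  }
  write_stage_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Aggregate pipeline outputs into one report
#'
#' Collects the per-session stage outputs under `out_dir` into a single JSON
#' summary plus a human-readable text table. Stages that did not run are
#' marked `"not run"`. Regenerating the report is idempotent.
#'
#' @param out_dir a [run_pipeline()] output root.
#' @return the report list, invisibly; writes `report.json` and
#'   `report.txt` under `out_dir`.
#' @export
make_report <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json under ", out_dir, call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  report <- list(sessions = list())
  lines <- c("session summary", "===============")
  for (name in names(manifest$sessions)) {
    sdir <- file.path(out_dir, name)
    entry <- list()
    bj <- file.path(sdir, "behavior_summary.json")
    entry$behavior <- if (file.exists(bj)) jsonlite::fromJSON(bj) else "not run"
    am <- file.path(sdir, "auc_metrics.tsv")
    if (file.exists(am)) {
      m <- utils::read.delim(am)
      entry$auc <- lapply(split(m, m$contrast), function(d) {
        list(
          mean_max_auc = mean(d$max_auc, na.rm = TRUE),
          median_onset_latency = stats::median(d$onset_latency, na.rm = TRUE),
          frac_significant = mean(d$significant == "TRUE" | d$significant == TRUE)
        )
      })
    } else {
      entry$auc <- "not run"
    }
    dj <- file.path(sdir, "decoding.json")
    entry$decoding <- if (file.exists(dj)) jsonlite::fromJSON(dj) else "not run"
    pj <- file.path(sdir, "population_sparseness.json")
    entry$tuning <- if (file.exists(pj)) jsonlite::fromJSON(pj) else "not run"
    report$sessions[[name]] <- entry
    d_easy <- if (is.list(entry$behavior)) entry$behavior$d_easy else NULL
    lines <- c(lines, sprintf(
      "%s: d'(easy)=%s, decoding=%s", name,
      if (is.null(d_easy) || !length(d_easy)) "NA" else fmt_num(d_easy),
      if (is.list(entry$decoding)) "run" else "not run"
    ))
  }
  write_stage_json(report, file.path(out_dir, "report.json"))
  writeLines(lines, file.path(out_dir, "report.txt"), useBytes = TRUE)
  invisible(report)
}
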