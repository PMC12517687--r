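# On-disk session layout: one directory per session holding tab-delimited
# UTF-8 text with header rows --
#   trials.tsv  per-trial table (times in seconds, 9 decimal places)
#   licks.tsv   column t_s
#   spikes.tsv  columns unit_id, t_s (long format across units)
#   units.tsv   columns unit_id, depth_um, region, layer, quality
#   meta.json   session-level key-value metadata
# This mirrors Kilosort/Phy-style tabular exports while staying fully
# human-readable; no sample-index representation is ever used.

fmt_time <- function(x) {
  out <- sprintf("%.9f", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv_raw <- function(df, path) {
  con <- file(path, open = "wb") # binary mode: identical bytes on any platform
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, as.character)
    lines <- do.call(paste, c(cols, sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Write a session directory
#'
#' Writes the documented delimited-text layout (`trials.tsv`, `licks.tsv`,
#' `spikes.tsv`, `units.tsv`, `meta.json`). Times are written in seconds with
#' nine decimal places, so [load_session()] round-trips integer fields exactly
#' and times to within 1e-9 s. Output is deterministic: saving the same
#' session twice produces byte-identical files.
#'
#' @param session a valid [gng_session()].
#' @param dir_path directory to create/overwrite.
#' @return `dir_path`, invisibly.
#' @export
save_session <- function(session, dir_path) {
  assert_valid_session(session)
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir_path)) {
    stop("cannot create session directory: ", dir_path, call. = FALSE)
  }
  tr <- session$trials
  out <- data.frame(
    trial_id = as.integer(tr$trial_id),
    t_onset = fmt_time(tr$t_onset),
    freq = sprintf("%.6f", tr$freq),
    level = sprintf("%.3f", tr$level),
    category = tr$category,
    task = tr$task,
    tone_dur = fmt_time(tr$tone_dur),
    outcome = tr$outcome,
    lick_count = as.integer(tr$lick_count),
    first_lick_latency = fmt_time(tr$first_lick_latency),
    stringsAsFactors = FALSE
  )
  write_tsv_raw(out, file.path(dir_path, "trials.tsv"))
  write_tsv_raw(
    data.frame(t_s = fmt_time(session$licks)),
    file.path(dir_path, "licks.tsv")
  )
  uid <- unlist(lapply(session$units, function(u) {
    rep(u$unit_id, length(u$spike_times))
  }))
  ts <- unlist(lapply(session$units, function(u) u$spike_times))
  write_tsv_raw(
    data.frame(unit_id = uid %||% character(), t_s = fmt_time(ts %||% numeric())),
    file.path(dir_path, "spikes.tsv")
  )
  um <- data.frame(
    unit_id = vapply(session$units, function(u) u$unit_id, ""),
    depth_um = sprintf("%.3f", vapply(session$units, function(u) u$depth, 0)),
    region = vapply(session$units, function(u) u$region, ""),
    layer = vapply(session$units, function(u) u$layer, ""),
    quality = vapply(session$units, function(u) u$quality, ""),
    stringsAsFactors = FALSE
  )
  write_tsv_raw(um, file.path(dir_path, "units.tsv"))
  meta_json <- jsonlite::toJSON(session$meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(meta_json, file.path(dir_path, "meta.json"), useBytes = TRUE)
  invisible(dir_path)
}

read_tsv_checked <- function(path, col_classes) {
  if (!file.exists(path)) {
    stop("missing session file: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path,
    colClasses = col_classes, na.strings = "NA",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  missing_cols <- setdiff(names(col_classes), names(df))
  if (length(missing_cols)) {
    stop(sprintf(
      "%s: missing column(s) %s", basename(path),
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

#' Load a session directory
#'
#' Reads the layout written by [save_session()], validates it, and returns a
#' [gng_session()]. Rows whose numeric fields fail to parse are rejected with
#' a per-row report. Non-monotonic trial onsets, missing files, and spikes
#' referencing unknown units are fatal; an unknown region label is a warning
#' and is mapped to `"other"`.
#'
#' @param dir_path session directory.
#' @param protocol passed to [validate_session()]; `"strict"` additionally
#'   enforces the learned-tone frequency protocol.
#' @return a validated [gng_session()].
#' @export
load_session <- function(dir_path, protocol = c("any", "strict")) {
  protocol <- match.arg(protocol)
  if (!dir.exists(dir_path)) {
    stop("no such session directory: ", dir_path, call. = FALSE)
  }
  tr <- read_tsv_checked(file.path(dir_path, "trials.tsv"), c(
    trial_id = "integer", t_onset = "character", freq = "character",
    level = "character", category = "character", task = "character",
    tone_dur = "character", outcome = "character", lick_count = "integer",
    first_lick_latency = "character"
  ))
  num_cols <- c("t_onset", "freq", "level", "tone_dur", "first_lick_latency")
  bad_rows <- integer()
  for (cc in num_cols) {
    parsed <- suppressWarnings(as.numeric(tr[[cc]]))
    bad <- which(is.na(parsed) & !is.na(tr[[cc]]) & tr[[cc]] != "NA")
    bad_rows <- union(bad_rows, bad)
    tr[[cc]] <- parsed
  }
  if (length(bad_rows)) {
    warning(sprintf(
      "trials.tsv: rejected %d unparseable row(s): %s",
      length(bad_rows), paste(sort(bad_rows), collapse = ", ")
    ), call. = FALSE)
    tr <- tr[-sort(bad_rows), , drop = FALSE]
  }
  if (nrow(tr) > 1 && any(diff(tr$t_onset) <= 0)) {
    stop("trials.tsv: trial onsets not strictly increasing", call. = FALSE)
  }
  licks <- read_tsv_checked(file.path(dir_path, "licks.tsv"), c(t_s = "numeric"))$t_s
  spikes <- read_tsv_checked(
    file.path(dir_path, "spikes.tsv"),
    c(unit_id = "character", t_s = "numeric")
  )
  um <- read_tsv_checked(file.path(dir_path, "units.tsv"), c(
    unit_id = "character", depth_um = "numeric", region = "character",
    layer = "character", quality = "character"
  ))
  unknown <- setdiff(unique(spikes$unit_id), um$unit_id)
  if (length(unknown)) {
    stop(
      "spikes.tsv references unit_id(s) absent from units.tsv: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  bad_region <- !um$region %in% REGION_LEVELS
  if (any(bad_region)) {
    warning(sprintf(
      "units.tsv: unknown region label(s) %s mapped to 'other'",
      paste(unique(um$region[bad_region]), collapse = ", ")
    ), call. = FALSE)
    um$region[bad_region] <- "other"
  }
  units <- lapply(seq_len(nrow(um)), function(i) {
    st <- spikes$t_s[spikes$unit_id == um$unit_id[i]]
    unit(
      unit_id = um$unit_id[i], spike_times = sort(st), depth = um$depth_um[i],
      region = um$region[i], layer = um$layer[i], quality = um$quality[i]
    )
  })
  meta_path <- file.path(dir_path, "meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  s <- gng_session(trials = tr, licks = licks, units = units, meta = meta)
  assert_valid_session(s, protocol)
  s
}
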