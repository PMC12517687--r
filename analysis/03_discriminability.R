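#!/usr/bin/env Rscript
# Stage 3: single-neuron ROC discriminability (choice contrast).
# The planted choice signal starts earlier and is stronger in the adult-like
# cohort, so its units should show earlier AUC onset latencies and larger
# maximal AUC.

suppressPackageStartupMessages(library(neurodisc))

dirs <- list.dirs("results/sessions", recursive = FALSE)
dirs <- dirs[!grepl("_fra$", dirs)]
seed <- 77

rows <- list()
for (d in dirs) {
  s <- load_session(d)
  ru <- responsive_units(s)
  units <- Filter(function(u) u$unit_id %in% ru$unit_id[ru$is_excited], s$units)
  pairs <- tryCatch(contrast_builder(s$trials, "choice"), error = function(e) NULL)
  if (is.null(pairs)) {
    cat(basename(d), ": choice contrast not available\n")
    next
  }
  # the resampled ROC needs 20 trials per class; drop task pairs that are short
  enough <- vapply(pairs, function(pr) nrow(pr$a) >= 20 && nrow(pr$b) >= 20, TRUE)
  if (!all(enough)) {
    cat(basename(d), ":", sum(!enough), "task pair(s) below 20 trials/class, skipped\n")
    pairs <- pairs[enough]
  }
  if (!length(pairs)) next
  for (k in seq_along(units)) {
    m_by_pair <- lapply(seq_along(pairs), function(pi) {
      tr <- auc_timecourse(units[[k]], pairs[[pi]]$a, pairs[[pi]]$b,
        seed = seed + 1000 * match(d, dirs) + 10 * k + pi, contrast = "choice"
      )
      discrimination_metrics(tr)
    })
    rows[[length(rows) + 1]] <- data.frame(
      session = basename(d), group = s$meta$group, unit_id = units[[k]]$unit_id,
      onset_latency = mean(vapply(m_by_pair, function(m) m$onset_latency, 0), na.rm = TRUE),
      max_auc = mean(vapply(m_by_pair, function(m) m$max_auc, 0)),
      duration = mean(vapply(m_by_pair, function(m) m$duration, 0)),
      significant = any(vapply(m_by_pair, function(m) m$significant, TRUE)),
      stringsAsFactors = FALSE
    )
  }
  cat(basename(d), ": ", length(units), "units scored\n")
}
tbl <- do.call(rbind, rows)
write.table(tbl, "results/auc_choice_metrics.tsv",
  sep = "\t", row.names = FALSE,
  quote = FALSE
)
sig <- tbl[tbl$significant, ]
agg <- aggregate(cbind(onset_latency, max_auc, duration) ~ group, sig, median)
cat("\nmedians over significant units:\n")
print(agg, digits = 3)
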