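#!/usr/bin/env Rscript
# Stage 5: passive-listening tuning metrics at 62 dB SPL.

suppressPackageStartupMessages(library(neurodisc))

dirs <- list.dirs("results/sessions", recursive = FALSE)
dirs <- dirs[grepl("_fra$", dirs)]

rows <- list()
for (d in dirs) {
  s <- load_session(d)
  at_level <- s$trials[s$trials$level == 62, ]
  ru <- responsive_units(s, trials = at_level)
  units <- Filter(function(u) u$unit_id %in% ru$unit_id[ru$is_excited], s$units)
  fras <- lapply(units, compute_fra, fra_trials = s$trials)
  for (k in seq_along(units)) {
    pd <- suppressWarnings(pairwise_dprime(units[[k]], s$trials))
    rows[[length(rows) + 1]] <- data.frame(
      session = basename(d), group = s$meta$group, unit_id = units[[k]]$unit_id,
      best_frequency = fras[[k]]$best_frequency,
      bandwidth_oct = bandwidth(fras[[k]]),
      bf_to_go_oct = bf_distance_to_go(fras[[k]]),
      mean_pairwise_dprime = pd$mean_learned, stringsAsFactors = FALSE
    )
  }
  cat(sprintf(
    "%s: %d/%d responsive units, population sparseness %.3f\n",
    basename(d), length(units), length(s$units),
    population_sparseness(fras)
  ))
}
tbl <- do.call(rbind, rows)
write.table(tbl, "results/tuning_summary.tsv",
  sep = "\t", row.names = FALSE,
  quote = FALSE
)
agg <- aggregate(
  cbind(bandwidth_oct, bf_to_go_oct, mean_pairwise_dprime) ~ group, tbl,
  median
)
cat("\ncohort medians:\n")
print(agg, digits = 3)
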