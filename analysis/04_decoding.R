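#!/usr/bin/env Rscript
# Stage 4: population decoding of hit vs correct-reject activity.
# The adolescent-like cohort carries a weaker hard-task stimulus separation,
# so its hard-task decoding accuracy and Fisher separation should be lower.

suppressPackageStartupMessages(library(neurodisc))

dirs <- list.dirs("results/sessions", recursive = FALSE)
dirs <- dirs[!grepl("_fra$", dirs)]
seed <- 911

rows <- list()
for (d in dirs) {
  s <- load_session(d)
  ru <- responsive_units(s)
  keep <- ru$unit_id[ru$is_excited]
  row <- data.frame(
    session = basename(d), group = s$meta$group,
    acc_easy = NA_real_, acc_hard = NA_real_, sep_easy = NA_real_,
    sep_hard = NA_real_, latency_easy = NA_real_, stringsAsFactors = FALSE
  )
  for (tk in c("easy", "hard")) {
    pm <- build_population(s, tk, unit_ids = keep)
    if (!pm$accepted) {
      cat(basename(d), tk, "rejected:", pm$reason, "\n")
      next
    }
    row[[paste0("acc_", tk)]] <- lda_decode(pm,
      n_repeats = 100,
      seed = seed + match(d, dirs)
    )
    row[[paste0("sep_", tk)]] <- fisher_separation(pm)$S
  }
  lat <- decoding_latency(s, "easy",
    unit_ids = keep, n_repeats = 30,
    seed = seed + 100 + match(d, dirs)
  )
  row$latency_easy <- lat$latency
  rows[[length(rows) + 1]] <- row
}
tbl <- do.call(rbind, rows)
write.table(tbl, "results/decoding_summary.tsv",
  sep = "\t", row.names = FALSE,
  quote = FALSE
)
print(tbl, digits = 3)

ok <- tbl[is.finite(tbl$sep_easy) & is.finite(tbl$sep_hard), ]
if (nrow(ok) >= 3) {
  fit <- separation_regression(data.frame(
    s_easy = ok$sep_easy,
    s_hard = ok$sep_hard
  ))
  cat(sprintf(
    "\nhard ~ beta * easy separation (Huber, no intercept): beta = %.3f (n = %d)\n",
    fit$beta, fit$n
  ))
}
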