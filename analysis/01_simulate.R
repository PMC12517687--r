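#!/usr/bin/env Rscript
# Stage 1: build the demo cohorts.
#
# Two synthetic cohorts bracket the age contrast the analysis chain is meant
# to expose: an "adult-like" parameter set (higher planted sensitivity,
# earlier and stronger choice signal, sharper tuning) and an
# "adolescent-like" set (lower hard-task sensitivity, later and weaker
# choice signal). Two engaged sessions plus one passive pure-tone session
# per cohort, written as plain-text session directories under
# results/sessions/.

suppressPackageStartupMessages(library(neurodisc))

seed <- 20260601
out_root <- "results/sessions"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

cohorts <- list(
  adult = list(
    behavior = behavior_params(
      d_easy = 3.0, d_hard = 1.5, c_bias = -0.6,
      n_trials = 320
    ),
    units = unit_params(
      n_units = 22, baseline_rate = 5, evoked_gain = 35, bf_log2 = log2(10),
      bf_jitter_oct = 1, tuning_sd_oct = 0.4, choice_gain = 10,
      choice_onset = 0.15
    )
  ),
  adolescent = list(
    behavior = behavior_params(
      d_easy = 2.2, d_hard = 0.6, c_bias = -0.6,
      n_trials = 320
    ),
    units = unit_params(
      n_units = 22, baseline_rate = 5, evoked_gain = 25, bf_log2 = log2(10),
      bf_jitter_oct = 1, tuning_sd_oct = 0.6, choice_gain = 5,
      choice_onset = 0.30
    )
  )
)

for (grp in names(cohorts)) {
  for (i in 1:2) {
    name <- sprintf("%s_%02d", grp, i)
    s <- simulate_session(
      cohorts[[grp]]$behavior, cohorts[[grp]]$units,
      seed = seed + match(grp, names(cohorts)) * 100 + i,
      meta = list(name = name, group = grp)
    )
    save_session(s, file.path(out_root, name))
    cat(sprintf(
      "%s: %d trials, %d units, outcomes %s\n", name, nrow(s$trials),
      length(s$units),
      paste(names(table(s$trials$outcome)), table(s$trials$outcome),
        sep = "=", collapse = " "
      )
    ))
  }
  fra <- simulate_fra_protocol(
    cohorts[[grp]]$units,
    seed = seed + match(grp, names(cohorts)) * 100 + 50
  )
  fra$meta$name <- sprintf("%s_fra", grp)
  fra$meta$group <- grp
  save_session(fra, file.path(out_root, sprintf("%s_fra", grp)))
  cat(sprintf("%s_fra: %d pure-tone trials\n", grp, nrow(fra$trials)))
}
cat("sessions written under", out_root, "\n")
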