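#!/usr/bin/env Rscript
# Worked example: how much of the single-trial change can persist?
#
# The trial-by-trial analysis finds a next-trial change of roughly 10% of
# the average firing rate. If that change persisted in its entirety and
# accumulated over the ~1000 such trials in an hour of training, the
# cumulative change would be enormous; the net behavioural change actually
# observed is under 50%, which bounds the persistent fraction.

suppressPackageStartupMessages(library(vortrial))
dir.create("results", showWarnings = FALSE)

extrap <- accumulate_trial_changes(10, 1000, persistence = 1)
bound <- persistent_fraction_bound(50, extrap)
cat(sprintf("fully persistent extrapolation: %g%% over 1000 trials\n", extrap))
cat(sprintf("observed net change: <= 50%%\n"))
cat(sprintf("=> at most %.2g%% of each single-trial change persists\n", bound))

jsonlite::write_json(
  list(percent_per_trial = 10, n_trials = 1000,
       cumulative_change_pct = extrap, observed_change_pct = 50,
       persistent_fraction_pct = bound),
  "results/persistence.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("  -> results/persistence.json\n")
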