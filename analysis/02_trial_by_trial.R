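#!/usr/bin/env Rscript
# Trial-by-trial analysis: does a climbing-fiber spike on one trial predict a
# change in the Purkinje cell's simple-spike output on the next trial?
#
# For each cell we form all consecutive same-direction trial pairs, classify
# them by CF occurrence in the 75-250 ms window, average the second-minus-
# first rate differences over the first 100 ms, and compare the CF-NoCF and
# NoCF-NoCF grand averages against matched-count bootstrap null bands.

suppressPackageStartupMessages(library(vortrial))
dir.create("results", showWarnings = FALSE)

load_cohort <- function(cond) {
  paths <- Sys.glob(sprintf("scratch/sessions/monkey_%s_*", cond))
  if (length(paths) == 0)
    stop("run analysis/01_simulate_sessions.R first", call. = FALSE)
  lapply(paths, read_session)
}

summaries <- list()
for (cond in c("increase", "decrease")) {
  sessions <- load_cohort(cond)
  res <- trial_by_trial_analysis(sessions, n_reps = 1000)
  tab <- data.frame(time_s = res$time)
  for (cl in names(res$classes)) {
    g <- res$classes[[cl]]
    tab[[paste0(cl, "_mean")]] <- g$grand$mean
    tab[[paste0(cl, "_sem")]] <- g$grand$sem
    tab[[paste0(cl, "_ci_lo")]] <- g$band$lower
    tab[[paste0(cl, "_ci_hi")]] <- g$band$upper
  }
  out <- sprintf("results/pair_differences_%s.csv", cond)
  write.csv(tab, out, row.names = FALSE)
  cf <- res$classes$cf_nocf
  nn <- res$classes$nocf_nocf
  summaries[[cond]] <- c(cf = mean(cf$grand$mean),
                         exit = mean(cf$significant))
  cat(sprintf(
    "VOR-%s: CF-NoCF mean %+.2f sp/s (band exit at %.0f%% of samples); NoCF-NoCF mean %+.2f sp/s (exit %.0f%%)\n",
    cond, mean(cf$grand$mean), 100 * mean(cf$significant),
    mean(nn$grand$mean), 100 * mean(nn$significant)))
  cat("  ->", out, "\n")
}
cat(sprintf(
  "\nThe implanted CF-coupled change is detected in the increase cohort\n(CF-NoCF %+.1f sp/s, outside the null band at %.0f%% of samples); the\ndecrease cohort carries no implant, so its CF-NoCF average (%+.1f sp/s)\nreflects sampling noise at this cohort size.\n",
  summaries$increase["cf"], 100 * summaries$increase["exit"],
  summaries$decrease["cf"]))
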