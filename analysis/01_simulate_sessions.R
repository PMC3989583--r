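#!/usr/bin/env Rscript
# Simulate the demonstration cohorts used by the downstream analysis scripts
# and write them out as session bundles.
#
# Monkey: 10 Purkinje cells recorded during VOR-increase training with a
# climbing-fiber-triggered -8 sp/s next-trial change implanted, and the same
# 10 cells during VOR-decrease training with no implanted CF effect
# (climbing fibers fire equally in both conditions; only their coupling to
# plasticity differs).
# Mouse: per-animal VOR test blocks before and after training.

suppressPackageStartupMessages(library(vortrial))
dir.create("scratch/sessions", recursive = TRUE, showWarnings = FALSE)

n_cells <- 10
for (k in seq_len(n_cells)) {
  inc <- generate_monkey_session(monkey_sim_config(
    n_trials_per_direction = 120, condition = "increase",
    cs_prob_in_window = 0.08, plasticity_delta = -8, seed = 100 + k))
  dec <- generate_monkey_session(monkey_sim_config(
    n_trials_per_direction = 120, condition = "decrease",
    cs_prob_in_window = 0.08, plasticity_delta = 0, seed = 200 + k))
  write_session(inc, sprintf("scratch/sessions/monkey_increase_%02d", k))
  write_session(dec, sprintf("scratch/sessions/monkey_decrease_%02d", k))
}
cat(sprintf("wrote %d monkey sessions per condition\n", n_cells))

# one mouse, pre and post measurement blocks (gain raised by training)
pre <- generate_mouse_session(mouse_sim_config(true_gain = 0.85, seed = 301))
post <- generate_mouse_session(mouse_sim_config(true_gain = 1.02, seed = 302))
write_session(pre, "scratch/sessions/mouse_pre")
write_session(post, "scratch/sessions/mouse_post")
cat("wrote mouse pre/post sessions\n")
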