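# Shared fixtures and independent oracles for the test suite.

# quick monkey cohort with small sessions
quick_cells <- function(n_cells = 4, n_trials = 40, seed = 1, ...) {
  simulate_monkey_cells(n_cells,
                        sim = c(list(n_trials_per_direction = n_trials),
                                list(...)),
                        seed = seed)
}

# random trial table of up to `n_max` trials for the pair-classifier oracle
random_trial_table <- function(n_max = 50, with_block = FALSE) {
  n <- sample(2:n_max, 1)
  tab <- data.frame(
    onset = sort(stats::runif(n, 0, 100)),
    direction = sample(c("ipsiversive", "contraversive"), n, replace = TRUE),
    cs_in_window = stats::runif(n) < stats::runif(1, 0.1, 0.9),
    valid = stats::runif(n) < 0.9)
  if (with_block) tab$block <- cumsum(c(1, stats::runif(n - 1) < 0.1))
  tab
}

# brute-force double-loop pair classifier (independent of classify_pairs):
# (i, j) is a pair iff same direction, j after i with no intervening trial of
# that direction, both valid, same block
brute_force_pairs <- function(trials) {
  n <- nrow(trials)
  valid <- if (is.null(trials$valid)) rep(TRUE, n) else trials$valid
  ord <- order(trials$onset)
  res <- list()
  for (ii in seq_len(n)) for (jj in seq_len(n)) {
    i <- ord[ii]; j <- ord[jj]
    if (ii >= jj) next
    if (trials$direction[i] != trials$direction[j]) next
    between <- ord[seq_len(n) > ii & seq_len(n) < jj]
    if (any(trials$direction[between] == trials$direction[i])) next
    if (!valid[i] || !valid[j]) next
    if (!is.null(trials$block) && trials$block[i] != trials$block[j]) next
    cls <- paste0(if (trials$cs_in_window[i]) "cf" else "nocf", "_",
                  if (trials$cs_in_window[j]) "cf" else "nocf")
    res[[length(res) + 1]] <- data.frame(first = i, second = j, class = cls)
  }
  if (length(res) == 0)
    return(data.frame(first = integer(0), second = integer(0),
                      class = character(0)))
  do.call(rbind, res)
}

# canonical sort for pair-set comparison
sort_pairs <- function(p) {
  p <- as.data.frame(p)[, c("first", "second", "class")]
  p <- p[order(p$first, p$second), ]
  rownames(p) <- NULL
  p
}
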