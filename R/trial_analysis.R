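#' Keep only trials in the climbing fiber's 'on' direction
#'
#' Trial-by-trial analysis is restricted to vestibular stimuli in the
#' direction that drives climbing-fiber firing: ipsiversive stimuli for
#' VOR-increase training, contraversive stimuli for VOR-decrease training.
#' Intervening opposite-direction trials (on which climbing fibers rarely
#' fire) are excluded and do not break trial-pair adjacency.
#'
#' @param trials trial table with a `direction` column.
#' @param condition `"increase"` or `"decrease"`.
#' @return the subset of `trials` in the 'on' direction.
#' @export
select_on_direction <- function(trials, condition) {
  dir <- on_direction(condition)
  trials[trials$direction == dir, , drop = FALSE]
}

#' Flag trials with a complex spike in the analysis window
#'
#' A trial is a CF trial when at least one complex spike falls in the
#' half-open window (default 75-250 ms) after stimulus onset — the period in
#' which climbing fibers fire with high probability during training.
#'
#' @param trials trial table with an `onset` column.
#' @param cs complex [spike_train()].
#' @param window analysis window relative to onset, s, half-open
#'   `[window[1], window[2])`.
#' @return `trials` with a logical `cs_in_window` column.
#' @export
flag_cs_in_window <- function(trials, cs, window = c(0.075, 0.250)) {
  times <- if (inherits(cs, "spike_train")) cs$times else as.numeric(cs)
  trials$cs_in_window <- vapply(trials$onset, function(on) {
    any(times >= on + window[1] & times < on + window[2])
  }, logical(1))
  trials
}

#' Classify consecutive same-direction trial pairs by CF occurrence
#'
#' Forms all sliding (overlapping) pairs of consecutive trials within each
#' same-direction subsequence, ordered by onset, and classifies each pair by
#' whether a climbing-fiber spike occurred in the analysis window on the
#' first and second trial: `cf_nocf`, `nocf_nocf`, `nocf_cf`, `cf_cf`. Pairs
#' containing an invalid trial are dropped; if a `block` column is present,
#' pairs never span a block boundary. The four classes partition all retained
#' pairs.
#'
#' @param trials trial table with `direction`, `cs_in_window`, and optional
#'   `valid` and `block` columns.
#' @return An object of class `"pair_set"`: a data frame with `first`,
#'   `second` (row indices into `trials`) and `class`.
#' @export
classify_pairs <- function(trials) {
  if (is.null(trials$cs_in_window))
    stop("trials must carry a `cs_in_window` flag; see flag_cs_in_window()",
         call. = FALSE)
  valid <- if (is.null(trials$valid)) rep(TRUE, nrow(trials)) else trials$valid
  out <- list()
  for (dir in unique(trials$direction)) {
    idx <- which(trials$direction == dir)
    idx <- idx[order(trials$onset[idx])]
    if (length(idx) < 2) next
    a <- idx[-length(idx)]
    b <- idx[-1]
    keep <- valid[a] & valid[b]
    if (!is.null(trials$block)) keep <- keep & trials$block[a] == trials$block[b]
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0) next
    cls <- paste0(ifelse(trials$cs_in_window[a], "cf", "nocf"), "_",
                  ifelse(trials$cs_in_window[b], "cf", "nocf"))
    out[[dir]] <- data.frame(first = a, second = b, class = cls,
                             stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, unname(out)) else
    data.frame(first = integer(0), second = integer(0), class = character(0))
  rownames(pairs) <- NULL
  structure(pairs, class = c("pair_set", "data.frame"))
}

#' Per-trial response matrix from a rate trace
#'
#' Extracts the rate samples in a fixed span after each trial onset into a
#' trials x samples matrix (gap samples are `NA`).
#'
#' @param rate a rate [vor_trace()] (typically baseline-subtracted).
#' @param onsets trial onset times, s.
#' @param span analysed span relative to onset, s, half-open.
#' @return numeric matrix with one row per trial.
#' @export
trial_response_matrix <- function(rate, onsets, span = c(0, 0.1)) {
  stopifnot(inherits(rate, "trace"))
  fs <- rate$sample_rate
  n_col <- round((span[2] - span[1]) * fs)
  col_off <- seq_len(n_col) - 1L
  start_idx <- round((onsets + span[1] - rate$t0) * fs) + 1L
  idx <- outer(start_idx, col_off, "+")
  bad <- idx < 1L | idx > length(rate$values)
  idx[bad] <- 1L
  m <- matrix(rate$values[idx], nrow = length(onsets))
  m[bad] <- NA_real_
  m
}

#' Mean trial-to-trial difference trace for one pair class
#'
#' For each pair in the class, the second trial's response is subtracted
#' from the first trial's response sample-wise (second minus first) over the
#' analysis span; pair differences are averaged (gap samples excluded
#' pairwise) and smoothed with a sliding boxcar window.
#'
#' @param pairs a `"pair_set"` from [classify_pairs()].
#' @param resp response matrix from [trial_response_matrix()], rows indexed
#'   like the trial table used for `pairs`.
#' @param class pair class to analyse.
#' @param smooth smoothing window, s.
#' @param sample_rate sampling rate of the response matrix, Hz.
#' @return list with `trace` (mean difference, sp/s), `n_pairs`, and
#'   `pair_diffs` (pairs x samples matrix).
#' @export
pair_difference_trace <- function(pairs, resp, class = "cf_nocf",
                                  smooth = 0.025, sample_rate = 500) {
  sel <- pairs[pairs$class == class, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning(sprintf("no pairs in class '%s'", class))
    return(list(trace = rep(NA_real_, ncol(resp)), n_pairs = 0L,
                pair_diffs = matrix(numeric(0), 0, ncol(resp))))
  }
  d <- resp[sel$second, , drop = FALSE] - resp[sel$first, , drop = FALSE]
  m <- colMeans(d, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  list(trace = boxcar_smooth(m, smooth * sample_rate), n_pairs = nrow(sel),
       pair_diffs = d)
}

#' Grand average across cells
#'
#' Unweighted mean across per-cell traces (every cell contributes equally
#' regardless of its pair count), with the pointwise SEM across cells.
#'
#' @param cell_traces list of per-cell numeric trace vectors (equal length).
#' @return list with `mean`, `sem`, `n_cells`.
#' @export
grand_average <- function(cell_traces) {
  cell_traces <- cell_traces[!vapply(cell_traces, is.null, logical(1))]
  if (length(cell_traces) == 0) stop("at least one cell required", call. = FALSE)
  m <- do.call(rbind, cell_traces)
  mu <- colMeans(m, na.rm = TRUE)
  n <- colSums(!is.na(m))
  sem <- apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1))
  list(mean = mu, sem = sem, n_cells = length(cell_traces))
}

#' Bootstrap null distribution for a pair class
#'
#' Builds the null distribution of the grand-average trial-to-trial
#' difference trace: on each repetition, for every cell, as many pairs as
#' were actually observed in the target class are drawn (with replacement)
#' from that cell's pool of all consecutive-trial pairs (all four classes);
#' the per-cell mean difference traces are averaged across cells to give one
#' grand trace per repetition. The confidence band is the pointwise mean
#' +/- 2 SD over the repetitions.
#'
#' @param pools list (one element per cell) of pooled pair-difference
#'   matrices (pairs x samples), i.e. the `pair_diffs` of all classes.
#' @param n_obs integer vector: observed pair count of the target class per
#'   cell.
#' @param n_reps number of bootstrap repetitions.
#' @param smooth smoothing window, s (applied to each rep's grand trace,
#'   matching the observed pipeline).
#' @param sample_rate sampling rate, Hz.
#' @param replace draw with replacement (the default); with `replace =
#'   FALSE`, requesting more pairs than the pool holds is an error.
#' @return list with `mean`, `lower`, `upper` (pointwise band), and `reps`
#'   (n_reps x samples matrix of grand traces).
#' @export
bootstrap_null <- function(pools, n_obs, n_reps = 1000, smooth = 0.025,
                           sample_rate = 500, replace = TRUE) {
  stopifnot(length(pools) == length(n_obs))
  use <- which(n_obs > 0 & vapply(pools, nrow, integer(1)) > 0)
  if (length(use) == 0) stop("no cell has a non-empty pool", call. = FALSE)
  n_samp <- ncol(pools[[use[1]]])
  acc <- matrix(0, n_reps, n_samp)
  cnt <- matrix(0, n_reps, n_samp)
  for (ci in use) {
    pool <- pools[[ci]]
    k <- n_obs[ci]
    if (!replace && k > nrow(pool))
      stop("observed count exceeds pool size and replace = FALSE",
           call. = FALSE)
    idx <- sample.int(nrow(pool), n_reps * k, replace = replace)
    grp <- rep(seq_len(n_reps), each = k)
    ok <- !is.na(pool)
    pool0 <- ifelse(ok, pool, 0)
    sums <- rowsum(pool0[idx, , drop = FALSE], grp)
    ns <- rowsum(ok[idx, , drop = FALSE] + 0, grp)
    cell_mean <- sums / pmax(ns, 1)
    cell_mean[ns == 0] <- NA
    has <- !is.na(cell_mean)
    acc <- acc + ifelse(has, cell_mean, 0)
    cnt <- cnt + has
  }
  grand <- acc / pmax(cnt, 1)
  grand[cnt == 0] <- NA
  grand <- t(apply(grand, 1, boxcar_smooth, width = smooth * sample_rate))
  mu <- colMeans(grand, na.rm = TRUE)
  sdv <- apply(grand, 2, stats::sd, na.rm = TRUE)
  list(mean = mu, lower = mu - 2 * sdv, upper = mu + 2 * sdv, reps = grand)
}

#' Session slope: rate of change of the trial response
#'
#' Ordinary least-squares slope of the per-trial response (mean
#' baseline-subtracted simple-spike rate over the first 100 ms of each
#' trial) against trial number, in sp/s per trial.
#'
#' @param responses per-trial responses, sp/s (NA = invalid trial).
#' @param trial_index trial numbers (1-based by default).
#' @return list of class `"session_slope"`: `slope`, `intercept`,
#'   `n_trials`.
#' @export
session_slope <- function(responses, trial_index = seq_along(responses)) {
  ok <- !is.na(responses) & !is.na(trial_index)
  x <- trial_index[ok]; y <- responses[ok]
  if (length(x) < 3) stop("at least 3 valid trials required", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n_trials = length(x)), class = "session_slope")
}

#' One-sample t test of session slopes against zero
#'
#' Tests whether the rates of change from all sessions in a learning
#' condition differ from zero.
#'
#' @param slopes numeric vector of session slopes (sp/s per trial).
#' @param mu null value.
#' @return list with `t`, `df`, `p`, `mean`, `degenerate` (TRUE when the
#'   slopes have zero variance; then p = 1 if the mean equals `mu`, else 0).
#' @export
slopes_group_test <- function(slopes, mu = 0) {
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) < 2) stop("at least 2 slopes required", call. = FALSE)
  if (stats::sd(slopes) == 0) {
    eq <- isTRUE(all.equal(mean(slopes), mu))
    return(list(t = if (eq) 0 else sign(mean(slopes) - mu) * Inf,
                df = length(slopes) - 1, p = if (eq) 1 else 0,
                mean = mean(slopes), degenerate = TRUE))
  }
  ht <- stats::t.test(slopes, mu = mu)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean = mean(slopes), degenerate = FALSE)
}

#' Full trial-by-trial analysis of one cell's session
#'
#' Runs the single-cell pipeline: reciprocal-interval simple-spike rate on
#' the session grid, saccade detection on eye velocity with
#' excision/interpolation mirrored onto the rate, 10-s moving-baseline
#' subtraction, CF flagging in the analysis window, restriction to
#' 'on'-direction trials, response-matrix extraction, validity marking, and
#' pair classification.
#'
#' @param session a monkey `"vor_session"`.
#' @param window CF analysis window after onset, s.
#' @param span response span analysed per trial, s.
#' @param baseline_window moving-average baseline window, s.
#' @param saccade_threshold residual eye-velocity threshold, deg/s.
#' @param max_gap longest interpolable saccade, s.
#' @param invalid_gap_frac trials with a larger fraction of gap samples in
#'   the span are marked invalid.
#' @return list with `trials` (on-direction, flagged), `resp` (response
#'   matrix), `pairs` (a `"pair_set"`), `pool` (all-pair difference matrix),
#'   `class_counts`, and `response_means` (per-trial span means, sp/s).
#' @export
cell_trial_analysis <- function(session,
                                window = c(0.075, 0.250),
                                span = c(0, 0.1),
                                baseline_window = 10,
                                saccade_threshold = 50,
                                max_gap = 0.2,
                                invalid_gap_frac = 0.5) {
  stopifnot(inherits(session, "vor_session"), session$species == "monkey")
  grid <- session$head
  rate <- reciprocal_interval_rate(session$ss, grid)

  # saccade handling: residual of eye on head (removes the VOR component),
  # excise/interpolate eye velocity and mirror the treatment onto the rate
  pred_fit <- stats::lm.fit(cbind(1, session$head$values), session$eye$values)
  predicted <- vor_trace(pred_fit$fitted.values, grid$sample_rate, grid$t0, "deg/s")
  mask <- detect_saccades(session$eye, threshold = saccade_threshold,
                          predicted = predicted)
  rate <- excise_interpolate(rate, mask, max_gap = max_gap)
  rate <- subtract_moving_baseline(rate, window = baseline_window)

  trials <- flag_cs_in_window(session$trials, session$cs, window = window)
  trials <- select_on_direction(trials, session$condition)
  resp <- trial_response_matrix(rate, trials$onset, span = span)
  trials$valid <- rowMeans(is.na(resp)) <= invalid_gap_frac
  pairs <- classify_pairs(trials)
  d_all <- resp[pairs$second, , drop = FALSE] - resp[pairs$first, , drop = FALSE]
  counts <- table(factor(pairs$class,
                         levels = c("cf_nocf", "nocf_nocf", "nocf_cf", "cf_cf")))
  list(trials = trials, resp = resp, pairs = pairs, pool = d_all,
       class_counts = counts,
       response_means = ifelse(trials$valid, rowMeans(resp, na.rm = TRUE),
                               NA_real_))
}

#' Trial-by-trial plasticity analysis across cells
#'
#' The population analysis: per cell, mean trial-to-trial difference traces
#' for the requested pair classes; across cells, unweighted grand averages
#' with SEM; and for each class a matched-count bootstrap null band
#' (pointwise mean +/- 2 SD over `n_reps` repetitions of random pair draws
#' from each cell's full pair pool). Samples where the observed grand trace
#' exits the band are flagged significant.
#'
#' @param sessions list of monkey `"vor_session"` objects (one per cell).
#' @param classes pair classes to analyse.
#' @param n_reps bootstrap repetitions; 0 skips the bootstrap (with a
#'   warning) and returns no bands.
#' @param smooth smoothing window, s.
#' @param ... passed to [cell_trial_analysis()].
#' @return list of class `"pair_diff_result"`: per-class `grand` (mean, sem),
#'   `band` (bootstrap CI), `significant` flags, `cell_traces`, `n_pairs`
#'   per cell, plus `time` (s, relative to onset).
#' @export
trial_by_trial_analysis <- function(sessions,
                                    classes = c("cf_nocf", "nocf_nocf"),
                                    n_reps = 1000, smooth = 0.025, ...) {
  fs <- sessions[[1]]$sample_rate
  cells <- lapply(sessions, cell_trial_analysis, ...)
  dots <- list(...)
  span <- if (!is.null(dots$span)) dots$span else c(0, 0.1)
  out <- list(time = span[1] + (seq_len(ncol(cells[[1]]$resp)) - 1) / fs,
              classes = list(), n_cells = length(cells))
  pools <- lapply(cells, `[[`, "pool")
  if (n_reps <= 0) warning("n_reps = 0: bootstrap confidence band omitted")
  for (cl in classes) {
    traces <- lapply(cells, function(ce) {
      if (ce$class_counts[[cl]] == 0) return(NULL)
      pair_difference_trace(ce$pairs, ce$resp, class = cl, smooth = smooth,
                            sample_rate = fs)$trace
    })
    n_pairs <- vapply(cells, function(ce) ce$class_counts[[cl]], numeric(1))
    grand <- grand_average(traces)
    band <- NULL; sig <- NULL
    if (n_reps > 0) {
      band <- bootstrap_null(pools, n_pairs, n_reps = n_reps, smooth = smooth,
                             sample_rate = fs)
      sig <- grand$mean < band$lower | grand$mean > band$upper
    }
    out$classes[[cl]] <- list(grand = grand, band = band, significant = sig,
                              cell_traces = traces, n_pairs = n_pairs)
  }
  class(out) <- "pair_diff_result"
  out
}

#' @export
print.pair_diff_result <- function(x, ...) {
  cat(sprintf("<pair_diff_result> %d cells, span mean (sp/s):\n", x$n_cells))
  for (cl in names(x$classes)) {
    g <- x$classes[[cl]]
    cat(sprintf("  %-10s mean %6.2f (pairs/cell: median %g)\n", cl,
                mean(g$grand$mean, na.rm = TRUE), stats::median(g$n_pairs)))
  }
  invisible(x)
}
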