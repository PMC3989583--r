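#' Spike train
#'
#' Ordered event times of one unit's simple or complex spikes, with optional
#' waveform snippets (rows = spikes) sampled at `waveform_rate`.
#'
#' @param times strictly increasing spike times, s.
#' @param kind `"simple"` or `"complex"`.
#' @param waveforms optional numeric matrix of snippets, one row per spike.
#' @param waveform_rate snippet sampling rate, Hz.
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(times, kind = c("simple", "complex"),
                        waveforms = NULL, waveform_rate = 50000) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  if (!is.null(waveforms)) {
    waveforms <- as.matrix(waveforms)
    if (nrow(waveforms) != length(times))
      stop("one waveform row per spike required", call. = FALSE)
  }
  structure(list(times = times, kind = kind, waveforms = waveforms,
                 waveform_rate = waveform_rate), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d %s spikes%s\n", length(x$times), x$kind,
              if (is.null(x$waveforms)) "" else " (with waveforms)"))
  invisible(x)
}

#' Reciprocal-interval intervals
#'
#' The exact piecewise-constant representation of the reciprocal-interval
#' firing rate: on each half-open interval `(t_i, t_{i+1}]` between
#' consecutive spikes the rate is `1 / (t_{i+1} - t_i)`.
#'
#' @param spikes a [spike_train()] (or numeric spike times).
#' @return data frame with `start`, `end`, `rate` (sp/s).
#' @export
reciprocal_rate_intervals <- function(spikes) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  if (length(times) < 2)
    return(data.frame(start = numeric(0), end = numeric(0), rate = numeric(0)))
  isi <- diff(times)
  data.frame(start = times[-length(times)], end = times[-1], rate = 1 / isi)
}

#' Reciprocal-interval firing rate on a sampling grid
#'
#' The instantaneous firing rate at time t strictly between consecutive
#' spikes `(t_i, t_{i+1}]` is `1/(t_{i+1} - t_i)`. Samples before the first
#' or after the last spike are gap-marked.
#'
#' @param spikes a [spike_train()] with at least two spikes in the grid span.
#' @param grid a [vor_trace()] supplying the sampling grid (values ignored), or a
#'   numeric vector of sample times.
#' @return a rate [vor_trace()] in sp/s (when `grid` is a trace) or a numeric
#'   vector of rates.
#' @export
reciprocal_interval_rate <- function(spikes, grid) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  tt <- if (inherits(grid, "trace")) trace_times(grid) else as.numeric(grid)
  rate <- rep(NA_real_, length(tt))
  if (length(times) >= 2) {
    isi <- diff(times)
    # i such that times[i] < t <= times[i+1]
    i <- findInterval(tt, times, left.open = TRUE)
    ok <- i >= 1 & i < length(times)
    rate[ok] <- 1 / isi[i[ok]]
  }
  if (inherits(grid, "trace"))
    vor_trace(rate, grid$sample_rate, grid$t0, "sp/s")
  else rate
}

#' Subtract a moving-average baseline from a rate trace
#'
#' Removes slow drift in firing rate by subtracting a centred moving average
#' (default 10 s window, shrinking at the trace edges). Gap samples are
#' excluded from the window mean and stay gaps in the output.
#'
#' @param rate a rate [vor_trace()].
#' @param window moving-average window, s.
#' @return baseline-subtracted rate [vor_trace()].
#' @export
subtract_moving_baseline <- function(rate, window = 10) {
  stopifnot(inherits(rate, "trace"))
  n <- length(rate$values)
  if (n == 0 || all(is.na(rate$values))) return(rate)
  if (n / rate$sample_rate <= window)
    stop("trace must be longer than the baseline window", call. = FALSE)
  base <- boxcar_smooth(rate$values, window * rate$sample_rate)
  vor_trace(rate$values - base, rate$sample_rate, rate$t0, rate$unit)
}

#' Complex-spike probability histogram
#'
#' Per trial-aligned bin `[k*bin, (k+1)*bin)` after stimulus onset, the
#' number of complex spikes across trials divided by the number of trials.
#'
#' @param trials trial table with an `onset` column (s).
#' @param cs complex [spike_train()].
#' @param bin bin width, s.
#' @param span analysed window relative to onset, s.
#' @return data frame with `bin_start`, `bin_end`, `probability`.
#' @export
cs_probability_histogram <- function(trials, cs, bin = 0.05, span = c(0, 0.5)) {
  if (is.null(trials$onset) || nrow(trials) == 0)
    stop("at least one trial is required", call. = FALSE)
  times <- if (inherits(cs, "spike_train")) cs$times else as.numeric(cs)
  edges <- seq(span[1], span[2], by = bin)
  n_bins <- length(edges) - 1
  counts <- integer(n_bins)
  for (onset in trials$onset) {
    rel <- times - onset
    rel <- rel[rel >= span[1] & rel < span[2]]
    if (length(rel))
      counts <- counts + tabulate(floor((rel - span[1]) / bin + 1e-9) + 1L,
                                  n_bins)
  }
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             probability = counts / nrow(trials))
}

#' Post-complex-spike pause in simple spiking
#'
#' For each complex spike, the latency to the next simple spike. Complex
#' spikes with no following simple spike are excluded.
#'
#' @param cs complex [spike_train()].
#' @param ss simple [spike_train()] from the same cell.
#' @return list with `pauses` (s, one per retained CS), `cs_times`, and
#'   `mean_pause`.
#' @export
post_cs_pause <- function(cs, ss) {
  cs_t <- if (inherits(cs, "spike_train")) cs$times else as.numeric(cs)
  ss_t <- if (inherits(ss, "spike_train")) ss$times else as.numeric(ss)
  if (length(ss_t) == 0 || length(cs_t) == 0)
    return(list(pauses = numeric(0), cs_times = numeric(0),
                mean_pause = NA_real_))
  nxt <- findInterval(cs_t, ss_t, left.open = FALSE) + 1L
  keep <- nxt <= length(ss_t)
  # a simple spike exactly at the CS time does not end the pause
  pauses <- ss_t[nxt[keep]] - cs_t[keep]
  list(pauses = pauses, cs_times = cs_t[keep],
       mean_pause = if (length(pauses)) mean(pauses) else NA_real_)
}

#' Complex-spike waveform metrics
#'
#' Automated spikelet detection on a waveform snippet: local maxima after the
#' initial large transient whose prominence exceeds a fraction of the initial
#' transient's amplitude, within a search window after the peak. Duration is
#' the latency from the initial peak to the last spikelet peak (0 when there
#' are no spikelets). The prominence threshold is relative, so metrics are
#' invariant to amplitude scaling.
#'
#' @param waveform numeric snippet containing the initial transient peak.
#' @param sample_rate snippet sampling rate, Hz.
#' @param prominence_frac spikelet prominence threshold as a fraction of the
#'   initial transient amplitude.
#' @param search_window time after the initial peak searched for spikelets, s.
#' @return list with `n_spikelets`, `duration` (s), `peak_index`,
#'   `spikelet_indices`.
#' @export
cs_waveform_metrics <- function(waveform, sample_rate = 50000,
                                prominence_frac = 0.10,
                                search_window = 0.006) {
  w <- as.numeric(waveform)
  if (length(w) < 3 || diff(range(w)) == 0)
    stop("flat snippet: no initial transient peak", call. = FALSE)
  peak <- which.max(w)
  amp <- w[peak] - stats::median(w)
  if (amp <= 0) stop("no initial transient peak above baseline", call. = FALSE)
  last <- min(length(w), peak + round(search_window * sample_rate))
  seg <- w[peak:last]
  spikelets <- integer(0)
  if (length(seg) >= 3) {
    d <- diff(seg)
    is_max <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
    is_max <- is_max[is_max > 1L]
    for (i in is_max) {
      left_min <- min(seg[1:i])
      prom <- seg[i] - left_min
      if (prom >= prominence_frac * amp)
        spikelets <- c(spikelets, i)
    }
  }
  # keep only the prominence relative to the trough since the previous kept peak
  if (length(spikelets) > 1) {
    kept <- spikelets[1]
    for (i in spikelets[-1]) {
      prev <- kept[length(kept)]
      trough <- min(seg[prev:i])
      if (seg[i] - trough >= prominence_frac * amp) kept <- c(kept, i)
    }
    spikelets <- kept
  }
  n <- length(spikelets)
  duration <- if (n == 0) 0 else (spikelets[n] - 1) / sample_rate
  list(n_spikelets = n, duration = duration, peak_index = peak,
       spikelet_indices = if (n) peak + spikelets - 1L else integer(0))
}

#' Synthetic complex-spike waveform
#'
#' Builds a stylised complex-spike snippet (initial transient plus optional
#' spikelets) for testing and demonstration of [cs_waveform_metrics()].
#'
#' @param spikelet_latencies latencies of spikelet peaks after the initial
#'   transient peak, s.
#' @param spikelet_amp spikelet amplitude relative to the initial transient.
#' @param sample_rate sampling rate, Hz.
#' @param snippet_length snippet duration, s.
#' @return numeric waveform vector with the initial peak at 1 ms.
#' @export
synthetic_cs_waveform <- function(spikelet_latencies = c(0.0012, 0.0024),
                                  spikelet_amp = 0.35,
                                  sample_rate = 50000,
                                  snippet_length = 0.008) {
  n <- round(snippet_length * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  peak_t <- 0.001
  bump <- function(center, width, height) height * exp(-((tt - center) / width)^2)
  w <- bump(peak_t, 0.00015, 1)
  for (lat in spikelet_latencies) w <- w + bump(peak_t + lat, 0.00012, spikelet_amp)
  w
}
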