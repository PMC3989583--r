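#' Configuration for a synthetic monkey pulse-trial session
#'
#' Parameters of the synthetic Purkinje-cell recording session used to verify
#' the trial-by-trial analysis by parameter recovery. The stimulus layout
#' follows the primate training paradigm: velocity pulses at
#' `pulse_speed` deg/s with `accel_time` of linear acceleration, delivered in
#' alternating directions with a fixed interval of
#' `inter_stimulus_interval_same_direction` seconds between stimuli in a given
#' direction.
#'
#' Simple spikes are drawn from an inhomogeneous gamma-renewal process
#' (shape `ss_gamma_shape`) whose rate is `ss_baseline_rate` plus a
#' stimulus-locked modulation of depth `ss_modulation` (positive during
#' 'on'-direction pulses, negative during the opposite direction). On each
#' 'on'-direction trial a complex spike (CS) occurs with probability
#' `cs_prob_in_window`, at a latency drawn uniformly from `cs_latency_range`
#' after stimulus onset; background CSs occur elsewhere at `cs_baseline_rate`.
#' Every CS silences simple spikes for `pause_duration` seconds.
#'
#' A CS on 'on'-direction trial k offsets the simple-spike rate during the
#' response window of trial k+1 (same direction) by `plasticity_delta` sp/s;
#' the offset is retained at a fraction `plasticity_persistence` per
#' subsequent trial. With the default `plasticity_persistence = 1` implanted
#' offsets accumulate over the session, which makes the consecutive-trial
#' difference equal to `plasticity_delta` exactly on pairs whose first trial
#' had a CS — the regime in which the pair statistic recovers the implant
#' without attenuation (see the methods vignette for the derivation).
#'
#' @param n_trials_per_direction number of pulses in each direction.
#' @param pulse_durations candidate pulse durations in seconds; each trial's
#'   duration is drawn uniformly from this set.
#' @param pulse_speed plateau head speed, deg/s.
#' @param accel_time linear acceleration/deceleration time, s.
#' @param inter_stimulus_interval_same_direction fixed spacing of
#'   same-direction stimulus onsets, s.
#' @param condition `"increase"` or `"decrease"` (VOR training direction).
#' @param ss_baseline_rate baseline simple-spike rate, sp/s.
#' @param ss_modulation depth of stimulus-locked rate modulation, sp/s.
#' @param ss_gamma_shape shape of the gamma-renewal interval distribution.
#' @param cs_prob_in_window probability of a CS on an 'on'-direction trial.
#' @param cs_baseline_rate background CS rate outside analysis windows, sp/s.
#' @param cs_latency_range CS latency range after stimulus onset, s.
#' @param pause_duration post-CS simple-spike pause, s.
#' @param plasticity_delta signed rate offset (sp/s) implanted on the trial
#'   after a CS trial; 0 disables the implant (null model).
#' @param plasticity_persistence fraction of an implanted offset carried to
#'   each subsequent trial (0 = next trial only, 1 = permanent).
#' @param response_window duration after onset over which implanted offsets
#'   apply, s.
#' @param saccade_rate saccade rate, events/s.
#' @param vor_gain gain of the (unadapted) VOR used for eye velocity.
#' @param noise_sd white measurement noise on eye velocity, deg/s.
#' @param sample_rate trace sampling rate, Hz.
#' @param lead_in quiet time before the first stimulus onset, s.
#' @param seed RNG seed; all randomness in the session flows from it.
#' @return A list of class `"monkey_sim_config"`.
#' @export
monkey_sim_config <- function(n_trials_per_direction = 40,
                              pulse_durations = c(0.25, 0.5, 1.0),
                              pulse_speed = 15,
                              accel_time = 0.025,
                              inter_stimulus_interval_same_direction = 2.192,
                              condition = c("increase", "decrease"),
                              ss_baseline_rate = 71,
                              ss_modulation = 30,
                              ss_gamma_shape = 4,
                              cs_prob_in_window = 0.05,
                              cs_baseline_rate = 0.5,
                              cs_latency_range = c(0.100, 0.250),
                              pause_duration = 0.015,
                              plasticity_delta = 0,
                              plasticity_persistence = 1,
                              response_window = 0.25,
                              saccade_rate = 0.2,
                              vor_gain = 0.9,
                              noise_sd = 1,
                              sample_rate = 500,
                              lead_in = 1,
                              seed = 0) {
  condition <- match.arg(condition)
  cfg <- list(
    n_trials_per_direction = n_trials_per_direction,
    pulse_durations = pulse_durations, pulse_speed = pulse_speed,
    accel_time = accel_time,
    inter_stimulus_interval_same_direction = inter_stimulus_interval_same_direction,
    condition = condition, ss_baseline_rate = ss_baseline_rate,
    ss_modulation = ss_modulation, ss_gamma_shape = ss_gamma_shape,
    cs_prob_in_window = cs_prob_in_window, cs_baseline_rate = cs_baseline_rate,
    cs_latency_range = cs_latency_range, pause_duration = pause_duration,
    plasticity_delta = plasticity_delta,
    plasticity_persistence = plasticity_persistence,
    response_window = response_window, saccade_rate = saccade_rate,
    vor_gain = vor_gain, noise_sd = noise_sd, sample_rate = sample_rate,
    lead_in = lead_in, seed = seed)
  validate_monkey_config(cfg)
  structure(cfg, class = "monkey_sim_config")
}

validate_monkey_config <- function(cfg) {
  stopifnot(length(cfg$n_trials_per_direction) == 1L,
            cfg$n_trials_per_direction >= 0,
            cfg$n_trials_per_direction == round(cfg$n_trials_per_direction))
  if (any(cfg$pulse_durations <= 0))
    stop("pulse durations must be positive", call. = FALSE)
  if (cfg$accel_time <= 0 || any(cfg$pulse_durations < 2 * cfg$accel_time))
    stop("each pulse duration must allow two acceleration ramps", call. = FALSE)
  rates <- c(cfg$ss_baseline_rate, cfg$cs_baseline_rate, cfg$saccade_rate)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (cfg$cs_prob_in_window < 0 || cfg$cs_prob_in_window > 1)
    stop("cs_prob_in_window must be in [0, 1]", call. = FALSE)
  if (cfg$plasticity_persistence < 0 || cfg$plasticity_persistence > 1)
    stop("plasticity_persistence must be in [0, 1]", call. = FALSE)
  if (cfg$ss_gamma_shape <= 0) stop("ss_gamma_shape must be > 0", call. = FALSE)
  if (cfg$sample_rate <= 0) stop("sample_rate must be > 0", call. = FALSE)
  if (length(cfg$cs_latency_range) != 2L ||
      cfg$cs_latency_range[1] >= cfg$cs_latency_range[2])
    stop("cs_latency_range must be an increasing pair", call. = FALSE)
  invisible(cfg)
}

#' Configuration for a synthetic mouse sinusoidal session
#'
#' Emulates the rodent VOR test block: whole-body rotation with a sinusoidal
#' velocity profile while eye position is recorded. Smooth eye velocity is
#' `-true_gain` times head velocity, phase-shifted by `true_phase` degrees
#' (positive = eye leads head); saccadic velocity pulses and white noise are
#' added, and eye position is the running integral of the resulting velocity.
#'
#' @param stim_freq stimulus frequency, Hz.
#' @param peak_speed peak head speed, deg/s.
#' @param duration block duration, s (at least two stimulus cycles).
#' @param true_gain ground-truth VOR gain (>= 0).
#' @param true_phase ground-truth phase of the eye relative to the
#'   compensatory direction, degrees.
#' @param saccade_rate saccade rate, events/s.
#' @param noise_sd white noise SD on eye velocity, deg/s.
#' @param sample_rate sampling rate, Hz.
#' @param seed RNG seed.
#' @return A list of class `"mouse_sim_config"`.
#' @export
mouse_sim_config <- function(stim_freq = 1, peak_speed = 10, duration = 60,
                             true_gain = 0.8, true_phase = 0,
                             saccade_rate = 0.5, noise_sd = 1,
                             sample_rate = 1000, seed = 0) {
  if (true_gain < 0) stop("true_gain must be >= 0", call. = FALSE)
  if (stim_freq <= 0 || sample_rate <= 0)
    stop("frequencies must be positive", call. = FALSE)
  if (duration < 2 / stim_freq)
    stop("duration must cover at least two stimulus cycles", call. = FALSE)
  structure(list(stim_freq = stim_freq, peak_speed = peak_speed,
                 duration = duration, true_gain = true_gain,
                 true_phase = true_phase, saccade_rate = saccade_rate,
                 noise_sd = noise_sd, sample_rate = sample_rate, seed = seed),
            class = "mouse_sim_config")
}

# trapezoidal velocity profile of one pulse, sampled on the session grid
pulse_profile <- function(t_rel, duration, speed, accel) {
  v <- numeric(length(t_rel))
  up <- t_rel >= 0 & t_rel < accel
  flat <- t_rel >= accel & t_rel < duration - accel
  down <- t_rel >= duration - accel & t_rel < duration
  v[up] <- speed * t_rel[up] / accel
  v[flat] <- speed
  v[down] <- speed * (duration - t_rel[down]) / accel
  v
}

# trial layout shared by the stimulus builder and the session generator;
# durations are drawn from cfg$pulse_durations (uses the current RNG stream)
build_trial_table <- function(cfg) {
  n <- cfg$n_trials_per_direction
  if (n == 0)
    return(data.frame(onset = numeric(0), direction = character(0),
                      duration = numeric(0), condition = character(0),
                      stringsAsFactors = FALSE))
  isi <- cfg$inter_stimulus_interval_same_direction
  on_ipsi <- cfg$lead_in + (seq_len(n) - 1) * isi
  on_contra <- on_ipsi + isi / 2
  onsets <- c(rbind(on_ipsi, on_contra))
  dirs <- rep(c("ipsiversive", "contraversive"), n)
  durs <- if (length(cfg$pulse_durations) == 1L) {
    rep(cfg$pulse_durations, 2 * n)
  } else {
    sample(cfg$pulse_durations, 2 * n, replace = TRUE)
  }
  data.frame(onset = onsets, direction = dirs, duration = durs,
             condition = cfg$condition, stringsAsFactors = FALSE)
}

# sample indices i (times t_i = (i-1)/fs) with t_i in [from, to)
sample_span <- function(from, to, sample_rate, n_samp) {
  i0 <- floor(from * sample_rate) + 1L
  if ((i0 - 1) / sample_rate < from - 1e-12) i0 <- i0 + 1L
  i1 <- floor(to * sample_rate) + 1L
  if ((i1 - 1) / sample_rate >= to - 1e-12) i1 <- i1 - 1L
  i0 <- max(1L, i0); i1 <- min(n_samp, i1)
  if (i0 > i1) integer(0) else i0:i1
}

# sign of head velocity for a trial direction: contraversive positive
direction_sign <- function(direction) {
  ifelse(direction == "contraversive", 1, -1)
}

#' 'On' direction of the climbing fiber for a training condition
#'
#' During VOR-increase training climbing fibers fire during ipsiversive
#' vestibular stimuli; during VOR-decrease training, during contraversive
#' stimuli.
#'
#' @param condition `"increase"` or `"decrease"`.
#' @return `"ipsiversive"` or `"contraversive"`.
#' @export
on_direction <- function(condition) {
  switch(match.arg(condition, c("increase", "decrease")),
         increase = "ipsiversive", decrease = "contraversive")
}

#' Build the pulse head-velocity stimulus and trial table
#'
#' Trapezoidal velocity pulses (linear ramps of `accel_time` up to
#' `pulse_speed`) delivered in alternating directions, with same-direction
#' onsets spaced exactly by the configured inter-stimulus interval. Sign
#' convention: contraversive head velocity is positive.
#'
#' @param config a [monkey_sim_config()].
#' @return list with `head` (velocity [vor_trace()]) and `trials` (data frame
#'   with onset, direction, duration, condition).
#' @export
make_pulse_stimulus <- function(config) {
  validate_monkey_config(config)
  with_seed_(config$seed, make_pulse_stimulus_(config))
}

make_pulse_stimulus_ <- function(cfg) {
  trials <- build_trial_table(cfg)
  if (nrow(trials) == 0)
    return(list(head = vor_trace(numeric(0), cfg$sample_rate, 0, "deg/s"),
                trials = trials))
  total <- max(trials$onset + trials$duration) + cfg$lead_in
  n_samp <- ceiling(total * cfg$sample_rate)
  v <- numeric(n_samp)
  fs <- cfg$sample_rate
  for (i in seq_len(nrow(trials))) {
    idx <- sample_span(trials$onset[i], trials$onset[i] + trials$duration[i],
                       fs, n_samp)
    v[idx] <- direction_sign(trials$direction[i]) *
      pulse_profile((idx - 1) / fs - trials$onset[i], trials$duration[i],
                    cfg$pulse_speed, cfg$accel_time)
  }
  list(head = vor_trace(v, cfg$sample_rate, 0, "deg/s"), trials = trials)
}

#' Build the sinusoidal head-velocity stimulus
#'
#' @param config a [mouse_sim_config()].
#' @return head velocity [vor_trace()], `v(t) = peak_speed * sin(2 pi f t)`.
#' @export
make_sine_stimulus <- function(config) {
  stopifnot(inherits(config, "mouse_sim_config"))
  n <- round(config$duration * config$sample_rate)
  tt <- (seq_len(n) - 1) / config$sample_rate
  vor_trace(config$peak_speed * sin(2 * pi * config$stim_freq * tt),
        config$sample_rate, 0, "deg/s")
}

# draw an (in)homogeneous gamma-renewal spike train by time rescaling:
# unit-mean gamma interarrivals in integrated-rate time, mapped back through
# the inverse cumulative rate. rate_values is stepwise-constant on the grid.
sample_gamma_renewal <- function(rate_values, sample_rate, shape, t0 = 0) {
  dt <- 1 / sample_rate
  lam <- c(0, cumsum(pmax(rate_values, 0)) * dt)
  total <- lam[length(lam)]
  if (total <= 0) return(numeric(0))
  edges <- t0 + (seq_along(lam) - 1) * dt
  arr <- numeric(0)
  acc <- 0
  while (acc < total) {
    m <- max(64L, ceiling((total - acc) + 6 * sqrt((total - acc)) + 16))
    gaps <- stats::rgamma(m, shape = shape, rate = shape)
    arr <- c(arr, acc + cumsum(gaps))
    acc <- arr[length(arr)]
  }
  arr <- arr[arr <= total]
  if (length(arr) == 0) return(numeric(0))
  keep <- c(TRUE, diff(lam) > 0)
  keep[1] <- TRUE
  stats::approx(lam[keep], edges[keep], xout = arr, ties = "ordered")$y
}

# saccadic velocity component: Poisson-timed 30 ms half-sine pulses,
# amplitude ~100 deg/s with random sign
saccade_velocity <- function(n_samp, sample_rate, rate, t0 = 0,
                             sacc_dur = 0.030, amplitude = 100) {
  v <- numeric(n_samp)
  if (rate <= 0 || n_samp == 0) return(list(values = v, times = numeric(0)))
  total <- n_samp / sample_rate
  n_sacc <- stats::rpois(1, rate * total)
  if (n_sacc == 0) return(list(values = v, times = numeric(0)))
  starts <- sort(stats::runif(n_sacc, 0, total - sacc_dur))
  signs <- sample(c(-1, 1), n_sacc, replace = TRUE)
  amps <- amplitude * stats::runif(n_sacc, 0.8, 1.2)
  w <- round(sacc_dur * sample_rate)
  prof <- sin(pi * (seq_len(w) - 0.5) / w)
  for (i in seq_len(n_sacc)) {
    i0 <- floor(starts[i] * sample_rate) + 1
    idx <- i0:min(i0 + w - 1, n_samp)
    v[idx] <- v[idx] + signs[i] * amps[i] * prof[seq_along(idx)]
  }
  list(values = v, times = t0 + starts)
}

#' Generate a synthetic monkey Purkinje-cell session
#'
#' Produces head/eye/visual velocity traces, simple- and complex-spike trains,
#' the trial table, and a ground-truth record of the realized CS flags and
#' implanted per-trial rate offsets. Identical `(config, seed)` produce
#' identical sessions.
#'
#' @param config a [monkey_sim_config()].
#' @return A list of class `"vor_session"` with elements `species`,
#'   `condition`, `sample_rate`, `head`, `eye`, `visual` (velocity traces),
#'   `ss`, `cs` ([spike_train()]s), `trials`, `config` and `ground_truth`.
#' @export
generate_monkey_session <- function(config) {
  validate_monkey_config(config)
  with_seed_(config$seed, generate_monkey_session_(config))
}

generate_monkey_session_ <- function(cfg) {
  stim <- make_pulse_stimulus_(cfg)
  trials <- stim$trials
  head <- stim$head
  n_samp <- length(head$values)
  fs <- cfg$sample_rate
  tt <- trace_times(head)
  total <- n_samp / fs
  on_dir <- on_direction(cfg$condition)
  is_on <- trials$direction == on_dir

  # climbing spikes: Bernoulli in-window CS on 'on' trials at the configured
  # latency; background CSs elsewhere, thinned out of all trial windows so the
  # realized flags match the ground truth exactly
  cs_flag <- rep(FALSE, nrow(trials))
  cs_flag[is_on] <- stats::runif(sum(is_on)) < cfg$cs_prob_in_window
  cs_lat <- stats::runif(nrow(trials), cfg$cs_latency_range[1], cfg$cs_latency_range[2])
  cs_times <- trials$onset[cs_flag] + cs_lat[cs_flag]
  if (cfg$cs_baseline_rate > 0 && total > 0) {
    n_bg <- stats::rpois(1, cfg$cs_baseline_rate * total)
    bg <- stats::runif(n_bg, 0, total)
    in_any_window <- rep(FALSE, length(bg))
    for (i in seq_len(nrow(trials))) {
      in_any_window <- in_any_window |
        (bg >= trials$onset[i] + 0.075 & bg < trials$onset[i] + 0.250)
    }
    cs_times <- c(cs_times, bg[!in_any_window])
  }
  cs_times <- sort(cs_times)

  # implanted plasticity offsets on the rate function (on-direction trials);
  # a CS on trial k contributes delta * persistence^(j-1) to trial k+j
  offsets <- rep(0, nrow(trials))
  state <- 0
  on_idx <- which(is_on)
  for (k in seq_along(on_idx)) {
    offsets[on_idx[k]] <- state
    state <- state * cfg$plasticity_persistence +
      cfg$plasticity_delta * cs_flag[on_idx[k]]
  }

  # simple-spike rate function: baseline + stimulus-locked modulation
  # (scaled head-velocity profile, positive in the 'on' direction) + offsets
  on_sign <- direction_sign(on_dir)
  rate <- cfg$ss_baseline_rate +
    cfg$ss_modulation * on_sign * head$values / cfg$pulse_speed
  for (i in which(offsets != 0)) {
    idx <- sample_span(trials$onset[i], trials$onset[i] + cfg$response_window,
                       fs, n_samp)
    rate[idx] <- rate[idx] + offsets[i]
  }
  ss_times <- sample_gamma_renewal(rate, fs, cfg$ss_gamma_shape)

  # post-CS pause: no simple spikes within pause_duration of any CS
  if (length(cs_times) && cfg$pause_duration > 0) {
    i <- findInterval(ss_times, cs_times)
    in_pause <- i >= 1 & (ss_times - cs_times[pmax(i, 1)]) < cfg$pause_duration
    ss_times <- ss_times[!in_pause]
  }

  sacc <- saccade_velocity(n_samp, fs, cfg$saccade_rate)
  eye_v <- -cfg$vor_gain * head$values + sacc$values +
    stats::rnorm(n_samp, 0, cfg$noise_sd)
  visual_v <- if (cfg$condition == "increase") -head$values else head$values

  gt <- data.frame(onset = trials$onset, direction = trials$direction,
                   on_direction = is_on, cs_in_window = cs_flag,
                   implanted_offset = offsets)
  structure(list(
    species = "monkey", condition = cfg$condition, sample_rate = fs,
    head = head,
    eye = vor_trace(eye_v, fs, 0, "deg/s"),
    visual = vor_trace(visual_v, fs, 0, "deg/s"),
    ss = spike_train(ss_times, "simple"),
    cs = spike_train(cs_times, "complex"),
    trials = trials, config = cfg,
    ground_truth = list(config = cfg, trials = gt,
                        saccade_times = sacc$times)),
    class = "vor_session")
}

#' Generate a synthetic mouse VOR test session
#'
#' Eye position is integrated from smooth eye velocity
#' `-true_gain * head` (phase-shifted by `true_phase`) plus saccadic pulses
#' and white noise. Head position is integrated from head velocity through the
#' same numerical path so that gain estimation from the two position traces is
#' free of common processing error.
#'
#' @param config a [mouse_sim_config()].
#' @return A list of class `"vor_session"` with traces `head_pos`, `head`
#'   (velocity), `eye_pos`, `eye` (velocity), plus `config` and
#'   `ground_truth` (gain, phase).
#' @export
generate_mouse_session <- function(config) {
  stopifnot(inherits(config, "mouse_sim_config"))
  with_seed_(config$seed, {
    fs <- config$sample_rate
    head <- make_sine_stimulus(config)
    n <- length(head$values)
    tt <- trace_times(head)
    phi <- config$true_phase * pi / 180
    eye_smooth <- -config$true_gain * config$peak_speed *
      sin(2 * pi * config$stim_freq * tt + phi)
    sacc <- saccade_velocity(n, fs, config$saccade_rate, amplitude = 150)
    eye_v <- eye_smooth + sacc$values + stats::rnorm(n, 0, config$noise_sd)
    dt <- 1 / fs
    structure(list(
      species = "mouse", condition = "test", sample_rate = fs,
      head_pos = vor_trace(cumsum(head$values) * dt, fs, 0, "deg"),
      head = head,
      eye_pos = vor_trace(cumsum(eye_v) * dt, fs, 0, "deg"),
      eye = vor_trace(eye_v, fs, 0, "deg/s"),
      config = config,
      ground_truth = list(gain = config$true_gain, phase = config$true_phase,
                          saccade_times = sacc$times)),
      class = "vor_session")
  })
}

#' @export
print.vor_session <- function(x, ...) {
  cat(sprintf("<vor_session> %s / %s, %g Hz", x$species, x$condition,
              x$sample_rate))
  if (!is.null(x$trials)) cat(sprintf(", %d trials", nrow(x$trials)))
  if (!is.null(x$ss)) cat(sprintf(", %d SS / %d CS", length(x$ss$times),
                                  length(x$cs$times)))
  cat("\n")
  invisible(x)
}
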