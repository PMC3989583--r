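#' Extrapolate a per-trial change over a training session
#'
#' Accumulates a single-trial change in cerebellar output (expressed in
#' percent of the average firing rate) over many trials. With full
#' persistence every trial's change is retained in its entirety and the
#' cumulative change is `percent_per_trial * n_trials`; with persistence
#' `s < 1` each trial's contribution is retained at a fraction `s` per
#' subsequent trial, giving `percent_per_trial * (1 - s^n) / (1 - s)`.
#'
#' @param percent_per_trial single-trial change, percent.
#' @param n_trials number of trials.
#' @param persistence fraction of each trial's change retained per
#'   subsequent trial (1 = full persistence).
#' @return cumulative change, percent.
#' @examples
#' # a 10% single-trial change, fully persistent over ~1000 trials in an
#' # hour of training, would accumulate to a 10,000% change
#' accumulate_trial_changes(10, 1000)
#' @export
accumulate_trial_changes <- function(percent_per_trial, n_trials,
                                     persistence = 1) {
  stopifnot(n_trials >= 0, persistence >= 0, persistence <= 1)
  if (persistence == 1) return(percent_per_trial * n_trials)
  percent_per_trial * (1 - persistence^n_trials) / (1 - persistence)
}

#' Upper bound on the persistent fraction of single-trial plasticity
#'
#' Compares the net behavioural change observed after training with the
#' change that full persistence of the single-trial effects would have
#' produced: the ratio bounds the fraction of each single-trial change that
#' can persist over the session.
#'
#' @param observed_change_pct net change observed over the session, percent.
#' @param extrapolated_change_pct fully-persistent extrapolation, percent
#'   (from [accumulate_trial_changes()]).
#' @return maximal persistent fraction, percent.
#' @examples
#' # <= 50% net change vs a 10,000% extrapolation: under 1% can persist
#' persistent_fraction_bound(50, accumulate_trial_changes(10, 1000))
#' @export
persistent_fraction_bound <- function(observed_change_pct,
                                      extrapolated_change_pct) {
  if (extrapolated_change_pct <= 0)
    stop("extrapolated change must be positive", call. = FALSE)
  100 * observed_change_pct / extrapolated_change_pct
}
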