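#' Uniformly sampled continuous trace
#'
#' The basic container for continuous signals: eye/head/visual position or
#' velocity in degrees or deg/s, or firing rate in sp/s. A trace is a numeric
#' vector of samples together with its sample rate and start time. Gaps
#' (samples excised and not interpolable, e.g. long saccades) are encoded as
#' `NA` and propagate through all downstream averages.
#'
#' @param values numeric vector of samples; `NA` marks a gap.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param unit unit label carried as metadata (e.g. `"deg/s"`, `"sp/s"`).
#' @return An object of class `"trace"`.
#' @examples
#' tr <- vor_trace(sin(2 * pi * seq(0, 1, by = 0.002)), sample_rate = 500)
#' trace_times(tr)[1:3]
#' @export
vor_trace <- function(values, sample_rate, t0 = 0, unit = "") {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (any(!is.finite(values) & !is.na(values)))
    stop("trace values must be finite or NA (gap)", call. = FALSE)
  structure(
    list(values = as.numeric(values), sample_rate = as.numeric(sample_rate),
         t0 = as.numeric(t0), unit = unit),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<trace> %d samples @ %g Hz, t0 = %g s%s, %d gap samples\n",
              n, x$sample_rate, x$t0,
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else "",
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param x a [vor_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$values) - 1) / x$sample_rate
}

#' Index of the sample at or immediately before a time point
#' @noRd
trace_index <- function(x, t) {
  pmin(pmax(1L, floor((t - x$t0) * x$sample_rate + 1e-9) + 1L), length(x$values))
}

#' Check that two traces share sampling (rate, length, origin)
#' @noRd
check_aligned <- function(a, b, what = "traces") {
  if (length(a$values) != length(b$values) ||
      abs(a$sample_rate - b$sample_rate) > 1e-9 ||
      abs(a$t0 - b$t0) > 1e-9)
    stop(sprintf("%s must share length, sample rate and start time", what),
         call. = FALSE)
  invisible(TRUE)
}

#' NA-aware centred boxcar smoothing
#'
#' Boxcar (moving-average) smoothing with a centred window, shrinking at the
#' edges. Gap (`NA`) samples are excluded from each window mean; a sample that
#' is itself a gap stays a gap.
#'
#' @param values numeric vector.
#' @param width window width in samples (>= 1).
#' @return smoothed numeric vector of the same length.
#' @keywords internal
boxcar_smooth <- function(values, width) {
  width <- max(1L, as.integer(round(width)))
  if (width == 1L) return(values)
  n <- length(values)
  half <- width %/% 2  # symmetric window of 2*half + 1 samples
  ok <- !is.na(values)
  v <- ifelse(ok, values, 0)
  cs <- c(0, cumsum(v))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- ifelse(cnt > 0, tot / cnt, NA_real_)
  out[!ok] <- NA_real_
  out
}

#' Evaluate randomness with a local, restorable seed
#' @noRd
with_seed_ <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
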