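#' Zero-phase low-pass filtering and differentiation
#'
#' Position traces are low-pass filtered with a Butterworth filter of the
#' given order and cutoff, applied forward and backward (zero phase, so event
#' latencies are preserved), then differentiated by central differences.
#' Units deg -> deg/s. The first and last samples, where the central
#' difference is undefined, are gap-marked.
#'
#' @param position a position [vor_trace()] in degrees.
#' @param cutoff_hz low-pass cutoff frequency, Hz (must be below Nyquist).
#' @param order filter order.
#' @return a velocity [vor_trace()] in deg/s.
#' @export
lowpass_differentiate <- function(position, cutoff_hz = 9, order = 3) {
  stopifnot(inherits(position, "trace"))
  nyq <- position$sample_rate / 2
  if (cutoff_hz >= nyq)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  if (anyNA(position$values))
    stop("cannot filter a trace containing gaps", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # odd-reflection padding so the forward-backward pass settles before the
  # data proper; the pad is discarded afterwards
  mu <- mean(position$values)
  x <- position$values - mu  # centring shrinks the pad transient; linear op
  n <- length(x)
  pad <- min(n - 1, ceiling(6 * position$sample_rate / cutoff_hz))
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    filt <- signal::filtfilt(bf, c(left, x, right))
    filt <- filt[(pad + 1):(pad + n)]
  } else {
    filt <- signal::filtfilt(bf, x)
  }
  v <- rep(NA_real_, n)
  if (n >= 3)
    v[2:(n - 1)] <- (filt[3:n] - filt[1:(n - 2)]) * position$sample_rate / 2
  vor_trace(v, position$sample_rate, position$t0, "deg/s")
}

#' Detect saccades by velocity threshold
#'
#' Flags samples where the eye velocity deviates from its stimulus-predicted
#' component by more than a threshold, dilates the flagged region by `pad` on
#' both sides, and merges overlapping intervals. If no threshold is given, it
#' defaults to 3 times the robust (MAD-based) SD of the residual velocity.
#'
#' @param velocity eye velocity [vor_trace()].
#' @param threshold residual speed threshold, deg/s; `NULL` for the robust
#'   default.
#' @param pad padding added to each side of a detection, s.
#' @param predicted optional [vor_trace()] of the stimulus-predicted smooth eye
#'   velocity (e.g. `-gain * head`); defaults to zero.
#' @return A list of class `"saccade_mask"`: `mask` (logical per sample) and
#'   `intervals` (data frame of half-open `[start, end)` times in s).
#' @export
detect_saccades <- function(velocity, threshold = NULL, pad = 0.010,
                            predicted = NULL) {
  stopifnot(inherits(velocity, "trace"))
  resid <- velocity$values
  if (!is.null(predicted)) {
    check_aligned(velocity, predicted, "velocity and predicted traces")
    resid <- resid - predicted$values
  }
  auto <- is.null(threshold)
  if (auto) {
    med <- stats::median(resid, na.rm = TRUE)
    threshold <- 3 * stats::mad(resid, na.rm = TRUE)
    resid <- resid - med
    if (threshold == 0) {
      # perfectly smooth residual: nothing to detect
      return(mask_to_saccade_mask(rep(FALSE, length(resid)),
                                  velocity$sample_rate, velocity$t0))
    }
  }
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  hit <- !is.na(resid) & abs(resid) > threshold
  n <- length(hit)
  fs <- velocity$sample_rate
  pad_n <- round(pad * fs)
  if (any(hit) && pad_n > 0) {
    idx <- which(hit)
    lo <- pmax(idx - pad_n, 1L)
    hi <- pmin(idx + pad_n, n)
    for (k in seq_along(idx)) hit[lo[k]:hi[k]] <- TRUE
  }
  mask_to_saccade_mask(hit, fs, velocity$t0)
}

mask_to_saccade_mask <- function(mask, sample_rate, t0) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  iv <- data.frame(
    start = t0 + (starts[keep] - 1L) / sample_rate,
    end = t0 + ends[keep] / sample_rate)
  structure(list(mask = mask, intervals = iv, sample_rate = sample_rate,
                 t0 = t0), class = "saccade_mask")
}

#' Excise masked intervals and interpolate short gaps
#'
#' Masked intervals no longer than `max_gap` are replaced by linear
#' interpolation between the flanking smooth samples; longer intervals are
#' removed (gap-marked with `NA`), and the gap propagates to all downstream
#' averages. Samples outside masked intervals are never changed.
#'
#' @param velocity a [vor_trace()].
#' @param mask a `"saccade_mask"` from [detect_saccades()], aligned to the
#'   trace.
#' @param max_gap longest interpolable interval, s.
#' @return a [vor_trace()] with saccades interpolated or excised.
#' @export
excise_interpolate <- function(velocity, mask, max_gap = 0.2) {
  stopifnot(inherits(velocity, "trace"), inherits(mask, "saccade_mask"))
  if (length(mask$mask) != length(velocity$values))
    stop("mask is not aligned to the trace", call. = FALSE)
  v <- velocity$values
  if (all(mask$mask)) {
    warning("mask covers the entire trace; all samples removed")
    v[] <- NA_real_
    return(vor_trace(v, velocity$sample_rate, velocity$t0, velocity$unit))
  }
  r <- rle(mask$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fs <- velocity$sample_rate
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    len_s <- (i1 - i0 + 1L) / fs
    left <- i0 - 1L; right <- i1 + 1L
    if (len_s <= max_gap && left >= 1L && right <= length(v) &&
        !is.na(v[left]) && !is.na(v[right])) {
      v[i0:i1] <- v[left] + (v[right] - v[left]) *
        (seq.int(i0, i1) - left) / (right - left)
    } else {
      v[i0:i1] <- NA_real_
    }
  }
  vor_trace(v, velocity$sample_rate, velocity$t0, velocity$unit)
}

#' Retinal slip velocity
#'
#' Image motion on the retina: the visual stimulus velocity (world frame)
#' minus the sum of eye velocity (head frame) and head velocity (world
#' frame). Positive values are contraversive. Gap samples in any input
#' propagate.
#'
#' @param visual_vel,eye_vel,head_vel aligned velocity [vor_trace()]s, deg/s.
#' @return retinal slip [vor_trace()], deg/s.
#' @export
retinal_slip <- function(visual_vel, eye_vel, head_vel) {
  stopifnot(inherits(visual_vel, "trace"), inherits(eye_vel, "trace"),
            inherits(head_vel, "trace"))
  check_aligned(visual_vel, eye_vel, "visual and eye traces")
  check_aligned(visual_vel, head_vel, "visual and head traces")
  vor_trace(visual_vel$values - (eye_vel$values + head_vel$values),
        visual_vel$sample_rate, visual_vel$t0, "deg/s")
}
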