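#' Least-squares sine fit at a known frequency
#'
#' Fits `a*sin(2*pi*f*t) + b*cos(2*pi*f*t) + c` to the valid (non-gap)
#' samples of a trace by linear least squares; the stimulus frequency is
#' known and not free, which makes the fit closed-form. Amplitude is
#' `sqrt(a^2 + b^2)` and phase `atan2(b, a)` in degrees in (-180, 180].
#'
#' @param x a [vor_trace()] (gap samples are dropped from the fit).
#' @param freq stimulus frequency, Hz.
#' @return list of class `"sine_fit"`: `amplitude`, `phase` (deg), `offset`,
#'   `frequency`, `residual_rms`, `n_used`.
#' @export
fit_sine <- function(x, freq) {
  stopifnot(inherits(x, "trace"))
  tt <- trace_times(x)
  ok <- !is.na(x$values)
  span <- if (any(ok)) diff(range(tt[ok])) else 0
  if (sum(ok) < 8 || span < 2 / freq)
    stop("need at least two cycles of valid data for the sine fit",
         call. = FALSE)
  s <- sin(2 * pi * freq * tt[ok])
  co <- cos(2 * pi * freq * tt[ok])
  fit <- stats::lm.fit(cbind(s, co, 1), x$values[ok])
  a <- fit$coefficients[[1]]; b <- fit$coefficients[[2]]
  phase <- atan2(b, a) * 180 / pi
  if (phase <= -180) phase <- phase + 360
  structure(list(amplitude = sqrt(a^2 + b^2), phase = phase,
                 offset = fit$coefficients[[3]], frequency = freq,
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 n_used = sum(ok)),
            class = "sine_fit")
}

#' VOR gain from eye and head sine fits
#'
#' Gain is the amplitude of the eye-velocity fit divided by the amplitude of
#' the head-velocity fit; the phase difference (eye relative to head,
#' degrees, positive = eye leads) is reported alongside. Compensatory VOR
#' eye velocity is anti-phase to the head, so the gain uses amplitudes only.
#'
#' @param eye_fit,head_fit `"sine_fit"` objects from [fit_sine()].
#' @param timepoint optional label (e.g. `"pre"`, `"post1"`, `"2hr"`).
#' @return list of class `"gain_measurement"`: `gain`, `phase_diff`,
#'   `eye_fit`, `head_fit`, `timepoint`.
#' @export
compute_gain <- function(eye_fit, head_fit, timepoint = NA_character_) {
  stopifnot(inherits(eye_fit, "sine_fit"), inherits(head_fit, "sine_fit"))
  if (head_fit$amplitude < 1e-12)
    stop("head-velocity amplitude is zero; gain undefined", call. = FALSE)
  dphi <- eye_fit$phase - head_fit$phase
  dphi <- ((dphi + 180) %% 360) - 180
  structure(list(gain = eye_fit$amplitude / head_fit$amplitude,
                 phase_diff = dphi, eye_fit = eye_fit, head_fit = head_fit,
                 timepoint = timepoint),
            class = "gain_measurement")
}

#' Measure VOR gain from a mouse session
#'
#' The behavioural pipeline: eye and head position are low-pass filtered
#' (9 Hz, third-order Butterworth, zero phase) and differentiated through
#' the same path, saccades are removed from the eye velocity by a velocity
#' threshold on the residual (gap samples are dropped from the fit, not
#' interpolated), and both velocities are fit with sine waves at the
#' stimulus frequency.
#'
#' @param session a mouse `"vor_session"`.
#' @param cutoff_hz,order filter parameters for [lowpass_differentiate()].
#' @param saccade_threshold residual speed threshold, deg/s; `NULL` for the
#'   robust default.
#' @param desaccade drop saccade samples before fitting.
#' @param timepoint optional label.
#' @return a `"gain_measurement"`.
#' @export
measure_vor_gain <- function(session, cutoff_hz = 9, order = 3,
                             saccade_threshold = NULL, desaccade = TRUE,
                             timepoint = NA_character_) {
  stopifnot(inherits(session, "vor_session"), session$species == "mouse")
  freq <- session$config$stim_freq
  eye_v <- lowpass_differentiate(session$eye_pos, cutoff_hz, order)
  head_v <- lowpass_differentiate(session$head_pos, cutoff_hz, order)
  if (desaccade) {
    pred_fit <- fit_sine(eye_v, freq)
    tt <- trace_times(eye_v)
    pred <- vor_trace(pred_fit$amplitude *
                    sin(2 * pi * freq * tt + pred_fit$phase * pi / 180) +
                    pred_fit$offset,
                  eye_v$sample_rate, eye_v$t0, "deg/s")
    mask <- detect_saccades(eye_v, threshold = saccade_threshold,
                            predicted = pred)
    # drop the same epochs from eye and head so both fits see identical
    # samples and common processing error cancels in the gain ratio
    ev <- eye_v$values; hv <- head_v$values
    ev[mask$mask] <- NA_real_
    hv[mask$mask] <- NA_real_
    eye_v <- vor_trace(ev, eye_v$sample_rate, eye_v$t0, eye_v$unit)
    head_v <- vor_trace(hv, head_v$sample_rate, head_v$t0, head_v$unit)
  }
  compute_gain(fit_sine(eye_v, freq), fit_sine(head_v, freq),
               timepoint = timepoint)
}

#' Percent-change learning values relative to baseline
#'
#' Learning is the percent change in VOR gain relative to the pre-training
#' baseline: 0% means no learning.
#'
#' @param measurements list of `"gain_measurement"` objects (or numeric
#'   gains), one per timepoint.
#' @param pre the pre-training `"gain_measurement"` (or numeric gain).
#' @return data frame with `timepoint` and `percent_change`.
#' @export
learning_curve <- function(measurements, pre) {
  g0 <- if (inherits(pre, "gain_measurement")) pre$gain else as.numeric(pre)
  if (!is.finite(g0) || g0 <= 0)
    stop("pre-training gain must be positive", call. = FALSE)
  if (inherits(measurements, "gain_measurement"))
    measurements <- list(measurements)
  gains <- vapply(measurements, function(m)
    if (inherits(m, "gain_measurement")) m$gain else as.numeric(m), numeric(1))
  tp <- vapply(seq_along(measurements), function(i) {
    m <- measurements[[i]]
    if (inherits(m, "gain_measurement") && !is.na(m$timepoint)) m$timepoint
    else as.character(i)
  }, character(1))
  data.frame(timepoint = tp, percent_change = 100 * (gains - g0) / g0,
             stringsAsFactors = FALSE)
}

shapiro_ok <- function(x, alpha = 0.05) {
  # constant data carries no evidence against normality; flag but pass
  if (length(unique(x)) < 3 || stats::sd(x) == 0) return(TRUE)
  stats::shapiro.test(x)$p.value >= alpha
}

dunn_vs_control <- function(values, groups, control) {
  # Dunn's rank-sum z tests of each group against the control, with tie
  # correction; two-sided p, unadjusted
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- setdiff(unique(groups), control)
  res <- lapply(lev, function(g) {
    i <- groups == g; j <- groups == control
    ni <- sum(i); nj <- sum(j)
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    data.frame(group = g, z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  do.call(rbind, res)
}

#' Normality-gated comparison of learning values
#'
#' Statistical testing with the normality gate: each group is first checked
#' with the Shapiro-Wilk test (alpha = 0.05); if every group is consistent
#' with normality a parametric test is used, otherwise the non-parametric
#' counterpart. Designs and test pairs: one-sample vs zero (one-sample t /
#' Wilcoxon signed rank), two-group (unpaired t / Mann-Whitney), multi-group
#' (one-way ANOVA with Dunnett's post-hoc vs the control group /
#' Kruskal-Wallis with Dunn's post-hoc), repeated-measures (two-way ANOVA
#' with subject error term and Fisher-LSD-style post-hoc / Friedman).
#'
#' @param values numeric values (e.g. percent-change learning), or for
#'   `"one_sample"` a single group.
#' @param groups factor/character of group labels (ignored for
#'   `"one_sample"`).
#' @param design one of `"one_sample"`, `"two_group"`, `"multi_group"`,
#'   `"repeated_measures"`.
#' @param subject subject ids (required for `"repeated_measures"`).
#' @param control control group label for post-hoc comparisons
#'   (`"multi_group"`); defaults to the first group level.
#' @param mu null value for `"one_sample"`.
#' @param alpha significance level of the normality gate.
#' @return list with `design`, `path` (`"parametric"` or
#'   `"nonparametric"`), `test` (name), `statistic`, `p`, optional
#'   `posthoc` data frame, and `normality` (per-group Shapiro outcome).
#' @export
compare_conditions <- function(values, groups = NULL,
                               design = c("one_sample", "two_group",
                                          "multi_group", "repeated_measures"),
                               subject = NULL, control = NULL, mu = 0,
                               alpha = 0.05) {
  design <- match.arg(design)
  if (design == "one_sample") {
    grp_list <- list(values)
  } else {
    if (is.null(groups)) stop("`groups` required for this design", call. = FALSE)
    groups <- as.character(groups)
    grp_list <- split(values, groups)
  }
  if (any(vapply(grp_list, length, integer(1)) < 3))
    stop("each group needs at least 3 values", call. = FALSE)
  normal <- vapply(grp_list, shapiro_ok, logical(1), alpha = alpha)
  parametric <- all(normal)
  path <- if (parametric) "parametric" else "nonparametric"

  degenerate_p <- function() {
    # all observations identical across groups: no evidence of any effect
    list(statistic = 0, p = 1, degenerate = TRUE)
  }

  res <- switch(design,
    one_sample = {
      if (stats::sd(values) == 0) {
        eq <- isTRUE(all.equal(mean(values), mu))
        list(test = "one-sample t (degenerate)", statistic = 0,
             p = if (eq) 1 else 0)
      } else if (parametric) {
        ht <- stats::t.test(values, mu = mu)
        list(test = "one-sample t", statistic = unname(ht$statistic),
             p = ht$p.value)
      } else {
        ht <- stats::wilcox.test(values, mu = mu, exact = FALSE)
        list(test = "Wilcoxon signed rank", statistic = unname(ht$statistic),
             p = ht$p.value)
      }
    },
    two_group = {
      a <- grp_list[[1]]; b <- grp_list[[2]]
      if (stats::sd(values) == 0) {
        c(list(test = "two-group (degenerate)"), degenerate_p())
      } else if (parametric) {
        ht <- stats::t.test(a, b)
        list(test = "unpaired t", statistic = unname(ht$statistic),
             p = ht$p.value)
      } else {
        ht <- stats::wilcox.test(a, b, exact = FALSE)
        list(test = "Mann-Whitney", statistic = unname(ht$statistic),
             p = ht$p.value)
      }
    },
    multi_group = {
      g <- factor(groups)
      if (is.null(control)) control <- levels(g)[1]
      if (stats::sd(values) == 0) {
        c(list(test = "multi-group (degenerate)"), degenerate_p())
      } else if (parametric) {
        fit <- stats::aov(values ~ g)
        an <- summary(fit)[[1]]
        ph <- NULL
        if (requireNamespace("multcomp", quietly = TRUE)) {
          g <- stats::relevel(g, ref = control)
          fit <- stats::aov(values ~ g)
          mc <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
          sm <- summary(mc)
          ph <- data.frame(group = sub(" - .*", "", names(sm$test$coefficients)),
                           z = unname(sm$test$tstat),
                           p = unname(as.numeric(sm$test$pvalues)))
        }
        list(test = "one-way ANOVA + Dunnett",
             statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1],
             posthoc = ph)
      } else {
        ht <- stats::kruskal.test(values, g)
        list(test = "Kruskal-Wallis + Dunn",
             statistic = unname(ht$statistic), p = ht$p.value,
             posthoc = dunn_vs_control(values, groups, control))
      }
    },
    repeated_measures = {
      if (is.null(subject))
        stop("`subject` required for repeated measures", call. = FALSE)
      g <- factor(groups); id <- factor(subject)
      if (parametric) {
        fit <- stats::aov(values ~ g + Error(id))
        an <- summary(fit)
        within <- an[["Error: Within"]][[1]]
        ph <- NULL
        if (requireNamespace("emmeans", quietly = TRUE)) {
          lmfit <- stats::lm(values ~ g + id)
          em <- emmeans::emmeans(lmfit, "g")
          pw <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
          ph <- data.frame(contrast = pw$contrast, t = pw$t.ratio, p = pw$p.value)
        }
        list(test = "repeated-measures ANOVA + Fisher LSD",
             statistic = within[["F value"]][1], p = within[["Pr(>F)"]][1],
             posthoc = ph)
      } else {
        ht <- stats::friedman.test(values, g, id)
        list(test = "Friedman", statistic = unname(ht$statistic),
             p = ht$p.value)
      }
    })
  c(list(design = design, path = path,
         normality = stats::setNames(normal, names(grp_list))), res)
}
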