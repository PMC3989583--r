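#' Write a session bundle to disk
#'
#' A session bundle is a directory of plain-text files: `manifest.json`
#' (species, condition, sample rates, channel units, seed/provenance and
#' per-file checksums), `traces.csv` (one column per channel, time implicit,
#' with a commented header carrying `sample_rate` and `t0`), `spikes.csv`
#' (`time_s`, `kind`), `trials.csv`, and a `ground_truth.json` sidecar for
#' synthetic sessions.
#'
#' @param session a `"vor_session"`.
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "vor_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  chan_names <- intersect(c("head", "eye", "visual", "head_pos", "eye_pos"),
                          names(session))
  chans <- session[chan_names]
  tr_file <- file.path(path, "traces.csv")
  con <- file(tr_file, "w")
  writeLines(sprintf("# sample_rate=%.17g t0=%.17g", session$sample_rate,
                     chans[[1]]$t0), con)
  writeLines(paste(chan_names, collapse = ","), con)
  cols <- lapply(chans, function(tr) sprintf("%.17g", tr$values))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  close(con)

  files <- "traces.csv"
  if (!is.null(session$ss)) {
    sp <- rbind(data.frame(time_s = session$ss$times, kind = "simple"),
                data.frame(time_s = session$cs$times, kind = "complex"))
    sp <- sp[order(sp$time_s), ]
    con <- file(file.path(path, "spikes.csv"), "w")
    writeLines("time_s,kind", con)
    writeLines(sprintf("%.17g,%s", sp$time_s, sp$kind), con)
    close(con)
    files <- c(files, "spikes.csv")
  }
  if (!is.null(session$trials)) {
    utils::write.csv(session$trials, file.path(path, "trials.csv"),
                     row.names = FALSE)
    files <- c(files, "trials.csv")
  }
  if (!is.null(session$ground_truth)) {
    session$ground_truth$config <- unclass(session$ground_truth$config)
    jsonlite::write_json(session$ground_truth,
                         file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, "ground_truth.json")
  }
  units <- vapply(chans, function(tr) tr$unit, character(1))
  manifest <- list(
    format = "vortrial-session-bundle", version = 1,
    species = session$species, condition = session$condition,
    sample_rate = session$sample_rate,
    channels = as.list(units),
    seed = session$config$seed,
    config = unclass(session$config),
    checksums = as.list(tools::md5sum(file.path(path, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session bundle
#'
#' Validates the manifest (file presence, checksums, sample-rate consistency
#' between the manifest and the trace header) and reconstructs the typed
#' session.
#'
#' @param path bundle directory written by [write_session()].
#' @return a `"vor_session"`.
#' @export
read_session <- function(path) {
  mf_file <- file.path(path, "manifest.json")
  if (!file.exists(mf_file)) stop("missing manifest.json in ", path, call. = FALSE)
  mf <- jsonlite::read_json(mf_file, simplifyVector = TRUE)
  for (f in names(mf$checksums)) {
    fp <- file.path(path, f)
    if (!file.exists(fp))
      stop(sprintf("bundle file missing: %s", f), call. = FALSE)
    if (!identical(unname(tools::md5sum(fp)), mf$checksums[[f]]))
      stop(sprintf("checksum mismatch for %s", f), call. = FALSE)
  }
  hdr <- readLines(file.path(path, "traces.csv"), n = 1)
  m <- regmatches(hdr, regexec("sample_rate=([0-9.eE+-]+) t0=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3) stop("traces.csv lacks a sample-rate header", call. = FALSE)
  fs_hdr <- as.numeric(m[2]); t0 <- as.numeric(m[3])
  if (abs(fs_hdr - mf$sample_rate) > 1e-9)
    stop(sprintf("sample rate mismatch: manifest %g vs trace header %g",
                 mf$sample_rate, fs_hdr), call. = FALSE)
  tr <- utils::read.csv(file.path(path, "traces.csv"), comment.char = "#")
  if (!setequal(names(tr), names(mf$channels)))
    stop("trace channels do not match the manifest", call. = FALSE)
  session <- list(species = mf$species, condition = mf$condition,
                  sample_rate = mf$sample_rate)
  for (ch in names(mf$channels))
    session[[ch]] <- vor_trace(tr[[ch]], fs_hdr, t0, mf$channels[[ch]])
  if ("spikes.csv" %in% names(mf$checksums)) {
    sp <- utils::read.csv(file.path(path, "spikes.csv"))
    session$ss <- spike_train(sp$time_s[sp$kind == "simple"], "simple")
    session$cs <- spike_train(sp$time_s[sp$kind == "complex"], "complex")
  }
  if ("trials.csv" %in% names(mf$checksums))
    session$trials <- utils::read.csv(file.path(path, "trials.csv"),
                                      stringsAsFactors = FALSE)
  if ("ground_truth.json" %in% names(mf$checksums))
    session$ground_truth <- jsonlite::read_json(
      file.path(path, "ground_truth.json"), simplifyVector = TRUE)
  cfg <- mf$config
  if (!is.null(cfg))
    class(cfg) <- if (mf$species == "monkey") "monkey_sim_config" else
      "mouse_sim_config"
  session$config <- cfg
  structure(session, class = "vor_session")
}

#' Pipeline run configuration
#'
#' Defaults reproduce the published analysis settings: 75-250 ms CF window,
#' 50 ms CS probability bins, 25 ms response smoothing, 10 s moving-average
#' baseline, first 100 ms response span, 1000 bootstrap repetitions with a
#' mean +/- 2 SD confidence band.
#'
#' @param species `"monkey"` or `"mouse"`.
#' @param n_cells number of cells (monkey) or mice to simulate.
#' @param sim named list of overrides for [monkey_sim_config()] /
#'   [mouse_sim_config()].
#' @param window CF analysis window, s.
#' @param cs_bin CS probability bin width, s.
#' @param span response span, s.
#' @param smooth smoothing window, s.
#' @param baseline_window moving-baseline window, s.
#' @param n_reps bootstrap repetitions.
#' @param seed master seed; per-cell seeds are derived from it.
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `"run_config"`.
#' @export
pipeline_config <- function(species = c("monkey", "mouse"), n_cells = 10,
                            sim = list(), window = c(0.075, 0.250),
                            cs_bin = 0.05, span = c(0, 0.1), smooth = 0.025,
                            baseline_window = 10, n_reps = 1000, seed = 0,
                            out_dir = NULL) {
  species <- match.arg(species)
  structure(list(species = species, n_cells = n_cells, sim = sim,
                 window = window, cs_bin = cs_bin, span = span,
                 smooth = smooth, baseline_window = baseline_window,
                 n_reps = n_reps, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Simulate a cohort of monkey cells
#'
#' @param n_cells number of cells.
#' @param sim named overrides for [monkey_sim_config()].
#' @param seed master seed; cell k uses `seed + k`.
#' @return list of `"vor_session"` objects.
#' @export
simulate_monkey_cells <- function(n_cells, sim = list(), seed = 0) {
  lapply(seq_len(n_cells), function(k) {
    cfg <- do.call(monkey_sim_config, utils::modifyList(sim, list(seed = seed + k)))
    generate_monkey_session(cfg)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates the configured cohort and runs the full analysis. For monkey
#' configurations: trial-by-trial pair analysis with bootstrap bands, CS
#' probability histogram, session slopes with the one-sample t test, and
#' post-CS pause summary. For mouse configurations: VOR gain per session and
#' percent-change learning relative to the first (pre) session. Results are
#' returned and, when `out_dir` is set, written as columnar CSV plus a JSON
#' summary stamped with the seed and a configuration hash.
#'
#' @param config a [pipeline_config()].
#' @return list of results (content depends on species).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  res <- if (config$species == "monkey") run_pipeline_monkey(config)
         else run_pipeline_mouse(config)
  res$provenance <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(textConnection_hash(config))),
    timestamp_utc = format(Sys.time(), tz = "UTC"))
  if (!is.null(config$out_dir)) write_pipeline_results(res, config)
  res
}

# hash helper: serialize config deterministically to a temp file
textConnection_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, null = "null")
  f
}

run_pipeline_monkey <- function(config) {
  sessions <- simulate_monkey_cells(config$n_cells, config$sim, config$seed)
  tbt <- trial_by_trial_analysis(
    sessions, n_reps = config$n_reps, smooth = config$smooth,
    window = config$window, span = config$span,
    baseline_window = config$baseline_window)
  slopes <- vapply(sessions, function(s) {
    ca <- cell_trial_analysis(s, window = config$window, span = config$span,
                              baseline_window = config$baseline_window)
    session_slope(ca$response_means)$slope
  }, numeric(1))
  cshist <- cs_probability_histogram(
    select_on_direction(sessions[[1]]$trials, sessions[[1]]$condition),
    sessions[[1]]$cs, bin = config$cs_bin)
  pause <- post_cs_pause(sessions[[1]]$cs, sessions[[1]]$ss)
  list(species = "monkey", sessions = sessions, trial_by_trial = tbt,
       slopes = slopes, slope_test = slopes_group_test(slopes),
       cs_histogram = cshist, mean_pause = pause$mean_pause)
}

run_pipeline_mouse <- function(config) {
  gains <- vapply(seq_len(config$n_cells), function(k) {
    cfg <- do.call(mouse_sim_config,
                   utils::modifyList(config$sim, list(seed = config$seed + k)))
    measure_vor_gain(generate_mouse_session(cfg))$gain
  }, numeric(1))
  learning <- if (length(gains) > 1)
    learning_curve(as.list(gains[-1]), gains[1]) else NULL
  list(species = "mouse", gains = gains, learning = learning)
}

write_pipeline_results <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# seed=%s config_hash=%s", config$seed,
                 res$provenance$config_hash)
  summary <- list(provenance = res$provenance, species = res$species)
  if (res$species == "monkey") {
    tbt <- res$trial_by_trial
    tab <- data.frame(time_s = tbt$time)
    for (cl in names(tbt$classes)) {
      g <- tbt$classes[[cl]]
      tab[[paste0(cl, "_mean")]] <- g$grand$mean
      tab[[paste0(cl, "_sem")]] <- g$grand$sem
      if (!is.null(g$band)) {
        tab[[paste0(cl, "_ci_lo")]] <- g$band$lower
        tab[[paste0(cl, "_ci_hi")]] <- g$band$upper
      }
      summary[[paste0(cl, "_span_mean_sp_s")]] <- mean(g$grand$mean, na.rm = TRUE)
    }
    write_commented_csv(tab, file.path(config$out_dir, "pair_differences.csv"), hdr)
    write_commented_csv(data.frame(cell = seq_along(res$slopes),
                                   slope_sp_s_per_trial = res$slopes),
                        file.path(config$out_dir, "session_slopes.csv"), hdr)
    summary$slope_t <- res$slope_test$t
    summary$slope_p <- res$slope_test$p
    summary$mean_pause_s <- res$mean_pause
  } else {
    write_commented_csv(data.frame(session = seq_along(res$gains),
                                   gain = res$gains),
                        file.path(config$out_dir, "gains.csv"), hdr)
    summary$gains <- res$gains
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(config$out_dir)
}

write_commented_csv <- function(df, path, header_line) {
  con <- file(path, "w")
  writeLines(header_line, con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}
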