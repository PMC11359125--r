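# Readers and writers for the frame-log CSV, events CSV, EEG CSV, and the
# JSON evaluation report, plus the run configuration.

FRAME_LOG_COLUMNS <- c("t_s", "n_faces", "pitch_deg", "yaw_deg", "roll_deg",
                       "gaze_pitch_deg", "gaze_yaw_deg", "gaze_x_cm", "gaze_y_cm")

#' Read a frame-log CSV
#'
#' The frame log has exactly the columns \code{t_s, n_faces, pitch_deg,
#' yaw_deg, roll_deg, gaze_pitch_deg, gaze_yaw_deg, gaze_x_cm, gaze_y_cm};
#' empty cells become missing fields.  Timestamps must be strictly
#' increasing.
#'
#' @param path Path to the CSV file.
#' @return Frame-stream data.frame.
#' @export
read_frame_log <- function(path) {
  if (!file.exists(path)) stop("read_frame_log: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("read_frame_log: empty frame log")
  if (!identical(sort(names(df)), sort(FRAME_LOG_COLUMNS))) {
    bad <- c(setdiff(names(df), FRAME_LOG_COLUMNS), setdiff(FRAME_LOG_COLUMNS, names(df)))
    stop("read_frame_log: column mismatch: ", paste(bad, collapse = ", "))
  }
  df <- df[, FRAME_LOG_COLUMNS]
  for (cc in FRAME_LOG_COLUMNS) df[[cc]] <- as.numeric(df[[cc]])
  df$n_faces <- as.integer(df$n_faces)
  dt <- diff(df$t_s)
  if (any(is.na(df$t_s)) || any(dt <= 0)) {
    row <- if (any(is.na(df$t_s))) which(is.na(df$t_s))[1] else which(dt <= 0)[1] + 1L
    stop("read_frame_log: timestamps not strictly increasing at row ", row)
  }
  df
}

#' Write a frame-log CSV
#'
#' @param stream Frame-stream data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_frame_log <- function(stream, path) {
  utils::write.csv(stream[, FRAME_LOG_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write classified gaze events as CSV
#'
#' Columns: kind, t_start, t_end, x, y, effective, serious (the flags are
#' empty for non-fixation events).
#'
#' @param events data.frame of events (fixations should already carry
#'   \code{effective}/\code{serious} flags from [label_fixations()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events_csv <- function(events, path) {
  for (cc in c("effective", "serious"))
    if (is.null(events[[cc]])) events[[cc]] <- NA
  utils::write.csv(events[, c("kind", "t_start", "t_end", "x", "y",
                              "effective", "serious")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an EEG session from CSV
#'
#' Column 1 is \code{time_s}; the remaining columns are channels named per
#' the 10-20 system, values in microvolts.  The sampling rate is inferred
#' from the median timestamp step unless given.
#'
#' @param path Path to the CSV file.
#' @param sfreq Sampling rate in Hz; inferred from timestamps when NULL.
#' @return \code{eeg_session}.
#' @export
read_eeg_csv <- function(path, sfreq = NULL) {
  if (!file.exists(path)) stop("read_eeg_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("read_eeg_csv: need a time column plus at least one channel")
  if (names(df)[1] != "time_s") stop("read_eeg_csv: first column must be time_s")
  if (is.null(sfreq)) {
    dt <- stats::median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) stop("read_eeg_csv: cannot infer sampling rate")
    sfreq <- 1 / dt
  }
  eeg_session(as.matrix(df[, -1, drop = FALSE]), sfreq, names(df)[-1])
}

#' Write an EEG session as CSV
#'
#' @param s \code{eeg_session}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_eeg_csv <- function(s, path) {
  df <- data.frame(time_s = (seq_len(nrow(s$samples)) - 1) / s$sfreq)
  for (ch in s$channels) df[[ch]] <- s$samples[, ch]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Every tunable parameter of the pipeline with its default: screen
#' geometry, indicator thresholds, event-classification parameters, EEG
#' band and Welch settings, and the master seed.
#'
#' @param ... Named overrides of top-level fields.
#' @return Nested list of class \code{run_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    screen = list(width_cm = 34.5, height_cm = 19.4, roi_top_fraction = 0.7),
    thresholds = unclass(index_thresholds()),
    events = list(dispersion_cm = 1.69, min_duration_ms = 500, serious_min_s = 3,
                  saccade_min_deg = 10, bin_frames = 100, reading_min_run = 3,
                  reading_vertical_ratio = 0.2),
    window_s = 600,
    eeg = list(highpass_hz = 0.1, notch_hz = 50, notch_q = 30, epoch_s = 4,
               amp_uv = 200, segment_s = 2, overlap = 0.5,
               channels = c("F3", "Fz", "F4"), min_diff_db = 1,
               theta_hz = c(4, 8), beta_hz = c(13, 32)),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @return \code{read_run_config}: the configuration list;
#'   \code{write_run_config}: the path, invisibly.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_run_config: the 'yaml' package is required")
  cfg <- default_config()
  over <- yaml::read_yaml(path)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg \code{run_config} list.
#' @export
write_run_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("write_run_config: the 'yaml' package is required")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write the JSON evaluation report
#'
#' Emits schema version, a configuration echo, the per-window indicator
#' values with pass flags and verdicts, and (when supplied) the EEG
#' half-split comparison.  Absent optional indicators (GPC/GTFI) are
#' omitted from each window object rather than null-filled.  Values
#' round-trip through [jsonlite::read_json] to double precision.
#'
#' @param report Per-window data.frame from [compute_indices()].
#' @param path Output path.
#' @param eeg Optional half-split comparison record from
#'   [half_split_compare()].
#' @param config Optional configuration list to echo.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, eeg = NULL, config = NULL) {
  windows <- lapply(seq_len(nrow(report)), function(i) {
    row <- as.list(report[i, ])
    if (is.na(row$gpc)) row$gpc <- NULL
    if (is.na(row$gtfi)) row$gtfi <- NULL
    row$pass_gpc <- if (is.null(row$gpc)) NULL else row$pass_gpc
    row$pass_gtfi <- if (is.null(row$gtfi)) NULL else row$pass_gtfi
    row
  })
  obj <- list(schema_version = "1.0", windows = windows)
  if (!is.null(eeg)) obj$eeg_half_split <- eeg
  if (!is.null(config)) obj$config <- unclass(config)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
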