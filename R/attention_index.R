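# The attention-indicator system: per-window indicator values, threshold
# verdicts, and the overall focus classification.

#' Indicator thresholds
#'
#' The default thresholds of the indicator system.  All comparisons are
#' strict, matching the defining wording ("more than" / "less than"):
#' \itemize{
#'   \item POOF: proportion of frames with exactly one face > 0.95
#'   \item POHCHP: proportion of face frames in the high tier > 0.50
#'   \item POMCHP: proportion of face frames in the high-or-medium tier > 0.90
#'   \item POEFT: effective fixation time / total fixation time > 0.90
#'   \item POSEFT: serious fixation time / total fixation time > 0.50
#'   \item GPC: gaze share on pictures/charts > 0.30 (optional)
#'   \item GTFI: gaze share on the speaker's face > 0.20 (optional)
#'   \item NOS variance: variance of saccade counts per 100 frames < 10
#'   \item NORSP: reading pursuits per 10 minutes > 5
#' }
#'
#' @param poof_min,pohchp_min,pomchp_min,poeft_min,poseft_min,gpc_min,gtfi_min
#'   Proportion thresholds (strict lower bounds).
#' @param nos_var_max Strict upper bound on the saccade-count variance.
#' @param norsp_min_per_10min Strict lower bound on the reading-pursuit rate.
#' @return List of class \code{index_thresholds}.
#' @export
index_thresholds <- function(poof_min = 0.95, pohchp_min = 0.50,
                             pomchp_min = 0.90, poeft_min = 0.90,
                             poseft_min = 0.50, gpc_min = 0.30,
                             gtfi_min = 0.20, nos_var_max = 10,
                             norsp_min_per_10min = 5) {
  props <- c(poof_min, pohchp_min, pomchp_min, poeft_min, poseft_min, gpc_min, gtfi_min)
  if (any(props < 0 | props > 1)) stop("index_thresholds: proportions must be in [0, 1]")
  if (nos_var_max <= 0) stop("index_thresholds: nos_var_max must be positive")
  structure(list(poof_min = poof_min, pohchp_min = pohchp_min,
                 pomchp_min = pomchp_min, poeft_min = poeft_min,
                 poseft_min = poseft_min, gpc_min = gpc_min,
                 gtfi_min = gtfi_min, nos_var_max = nos_var_max,
                 norsp_min_per_10min = norsp_min_per_10min),
            class = "index_thresholds")
}

#' Screen region annotations for the optional gaze-share indicators
#'
#' Labelled rectangles (cm, origin top-left) with time-validity intervals.
#'
#' @param picture_chart,speaker_face Either \code{NULL} or a list with
#'   \code{x0, y0, x1, y1} (rectangle) and optionally \code{t0, t1}
#'   (validity interval in seconds; defaults to always valid).
#' @return List of class \code{region_annotation}.
#' @export
region_annotation <- function(picture_chart = NULL, speaker_face = NULL) {
  norm <- function(r) {
    if (is.null(r)) return(NULL)
    stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(r)))
    if (is.null(r$t0)) r$t0 <- -Inf
    if (is.null(r$t1)) r$t1 <- Inf
    if (r$t1 < r$t0) stop("region_annotation: invalid time interval")
    r
  }
  structure(list(picture_chart = norm(picture_chart),
                 speaker_face = norm(speaker_face)),
            class = "region_annotation")
}

# fixation time share whose centroid falls inside a region during its
# validity interval; NULL region -> NA
.region_share <- function(fx, region, total_fix_time) {
  if (is.null(region) || total_fix_time <= 0) return(NA_real_)
  dur <- fx$t_end - fx$t_start
  inside <- fx$x >= region$x0 & fx$x <= region$x1 &
            fx$y >= region$y0 & fx$y <= region$y1 &
            fx$t_start >= region$t0 & fx$t_end <= region$t1
  sum(dur[inside]) / total_fix_time
}

#' Compute attention indicators per evaluation window
#'
#' Splits the stream into consecutive windows of \code{window_s} seconds
#' and computes, for each window: POOF (one-face frame proportion), POHCHP
#' and POMCHP (high and high-or-medium head-pose tier proportions among
#' face frames), POEFT and POSEFT (effective and serious fixation-time
#' shares of total fixation time), the NOS variance (population variance of
#' saccade counts per \code{bin_frames}-frame bin), the NORSP rate (reading
#' pursuits scaled to a per-10-minute rate), and, when \code{regions} are
#' supplied, GPC and GTFI (fixation-time shares on the annotated
#' rectangles).  Pass flags and the verdict come from
#' [apply_thresholds()].
#'
#' @param stream Frame-stream data.frame.
#' @param geom \code{screen_geometry}.
#' @param regions Optional \code{region_annotation}.
#' @param window_s Evaluation window in seconds (default 600; windows
#'   shorter than 60 s are refused).  The final partial window is evaluated
#'   over its actual span.
#' @param thresholds \code{index_thresholds}.
#' @param dispersion_cm,min_duration_ms,serious_min_s Fixation parameters,
#'   see [segment_fixations()] and [label_fixations()].
#' @param bin_frames Saccade-count bin size in frames (default 100).
#' @param saccade_min_deg Saccade threshold in degrees (default 10).
#' @param reading_min_run,reading_vertical_ratio Reading-pursuit parameters,
#'   see [detect_reading_pursuits()].
#' @return data.frame with one row per window: window id, indicator values,
#'   per-indicator pass flags (\code{pass_*}) and \code{verdict}.
#' @export
compute_indices <- function(stream, geom, regions = NULL, window_s = 600,
                            thresholds = index_thresholds(),
                            dispersion_cm = 1.69, min_duration_ms = 500,
                            serious_min_s = 3, bin_frames = 100,
                            saccade_min_deg = 10, reading_min_run = 3,
                            reading_vertical_ratio = 0.2) {
  if (window_s < 60) stop("compute_indices: windows shorter than 60 s are refused")
  if (nrow(stream) == 0L) stop("compute_indices: empty stream")
  t0 <- stream$t_s[1]
  win_id <- floor((stream$t_s - t0) / window_s)
  out <- list()
  for (w in sort(unique(win_id))) {
    sub <- stream[win_id == w, , drop = FALSE]
    span <- sub$t_s[nrow(sub)] - sub$t_s[1]
    n_frames <- nrow(sub)
    face <- sub$n_faces == 1
    poof <- mean(face)
    posed <- face & !is.na(sub$pitch_deg) & !is.na(sub$yaw_deg)
    if (any(posed)) {
      tier <- classify_concentration(sub$pitch_deg[posed], sub$yaw_deg[posed])
      pohchp <- mean(tier == "high")
      pomchp <- mean(tier %in% c("high", "medium"))
    } else {
      pohchp <- NA_real_; pomchp <- NA_real_
    }
    fx <- segment_fixations(sub, dispersion_cm, min_duration_ms)
    fx <- label_fixations(fx, geom, serious_min_s)
    dur <- fx$t_end - fx$t_start
    total_fix <- sum(dur)
    if (total_fix > 0) {
      poeft <- sum(dur[fx$effective]) / total_fix
      poseft <- sum(dur[fx$serious]) / total_fix
    } else {
      poeft <- NA_real_; poseft <- NA_real_
    }
    counts <- suppressWarnings(count_saccades_per_bin(sub, bin_frames, saccade_min_deg))
    nos_mean <- if (length(counts)) mean_and_variance(counts)$mean else NA_real_
    nos_var <- if (length(counts)) mean_and_variance(counts)$variance else NA_real_
    rp <- detect_reading_pursuits(sub, reading_min_run, reading_vertical_ratio,
                                  saccade_min_deg)
    norsp <- if (span > 0) nrow(rp) * 600 / span else NA_real_
    gpc <- .region_share(fx, if (is.null(regions)) NULL else regions$picture_chart, total_fix)
    gtfi <- .region_share(fx, if (is.null(regions)) NULL else regions$speaker_face, total_fix)
    row <- data.frame(window = w, t_start = sub$t_s[1], t_end = sub$t_s[n_frames],
                      n_frames = n_frames, poof = poof, pohchp = pohchp,
                      pomchp = pomchp, poeft = poeft, poseft = poseft,
                      nos_mean = nos_mean, nos_variance = nos_var,
                      norsp_rate = norsp, gpc = gpc, gtfi = gtfi)
    out[[length(out) + 1L]] <- row
  }
  rep_df <- do.call(rbind, out)
  apply_thresholds(rep_df, thresholds)
}

#' Apply indicator thresholds and derive a verdict
#'
#' Adds strict pass flags for every indicator and an overall verdict:
#' \code{focused} when every available indicator passes,
#' \code{unfocused} when at least half of the available indicators fail,
#' \code{partially_focused} otherwise.  Indicators that are absent (NA,
#' e.g. GPC/GTFI without region annotations, or fixation shares with zero
#' fixation time) carry an NA flag; absent optional indicators are excluded
#' from the verdict, while an absent fixation-share indicator counts as a
#' failure (no fixation time is itself evidence of inattention).
#'
#' @param report data.frame of indicator values (as built by
#'   [compute_indices()]).
#' @param thresholds \code{index_thresholds}.
#' @return The report with \code{pass_*} columns and \code{verdict}.
#' @export
apply_thresholds <- function(report, thresholds = index_thresholds()) {
  th <- thresholds
  report$pass_poof   <- report$poof   > th$poof_min
  report$pass_pohchp <- report$pohchp > th$pohchp_min
  report$pass_pomchp <- report$pomchp > th$pomchp_min
  report$pass_poeft  <- report$poeft  > th$poeft_min
  report$pass_poseft <- report$poseft > th$poseft_min
  report$pass_nos_variance <- report$nos_variance < th$nos_var_max
  report$pass_norsp  <- report$norsp_rate > th$norsp_min_per_10min
  report$pass_gpc    <- report$gpc  > th$gpc_min
  report$pass_gtfi   <- report$gtfi > th$gtfi_min
  core <- c("pass_poof", "pass_pohchp", "pass_pomchp", "pass_poeft",
            "pass_poseft", "pass_nos_variance", "pass_norsp")
  # an undefined core indicator (e.g. no fixation time at all) is a failure
  for (cc in core) report[[cc]][is.na(report[[cc]])] <- FALSE
  optional <- c("pass_gpc", "pass_gtfi")
  verdict <- character(nrow(report))
  for (i in seq_len(nrow(report))) {
    flags <- unlist(report[i, core])
    opt <- unlist(report[i, optional])
    flags <- c(flags, opt[!is.na(opt)])  # optional indicators only when present
    n_fail <- sum(!flags)
    verdict[i] <- if (n_fail == 0L) "focused"
                  else if (n_fail >= length(flags) / 2) "unfocused"
                  else "partially_focused"
  }
  report$verdict <- verdict
  report
}
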