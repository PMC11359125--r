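# Eye-movement event classification over timestamped frame streams.
#
# A frame stream is a data.frame with the columns
#   t_s, n_faces, pitch_deg, yaw_deg, roll_deg,
#   gaze_pitch_deg, gaze_yaw_deg, gaze_x_cm, gaze_y_cm
# (one row per video frame, t_s strictly increasing, NA = missing field).
# Gaze points are on-screen coordinates in cm, origin top-left, y downward.

#' Screen geometry
#'
#' @param width_cm,height_cm Physical screen size in cm (positive).
#' @param roi_top_fraction Fraction of the screen height, measured from the
#'   top, that constitutes the region of interest where lecture content
#'   concentrates (default 0.7: the top 70 percent).
#' @return List of class \code{screen_geometry}.
#' @export
screen_geometry <- function(width_cm, height_cm, roi_top_fraction = 0.7) {
  if (width_cm <= 0 || height_cm <= 0)
    stop("screen_geometry: screen dimensions must be positive")
  if (roi_top_fraction <= 0 || roi_top_fraction > 1)
    stop("screen_geometry: roi_top_fraction must be in (0, 1]")
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 roi_top_fraction = roi_top_fraction),
            class = "screen_geometry")
}

#' Unit 3-D vector of a gaze direction
#'
#' Spherical-to-Cartesian conversion of a (pitch, yaw) gaze direction in
#' degrees: pitch elevates about the X axis (positive up), yaw rotates about
#' the Y axis (positive right); (0, 0) looks straight ahead (+Z).
#'
#' @param pitch,yaw Angles in degrees (vectorized).
#' @return n x 3 matrix of unit vectors (columns x, y-up, z).
#' @export
gaze_direction_vector <- function(pitch, yaw) {
  p <- pitch * pi / 180
  y <- yaw * pi / 180
  cbind(cos(p) * sin(y), sin(p), cos(p) * cos(y))
}

#' Angle between two gaze directions
#'
#' The 3-D angle between the unit vectors of two (pitch, yaw) gaze
#' directions, in degrees, in \code{[0, 180]}.  Vectorized over pairs.
#'
#' @param p1,y1 First direction's pitch and yaw (degrees).
#' @param p2,y2 Second direction's pitch and yaw (degrees).
#' @return Angle(s) in degrees; NA where any input is missing.
#' @export
interframe_gaze_angle <- function(p1, y1, p2, y2) {
  v1 <- gaze_direction_vector(p1, y1)
  v2 <- gaze_direction_vector(p2, y2)
  d <- rowSums(v1 * v2)
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

#' Classify an inter-frame transition
#'
#' A gaze-direction change of 10 degrees or more between consecutive frames
#' is a saccade; anything smaller is smooth pursuit.  Vectorized.
#'
#' @param angle Inter-frame gaze angle(s) in degrees.
#' @param saccade_min_deg Saccade threshold (default 10, inclusive).
#' @return Character vector \code{"saccade"} / \code{"smooth_pursuit"}
#'   (NA propagates).
#' @export
classify_transition <- function(angle, saccade_min_deg = 10) {
  ifelse(angle >= saccade_min_deg, "saccade", "smooth_pursuit")
}

# internal: per-transition classification over a stream.
# Returns a data.frame with i (index of first frame of the pair), kind
# (saccade / smooth_pursuit / NA when either frame lacks a usable direction).
.stream_transitions <- function(stream, saccade_min_deg = 10) {
  n <- nrow(stream)
  if (n < 2L) return(data.frame(i = integer(), kind = character()))
  ok <- stream$n_faces == 1 & !is.na(stream$gaze_pitch_deg) & !is.na(stream$gaze_yaw_deg)
  i <- seq_len(n - 1L)
  valid <- ok[i] & ok[i + 1L]
  ang <- rep(NA_real_, n - 1L)
  if (any(valid)) {
    ang[valid] <- interframe_gaze_angle(
      stream$gaze_pitch_deg[i][valid], stream$gaze_yaw_deg[i][valid],
      stream$gaze_pitch_deg[i + 1L][valid], stream$gaze_yaw_deg[i + 1L][valid])
  }
  data.frame(i = i, angle = ang,
             kind = ifelse(valid, classify_transition(ang, saccade_min_deg), NA_character_),
             stringsAsFactors = FALSE)
}

#' Segment fixations by dispersion (I-DT style)
#'
#' Greedily grows runs of consecutive frames whose gaze points all stay
#' within \code{dispersion_cm} of the running centroid; a run whose time
#' span strictly exceeds \code{min_duration_ms} becomes one fixation event
#' with the run's mean gaze point as centroid.  Frames without a single
#' face or without a gaze point break runs.
#'
#' @param stream Frame-stream data.frame (see module header).
#' @param dispersion_cm Maximum distance of any run member from the run
#'   centroid (default 1.69 cm, the pipeline's on-screen error tolerance).
#' @param min_duration_ms Minimum fixation span in ms, exclusive
#'   (default 500).
#' @return data.frame of events: kind, t_start, t_end, x, y, n_frames.
#' @export
segment_fixations <- function(stream, dispersion_cm = 1.69, min_duration_ms = 500) {
  if (dispersion_cm <= 0) stop("segment_fixations: dispersion_cm must be positive")
  out <- list()
  n <- nrow(stream)
  if (n == 0L) {
    return(data.frame(kind = character(), t_start = numeric(), t_end = numeric(),
                      x = numeric(), y = numeric(), n_frames = integer()))
  }
  usable <- stream$n_faces == 1 & !is.na(stream$gaze_x_cm) & !is.na(stream$gaze_y_cm)
  t <- stream$t_s; gx <- stream$gaze_x_cm; gy <- stream$gaze_y_cm
  min_s <- min_duration_ms / 1000

  flush <- function(i0, i1) {
    if (i1 <= i0) return(NULL)
    span <- t[i1] - t[i0]
    if (span <= min_s) return(NULL)
    idx <- i0:i1
    data.frame(kind = "fixation", t_start = t[i0], t_end = t[i1],
               x = mean(gx[idx]), y = mean(gy[idx]), n_frames = length(idx))
  }

  i0 <- NA_integer_; sx <- 0; sy <- 0; k <- 0L
  for (i in seq_len(n)) {
    if (!usable[i]) {
      if (!is.na(i0)) { ev <- flush(i0, i - 1L); if (!is.null(ev)) out[[length(out) + 1L]] <- ev }
      i0 <- NA_integer_
      next
    }
    if (is.na(i0)) {
      i0 <- i; sx <- gx[i]; sy <- gy[i]; k <- 1L
      next
    }
    nx <- (sx + gx[i]) / (k + 1L); ny <- (sy + gy[i]) / (k + 1L)
    idx <- i0:i
    if (max(sqrt((gx[idx] - nx)^2 + (gy[idx] - ny)^2)) <= dispersion_cm) {
      sx <- sx + gx[i]; sy <- sy + gy[i]; k <- k + 1L
    } else {
      ev <- flush(i0, i - 1L); if (!is.null(ev)) out[[length(out) + 1L]] <- ev
      i0 <- i; sx <- gx[i]; sy <- gy[i]; k <- 1L
    }
  }
  if (!is.na(i0)) { ev <- flush(i0, n); if (!is.null(ev)) out[[length(out) + 1L]] <- ev }
  if (length(out) == 0L) {
    return(data.frame(kind = character(), t_start = numeric(), t_end = numeric(),
                      x = numeric(), y = numeric(), n_frames = integer()))
  }
  do.call(rbind, out)
}

#' Label fixations as effective / serious
#'
#' A fixation is \emph{effective} when its centroid lies inside the region
#' of interest (the top \code{roi_top_fraction} of the screen) and
#' \emph{serious} when it is effective and strictly longer than
#' \code{serious_min_s}.  Centroids outside the physical screen are flagged
#' not effective with a warning.
#'
#' @param fixations data.frame from [segment_fixations()].
#' @param geom \code{screen_geometry}.
#' @param serious_min_s Serious-fixation duration threshold in seconds,
#'   exclusive (default 3).
#' @return The input with logical columns \code{effective}, \code{serious}.
#' @export
label_fixations <- function(fixations, geom, serious_min_s = 3) {
  if (nrow(fixations) == 0L) {
    fixations$effective <- logical(0); fixations$serious <- logical(0)
    return(fixations)
  }
  on_screen <- fixations$x >= 0 & fixations$x < geom$width_cm &
               fixations$y >= 0 & fixations$y < geom$height_cm
  if (any(!on_screen))
    warning("label_fixations: centroid outside the physical screen; marked not effective")
  eff <- on_screen & fixations$y <= geom$roi_top_fraction * geom$height_cm
  dur <- fixations$t_end - fixations$t_start
  fixations$effective <- eff
  fixations$serious <- eff & dur > serious_min_s
  fixations
}

#' Detect reading smooth pursuits
#'
#' A reading pursuit is a maximal run of at least \code{min_run_frames}
#' consecutive smooth-pursuit transitions whose net x-displacement is
#' strictly positive (left to right, the Western reading direction) and
#' whose vertical amplitude (max y minus min y over the run) is at most
#' \code{vertical_ratio_max} times the net x-displacement.
#'
#' @param stream Frame-stream data.frame.
#' @param min_run_frames Minimum number of smooth transitions in a run
#'   (default 3).
#' @param vertical_ratio_max Maximum vertical amplitude as a fraction of
#'   the net rightward sweep (default 0.2).
#' @param saccade_min_deg Saccade threshold passed to the transition
#'   classifier.
#' @return data.frame of events: kind, t_start, t_end, x, y (net dx and
#'   vertical amplitude), n_frames.
#' @export
detect_reading_pursuits <- function(stream, min_run_frames = 3,
                                    vertical_ratio_max = 0.2,
                                    saccade_min_deg = 10) {
  empty <- data.frame(kind = character(), t_start = numeric(), t_end = numeric(),
                      x = numeric(), y = numeric(), n_frames = integer())
  tr <- .stream_transitions(stream, saccade_min_deg)
  if (nrow(tr) == 0L) return(empty)
  smooth <- !is.na(tr$kind) & tr$kind == "smooth_pursuit" &
            !is.na(stream$gaze_x_cm[tr$i]) & !is.na(stream$gaze_x_cm[tr$i + 1L])
  r <- rle(smooth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in which(r$values & r$lengths >= min_run_frames)) {
    i0 <- tr$i[starts[j]]            # first frame of the run
    i1 <- tr$i[ends[j]] + 1L         # last frame of the run
    idx <- i0:i1
    dx <- stream$gaze_x_cm[i1] - stream$gaze_x_cm[i0]
    amp <- diff(range(stream$gaze_y_cm[idx]))
    if (dx > 0 && amp <= vertical_ratio_max * dx) {
      out[[length(out) + 1L]] <- data.frame(
        kind = "reading_pursuit", t_start = stream$t_s[i0], t_end = stream$t_s[i1],
        x = dx, y = amp, n_frames = length(idx))
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Saccade counts per fixed-size frame bin
#'
#' Partitions the stream into consecutive non-overlapping bins of
#' \code{bin_frames} frames (an incomplete final bin is dropped) and counts
#' the saccade transitions inside each; a transition between frames i and
#' i+1 belongs to the bin containing frame i.
#'
#' @param stream Frame-stream data.frame.
#' @param bin_frames Bin size in frames (default 100, at least 2).
#' @param saccade_min_deg Saccade threshold in degrees.
#' @return Integer vector of per-bin saccade counts (possibly empty, with a
#'   warning, when the stream is shorter than one bin).
#' @export
count_saccades_per_bin <- function(stream, bin_frames = 100, saccade_min_deg = 10) {
  if (bin_frames < 2L) stop("count_saccades_per_bin: bin_frames must be at least 2")
  n <- nrow(stream)
  n_bins <- n %/% bin_frames
  if (n_bins == 0L) {
    warning("count_saccades_per_bin: stream shorter than one bin")
    return(integer(0))
  }
  tr <- .stream_transitions(stream, saccade_min_deg)
  sac <- tr$i[!is.na(tr$kind) & tr$kind == "saccade"]
  sac <- sac[sac <= n_bins * bin_frames]
  counts <- tabulate(((sac - 1L) %/% bin_frames) + 1L, nbins = n_bins)
  as.integer(counts)
}
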