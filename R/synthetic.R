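# Seeded generators for every input the pipeline consumes: behaviour-
# profiled gaze streams, band-power-controlled EEG sessions, and synthetic
# eye images.
#
# The gaze generator builds a session as a sequence of gaze segments
# (dwells on a target, frantic scanning bursts, and left-to-right reading
# sweeps), renders them to per-frame gaze points, and derives the gaze
# direction from the gaze point through a pinhole model with the viewer's
# eye 50 cm in front of the screen centre, so that the two channels stay
# geometrically consistent.

VIEW_DISTANCE_CM <- 50

#' Behaviour profile for the gaze-stream generator
#'
#' Presets map to the three attention levels of the classroom-simulation
#' design: \code{"focused"} (level 3) holds a screen-facing pose and long
#' in-ROI dwells throughout; \code{"distracted"} (level 1) turns away
#' often, looks off-screen, rarely reads, and alternates blank staring with
#' short frantic scanning bursts; \code{"half_focused"} (level 2) behaves
#' like the focused profile for the first half of the session and like the
#' distracted profile afterwards.
#'
#' @param preset One of \code{"focused"}, \code{"half_focused"},
#'   \code{"distracted"}.
#' @return List of class \code{behavior_profile}; for
#'   \code{"half_focused"} the fields \code{switch_at_fraction} and
#'   \code{phase2} describe the mid-session switch.
#' @export
behavior_profile <- function(preset = c("focused", "half_focused", "distracted")) {
  preset <- match.arg(preset)
  focused <- list(
    name = "focused", attention_level = 3L,
    tier_fracs = c(high = 0.88, medium = 0.10, low = 0.02),
    glitch_bursts_per_10min = 2, glitch_burst_s = 0.7,
    q_long = 0.3, short_range_s = c(0.6, 1.0), long_range_s = c(4, 6),
    burst_bin_frac = 0, burst_seg_range_s = c(0.085, 0.165),
    in_roi_prob = 0.98, off_screen_prob = 0.01,
    sweeps_per_10min = 9,
    switch_at_fraction = NULL, phase2 = NULL)
  distracted <- list(
    name = "distracted", attention_level = 1L,
    tier_fracs = c(high = 0.18, medium = 0.22, low = 0.60),
    glitch_bursts_per_10min = 12, glitch_burst_s = 5,
    q_long = 0, short_range_s = c(4.5, 11), long_range_s = c(4, 6),
    burst_bin_frac = 0.05, burst_seg_range_s = c(0.085, 0.165),
    in_roi_prob = 0.25, off_screen_prob = 0.15,
    sweeps_per_10min = 1,
    switch_at_fraction = NULL, phase2 = NULL)
  out <- switch(preset,
    focused = focused,
    distracted = distracted,
    half_focused = {
      p <- focused
      p$name <- "half_focused"; p$attention_level <- 2L
      p$switch_at_fraction <- 0.5
      p2 <- distracted
      # the deliberate mid-session disengagement is restless rather than
      # zoned out: shorter idle dwells than constant distraction
      p2$short_range_s <- c(2.8, 7)
      p$phase2 <- p2
      p
    })
  structure(out, class = "behavior_profile")
}

.validate_profile <- function(p) {
  if (abs(sum(p$tier_fracs) - 1) > 1e-8)
    stop("behavior_profile: tier fractions must sum to 1")
  probs <- c(p$in_roi_prob, p$off_screen_prob, p$q_long, p$burst_bin_frac)
  if (any(probs < 0 | probs > 1))
    stop("behavior_profile: probabilities must be in [0, 1]")
  if (p$sweeps_per_10min < 0 || p$glitch_bursts_per_10min < 0)
    stop("behavior_profile: rates must be non-negative")
  invisible(TRUE)
}

# gaze direction (pitch, yaw in degrees) of screen point(s) seen from an
# eye VIEW_DISTANCE_CM in front of the screen centre
.point_to_direction <- function(x, y, geom) {
  dx <- x - geom$width_cm / 2
  dy <- y - geom$height_cm / 2
  nrm <- sqrt(dx^2 + dy^2 + VIEW_DISTANCE_CM^2)
  list(pitch = asin(-dy / nrm) * 180 / pi,
       yaw = atan2(dx, VIEW_DISTANCE_CM) * 180 / pi)
}

.angle_between_points <- function(x1, y1, x2, y2, geom) {
  d1 <- .point_to_direction(x1, y1, geom)
  d2 <- .point_to_direction(x2, y2, geom)
  interframe_gaze_angle(d1$pitch, d1$yaw, d2$pitch, d2$yaw)
}

# sample a dwell target: off-screen virtual point, in-ROI point, or
# below-ROI point; resample until the jump from the previous target spans
# at least min_jump_deg of visual angle (so the transition is a saccade)
.sample_target <- function(prev, p, geom, min_jump_deg = 10.5) {
  roi_h <- geom$roi_top_fraction * geom$height_cm
  for (try in 1:80) {
    u <- stats::runif(1)
    if (u < p$off_screen_prob) {
      side <- sample(4L, 1L)
      off <- stats::runif(1, 12, 20)
      tgt <- switch(side,
        c(-off, stats::runif(1, 0, geom$height_cm)),
        c(geom$width_cm + off, stats::runif(1, 0, geom$height_cm)),
        c(stats::runif(1, 0, geom$width_cm), -off),
        c(stats::runif(1, 0, geom$width_cm), geom$height_cm + off))
      tgt <- c(tgt, 0)                       # 0 = off-screen
    } else if (u < p$off_screen_prob + (1 - p$off_screen_prob) * p$in_roi_prob) {
      tgt <- c(stats::runif(1, 1.5, geom$width_cm - 1.5),
               stats::runif(1, 1.0, roi_h - 1.0), 1)
    } else {
      tgt <- c(stats::runif(1, 1.5, geom$width_cm - 1.5),
               stats::runif(1, roi_h + 0.5, geom$height_cm - 0.5), 1)
    }
    if (is.null(prev)) return(tgt)
    if (.angle_between_points(prev[1], prev[2], tgt[1], tgt[2], geom) >= min_jump_deg)
      return(tgt)
  }
  tgt
}

# one homogeneous phase of a simulated session; returns the frame table
.simulate_phase <- function(p, duration_s, fps, geom) {
  n <- floor(duration_s * fps)
  t <- (seq_len(n) - 1L) / fps
  bin_frames <- 100L

  # face-count glitch bursts (frames without a single detected face)
  glitch <- rep(FALSE, n)
  n_gl <- round(p$glitch_bursts_per_10min * duration_s / 600)
  if (n_gl > 0) {
    starts <- stats::runif(n_gl, 0, max(duration_s - p$glitch_burst_s, 0))
    for (s0 in starts) glitch[t >= s0 & t < s0 + p$glitch_burst_s] <- TRUE
  }

  # frantic-scanning windows, aligned to the 100-frame analysis bins;
  # the number of burst windows is fixed by the profile, their placement
  # random, so the across-bin count variance is a stable profile property
  n_bins <- n %/% bin_frames
  burst_bin <- logical(n_bins)
  n_burst <- round(p$burst_bin_frac * n_bins)
  if (n_burst > 0) burst_bin[sample(n_bins, n_burst)] <- TRUE
  burst_start_t <- (which(burst_bin) - 1L) * bin_frames / fps
  burst_end_t <- burst_start_t + bin_frames / fps
  in_burst <- function(tt) any(tt >= burst_start_t & tt < burst_end_t)
  next_burst_after <- function(tt) {
    nb <- burst_start_t[burst_start_t > tt + 1e-9]
    if (length(nb)) min(nb) else Inf
  }

  # reading-sweep schedule (start times, avoiding burst windows)
  sweep_len <- 1.5
  n_sw <- round(p$sweeps_per_10min * duration_s / 600)
  sweep_start <- numeric(0)
  if (n_sw > 0) {
    sweep_start <- seq(0.05, 0.95, length.out = n_sw) * duration_s +
      stats::runif(n_sw, -8, 8)
    sweep_start <- pmin(pmax(sweep_start, 1), duration_s - sweep_len - 1)
    for (k in seq_along(sweep_start)) {
      while (in_burst(sweep_start[k]) || in_burst(sweep_start[k] + sweep_len)) {
        sweep_start[k] <- sweep_start[k] + bin_frames / fps
        if (sweep_start[k] > duration_s - sweep_len - 0.5) {
          sweep_start[k] <- stats::runif(1, 1, duration_s / 2); break
        }
      }
    }
    sweep_start <- sort(sweep_start)
  }

  # build the segment timeline
  seg_t0 <- numeric(0); seg_t1 <- numeric(0); seg_type <- character(0)
  seg_x <- numeric(0); seg_y <- numeric(0); seg_on <- logical(0)
  prev_tgt <- NULL
  tc <- 0
  sw_i <- 1L
  while (tc < duration_s - 1e-9) {
    if (sw_i <= length(sweep_start) && tc >= sweep_start[sw_i] - 1e-9) {
      # reading sweep: left-to-right, flat
      x0 <- stats::runif(1, 3, 15)
      y0 <- stats::runif(1, 2, geom$roi_top_fraction * geom$height_cm - 2)
      seg_t0 <- c(seg_t0, tc); seg_t1 <- c(seg_t1, min(tc + sweep_len, duration_s))
      seg_type <- c(seg_type, "sweep")
      seg_x <- c(seg_x, x0); seg_y <- c(seg_y, y0); seg_on <- c(seg_on, TRUE)
      prev_tgt <- c(x0 + 15, y0, 1)
      tc <- tc + sweep_len
      sw_i <- sw_i + 1L
      next
    }
    if (in_burst(tc)) {
      dur <- stats::runif(1, p$burst_seg_range_s[1], p$burst_seg_range_s[2])
      tgt <- .sample_target(prev_tgt, p, geom)
    } else {
      dur <- if (stats::runif(1) < p$q_long)
        stats::runif(1, p$long_range_s[1], p$long_range_s[2])
      else
        stats::runif(1, p$short_range_s[1], p$short_range_s[2])
      # do not run past the next sweep or burst window
      lim <- min(next_burst_after(tc),
                 if (sw_i <= length(sweep_start)) sweep_start[sw_i] else Inf)
      dur <- min(dur, lim - tc)
      tgt <- .sample_target(prev_tgt, p, geom)
    }
    dur <- max(dur, 1.5 / fps)
    seg_t0 <- c(seg_t0, tc); seg_t1 <- c(seg_t1, min(tc + dur, duration_s))
    seg_type <- c(seg_type, "dwell")
    seg_x <- c(seg_x, tgt[1]); seg_y <- c(seg_y, tgt[2]); seg_on <- c(seg_on, tgt[3] == 1)
    prev_tgt <- tgt
    tc <- tc + dur
  }

  # render frames
  seg_of <- findInterval(t + 1e-9, seg_t0)
  seg_of[seg_of < 1L] <- 1L
  gx <- gy <- rep(NA_real_, n)
  vx <- vy <- rep(NA_real_, n)            # virtual point used for direction
  is_sweep <- seg_type[seg_of] == "sweep"
  on <- seg_on[seg_of]
  # dwells
  dw <- !is_sweep
  vx[dw] <- seg_x[seg_of[dw]] + stats::rnorm(sum(dw), 0, 0.08)
  vy[dw] <- seg_y[seg_of[dw]] + stats::rnorm(sum(dw), 0, 0.08)
  # sweeps: linear left-to-right motion over the segment
  if (any(is_sweep)) {
    frac <- (t[is_sweep] - seg_t0[seg_of[is_sweep]]) / sweep_len
    vx[is_sweep] <- seg_x[seg_of[is_sweep]] + 15 * frac +
      stats::rnorm(sum(is_sweep), 0, 0.03)
    vy[is_sweep] <- seg_y[seg_of[is_sweep]] + stats::rnorm(sum(is_sweep), 0, 0.03)
  }
  on_screen <- on & vx >= 0 & vx < geom$width_cm & vy >= 0 & vy < geom$height_cm
  gx[on_screen] <- vx[on_screen]
  gy[on_screen] <- vy[on_screen]
  dir <- .point_to_direction(vx, vy, geom)

  # head pose in 2-second tier blocks
  block <- floor(t / 2)
  ub <- unique(block)
  tier_b <- sample(names(p$tier_fracs), length(ub), replace = TRUE, prob = p$tier_fracs)
  m_b <- ifelse(tier_b == "high", stats::runif(length(ub), 1, 8),
         ifelse(tier_b == "medium", stats::runif(length(ub), 12, 28),
                stats::runif(length(ub), 32, 58)))
  minor_b <- stats::runif(length(ub), 0, 0.8) * pmin(m_b, 28)
  major_is_yaw <- stats::runif(length(ub)) < 0.5
  sgn1 <- sample(c(-1, 1), length(ub), replace = TRUE)
  sgn2 <- sample(c(-1, 1), length(ub), replace = TRUE)
  pitch_b <- ifelse(major_is_yaw, sgn2 * minor_b, sgn1 * m_b)
  yaw_b <- ifelse(major_is_yaw, sgn1 * m_b, sgn2 * minor_b)
  roll_b <- stats::runif(length(ub), -6, 6)
  bi <- match(block, ub)

  n_faces <- rep(1L, n)
  n_faces[glitch] <- sample(c(0L, 2L), sum(glitch), replace = TRUE)
  out <- data.frame(
    t_s = t, n_faces = n_faces,
    pitch_deg = pitch_b[bi], yaw_deg = yaw_b[bi], roll_deg = roll_b[bi],
    gaze_pitch_deg = dir$pitch, gaze_yaw_deg = dir$yaw,
    gaze_x_cm = gx, gaze_y_cm = gy)
  out[glitch, c("pitch_deg", "yaw_deg", "roll_deg",
                "gaze_pitch_deg", "gaze_yaw_deg", "gaze_x_cm", "gaze_y_cm")] <- NA_real_
  out
}

#' Simulate a behaviour-profiled gaze stream
#'
#' Generates a per-frame gaze log whose head-pose tier fractions, fixation
#' statistics, per-bin saccade counts, and reading-sweep count follow the
#' behaviour profile; deterministic for a given seed.  Profiles with a
#' mid-session switch (the half-focused preset) generate each phase with
#' its own parameter set.
#'
#' @param profile \code{behavior_profile} (or a preset name).
#' @param duration_s Session length in seconds.
#' @param fps Frame rate (the nominal webcam rate is 30).
#' @param geom \code{screen_geometry}; the default is a 15.6-inch 16:9
#'   laptop panel (34.5 x 19.4 cm).
#' @param seed Integer seed.
#' @return Frame-stream data.frame (see [segment_fixations()] for the
#'   column contract).
#' @export
simulate_gaze_stream <- function(profile = behavior_profile("focused"),
                                 duration_s = 600, fps = 30,
                                 geom = screen_geometry(34.5, 19.4),
                                 seed = 1L) {
  if (is.character(profile)) profile <- behavior_profile(profile)
  .validate_profile(profile)
  if (duration_s <= 0 || fps <= 0)
    stop("simulate_gaze_stream: duration and fps must be positive")
  set.seed(seed)
  if (is.null(profile$switch_at_fraction)) {
    return(.simulate_phase(profile, duration_s, fps, geom))
  }
  t_switch <- duration_s * profile$switch_at_fraction
  a <- .simulate_phase(profile, t_switch, fps, geom)
  b <- .simulate_phase(profile$phase2, duration_s - t_switch, fps, geom)
  b$t_s <- b$t_s + t_switch
  rbind(a, b)
}

#' EEG generation profile
#'
#' Band-limited noise variances (microvolts squared) for the two halves of
#' a synthetic session.  The \code{"declining"} preset realizes the
#' focused-then-distracted contrast: beta variance drops 4 to 1 and theta
#' rises 1 to 2 at the midpoint; \code{"stationary"} holds every band
#' constant.
#'
#' @param preset \code{"declining"} or \code{"stationary"}.
#' @param sfreq Sampling rate in Hz (default 300).
#' @param duration_s Session length in seconds (default 120).
#' @param channels Channel names (default frontal F3, Fz, F4 plus Cz).
#' @return List of class \code{eeg_profile}; \code{bands} maps band name to
#'   \code{list(range_hz, var_first, var_second)}.
#' @export
eeg_profile <- function(preset = c("declining", "stationary"), sfreq = 300,
                        duration_s = 120,
                        channels = c("F3", "Fz", "F4", "Cz")) {
  preset <- match.arg(preset)
  bands <- switch(preset,
    declining = list(
      theta = list(range_hz = c(4, 8), var_first = 1, var_second = 2),
      alpha = list(range_hz = c(8, 13), var_first = 1, var_second = 1),
      beta  = list(range_hz = c(13, 32), var_first = 4, var_second = 1)),
    stationary = list(
      theta = list(range_hz = c(4, 8), var_first = 2, var_second = 2),
      alpha = list(range_hz = c(8, 13), var_first = 1, var_second = 1),
      beta  = list(range_hz = c(13, 32), var_first = 2, var_second = 2)))
  structure(list(name = preset, bands = bands, sfreq = sfreq,
                 duration_s = duration_s, channels = channels,
                 shared_frac = 0.5),
            class = "eeg_profile")
}

#' Simulate a band-power-controlled EEG session
#'
#' Each band is realized as band-pass-filtered white noise rescaled so that
#' each half of the session attains exactly the profile's variance for that
#' band; bands are summed.  Channels share a common frontal component
#' (\code{shared_frac} of the variance) plus independent noise.
#' Deterministic per seed.
#'
#' @param profile \code{eeg_profile} (or a preset name).
#' @param seed Integer seed.
#' @return \code{eeg_session}.
#' @export
simulate_eeg <- function(profile = eeg_profile("declining"), seed = 1L) {
  if (is.character(profile)) profile <- eeg_profile(profile)
  set.seed(seed)
  n <- round(profile$duration_s * profile$sfreq)
  mid <- n %/% 2
  total_var <- sum(vapply(profile$bands,
                          function(b) b$var_first + b$var_second, numeric(1)))
  if (total_var == 0) warning("simulate_eeg: zero total variance, degenerate signal")
  halves <- list(1:mid, (mid + 1L):n)
  make_band <- function(b) {
    bf <- signal::butter(4, b$range_hz / (profile$sfreq / 2), type = "pass")
    x <- signal::filtfilt(bf, stats::rnorm(n))
    for (h in 1:2) {
      v <- if (h == 1) b$var_first else b$var_second
      idx <- halves[[h]]
      s <- stats::sd(x[idx])
      x[idx] <- if (s > 0 && v > 0) x[idx] * sqrt(v) / s else 0
    }
    x
  }
  nch <- length(profile$channels)
  sh <- profile$shared_frac
  samples <- matrix(0, n, nch)
  for (b in profile$bands) {
    common <- make_band(b)
    for (j in seq_len(nch)) {
      samples[, j] <- samples[, j] +
        sqrt(sh) * common + sqrt(1 - sh) * make_band(b)
    }
  }
  eeg_session(samples, profile$sfreq, profile$channels)
}

#' Synthesize an eye image with a known pupil
#'
#' An anti-aliased dark disk on a brighter background with Gaussian noise.
#' Antialiasing linearly ramps the intensity across the one-pixel boundary
#' band of the disk.  Deterministic per seed.
#'
#' @param center Length-2 numeric \code{c(x, y)} disk centre in pixels
#'   (1-based, may be fractional).
#' @param radius Disk radius in pixels.
#' @param width,height Image size in pixels.
#' @param fg_intensity,bg_intensity Disk and background intensities.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return Numeric matrix (rows = y, columns = x), clamped to [0, 255].
#' @export
synth_eye_image <- function(center = c(30, 20), radius = 10, width = 60,
                            height = 40, fg_intensity = 30,
                            bg_intensity = 200, noise_sd = 5, seed = 1L) {
  if (center[1] - radius < 1 || center[1] + radius > width ||
      center[2] - radius < 1 || center[2] + radius > height)
    stop("synth_eye_image: disk must lie fully inside the image")
  set.seed(seed)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  d <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
  cov <- pmin(pmax(radius + 0.5 - d, 0), 1)
  img <- bg_intensity + (fg_intensity - bg_intensity) * cov
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(width * height, 0, noise_sd),
                                        height, width)
  pmin(pmax(img, 0), 255)
}
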