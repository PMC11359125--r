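test_that("inter-frame gaze angle matches the spherical geometry", {
  expect_equal(interframe_gaze_angle(3, -7, 3, -7), 0, tolerance = 1e-5)
  expect_equal(interframe_gaze_angle(0, 0, 0, 15), 15, tolerance = 1e-9)
  expect_equal(interframe_gaze_angle(15, 0, 0, 0), 15, tolerance = 1e-9)
  # frozen from the explicit spherical-to-Cartesian dot-product oracle
  expect_equal(interframe_gaze_angle(10, 10, 0, 0), 14.10604, tolerance = 1e-5)
  set.seed(51)
  a <- interframe_gaze_angle(runif(50, -80, 80), runif(50, -170, 170),
                             runif(50, -80, 80), runif(50, -170, 170))
  expect_true(all(a >= 0 & a <= 180))
})

test_that("transition classification puts the 10-degree boundary in saccades", {
  expect_equal(classify_transition(12), "saccade")
  expect_equal(classify_transition(0), "smooth_pursuit")
  expect_equal(classify_transition(10), "saccade")
  expect_equal(classify_transition(9.999), "smooth_pursuit")
})

test_that("every valid frame pair is exactly one of saccade or smooth pursuit", {
  set.seed(52)
  st <- simulate_gaze_stream("half_focused", duration_s = 60, fps = 30, seed = 5)
  tr <- attentrics:::.stream_transitions(st)
  valid <- !is.na(tr$kind)
  expect_true(all(tr$kind[valid] %in% c("saccade", "smooth_pursuit")))
  # invalid pairs are exactly those touching a frame without face or direction
  ok <- st$n_faces == 1 & !is.na(st$gaze_pitch_deg)
  expect_identical(valid, ok[-nrow(st)] & ok[-1])
})

test_that("dispersion-based fixation segmentation honours the duration bound", {
  # 600 ms at the same point -> one fixation spanning 0.6 s
  st <- make_stream(t = (0:18) / 30, x = 10, y = 5)
  fx <- segment_fixations(st)
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$t_end - fx$t_start, 0.6, tolerance = 1e-9)
  expect_equal(fx$x, 10); expect_equal(fx$y, 5)

  # 400 ms is below the bound
  expect_equal(nrow(segment_fixations(make_stream((0:12) / 30, 10, 5))), 0L)

  # alternating far-apart points never settle
  n <- 60
  st2 <- make_stream((0:(n - 1)) / 30, rep(c(5, 25), n / 2), 5)
  expect_equal(nrow(segment_fixations(st2)), 0L)

  # empty stream
  expect_equal(nrow(segment_fixations(st2[0, ])), 0L)

  # a face-count glitch breaks the run
  st3 <- make_stream((0:29) / 30, 10, 5)
  st3$n_faces[15] <- 2L
  fx3 <- segment_fixations(st3)
  expect_true(all(fx3$t_end - fx3$t_start < 0.5))
})

test_that("fixation labels follow the ROI and the serious-duration rule", {
  geom <- screen_geometry(34.5, 19.4)   # ROI: top 70 percent -> y <= 13.58
  fx <- data.frame(kind = "fixation",
                   t_start = c(0, 10, 20), t_end = c(4, 20, 21),
                   x = c(10, 10, 10),
                   y = c(9.7, 17.5, 1.9),   # 50, 90, 10 percent of height
                   n_frames = c(120, 300, 30))
  lab <- label_fixations(fx, geom)
  expect_equal(lab$effective, c(TRUE, FALSE, TRUE))
  expect_equal(lab$serious, c(TRUE, FALSE, FALSE))

  off <- data.frame(kind = "fixation", t_start = 0, t_end = 10, x = -5, y = 5,
                    n_frames = 300)
  expect_warning(lab2 <- label_fixations(off, geom), "outside")
  expect_false(lab2$effective)
})

test_that("serious implies effective and fixation time is bounded by the session", {
  geom <- screen_geometry(34.5, 19.4)
  for (s in 1:5) {
    st <- simulate_gaze_stream("half_focused", duration_s = 90, fps = 30, seed = 60 + s)
    fx <- label_fixations(segment_fixations(st), geom)
    dur <- fx$t_end - fx$t_start
    expect_true(all(!fx$serious | fx$effective))
    expect_lte(sum(dur), max(st$t_s) - min(st$t_s))
    expect_lte(sum(dur[fx$serious]), sum(dur[fx$effective]))
  }
})

test_that("doubling the frame rate preserves fixations", {
  traj <- function(fps) {
    # two dwells separated by a jump, sampled at the given rate
    t1 <- seq(0, 2, by = 1 / fps); t2 <- seq(2 + 1 / fps, 4, by = 1 / fps)
    make_stream(c(t1, t2), c(rep(8, length(t1)), rep(25, length(t2))), 6)
  }
  f30 <- segment_fixations(traj(30))
  f60 <- segment_fixations(traj(60))
  expect_equal(nrow(f30), nrow(f60))
  expect_lt(max(abs((f30$t_end - f30$t_start) - (f60$t_end - f60$t_start))), 1 / 30)
})

test_that("reading pursuits require a rightward sweep with small vertical drift", {
  geom <- screen_geometry(34.5, 19.4)
  t <- (0:29) / 30
  sweep <- make_stream(t, x = 5 + 10 * t, y = 5, geom = geom)
  expect_equal(nrow(detect_reading_pursuits(sweep)), 1L)

  mirror <- make_stream(t, x = geom$width_cm - (5 + 10 * t), y = 5, geom = geom)
  expect_equal(nrow(detect_reading_pursuits(mirror)), 0L)

  static <- make_stream(t, x = 10, y = 5)
  expect_equal(nrow(detect_reading_pursuits(static)), 0L)

  wavy <- make_stream(t, x = 5 + 10 * t, y = 5 + 3 * sin(20 * t))
  expect_equal(nrow(detect_reading_pursuits(wavy)), 0L)
})

test_that("saccade bin counts match a hand-enumerated fixture", {
  # 300 frames looking straight ahead, with 20-degree yaw jumps placed so
  # the saccade transitions are exactly 5, 150 and 151
  yaw <- rep(0, 300)
  yaw[6:150] <- 20       # transition 5 jumps out, 150 jumps back...
  yaw[152:300] <- 20     # ...and 151 jumps out again
  st <- make_direction_stream(pitch = rep(0, 300), yaw = yaw)
  expect_equal(count_saccades_per_bin(st, 100), c(1L, 2L, 0L))

  # all-static stream: zero counts
  st0 <- make_direction_stream(rep(0, 250), rep(0, 250))
  expect_equal(count_saccades_per_bin(st0, 100), c(0L, 0L))

  # stream shorter than one bin
  expect_warning(out <- count_saccades_per_bin(st0[1:99, ], 100), "shorter")
  expect_length(out, 0)
  expect_error(count_saccades_per_bin(st0, 1), "at least 2")
})

test_that("mirrored streams yield no reading pursuits when originals do", {
  geom <- screen_geometry(34.5, 19.4)
  set.seed(53)
  for (i in 1:5) {
    st <- simulate_gaze_stream("focused", duration_s = 120, fps = 30, seed = 70 + i)
    n_fwd <- nrow(detect_reading_pursuits(st))
    if (n_fwd == 0) next
    st$gaze_x_cm <- geom$width_cm - st$gaze_x_cm
    expect_equal(nrow(detect_reading_pursuits(st)), 0L)
  }
})
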