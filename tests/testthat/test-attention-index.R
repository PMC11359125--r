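test_that("indicator values match a hand-computed fixture", {
  geom <- screen_geometry(34.5, 19.4)
  n <- 3000; fps <- 30
  st <- data.frame(t_s = (0:(n - 1)) / fps, n_faces = 1L,
                   pitch_deg = NA_real_, yaw_deg = NA_real_, roll_deg = 0,
                   gaze_pitch_deg = 0, gaze_yaw_deg = 0,
                   gaze_x_cm = NA_real_, gaze_y_cm = NA_real_)
  # head pose: 2000 high, 600 medium, 250 low, 150 frames without a face
  st$pitch_deg[1:2000] <- 5;    st$yaw_deg[1:2000] <- 0
  st$pitch_deg[2001:2600] <- 15; st$yaw_deg[2001:2600] <- 0
  st$pitch_deg[2601:2850] <- 45; st$yaw_deg[2601:2850] <- 0
  st$n_faces[2851:3000] <- 2L
  st[2851:3000, c("pitch_deg", "yaw_deg", "gaze_pitch_deg", "gaze_yaw_deg")] <- NA_real_
  # three fixations: 4 s in ROI (serious), 2 s below ROI, 1 s in ROI
  st$gaze_x_cm[1:121] <- 10;   st$gaze_y_cm[1:121] <- 5
  st$gaze_x_cm[151:211] <- 10; st$gaze_y_cm[151:211] <- 18
  st$gaze_x_cm[241:271] <- 20; st$gaze_y_cm[241:271] <- 5
  regions <- region_annotation(picture_chart = list(x0 = 8, y0 = 3, x1 = 12, y1 = 7),
                               speaker_face = list(x0 = 18, y0 = 3, x1 = 22, y1 = 7))
  r <- compute_indices(st, geom, regions = regions, window_s = 600)
  expect_equal(nrow(r), 1L)
  expect_equal(r$poof, 2850 / 3000)
  expect_equal(r$pohchp, 2000 / 2850)
  expect_equal(r$pomchp, 2600 / 2850)
  expect_equal(r$poeft, 5 / 7)
  expect_equal(r$poseft, 4 / 7)
  expect_equal(r$nos_mean, 0)
  expect_equal(r$nos_variance, 0)
  expect_equal(r$norsp_rate, 0)
  expect_equal(r$gpc, 4 / 7)
  expect_equal(r$gtfi, 1 / 7)
  expect_true(r$pass_gpc); expect_false(r$pass_gtfi)
  # poof sits exactly at its threshold: strict comparison fails it
  expect_false(r$pass_poof)
  expect_equal(r$verdict, "partially_focused")
})

test_that("structural invariants of the report hold on simulated sessions", {
  geom <- screen_geometry(34.5, 19.4)
  for (s in 1:4) {
    st <- simulate_gaze_stream(c("focused", "half_focused", "distracted",
                                 "half_focused")[s],
                               duration_s = 180, fps = 30, seed = 80 + s)
    r <- compute_indices(st, geom, window_s = 180)
    expect_true(all(r$poseft <= r$poeft + 1e-12))
    expect_true(all(r$pohchp <= r$pomchp + 1e-12))
    props <- unlist(r[, c("poof", "pohchp", "pomchp", "poeft", "poseft")])
    expect_true(all(props >= 0 & props <= 1))
    expect_true(is.na(r$gpc) && is.na(r$gtfi))
  }
})

test_that("a faceless stream zeroes POOF and leaves fixation shares absent", {
  st <- make_stream((0:999) / 30, 10, 5, n_faces = 2L)
  st[, c("pitch_deg", "yaw_deg", "gaze_pitch_deg", "gaze_yaw_deg",
         "gaze_x_cm", "gaze_y_cm")] <- NA_real_
  r <- compute_indices(st, screen_geometry(34.5, 19.4), window_s = 600)
  expect_equal(r$poof, 0)
  expect_true(is.na(r$poeft) && is.na(r$poseft))
  expect_false(r$pass_poeft)    # absent core indicator counts as failed
  expect_equal(r$verdict, "unfocused")
})

test_that("windows shorter than a minute are refused", {
  st <- make_stream((0:100) / 30, 10, 5)
  expect_error(compute_indices(st, screen_geometry(34.5, 19.4), window_s = 30),
               "60 s")
})

test_that("values exactly at every threshold fail under strict comparison", {
  report <- data.frame(window = 0, t_start = 0, t_end = 600, n_frames = 18000,
                       poof = 0.95, pohchp = 0.50, pomchp = 0.90,
                       poeft = 0.90, poseft = 0.50, nos_mean = 2,
                       nos_variance = 10, norsp_rate = 5,
                       gpc = 0.30, gtfi = 0.20)
  r <- apply_thresholds(report, index_thresholds())
  flags <- unlist(r[, grep("^pass_", names(r))])
  expect_true(all(!flags))
  expect_equal(r$verdict, "unfocused")
  # nudging every value strictly past its threshold passes everything
  report2 <- transform(report, poof = 0.96, pohchp = 0.51, pomchp = 0.91,
                       poeft = 0.91, poseft = 0.51, nos_variance = 9.9,
                       norsp_rate = 5.1, gpc = 0.31, gtfi = 0.21)
  r2 <- apply_thresholds(report2, index_thresholds())
  expect_true(all(unlist(r2[, grep("^pass_", names(r2))])))
  expect_equal(r2$verdict, "focused")
})

test_that("majority failure yields the unfocused verdict", {
  report <- data.frame(window = 0, t_start = 0, t_end = 600, n_frames = 18000,
                       poof = 0.99, pohchp = 0.2, pomchp = 0.5,
                       poeft = 0.5, poseft = 0.6, nos_mean = 2,
                       nos_variance = 25, norsp_rate = 8,
                       gpc = NA_real_, gtfi = NA_real_)
  r <- apply_thresholds(report)  # 4 of 7 core indicators fail
  expect_equal(r$verdict, "unfocused")
})

test_that("raising attention level orders the indicators monotonically", {
  geom <- screen_geometry(34.5, 19.4)
  presets <- c("distracted", "half_focused", "focused")
  for (k in 1:20) {
    r <- lapply(presets, function(p) {
      st <- simulate_gaze_stream(p, duration_s = 600, fps = 30, geom = geom,
                                 seed = 500 + k)
      compute_indices(st, geom, window_s = 600)
    })
    for (ind in c("pohchp", "pomchp", "poeft", "poseft", "norsp_rate")) {
      v <- vapply(r, function(x) x[[ind]], numeric(1))
      expect_true(v[2] >= v[1] && v[3] >= v[2],
                  label = sprintf("%s monotone at seed %d (%s)", ind, 500 + k,
                                  paste(round(v, 3), collapse = "/")))
    }
    v <- vapply(r, function(x) x$nos_variance, numeric(1))
    expect_true(v[2] <= v[1] && v[3] <= v[2],
                label = sprintf("nos_variance antitone at seed %d (%s)", 500 + k,
                                paste(round(v, 1), collapse = "/")))
  }
})
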