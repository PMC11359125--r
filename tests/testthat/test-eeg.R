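test_that("preprocessing notches mains and preserves the EEG passband", {
  fs <- 300
  t <- (0:(fs * 40 - 1)) / fs
  core <- 3000:9000           # away from filter edges
  s50 <- eeg_session(matrix(100 * sin(2 * pi * 50 * t), ncol = 1), fs, "F3")
  out <- preprocess_eeg(s50)
  expect_lt(sqrt(mean(out$samples[core]^2)), 10)       # >20 dB at the notch

  s10 <- eeg_session(matrix(50 * sin(2 * pi * 10 * t), ncol = 1), fs, "F3")
  out10 <- preprocess_eeg(s10)
  gain <- sd(out10$samples[core]) / sd(s10$samples[core])
  expect_lt(abs(gain - 1), 0.12)

  sdc <- eeg_session(matrix(100, length(t), 1), fs, "F3")
  expect_lt(max(abs(preprocess_eeg(sdc)$samples[core])), 10)  # DC >= 20 dB down

  z <- eeg_session(matrix(0, length(t), 1), fs, "F3")
  expect_equal(max(abs(preprocess_eeg(z)$samples)), 0)

  expect_error(preprocess_eeg(eeg_session(matrix(0, 100, 1), 80, "F3")),
               "twice the notch")
})

test_that("artifact rejection removes exactly the contaminated epochs", {
  fs <- 300
  set.seed(91)
  x <- matrix(rnorm(fs * 60 * 2, 0, 20), ncol = 2)
  s <- eeg_session(x, fs, c("F3", "Fz"))
  clean <- reject_artifacts(s)
  expect_equal(length(clean$retained), 15L)
  expect_true(all(clean$retained))

  x2 <- x; x2[round(10 * fs), 1] <- 250       # one spike at t = 10 s -> epoch 3
  s2 <- eeg_session(x2, fs, c("F3", "Fz"))
  r2 <- reject_artifacts(s2)
  expect_equal(which(!r2$retained), 3L)
  expect_equal(nrow(r2$samples), 14L * 4L * fs)

  # rejection is idempotent
  r3 <- reject_artifacts(r2)
  expect_true(all(r3$retained))
  expect_equal(r3$samples, r2$samples)

  sq <- eeg_session(matrix(300 * rep(c(1, -1), each = fs * 2, length.out = fs * 20)),
                    fs, "F3")
  expect_error(reject_artifacts(sq), "every epoch")
})

test_that("welch psd concentrates sinusoid power and satisfies Parseval", {
  fs <- 300
  t <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  p <- welch_psd(x, fs, segment_s = 2)
  expect_equal(p$freq[which.max(p$p_xx)], 20, tolerance = 0.5)
  df <- p$freq[2] - p$freq[1]
  expect_lt(abs(sum(p$p_xx) * df - 0.5) / 0.5, 0.05)   # sinusoid power A^2/2
  expect_true(all(p$p_xx >= 0))

  set.seed(92)
  for (i in 1:5) {
    w <- rnorm(fs * 15, sd = runif(1, 0.5, 3))
    pw <- welch_psd(w, fs, segment_s = 2)
    dfw <- pw$freq[2] - pw$freq[1]
    expect_lt(abs(sum(pw$p_xx) * dfw - var(w)) / var(w), 0.10)
  }

  # halving the segment doubles the frequency step
  pa <- welch_psd(x, fs, segment_s = 2); pb <- welch_psd(x, fs, segment_s = 1)
  expect_equal(pb$freq[2] / pa$freq[2], 2)

  z <- welch_psd(rep(0, fs * 10), fs)
  expect_true(all(is.finite(z$p_welch)))
  expect_equal(diff(range(z$p_welch)), 0)

  expect_error(welch_psd(rnorm(100), fs, segment_s = 2), "shorter")
})

test_that("band power separates theta- and beta-dominant signals", {
  fs <- 300
  t <- (0:(fs * 20 - 1)) / fs
  p20 <- welch_psd(sin(2 * pi * 20 * t), fs)
  expect_gt(band_power(p20, "beta"), band_power(p20, "theta"))
  p6 <- welch_psd(sin(2 * pi * 6 * t), fs)
  expect_gt(band_power(p6, "theta"), band_power(p6, "beta"))
  flat <- p20; flat$p_welch[] <- -40
  expect_equal(band_power(flat, "beta"), band_power(flat, "theta"))
  expect_error(band_power(p20, c(200, 300)), "no frequency bins")
})

test_that("synthetic band density ratios are recovered in sign by the band powers", {
  # band power is the mean over band bins, i.e. a per-Hz density; the
  # beta:theta density ratio r is realized by scaling each band's variance
  # by its bandwidth (theta 4 Hz, beta 19 Hz)
  set.seed(93)
  ok <- 0L
  for (i in 1:20) {
    r <- c(0.5, 1, 2)[(i %% 3) + 1]
    prof <- eeg_profile("stationary", duration_s = 40)
    prof$bands$beta$var_first <- prof$bands$beta$var_second <- 0.5 * 19 * r
    prof$bands$theta$var_first <- prof$bands$theta$var_second <- 0.5 * 4
    s <- simulate_eeg(prof, seed = 930 + i)
    p <- welch_psd(s$samples[, "Fz"], s$sfreq)
    d <- band_power(p, "beta") - band_power(p, "theta")
    if (r == 1 || sign(d) == sign(log(r))) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("half-split comparison flags the declining profile and not stationarity", {
  cmp <- half_split_compare(simulate_eeg("declining", seed = 94))
  expect_true(cmp$attention_decline)
  expect_lt(cmp$beta_change, 0)
  expect_gt(cmp$theta_change, 0)

  cmp2 <- half_split_compare(simulate_eeg("stationary", seed = 94))
  expect_false(cmp2$attention_decline)

  s <- simulate_eeg("declining", seed = 95)
  s$channels[1] <- "C3"; colnames(s$samples)[1] <- "C3"
  expect_error(half_split_compare(s), "missing channel")
})
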