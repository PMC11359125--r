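# EEG verification arm: filtering, epoch-based artifact rejection, Welch
# power spectral density, frontal band power, and the first-half versus
# second-half attention comparison.

#' EEG session container
#'
#' @param samples Numeric matrix, samples x channels, in microvolts.
#' @param sfreq Sampling frequency in Hz.
#' @param channels Character vector of 10-20 channel names (unique, one per
#'   column).
#' @return List of class \code{eeg_session} with fields \code{samples},
#'   \code{sfreq}, \code{channels}, \code{epoch_s}, \code{retained}
#'   (per-epoch logical mask, NULL until rejection has run).
#' @export
eeg_session <- function(samples, sfreq, channels) {
  samples <- as.matrix(samples)
  if (sfreq <= 0) stop("eeg_session: sfreq must be positive")
  if (length(channels) != ncol(samples)) stop("eeg_session: one name per channel")
  if (anyDuplicated(channels)) stop("eeg_session: channel names must be unique")
  colnames(samples) <- channels
  structure(list(samples = samples, sfreq = sfreq, channels = channels,
                 epoch_s = NULL, retained = NULL),
            class = "eeg_session")
}

#' Band-pass preprocessing: high-pass and mains notch
#'
#' Applies, per channel and forward-backward (zero phase), a Butterworth
#' high-pass at \code{highpass_hz} (default 0.1 Hz, removing the dominant
#' ultra-slow drift) and a biquad notch at \code{notch_hz} (default 50 Hz
#' mains interference, quality factor \code{notch_q}).  The forward-backward
#' pass squares the magnitude response, so the order-2 high-pass realizes a
#' 4th-order zero-phase roll-off while staying numerically stable at the
#' very low cutoff-to-sampling ratio.
#'
#' @param s \code{eeg_session}.
#' @param highpass_hz High-pass cutoff in Hz.
#' @param notch_hz Notch centre frequency in Hz.
#' @param notch_q Notch quality factor (default 30).
#' @return The filtered \code{eeg_session}.
#' @export
preprocess_eeg <- function(s, highpass_hz = 0.1, notch_hz = 50, notch_q = 30) {
  stopifnot(inherits(s, "eeg_session"))
  if (s$sfreq <= 2 * notch_hz)
    stop("preprocess_eeg: sampling rate must exceed twice the notch frequency")
  hp <- signal::butter(2, highpass_hz / (s$sfreq / 2), type = "high")
  w0 <- 2 * pi * notch_hz / s$sfreq
  alpha <- sin(w0) / (2 * notch_q)
  nb <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  na <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  for (j in seq_len(ncol(s$samples))) {
    x <- s$samples[, j]
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(signal::Arma(b = nb, a = na), x)
    s$samples[, j] <- x
  }
  s
}

#' Epoch-based artifact rejection
#'
#' Splits the session into consecutive \code{epoch_s}-second epochs and
#' masks out every epoch in which any analysed channel exceeds
#' \code{amp_uv} microvolts in absolute value (muscle and motion residuals).
#' Retained data are the concatenation of the kept epochs; the operation is
#' idempotent.
#'
#' @param s \code{eeg_session}.
#' @param epoch_s Epoch length in seconds (default 4).
#' @param amp_uv Absolute amplitude criterion in microvolts (default 200).
#' @return \code{eeg_session} containing only the kept epochs, with
#'   \code{epoch_s} and the \code{retained} mask recorded.
#' @export
reject_artifacts <- function(s, epoch_s = 4, amp_uv = 200) {
  stopifnot(inherits(s, "eeg_session"))
  len <- round(epoch_s * s$sfreq)
  n_ep <- nrow(s$samples) %/% len
  if (n_ep < 1L) stop("reject_artifacts: session shorter than one epoch")
  keep <- logical(n_ep)
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * len + 1L):(e * len)
    keep[e] <- max(abs(s$samples[idx, , drop = FALSE])) <= amp_uv
  }
  if (!any(keep)) stop("reject_artifacts: every epoch rejected")
  idx <- unlist(lapply(which(keep), function(e) ((e - 1L) * len + 1L):(e * len)))
  out <- eeg_session(s$samples[idx, , drop = FALSE], s$sfreq, s$channels)
  out$epoch_s <- epoch_s
  out$retained <- keep
  out
}

#' Welch power spectral density of one channel
#'
#' Splits the signal into \code{L} overlapping segments of
#' \code{segment_s} seconds, windows each, averages the windowed
#' periodograms with the window-energy normalization
#' \code{U = mean(w^2)}, and log-scales the average:
#' \code{P_welch = 10 log10(P_xx + eps)} with a floor of 1e-12 relative to
#' the spectral maximum so that empty bins (or an all-zero signal) do not
#' fail.  The linear density is one-sided and satisfies
#' \code{sum(P_xx) * df ~ var(x)} for stationary signals.
#'
#' @param x Numeric vector (single channel, microvolts).
#' @param sfreq Sampling frequency in Hz.
#' @param segment_s Segment length in seconds (default 2, giving 0.5 Hz
#'   resolution).
#' @param overlap Overlap fraction in \code{[0, 1)} (default 0.5).
#' @param window Window type: \code{"hamming"} (default) or \code{"hann"}.
#' @return List of class \code{psd_estimate}: \code{freq}, \code{p_xx}
#'   (linear), \code{p_welch} (dB), \code{n_segments}, \code{segment_n},
#'   \code{overlap_n}, \code{window}.
#' @export
welch_psd <- function(x, sfreq, segment_s = 2, overlap = 0.5,
                      window = c("hamming", "hann")) {
  window <- match.arg(window)
  n <- round(segment_s * sfreq)
  if (n > length(x)) stop("welch_psd: signal shorter than one segment")
  if (overlap < 0 || overlap >= 1) stop("welch_psd: overlap must be in [0, 1)")
  d <- floor(n * overlap)
  step <- n - d
  w <- if (window == "hamming") 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
       else 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  u <- mean(w^2)
  starts <- seq(1L, length(x) - n + 1L, by = step)
  n_half <- n %/% 2 + 1L
  acc <- numeric(n_half)
  for (s0 in starts) {
    seg <- x[s0:(s0 + n - 1L)] * w
    sp <- abs(stats::fft(seg)[seq_len(n_half)])^2 / (n * u * sfreq)
    acc <- acc + sp
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, n_half); dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_half] <- 1
  p <- p * dbl
  eps <- 1e-12 * max(p)
  if (eps == 0) eps <- 1e-12
  structure(list(freq = (seq_len(n_half) - 1L) * sfreq / n,
                 p_xx = p, p_welch = 10 * log10(p + eps),
                 n_segments = length(starts), segment_n = n, overlap_n = d,
                 window = window),
            class = "psd_estimate")
}

#' Mean log band power of a PSD estimate
#'
#' Averages the log-scaled Welch density over the bins inside a frequency
#' band (bounds inclusive).  The canonical bands are theta (4-8 Hz) and
#' beta (13-32 Hz).
#'
#' @param psd \code{psd_estimate}.
#' @param band Length-2 numeric \code{c(low, high)} in Hz, or one of
#'   \code{"theta"}, \code{"beta"}.
#' @param scale \code{"log"} (default: mean of \code{p_welch} in dB) or
#'   \code{"linear"} (mean of \code{p_xx}).
#' @return Band-power value (scalar).
#' @export
band_power <- function(psd, band, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (is.character(band)) {
    band <- switch(band, theta = c(4, 8), beta = c(13, 32),
                   stop("band_power: unknown band name"))
  }
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("band_power: no frequency bins inside the band")
  if (scale == "log") mean(psd$p_welch[sel]) else mean(psd$p_xx[sel])
}

#' First-half versus second-half frontal band-power comparison
#'
#' Splits the session at its temporal midpoint, preprocesses and
#' artifact-rejects each half, estimates the Welch band power of the theta
#' (4-8 Hz) and beta (13-32 Hz) bands on the frontal channels (F3, Fz, F4
#' by default), averages across channels, and flags
#' \code{attention_decline} when beta power dropped and theta power rose
#' from the first to the second half by more than \code{min_diff_db}
#' (focused attention raises beta and lowers theta, so the joint reversal
#' indicates declining attention).  The decision margin exists because two
#' stationary halves differ only by sampling noise, whose sign is
#' uninformative.
#'
#' @param s \code{eeg_session} (raw; filtering and rejection run per half).
#' @param channels Channels averaged (default \code{c("F3", "Fz", "F4")}).
#' @param scale Band-power scale, \code{"log"} (default) or
#'   \code{"linear"}; the margin is interpreted in the chosen scale's units.
#' @param min_diff_db Decision margin (default 1 dB).
#' @param preprocess Run [preprocess_eeg()] on each half first
#'   (default TRUE).
#' @param epoch_s,amp_uv Artifact-rejection parameters.
#' @param segment_s,overlap Welch parameters.
#' @return List: per-band first/second-half powers (\code{beta_first},
#'   \code{beta_second}, \code{theta_first}, \code{theta_second}),
#'   \code{beta_change}, \code{theta_change} (second minus first) and
#'   logical \code{attention_decline}.
#' @export
half_split_compare <- function(s, channels = c("F3", "Fz", "F4"),
                               scale = c("log", "linear"), min_diff_db = 1,
                               preprocess = TRUE, epoch_s = 4, amp_uv = 200,
                               segment_s = 2, overlap = 0.5) {
  scale <- match.arg(scale)
  stopifnot(inherits(s, "eeg_session"))
  missing_ch <- setdiff(channels, s$channels)
  if (length(missing_ch))
    stop("half_split_compare: missing channel(s): ", paste(missing_ch, collapse = ", "))
  n <- nrow(s$samples)
  mid <- n %/% 2
  halves <- list(first = 1:mid, second = (mid + 1L):n)
  power <- list()
  for (h in names(halves)) {
    hs <- eeg_session(s$samples[halves[[h]], channels, drop = FALSE], s$sfreq, channels)
    if (preprocess) hs <- preprocess_eeg(hs)
    hs <- reject_artifacts(hs, epoch_s, amp_uv)
    if (nrow(hs$samples) < round(segment_s * s$sfreq))
      stop("half_split_compare: a half has too little retained data for one segment")
    for (b in c("theta", "beta")) {
      vals <- vapply(channels, function(ch) {
        band_power(welch_psd(hs$samples[, ch], s$sfreq, segment_s, overlap), b, scale)
      }, numeric(1))
      power[[paste0(b, "_", h)]] <- mean(vals)
    }
  }
  beta_change <- power$beta_second - power$beta_first
  theta_change <- power$theta_second - power$theta_first
  c(power,
    list(beta_change = beta_change, theta_change = theta_change,
         attention_decline = (beta_change < -min_diff_db) && (theta_change > min_diff_db)))
}
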