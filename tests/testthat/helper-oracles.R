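# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use the most direct (slow) formulation so they stay
# independent of the package's implementation path.

# exhaustive between-class-variance maximizer, written as a plain loop over
# all 256 candidate thresholds with explicit class means
oracle_otsu <- function(values) {
  v <- pmin(pmax(round(values), 0), 255)
  best <- -Inf; best_t <- integer(0)
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    sb <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
    else if (abs(sb - best) <= 1e-12) best_t <- c(best_t, t)
  }
  best_t
}

# brute-force pupil localization: every pixel is a candidate centre and the
# objective is accumulated edge point by edge point
oracle_pupil <- function(img, gradient_floor = NULL) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  for (r in 1:h) for (cc in 1:w) {
    gx[r, cc] <- (img[r, min(cc + 1, w)] - img[r, max(cc - 1, 1)]) / 2
    gy[r, cc] <- (img[min(r + 1, h), cc] - img[max(r - 1, 1), cc]) / 2
  }
  mag <- sqrt(gx^2 + gy^2)
  if (is.null(gradient_floor)) gradient_floor <- mean(mag) + 0.3 * sd(as.numeric(mag))
  edge <- which(mag > gradient_floor, arr.ind = TRUE)
  best <- -Inf; bx <- 1; by <- 1
  for (cy in 1:h) for (cx in 1:w) {
    acc <- 0; n <- 0
    for (e in seq_len(nrow(edge))) {
      ey <- unname(edge[e, 1]); ex <- unname(edge[e, 2])
      dx <- ex - cx; dy <- ey - cy
      dn <- sqrt(dx^2 + dy^2)
      if (dn == 0) { n <- n + 1; next }
      m <- mag[ey, ex]
      d <- (dx * gx[ey, ex] / m + dy * gy[ey, ex] / m) / dn
      acc <- acc + d^2; n <- n + 1
    }
    obj <- acc / n
    if (obj > best + 1e-12) { best <- obj; bx <- cx; by <- cy }
  }
  list(x = bx, y = by, objective = best)
}

# rank-then-correlate Spearman oracle: average ranks assigned by explicit
# enumeration, then the product-moment formula applied term by term
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# constant-gaze frame stream builder
make_stream <- function(t, x, y, n_faces = 1L, pitch = 0, yaw = 0,
                        geom = screen_geometry(34.5, 19.4)) {
  dx <- x - geom$width_cm / 2; dy <- y - geom$height_cm / 2
  nrm <- sqrt(dx^2 + dy^2 + 50^2)
  data.frame(t_s = t, n_faces = n_faces,
             pitch_deg = pitch, yaw_deg = yaw, roll_deg = 0,
             gaze_pitch_deg = asin(-dy / nrm) * 180 / pi,
             gaze_yaw_deg = atan2(dx, 50) * 180 / pi,
             gaze_x_cm = x, gaze_y_cm = y)
}

# stream with prescribed gaze directions only (no useful gaze point)
make_direction_stream <- function(pitch, yaw, fps = 30) {
  n <- length(pitch)
  data.frame(t_s = (seq_len(n) - 1) / fps, n_faces = 1L,
             pitch_deg = 0, yaw_deg = 0, roll_deg = 0,
             gaze_pitch_deg = pitch, gaze_yaw_deg = yaw,
             gaze_x_cm = NA_real_, gaze_y_cm = NA_real_)
}
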