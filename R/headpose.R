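# Head-pose recovery from 2D-3D landmark correspondences, Euler-angle
# extraction, and concentration-tier classification.
#
# Camera frame: +X right, +Y down (image convention), +Z toward the scene.
# Euler convention: intrinsic X-Y-Z, i.e. R = Rx(pitch) Ry(yaw) Rz(roll),
# angles in degrees.

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

#' Camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels (positive).
#' @param cx,cy Principal point in pixels.
#' @return List of class \code{camera_intrinsics}.
#' @export
camera_intrinsics <- function(fx, fy = fx, cx = 0, cy = 0) {
  if (fx <= 0 || fy <= 0) stop("camera_intrinsics: focal lengths must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy), class = "camera_intrinsics")
}

#' Compose a rotation matrix from Euler angles
#'
#' Intrinsic X-Y-Z composition: \code{R = Rx(pitch) Ry(yaw) Rz(roll)}.
#'
#' @param pitch,yaw,roll Angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_rotation <- function(pitch, yaw, roll) {
  p <- .deg2rad(pitch); y <- .deg2rad(yaw); r <- .deg2rad(roll)
  rx <- matrix(c(1, 0, 0, 0, cos(p), -sin(p), 0, sin(p), cos(p)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(y), 0, sin(y), 0, 1, 0, -sin(y), 0, cos(y)), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(r), -sin(r), 0, sin(r), cos(r), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rx %*% ry %*% rz
}

#' Euler angles of a rotation matrix
#'
#' Decomposes an orthonormal rotation into intrinsic X-Y-Z angles
#' (pitch about X, yaw about Y, roll about Z).  Away from the gimbal-lock
#' configuration |yaw| = 90 deg, recomposition via
#' [euler_to_rotation()] reproduces the input.
#'
#' @param R 3x3 rotation matrix (orthonormal, determinant +1).
#' @return List with \code{pitch}, \code{yaw}, \code{roll} in degrees.
#' @export
rotation_to_euler <- function(R) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)))
    stop("rotation_to_euler: R must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("rotation_to_euler: R is not a proper rotation matrix")
  # R = Rx(p) Ry(y) Rz(r): R[1,3] = sin(y)
  yaw <- asin(pmin(pmax(R[1, 3], -1), 1))
  if (abs(abs(R[1, 3]) - 1) < 1e-9) {
    # gimbal lock: pitch and roll are coupled; attribute all to pitch
    pitch <- atan2(R[2, 1], R[2, 2])
    roll <- 0
  } else {
    pitch <- atan2(-R[2, 3], R[3, 3])
    roll <- atan2(-R[1, 2], R[1, 1])
  }
  list(pitch = .rad2deg(pitch), yaw = .rad2deg(yaw), roll = .rad2deg(roll))
}

#' Project 3-D model points through a pose and camera
#'
#' Pinhole projection \code{x = fx X'/Z' + cx}, \code{y = fy Y'/Z' + cy}
#' with \code{(X', Y', Z')' = R P + T}.
#'
#' @param model_points n x 3 matrix of 3-D points.
#' @param R 3x3 rotation matrix.
#' @param T Length-3 translation.
#' @param K \code{camera_intrinsics}.
#' @return n x 2 matrix of image points.
#' @export
project_points <- function(model_points, R, T, K) {
  p <- t(R %*% t(model_points) + T)
  if (any(p[, 3] <= 0)) warning("project_points: points behind the camera")
  cbind(K$fx * p[, 1] / p[, 3] + K$cx,
        K$fy * p[, 2] / p[, 3] + K$cy)
}

.rodrigues <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' A generic 6-point 3-D head model
#'
#' The widely used generic facial landmark model (millimetres, origin at the
#' nose tip): nose tip, chin, outer eye corners, mouth corners.  Pose
#' recovery needs only consistent 2D-3D correspondences, so this generic
#' rigid model stands in for any specific head.
#'
#' @return 6 x 3 numeric matrix with row names.
#' @export
generic_head_model <- function() {
  m <- rbind(
    nose_tip        = c(0, 0, 0),
    chin            = c(0, -330, -65),
    left_eye_corner = c(-225, 170, -135),
    right_eye_corner = c(225, 170, -135),
    left_mouth      = c(-150, -150, -125),
    right_mouth     = c(150, -150, -125)
  )
  colnames(m) <- c("X", "Y", "Z")
  m
}

#' Recover head pose from 2D-3D correspondences
#'
#' Solves the perspective-n-point problem: finds the rotation \code{R} and
#' translation \code{T} whose pinhole projection of \code{model_points}
#' best reproduces \code{image_points}, by Levenberg-Marquardt minimization
#' of the reprojection residual over an axis-angle rotation
#' parameterization, restarted from a small set of coarse initial rotations.
#'
#' @param image_points n x 2 matrix of observed image points (pixels).
#' @param model_points n x 3 matrix of corresponding 3-D points.
#' @param K \code{camera_intrinsics}.
#' @param tol RMS reprojection error (pixels) above which the best solution
#'   is reported with a warning.
#' @return List with \code{R} (3x3), \code{T} (length 3), \code{euler}
#'   (from [rotation_to_euler()]) and \code{rms} reprojection error.
#' @export
solve_head_pose <- function(image_points, model_points, K, tol = 1) {
  image_points <- as.matrix(image_points)
  model_points <- as.matrix(model_points)
  n <- nrow(image_points)
  if (n < 4L || nrow(model_points) != n)
    stop("solve_head_pose: need at least 4 matched correspondences")
  cm <- scale(model_points, scale = FALSE)
  if (svd(cm)$d[2] < 1e-8 * max(svd(cm)$d[1], 1))
    stop("solve_head_pose: collinear model points are a degenerate configuration")

  obs <- as.numeric(t(image_points))
  spread_m <- max(stats::dist(model_points))
  spread_i <- max(stats::dist(image_points))
  z0 <- K$fx * spread_m / max(spread_i, 1e-9)

  resid <- function(par) {
    R <- .rodrigues(par[1:3])
    p <- t(R %*% t(model_points) + par[4:6])
    z <- pmax(p[, 3], 1e-6)
    pr <- cbind(K$fx * p[, 1] / z + K$cx, K$fy * p[, 2] / z + K$cy)
    as.numeric(t(pr)) - obs
  }

  starts <- list(c(0, 0, 0), c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0),
                 c(0, -0.5, 0), c(0.3, 0.3, 0), c(-0.3, -0.3, 0))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(s, 0, 0, z0), fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rms <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || rms < best$rms) best <- list(fit = fit, rms = rms)
    if (best$rms < 1e-8) break
  }
  if (is.null(best)) stop("solve_head_pose: optimization failed")
  if (best$rms > tol)
    warning(sprintf("solve_head_pose: RMS reprojection error %.3g px exceeds tol", best$rms))
  par <- best$fit$par
  R <- .rodrigues(par[1:3])
  list(R = R, T = par[4:6], euler = rotation_to_euler(R), rms = best$rms)
}

#' Concentration tier of a head pose
#'
#' Partitions poses by \code{m = max(|pitch|, |yaw|)}: \code{high} for
#' m <= 10 deg (head facing the screen), \code{medium} for 10 < m <= 30,
#' \code{low} for m > 30.  Roll is ignored: tilting the head without turning
#' away does not move the gaze off the screen.
#'
#' @param pitch,yaw Head-pose angles in degrees (vectorized).
#' @param roll Ignored; accepted for interface symmetry.
#' @return Character vector: \code{"high"}, \code{"medium"} or \code{"low"}.
#' @export
classify_concentration <- function(pitch, yaw, roll = NULL) {
  m <- pmax(abs(pitch), abs(yaw))
  ifelse(m <= 10, "high", ifelse(m <= 30, "medium", "low"))
}
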