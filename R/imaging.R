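# Image-level operators: Otsu thresholding, YCrCb skin masking, and
# gradient dot-product pupil-centre localization.  Images are plain numeric
# matrices (rows = y, columns = x, origin top-left) with intensities in
# [0, 255]; colour images are height x width x 3 arrays.

#' Otsu threshold of an intensity sample
#'
#' Exhaustively searches the integer thresholds 0..255 for the split
#' maximizing the between-class variance of the two classes
#' \code{v <= t} and \code{v > t}.  Ties (plateaus of equal between-class
#' variance, as with perfectly bimodal data) are resolved to the mean of the
#' tied thresholds, placing the cut mid-way between the classes.
#'
#' @param values Numeric vector of intensities in \code{[0, 255]}.
#' @return Integer threshold \code{t}; the foreground class is \code{v > t}.
#' @export
otsu_threshold <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("otsu_threshold: intensities must be finite")
  if (length(unique(values)) < 2L)
    stop("otsu_threshold: constant input, classes cannot be separated")
  v <- pmin(pmax(round(values), 0), 255)
  h <- tabulate(v + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                        # count of class v <= t
  s0 <- cumsum(h * lev)                  # intensity sum of class v <= t
  stot <- s0[256]
  w1 <- n - w0
  ok <- w0 > 0 & w1 > 0
  mu0 <- s0 / w0
  mu1 <- (stot - s0) / w1
  sb <- ifelse(ok, (w0 / n) * (w1 / n) * (mu0 - mu1)^2, -Inf)
  best <- which(sb >= max(sb) - 1e-12)
  round(mean(lev[best]))
}

#' Convert an RGB raster to YCrCb
#'
#' ITU-R BT.601 full-range conversion.  Input and output are
#' height x width x 3 arrays with values in \code{[0, 255]}; output channels
#' are Y, Cr, Cb.
#'
#' @param img RGB array.
#' @return YCrCb array of the same dimensions.
#' @export
rgb_to_ycrcb <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y  <- 0.299 * r + 0.587 * g + 0.114 * b
  cr <- (r - y) * 0.713 + 128
  cb <- (b - y) * 0.564 + 128
  out <- array(0, dim = dim(img))
  out[, , 1] <- y; out[, , 2] <- cr; out[, , 3] <- cb
  out
}

#' Convert a YCrCb raster back to RGB
#'
#' Inverse of [rgb_to_ycrcb()]; round-trips within rounding error.
#'
#' @param img YCrCb array (channels Y, Cr, Cb).
#' @return RGB array of the same dimensions.
#' @export
ycrcb_to_rgb <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  y <- img[, , 1]; cr <- img[, , 2]; cb <- img[, , 3]
  r <- y + (cr - 128) / 0.713
  b <- y + (cb - 128) / 0.564
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, dim = dim(img))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  pmin(pmax(out, 0), 255)
}

#' Skin-region mask from the Cr chroma channel
#'
#' Converts the image to YCrCb (if given as RGB), Otsu-splits the Cr
#' channel, and retains the higher-Cr class, which is where skin chroma
#' concentrates.  A constant-Cr image cannot be split; it is returned fully
#' retained with a warning.
#'
#' @param img height x width x 3 array, values in \code{[0, 255]}.
#' @param space Either \code{"rgb"} (default, converted internally) or
#'   \code{"ycrcb"} if the image is already in YCrCb.
#' @return Logical matrix (height x width); \code{TRUE} = retained skin pixel.
#' @export
skin_mask <- function(img, space = c("rgb", "ycrcb")) {
  space <- match.arg(space)
  ycc <- if (space == "rgb") rgb_to_ycrcb(img) else img
  cr <- ycc[, , 2]
  if (length(unique(round(as.numeric(cr)))) < 2L) {
    warning("skin_mask: constant Cr channel; retaining all pixels")
    return(matrix(TRUE, nrow(cr), ncol(cr)))
  }
  t <- otsu_threshold(cr)
  cr > t
}

#' Image gradients by central differences
#'
#' Central differences in x (columns) and y (rows) with replicated borders.
#'
#' @param img Numeric matrix (rows = y, columns = x).
#' @return List with matrices \code{gx}, \code{gy} and \code{mag}.
#' @export
image_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h < 2L || w < 2L) stop("image_gradients: image must be at least 2x2")
  xl <- img[, c(1L, seq_len(w - 1L))]
  xr <- img[, c(seq_len(w - 1L) + 1L, w)]
  yu <- img[c(1L, seq_len(h - 1L)), ]
  yd <- img[c(seq_len(h - 1L) + 1L, h), ]
  gx <- (xr - xl) / 2
  gy <- (yd - yu) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Gradient dot-product pupil-centre localization
#'
#' Locates the pupil centre as the candidate pixel \code{c} maximizing
#' \deqn{(1/N) \sum_i (d_i^T g_i)^2,} where \code{x_i} are the edge points
#' (pixels whose gradient magnitude exceeds \code{gradient_floor}),
#' \code{g_i} the unit image gradient at \code{x_i}, and
#' \code{d_i = (x_i - c)/||x_i - c||} the unit displacement from the
#' candidate to the edge point.  At the true centre of a dark circular pupil
#' every \code{d_i} is collinear with \code{g_i}, so the objective peaks
#' there.  Candidates are restricted to the darkest \code{dark_fraction} of
#' pixels, since the pupil is the darkest structure in an eye image; ties
#' break to the smallest (y, x).
#'
#' @param img Numeric matrix, intensities in \code{[0, 255]}.
#' @param dark_fraction Proportion of darkest pixels admitted as candidate
#'   centres (default 0.3; 1 means every pixel).
#' @param gradient_floor Gradient-magnitude cutoff defining edge points;
#'   default \code{NULL} uses mean + 0.3 sd of the magnitudes.
#' @return List with \code{x}, \code{y} (1-based pixel coordinates of the
#'   centre) and \code{objective} (the maximized mean squared dot product).
#' @export
locate_pupil <- function(img, dark_fraction = 0.3, gradient_floor = NULL) {
  h <- nrow(img); w <- ncol(img)
  if (is.null(h) || h < 2L || w < 2L) stop("locate_pupil: image must be at least 2x2")
  if (dark_fraction <= 0 || dark_fraction > 1)
    stop("locate_pupil: dark_fraction must be in (0, 1]")
  g <- image_gradients(img)
  if (all(g$mag == 0)) stop("locate_pupil: uniform image has no gradients")
  if (is.null(gradient_floor))
    gradient_floor <- mean(g$mag) + 0.3 * stats::sd(as.numeric(g$mag))
  edge <- which(g$mag > gradient_floor, arr.ind = TRUE)
  if (nrow(edge) == 0L) stop("locate_pupil: no edge points above the gradient floor")
  em <- g$mag[edge]
  egx <- g$gx[edge] / em
  egy <- g$gy[edge] / em
  ex <- edge[, 2]; ey <- edge[, 1]

  # candidate centres: darkest dark_fraction of pixels, ordered by (y, x)
  cutoff <- stats::quantile(img, probs = dark_fraction, type = 1)
  cand <- which(img <= cutoff, arr.ind = TRUE)
  cx <- cand[, 2]; cy <- cand[, 1]

  n_edge <- length(ex)
  best_obj <- -Inf; best_i <- 1L
  # chunked over candidates to bound memory on large images
  chunk <- max(1L, floor(2e6 / n_edge))
  for (s in seq(1L, length(cx), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(cx))
    dx <- outer(ex, cx[idx], "-")          # n_edge x n_cand
    dy <- outer(ey, cy[idx], "-")
    nrm <- sqrt(dx^2 + dy^2)
    nrm[nrm == 0] <- Inf                   # a candidate at an edge point: skip that term
    dot <- (dx * egx + dy * egy) / nrm
    obj <- colSums(dot^2) / n_edge
    for (j in seq_along(idx)) {
      if (obj[j] > best_obj + 1e-12) {
        best_obj <- obj[j]; best_i <- idx[j]
      } else if (abs(obj[j] - best_obj) <= 1e-12) {
        # tie: smallest (y, x)
        if (cy[idx[j]] < cy[best_i] ||
            (cy[idx[j]] == cy[best_i] && cx[idx[j]] < cx[best_i])) {
          best_i <- idx[j]
        }
      }
    }
  }
  list(x = unname(cx[best_i]), y = unname(cy[best_i]), objective = unname(best_obj))
}

#' Read a grayscale PNG image as an intensity matrix
#'
#' Reads a PNG file and returns a matrix in \code{[0, 255]} (colour inputs
#' are converted to luma).  Requires the \pkg{png} package.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix (rows = y, columns = x).
#' @export
read_gray_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("read_gray_png: the 'png' package is required")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a * 255
}
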