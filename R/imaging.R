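# --- low-level image helpers -------------------------------------------------

# separable Gaussian convolution with symmetric (reflective) boundary
# handling; kernel truncated at 3 sigma.
smoothAlongRows <- function(m, k) {
  n <- nrow(m)
  half <- (length(k) - 1L) %/% 2L
  if (half == 0L) return(m)
  ext <- m[c(half:1, seq_len(n), n:(n - half + 1L)), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * ext[t:(t + n - 1L), , drop = FALSE]
  out
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian filter with reflective boundary handling and the
#' kernel truncated at three standard deviations.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; \code{sigma <= 0} returns
#'   the image unchanged.
#' @return smoothed matrix of the same dimension.
#' @export
gaussianSmooth <- function(img, sigma) {
  img <- as.matrix(img)
  if (sigma <= 0) return(img)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  half <- min(half, nrow(img) - 1L, ncol(img) - 1L)
  k <- stats::dnorm(seq.int(-half, half), sd = sigma)
  k <- k / sum(k)
  t(smoothAlongRows(t(smoothAlongRows(img, k)), k))
}

# central differences, one-sided at the borders
centralDiff <- function(m, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(centralDiff(t(m), "col")))
  W <- ncol(m)
  g <- matrix(0, nrow(m), W)
  if (W >= 3L) g[, 2:(W - 1L)] <- (m[, 3:W] - m[, 1:(W - 2L)]) / 2
  if (W >= 2L) {
    g[, 1L] <- m[, 2L] - m[, 1L]
    g[, W] <- m[, W] - m[, W - 1L]
  }
  g
}

#' Signed radial (directional) gradient
#'
#' Intensity derivative along the outward radial direction from a
#' centre: the dot product of the central-difference image gradient with
#' the unit radial vector at each pixel.  For a bright object on a
#' darker background the boundary shows up as a strongly negative
#' ridge.  At the centre itself the radial direction is undefined and
#' the output is 0.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param center numeric(2), centre \code{c(x, y)} in 1-based pixel
#'   coordinates; must lie inside the image.
#' @return matrix of the same dimension.
#' @export
radialGradient <- function(img, center) {
  img <- as.matrix(img)
  H <- nrow(img)
  W <- ncol(img)
  cx <- center[1L]
  cy <- center[2L]
  if (length(center) != 2L || !all(is.finite(center)))
    stop("center must be two finite numbers c(x, y)")
  if (cx < 1 || cx > W || cy < 1 || cy > H)
    stop("center lies outside the image")
  gx <- centralDiff(img, "col")
  gy <- centralDiff(img, "row")
  dx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  dy <- matrix(seq_len(H), H, W) - cy
  r <- sqrt(dx^2 + dy^2)
  out <- gx * dx + gy * dy
  nz <- r > 0
  out[nz] <- out[nz] / r[nz]
  out[!nz] <- 0
  out
}

#' Bilinear sampling at arbitrary positions
#'
#' Samples an image at real-valued coordinates with bilinear
#' interpolation; positions outside the image are clamped to the nearest
#' valid pixel.
#'
#' @param img numeric matrix.
#' @param x,y coordinate arrays of equal shape (x = column, y = row,
#'   1-based pixel centres).
#' @return sampled values in the shape of \code{x}.
#' @export
bilinearSample <- function(img, x, y) {
  H <- nrow(img)
  W <- ncol(img)
  if (H < 2L || W < 2L) stop("image must be at least 2x2")
  dm <- dim(x)
  x <- pmin(pmax(as.vector(x), 1), W)
  y <- pmin(pmax(as.vector(y), 1), H)
  x0 <- pmin(floor(x), W - 1L)
  y0 <- pmin(floor(y), H - 1L)
  fx <- x - x0
  fy <- y - y0
  v <- img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
       img[cbind(y0, x0 + 1L)] * fx * (1 - fy) +
       img[cbind(y0 + 1L, x0)] * (1 - fx) * fy +
       img[cbind(y0 + 1L, x0 + 1L)] * fx * fy
  if (!is.null(dm)) dim(v) <- dm
  v
}

# 1D cubic-convolution (Keys, a = -0.5) resampling weights from nIn
# source samples to nOut targets, pixel-centre convention, edges clamped.
cubicWeights <- function(nIn, nOut) {
  p <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
  kern <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
           ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
  }
  W <- matrix(0, nOut, nIn)
  for (off in -1:2) {
    idx <- floor(p) + off
    w <- kern(p - idx)
    idx <- pmin(pmax(idx, 1), nIn)
    ii <- cbind(seq_len(nOut), idx)
    W[ii] <- W[ii] + w
  }
  W
}

#' Bicubic image resize
#'
#' Separable cubic-convolution (Keys kernel, a = -0.5) resampling with
#' the pixel-centre convention.  Unlike bilinear interpolation, whose
#' piecewise-linear output pins interpolated extrema to the source
#' pixel grid, cubic interpolation lets upsampled gradient extrema fall
#' between source pixels -- which is what makes radial refinement by
#' upsampling effective (see the methods vignette).
#'
#' @param img numeric matrix.
#' @param factor scale factor (output pixels per input pixel).
#' @return resized matrix of dimension \code{round(dim(img) * factor)}.
#' @export
resizeBicubic <- function(img, factor) {
  if (abs(factor - 1) < 1e-12) return(img)
  nr <- max(2L, as.integer(round(nrow(img) * factor)))
  nc <- max(2L, as.integer(round(ncol(img) * factor)))
  cubicWeights(nrow(img), nr) %*% img %*% t(cubicWeights(ncol(img), nc))
}

#' Polygon area by the shoelace formula
#'
#' @param x,y vertex coordinates of a simple polygon, closed implicitly.
#' @return the enclosed area (non-negative).
#' @export
shoelaceArea <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("a polygon needs at least 3 vertices")
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
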