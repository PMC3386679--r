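# extract z-slice of a 3D array as a matrix without dropping dims
zSlice <- function(a, z) {
  d <- dim(a)
  matrix(a[, , z], d[1L], d[2L])
}

#' First accumulation pass: in-plane (angle direction) smoothing
#'
#' Runs the 2D cost accumulation independently on every depth slice of
#' the feature volume: node connections are considered only at the same
#' depth z, with jump bound \code{d1} and weight \code{alpha1}.  The
#' result \code{c1} carries, at each node, the best in-plane path cost
#' ending there.
#'
#' @param R 3D numeric array (M radii x N angles x P frames) of finite
#'   values.
#' @param d1 non-negative integer jump bound along the angle axis.
#' @param alpha1 non-negative smoothness weight along the angle axis.
#' @return list with \code{c1} and integer pointer array \code{y1}, both
#'   of dimension M x N x P.
#' @seealso [dp3dPass2()], [dp3dDetect()]
#' @export
dp3dPass1 <- function(R, d1, alpha1) {
  R <- checkVolume(R)
  d <- dim(R)
  c1 <- array(0, d)
  y1 <- array(0L, d)
  for (z in seq_len(d[3L])) {
    st <- dp2dAccumulate(zSlice(R, z), d1, alpha1)
    c1[, , z] <- st$cost
    y1[, , z] <- st$pointer
  }
  list(c1 = c1, y1 = y1)
}

#' Second accumulation pass: through-plane (frame direction) smoothing
#'
#' Accumulates the first-pass costs along the depth axis at fixed angle:
#' \deqn{C_2(y, z, x) = \min_{|i| \le d_2} C_2(y+i, z-1, x) +
#'   \alpha_2 |i| + C_1(y, x, z)}
#' for \eqn{z \ge 2}.  Two initialisations of the first depth column are
#' supported: \code{"featureVolume"} starts from the raw feature values
#' \code{R[, x, 1]}, \code{"pass1"} starts from the accumulated
#' \code{c1[, x, 1]} so that the in-plane smoothing of the first frame
#' also enters the objective (see the methods vignette for why both
#' exist).
#'
#' @param c1 first-pass accumulation array from [dp3dPass1()] on the
#'   same \code{R}.
#' @param R the feature volume, M x N x P.
#' @param d2 non-negative integer jump bound along the frame axis.
#' @param alpha2 non-negative smoothness weight along the frame axis.
#' @param c2Init initialisation of the first depth column, see Details.
#' @return list with \code{c2} and pointer array \code{y2}, both of
#'   dimension M x P x N (note the axis order: depth becomes the column
#'   axis).
#' @export
dp3dPass2 <- function(c1, R, d2, alpha2,
                      c2Init = c("featureVolume", "pass1")) {
  R <- checkVolume(R)
  c2Init <- match.arg(c2Init)
  if (!identical(dim(c1), dim(R)))
    stop("c1 and R must have identical dimensions")
  d <- dim(R)
  M <- d[1L]; N <- d[2L]; P <- d[3L]
  d2 <- checkJump(d2, M, "d2")
  alpha2 <- checkWeight(alpha2, "alpha2")
  c2 <- array(0, c(M, P, N))
  y2 <- array(0L, c(M, P, N))
  for (x in seq_len(N)) {
    c2[, 1L, x] <- if (c2Init == "featureVolume") R[, x, 1L] else c1[, x, 1L]
    y2[, 1L, x] <- seq_len(M)
    if (P > 1L) {
      for (z in 2:P) {
        mj <- minOverJumps(c2[, z - 1L, x], d2, alpha2)
        c2[, z, x] <- mj$min + c1[, x, z]
        y2[, z, x] <- mj$arg
      }
    }
  }
  list(c2 = c2, y2 = y2, c2Init = c2Init)
}

#' Trace the optimal surface backwards
#'
#' For each angle x independently, starts from the row minimising the
#' final depth column \code{c2[, P, x]} (smallest row on ties) and
#' follows the second-pass pointers back through the frames.  The traced
#' height field therefore satisfies the frame-direction jump bound d2 by
#' construction; the angle-direction bound d1 is only encouraged through
#' the first-pass costs.
#'
#' @param c2,y2 accumulation and pointer arrays from [dp3dPass2()].
#' @return a [DPSurface-class]; its total cost is the sum over angles of
#'   the per-angle terminal minima.
#' @export
dp3dTraceback <- function(c2, y2) {
  d <- dim(c2)
  M <- d[1L]; P <- d[2L]; N <- d[3L]
  heights <- matrix(0L, N, P)
  total <- 0
  for (x in seq_len(N)) {
    y <- which.min(c2[, P, x])
    total <- total + c2[y, P, x]
    heights[x, P] <- y
    if (P > 1L) {
      for (z in P:2) heights[x, z - 1L] <- y2[heights[x, z], z, x]
    }
  }
  new("DPSurface", heights = heights, totalCost = total)
}

#' Detect the minimal-cost surface in a feature volume
#'
#' End-to-end surface search: in-plane accumulation ([dp3dPass1()]),
#' through-plane accumulation ([dp3dPass2()]) and backward tracing
#' ([dp3dTraceback()]).  The two-pass scheme is a fast approximation of
#' the full constrained surface optimisation; it links boundary evidence
#' across frames so that a frame with no usable evidence is bridged by
#' its neighbours.
#'
#' With \code{traceC1 = TRUE} the tracing is performed per frame on the
#' first-pass costs instead, which reproduces the traditional 2D
#' dynamic programme independently on every slice (the through-plane
#' parameters are then ignored).
#'
#' @inheritParams dp3dPass1
#' @inheritParams dp3dPass2
#' @param traceC1 logical; trace each frame independently on \code{c1}.
#' @return a [DPSurface-class].
#' @examples
#' R <- array(1, c(5, 12, 3)); R[3, , ] <- 0   # zero-cost plane at row 3
#' surfaceHeights(dp3dDetect(R, d1 = 1, d2 = 1, alpha1 = 0.05))
#' @export
dp3dDetect <- function(R, d1 = 1L, d2 = 2L, alpha1 = 0.1, alpha2 = alpha1,
                       c2Init = c("featureVolume", "pass1"),
                       traceC1 = FALSE) {
  R <- checkVolume(R)
  p1 <- dp3dPass1(R, d1, alpha1)
  if (traceC1) {
    d <- dim(R)
    heights <- matrix(0L, d[2L], d[3L])
    total <- 0
    for (z in seq_len(d[3L])) {
      tb <- dp2dTraceback(list(cost = zSlice(p1$c1, z),
                               pointer = zSlice(p1$y1, z)))
      heights[, z] <- tb$path
      total <- total + tb$cost
    }
    return(new("DPSurface", heights = heights, totalCost = total))
  }
  p2 <- dp3dPass2(p1$c1, R, d2, alpha2, c2Init)
  dp3dTraceback(p2$c2, p2$y2)
}

checkVolume <- function(R) {
  if (is(R, "FeatureVolume")) R <- R@values
  if (!is.array(R) || length(dim(R)) != 3L)
    stop("feature volume must be a 3D array")
  if (!all(is.finite(R)))
    stop("feature volume must be finite")
  R
}
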