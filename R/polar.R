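#' Construct a polar resampling grid
#'
#' @param center numeric(2), contour centre \code{c(x, y)} in 1-based
#'   pixel coordinates of the original image.
#' @param nAngles number of angular samples; angles are
#'   \eqn{\theta_k = 2\pi (k-1)/N}, counter-clockwise from +x, on the
#'   half-open interval \eqn{[0, 2\pi)}.
#' @param rMin,rMax radial search range in original-image pixels.  The
#'   default \code{rMax = NULL} is resolved against the image at
#'   [buildFeatureVolume()] time as \code{floor(min(H, W) / 2) - 2}.
#' @param resizeFactor bilinear upsampling factor applied to the
#'   gradient image before polar sampling; radial rows are spaced one
#'   pixel of the \emph{resized} image, so factors above 1 refine the
#'   radial quantisation.
#' @return a [PolarGrid-class].
#' @export
polarGrid <- function(center, nAngles = 72L, rMin = 2, rMax = NULL,
                      resizeFactor = 1) {
  new("PolarGrid", center = as.numeric(center),
      nAngles = as.integer(nAngles), rMin = as.numeric(rMin),
      rMax = if (is.null(rMax)) NA_real_ else as.numeric(rMax),
      resizeFactor = as.numeric(resizeFactor))
}

resolveGrid <- function(grid, H, W) {
  g <- grid
  if (is.na(g@rMax)) g@rMax <- floor(min(H, W) / 2) - 2
  validObject(g)
  border <- min(g@center[1L] - 1, W - g@center[1L],
                g@center[2L] - 1, H - g@center[2L])
  if (g@rMax > border + 1e-9)
    stop("rMax (", g@rMax, ") exceeds the distance from the centre to the ",
         "image border (", border, ")")
  g
}

#' Build the feature volume from an image sequence
#'
#' Per frame: signed radial gradient around the grid centre, bilinear
#' upsampling by the resize factor, bilinear sampling onto the polar
#' grid (rows = radii, columns = angles), and min-max rescaling of the
#' frame to [0, 1] so that the strongest negative radial gradient (the
#' bright-to-dark boundary of a bright object) maps to 0, the value the
#' surface search seeks.  Frames stack along the depth axis.
#'
#' A frame with no gradient contrast at all cannot be rescaled; it is
#' emitted as a flat 0.5 feature with a warning.
#'
#' @param images image sequence: a 3D array (H x W x P), a list of
#'   matrices of identical shape, or a [PhantomSequence-class].
#' @param grid a [PolarGrid-class]; an unset \code{rMax} is resolved to
#'   \code{floor(min(H, W)/2) - 2}.
#' @param invert logical; negate the gradient first to detect a dark
#'   object on a bright background.
#' @return a [FeatureVolume-class].
#' @examples
#' ph <- generatePhantom()
#' fv <- buildFeatureVolume(ph, polarGrid(center = c(21, 21)))
#' dim(featureValues(fv))
#' @export
buildFeatureVolume <- function(images, grid, invert = FALSE) {
  fr <- asFrameList(images)
  H <- nrow(fr[[1L]])
  W <- ncol(fr[[1L]])
  if (H < 8L || W < 8L) stop("images must be at least 8x8")
  g <- resolveGrid(grid, H, W)
  f <- g@resizeFactor

  nr <- max(2L, as.integer(round(H * f)))
  nc <- max(2L, as.integer(round(W * f)))
  sy <- nr / H
  sx <- nc / W
  s <- (sx + sy) / 2
  if (abs(sx - sy) / s > 0.01)
    warning("anisotropic realised resize (", signif(sx, 4), " vs ",
            signif(sy, 4), "); radii use the mean scale")

  radiiRes <- seq(g@rMin * s, g@rMax * s, by = 1)
  if (length(radiiRes) < 4L)
    stop("radial range supports fewer than 4 samples; widen rMin..rMax")
  angles <- 2 * pi * (seq_len(g@nAngles) - 1L) / g@nAngles

  cxr <- (g@center[1L] - 0.5) * sx + 0.5
  cyr <- (g@center[2L] - 0.5) * sy + 0.5
  xs <- cxr + outer(radiiRes, cos(angles))
  ys <- cyr + outer(radiiRes, sin(angles))

  vals <- array(0, c(length(radiiRes), g@nAngles, length(fr)))
  for (z in seq_along(fr)) {
    gr <- radialGradient(fr[[z]], g@center)
    if (invert) gr <- -gr
    if (f > 1) gr <- resizeBicubic(gr, f)
    pm <- bilinearSample(gr, xs, ys)
    rng <- range(pm)
    if (rng[2L] - rng[1L] < 1e-12) {
      warning("frame ", z, " has no gradient contrast; emitting flat 0.5")
      pm[] <- 0.5
    } else {
      pm <- (pm - rng[1L]) / (rng[2L] - rng[1L])
    }
    vals[, , z] <- pm
  }
  new("FeatureVolume", values = vals, radiiRes = radiiRes, angles = angles,
      scale = c(sx, sy), grid = g)
}

#' Map a detected surface back to Cartesian contours
#'
#' Inverts the polar transform: each surface row index becomes a radius
#' of the resized image, divided by the realised resize scale to return
#' to original-image pixels; vertices are placed at
#' \code{centre + radius * (cos, sin)} per angle and the enclosed area
#' is computed with the shoelace formula.
#'
#' @param surface a [DPSurface-class] detected on \code{volume}.
#' @param volume the [FeatureVolume-class] the surface was detected in
#'   (supplies the grid geometry).
#' @param pixelSize mm per pixel; physical areas are
#'   \code{areaPx2 * pixelSize^2}.
#' @return a [ContourSet-class] with one closed contour per frame.
#' @export
surfaceToContours <- function(surface, volume, pixelSize = 1) {
  h <- surfaceHeights(surface)
  g <- volume@grid
  s <- mean(volume@scale)
  N <- nrow(h)
  P <- ncol(h)
  if (N != length(volume@angles))
    stop("surface angle count does not match the feature volume")
  ca <- cos(volume@angles)
  sa <- sin(volume@angles)
  pts <- vector("list", P)
  areaPx2 <- numeric(P)
  for (z in seq_len(P)) {
    r <- volume@radiiRes[h[, z]] / s
    x <- g@center[1L] + r * ca
    y <- g@center[2L] + r * sa
    pts[[z]] <- cbind(x = x, y = y)
    areaPx2[z] <- shoelaceArea(x, y)
  }
  new("ContourSet", points = pts, areaPx2 = areaPx2,
      areaMm2 = areaPx2 * pixelSize^2, pixelSize = as.numeric(pixelSize))
}

# coerce the accepted sequence representations to a list of matrices
asFrameList <- function(images) {
  if (is(images, "PhantomSequence")) images <- frames(images)
  if (is.array(images) && length(dim(images)) == 3L) {
    d <- dim(images)
    images <- lapply(seq_len(d[3L]), function(z) matrix(images[, , z],
                                                        d[1L], d[2L]))
  }
  if (is.matrix(images)) images <- list(images)
  if (!is.list(images) || !length(images))
    stop("images must be a 3D array, a matrix, or a non-empty list")
  dims <- vapply(images, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("all frames must have identical dimensions")
  lapply(images, as.matrix)
}
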