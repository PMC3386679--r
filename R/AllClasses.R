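#' @import methods
NULL

#' Polar resampling grid
#'
#' Describes how an image is resampled around a centre into an
#' angle-by-radius feature matrix.  Rows of the resulting matrix are
#' radii (one row per pixel of the \emph{resized} image, so a resize
#' factor greater than 1 refines the radial quantisation), columns are
#' angles on the half-open interval \eqn{[0, 2\pi)} measured
#' counter-clockwise from the +x axis.
#'
#' @slot center numeric(2), centre \code{c(x, y)} in 1-based pixel
#'   coordinates (x = column, y = row).
#' @slot nAngles integer, number of angular samples (columns).
#' @slot rMin,rMax numeric, radial search range in pixels of the
#'   original image.
#' @slot resizeFactor numeric, bilinear upsampling factor applied to the
#'   gradient image before polar sampling.
#'
#' @seealso [polarGrid()], [buildFeatureVolume()]
#' @export
setClass("PolarGrid",
  representation(center = "numeric", nAngles = "integer",
                 rMin = "numeric", rMax = "numeric",
                 resizeFactor = "numeric"))

setValidity("PolarGrid", function(object) {
  msg <- character()
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    msg <- c(msg, "center must be two finite numbers c(x, y)")
  if (object@nAngles < 8L)
    msg <- c(msg, "nAngles must be at least 8")
  if (!is.finite(object@rMin) || object@rMin < 0)
    msg <- c(msg, "rMin must be non-negative")
  if (!is.na(object@rMax) &&
      (!is.finite(object@rMax) || object@rMax <= object@rMin))
    msg <- c(msg, "rMax must exceed rMin")  # NA = resolve from image later
  if (!is.finite(object@resizeFactor) || object@resizeFactor < 1)
    msg <- c(msg, "resizeFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Volumetric feature matrix for the 3D dynamic programme
#'
#' A normalised 3D cost array with dimensions radius (y) by angle (x) by
#' frame (z), together with the geometry needed to map detected rows
#' back to Cartesian coordinates.  Low values mark likely boundary
#' positions; each frame is min-max rescaled to [0, 1].
#'
#' @slot values 3D numeric array, M radii x N angles x P frames.
#' @slot radiiRes numeric(M), the radius of each row in pixels of the
#'   resized image.
#' @slot angles numeric(N), angular sample positions in radians.
#' @slot scale numeric(2), realised resize scale per axis
#'   \code{c(sx, sy)} (output pixels per input pixel).
#' @slot grid the [PolarGrid-class] the volume was built on.
#'
#' @export
setClass("FeatureVolume",
  representation(values = "array", radiiRes = "numeric",
                 angles = "numeric", scale = "numeric", grid = "PolarGrid"))

setValidity("FeatureVolume", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3D array")
  else {
    if (length(object@radiiRes) != d[1L])
      msg <- c(msg, "radiiRes length must match dim 1 of values")
    if (length(object@angles) != d[2L])
      msg <- c(msg, "angles length must match dim 2 of values")
  }
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  else if (min(object@values) < 0 || max(object@values) > 1)
    msg <- c(msg, "values must be normalised to [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Detected optimal surface
#'
#' The height field \code{y(x, z)} returned by the surface search: one
#' radial row index per (angle, frame) node, plus the total accumulated
#' cost of the tracing minima.
#'
#' @slot heights integer matrix, N angles x P frames; entries are row
#'   indices into the feature volume's radial axis.
#' @slot totalCost numeric, sum over angles of the per-angle terminal
#'   minima used for tracing.
#'
#' @export
setClass("DPSurface",
  representation(heights = "matrix", totalCost = "numeric"))

setValidity("DPSurface", function(object) {
  h <- object@heights
  if (!is.numeric(h) || any(h < 1) || any(h != round(h)))
    return("heights must be positive integer row indices")
  TRUE
})

#' Synthetic disc-phantom sequence
#'
#' An image stack of bright discs on a darker background with known
#' (analytic) radii and areas serving as the gold standard for accuracy
#' experiments, optionally with calibrated uniform noise added.
#'
#' @slot frames 3D numeric array, height x width x frames.
#' @slot trueRadii numeric, the simulated disc radius per frame (pixels).
#' @slot trueAreasPx2 numeric, analytic areas \eqn{\pi r^2} per frame.
#' @slot measuredSnrDb numeric, per-frame measured SNR in dB
#'   (\code{NA} for a noise-free sequence).
#' @slot nLevel numeric, the uniform noise amplitude used (\code{NA} if
#'   noise free).
#' @slot spec list of generation parameters (imageSize, fg, bg, radii,
#'   smoothSigma).
#'
#' @seealso [generatePhantom()], [addNoise()]
#' @export
setClass("PhantomSequence",
  representation(frames = "array", trueRadii = "numeric",
                 trueAreasPx2 = "numeric", measuredSnrDb = "numeric",
                 nLevel = "numeric", spec = "list"))

setValidity("PhantomSequence", function(object) {
  d <- dim(object@frames)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3D array (H x W x P)")
  else {
    p <- d[3L]
    if (length(object@trueRadii) != p || length(object@trueAreasPx2) != p ||
        length(object@measuredSnrDb) != p)
      msg <- c(msg, "one radius, area and SNR entry per frame required")
    else if (any(abs(object@trueAreasPx2 - pi * object@trueRadii^2) > 1e-8))
      msg <- c(msg, "trueAreasPx2 must equal pi * trueRadii^2")
  }
  if (length(msg)) msg else TRUE
})

#' Closed boundary contours with areas
#'
#' Per-frame closed polygons in Cartesian pixel coordinates, with areas
#' from the shoelace formula.  Physical areas apply the squared pixel
#' size.
#'
#' @slot points list of two-column matrices (x, y), one per frame,
#'   vertices ordered by angle; the polygon is closed implicitly.
#' @slot areaPx2 numeric, polygon area per frame in squared pixels.
#' @slot areaMm2 numeric, polygon area per frame in mm^2
#'   (\code{areaPx2 * pixelSize^2}).
#' @slot pixelSize numeric, mm per pixel.
#'
#' @export
setClass("ContourSet",
  representation(points = "list", areaPx2 = "numeric",
                 areaMm2 = "numeric", pixelSize = "numeric"))

setValidity("ContourSet", function(object) {
  msg <- character()
  if (length(object@points) != length(object@areaPx2) ||
      length(object@points) != length(object@areaMm2))
    msg <- c(msg, "one area per contour required")
  if (any(vapply(object@points, nrow, 0L) < 8L))
    msg <- c(msg, "each contour needs at least 8 vertices")
  if (any(object@areaPx2 <= 0))
    msg <- c(msg, "areas must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PolarGrid", function(object) {
  cat(sprintf(
    "PolarGrid: centre (%.2f, %.2f), %d angles, r in [%.1f, %.1f] px, resize %.2f\n",
    object@center[1L], object@center[2L], object@nAngles,
    object@rMin, object@rMax, object@resizeFactor))
})

setMethod("show", "FeatureVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureVolume: %d radii x %d angles x %d frames\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  radial range %.2f..%.2f resized px (scale %.3f, %.3f)\n",
              min(object@radiiRes), max(object@radiiRes),
              object@scale[1L], object@scale[2L]))
})

setMethod("show", "DPSurface", function(object) {
  d <- dim(object@heights)
  cat(sprintf("DPSurface: %d angles x %d frames, total cost %.4f\n",
              d[1L], d[2L], object@totalCost))
})

setMethod("show", "PhantomSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("PhantomSequence: %d frames of %dx%d, radii %s\n",
              d[3L], d[1L], d[2L],
              paste(object@trueRadii, collapse = ",")))
  if (all(is.na(object@measuredSnrDb))) {
    cat("  noise free\n")
  } else {
    cat(sprintf("  nLevel %.4f, mean SNR %.2f dB\n", object@nLevel,
                mean(object@measuredSnrDb)))
  }
})

setMethod("show", "ContourSet", function(object) {
  cat(sprintf("ContourSet: %d contours, areas %.1f..%.1f px^2 (pixel %.4g mm)\n",
              length(object@points), min(object@areaPx2),
              max(object@areaPx2), object@pixelSize))
})
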