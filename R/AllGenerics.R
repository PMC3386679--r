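#' Accessors for SurfaceDP containers
#'
#' Small accessor layer over the S4 containers: image frames and gold
#' standard of a [PhantomSequence-class], the height field and total
#' cost of a [DPSurface-class], the normalised values of a
#' [FeatureVolume-class] and the area table of a [ContourSet-class].
#'
#' @param object a SurfaceDP S4 object.
#' @return `frames` returns the H x W x P numeric array of images;
#'   `trueRadii`/`trueAreasPx2`/`snrDb` the per-frame gold standard and
#'   measured SNR; `surfaceHeights` the N x P integer matrix of radial
#'   row indices; `totalCost` a number; `featureValues` the M x N x P
#'   feature array; `areaTable` a data.frame with columns `frame`,
#'   `areaPx2`, `areaMm2`.
#' @name accessors
#' @examples
#' ph <- generatePhantom()
#' dim(frames(ph))
#' trueRadii(ph)
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("trueRadii", function(object) standardGeneric("trueRadii"))

#' @rdname accessors
#' @export
setGeneric("trueAreasPx2", function(object) standardGeneric("trueAreasPx2"))

#' @rdname accessors
#' @export
setGeneric("snrDb", function(object) standardGeneric("snrDb"))

#' @rdname accessors
#' @export
setGeneric("surfaceHeights", function(object) standardGeneric("surfaceHeights"))

#' @rdname accessors
#' @export
setGeneric("totalCost", function(object) standardGeneric("totalCost"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("areaTable", function(object) standardGeneric("areaTable"))

#' @rdname accessors
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))

#' @rdname accessors
setMethod("frames", "PhantomSequence", function(object) object@frames)

#' @rdname accessors
setMethod("trueRadii", "PhantomSequence", function(object) object@trueRadii)

#' @rdname accessors
setMethod("trueAreasPx2", "PhantomSequence",
          function(object) object@trueAreasPx2)

#' @rdname accessors
setMethod("snrDb", "PhantomSequence", function(object) object@measuredSnrDb)

#' @rdname accessors
setMethod("surfaceHeights", "DPSurface", function(object) object@heights)

#' @rdname accessors
setMethod("totalCost", "DPSurface", function(object) object@totalCost)

#' @rdname accessors
setMethod("featureValues", "FeatureVolume", function(object) object@values)

#' @rdname accessors
setMethod("areaTable", "ContourSet", function(object) {
  data.frame(frame = seq_along(object@areaPx2),
             areaPx2 = object@areaPx2,
             areaMm2 = object@areaMm2)
})

#' @rdname accessors
setMethod("contourPoints", "ContourSet", function(object) object@points)
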