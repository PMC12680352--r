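#' @include AllClasses.R
NULL

#' Accessors for LAFMkit containers
#'
#' \code{heights} returns the raw H x W x N height array of an [AFMStack-class];
#' \code{pixelSize} the pixel edge length in Angstrom; \code{nFrames} the stack
#' depth; \code{frameAt} one frame as a matrix; \code{stackCode} the provenance
#' code string.
#'
#' @param x an AFMStack or LAFMImage.
#' @param i frame index for \code{frameAt}.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases heights pixelSize nFrames frameAt stackCode
#' @examples
#' s <- AFMStack(matrix(1, 4, 4), pixelSize = 2)
#' nFrames(s)
#' pixelSize(s)
NULL

#' @rdname accessors
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameAt", function(x, i) standardGeneric("frameAt"))
#' @rdname accessors
#' @export
setGeneric("stackCode", function(x) standardGeneric("stackCode"))

#' @rdname accessors
setMethod("heights", "AFMStack", function(x) x@heights)
#' @rdname accessors
setMethod("pixelSize", "AFMStack", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "LAFMImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("nFrames", "AFMStack", function(x) dim(x@heights)[3L])
#' @rdname accessors
setMethod("frameAt", "AFMStack", function(x, i) x@heights[, , i])
#' @rdname accessors
setMethod("stackCode", "AFMStack", function(x) x@code)

#' Accessors for LAFMImage components
#'
#' @param x a [LAFMImage-class].
#' @return \code{probabilityMap} and \code{meanHeightMap} return matrices on
#'   the expanded grid; \code{lafmValues} their elementwise product (the final
#'   LAFM image).
#' @name lafm-accessors
#' @aliases probabilityMap meanHeightMap lafmValues
NULL

#' @rdname lafm-accessors
#' @export
setGeneric("probabilityMap", function(x) standardGeneric("probabilityMap"))
#' @rdname lafm-accessors
#' @export
setGeneric("meanHeightMap", function(x) standardGeneric("meanHeightMap"))
#' @rdname lafm-accessors
#' @export
setGeneric("lafmValues", function(x) standardGeneric("lafmValues"))

#' @rdname lafm-accessors
setMethod("probabilityMap", "LAFMImage", function(x) x@probabilityMap)
#' @rdname lafm-accessors
setMethod("meanHeightMap", "LAFMImage", function(x) x@meanHeightMap)
#' @rdname lafm-accessors
setMethod("lafmValues", "LAFMImage", function(x) x@values)

setMethod("show", "AtomSet", function(object) {
  cat("AtomSet with", nrow(object@coords), "atoms, backgroundZ =",
      object@backgroundZ, "A\n")
  if (nrow(object@coords)) {
    above <- sum(object@coords[, 3] + object@radii > object@backgroundZ)
    cat("  atoms protruding above background:", above, "\n")
  }
})

setMethod("show", "TipModel", function(object) {
  cat(sprintf("TipModel: cone with spherical apex, R = %g A, theta = %g deg\n",
              object@radius, object@thetaDeg))
})

setMethod("show", "ScanGrid", function(object) {
  ax <- gridAxes(object)
  cat(sprintf("ScanGrid: x [%g, %g] A, y [%g, %g] A, P = %g A/px (%d x %d px)\n",
              object@xMin, object@xMax, object@yMin, object@yMax,
              object@pixelSize, length(ax$y), length(ax$x)))
})

setMethod("show", "AFMStack", function(object) {
  d <- dim(object@heights)
  cat(sprintf("AFMStack: %d frames of %d x %d px, P = %g A/px", d[3], d[1],
              d[2], object@pixelSize))
  if (!is.na(object@code)) cat(", code", object@code)
  cat(sprintf("\n  height range [0, %.3g] A\n", max(object@heights)))
})

setMethod("show", "LAFMImage", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "LAFMImage: %d x %d px at %g A/px, max %.3g A (expansion %d, sigma %g)\n",
    d[1], d[2], object@pixelSize, max(object@values),
    object@params$expansionFactor, object@params$kernelSigma))
})
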