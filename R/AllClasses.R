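#' @import methods
NULL

#' AtomSet: scannable atoms above a membrane plane
#'
#' A set of 3D atomic positions with per-atom van der Waals radii and the
#' height of the membrane plane (\code{backgroundZ}) that acts as the zero
#' level of simulated topographs.  Atoms whose sphere top (\code{z + r}) lies
#' at or below the background contribute nothing to a rendered image.
#'
#' @slot coords numeric matrix, n x 3, columns x/y/z in Angstrom.
#' @slot radii numeric vector of length n, van der Waals radii in Angstrom,
#'   all strictly positive.
#' @slot backgroundZ single numeric, membrane plane height in Angstrom.
#'
#' @seealso [AtomSet()] for the constructor, [renderFrame()].
#' @exportClass AtomSet
setClass("AtomSet",
  representation(coords = "matrix", radii = "numeric", backgroundZ = "numeric"),
  prototype(coords = matrix(numeric(0), 0, 3), radii = numeric(0), backgroundZ = 0)
)

setValidity("AtomSet", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have 3 columns (x, y, z)")
  if (nrow(object@coords) != length(object@radii))
    msg <- c(msg, "length(radii) must equal nrow(coords)")
  if (length(object@radii) && any(!is.finite(object@radii) | object@radii <= 0))
    msg <- c(msg, "all radii must be finite and > 0")
  if (length(object@backgroundZ) != 1L || !is.finite(object@backgroundZ))
    msg <- c(msg, "backgroundZ must be a single finite numeric")
  if (length(msg)) msg else TRUE
})

#' Construct an AtomSet
#'
#' @param coords n x 3 numeric matrix of atomic positions (Angstrom).
#' @param radii van der Waals radii (Angstrom); recycled if length 1.
#' @param backgroundZ membrane plane height (Angstrom); default 0.
#' @return An [AtomSet-class] object.
#' @examples
#' AtomSet(matrix(c(0, 0, 5), 1, 3), radii = 2)
#' @export
AtomSet <- function(coords, radii, backgroundZ = 0) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(radii) == 1L) radii <- rep(as.numeric(radii), nrow(coords))
  new("AtomSet", coords = coords, radii = as.numeric(radii),
      backgroundZ = as.numeric(backgroundZ))
}

#' TipModel: cone with spherical apex
#'
#' Geometry of the scanning probe: a cone of half-angle \code{thetaDeg}
#' terminated by a spherical apex of radius \code{radius}.  The default
#' half-angle of 18 degrees matches typical experimental AFM tips.
#'
#' @slot radius apex sphere radius R, Angstrom, > 0.
#' @slot thetaDeg cone half-angle in degrees, in (0, 90).
#' @exportClass TipModel
setClass("TipModel",
  representation(radius = "numeric", thetaDeg = "numeric"),
  prototype(radius = 20, thetaDeg = 18)
)

setValidity("TipModel", function(object) {
  msg <- character(0)
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    msg <- c(msg, "radius must be a single positive number")
  if (length(object@thetaDeg) != 1L || !is.finite(object@thetaDeg) ||
      object@thetaDeg <= 0 || object@thetaDeg >= 90)
    msg <- c(msg, "thetaDeg must lie strictly between 0 and 90 degrees")
  if (length(msg)) msg else TRUE
})

#' @param radius apex sphere radius (Angstrom).
#' @param thetaDeg cone half-angle (degrees), default 18.
#' @return A [TipModel-class] object.
#' @rdname TipModel-class
#' @examples
#' TipModel(radius = 20)
#' @export
TipModel <- function(radius, thetaDeg = 18) {
  new("TipModel", radius = as.numeric(radius), thetaDeg = as.numeric(thetaDeg))
}

#' ScanGrid: uniform raster over a rectangular scan area
#'
#' Pixel centers sit at \code{xMin + (i + 0.5) * pixelSize} (half-open
#' convention), so refining \code{pixelSize} by an integer factor nests the
#' coarser grid inside the finer one.
#'
#' @slot xMin,xMax,yMin,yMax scan boundaries, Angstrom.
#' @slot pixelSize pixel edge length P, Angstrom per pixel, > 0.
#' @exportClass ScanGrid
setClass("ScanGrid",
  representation(xMin = "numeric", xMax = "numeric",
                 yMin = "numeric", yMax = "numeric", pixelSize = "numeric"))

setValidity("ScanGrid", function(object) {
  msg <- character(0)
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@xMax - object@xMin < object@pixelSize ||
      object@yMax - object@yMin < object@pixelSize)
    msg <- c(msg, "scan extents must cover at least one pixel")
  if (length(msg)) msg else TRUE
})

#' @param xMin,xMax,yMin,yMax scan boundaries (Angstrom).
#' @param pixelSize pixel size (Angstrom per pixel).
#' @return A [ScanGrid-class] object.
#' @rdname ScanGrid-class
#' @examples
#' ScanGrid(-32, 32, -32, 32, pixelSize = 4)
#' @export
ScanGrid <- function(xMin, xMax, yMin, yMax, pixelSize) {
  new("ScanGrid", xMin = as.numeric(xMin), xMax = as.numeric(xMax),
      yMin = as.numeric(yMin), yMax = as.numeric(yMax),
      pixelSize = as.numeric(pixelSize))
}

## pixel-center coordinate vectors of a grid (x runs over columns, y over rows)
gridAxes <- function(grid) {
  nx <- floor((grid@xMax - grid@xMin) / grid@pixelSize)
  ny <- floor((grid@yMax - grid@yMin) / grid@pixelSize)
  list(x = grid@xMin + (seq_len(nx) - 0.5) * grid@pixelSize,
       y = grid@yMin + (seq_len(ny) - 0.5) * grid@pixelSize)
}

#' AFMStack: a stack of simulated or measured AFM topographs
#'
#' Heights are stored as an H x W x N array in Angstrom above the membrane
#' background (all values >= 0).  The stack carries its pixel size and a
#' provenance code such as \code{"AC-20-4"} (alignment, membrane side, tip
#' radius, pixel size); see [parseStackCode()].
#'
#' @slot heights numeric array, H x W x N, >= 0.
#' @slot pixelSize Angstrom per pixel.
#' @slot code character stack code (may be \code{NA_character_}).
#' @slot meta list of free-form metadata (tip radius, theta, seed, provenance).
#' @exportClass AFMStack
setClass("AFMStack",
  representation(heights = "array", pixelSize = "numeric",
                 code = "character", meta = "list"),
  prototype(code = NA_character_, meta = list())
)

setValidity("AFMStack", function(object) {
  msg <- character(0)
  d <- dim(object@heights)
  if (length(d) != 3L) msg <- c(msg, "heights must be an H x W x N array")
  if (any(!is.finite(object@heights))) msg <- c(msg, "heights must be finite")
  else if (any(object@heights < 0)) msg <- c(msg, "heights must be >= 0")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an AFMStack
#'
#' @param heights H x W x N array, or a list of equally sized matrices, or a
#'   single matrix (treated as a depth-1 stack).  Angstrom above background.
#' @param pixelSize Angstrom per pixel.
#' @param code optional stack code string (e.g. "AC-20-4").
#' @param meta optional metadata list.
#' @return An [AFMStack-class] object.
#' @examples
#' AFMStack(matrix(0, 8, 8), pixelSize = 4)
#' @export
AFMStack <- function(heights, pixelSize, code = NA_character_, meta = list()) {
  if (is.list(heights)) {
    d <- dim(heights[[1]])
    if (!all(vapply(heights, function(m) identical(dim(m), d), logical(1))))
      stop("all frames must have identical dimensions")
    heights <- array(unlist(heights, use.names = FALSE), c(d, length(heights)))
  } else if (is.matrix(heights)) {
    heights <- array(heights, c(dim(heights), 1L))
  }
  storage.mode(heights) <- "double"
  new("AFMStack", heights = heights, pixelSize = as.numeric(pixelSize),
      code = as.character(code), meta = meta)
}

#' Subset the frames of a stack
#'
#' @param x an [AFMStack-class].
#' @param i frame indices to keep.
#' @return An [AFMStack-class] with the selected frames, metadata preserved.
#' @examples
#' s <- AFMStack(array(1, c(4, 4, 6)), pixelSize = 2)
#' nFrames(subsetFrames(s, 1:3))
#' @export
subsetFrames <- function(x, i) {
  stopifnot(is(x, "AFMStack"))
  AFMStack(x@heights[, , i, drop = FALSE], pixelSize = x@pixelSize,
           code = x@code, meta = x@meta)
}

#' Concatenate AFM stacks scanned on a common grid
#'
#' @param ... two or more [AFMStack-class] objects with identical frame
#'   dimensions and pixel size.
#' @param code optional code for the combined stack.
#' @return An [AFMStack-class] containing all frames in argument order.
#' @export
bindStacks <- function(..., code = NA_character_) {
  stacks <- list(...)
  stopifnot(length(stacks) >= 2)
  d <- dim(stacks[[1]]@heights)[1:2]
  ps <- stacks[[1]]@pixelSize
  for (s in stacks) {
    stopifnot(is(s, "AFMStack"), identical(dim(s@heights)[1:2], d),
              isTRUE(all.equal(s@pixelSize, ps)))
  }
  h <- array(unlist(lapply(stacks, slot, "heights"), use.names = FALSE),
             c(d, sum(vapply(stacks, nFrames, integer(1)))))
  AFMStack(h, pixelSize = ps, code = code)
}

#' LAFMImage: localization AFM reconstruction
#'
#' The composed LAFM image is the elementwise product of a cumulative peaking
#' probability map (in [0, 1]) and the per-pixel mean real-space height map
#' (Angstrom), both on the expanded grid.
#'
#' @slot values probability-weighted height image (Angstrom scale).
#' @slot probabilityMap per-pixel peaking probability in [0, 1].
#' @slot meanHeightMap per-pixel mean height (Angstrom).
#' @slot pixelSize expanded-grid pixel size, Angstrom per pixel.
#' @slot params the [lafmParams()] list used for the reconstruction.
#' @exportClass LAFMImage
setClass("LAFMImage",
  representation(values = "matrix", probabilityMap = "matrix",
                 meanHeightMap = "matrix", pixelSize = "numeric",
                 params = "list"))

setValidity("LAFMImage", function(object) {
  msg <- character(0)
  if (!identical(dim(object@values), dim(object@probabilityMap)) ||
      !identical(dim(object@values), dim(object@meanHeightMap)))
    msg <- c(msg, "values, probabilityMap and meanHeightMap must share dimensions")
  if (any(object@probabilityMap < -1e-12 | object@probabilityMap > 1 + 1e-12))
    msg <- c(msg, "probabilityMap must lie in [0, 1]")
  if (max(abs(object@values - object@probabilityMap * object@meanHeightMap)) > 1e-9)
    msg <- c(msg, "values must equal probabilityMap * meanHeightMap")
  if (length(msg)) msg else TRUE
})
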