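## Simulated AFM rendering: grayscale dilation of van der Waals spheres by a
## cone-with-spherical-apex tip, sampled on a uniform pixel-center grid.

#' Tip-sample contact height for a single atom
#'
#' Closed-form height of the lowest point of a cone-with-spherical-apex tip
#' when it first touches a hard sphere of radius \code{r} centred at height
#' \code{z}, as a function of the lateral distance \code{d} between the tip
#' axis and the atom centre.  Contact with the apex sphere applies while
#' \code{d <= (R + r) * cos(theta)}; beyond that the cone flank makes contact.
#' The two branches join continuously:
#' \deqn{h(d) = z + \sqrt{(R+r)^2 - d^2} - R, \quad d \le (R+r)\cos\theta}
#' \deqn{h(d) = z + (R+r)/\sin\theta - R - d\cot\theta, \quad d > (R+r)\cos\theta}
#' At \code{d = 0} this reduces to \code{z + r} for any tip radius: the tip
#' bottom rests on the sphere top.  Far from the atom the value goes negative;
#' image rendering clips at the background level.
#'
#' @param z atom centre height (Angstrom); vectorized.
#' @param r atom van der Waals radius (Angstrom); vectorized.
#' @param tip a [TipModel-class].
#' @param d lateral distance(s) from the tip axis to the atom centre,
#'   Angstrom, >= 0.
#' @return Contact height(s) of the tip's lowest point, Angstrom (unclipped).
#' @examples
#' contactHeight(z = 5, r = 2, tip = TipModel(20), d = 0)   # 7
#' @export
contactHeight <- function(z, r, tip, d) {
  stopifnot(is(tip, "TipModel"), all(d >= 0))
  R <- tip@radius
  theta <- tip@thetaDeg * pi / 180
  n <- max(length(z), length(r), length(d))
  z <- rep_len(z, n); r <- rep_len(r, n); d <- rep_len(d, n)
  Rr <- R + r
  sphere <- d <= Rr * cos(theta)
  h <- numeric(n)
  h[sphere] <- z[sphere] + sqrt(Rr[sphere]^2 - d[sphere]^2) - R
  h[!sphere] <- z[!sphere] + Rr[!sphere] / sin(theta) - R -
    d[!sphere] / tan(theta)
  h
}

#' Render one simulated AFM frame
#'
#' Scans the tip across every pixel centre of the grid and records the height
#' at which it contacts the highest atom sphere, relative to the membrane
#' background; pixels with no contact above the background are 0.  Atoms whose
#' sphere top lies at or below the background are skipped.
#'
#' @param atoms an [AtomSet-class].
#' @param tip a [TipModel-class].
#' @param grid a [ScanGrid-class].
#' @return H x W numeric matrix of heights (Angstrom above background, >= 0).
#'   Rows index y, columns x.
#' @seealso [renderStack()], [contactHeight()]
#' @export
renderFrame <- function(atoms, tip, grid) {
  stopifnot(is(atoms, "AtomSet"), is(tip, "TipModel"), is(grid, "ScanGrid"))
  ax <- gridAxes(grid)
  H <- length(ax$y); W <- length(ax$x)
  img <- matrix(0, H, W)
  if (!nrow(atoms@coords)) return(img)
  bg <- atoms@backgroundZ
  keep <- atoms@coords[, 3] + atoms@radii > bg
  if (!any(keep)) return(img)
  xyz <- atoms@coords[keep, , drop = FALSE]
  rad <- atoms@radii[keep]
  theta <- tip@thetaDeg * pi / 180
  R <- tip@radius
  for (a in seq_len(nrow(xyz))) {
    dx <- ax$x - xyz[a, 1]
    dy <- ax$y - xyz[a, 2]
    d <- sqrt(outer(dy^2, dx^2, `+`))
    Rr <- R + rad[a]
    z <- xyz[a, 3]
    h <- z + Rr / sin(theta) - R - d / tan(theta)
    sph <- d <= Rr * cos(theta)
    h[sph] <- z + sqrt(Rr^2 - d[sph]^2) - R
    img <- pmax(img, h - bg)
  }
  img
}

#' Render a stack of simulated AFM frames
#'
#' Applies [renderFrame()] to each atom set in sequence over a fixed grid and
#' fixed tip, returning an [AFMStack-class] with the given provenance code.
#'
#' @param frames list of [AtomSet-class] objects (e.g. from
#'   [generateAtomFrames()]).
#' @param tip a [TipModel-class].
#' @param grid a [ScanGrid-class].
#' @param code optional stack code string; see [formatStackCode()].
#' @return An [AFMStack-class].
#' @examples
#' atoms <- AtomSet(matrix(c(0, 0, 5), 1, 3), radii = 2)
#' grid <- ScanGrid(-16, 16, -16, 16, pixelSize = 4)
#' s <- renderStack(list(atoms), TipModel(20), grid)
#' max(heights(s))
#' @export
renderStack <- function(frames, tip, grid, code = NA_character_) {
  stopifnot(length(frames) >= 1)
  imgs <- lapply(frames, renderFrame, tip = tip, grid = grid)
  AFMStack(imgs, pixelSize = grid@pixelSize, code = code,
           meta = list(tipRadiusA = tip@radius, thetaDeg = tip@thetaDeg))
}

#' Orient an atom set so the requested membrane side faces +Z
#'
#' The cytoplasmic side (\code{"C"}) is the identity.  For the periplasmic
#' side (\code{"P"}) the structure is flipped 180 degrees about the X axis
#' (\code{(x, y, z) -> (x, -y, -z)}) so that features protruding below the
#' lower leaflet come to face +Z, and the background is recomputed as the
#' flipped lower-leaflet plane.  Applying the flip twice restores the original
#' coordinates.
#'
#' @param atoms an [AtomSet-class]; its \code{backgroundZ} is taken to be the
#'   upper-leaflet plane.
#' @param side \code{"C"} or \code{"P"}.
#' @param lowerLeafletZ height of the lower leaflet plane (Angstrom); defaults
#'   to \code{-backgroundZ} (membrane symmetric about z = 0).
#' @return An [AtomSet-class] in the oriented frame.
#' @export
orientSide <- function(atoms, side = c("C", "P"),
                       lowerLeafletZ = -atoms@backgroundZ) {
  side <- match.arg(side)
  if (side == "C") return(atoms)
  co <- atoms@coords
  co[, 2] <- -co[, 2]
  co[, 3] <- -co[, 3]
  AtomSet(co, atoms@radii, backgroundZ = -lowerLeafletZ)
}

#' Brute-force tip-lowering oracle for one pixel
#'
#' Numerically lowers a densely sampled tip surface onto the atom spheres and
#' reports the tip-bottom height at first contact, independently of the
#' closed-form dilation in [contactHeight()]/[renderFrame()].  The tip is
#' rotationally symmetric, so for each atom the first contact lies in the
#' vertical plane through the tip axis and the atom centre; the oracle
#' samples the tip height profile densely along that plane and refines the
#' sampling window around the contact point until converged.  Orders of
#' magnitude slower than the closed form; exists for verification only.
#'
#' @param atoms an [AtomSet-class].
#' @param tip a [TipModel-class].
#' @param px,py pixel-centre position of the tip axis (Angstrom).
#' @param nSamples tip-profile samples per refinement round (three rounds,
#'   so the total sampled surface points per atom is \code{3 * nSamples}).
#' @return Tip-bottom contact height (Angstrom, unclipped), or \code{-Inf}
#'   when no atom is touched.
#' @keywords internal
#' @export
tipLowerOracle <- function(atoms, tip, px, py, nSamples = 4001) {
  R <- tip@radius
  theta <- tip@thetaDeg * pi / 180
  ## tip surface height profile above its lowest point, at lateral offset s
  profile <- function(s)
    ifelse(s <= R * cos(theta),
           R - sqrt(pmax(R^2 - s^2, 0)),
           R * (1 - sin(theta)) + (s - R * cos(theta)) / tan(theta))
  xyz <- atoms@coords; rad <- atoms@radii
  best <- -Inf
  for (a in seq_len(nrow(xyz))) {
    d <- sqrt((xyz[a, 1] - px)^2 + (xyz[a, 2] - py)^2)
    lo <- max(0, d - rad[a]); hi <- d + rad[a]
    for (round in 1:3) {
      s <- seq(lo, hi, length.out = nSamples)
      l <- abs(d - s)                       # lateral distance to atom centre
      ok <- l <= rad[a]
      if (!any(ok)) break
      h <- xyz[a, 3] + sqrt(rad[a]^2 - l[ok]^2) - profile(s[ok])
      iBest <- which.max(h)
      best <- max(best, h[iBest])
      sStar <- s[ok][iBest]
      step <- (hi - lo) / (nSamples - 1)
      lo <- max(0, sStar - 2 * step); hi <- sStar + 2 * step
    }
  }
  best
}
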