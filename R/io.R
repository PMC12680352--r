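## File formats and provenance codes: stack code strings, float32 multi-page
## TIFF stacks with JSON sidecars, PDB atom input via bio3d, and the bundled
## element -> van der Waals radius table.

#' Parse a stack code
#'
#' Stack codes record alignment status (A = aligned, U = unaligned), membrane
#' side (C = cytoplasmic, P = periplasmic), tip radius in Angstrom and scan
#' resolution in Angstrom per pixel, joined by dashes: \code{"AC-20-2"} is an
#' aligned cytoplasmic stack scanned with a 20 A tip at 2 A/px.  Both the
#' plain hyphen and the typographic en dash are accepted; formatting uses the
#' en dash, so \code{formatStackCode(parseStackCode(x))} reproduces printed
#' codes exactly.
#'
#' @param text a code string such as \code{"AC-20-2"}.
#' @return list with fields \code{alignment}, \code{side}, \code{tipRadius},
#'   \code{pixelSize}.
#' @examples
#' parseStackCode("AC-20-2")
#' @export
parseStackCode <- function(text) {
  norm <- gsub("\u2013|\u2014", "-", text)
  m <- regmatches(norm, regexec("^([A-Z])([A-Z])-([0-9]+)-([0-9]+)$", norm))[[1]]
  if (!length(m)) stop("malformed stack code: ", text,
                       " (expected [AU][CP]-<tip>-<pixel>)")
  if (!m[2] %in% c("A", "U"))
    stop("invalid alignment flag '", m[2], "' in stack code ", text)
  if (!m[3] %in% c("C", "P"))
    stop("invalid membrane side '", m[3], "' in stack code ", text)
  list(alignment = m[2], side = m[3], tipRadius = as.numeric(m[4]),
       pixelSize = as.numeric(m[5]))
}

#' Format a stack code
#'
#' Exact inverse of [parseStackCode()]; fields are joined with the
#' typographic en dash used in print.
#'
#' @param code list with alignment, side, tipRadius, pixelSize.
#' @return The code string.
#' @export
formatStackCode <- function(code) {
  stopifnot(code$alignment %in% c("A", "U"), code$side %in% c("C", "P"))
  paste0(code$alignment, code$side, "\u2013", format(code$tipRadius),
         "\u2013", format(code$pixelSize))
}

#' Van der Waals radii by element
#'
#' A bundled element-to-radius table with values typical of biomolecular
#' force fields, used when atom input carries no explicit radius column.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdwRadii <- function() {
  c(H = 1.20, C = 2.00, N = 1.85, O = 1.70, S = 2.00, P = 2.15,
    F = 1.70, CL = 2.27, BR = 2.22, I = 2.36, "NA" = 1.36, K = 1.76,
    MG = 1.19, CA = 1.37, ZN = 1.09, FE = 0.65, MN = 1.18, SE = 2.10)
}

#' Read an AtomSet (or frame sequence) from a PDB file
#'
#' Coordinates come from ATOM/HETATM records (multi-model files yield one
#' frame per MODEL); radii come from the bundled element table, with unknown
#' elements falling back to a default radius with a warning.  The membrane
#' plane defaults to z = 0 unless phosphorus atoms are present, in which case
#' the mean z of the upper-leaflet phosphorus atoms (those above the overall
#' phosphorus mean) defines the background.
#'
#' @param path PDB file path.
#' @param radiusTable named radius vector, see [vdwRadii()].
#' @param defaultRadius fallback radius for unknown elements (Angstrom).
#' @return A single [AtomSet-class], or a list of them for multi-model files.
#' @export
readPDBAtoms <- function(path, radiusTable = vdwRadii(), defaultRadius = 1.7) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  if (!nrow(atoms)) stop("no ATOM records in ", path)
  elem <- toupper(sub("^\\s+|\\s+$", "", atoms$elesy))
  bad <- !elem %in% names(radiusTable)
  if (any(bad)) {
    warning("unknown element(s) ", paste(unique(elem[bad]), collapse = ", "),
            ": using default radius ", defaultRadius, " A")
  }
  radii <- ifelse(bad, defaultRadius, radiusTable[elem])
  isP <- elem == "P"
  nModels <- dim(pdb$xyz)[1]
  makeFrame <- function(xyzRow) {
    co <- matrix(xyzRow, ncol = 3, byrow = TRUE)
    bg <- 0
    if (any(isP)) {
      pz <- co[isP, 3]
      upper <- pz >= mean(pz)
      bg <- mean(pz[upper])
    }
    AtomSet(co, radii, backgroundZ = bg)
  }
  if (is.null(nModels) || nModels <= 1) return(makeFrame(as.numeric(pdb$xyz)))
  lapply(seq_len(nModels), function(i) makeFrame(pdb$xyz[i, ]))
}

#' Write atom frames as a multi-model PDB
#'
#' @param frames list of [AtomSet-class] objects (equal atom counts).
#' @param path output path.
#' @param element element symbol written for every atom (radii are not
#'   representable in PDB; they are re-derived from the element on reading).
#' @return \code{path}, invisibly.
#' @export
writePDBFrames <- function(frames, path, element = "C") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    co <- frames[[i]]@coords
    lines <- sprintf(
      "ATOM  %5d  %-3s DUM A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(co)), element, 1L, co[, 1], co[, 2], co[, 3], element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- float32 multi-page TIFF ----------------------------------------------
## The CRAN tiff package reads float TIFFs but can only write images scaled
## to [0, 1]; heights in Angstrom need genuine 32-bit float samples, so the
## writer below emits a minimal uncompressed little-endian float32 TIFF (one
## strip per page) that tiff::readTIFF, ImageJ and tifffile all read.

sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write an AFM stack as float32 TIFF plus JSON sidecar
#'
#' Heights are stored as one 32-bit float page per frame (row-major,
#' Angstrom); pixel size, stack code and other metadata go to an adjacent
#' \code{.json} sidecar.  Stacks containing NaN are rejected.  Reading the
#' file back yields bit-identical float32 arrays.
#'
#' @param stack an [AFMStack-class].
#' @param path output TIFF path (sidecar written next to it).
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "AFMStack"))
  if (any(is.na(stack@heights))) stop("stack contains NaN; refusing to write")
  ## TIFF pages are row-major: transpose each frame so readers agree on
  ## orientation
  pages <- lapply(seq_len(nFrames(stack)), function(i) t(frameAt(stack, i)))
  ## store column counts correctly: after transpose, nrow = W, ncol = H;
  ## writeFloatTIFF takes pages as written matrices whose *columns* vary
  ## slowest, so pass dims explicitly via attributes
  writeFloatTIFFStack(pages, dim(stack@heights)[1:2], path)
  meta <- c(list(code = stack@code, pixel_size_A = stack@pixelSize,
                 n_frames = nFrames(stack)), stack@meta)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

## pages: list of t(frame) matrices (so as.vector gives row-major pixel order)
writeFloatTIFFStack <- function(pages, hw, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  H <- hw[1]; W <- hw[2]
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)
  wr2(42L)
  nPages <- length(pages)
  pageBytes <- H * W * 4L
  dataOffsets <- 8L + (seq_len(nPages) - 1L) * pageBytes
  ifdStart <- 8L + nPages * pageBytes
  nTags <- 10L
  ifdSize <- 2L + nTags * 12L + 4L
  wr4(ifdStart)
  for (p in pages)
    writeBin(as.numeric(p), con, size = 4, endian = "little")
  for (i in seq_len(nPages)) {
    tag <- function(id, type, count, value) {
      wr2(id); wr2(type); wr4(count); wr4(value)
    }
    wr2(nTags)
    tag(256L, 4L, 1L, W)
    tag(257L, 4L, 1L, H)
    tag(258L, 3L, 1L, 32L)
    tag(259L, 3L, 1L, 1L)
    tag(262L, 3L, 1L, 1L)
    tag(273L, 4L, 1L, dataOffsets[i])
    tag(277L, 3L, 1L, 1L)
    tag(278L, 4L, 1L, H)
    tag(279L, 4L, 1L, pageBytes)
    tag(339L, 3L, 1L, 3L)
    wr4(if (i < nPages) ifdStart + i * ifdSize else 0L)
  }
  invisible(path)
}

#' Read an AFM stack written by [writeStack()]
#'
#' Pages are read with \code{tiff::readTIFF}; metadata comes from the JSON
#' sidecar.  A missing sidecar falls back to defaults with a warning.
#' Explicit arguments override sidecar values (and say so), mirroring the
#' CLI-over-sidecar precedence rule.
#'
#' @param path TIFF path.
#' @param pixelSize optional override of the sidecar pixel size.
#' @param code optional override of the sidecar stack code.
#' @return An [AFMStack-class].
#' @export
readStack <- function(path, pixelSize = NULL, code = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p
  })
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("TIFF pages disagree in shape")
  sp <- sidecarPath(path)
  meta <- if (file.exists(sp)) {
    jsonlite::read_json(sp, simplifyVector = TRUE)
  } else {
    warning("no JSON sidecar next to ", path, "; assuming defaults")
    list(pixel_size_A = 1, code = NA)
  }
  ps <- meta$pixel_size_A
  if (!is.null(pixelSize)) {
    if (!is.null(ps) && !isTRUE(all.equal(ps, pixelSize)))
      message("pixelSize override (", pixelSize, ") takes precedence over sidecar (",
              ps, ")")
    ps <- pixelSize
  }
  cd <- meta$code
  if (!is.null(code)) {
    if (!is.null(cd) && !identical(cd, code))
      message("code override ('", code, "') takes precedence over sidecar ('",
              cd, "')")
    cd <- code
  }
  if (is.null(ps)) ps <- 1
  if (is.null(cd)) cd <- NA_character_
  extra <- meta[setdiff(names(meta), c("pixel_size_A", "code", "n_frames"))]
  AFMStack(pages, pixelSize = ps,
           code = if (is.na(cd) || is.character(cd)) cd else NA_character_,
           meta = as.list(extra))
}
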