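## Synthetic pseudo-protein generator: discrete conformational states built
## from rigid atom domains, per-frame thermal jitter, optional random-walk
## in-plane drift, and per-pixel Gaussian image noise, with ground truth.

#' Describe one conformational state of a pseudo-protein
#'
#' A conformer is a rigid arrangement of spherical-atom "domains"; each domain
#' is a Gaussian cloud of atoms around a centre.  Flexibility across
#' conformers is expressed by moving or adding domains (e.g. a mobile arm),
#' mimicking the loop rearrangements of flexible membrane proteins.
#'
#' @param conformerId integer label for the state.
#' @param domains list of domain descriptors, each a list with \code{center}
#'   (xyz, Angstrom), \code{nAtoms}, \code{spread} (sd of the atom cloud,
#'   Angstrom, >= 0) and \code{atomRadius} (Angstrom, > 0).
#' @param occupancy fraction of frames in this state, in [0, 1].
#' @return A \code{ConformerSpec} list.
#' @seealso [stackRecipe()], [generateAtomFrames()]
#' @export
conformerSpec <- function(conformerId, domains, occupancy) {
  for (d in domains) {
    stopifnot(length(d$center) == 3, d$nAtoms >= 1, d$spread >= 0,
              d$atomRadius > 0)
  }
  stopifnot(occupancy >= 0, occupancy <= 1)
  structure(list(conformerId = as.integer(conformerId), domains = domains,
                 occupancy = occupancy), class = "ConformerSpec")
}

#' Frame-to-frame motion model
#'
#' \code{jitterSigma} is the per-atom, per-frame isotropic Gaussian
#' displacement (thermal jitter).  Drift is a rigid in-plane random walk:
#' per-frame Gaussian steps in translation and rotation are accumulated, so
#' unaligned stacks carry temporally correlated misregistration, as in a
#' molecular-dynamics trajectory that slides and turns on the membrane.
#' \code{aligned = TRUE} forces both drift sigmas to 0.
#'
#' @param jitterSigma Angstrom, >= 0.
#' @param driftTranslationSigma Angstrom per frame step, >= 0.
#' @param driftRotationSigma degrees per frame step, >= 0.
#' @param aligned logical.
#' @return A \code{MotionModel} list.
#' @export
motionModel <- function(jitterSigma = 0.5, driftTranslationSigma = 0,
                        driftRotationSigma = 0, aligned = TRUE) {
  stopifnot(jitterSigma >= 0, driftTranslationSigma >= 0,
            driftRotationSigma >= 0)
  if (aligned) {
    driftTranslationSigma <- 0
    driftRotationSigma <- 0
  }
  structure(list(jitterSigma = jitterSigma,
                 driftTranslationSigma = driftTranslationSigma,
                 driftRotationSigma = driftRotationSigma,
                 aligned = aligned), class = "MotionModel")
}

#' Recipe for a synthetic stack
#'
#' @param conformers list of [conformerSpec()] objects; occupancies must sum
#'   to 1 (within 1e-9).
#' @param motion a [motionModel()].
#' @param nFrames number of frames, >= 1.
#' @param stateSequenceMode \code{"block"} (contiguous runs per conformer,
#'   realized counts match occupancies to +/- 1 frame) or \code{"markov"}
#'   (sticky Markov chain with stationary occupancies).
#' @param seed integer seed; the whole generation is deterministic given it.
#' @param markovStay probability of staying in the current state per step in
#'   markov mode.
#' @return A \code{StackRecipe} list.
#' @export
stackRecipe <- function(conformers, motion = motionModel(), nFrames = 100,
                        stateSequenceMode = c("block", "markov"), seed = 1,
                        markovStay = 0.98) {
  stateSequenceMode <- match.arg(stateSequenceMode)
  occ <- vapply(conformers, `[[`, numeric(1), "occupancy")
  if (abs(sum(occ) - 1) > 1e-9)
    stop("conformer occupancies must sum to 1 (got ", sum(occ), ")")
  stopifnot(nFrames >= 1)
  structure(list(conformers = conformers, motion = motion,
                 nFrames = as.integer(nFrames),
                 stateSequenceMode = stateSequenceMode,
                 seed = as.integer(seed), markovStay = markovStay),
            class = "StackRecipe")
}

## Largest-remainder apportionment of nFrames across occupancies: realized
## counts match occupancies to within one frame.
apportionFrames <- function(occ, nFrames) {
  raw <- occ * nFrames
  base <- floor(raw)
  rem <- nFrames - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## materialize the rigid atom template of one conformer (deterministic given
## the recipe seed; the template is fixed, only jitter varies per frame)
conformerTemplate <- function(conf, seed) {
  withPrivateSeed(seed * 1000003L + conf$conformerId, {
    pieces <- lapply(conf$domains, function(d) {
      pts <- matrix(rnorm(3 * d$nAtoms, sd = d$spread), ncol = 3)
      pts <- sweep(pts, 2, as.numeric(d$center), `+`)
      list(coords = pts, radii = rep(d$atomRadius, d$nAtoms))
    })
    list(coords = do.call(rbind, lapply(pieces, `[[`, "coords")),
         radii = unlist(lapply(pieces, `[[`, "radii")))
  })
}

#' Generate jittered, drifting atom frames with ground truth
#'
#' For each frame the selected conformer's rigid atom template is perturbed by
#' isotropic Gaussian jitter and then rigidly transformed by the accumulated
#' in-plane drift (rotation about the z axis through the origin, then
#' translation).  Deterministic given \code{recipe$seed}.
#'
#' @param recipe a [stackRecipe()].
#' @param backgroundZ membrane plane height passed through to every
#'   [AtomSet-class].
#' @return A list with \code{frames} (list of [AtomSet-class]) and
#'   \code{groundTruth}: \code{labels} (per-frame conformer id),
#'   \code{transforms} (data.frame rotationDeg/dxA/dyA, identity when
#'   aligned), \code{seed}.
#' @examples
#' cf <- conformerSpec(0, list(list(center = c(0, 0, 5), nAtoms = 5,
#'   spread = 2, atomRadius = 2)), occupancy = 1)
#' gen <- generateAtomFrames(stackRecipe(list(cf), nFrames = 3, seed = 7))
#' gen$groundTruth$labels
#' @export
generateAtomFrames <- function(recipe, backgroundZ = 0) {
  stopifnot(inherits(recipe, "StackRecipe"))
  occ <- vapply(recipe$conformers, `[[`, numeric(1), "occupancy")
  ids <- vapply(recipe$conformers, `[[`, integer(1), "conformerId")
  n <- recipe$nFrames
  templates <- lapply(recipe$conformers, conformerTemplate, seed = recipe$seed)
  withPrivateSeed(recipe$seed, {
    labels <- if (recipe$stateSequenceMode == "block") {
      rep(ids, times = apportionFrames(occ, n))
    } else {
      stay <- recipe$markovStay
      lab <- integer(n)
      state <- sample.int(length(ids), 1, prob = occ)
      for (t in seq_len(n)) {
        lab[t] <- ids[state]
        if (runif(1) > stay)
          state <- sample.int(length(ids), 1, prob = occ)
      }
      lab
    }
    m <- recipe$motion
    rot <- cumsum(rnorm(n, sd = m$driftRotationSigma))
    dx <- cumsum(rnorm(n, sd = m$driftTranslationSigma))
    dy <- cumsum(rnorm(n, sd = m$driftTranslationSigma))
    if (m$aligned) rot[] <- dx[] <- dy[] <- 0
    frames <- vector("list", n)
    for (t in seq_len(n)) {
      tpl <- templates[[match(labels[t], ids)]]
      co <- tpl$coords
      if (m$jitterSigma > 0)
        co <- co + matrix(rnorm(length(co), sd = m$jitterSigma), ncol = 3)
      if (!m$aligned) {
        a <- rot[t] * pi / 180
        x <- co[, 1] * cos(a) - co[, 2] * sin(a) + dx[t]
        y <- co[, 1] * sin(a) + co[, 2] * cos(a) + dy[t]
        co <- cbind(x, y, co[, 3])
      }
      frames[[t]] <- AtomSet(co, tpl$radii, backgroundZ = backgroundZ)
    }
    list(frames = frames,
         groundTruth = list(labels = labels,
                            transforms = data.frame(rotationDeg = rot,
                                                    dxA = dx, dyA = dy),
                            seed = recipe$seed))
  })
}

#' Add Gaussian pixel noise to a stack
#'
#' Independent Gaussian noise with standard deviation \code{level} times the
#' stack's maximum height is added to every pixel; negative results are
#' clipped at 0 since heights are non-negative.  \code{level = 0} returns the
#' stack unchanged.
#'
#' @param stack an [AFMStack-class].
#' @param level noise level as a fraction of the stack maximum, in [0, 1].
#' @param seed integer seed for reproducibility.
#' @return A noisy [AFMStack-class]; \code{meta$noiseLevel} records the level.
#' @export
addPixelNoise <- function(stack, level, seed = 1) {
  stopifnot(is(stack, "AFMStack"))
  if (level < 0 || level > 1)
    stop("noise level must lie in [0, 1]")
  if (level == 0) return(stack)
  sdA <- level * max(stack@heights)
  h <- withPrivateSeed(seed, {
    pmax(stack@heights + array(rnorm(length(stack@heights), sd = sdA),
                               dim(stack@heights)), 0)
  })
  meta <- stack@meta
  meta$noiseLevel <- level
  meta$noiseSeed <- seed
  AFMStack(h, pixelSize = stack@pixelSize, code = stack@code, meta = meta)
}

#' Ready-made pseudo-protein stack recipes
#'
#' Convenience fixtures used throughout the examples and tests.  The default
#' three-state recipe carries two major conformers of roughly equal occupancy
#' (0.45/0.45) plus one rare transient (0.10), echoing the major/transient
#' split seen in flexible membrane proteins; the conformers share two static
#' domains and differ in the placement of one mobile arm domain.
#'
#' @param nStates 1, 2 or 3 conformational states.
#' @param nFrames number of frames.
#' @param jitterSigma thermal jitter (Angstrom).
#' @param aligned if \code{FALSE}, adds slow random-walk drift
#'   (translation 0.15 A/step, rotation 0.4 deg/step).
#' @param seed integer seed.
#' @param armShift lateral separation between the mobile-arm positions of the
#'   major conformers (Angstrom); keep well above \code{jitterSigma} for
#'   separable states.
#' @param morphology gross structural class: \code{"cyto"} is the default
#'   large multi-domain protrusion with a mobile arm; \code{"peri"} is a
#'   compact low dome with a small mobile knob, emulating the much smaller
#'   protrusion on the opposite membrane face.  Mixing stacks of the two
#'   morphologies yields the merged-stack scenario for hierarchical
#'   clustering.
#' @return A [stackRecipe()].
#' @export
pseudoProteinRecipe <- function(nStates = 3, nFrames = 300, jitterSigma = 0.6,
                                aligned = TRUE, seed = 1, armShift = 12,
                                morphology = c("cyto", "peri")) {
  morphology <- match.arg(morphology)
  if (morphology == "cyto") {
    core <- list(center = c(0, 0, 8), nAtoms = 30, spread = 3.5, atomRadius = 2)
    knob <- list(center = c(9, 6, 6), nAtoms = 12, spread = 2, atomRadius = 2)
    armA <- list(center = c(-armShift / 2, -8, 7), nAtoms = 15, spread = 2.2,
                 atomRadius = 2)
    armB <- list(center = c(armShift / 2, -8, 7), nAtoms = 15, spread = 2.2,
                 atomRadius = 2)
    armC <- list(center = c(0, -2 - armShift / 2, 10), nAtoms = 15,
                 spread = 2.2, atomRadius = 2)
  } else {
    ## compact low dome: one core, a small mobile knob, no arm
    core <- list(center = c(0, 0, 4.5), nAtoms = 16, spread = 2.5,
                 atomRadius = 2)
    armA <- list(center = c(-armShift / 2, 4, 4), nAtoms = 6, spread = 1.5,
                 atomRadius = 2)
    armB <- list(center = c(armShift / 2, 4, 4), nAtoms = 6, spread = 1.5,
                 atomRadius = 2)
    armC <- list(center = c(0, 4 + armShift / 2, 5), nAtoms = 6, spread = 1.5,
                 atomRadius = 2)
    knob <- NULL
  }
  dom <- function(...) Filter(Negate(is.null), list(...))
  confs <- switch(as.character(nStates),
    "1" = list(conformerSpec(0, dom(core, knob, armA), 1)),
    "2" = list(conformerSpec(0, dom(core, knob, armA), 0.5),
               conformerSpec(1, dom(core, knob, armB), 0.5)),
    "3" = list(conformerSpec(0, dom(core, knob, armA), 0.45),
               conformerSpec(1, dom(core, knob, armB), 0.45),
               conformerSpec(2, dom(core, knob, armC), 0.10)),
    stop("nStates must be 1, 2 or 3"))
  motion <- motionModel(jitterSigma = jitterSigma,
                        driftTranslationSigma = if (aligned) 0 else 0.15,
                        driftRotationSigma = if (aligned) 0 else 0.4,
                        aligned = aligned)
  stackRecipe(confs, motion, nFrames = nFrames, seed = seed)
}

#' Render a pseudo-protein recipe into an AFM stack
#'
#' Generates atom frames from the recipe and scans them with the given tip
#' over a grid centred on the origin.
#'
#' @param recipe a [stackRecipe()].
#' @param tip a [TipModel-class].
#' @param pixelSize Angstrom per pixel.
#' @param extent half-width of the square scan area (Angstrom).
#' @param side membrane side letter for the stack code.
#' @return list with \code{stack} ([AFMStack-class]) and \code{groundTruth}.
#' @export
renderRecipe <- function(recipe, tip = TipModel(20), pixelSize = 2,
                         extent = 32, side = "C") {
  gen <- generateAtomFrames(recipe)
  grid <- ScanGrid(-extent, extent, -extent, extent, pixelSize)
  code <- formatStackCode(list(
    alignment = if (recipe$motion$aligned) "A" else "U", side = side,
    tipRadius = tip@radius, pixelSize = pixelSize))
  st <- renderStack(gen$frames, tip, grid, code = code)
  st@meta$seed <- recipe$seed
  st@meta$provenance <- "pseudoProteinRecipe"
  list(stack = st, groundTruth = gen$groundTruth)
}
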