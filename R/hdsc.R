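## Hierarchical DSC: iteratively peel off conformational clusters whose
## clustered LAFM images are reproducible between the n = 2 and n = 3
## partitions of the remaining frames.

#' Configuration for hierarchical DSC
#'
#' @param stableMatchThreshold masked-SSIM value at or above which two
#'   clustered LAFM images are considered the same conformation.  The default
#'   0.65 is the threshold at which clusters become indistinguishable to the
#'   peeling loop in practice; raise it (e.g. 0.8) for deeply sampled stacks
#'   whose per-cluster LAFM maps are well converged.
#' @param minClusterSize minimum stable cluster size: a frame count (>= 1) or
#'   a fraction of the input stack depth (default 0.05).
#' @param maxRounds hard cap on peeling rounds.
#' @param lafm a [lafmParams()] list for the clustered LAFM images.
#' @param cae a [caeConfig()] for the one-off CAE training.
#' @param kScale local-scaling neighbour rank.
#' @param retrainPerRound retrain the CAE on the reduced stack at the start
#'   of every round instead of reusing the affinity submatrix (slower;
#'   default FALSE).
#' @return An HDSC configuration list.
#' @export
hdscConfig <- function(stableMatchThreshold = 0.65, minClusterSize = 0.05,
                       maxRounds = 10, lafm = lafmParams(), cae = caeConfig(),
                       kScale = 7, retrainPerRound = FALSE) {
  stopifnot(stableMatchThreshold > 0, stableMatchThreshold < 1,
            minClusterSize > 0)
  list(stableMatchThreshold = stableMatchThreshold,
       minClusterSize = minClusterSize, maxRounds = as.integer(maxRounds),
       lafmParams = lafm, caeConfig = cae, kScale = kScale,
       retrainPerRound = retrainPerRound)
}

#' Classify a cluster as stable or transient
#'
#' A cluster is stable iff its population reaches the minimum stable cluster
#' size (inclusive: exactly \code{minClusterSize} frames is stable);
#' smaller clusters are transient states.
#'
#' @param size cluster population (frame count).
#' @param minClusterSize minimum stable size in frames.
#' @return \code{"stable"} or \code{"transient"}.
#' @export
classifyStability <- function(size, minClusterSize) {
  if (size >= minClusterSize) "stable" else "transient"
}

subStack <- function(stack, idx) subsetFrames(stack, idx)

clusterLAFM <- function(stack, idx, params) {
  composeLAFM(subStack(stack, idx), params)
}

#' Hierarchical deep spectral clustering
#'
#' Implements the peeling loop: (1) cluster the remaining frames with n = 2
#' and compare the two clustered LAFM images; if their masked SSIM reaches
#' the threshold the clusters are combined and the loop halts.  (2) Otherwise
#' the affinity (sub)matrix is reclustered with n = 3 and the n = 3 clustered
#' LAFM images are cross-compared with the n = 2 ones; n = 3 clusters that
#' match an n = 2 image at or above the threshold (greedy best pair, each
#' n = 2 image certifying at most one cluster) are emitted and their frames
#' removed.  (3) The loop repeats on the reduced frame set until no cluster
#' is emitted or too few frames remain.  The CAE and affinity matrix are
#' computed once on the input stack and the affinity submatrix is reused
#' after frames are removed (set \code{retrainPerRound} to retrain instead).
#'
#' Emitted clusters are classified stable or transient by
#' [classifyStability()]; emitted clusters plus the residual always
#' partition the input frames, and each productive round removes at least
#' one cluster, bounding the number of rounds.
#'
#' @param stack an aligned [AFMStack-class] of depth >= 2 * minClusterSize.
#' @param cfg an [hdscConfig()].
#' @return An \code{HDSCResult}: list with \code{clusters} (each a list with
#'   \code{frames}, \code{lafm}, \code{stability}, \code{round}),
#'   \code{residual} (frame indices), \code{audit} (per-round log) and
#'   \code{minClusterSize} (in frames).
#' @export
hdsc <- function(stack, cfg = hdscConfig()) {
  stopifnot(is(stack, "AFMStack"))
  n0 <- nFrames(stack)
  minSize <- if (cfg$minClusterSize < 1)
    max(1L, ceiling(cfg$minClusterSize * n0)) else as.integer(cfg$minClusterSize)
  if (n0 < 2 * minSize)
    stop("stack depth must be at least twice the minimum cluster size")
  model <- trainCAE(stack, cfg$caeConfig)
  lfv <- extractLFV(model, stack)
  A <- localAffinity(lfv, kScale = cfg$kScale)
  remaining <- seq_len(n0)
  clusters <- list()
  audit <- list()
  for (round in seq_len(cfg$maxRounds)) {
    if (length(remaining) < max(2 * minSize, 3)) break
    if (cfg$retrainPerRound && round > 1) {
      model <- trainCAE(subStack(stack, remaining), cfg$caeConfig)
      lfvR <- extractLFV(model, subStack(stack, remaining))
      Asub <- localAffinity(lfvR, kScale = cfg$kScale)
    } else {
      Asub <- A[remaining, remaining]
    }
    cl2 <- spectralCluster(Asub, 2, seed = cfg$caeConfig$seed)
    g2 <- lapply(cl2$members, function(m) remaining[m])
    lafm2 <- lapply(g2, clusterLAFM, stack = stack, params = cfg$lafmParams)
    s22 <- maskedSSIM(lafmValues(lafm2[[1]]), lafmValues(lafm2[[2]]))
    if (s22 >= cfg$stableMatchThreshold) {
      ## the two halves show the same conformation: combine and halt
      clusters[[length(clusters) + 1]] <- list(
        frames = remaining,
        lafm = clusterLAFM(stack, remaining, cfg$lafmParams),
        stability = classifyStability(length(remaining), minSize),
        round = round)
      audit[[round]] <- list(round = round, action = "merge-halt",
                             ssim22 = s22, remaining = length(remaining))
      remaining <- integer(0)
      break
    }
    cl3 <- spectralCluster(Asub, 3, seed = cfg$caeConfig$seed)
    g3 <- lapply(cl3$members, function(m) remaining[m])
    lafm3 <- lapply(g3, clusterLAFM, stack = stack, params = cfg$lafmParams)
    cross <- outer(seq_along(g3), seq_along(g2),
                   Vectorize(function(i, j)
                     maskedSSIM(lafmValues(lafm3[[i]]), lafmValues(lafm2[[j]]))))
    ## certify each n=3 cluster against its best-matching n=2 image; clusters
    ## certified by the same n=2 image show the same conformation (the n=3
    ## partition over-split it) and are emitted combined
    bestMatch <- apply(cross, 1, which.max)
    bestScore <- cross[cbind(seq_len(nrow(cross)), bestMatch)]
    certified <- which(bestScore >= cfg$stableMatchThreshold)
    audit[[round]] <- list(round = round, action = "peel", ssim22 = s22,
                           cross = cross, certified = certified,
                           remaining = length(remaining))
    if (!length(certified)) {
      break
    }
    for (j in unique(bestMatch[certified])) {
      grp <- certified[bestMatch[certified] == j]
      frames <- sort(unlist(g3[grp], use.names = FALSE))
      lafmG <- if (length(grp) == 1) lafm3[[grp]] else
        clusterLAFM(stack, frames, cfg$lafmParams)
      clusters[[length(clusters) + 1]] <- list(
        frames = frames, lafm = lafmG,
        stability = classifyStability(length(frames), minSize),
        round = round)
    }
    remaining <- setdiff(remaining, unlist(g3[certified], use.names = FALSE))
  }
  structure(list(clusters = clusters, residual = remaining, audit = audit,
                 minClusterSize = minSize, model = model, affinity = A),
            class = "HDSCResult")
}

#' @export
print.HDSCResult <- function(x, ...) {
  cat("HDSCResult:", length(x$clusters), "clusters,",
      length(x$residual), "residual frames\n")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d frames (%s, round %d)\n", i,
                length(cl$frames), cl$stability, cl$round))
  }
  invisible(x)
}

#' Per-frame labels from an HDSC result
#'
#' @param result an \code{HDSCResult}.
#' @param nTotal total frame count of the input stack.
#' @return Integer vector: cluster number per frame, 0 for residual frames.
#' @export
hdscLabels <- function(result, nTotal) {
  lab <- integer(nTotal)
  for (i in seq_along(result$clusters))
    lab[result$clusters[[i]]$frames] <- i
  lab
}

#' Cluster occupancy over trajectory time
#'
#' Counts cluster membership in consecutive fixed-width frame bins; bins
#' partition the frame axis (the last bin may be shorter) and counts summed
#' over bins equal the total frame count.
#'
#' @param labels per-frame cluster labels in trajectory order.
#' @param binWidth bin width in frames, >= 1.
#' @return data.frame with columns \code{bin}, \code{cluster}, \code{count}.
#' @export
occupancySeries <- function(labels, binWidth) {
  if (binWidth < 1) stop("bin width must be >= 1 frame")
  binWidth <- as.integer(binWidth)
  n <- length(labels)
  bins <- ((seq_len(n) - 1L) %/% binWidth) + 1L
  tab <- table(bin = bins, cluster = labels)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$bin <- as.integer(df$bin)
  df$count <- df$Freq
  df$Freq <- NULL
  df[order(df$bin), ]
}
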