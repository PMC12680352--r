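## Registration-and-clustering (REC) with reference retention and silhouette
## refinement, its fixed-point iteration (IREC), automatic cluster-count
## selection by LAFM redundancy, and hierarchical application.

#' Configuration for REC / IREC
#'
#' @param cae a [caeConfig()] used by every embedded DSC run.
#' @param lafm a [lafmParams()] list for clustered LAFM images.
#' @param kScale local-scaling neighbour rank for the affinity matrix.
#' @param similarityThreshold masked-SSIM redundancy threshold for cluster
#'   count selection.  Redundant clusters that share frames score ~0.99, but
#'   redundant *disjoint* same-conformation clusters on stacks of a few
#'   hundred frames score 0.83-0.89 because their LAFM probability maps are
#'   under-converged; the default 0.8 captures both regimes while distinct
#'   conformations stay well below it.  Raise towards 0.9 for deeply
#'   sampled stacks.
#' @param maxIter maximum IREC iterations (default 10).
#' @param minClusterSize minimum cluster size (frames, or fraction of the
#'   stack) used by [hierarchicalIREC()] recursion.
#' @param rotRange,rotStep rotation search parameters for [estimateRigid()];
#'   the default window of +/- 20 degrees covers slow rotational drift along
#'   a membrane (widen for stacks with arbitrary in-plane orientation).
#' @return An IREC configuration list.
#' @export
irecConfig <- function(cae = caeConfig(), lafm = lafmParams(), kScale = 7,
                       similarityThreshold = 0.8, maxIter = 10,
                       minClusterSize = 0.05, rotRange = 20, rotStep = 5) {
  stopifnot(similarityThreshold > 0, similarityThreshold < 1, maxIter >= 1)
  list(cae = cae, lafm = lafm, kScale = kScale,
       similarityThreshold = similarityThreshold,
       maxIter = as.integer(maxIter), minClusterSize = minClusterSize,
       rotRange = rotRange, rotStep = rotStep)
}

#' Select a cluster's best registration reference by silhouette score
#'
#' Per-frame silhouette \code{s = (b - a) / max(a, b)} in latent feature
#' space (Euclidean), with \code{a} the mean intra-cluster distance and
#' \code{b} the smallest mean distance to another cluster; the member with
#' maximal \code{s} is returned, ties broken by lowest frame index.
#' Singleton clusters have \code{s = 0} by convention.  With a single-cluster
#' labeling the silhouette is undefined and the cluster medoid (minimum mean
#' intra-cluster distance) is returned instead.
#'
#' @param members frame indices of the cluster to pick a reference from.
#' @param lfv N x d latent feature matrix for all frames.
#' @param labels per-frame cluster labels of the full partition.
#' @return A single frame index.
#' @export
silhouetteSelect <- function(members, lfv, labels) {
  stopifnot(length(members) >= 1)
  if (length(members) == 1) return(members)
  D <- as.matrix(stats::dist(lfv))
  cl <- unique(labels)
  if (length(cl) < 2) {
    ## medoid fallback
    intra <- rowMeans(D[members, members, drop = FALSE])
    return(members[which.min(intra)])
  }
  s <- vapply(members, function(i) {
    own <- labels[i]
    same <- setdiff(which(labels == own), i)
    if (!length(same)) return(0)
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(cl, own), function(k)
      mean(D[i, labels == k]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  members[which.max(s)]   # which.max takes the first (lowest index) on ties
}

#' Register-then-cluster with reference retention
#'
#' In single-reference mode (one reference, explicit \code{n}) the stack is
#' registered to the reference and DSC partitions it into \code{n} clusters;
#' all clusters are reported, the reference-containing one is flagged as
#' well-registered, and the maximum-silhouette frame of every cluster forms
#' the refined reference set.  In multi-reference mode (\code{n} references)
#' the stack is registered separately to each reference, each registered
#' stack is clustered with DSC, and only the cluster containing its own
#' registration reference is retained; its maximum-silhouette frame becomes
#' that reference's refinement.  Heavily overlapping retained clusters
#' (degenerate reference choices) are flagged in the audit.
#'
#' @param stack an [AFMStack-class] (typically unaligned).
#' @param refs integer frame indices (length 1, or length \code{n}).
#' @param n number of clusters.
#' @param cfg an [irecConfig()].
#' @param .regCache optional environment memoizing stack registrations by
#'   reference frame index (used by [irec()] to avoid re-registering to
#'   previously visited references).
#' @return A \code{RECResult}: list with \code{retained} (list, per
#'   reference: \code{frames}, \code{reference}, \code{registered} frames
#'   array), \code{refinedRefs}, \code{partition} (disjoint assignment,
#'   0 = unassigned), and \code{audit}.
#' @export
rec <- function(stack, refs, n, cfg = irecConfig(), .regCache = NULL) {
  stopifnot(is(stack, "AFMStack"), n >= 1)
  N <- nFrames(stack)
  if (any(refs < 1 | refs > N)) stop("reference index out of range")
  single <- length(refs) == 1 && n >= 1
  if (!single && length(refs) != n)
    stop("multi-reference mode needs exactly n references")
  audit <- list()
  retained <- list()
  refinedRefs <- integer(0)
  registerCached <- function(refIdx) {
    if (is.null(.regCache))
      return(registerStack(stack, refIdx, rotRange = cfg$rotRange,
                           rotStep = cfg$rotStep))
    key <- as.character(refIdx)
    reg <- get0(key, envir = .regCache)
    if (is.null(reg)) {
      reg <- registerStack(stack, refIdx, rotRange = cfg$rotRange,
                           rotStep = cfg$rotStep)
      assign(key, reg, envir = .regCache)
    }
    reg
  }
  if (single) {
    reg <- registerCached(refs)
    ds <- dsc(reg$stack, n, cfg$cae, kScale = cfg$kScale)
    labels <- ds$clusters$labels
    refinedRefs <- vapply(ds$clusters$members, silhouetteSelect,
                          integer(1), lfv = ds$lfv, labels = labels)
    refCluster <- labels[refs]
    for (k in seq_along(ds$clusters$members)) {
      retained[[k]] <- list(frames = ds$clusters$members[[k]],
                            reference = refinedRefs[k],
                            wellRegistered = (k == refCluster),
                            registered = reg$stack@heights[, , ds$clusters$members[[k]],
                                                           drop = FALSE])
    }
    partition <- labels
    audit$mode <- "single-reference"
  } else {
    partition <- integer(N)
    for (j in seq_len(n)) {
      reg <- registerCached(refs[j])
      ds <- dsc(reg$stack, n, cfg$cae, kScale = cfg$kScale)
      labels <- ds$clusters$labels
      keep <- which(labels == labels[refs[j]])
      refined <- silhouetteSelect(keep, ds$lfv, labels)
      retained[[j]] <- list(frames = keep, reference = refined,
                            wellRegistered = TRUE,
                            registered = reg$stack@heights[, , keep,
                                                           drop = FALSE])
      refinedRefs[j] <- refined
      free <- keep[partition[keep] == 0]
      partition[free] <- j
    }
    ## overlap diagnostics between raw retained clusters
    ov <- matrix(0, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b) {
        ia <- retained[[a]]$frames; ib <- retained[[b]]$frames
        ov[a, b] <- length(intersect(ia, ib)) / length(union(ia, ib))
      }
    }
    audit$overlapJaccard <- ov
    audit$degenerateReferences <- any(ov > 0.5)
    audit$mode <- "multi-reference"
  }
  structure(list(retained = retained, refinedRefs = refinedRefs,
                 partition = partition, audit = audit, n = n),
            class = "RECResult")
}

## mean global-SSIM medoid frame over an evenly spaced subsample
medoidFrame <- function(stack, maxSample = 24) {
  N <- nFrames(stack)
  idx <- unique(round(seq(1, N, length.out = min(maxSample, N))))
  m <- length(idx)
  S <- matrix(1, m, m)
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    S[a, b] <- S[b, a] <- mean(ssimMap(frameAt(stack, idx[a]),
                                       frameAt(stack, idx[b])))
  }
  idx[which.max(rowMeans(S))]
}

#' Iterative registration and clustering
#'
#' Bootstraps with single-reference REC from \code{r0} to obtain \code{n}
#' references, then iterates multi-reference REC: each iteration re-registers
#' and re-clusters the stack with the current references and replaces them by
#' the refined maximum-silhouette references.  Iteration stops when the
#' reference set converges, a previously seen reference set recurs (cycle;
#' the best-scoring iteration is returned), or \code{maxIter} is reached.
#'
#' @param stack an [AFMStack-class].
#' @param r0 initial reference frame index; \code{NULL} picks the stack
#'   medoid (maximum mean SSIM over a subsample).
#' @param n number of clusters.
#' @param cfg an [irecConfig()].
#' @return An \code{IRECResult}: list with \code{rec} (final
#'   \code{RECResult}), \code{references}, \code{trace} (reference sets and
#'   quality scores per iteration), \code{termination} in
#'   \code{c("converged", "cycle", "max_iter")}.
#' @export
irec <- function(stack, r0 = NULL, n = 2, cfg = irecConfig(),
                 .regCache = NULL) {
  stopifnot(is(stack, "AFMStack"))
  if (is.null(.regCache)) .regCache <- new.env(parent = emptyenv())
  if (is.null(r0)) r0 <- medoidFrame(stack)
  boot <- rec(stack, r0, n, cfg, .regCache = .regCache)
  refs <- sort(boot$refinedRefs)
  history <- list(refs)
  results <- list()
  scores <- numeric(0)
  termination <- "max_iter"
  res <- boot
  for (it in seq_len(cfg$maxIter)) {
    res <- rec(stack, refs, n, cfg, .regCache = .regCache)
    newRefs <- sort(res$refinedRefs)
    results[[it]] <- res
    scores[it] <- mean(vapply(res$retained, function(cl)
      length(cl$frames), numeric(1))) / nFrames(stack)
    if (identical(newRefs, refs)) {
      termination <- "converged"
      break
    }
    if (any(vapply(history, identical, logical(1), y = newRefs))) {
      termination <- "cycle"
      res <- results[[which.max(scores)]]
      break
    }
    history[[length(history) + 1]] <- newRefs
    refs <- newRefs
  }
  structure(list(rec = res, references = res$refinedRefs,
                 trace = list(history = history, scores = scores),
                 termination = termination, n = n, r0 = r0),
            class = "IRECResult")
}

#' @export
print.IRECResult <- function(x, ...) {
  cat(sprintf("IRECResult: n = %d, termination = %s, references [%s]\n",
              x$n, x$termination, paste(x$references, collapse = ", ")))
  invisible(x)
}

## clustered LAFM images of an (I)REC result: each retained cluster's frames
## registered to its own reference
recClusterLAFMs <- function(recRes, pixelSize, params) {
  lapply(recRes$retained, function(cl) {
    composeLAFM(AFMStack(cl$registered, pixelSize = pixelSize), params)
  })
}

## register LAFM images to one another pairwise and return the masked-SSIM
## matrix.  Registration must be per pair: aligning every image to one common
## member would route same-conformation pairs through a cross-conformation
## registration whose rotation is arbitrary, destroying their similarity.
lafmCrossSSIM <- function(lafms, rotRange = 60, rotStep = 5) {
  imgs <- lapply(lafms, lafmValues)
  m <- length(imgs)
  S <- diag(1, m)
  if (m > 1) {
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      t <- estimateRigid(imgs[[b]], imgs[[a]], rotRange, rotStep)
      S[a, b] <- S[b, a] <- maskedSSIM(imgs[[a]],
                                       pmax(applyRigid(imgs[[b]], t), 0))
    }
  }
  S
}

#' Select the number of conformational clusters with IREC
#'
#' Runs [irec()] for n = 2, 3, ... and compares the clustered LAFM images of
#' each solution after mutual rigid registration.  While all pairwise masked
#' SSIM scores stay below the similarity threshold the clusters represent
#' distinct conformations and \code{n} is incremented; as soon as any pair
#' reaches the threshold the extra cluster is redundant and \code{n - 1} is
#' returned with the previous solution.  If already the n = 2 solution is
#' redundant the stack is homogeneous and n = 1 is selected.
#'
#' @param stack an [AFMStack-class].
#' @param r0 initial reference (NULL = stack medoid).
#' @param cfg an [irecConfig()].
#' @param nMax largest n tried; reaching it without redundancy returns
#'   \code{nMax} flagged as non-converged.
#' @return list with \code{n} (selected count), \code{result} (the
#'   [irec()] output for the selected n, or NULL when n = 1), \code{lafms}
#'   (clustered LAFM images of the selected solution), \code{converged}
#'   (FALSE iff nMax was exhausted), \code{ssimTrace}.
#' @export
selectClusterCount <- function(stack, r0 = NULL, cfg = irecConfig(),
                               nMax = 4) {
  stopifnot(nMax >= 2)
  if (is.null(r0)) r0 <- medoidFrame(stack)
  regCache <- new.env(parent = emptyenv())
  prev <- NULL
  prevLafms <- NULL
  ssimTrace <- list()
  for (n in 2:nMax) {
    resN <- irec(stack, r0, n, cfg, .regCache = regCache)
    lafms <- recClusterLAFMs(resN$rec, pixelSize(stack), cfg$lafm)
    S <- lafmCrossSSIM(lafms, cfg$rotRange, cfg$rotStep)
    ssimTrace[[as.character(n)]] <- S
    off <- S[upper.tri(S)]
    if (any(off >= cfg$similarityThreshold)) {
      if (n == 2) {
        ## both halves show one conformation: homogeneous stack
        reg <- registerStack(stack, r0, rotRange = cfg$rotRange,
                             rotStep = cfg$rotStep)
        whole <- composeLAFM(reg$stack, cfg$lafm)
        return(list(n = 1L, result = NULL, lafms = list(whole),
                    converged = TRUE, ssimTrace = ssimTrace))
      }
      return(list(n = n - 1L, result = prev, lafms = prevLafms,
                  converged = TRUE, ssimTrace = ssimTrace))
    }
    prev <- resN
    prevLafms <- lafms
  }
  warning("no redundant clustering up to nMax = ", nMax,
          "; returning nMax, not converged")
  list(n = as.integer(nMax), result = prev, lafms = prevLafms,
       converged = FALSE, ssimTrace = ssimTrace)
}

#' Hierarchical IREC
#'
#' Applies [selectClusterCount()] to the stack and recurses into every
#' resulting cluster (on the original, still-unaligned frames) until a
#' cluster is homogeneous (n = 1 selected) or too small.  Partitioning by
#' gross morphology first and refining within each branch avoids the
#' reference bias that a flat IREC run can show on stacks mixing very
#' different structures.
#'
#' @param stack an [AFMStack-class].
#' @param cfg an [irecConfig()].
#' @param minFrames smallest substack that is still recursed into; defaults
#'   to twice the minimum cluster size.
#' @param nMax largest cluster count tried per level (see
#'   [selectClusterCount()]).
#' @param .frames internal: original-frame indices of this branch.
#' @return A tree: list with \code{frames}, \code{n}, \code{selection} and
#'   \code{children} (list of subtrees; empty at leaves).
#' @export
hierarchicalIREC <- function(stack, cfg = irecConfig(), minFrames = NULL,
                             nMax = 4,
                             .frames = seq_len(nFrames(stack))) {
  N <- nFrames(stack)
  minSize <- if (cfg$minClusterSize < 1)
    max(2L, ceiling(cfg$minClusterSize * N)) else as.integer(cfg$minClusterSize)
  if (is.null(minFrames)) minFrames <- 2L * minSize
  sel <- selectClusterCount(stack, r0 = NULL, cfg = cfg, nMax = nMax)
  node <- list(frames = .frames, n = sel$n, selection = sel,
               children = list())
  if (sel$n <= 1 || is.null(sel$result)) return(node)
  for (k in seq_along(sel$result$rec$retained)) {
    sub <- sel$result$rec$retained[[k]]$frames
    if (length(sub) < max(minFrames, cfg$cae$batchSize)) next
    child <- hierarchicalIREC(subStack(stack, sub), cfg,
                              minFrames = minFrames, nMax = nMax,
                              .frames = .frames[sub])
    node$children[[length(node$children) + 1]] <- child
  }
  node
}
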