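## Deep spectral clustering: locally scaled affinity over latent feature
## vectors, symmetric-normalized spectral embedding, seeded k-means.

#' Locally scaled affinity matrix
#'
#' Pairwise affinities \code{A_ij = exp(-d(i,j)^2 / (sigma_i * sigma_j))}
#' with Euclidean distance \code{d} in latent space and local scale
#' \code{sigma_i} equal to the distance from point i to its
#' \code{kScale}-th nearest neighbour (self excluded).  Points with at least
#' \code{kScale} exact duplicates would get \code{sigma_i = 0}; those fall
#' back to their smallest positive neighbour distance.  The result is
#' symmetric with zero diagonal and entries in [0, 1].
#'
#' @param lfv N x d numeric matrix (one latent feature vector per frame).
#' @param kScale neighbour rank used for the local scale (default 7, the
#'   self-tuning spectral clustering convention); must be < N.
#' @return N x N affinity matrix.
#' @export
localAffinity <- function(lfv, kScale = 7) {
  lfv <- as.matrix(lfv)
  n <- nrow(lfv)
  if (n <= kScale) stop("need more points than kScale")
  D <- as.matrix(stats::dist(lfv))
  ## k-th nearest neighbour distance per row, self excluded
  sig <- vapply(seq_len(n), function(i) {
    d <- sort(D[i, -i])
    s <- d[kScale]
    if (s == 0) {
      pos <- d[d > 0]
      if (!length(pos)) return(0)
      s <- pos[1]
    }
    s
  }, numeric(1))
  if (all(sig == 0))
    stop("degenerate input: all latent feature vectors are identical")
  sig[sig == 0] <- min(sig[sig > 0])
  A <- exp(-D^2 / outer(sig, sig))
  diag(A) <- 0
  dimnames(A) <- NULL
  A
}

#' Spectral clustering of an affinity matrix
#'
#' Normalized-cut style clustering: the symmetric-normalized matrix
#' \code{D^-1/2 A D^-1/2} is eigendecomposed, the top-n eigenvectors are
#' row-normalized to the unit sphere, and k-means (seeded, multiple restarts)
#' assigns labels.  Deterministic given \code{seed}.  Disconnected affinity
#' graphs with more components than \code{n} still return a partition
#' (components merge by embedding proximity).
#'
#' @param A N x N symmetric affinity matrix, zero diagonal.
#' @param n number of clusters, 1 <= n <= N.
#' @param seed integer seed for k-means initialization.
#' @return A \code{ClusterSet}: list with \code{n}, \code{labels} (integer in
#'   1..n per frame) and \code{members} (list of frame index vectors, all
#'   nonempty).
#' @export
spectralCluster <- function(A, n, seed = 1) {
  N <- nrow(A)
  stopifnot(n >= 1, n <= N, ncol(A) == N)
  if (n == 1) {
    labels <- rep(1L, N)
  } else if (n == N) {
    labels <- seq_len(N)
  } else {
    deg <- rowSums(A)
    dInv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    M <- A * outer(dInv, dInv)
    ev <- eigen(M, symmetric = TRUE)
    U <- ev$vectors[, seq_len(n), drop = FALSE]
    rn <- sqrt(rowSums(U^2))
    rn[rn == 0] <- 1
    U <- U / rn
    km <- withPrivateSeed(seed,
      stats::kmeans(U, centers = n, nstart = 10, iter.max = 50))
    labels <- as.integer(km$cluster)
    ## guard: kmeans can in principle return empty clusters only with
    ## degenerate duplicated centers; relabel to a dense 1..n' range
    if (length(unique(labels)) < n) {
      labels <- as.integer(factor(labels))
      n <- length(unique(labels))
    }
  }
  list(n = as.integer(n), labels = labels,
       members = unname(split(seq_len(N), labels)))
}

#' Deep spectral clustering of an image stack
#'
#' Composition of the DSC pipeline: train the CAE on the stack, extract
#' latent feature vectors, build the locally scaled affinity matrix and
#' spectral-cluster it into \code{n} groups.  Up to label permutation the
#' partition is invariant under shuffling of the input frames (the pipeline
#' carries no positional information).
#'
#' @param stack an [AFMStack-class].
#' @param n number of conformational clusters.
#' @param cfg a [caeConfig()].
#' @param kScale local-scaling neighbour rank (see [localAffinity()]).
#' @param model optionally, an already trained \code{"lafmCAE"} to reuse
#'   (skips training).
#' @return list with \code{clusters} (a \code{ClusterSet}), \code{lfv},
#'   \code{affinity} and \code{model}.
#' @examples
#' \donttest{
#' fx <- renderRecipe(pseudoProteinRecipe(2, nFrames = 64, seed = 3),
#'                    pixelSize = 4, extent = 32)
#' res <- dsc(fx$stack, n = 2, cfg = caeConfig(latentDim = 8,
#'   convChannels = c(8, 16), epochs = 3, seed = 1))
#' table(res$clusters$labels, fx$groundTruth$labels)
#' }
#' @export
dsc <- function(stack, n, cfg = caeConfig(), kScale = 7, model = NULL) {
  if (is.null(model)) model <- trainCAE(stack, cfg)
  lfv <- extractLFV(model, stack)
  A <- localAffinity(lfv, kScale = kScale)
  cl <- spectralCluster(A, n, seed = cfg$seed)
  list(clusters = cl, lfv = lfv, affinity = A, model = model)
}
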