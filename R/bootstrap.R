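#' Draw a SNP bootstrap index vector
#'
#' Samples K column indices uniformly with replacement, reproducibly from
#' the given seed, without disturbing the caller's RNG state.
#'
#' @param K number of SNPs (>= 1).
#' @param seed integer seed for this replicate.
#' @return integer vector of K indices in 1..K.
#' @export
bootstrapIndices <- function(K, seed) {
  if (K < 1L) stop("K must be at least 1")
  withr::with_seed(as.integer(seed), sample.int(K, K, replace = TRUE))
}

#' Build a bootstrap replicate dataset by gathering SNP columns
#'
#' A replicate keeps the exact same individuals but a resampled SNP
#' composition: dosages, missing mask and SNP metadata are gathered by the
#' same index vector (duplicated columns allowed).
#'
#' @param x a [GenotypeData-class] object.
#' @param indices integer vector of column indices in 1..K.
#' @return a [GenotypeData-class] object with `length(indices)` SNP columns.
#' @export
buildReplicate <- function(x, indices) {
  stopifnot(is(x, "GenotypeData"))
  K <- ncol(x@dosages)
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > K)) {
    stop(sprintf("bootstrap index out of range 1..%d", K))
  }
  newGenotypeData(
    x@dosages[, indices, drop = FALSE],
    x@individualIds, x@populations,
    # resampled SNP ids must stay unique labels of the gathered columns
    make.unique(x@snpIds[indices], sep = ".rep"),
    if (length(x@snpChrom)) x@snpChrom[indices] else character(0),
    if (length(x@snpPos)) x@snpPos[indices] else numeric(0)
  )
}

embedReplicate <- function(x, method, methodParams) {
  if (method == "pca") {
    do.call(pcaEmbed, c(list(x = x), methodParams))
  } else {
    dm <- do.call(pairwiseDistance, c(list(x = x), methodParams$distance))
    mdsEmbed(dm, nComponents = methodParams$nComponents %||% 2L)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assess bootstrap convergence from the replicates computed so far
#'
#' Heuristic stopping rule: draw `nSubsets` random subsets of size
#' `ceiling(n/2)` (without replacement) from the n completed replicates,
#' compute the embedding stability score on each subset, and declare
#' convergence when the relative spread `(max - min) / max` of the subset
#' scores is at most `tolerance`.  A small spread means additional
#' replicates would barely move the overall score.
#'
#' @param embeddings list of at least 10 replicate embeddings.
#' @param tolerance maximum admissible relative spread (default 0.05).
#' @param nSubsets number of random subsets (default 10).
#' @param seed integer seed for the subset draws.
#' @param simMatrix optional pre-computed pairwise similarity matrix for the
#'   embeddings (an internal cache used by [runBootstrap()]).
#' @return `TRUE` when converged.
#' @export
checkConvergence <- function(embeddings, tolerance = 0.05, nSubsets = 10L,
                             seed = 0L, simMatrix = NULL) {
  n <- length(embeddings)
  if (n < 10L) stop("convergence assessment needs at least 10 replicates")
  if (is.null(simMatrix)) simMatrix <- pairwiseSimilarityMatrix(embeddings)
  subSize <- ceiling(n / 2)
  subsets <- withr::with_seed(as.integer(seed), {
    replicate(nSubsets, sample.int(n, subSize, replace = FALSE),
              simplify = FALSE)
  })
  ps <- vapply(subsets, function(idx) {
    sub <- simMatrix[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  mx <- max(ps)
  if (mx <= 0) return(TRUE)  # all-zero scores: nothing left to resolve
  (mx - min(ps)) / mx <= tolerance
}

#' Run the SNP bootstrap and embed every replicate
#'
#' Generates up to `nMax` SNP-bootstrap replicates of the dataset, embeds
#' each with PCA or MDS, and stops early once the subset-stability spread
#' falls below `tolerance`.  Replicates are dispatched in parallel batches of
#' `threads`, but every per-replicate seed is derived from the master seed
#' before dispatch (`seed + replicate number`) and convergence is evaluated
#' at deterministic checkpoints (each replicate count from 10 upward, in
#' order), so the result — including the stopping point — is identical for
#' any thread count.
#'
#' @param x a [GenotypeData-class] object.
#' @param method `"pca"` or `"mds"`.
#' @param nComponents components per embedding (default 10 for PCA, 2 for
#'   MDS).
#' @param projectIds individuals to project rather than fit (PCA only).
#' @param distanceMetric,distanceLevel distance specification (MDS only).
#' @param nMax maximum number of replicates (default 100).
#' @param tolerance convergence tolerance (default 0.05); `tolerance = 0`
#'   effectively disables early stopping.
#' @param disableConvergence logical; compute all `nMax` replicates.
#' @param threads parallel workers for replicate embedding.
#' @param seed master seed; all randomness in the run derives from it.
#' @param verbose logical; one progress line per batch to stderr.
#' @param fixIdentityIndices test hook: every replicate uses the identity
#'   index vector 1..K (so all replicates equal the input dataset).
#' @return a [BootstrapEmbeddings-class] object.
#' @examples
#' g <- simulateGenotypes(nPopulations = 2, nPerPopulation = 5,
#'                        nSnps = 100, divergenceFst = 0.3, seed = 1)
#' br <- runBootstrap(g, "pca", nComponents = 2, nMax = 12, seed = 1)
#' embeddingStability(br)
#' @export
runBootstrap <- function(x, method = c("pca", "mds"),
                         nComponents = NULL,
                         projectIds = character(0),
                         distanceMetric = "euclidean",
                         distanceLevel = "individual",
                         nMax = 100L, tolerance = 0.05,
                         disableConvergence = FALSE,
                         threads = 1L, seed = 42L,
                         verbose = FALSE,
                         fixIdentityIndices = FALSE) {
  stopifnot(is(x, "GenotypeData"))
  method <- match.arg(method)
  if (nMax < 2L) stop("nMax must be at least 2")
  seed <- as.integer(seed)
  nComponents <- as.integer(nComponents %||% if (method == "pca") 10L else 2L)
  methodParams <- if (method == "pca") {
    list(nComponents = nComponents, projectIds = projectIds)
  } else {
    list(nComponents = nComponents,
         distance = list(metric = distanceMetric, level = distanceLevel))
  }
  K <- ncol(x@dosages)

  oneReplicate <- function(i) {
    idx <- if (fixIdentityIndices) seq_len(K) else bootstrapIndices(K, seed + i)
    emb <- tryCatch(
      embedReplicate(buildReplicate(x, idx), method, methodParams),
      error = function(e) {
        stop(sprintf("embedding failed on bootstrap replicate %d: %s",
                     i, conditionMessage(e)), call. = FALSE)
      }
    )
    emb
  }

  threads <- max(1L, as.integer(threads))
  embeddings <- vector("list", nMax)
  stdCoords <- vector("list", nMax)
  simMat <- matrix(1, nMax, nMax)
  nDone <- 0L
  convergedAt <- NA_integer_
  nextCheck <- 10L

  while (nDone < nMax && is.na(convergedAt)) {
    batch <- seq(nDone + 1L, min(nDone + threads, nMax))
    res <- if (threads > 1L) {
      parallel::mclapply(batch, oneReplicate, mc.cores = threads,
                         mc.preschedule = FALSE)
    } else {
      lapply(batch, oneReplicate)
    }
    for (b in seq_along(batch)) {
      if (inherits(res[[b]], "try-error") || !is(res[[b]], "GenotypeEmbedding")) {
        stop(sprintf("bootstrap replicate %d failed: %s", batch[b],
                     paste(as.character(res[[b]]), collapse = " ")))
      }
    }
    for (b in seq_along(batch)) {
      i <- batch[b]
      embeddings[[i]] <- res[[b]]
      stdCoords[[i]] <- standardizeCoords(res[[b]]@coords)
      for (j in seq_len(i - 1L)) {
        sigma <- sum(svd(crossprod(stdCoords[[j]], stdCoords[[i]]))$d)
        simMat[j, i] <- simMat[i, j] <- max(0, min(1, sigma^2))
      }
    }
    nDone <- max(batch)

    if (!disableConvergence && tolerance > 0) {
      # deterministic checkpoints: walk each replicate count in order so the
      # stopping point does not depend on the batch (thread) size
      while (nextCheck <= nDone) {
        idx <- seq_len(nextCheck)
        if (checkConvergence(embeddings[idx], tolerance = tolerance,
                             seed = seed + 1000L + nextCheck,
                             simMatrix = simMat[idx, idx, drop = FALSE])) {
          convergedAt <- nextCheck
          break
        }
        nextCheck <- nextCheck + 1L
      }
    }
    if (verbose) {
      message(sprintf("bootstrap: %d/%d replicates computed%s", nDone, nMax,
                      if (!is.na(convergedAt))
                        sprintf(", converged at %d", convergedAt) else ""))
    }
  }

  nKeep <- if (is.na(convergedAt)) nDone else convergedAt
  new("BootstrapEmbeddings",
      embeddings = embeddings[seq_len(nKeep)],
      converged = !is.na(convergedAt),
      nComputed = as.integer(nKeep),
      seed = seed)
}
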