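#' Fowlkes-Mallows index between two partitions
#'
#' Agreement of two clusterings over all unordered item pairs:
#' `FM = TP / sqrt((TP + FP) (TP + FN))` where TP counts pairs co-clustered
#' in both partitions, FP pairs co-clustered only in the first, FN only in
#' the second.  Invariant to permuting cluster labels; 1 for identical
#' partitions, 0 when no pair is co-clustered in both.
#'
#' @param a,b integer (or factor) label vectors of equal length >= 2.
#' @return the index, in \[0, 1\].
#' @examples
#' fowlkesMallows(c(1, 1, 2, 2), c(1, 2, 1, 2))  # no co-clustered pair shared
#' @export
fowlkesMallows <- function(a, b) {
  if (length(a) != length(b)) {
    stop(sprintf("label vectors differ in length: %d vs %d",
                 length(a), length(b)))
  }
  n <- length(a)
  if (n < 2L) stop("need at least 2 items")
  ct <- table(a, b)
  tpPlus <- sum(ct^2) - n                 # 2 * TP
  fpSide <- sum(rowSums(ct)^2) - n        # 2 * (TP + FP)
  fnSide <- sum(colSums(ct)^2) - n        # 2 * (TP + FN)
  if (fpSide == 0 || fnSide == 0) return(0)
  tpPlus / sqrt(fpSide * fnSide)
}

#' k-means clustering of an embedding
#'
#' Hard k-means on the embedding coordinates with k-means++ seeding and a
#' fixed number of restarts; deterministic given the seed.  The best restart
#' (lowest within-cluster sum of squares) is returned.
#'
#' @param x a [GenotypeEmbedding-class] or coordinate matrix.
#' @param k number of clusters, 2 <= k <= R.
#' @param seed integer seed.
#' @param nRestarts number of k-means++ restarts (default 10).
#' @return list with `labels` (integer vector in 1..k, named by row label),
#'   `k` and `inertia` (total within-cluster sum of squares).
#' @export
kmeansCluster <- function(x, k, seed = 0L, nRestarts = 10L) {
  cc <- if (is(x, "GenotypeEmbedding")) x@coords else as.matrix(x)
  R <- nrow(cc)
  if (k < 2L || k > R) stop(sprintf("k must be in 2..%d", R))
  if (k == R) {
    labels <- seq_len(R)
    names(labels) <- rownames(cc)
    return(list(labels = labels, k = as.integer(k), inertia = 0))
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nRestarts)) {
      centers <- kppCenters(cc, k)
      fit <- suppressWarnings(stats::kmeans(cc, centers = centers,
                                            iter.max = 100L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  labels <- as.integer(best$cluster)
  names(labels) <- rownames(cc)
  list(labels = labels, k = as.integer(k), inertia = best$tot.withinss)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
kppCenters <- function(cc, k) {
  R <- nrow(cc)
  centers <- matrix(NA_real_, k, ncol(cc))
  chosen <- integer(k)
  chosen[1L] <- sample.int(R, 1L)
  centers[1L, ] <- cc[chosen[1L], ]
  d2 <- rowSums(sweep(cc, 2L, centers[1L, ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / R, R)
    chosen[j] <- sample.int(R, 1L, prob = prob)
    centers[j, ] <- cc[chosen[j], ]
    d2 <- pmin(d2, rowSums(sweep(cc, 2L, centers[j, ], "-")^2))
  }
  # duplicated centers break stats::kmeans; nudge to distinct points if needed
  if (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    free <- setdiff(seq_len(R), chosen)
    for (i in seq_along(dup)) {
      if (length(free)) {
        centers[dup[i], ] <- cc[free[1L], ]
        free <- free[-1L]
      } else {
        centers[dup[i], ] <- centers[dup[i], ] + 1e-8 * i
      }
    }
  }
  centers
}

#' Choose the number of clusters by BIC grid search
#'
#' Fits k-means for each k between `kMin` and an automatically determined
#' upper bound and scores each fit with the Bayesian information criterion
#' of a spherical Gaussian mixture with shared variance (the x-means
#' formulation): `BIC = p ln R - 2 ln L` with `p = k (D + 1)` free
#' parameters and `sigma^2 = inertia / (D (R - k))`.  The upper bound is the
#' number of distinct population labels when available, otherwise
#' `ceiling(sqrt(R))`, floored at `kMin`.
#'
#' @param x a [GenotypeEmbedding-class] or coordinate matrix.
#' @param populations optional population labels driving the upper bound.
#' @param kMin lower bound of the grid (default 3).
#' @param kMax optional explicit upper bound.
#' @param seed integer seed for the k-means fits.
#' @return the k with the smallest BIC (ties broken toward smaller k).
#' @export
optimalK <- function(x, populations = NULL, kMin = 3L, kMax = NULL, seed = 0L) {
  cc <- if (is(x, "GenotypeEmbedding")) x@coords else as.matrix(x)
  R <- nrow(cc)
  D <- ncol(cc)
  if (R < kMin) {
    stop(sprintf(
      "only %d rows but kMin = %d; set the number of clusters k manually",
      R, kMin
    ))
  }
  if (is.null(kMax)) {
    pops <- populations[!is.na(populations) & nzchar(populations)]
    kMax <- if (length(pops)) length(unique(pops)) else ceiling(sqrt(R))
    kMax <- max(kMax, kMin)
  }
  kMax <- min(kMax, R - 1L)
  grid <- seq(kMin, kMax)
  bic <- vapply(grid, function(k) {
    fit <- kmeansCluster(cc, k, seed = seed + k)
    kmeansBIC(cc, fit$labels, fit$inertia)
  }, numeric(1))
  as.integer(grid[which.min(bic)])
}

# BIC of a hard-assignment spherical Gaussian mixture with shared variance
kmeansBIC <- function(cc, labels, inertia) {
  R <- nrow(cc)
  D <- ncol(cc)
  k <- length(unique(labels))
  sigma2 <- inertia / (D * (R - k))
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- .Machine$double.eps
  nc <- as.numeric(table(labels))
  logL <- sum(nc * log(nc / R)) -
    (R * D / 2) * log(2 * pi * sigma2) -
    D * (R - k) / 2
  p <- k * (D + 1)
  p * log(R) - 2 * logL
}

#' Cluster agreement of one pair of bootstrap embeddings
#'
#' Standardizes both embeddings, Procrustes-transforms the first onto the
#' second, clusters each with k-means (seeds derived from `seed` and the two
#' replicate indices so the "independent" clusterings are reproducible), and
#' returns the Fowlkes-Mallows agreement of the two label vectors.
#'
#' @param u,v label-compatible [GenotypeEmbedding-class] objects.
#' @param k number of clusters.
#' @param seed base seed.
#' @param indexU,indexV replicate indices of `u` and `v` used to derive the
#'   per-clustering seeds.
#' @return agreement in \[0, 1\].
#' @export
pairwiseClusterSimilarity <- function(u, v, k, seed = 0L,
                                      indexU = 1L, indexV = 2L) {
  comp <- procrustesDisparity(u, v)
  cu <- standardizeCoords(if (is(u, "GenotypeEmbedding")) u@coords else as.matrix(u))
  cv <- standardizeCoords(if (is(v, "GenotypeEmbedding")) v@coords else as.matrix(v))
  cuAligned <- applyProcrustes(cu, comp)
  labU <- kmeansCluster(cuAligned, k, seed = seed + 31L * indexU)$labels
  labV <- kmeansCluster(cv, k, seed = seed + 31L * indexV)$labels
  fowlkesMallows(labU, labV)
}

#' Overall cluster stability across bootstrap replicates
#'
#' Mean pairwise cluster agreement ([pairwiseClusterSimilarity()]) over all
#' N(N-1)/2 unordered pairs of replicate embeddings.
#'
#' @param embeddings list of label-compatible [GenotypeEmbedding-class]
#'   objects, or a [BootstrapEmbeddings-class].
#' @param k number of k-means clusters shared by all clusterings.
#' @param seed base seed for the per-pair clusterings.
#' @return cluster stability score in \[0, 1\].
#' @export
clusterStability <- function(embeddings, k, seed = 0L) {
  if (is(embeddings, "BootstrapEmbeddings")) embeddings <- embeddings@embeddings
  N <- length(embeddings)
  if (N < 2L) stop("at least 2 embeddings required")
  vals <- numeric(0)
  for (u in seq_len(N - 1L)) {
    for (v in seq((u + 1L), N)) {
      vals <- c(vals, pairwiseClusterSimilarity(
        embeddings[[u]], embeddings[[v]], k = k, seed = seed,
        indexU = u, indexV = v
      ))
    }
  }
  mean(vals)
}
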