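#' Patterson-scale a dosage matrix
#'
#' Centers each SNP column and divides by the binomial standard deviation
#' sqrt(p(1-p)) implied by the estimated allele frequency p = mean/2 — the
#' normalization used for genotype PCA in population genetics.  Columns with
#' zero variance (monomorphic after imputation) are mapped to all-zeros.
#'
#' @param d numeric M x K matrix with no missing values.
#' @param center optional pre-computed column means (for scaling new
#'   individuals with the fit-set statistics).
#' @return list with the scaled matrix `x`, column means `mu` and the scale
#'   divisor `sd` (0 marks a dropped, zero-variance column).
#' @keywords internal
pattersonScale <- function(d, center = NULL) {
  mu <- if (is.null(center)) colMeans(d) else center
  p <- mu / 2
  denom <- sqrt(p * (1 - p))
  colVar <- matrixStats_colVars(d)
  drop <- denom <= 0 | colVar <= .Machine$double.eps
  denom[drop] <- 0
  x <- sweep(d, 2L, mu, "-")
  keep <- !drop
  if (any(keep)) x[, keep] <- sweep(x[, keep, drop = FALSE], 2L, denom[keep], "/")
  if (any(drop)) x[, drop] <- 0
  list(x = x, mu = mu, sd = denom)
}

# column variances without an extra dependency
matrixStats_colVars <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(rep(0, ncol(d)))
  (colSums(d^2) - n * colMeans(d)^2) / (n - 1)
}

#' PCA embedding of a genotype dataset
#'
#' Computes principal-component scores of the mean-imputed, Patterson-scaled
#' dosage matrix.  Individuals listed in `projectIds` are excluded from the
#' fit (the typical use being low-coverage ancient samples) and afterwards
#' placed on the embedding by least-squares projection of their observed,
#' fit-set-scaled genotypes onto the SNP loadings — the analogue of
#' smartpca's least-squares projection mode.
#'
#' Scores are deterministic: the sign of each component is fixed so that its
#' largest-magnitude SNP loading is positive.
#'
#' @param x a [GenotypeData-class] object.
#' @param nComponents number of components (default 10, the standard choice
#'   for genotype data).
#' @param projectIds character vector of individual ids to project rather
#'   than fit.
#' @return a [GenotypeEmbedding-class] with one row per individual (fit
#'   individuals first order preserved; projected individuals stay in their
#'   original positions) and `explainedVariance` filled with the top
#'   eigenvalue ratios.
#' @examples
#' g <- simulateGenotypes(nPopulations = 2, nPerPopulation = 10,
#'                        nSnps = 200, divergenceFst = 0.2, seed = 1)
#' e <- pcaEmbed(g, nComponents = 2)
#' head(coords(e))
#' @export
pcaEmbed <- function(x, nComponents = 10L, projectIds = character(0)) {
  stopifnot(is(x, "GenotypeData"))
  ids <- x@individualIds
  unknown <- setdiff(projectIds, ids)
  if (length(unknown)) {
    stop("projectIds not found in dataset: ", paste(unknown, collapse = ", "))
  }
  isProj <- ids %in% projectIds
  Mfit <- sum(!isProj)
  if (Mfit < 2L) stop("fewer than 2 individuals remain to fit the PCA")
  K <- ncol(x@dosages)
  maxComp <- min(Mfit - 1L, K)
  if (nComponents > maxComp) {
    stop(sprintf("nComponents = %d exceeds min(M_fit - 1, K) = %d",
                 nComponents, maxComp))
  }

  fit <- meanImpute(x@dosages[!isProj, , drop = FALSE])
  sc <- pattersonScale(fit)
  X <- sc$x

  # eigendecomposition through the M x M cross-product (K >> M in genotype
  # data); eigenvalues of the sample covariance are d^2 / (M - 1)
  G <- tcrossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  total <- sum(evals)
  dvals <- sqrt(evals[seq_len(nComponents)])
  U <- eg$vectors[, seq_len(nComponents), drop = FALSE]
  scores <- U * rep(dvals, each = Mfit)

  # loadings V = X' U D^{-1}; needed for the sign convention and projection
  pos <- dvals > sqrt(.Machine$double.eps)
  V <- matrix(0, nrow = K, ncol = nComponents)
  if (any(pos)) {
    V[, pos] <- crossprod(X, U[, pos, drop = FALSE]) %*%
      diag(1 / dvals[pos], nrow = sum(pos))
  }
  # fixed sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(nComponents)) {
    lj <- V[, j]
    if (length(lj) && lj[which.max(abs(lj))] < 0) {
      V[, j] <- -lj
      scores[, j] <- -scores[, j]
    }
  }

  coordsAll <- matrix(NA_real_, nrow = length(ids), ncol = nComponents)
  coordsAll[!isProj, ] <- scores
  if (any(isProj)) {
    projRows <- which(isProj)
    rawProj <- x@dosages[projRows, , drop = FALSE]
    for (r in seq_along(projRows)) {
      obs <- !is.na(rawProj[r, ]) & sc$sd > 0
      if (!any(obs)) {
        coordsAll[projRows[r], ] <- 0
        next
      }
      z <- (rawProj[r, obs] - sc$mu[obs]) / sc$sd[obs]
      A <- V[obs, , drop = FALSE]
      coordsAll[projRows[r], ] <- qr.coef(qr(A), z)
    }
    coordsAll[is.na(coordsAll)] <- 0  # rank-deficient projection components
  }
  rownames(coordsAll) <- ids
  colnames(coordsAll) <- paste0("PC", seq_len(nComponents))
  ev <- if (total > 0) evals[seq_len(nComponents)] / total else rep(0, nComponents)
  new("GenotypeEmbedding", coords = coordsAll, level = "individual",
      explainedVariance = ev)
}
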