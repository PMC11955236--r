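#' Metric MDS by SMACOF stress majorization
#'
#' Embeds a pairwise distance matrix in `nComponents` dimensions by
#' minimizing raw stress (sum of squared differences between target and
#' embedded Euclidean distances) with the SMACOF majorization (Guttman
#' transform) update.  The configuration is initialized deterministically
#' from classical (Torgerson) scaling, so repeated runs are bit-identical;
#' majorization guarantees the final stress never exceeds the stress of that
#' initialization.
#'
#' @param x a [GenotypeDistances-class] object (or a symmetric numeric matrix
#'   with row names).
#' @param nComponents embedding dimensionality (default 2, the standard
#'   choice for MDS of genotype data).
#' @param maxIter iteration cap for the majorization loop.
#' @param tol relative stress-decrease tolerance for termination.
#' @return a [GenotypeEmbedding-class]; `explainedVariance` is left empty
#'   (not defined for MDS).
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' mdsEmbed(d, nComponents = 2)
#' @export
mdsEmbed <- function(x, nComponents = 2L, maxIter = 300L, tol = 1e-10) {
  if (is(x, "GenotypeDistances")) {
    delta <- x@values
    level <- x@level
  } else {
    delta <- as.matrix(x)
    level <- "individual"
    if (is.null(rownames(delta))) {
      stop("distance matrix must carry row names")
    }
    if (nrow(delta) != ncol(delta) || any(abs(delta - t(delta)) > 1e-12)) {
      stop("distance matrix must be square and symmetric")
    }
    if (any(diag(delta) != 0) || any(delta < 0)) {
      stop("distance matrix must have a zero diagonal and nonnegative entries")
    }
  }
  R <- nrow(delta)
  if (nComponents > R - 1L) {
    stop(sprintf("nComponents = %d exceeds R - 1 = %d", nComponents, R - 1L))
  }
  labels <- rownames(delta)

  if (all(delta == 0)) {
    cc <- matrix(0, R, nComponents, dimnames = list(labels, NULL))
    colnames(cc) <- paste0("MDS", seq_len(nComponents))
    return(new("GenotypeEmbedding", coords = cc, level = level,
               explainedVariance = numeric(0)))
  }

  # Torgerson initialization
  X <- suppressWarnings(stats::cmdscale(delta, k = nComponents))
  if (ncol(X) < nComponents) {
    X <- cbind(X, matrix(0, R, nComponents - ncol(X)))
  }

  stress <- function(X) {
    dX <- as.matrix(stats::dist(X))
    sum((delta[upper.tri(delta)] - dX[upper.tri(dX)])^2)
  }
  sOld <- stress(X)
  for (it in seq_len(maxIter)) {
    dX <- as.matrix(stats::dist(X))
    ratio <- ifelse(dX > 0, delta / dX, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / R  # Guttman transform
    sNew <- stress(X)
    if (sOld - sNew <= tol * max(sOld, .Machine$double.eps)) {
      sOld <- sNew
      break
    }
    sOld <- sNew
  }
  rownames(X) <- labels
  colnames(X) <- paste0("MDS", seq_len(nComponents))
  new("GenotypeEmbedding", coords = X, level = level,
      explainedVariance = numeric(0))
}
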