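#' Standardize an embedding for Procrustes comparison
#'
#' Centers the configuration at the origin and rescales it so that
#' `trace(P P') = 1` (unit Frobenius norm).  Both steps are required before
#' computing the disparity so that translation and global size never
#' contribute to it, and so the disparity is bounded by \[0, 1\].
#'
#' @param x a [GenotypeEmbedding-class] or a numeric coordinate matrix with
#'   row names.
#' @return the standardized object of the same type.
#' @export
standardizeEmbedding <- function(x) {
  if (is(x, "GenotypeEmbedding")) {
    out <- x
    out@coords <- standardizeCoords(x@coords)
    return(out)
  }
  standardizeCoords(as.matrix(x))
}

standardizeCoords <- function(cc) {
  ctr <- sweep(cc, 2L, colMeans(cc), "-")
  nrm <- sqrt(sum(ctr^2))
  if (nrm <= 0) {
    stop("degenerate embedding: all points identical (zero norm after centering)")
  }
  ctr / nrm
}

#' Procrustes disparity between two embeddings
#'
#' Both embeddings are standardized (centered, unit Frobenius norm), then the
#' optimal similarity transform — orthogonal rotation/reflection plus a
#' positive scale — mapping the first onto the second is obtained in closed
#' form from the SVD of the cross-product matrix.  The disparity is the
#' squared Frobenius norm of the residual, `1 - (sum of singular values)^2`,
#' which lies in \[0, 1\]: 0 means the configurations are identical up to a
#' similarity transform, 1 means no agreement at all.  The similarity score
#' is `1 - disparity`.
#'
#' @param u,v [GenotypeEmbedding-class] objects (or coordinate matrices) of
#'   identical shape with identical row labels in identical order.
#' @return a [ProcrustesComparison-class] holding disparity, similarity and
#'   the fitted transform.
#' @examples
#' cc <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
#' disparity(procrustesDisparity(cc, cc))  # exact copy -> 0
#' @export
procrustesDisparity <- function(u, v) {
  cu <- if (is(u, "GenotypeEmbedding")) u@coords else as.matrix(u)
  cv <- if (is(v, "GenotypeEmbedding")) v@coords else as.matrix(v)
  if (!identical(dim(cu), dim(cv))) {
    stop(sprintf("embedding shapes differ: %dx%d vs %dx%d",
                 nrow(cu), ncol(cu), nrow(cv), ncol(cv)))
  }
  lu <- rownames(cu); lv <- rownames(cv)
  if (!is.null(lu) || !is.null(lv)) {
    if (is.null(lu) || is.null(lv) || !identical(lu, lv)) {
      first <- which(lu != lv)[1L]
      stop(sprintf(
        "row labels differ between embeddings (first mismatch at row %s: '%s' vs '%s')",
        ifelse(is.na(first), "?", first),
        if (!is.na(first)) lu[first] else "<none>",
        if (!is.na(first)) lv[first] else "<none>"
      ))
    }
  }
  muU <- colMeans(cu); muV <- colMeans(cv)
  X <- standardizeCoords(cu)
  Y <- standardizeCoords(cv)
  sv <- svd(crossprod(X, Y))
  Q <- sv$u %*% t(sv$v)          # orthogonal map (may include a reflection)
  sigma <- sum(sv$d)             # optimal scale; also trace of the aligned fit
  disp <- max(0, min(1, 1 - sigma^2))
  new("ProcrustesComparison",
      disparity = disp,
      similarity = 1 - disp,
      scale = sigma,
      rotation = Q,
      translation = as.numeric(muV - muU))
}

#' Apply the fitted Procrustes transform to a standardized configuration
#' @keywords internal
applyProcrustes <- function(X, comparison) {
  (X %*% comparison@rotation) * comparison@scale
}

#' Overall embedding stability across bootstrap replicates
#'
#' Averages the pairwise Procrustes similarity `1 - disparity` over all
#' N(N-1)/2 unordered pairs of replicate embeddings.  The score lies in
#' \[0, 1\]; it is 1 exactly when every pair of replicates projects all
#' individuals identically (up to similarity transforms).
#'
#' @param embeddings a list of label-compatible [GenotypeEmbedding-class]
#'   objects, or a [BootstrapEmbeddings-class].
#' @return a single stability score in \[0, 1\].
#' @export
embeddingStability <- function(embeddings) {
  if (is(embeddings, "BootstrapEmbeddings")) embeddings <- embeddings@embeddings
  N <- length(embeddings)
  if (N < 2L) stop("at least 2 embeddings required")
  sims <- pairwiseSimilarityMatrix(embeddings)
  mean(sims[upper.tri(sims)])
}

# symmetric N x N matrix of pairwise Procrustes similarities; diagonal 1
pairwiseSimilarityMatrix <- function(embeddings) {
  N <- length(embeddings)
  mats <- lapply(embeddings, function(e) {
    standardizeCoords(if (is(e, "GenotypeEmbedding")) e@coords else as.matrix(e))
  })
  s <- diag(1, N)
  for (u in seq_len(N - 1L)) {
    for (v in seq((u + 1L), N)) {
      sigma <- sum(svd(crossprod(mats[[u]], mats[[v]]))$d)
      s[u, v] <- s[v, u] <- max(0, min(1, sigma^2))
    }
  }
  s
}
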