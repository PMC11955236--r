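#' @import methods
NULL

#' GenotypeData: biallelic SNP genotypes for a set of individuals
#'
#' Container for an M x K matrix of biallelic genotype dosages (rows =
#' individuals, columns = SNPs).  Each entry counts the reference allele, so
#' it is 0, 1 or 2; missing genotypes are stored as `NA`.  Individual and SNP
#' metadata travel with the matrix.
#'
#' @slot dosages numeric M x K matrix with entries in \{0, 1, 2\} or `NA`
#'   (missing).
#' @slot individualIds character vector of M unique individual identifiers.
#' @slot populations character vector of M population labels; `""` when
#'   unknown.
#' @slot snpIds character vector of K SNP identifiers.
#' @slot snpChrom character vector of K chromosome labels, or length 0 when
#'   no positional metadata is available.
#' @slot snpPos numeric vector of K 1-based physical positions, or length 0.
#'
#' @seealso [genotypeMatrix()], [readEigenstrat()], [readPlinkPed()],
#'   [simulateGenotypes()]
#' @exportClass GenotypeData
setClass("GenotypeData",
  slots = c(
    dosages       = "matrix",
    individualIds = "character",
    populations   = "character",
    snpIds        = "character",
    snpChrom      = "character",
    snpPos        = "numeric"
  )
)

setValidity("GenotypeData", function(object) {
  d <- object@dosages
  msgs <- character(0)
  if (!is.numeric(d)) {
    msgs <- c(msgs, "dosages must be a numeric matrix")
  } else {
    if (nrow(d) < 2L) msgs <- c(msgs, "at least 2 individuals required")
    if (ncol(d) < 1L) msgs <- c(msgs, "at least 1 SNP required")
    obs <- d[!is.na(d)]
    if (length(obs) && !all(obs %in% c(0, 1, 2))) {
      msgs <- c(msgs, "non-missing dosages must be 0, 1 or 2")
    }
  }
  if (length(object@individualIds) != nrow(d)) {
    msgs <- c(msgs, "individualIds length must equal nrow(dosages)")
  }
  if (anyDuplicated(object@individualIds)) {
    msgs <- c(msgs, "individualIds must be unique")
  }
  if (length(object@populations) != nrow(d)) {
    msgs <- c(msgs, "populations length must equal nrow(dosages)")
  }
  if (length(object@snpIds) != ncol(d)) {
    msgs <- c(msgs, "snpIds length must equal ncol(dosages)")
  }
  if (length(object@snpChrom) && length(object@snpChrom) != ncol(d)) {
    msgs <- c(msgs, "snpChrom must be empty or length ncol(dosages)")
  }
  if (length(object@snpPos) && length(object@snpPos) != ncol(d)) {
    msgs <- c(msgs, "snpPos must be empty or length ncol(dosages)")
  }
  if (length(msgs)) msgs else TRUE
})

#' GenotypeEmbedding: a low-dimensional PCA or MDS configuration
#'
#' Holds the R x D coordinate matrix produced by [pcaEmbed()] or [mdsEmbed()].
#' Rows are individuals (or populations, for population-level MDS); row names
#' carry the labels.  PCA embeddings additionally record the proportion of
#' variance explained per component.
#'
#' @slot coords numeric R x D matrix with unique row names.
#' @slot level `"individual"` or `"population"`.
#' @slot explainedVariance numeric vector of length D (PCA) or 0 (MDS);
#'   non-increasing.
#'
#' @exportClass GenotypeEmbedding
setClass("GenotypeEmbedding",
  slots = c(
    coords            = "matrix",
    level             = "character",
    explainedVariance = "numeric"
  )
)

setValidity("GenotypeEmbedding", function(object) {
  msgs <- character(0)
  cc <- object@coords
  if (!is.numeric(cc)) msgs <- c(msgs, "coords must be numeric")
  if (nrow(cc) < 2L) msgs <- c(msgs, "an embedding needs at least 2 rows")
  if (ncol(cc) < 1L) msgs <- c(msgs, "an embedding needs at least 1 dimension")
  if (is.null(rownames(cc))) {
    msgs <- c(msgs, "coords must have row names (labels)")
  } else if (anyDuplicated(rownames(cc))) {
    msgs <- c(msgs, "row labels must be unique")
  }
  if (!object@level %in% c("individual", "population")) {
    msgs <- c(msgs, "level must be 'individual' or 'population'")
  }
  ev <- object@explainedVariance
  if (length(ev)) {
    if (length(ev) != ncol(cc)) {
      msgs <- c(msgs, "explainedVariance must match the number of components")
    }
    if (any(ev < -1e-12)) msgs <- c(msgs, "explainedVariance must be nonnegative")
    if (is.unsorted(rev(ev), strictly = FALSE)) {
      msgs <- c(msgs, "explainedVariance must be non-increasing")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' GenotypeDistances: a symmetric pairwise distance matrix
#'
#' Square symmetric nonnegative matrix with zero diagonal, as consumed by
#' [mdsEmbed()].  Row/column names are individual ids or population names.
#'
#' @slot values numeric R x R symmetric matrix, zero diagonal.
#' @slot level `"individual"` or `"population"`.
#' @slot metric name of the distance metric used.
#'
#' @exportClass GenotypeDistances
setClass("GenotypeDistances",
  slots = c(values = "matrix", level = "character", metric = "character")
)

setValidity("GenotypeDistances", function(object) {
  v <- object@values
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (nrow(v) < 2L) msgs <- c(msgs, "need at least 2 rows")
  if (is.null(rownames(v))) {
    msgs <- c(msgs, "values must carry row names")
  }
  if (any(abs(v - t(v)) > 1e-12)) msgs <- c(msgs, "values must be symmetric")
  if (any(diag(v) != 0)) msgs <- c(msgs, "diagonal must be zero")
  if (any(v < 0)) msgs <- c(msgs, "distances must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' ProcrustesComparison: result of aligning one embedding onto another
#'
#' Records the disparity (minimal squared Frobenius residual after optimal
#' scaling, rotation/reflection and translation of standardized embeddings),
#' the similarity `1 - disparity`, and the fitted transform.
#'
#' @slot disparity squared Frobenius residual, in \[0, 1\].
#' @slot similarity `1 - disparity`.
#' @slot scale positive scaling factor applied to the first embedding.
#' @slot rotation D x D orthogonal matrix (may include a reflection).
#' @slot translation length-D vector: shift applied after rotation/scaling
#'   (difference of the centroids removed during standardization).
#'
#' @exportClass ProcrustesComparison
setClass("ProcrustesComparison",
  slots = c(
    disparity   = "numeric",
    similarity  = "numeric",
    scale       = "numeric",
    rotation    = "matrix",
    translation = "numeric"
  )
)

setValidity("ProcrustesComparison", function(object) {
  msgs <- character(0)
  if (abs(object@similarity - (1 - object@disparity)) > 1e-12) {
    msgs <- c(msgs, "similarity must equal 1 - disparity")
  }
  Q <- object@rotation
  if (nrow(Q) == ncol(Q)) {
    if (max(abs(crossprod(Q) - diag(ncol(Q)))) > 1e-6) {
      msgs <- c(msgs, "rotation must be orthogonal")
    }
  } else {
    msgs <- c(msgs, "rotation must be square")
  }
  if (length(msgs)) msgs else TRUE
})

#' BootstrapEmbeddings: embeddings of SNP-bootstrap replicates
#'
#' The output of [runBootstrap()]: one embedding per computed bootstrap
#' replicate (all sharing row labels and dimensionality), together with the
#' convergence status of the run.
#'
#' @slot embeddings list of [GenotypeEmbedding-class] objects.
#' @slot converged logical; `TRUE` when the run stopped early because the
#'   subset-stability spread fell below the tolerance.
#' @slot nComputed number of replicate embeddings retained.
#' @slot seed master seed of the run.
#'
#' @exportClass BootstrapEmbeddings
setClass("BootstrapEmbeddings",
  slots = c(
    embeddings = "list",
    converged  = "logical",
    nComputed  = "integer",
    seed       = "integer"
  )
)

setValidity("BootstrapEmbeddings", function(object) {
  msgs <- character(0)
  if (length(object@embeddings) != object@nComputed) {
    msgs <- c(msgs, "nComputed must equal length(embeddings)")
  }
  if (length(object@embeddings)) {
    if (!all(vapply(object@embeddings, is, logical(1), "GenotypeEmbedding"))) {
      msgs <- c(msgs, "embeddings must all be GenotypeEmbedding objects")
    } else {
      labs <- lapply(object@embeddings, function(e) rownames(e@coords))
      dims <- vapply(object@embeddings, function(e) ncol(e@coords), integer(1))
      if (length(unique(dims)) > 1L) {
        msgs <- c(msgs, "all embeddings must share the same dimensionality")
      }
      if (!all(vapply(labs, identical, logical(1), labs[[1]]))) {
        msgs <- c(msgs, "all embeddings must share identical row labels")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' StabilityResult: the full stability report of one analysis
#'
#' @slot stability overall embedding stability score (mean pairwise Procrustes
#'   similarity across bootstrap replicates), in \[0, 1\].
#' @slot clusterStab cluster stability score (mean pairwise Fowlkes-Mallows
#'   agreement of k-means clusterings), in \[0, 1\]; `NA` when clustering was
#'   skipped.
#' @slot k number of k-means clusters used; `NA` when clustering was skipped.
#' @slot support named numeric vector of per-row bootstrap support values.
#' @slot nReplicates number of bootstrap replicates used.
#' @slot converged logical convergence flag of the bootstrap run.
#' @slot seed master seed.
#'
#' @exportClass StabilityResult
setClass("StabilityResult",
  slots = c(
    stability   = "numeric",
    clusterStab = "numeric",
    k           = "integer",
    support     = "numeric",
    nReplicates = "integer",
    converged   = "logical",
    seed        = "integer"
  )
)
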