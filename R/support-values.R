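#' Align bootstrap embeddings into a common frame
#'
#' Standardizes every embedding and Procrustes-transforms embeddings 2..N
#' onto the first, so that per-row coordinates are comparable across
#' replicates.  Without this step arbitrary axis sign flips and rotations
#' between replicates would dominate any per-row dispersion measure.
#'
#' @param embeddings list of label-compatible [GenotypeEmbedding-class]
#'   objects, or a [BootstrapEmbeddings-class].
#' @return list of aligned [GenotypeEmbedding-class] objects (a single
#'   embedding is returned unchanged apart from standardization).
#' @export
alignToReference <- function(embeddings) {
  if (is(embeddings, "BootstrapEmbeddings")) embeddings <- embeddings@embeddings
  if (length(embeddings) == 1L) return(embeddings)
  ref <- standardizeEmbedding(embeddings[[1L]])
  out <- vector("list", length(embeddings))
  out[[1L]] <- ref
  for (i in seq_along(embeddings)[-1L]) {
    comp <- procrustesDisparity(embeddings[[i]], ref)
    e <- embeddings[[i]]
    aligned <- applyProcrustes(standardizeCoords(e@coords), comp)
    rownames(aligned) <- rownames(e@coords)
    colnames(aligned) <- colnames(ref@coords)
    e@coords <- aligned
    out[[i]] <- e
  }
  out
}

#' Per-row bootstrap support values
#'
#' For each row (individual or population) the dispersion of its projections
#' across the N aligned replicates is measured by the Gini-type ratio
#' `g_i = sum over replicate pairs of ||x_i^u - x_i^v|| / (N * sum over
#' replicates of ||x_i^u||)`; the support value is `1 - g_i`, clamped to
#' \[0, 1\].  A support of 1 means the row is projected identically in every
#' replicate; low values flag "rogue" rows whose placement in the embedding
#' should not be trusted.  A row whose projection is zero in every replicate
#' has an undefined ratio (0/0) and is assigned support 1 with a warning.
#'
#' @param embeddings aligned, label-compatible embeddings, e.g. the output
#'   of [alignToReference()]; a [BootstrapEmbeddings-class] is aligned
#'   automatically.
#' @param align logical; run [alignToReference()] first (default `TRUE`).
#' @return named numeric vector of support values in \[0, 1\], one per row
#'   label.
#' @examples
#' cc1 <- matrix(c(1, 2, 3, 0, 0, 0), 3, 2, dimnames = list(letters[1:3], NULL))
#' e <- new("GenotypeEmbedding", coords = cc1, level = "individual",
#'          explainedVariance = numeric(0))
#' supportValues(list(e, e))  # identical replicates -> all 1
#' @export
supportValues <- function(embeddings, align = TRUE) {
  if (is(embeddings, "BootstrapEmbeddings")) embeddings <- embeddings@embeddings
  N <- length(embeddings)
  if (N < 2L) stop("at least 2 embeddings required")
  if (align) embeddings <- alignToReference(embeddings)
  mats <- lapply(embeddings, function(e) {
    if (is(e, "GenotypeEmbedding")) e@coords else as.matrix(e)
  })
  labels <- rownames(mats[[1L]])
  R <- nrow(mats[[1L]])
  g <- numeric(R)
  normSum <- numeric(R)
  for (u in seq_len(N)) {
    normSum <- normSum + sqrt(rowSums(mats[[u]]^2))
  }
  for (u in seq_len(N - 1L)) {
    for (v in seq((u + 1L), N)) {
      g <- g + sqrt(rowSums((mats[[u]] - mats[[v]])^2))
    }
  }
  denom <- N * normSum
  psv <- 1 - g / denom
  zero <- denom == 0
  if (any(zero)) {
    warning(sprintf(
      "%d row(s) have all-zero projections across replicates; support set to 1",
      sum(zero)
    ))
    psv[zero] <- 1
  }
  psv <- pmin(pmax(psv, 0), 1)
  names(psv) <- labels
  psv
}

#' Write support values as TSV
#'
#' Two columns (`row_label`, `support`), sorted ascending by support so the
#' least stable rows come first.
#'
#' @param psv named numeric vector as returned by [supportValues()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeSupportValues <- function(psv, path) {
  ord <- order(psv)
  utils::write.table(
    data.frame(row_label = names(psv)[ord], support = unname(psv)[ord]),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
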