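#' Construct a GenotypeData object from a numeric matrix
#'
#' Generic in-memory ingestion: any numeric matrix with entries in \{0, 1, 2\}
#' plus a missing sentinel becomes a [GenotypeData-class].  The sentinel
#' (default `9`, the EIGENSTRAT convention) and `NA`/`NaN` entries are treated
#' as missing.
#'
#' @param table numeric matrix or data frame, individuals in rows, SNPs in
#'   columns.
#' @param individualIds character vector of row identifiers; synthesized as
#'   `ind_0 ... ind_{M-1}` when `NULL`.
#' @param populations character vector of population labels; empty strings
#'   when `NULL`.
#' @param snpIds character vector of column identifiers; synthesized as
#'   `snp_0 ...` when `NULL`.
#' @param missingCode numeric sentinel marking missing genotypes.
#' @return a [GenotypeData-class] object.
#' @examples
#' g <- genotypeMatrix(rbind(c(0, 1), c(2, 9)))
#' missingMask(g)
#' @export
genotypeMatrix <- function(table, individualIds = NULL, populations = NULL,
                           snpIds = NULL, missingCode = 9) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  m[is.nan(m)] <- NA_real_
  if (!is.na(missingCode)) m[!is.na(m) & m == missingCode] <- NA_real_
  bad <- !is.na(m) & !(m %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "genotype value %s at row %d, column %d is not in {0, 1, 2, %s}",
      format(m[bad][1L]), idx[1L], idx[2L], format(missingCode)
    ))
  }
  M <- nrow(m); K <- ncol(m)
  if (is.null(individualIds)) {
    individualIds <- if (!is.null(rownames(m))) rownames(m)
                     else paste0("ind_", seq_len(M) - 1L)
  }
  if (is.null(populations)) populations <- rep("", M)
  if (is.null(snpIds)) {
    snpIds <- if (!is.null(colnames(m))) colnames(m)
              else paste0("snp_", seq_len(K) - 1L)
  }
  dimnames(m) <- NULL
  new("GenotypeData",
      dosages = m,
      individualIds = as.character(individualIds),
      populations = as.character(populations),
      snpIds = as.character(snpIds),
      snpChrom = character(0), snpPos = numeric(0))
}

newGenotypeData <- function(dosages, individualIds, populations, snpIds,
                            snpChrom = character(0), snpPos = numeric(0)) {
  dimnames(dosages) <- NULL
  new("GenotypeData",
      dosages = dosages,
      individualIds = as.character(individualIds),
      populations = as.character(populations),
      snpIds = as.character(snpIds),
      snpChrom = as.character(snpChrom), snpPos = as.numeric(snpPos))
}

#' Read an EIGENSTRAT text triplet
#'
#' Parses the text EIGENSTRAT dialect: a `.geno` file with one line per SNP
#' and one character per individual (`0`/`1`/`2` dosage, `9` missing), a
#' `.snp` file with one metadata line per SNP (id, chromosome, genetic
#' position, physical position, alleles), and a `.ind` file with one line per
#' individual (id, sex, population).
#'
#' @param genoPath,snpPath,indPath file paths; alternatively give a common
#'   `prefix` and the three extensions are appended.
#' @param prefix common path prefix (used when the three paths are missing).
#' @return a [GenotypeData-class] object with populations taken from the
#'   `.ind` file.
#' @seealso [writeEigenstrat()] for the inverse operation.
#' @export
readEigenstrat <- function(prefix = NULL, genoPath = NULL, snpPath = NULL,
                           indPath = NULL) {
  if (!is.null(prefix)) {
    if (is.null(genoPath)) genoPath <- paste0(prefix, ".geno")
    if (is.null(snpPath))  snpPath  <- paste0(prefix, ".snp")
    if (is.null(indPath))  indPath  <- paste0(prefix, ".ind")
  }
  genoLines <- readLines(genoPath)
  genoLines <- genoLines[nzchar(genoLines)]
  indLines <- readLines(indPath)
  indLines <- indLines[nzchar(trimws(indLines))]
  snpLines <- readLines(snpPath)
  snpLines <- snpLines[nzchar(trimws(snpLines))]

  K <- length(genoLines)
  M <- length(indLines)
  if (K != length(snpLines)) {
    stop(sprintf(
      "EIGENSTRAT format error: %d .geno lines but %d .snp lines",
      K, length(snpLines)
    ))
  }
  widths <- nchar(genoLines)
  if (any(widths != M)) {
    bad <- which(widths != M)[1L]
    stop(sprintf(
      "EIGENSTRAT format error: .geno line %d has %d characters, expected %d (.ind lines)",
      bad, widths[bad], M
    ))
  }
  chars <- matrix(unlist(strsplit(genoLines, "", fixed = TRUE), use.names = FALSE),
                  nrow = M, ncol = K)
  ok <- matrix(chars %in% c("0", "1", "2", "9"), nrow = M, ncol = K)
  if (!all(ok)) {
    badIdx <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "EIGENSTRAT format error: invalid character '%s' in .geno line %d",
      chars[!ok][1L], badIdx[2L]
    ))
  }
  d <- matrix(as.numeric(chars), nrow = M, ncol = K)
  d[d == 9] <- NA_real_

  indFields <- strsplit(trimws(indLines), "\\s+")
  ids <- vapply(indFields, `[`, character(1), 1L)
  pops <- vapply(indFields, function(f) if (length(f) >= 3L) f[3L] else "",
                 character(1))
  snpFields <- strsplit(trimws(snpLines), "\\s+")
  sid <- vapply(snpFields, `[`, character(1), 1L)
  chrom <- vapply(snpFields, function(f) if (length(f) >= 2L) f[2L] else "0",
                  character(1))
  pos <- vapply(snpFields, function(f) {
    if (length(f) >= 4L) suppressWarnings(as.numeric(f[4L])) else NA_real_
  }, numeric(1))
  newGenotypeData(d, ids, pops, sid, chrom, pos)
}

#' Write an EIGENSTRAT text triplet
#'
#' @param x a [GenotypeData-class] object.
#' @param prefix output path prefix; `.geno`, `.snp` and `.ind` are appended.
#' @return invisibly, the three file paths.
#' @export
writeEigenstrat <- function(x, prefix) {
  stopifnot(is(x, "GenotypeData"))
  d <- x@dosages
  codes <- d
  codes[is.na(codes)] <- 9
  # .geno: one line per SNP, one character per individual
  genoLines <- apply(codes, 2L, function(col) paste(as.integer(col), collapse = ""))
  chrom <- if (length(x@snpChrom)) x@snpChrom else rep("1", ncol(d))
  pos <- if (length(x@snpPos)) x@snpPos else seq_len(ncol(d))
  pos[is.na(pos)] <- 0
  snpLines <- sprintf("%s\t%s\t%.6f\t%d\tA\tC",
                      x@snpIds, chrom, 0, as.integer(pos))
  pops <- ifelse(nzchar(x@populations), x@populations, "???")
  indLines <- sprintf("%s\tU\t%s", x@individualIds, pops)
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  writeLines(genoLines, paths[1L])
  writeLines(snpLines, paths[2L])
  writeLines(indLines, paths[3L])
  invisible(paths)
}

#' Read PLINK text pedigree files (.ped/.map)
#'
#' Decodes a PLINK 1.x text pedigree pair into genotype dosages.  Per SNP,
#' the two most frequent non-missing allele symbols define the biallelic
#' pair, the dosage counts the alphabetically-first allele of that pair, and
#' `0 0` denotes a missing genotype.  Decoding is unordered in the two allele
#' columns.  The family id column is used as the population label.
#'
#' @param pedPath path to the `.ped` file (6 leading columns, then 2K allele
#'   columns).
#' @param mapPath path to the `.map` file (chromosome, SNP id, genetic
#'   position, physical position).
#' @return a [GenotypeData-class] object.
#' @export
readPlinkPed <- function(pedPath, mapPath) {
  mapLines <- readLines(mapPath)
  mapLines <- mapLines[nzchar(trimws(mapLines))]
  mapFields <- strsplit(trimws(mapLines), "\\s+")
  K <- length(mapFields)
  sid <- vapply(mapFields, function(f) if (length(f) >= 2L) f[2L] else f[1L],
                character(1))
  chrom <- vapply(mapFields, `[`, character(1), 1L)
  pos <- vapply(mapFields, function(f) {
    if (length(f) >= 4L) suppressWarnings(as.numeric(f[4L])) else NA_real_
  }, numeric(1))

  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  M <- length(pedLines)
  fields <- strsplit(trimws(pedLines), "\\s+")
  nAllele <- lengths(fields) - 6L
  if (any(nAllele != 2L * K)) {
    bad <- which(nAllele != 2L * K)[1L]
    if (nAllele[bad] %% 2L == 1L) {
      stop(sprintf(".ped format error: line %d has an odd allele-column count (%d)",
                   bad, nAllele[bad]))
    }
    stop(sprintf(
      ".ped format error: line %d has %d allele columns, expected %d (2 x %d SNPs)",
      bad, nAllele[bad], 2L * K, K
    ))
  }
  fam <- vapply(fields, `[`, character(1), 1L)
  ids <- vapply(fields, `[`, character(1), 2L)
  if (anyDuplicated(ids)) ids <- paste(fam, ids, sep = ":")
  alleles <- t(vapply(fields, function(f) f[-seq_len(6L)], character(2L * K)))

  d <- matrix(NA_real_, nrow = M, ncol = K)
  for (s in seq_len(K)) {
    a1 <- alleles[, 2L * s - 1L]
    a2 <- alleles[, 2L * s]
    halfMissing <- xor(a1 == "0", a2 == "0")
    if (any(halfMissing)) {
      stop(sprintf(
        ".ped format error: half-missing genotype for SNP '%s' (individual '%s')",
        sid[s], ids[which(halfMissing)[1L]]
      ))
    }
    obs <- c(a1[a1 != "0"], a2[a2 != "0"])
    symbols <- sort(unique(obs))
    if (length(symbols) > 2L) {
      stop(sprintf(
        ".ped format error: SNP '%s' has %d distinct alleles (%s); biallelic data required",
        sid[s], length(symbols), paste(symbols, collapse = ", ")
      ))
    }
    if (length(symbols) == 0L) next  # all missing at this SNP
    ref <- symbols[1L]  # alphabetically-first allele of the observed pair
    nonMissing <- a1 != "0"
    d[nonMissing, s] <- (a1[nonMissing] == ref) + (a2[nonMissing] == ref)
  }
  newGenotypeData(d, ids, fam, sid, chrom, pos)
}

#' Read a genotype matrix from delimited text
#'
#' Expects a TSV/CSV table of 0/1/2 dosages with an optional header row of
#' individual ids (table transposed relative to [GenotypeData-class]: SNPs in
#' rows is NOT assumed — rows are individuals) and an optional leading
#' `population` column.  Empty cells, `NA` and the sentinel are missing.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param header logical; first row holds column (SNP) names.
#' @param missingCode missing sentinel (default 9).
#' @return a [GenotypeData-class] object.
#' @export
readGenotypeTable <- function(path, sep = "\t", header = TRUE, missingCode = 9) {
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           row.names = NULL, na.strings = c("NA", ""))
  ids <- NULL
  pops <- NULL
  first <- names(tab)[1L]
  if (!is.null(first) && tolower(first) %in% c("id", "individual", "individual_id")) {
    ids <- as.character(tab[[1L]])
    tab <- tab[-1L]
  }
  popCol <- which(tolower(names(tab)) == "population")
  if (length(popCol)) {
    pops <- as.character(tab[[popCol[1L]]])
    tab <- tab[-popCol[1L]]
  }
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  genotypeMatrix(m, individualIds = ids, populations = pops,
                 snpIds = if (header) colnames(tab) else NULL,
                 missingCode = missingCode)
}

#' Write a genotype matrix as delimited text
#'
#' Inverse of [readGenotypeTable()]: writes an `id` column, a `population`
#' column and one 0/1/2 column per SNP, with missing genotypes as the
#' sentinel.
#'
#' @param x a [GenotypeData-class] object.
#' @param path output file path.
#' @param sep field separator.
#' @param missingCode sentinel written for missing genotypes.
#' @return invisibly, `path`.
#' @export
writeGenotypeTable <- function(x, path, sep = "\t", missingCode = 9) {
  d <- x@dosages
  d[is.na(d)] <- missingCode
  df <- data.frame(id = x@individualIds, population = x@populations,
                   check.names = FALSE, stringsAsFactors = FALSE)
  dm <- as.data.frame(d)
  names(dm) <- x@snpIds
  utils::write.table(cbind(df, dm), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing genotype by the mean of the observed dosages at the
#' same SNP.  A SNP with no observed genotype at all is filled with 0 and
#' reported via a warning (so bootstrap replicates that happen to resample
#' only missing-heavy columns never abort).
#'
#' @param x a [GenotypeData-class] object or a numeric matrix with `NA`s.
#' @return a numeric M x K matrix with no missing values; observed entries
#'   are unchanged.
#' @examples
#' g <- genotypeMatrix(rbind(c(0, 1), c(2, 9)))
#' meanImpute(g)
#' @export
meanImpute <- function(x) {
  d <- if (is(x, "GenotypeData")) x@dosages else as.matrix(x)
  if (!anyNA(d)) return(d)
  colMeansObs <- colMeans(d, na.rm = TRUE)
  allMissing <- is.nan(colMeansObs)
  if (any(allMissing)) {
    colMeansObs[allMissing] <- 0
    warning(sprintf(
      "%d SNP column(s) entirely missing; filled with 0: %s",
      sum(allMissing),
      paste(utils::head(which(allMissing), 5L), collapse = ", ")
    ))
  }
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- colMeansObs[idx[, 2L]]
  d
}
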