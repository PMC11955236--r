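Package: genostab
Title: Bootstrap Stability Estimation for PCA and MDS Embeddings of Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the uncertainty of principal component analysis (PCA) and
    multidimensional scaling (MDS) embeddings of biallelic SNP genotype datasets by
    bootstrapping over SNPs. Provides an overall embedding stability score (mean pairwise
    Procrustes similarity across bootstrap replicates), a k-means cluster stability score
    (mean pairwise Fowlkes-Mallows agreement of clusterings of Procrustes-matched
    replicates), and per-individual bootstrap support values (one minus the Gini dispersion
    of each individual's projections across replicates). Includes readers for EIGENSTRAT
    text and PLINK pedigree genotype formats, Patterson-scaled PCA with least-squares
    projection of designated individuals, Hudson FST / Euclidean / Manhattan / Hamming
    distance matrices, SMACOF metric MDS, a Balding-Nichols synthetic genotype generator
    with missingness and noise distortion protocols, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
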