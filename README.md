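# genostab

Bootstrap stability estimation for PCA and MDS embeddings of SNP genotype
data.

## The problem

Population-genetic and ancient-DNA studies routinely project an
individuals × SNPs genotype matrix (dosages 0/1/2, often with heavy
missingness) into two or ten dimensions with PCA or metric MDS, and then
read population structure, ancestry, or the placement of an ancient sample
off the plot. A single embedding, however, reports nothing about its own
uncertainty: missing and noisy genotypes can move individuals far across
the plot. genostab quantifies that uncertainty for anyone running such
analyses, by bootstrapping over SNPs — resampling the K loci with
replacement (loci, unlike individuals, are approximately independent),
embedding every replicate, and summarizing the dispersion among replicate
embeddings.

## The statistics

For replicate embeddings $P_u, P_v$ (standardized to centroid 0 and
$\mathrm{trace}(PP^\top)=1$), Procrustes analysis gives the disparity
$D_{u,v} = \lVert f(P_u) - P_v\rVert_F^2 \in [0,1]$ under the optimal
rotation/reflection/scale $f$, and three scores follow:

* **Embedding stability** — mean of $1 - D_{u,v}$ over all replicate
  pairs; 1 = all replicates project all individuals identically.
* **Cluster stability** — mean Fowlkes–Mallows agreement of independent
  k-means clusterings of Procrustes-matched replicate pairs ($k$ chosen by
  a BIC grid search when not supplied).
* **Support values** — per individual $i$,
  $1 - \sum_{u<v}\lVert x_i^u - x_i^v\rVert \,/\, (N \sum_u \lVert x_i^u\rVert)$
  on Procrustes-aligned replicates: a Gini-type dispersion flag for
  "rogue" individuals whose placement should not be trusted.

PCA is computed natively with Patterson scaling (per-SNP centering and
division by $\sqrt{\hat p(1-\hat p)}$), including least-squares projection
of designated (e.g. ancient) individuals onto an embedding fit on the rest.
MDS runs SMACOF stress majorization on Euclidean/Manhattan/Hamming
individual distances or Hudson FST population distances. Inputs: EIGENSTRAT
text triplets, PLINK text pedigree pairs, delimited tables, or in-memory
matrices. See `vignettes/stability-methods.Rmd` for the full model
description.

## Worked example

```r
library(genostab)

g <- simulateGenotypes(nPopulations = 3, nPerPopulation = 20, nSnps = 2000,
                       divergenceFst = 0.05, seed = 7)
g
#> GenotypeData: 60 individuals x 2000 SNPs (0.0% missing, 3 populations)

res <- analyzeStability(g, method = "pca", nComponents = 10, nMax = 50, seed = 7)
res
#> StabilityResult
#>   embedding stability : 0.5110
#>   cluster stability   : 1.0000 (k = 3)
#>   support values      : median 0.6183, min 0.5267 (pop_2:ind_9)
#>   replicates          : 12 (converged), seed 7
```

The embedding stability of 0.51 says that, averaged over replicate pairs,
about half the (standardized) configuration is reproducible under SNP
resampling — a moderately differentiated dataset ($F_{ST} = 0.05$) at only
2000 SNPs. The cluster stability of 1.0 says the three-population cluster
assignment itself is completely reproducible even though the fine
coordinates wobble. The least supported individual (`pop_2:ind_9`, 0.53) is
the one whose position swings most between replicates. Injecting 30% random
genotype noise into the same dataset drops the scores markedly:

```r
gn <- simulateGenotypes(nPopulations = 3, nPerPopulation = 20, nSnps = 2000,
                        divergenceFst = 0.05, noiseProportion = 0.3, seed = 7)
analyzeStability(gn, method = "pca", nComponents = 10, nMax = 50, seed = 7)
#> StabilityResult
#>   embedding stability : 0.3934
#>   cluster stability   : 0.4738 (k = 3)
#>   support values      : median 0.5573, min 0.4078 (pop_1:ind_3)
#>   replicates          : 11 (converged), seed 7
```

A command-line interface with `run` and `simulate` subcommands is installed
at `inst/scripts/genostab`:

```sh
Rscript inst/scripts/genostab simulate --populations 2 --per-population 50 \
    --snps 5000 --fst 0.1 --seed 7 --output-prefix sim
Rscript inst/scripts/genostab run --input sim --format eigenstrat \
    --analysis pca --seed 7 --output-dir out/
# out/report.json, out/support_values.tsv, out/run.log
```

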