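---
title: "Bootstrap stability of genotype embeddings: models and methods"
author: "genostab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap stability of genotype embeddings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genostab)
```

## The problem

PCA and MDS plots of SNP genotype matrices drive conclusions about
population structure, ancestry and the placement of ancient individuals,
yet a single embedding carries no estimate of its own sampling
uncertainty. Missing data (routinely 90%+ in ancient samples) and genotyping
noise can move individuals far across the plot without any visible warning.
genostab quantifies this uncertainty by a bootstrap over SNPs: loci, unlike
individuals, can reasonably be treated as approximately independent
observations, so resampling the K SNP columns with replacement produces
replicate datasets with the same individuals but perturbed information
content. Each replicate is embedded, and the dispersion among replicate
embeddings is summarized by three statistics.

## The three stability statistics

**Embedding stability (overall score).** Two replicate embeddings $P_u$ and
$P_v$ (rows = individuals, columns = components) are compared by Procrustes
analysis. Both are first standardized — centered at the origin and scaled to
$\mathrm{trace}(PP^\top) = 1$ — then the similarity transform (orthogonal
rotation/reflection plus positive scale) minimizing the squared Frobenius
residual is found in closed form from the SVD of $P_u^\top P_v$. The
disparity

$$D_{u,v} = \lVert f(P_u) - P_v \rVert_F^2 = 1 - \Big(\textstyle\sum_i \sigma_i\Big)^2$$

(where $\sigma_i$ are the singular values of the cross-product of the
standardized matrices) lies in $[0, 1]$; the pairwise similarity is
$1 - D_{u,v}$, and the overall score is the mean similarity over all
$N(N-1)/2$ replicate pairs. A score of 1 means every replicate projects all
individuals identically up to a similarity transform.

**Cluster stability.** For each replicate pair the first embedding is
Procrustes-matched onto the second, each embedding is clustered
independently with k-means (shared $k$), and agreement is measured by the
Fowlkes–Mallows index
$\mathrm{FM} = \mathrm{TP}/\sqrt{(\mathrm{TP}+\mathrm{FP})(\mathrm{TP}+\mathrm{FN})}$
over co-clustered item pairs. The overall score is again the mean over
replicate pairs. When $k$ is not supplied, a grid search over
$k \in [3, k_{\max}]$ minimizes the BIC of a hard-assignment spherical
Gaussian mixture with shared variance ($p = k(D+1)$ free parameters,
$\hat\sigma^2 = \mathrm{inertia}/(D(R-k))$); $k_{\max}$ is the number of
distinct population labels when annotations exist, else
$\lceil\sqrt{R}\rceil$. The lower bound of 3 reflects that 2-cluster
solutions are almost always trivially stable and uninformative for
population data. $k$ influences the score substantially, so the reported
$k$ is part of the result and can be fixed by the user.

**Per-individual support values.** All replicates are standardized and
Procrustes-aligned to the first replicate (a common frame is logically
required: without it, arbitrary axis sign flips between replicates would
dominate the statistic). For each row $i$ the dispersion of its projections
$x_i^u$ across replicates is the Gini-type ratio

$$g_i = \frac{\sum_{u<v} \lVert x_i^u - x_i^v \rVert}{N \sum_u \lVert x_i^u \rVert},$$

and the support value is $1 - g_i$, clamped to $[0, 1]$. Identically
projected rows get support 1; "rogue" individuals whose placement swings
between replicates get low values and should be interpreted with caution
(or filtered before downstream analyses). The choice of a single reference
replicate for alignment is a design decision; aligning to the unbootstrapped
embedding or pairwise per term would be equally defensible, and the clamping
handles the rare mixed-sign/small-norm configurations where the raw ratio
exceeds 1.

## Embeddings

**PCA.** The dosage matrix is mean-imputed, then Patterson-scaled per SNP:
centered and divided by $\sqrt{\hat p(1-\hat p)}$ with
$\hat p = \mu_s/2$ — the binomial standard deviation implied by the
estimated allele frequency, the normalization standard for genotype PCA.
Zero-variance columns map to zeros. Scores come from the eigendecomposition
of the sample covariance (computed through the $M \times M$ cross-product,
since $K \gg M$ for genotype data); the default of 10 components follows
common population-genetics practice (variance-explained rules are
uninformative at genotype dimensionality). Signs are fixed by requiring the
largest-magnitude loading of each component to be positive, making runs
bit-reproducible; Procrustes comparison absorbs signs regardless. Designated
individuals (typically ancient, low-coverage samples) can be excluded from
the fit and then projected: their observed genotypes, scaled with the
fit-set statistics, are regressed onto the SNP loadings by least squares,
the analogue of smartpca's `lsqproject` mode. We use raw $\hat p$ without a
pseudo-count correction; this is one point where numbers may deviate
slightly from other implementations. Automatic outlier removal is
deliberately not implemented.

**MDS.** Metric MDS is run on a pairwise distance matrix: per-individual
Euclidean, Manhattan or Hamming distances on the mean-imputed (for Hamming:
re-rounded) dosages, or the per-population Hudson FST. The Hudson
ratio-of-averages estimator
$\sum_s N_s / \sum_s D_s$ with
$N_s = (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$ and
$D_s = p_1(1-p_2) + p_2(1-p_1)$ is used because it is stable under rare
variants and low diversity; which estimator other PCA toolchains use
internally is generally undocumented, so absolute FST-based MDS coordinates
may differ between tools (the stability statistics, being relative, are
insensitive to this). The MDS solver is SMACOF stress majorization with a
deterministic classical-scaling (Torgerson) initialization — majorization
guarantees monotone stress decrease, and the deterministic start makes
repeated runs bit-identical. Default: 2 components, the standard choice for
distance-based summaries of genotype data.

## Bootstrap and convergence

Up to `nMax = 100` replicates are generated; the per-replicate seed is
`master seed + replicate index`, so any thread count reproduces the same
replicate set. Because embedding every replicate is the dominant cost, the
run stops early once the overall score has stabilized: from 10 replicates
onward, 10 random half-size subsets of the completed replicates are scored
and the run is declared converged when the relative spread
$(\max - \min)/\max$ of the subset scores drops to the tolerance (default
0.05). Convergence is evaluated at deterministic checkpoints — each
replicate count in order, using a seed derived from the master seed and the
count — so the stopping point is a function of the master seed only, never
of the batch size; replicates computed beyond the converged checkpoint are
discarded. On strongly structured synthetic data the spread is often below
tolerance already at the 10-replicate floor; weakly structured or noisy data
run substantially longer. The subset count (10), subset size (half), and the
10-replicate floor are heuristic choices; `tolerance = 0` or
`disableConvergence = TRUE` forces the full `nMax` replicates, which is the
safer setting when per-individual support values (rather than the overall
score) are the quantity of interest, as they converge more slowly.

## The synthetic-data generator

`simulateGenotypes()` draws, per SNP, an ancestral allele frequency
$p \sim U(0.05, 0.95)$, per population a frequency
$p_j \sim \mathrm{Beta}\big(p(1-F)/F,\ (1-p)(1-F)/F\big)$ (the
Balding–Nichols model, whose divergence parameter $F$ equals the expected
pairwise FST), and per individual a dosage $\sim \mathrm{Binomial}(2, p_j)$.
Defaults — 2 populations × 50 individuals, 5000 SNPs, $F = 0.1$ — represent
a moderately differentiated two-population sample at desk scale.
Two distortion protocols emulate common data pathologies: `injectMissing()`
sets exactly $\lfloor \pi M K \rfloor$ uniformly chosen cells missing, and
`injectNoise()` replaces exactly $\lfloor \pi M K \rfloor$ uniformly chosen
non-missing cells with a uniformly random *different* genotype code, so the
nominal proportion is the effective one. The generator produces
unlinked loci with exchangeable individuals within populations: no linkage
disequilibrium, no admixture clines, no ascertainment bias, no
coverage-correlated missingness. Trend tests on these data therefore show
that the statistics respond correctly to information content, missingness
and noise — they do not certify behaviour on the more entangled error
structure of real ancient-DNA panels.

The package's test suite reproduces three qualitative trends on this
generator (2 × 50 individuals, $F = 0.1$, 20 replicates, three simulation
seeds): stability rises strictly across 200/1000/5000 SNPs, is
non-increasing across 0/10/20/50% injected missingness under mean
imputation, and falls strictly across 0/10/20/50% noise with a steeper PCA
decline than MDS decline. These problem sizes keep every simulation fully
reproducible on a laptop.

## Numerical choices and degenerate inputs

* Mean imputation fills a SNP column that is *entirely* missing with 0 (and
  warns) instead of erroring, so a bootstrap replicate that happens to
  resample only missing-heavy columns still embeds.
* A degenerate embedding (all rows identical) cannot be standardized and
  raises an error; an all-zero distance matrix embeds to all-identical
  points (stress 0) by convention.
* k-means uses k-means++ seeding with 10 restarts over the base-R
  Hartigan–Wong iteration; per-pair seeds are derived from the master seed
  and the replicate indices so the "independent" clusterings are
  reproducible. BIC ties break toward the smallest k.
* Disparities are clamped to $[0, 1]$ against double-precision SVD noise;
  "identical" assertions in the tests use 1e-10 absolute tolerance.
* All stability comparisons use *all* computed components, so the choice of
  `nComponents` is part of the analysis definition: comparing 10-component
  PCA runs asks a stricter question than comparing 2-component runs.

## Known limitations

Individual resampling is deliberately out of scope (selecting individuals
subjectively can steer PCA conclusions; bootstrapping SNPs cannot be used to
justify such selections). The PCA is a native re-implementation, not a
wrapper around EIGENSOFT; Patterson scaling matches standard practice but
bit-level agreement with smartpca is not claimed. FST-based MDS depends on
the estimator choice documented above. The convergence rule is a heuristic:
it bounds the dispersion of the overall score, not of individual support
values.
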