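---
title: "Deriving and evaluating an endothelial-senescence signature"
author: "senotec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating an endothelial-senescence signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senotec)
```

## The problem

Tumor endothelial cells (TEC) acquire a senescence-associated secretory
phenotype that reshapes the tumor microenvironment and has prognostic
weight. senotec implements a two-stage analysis around this observation:

1. **Signature derivation.** From several single-cell RNA-seq datasets,
   derive a consensus gene signature of endothelial senescence. Per
   dataset, each TEC receives a single-sample enrichment score for a known
   senescence gene set; genes whose expression correlates positively with
   that score within TECs (Spearman $\rho > 0$, BH FDR < 0.05) form the
   correlation evidence $G_x$; genes up-regulated in TECs versus all other
   cells (expressed in at least 25% of TECs, log2 fold change > 0.25,
   FDR < 0.05) form the marker evidence $G_y$; the dataset contributes
   $G_n = G_x \cap G_y$. Across datasets the geometric mean
   $(\prod_d \rho_d)^{1/k}$ of each gene's coefficients over its $k$
   supporting datasets is taken, and genes with a geometric mean strictly
   above 0.2 form the signature.
2. **Prognostic evaluation.** In a bulk cohort with overall survival, the
   signature genes enter a Cox proportional-hazards model; each patient's
   risk score is $\sum_g \beta_g z_{gj}$ over per-gene z-scored expression;
   patients are dichotomized at the median risk score and compared by
   Kaplan-Meier curves, the log-rank test and Harrell's concordance index.

Both stages are exercised end to end against a synthetic-data generator
with planted ground truth, so every statistical property claimed below is
checked by the test suite without any external download.

## The enrichment score

The per-cell score is a rank-based random-walk statistic. For gene $i$ in
observation $j$, the expression value is first reduced to
$z_{ij}$ — by default the mid-rank empirical CDF of the gene across all
observations of the dataset (`kernel = "ecdf"`), optionally a Gaussian
kernel CDF estimate with bandwidth $s_i/4$ (`kernel = "gaussian"`,
falling back to the ECDF for constant genes). Within each observation the
genes are ordered by decreasing $z_{ij}$ — ties broken lexically by gene
ID so results are platform-independent — and a walk over the ordered genes
adds, at rank $r$, the normalized symmetric weight $|p/2 - r|^{\tau}$ for
in-set genes and subtracts $1/(p-|G|)$ for out-set genes. The score
summarizes the walk's deviation profile: `method = "maxdiff"` (default)
adds the largest positive and smallest negative deviations;
`method = "maxdev"` takes the signed deviation of largest magnitude.
Scores always lie in $[-1, 1]$.

Choices worth stating explicitly:

* The ECDF kernel makes the score exactly invariant under any strictly
  increasing per-gene transform of expression, which in turn makes the
  whole derivation insensitive to the choice of normalization. The test
  suite asserts this invariance directly.
* All cells of a dataset serve as the ECDF reference population, including
  non-endothelial cells, because the senescence score of a TEC is
  interpreted relative to the dataset as a whole.
* Two degenerate corners are pinned down deterministically: when every
  in-set gene sits exactly at the zero-weight mid rank, in-set steps fall
  back to equal increments ($1/|G|$, the $\tau \to 0$ limit); and for
  `maxdev`, equal-magnitude positive/negative ties (within `1e-12`)
  resolve to the negative deviation. Both conventions are mirrored in the
  brute-force oracle used by the tests.

## Cell-level preprocessing

Cells are retained when they detect between 300 and 6500 genes (counts
> 0; boundaries inclusive, since the exclusion rule is strict) and their
mitochondrial percentage — counts on genes with the configurable `MT-`
prefix over total counts — is at most 10%. Zero-count cells are excluded
and flagged rather than treated as an arithmetic error, and the filter is
idempotent. Normalization is log1p-CP10K,
$\ln(1 + 10^4 \, c_{ij} / \sum_i c_{ij})$. Every downstream statistic in
scope (ECDF ranks, Spearman, Wilcoxon) depends only on within-gene
orderings, which any library-size normalization of this family preserves;
this is why a variance-stabilizing alternative would not change the
derivation and is not implemented.

## Marker detection and its thresholds

One-vs-rest Wilcoxon rank-sum per gene and cell type. The p-value uses the
normal approximation with tie correction and continuity correction; for
pooled sizes up to 12 it switches to exact enumeration of all group
assignments, which remains valid under ties. Genes are retained as markers
when the in-type expressed fraction is at least `min_pct = 0.25`, the
pseudocounted log2 fold change
$\log_2\frac{\mathrm{mean}(\mathrm{expm1}(x_{in}))+1}{\mathrm{mean}(\mathrm{expm1}(x_{out}))+1}$
exceeds `min_logfc = 0.25`, and the BH-adjusted p-value is below
`max_fdr = 0.05`. Two documented ambiguities: the fold-change cut is
strict (`>`) by default with `logfc_inclusive = TRUE` available, because
the two natural readings (`>` vs `>=`) differ at the boundary; and the
multiplicity correction is Benjamini-Hochberg per cell type across all
tested genes (not a Bonferroni correction), matching the package's global
FDR convention. Only positive (enriched) markers are reported.

## Consensus construction

`min_support` controls how many datasets must contribute a gene before it
can be a member; the default is 1 — the geometric mean is taken over the
datasets where the gene qualifies, however many there are. Requiring
presence in *every* dataset is available via
`min_support = length(datasets)`. The permissive default was chosen
because requiring all datasets makes membership brittle to a single
underpowered cohort, while the geometric mean already penalizes weak
support; the strict mode is one argument away. Genes are tested for
$G_x$ only when expressed in at least `min_cells_expr = 10` TECs and
non-constant there (degenerate Spearman inputs), and those excluded genes
do not enter the BH denominator.

## Cox stage

`cox_fit()` maximizes the partial likelihood with Breslow ties (Efron
behind a flag) by Newton-Raphson with step-halving: convergence when
successive log-likelihoods differ by less than 1e-9, cap of 100
iterations, divergence guard at $|\beta| > 50$ during iteration. A
separated (monotone-likelihood) fit flattens the objective while a
coefficient walks off to the boundary, so the stopping rule alone can
"converge" at an absurd coefficient; a post-fit diagnostic therefore
errors when any $|\hat\beta| > 20$ (hazard ratios beyond $e^{20}$ are
never identifiable). Tests verify agreement with both a golden-section
maximizer of the same hand-written likelihood and an independent
established implementation.

"Normalized expression" in the risk-score formula is read as per-gene
z-scores across the cohort (`zscore = FALSE` uses the matrix values
directly). Median dichotomization sends ties at the median to the low
group, mirroring the cell-level high/low-senescence split. Variable
selection (penalized or stepwise screening of signature genes before the
Cox fit) is deliberately out of scope: `run_prognostic()` accepts any
coefficient vector and otherwise fits all signature genes jointly.

## What the generator emulates

`simulate_sc()` builds, per dataset, five cell types
(TEC 300, Tumor 800, CAF 200, T cell 400, Myeloid 300) over a shared
2000-gene universe; counts are negative binomial with dispersion
$\phi = 0.2$ (variance $\mu + \phi\mu^2$, a typical droplet-UMI regime)
and lognormal library sizes (meanlog $\log 10^4$, sdlog 0.25). Each TEC
carries a latent senescence activity $s \sim U(0,1)$ — continuous rather
than binary so that both the median split and Spearman correlation have
non-degenerate targets. Three planted programs:

* a 50-gene senescence *readout* set responding as $e^{s}$ to a
  pan-lineage senescence latent (equal to $s$ in TECs, independent
  $U(0,1)$ elsewhere) — senescence is not endothelial-specific, so the
  readout genes correlate with the score inside TECs but are not TEC
  markers;
* 40 *planted* endothelial-senescence genes responding to $s$ in TECs
  only, plus a TEC baseline shift of 1.5 log units so they pass the marker
  filter — the recovery target, 20% of which overlap the readout set;
* 40 *decoy* genes with the same pan-lineage response as the readout set
  but outside it — they enter $G_x$ yet must be excluded from $G_n$ by
  the marker evidence.

Thirteen `MT-` genes carry about 3% of each library, and every cell type
has 30 baseline marker genes, so QC and marker detection face realistic
structure. Program genes are boosted about one log unit into the
moderately-expressed stratum — signature genes are, by construction,
genes one can measure. At these settings a calibration run gives the
planted genes a mean Spearman correlation with $s$ of about 0.36
(minimum about 0.24) inside TECs, comfortably in the detectable regime; at
$\phi = 0.5$ the same quantity drops to about 0.23 with individual genes
near 0.12, i.e. a signal the derivation could not be expected to recover.

What the generator does *not* emulate: batch effects (the derivation
operates per dataset, which isolates batches by construction), doublets,
ambient RNA, gene-gene correlation beyond the planted programs, and
cell-type proportions varying across datasets. Passing the recovery tests
therefore demonstrates that the statistical machinery behaves as
specified under its own assumptions — not that the thresholds are optimal
for any particular real cohort.

`simulate_bulk()` draws a latent activity $a \sim N(0,1)$ per sample,
loads it (coefficient 1) onto 20 signature genes over a baseline of 8
with unit noise, and draws exponential survival with hazard
$0.1\,e^{0.7 a}$. Censoring is exponential with its rate solved
analytically so the expected censored fraction hits the 30% target given
the realized activities.

## Problem sizes and reproducibility

The acceptance-level checks run the full derivation at its default scale
(6 datasets x 2000 cells x 2000 genes) for five generator seeds, the
bulk recovery at n = 500 for five seeds, 200 permutation replicates for
FDR control and 1000 null replicates for log-rank size; unit tests use
smaller fixtures (hundreds of cells, tens of genes) chosen so each
statistical assertion retains adequate Monte-Carlo precision. One global
seed fans out to per-stage seeds through a documented hash
(`stage_seed()`), both workflow drivers stamp a serialized copy and MD5
hash of their configuration into every output directory, and rerunning
either workflow with the same inputs and configuration produces
byte-identical files.

## Known limitations

* Gene identity is the bare case-sensitive symbol; no alias harmonization
  is attempted, so cross-dataset input must already share a vocabulary.
* Missing expression values are rejected rather than imputed; none of the
  statistics in scope define their handling.
* The Gaussian kernel is provided for fidelity to common enrichment
  defaults but gives up the exact monotone-transform invariance.
* The log-rank test and Cox model assume proportional hazards; the
  generator satisfies this by construction, and no diagnostic for its
  violation is included.
* The consensus stage requires at least one dataset and treats datasets
  as exchangeable; no weighting by dataset size or quality is applied.
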