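# senotec

Derivation and prognostic evaluation of a tumor-endothelial-cell (TEC)
senescence gene signature, for computational biologists working with
single-cell and bulk tumor transcriptomes.

Tumor endothelial cells acquire a senescence-associated secretory phenotype
with prognostic consequences. senotec implements the full analysis around
that observation as a reusable R package plus a numbered analysis workflow:

1. **Signature derivation** (single-cell stage). Per dataset, every cell is
   scored for a senescence gene set with a rank-based random-walk enrichment
   statistic (ECDF kernel, symmetric weights `|p/2 − r|^τ`). Genes whose
   expression correlates with that score within TECs (Spearman ρ > 0,
   Benjamini–Hochberg FDR < 0.05) form the correlation evidence *Gx*; genes
   up-regulated in TECs versus all other cells (Wilcoxon one-vs-rest,
   expressed in ≥ 25% of TECs, log2 fold change > 0.25, FDR < 0.05) form the
   marker evidence *Gy*; each dataset contributes *Gn = Gx ∩ Gy*. Across
   datasets, a gene's Spearman coefficients are combined by their geometric
   mean `(∏ ρ_d)^(1/k)`; genes above 0.2 form the consensus signature.
2. **Prognostic evaluation** (bulk stage). Signature genes enter a Cox
   proportional-hazards model (Newton–Raphson on the Breslow partial
   likelihood); each patient's risk score is `Σ β_g · z_g` over per-gene
   z-scored expression; patients are split at the median risk score and
   compared by Kaplan–Meier curves, the log-rank test and Harrell's C.
3. **Synthetic cohorts with planted truth.** A negative-binomial single-cell
   generator (five cell types, latent per-TEC senescence activity, planted
   signature genes, pan-lineage decoys) and a bulk survival generator
   (latent activity with log hazard ratio 0.7, calibrated censoring) make
   every stage testable offline.

## Worked example

The analysis workflow lives in `analysis/` and writes its tables to
`results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_derive_signature.R
Rscript analysis/03_prognostic_model.R
Rscript analysis/04_calibration.R
```

Step 2 derives the signature from six simulated datasets (2000 cells ×
2000 genes each, 40 planted endothelial-senescence genes) and prints:

```
consensus signature: 40 member genes (threshold 0.20)
  sim01: |Gx| = 122, |Gy| = 70, |Gn| = 40
  ...
recovery of the planted program: precision 1.000, recall 1.000
pan-lineage decoys in any Gn: 0
```

i.e. the intersection-plus-consensus procedure recovers exactly the planted
endothelial-senescence program, while the 40 decoy genes that respond to
senescence in *all* lineages enter the correlation evidence but are removed
by the endothelial-marker filter. Step 3 evaluates a 20-gene signature on a
synthetic 500-patient cohort:

```
cox model on 20 signature genes: converged in 4 iterations
log-rank (high vs low risk): chi-square 90.36, p = 1.99e-21
concordance index: 0.687
planted log-HR 0.7, recovered 0.724 (on the latent activity)
risk score vs latent activity: r = 0.938
```

The planted log hazard ratio (0.7) is recovered within the sampling error
expected at n = 500, and the median risk split separates survival sharply.
Step 4 confirms the two statistical gates are calibrated: the Gx filter
selects ~0% of genes when the senescence scores are permuted (nominal FDR
0.05), and the log-rank test rejects at 5.1% under the null at α = 0.05.

In code, the same two workflows are three calls:

```r
library(senotec)
sim <- simulate_sc(sc_sim_config(seed = 1))
der <- run_derive(sim$datasets, sim$senescence_set, pipeline_config(),
                  out_dir = "results/02_signature")
bulk <- simulate_bulk(bulk_sim_config(seed = 1))
prog <- run_prognostic(bulk$matrix, bulk$clinical, bulk$signature,
                       out_dir = "results/03_prognostic")
```

Real data enter through `read_expression()` (10x MTX directory or dense
TSV), `read_gmt()` (MSigDB gene sets) and `read_clinical()` (TSV with
`sample_id`, `time`, `event`); `run_derive()` also accepts a manifest TSV
listing one matrix and annotation per dataset.

## Package layout

* `R/` — the implementation: I/O and validation, QC/normalization,
  enrichment scoring, marker detection, Gx/Gy/Gn and the consensus,
  Cox/KM/log-rank, the generators, and the two workflow drivers.
* `tests/testthat/` — unit, property and acceptance suites (brute-force
  oracles live in `helper-fixtures.R`).
* `vignettes/endothelial-senescence-signature.Rmd` — the methods vignette:
  model, parameter rationale, generator assumptions, numerical conventions,
  limitations.
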