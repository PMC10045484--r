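#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study cohorts.
#
# Six multi-cell-type single-cell datasets share a planted endothelial
# senescence program (40 genes), a 50-gene senescence readout set and 40
# pan-lineage decoy genes; one bulk cohort of 500 samples carries a latent
# activity with log hazard ratio 0.7. Summaries go to results/01_simulation.

suppressMessages(library(senotec))

out <- "results/01_simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1

cfg <- sc_sim_config(seed = seed)
sim <- simulate_sc(cfg)
cat(sprintf("simulated %d single-cell datasets (%d genes, %d cells each)\n",
            cfg$n_datasets, cfg$n_genes, sum(cfg$cell_counts)))

qc_summary <- do.call(rbind, lapply(sim$datasets, function(ds) {
  qc <- qc_filter_cells(ds$matrix)
  data.frame(dataset_id = ds$matrix$dataset_id,
             n_cells = length(ds$matrix$obs_ids),
             n_kept = length(qc$matrix$obs_ids),
             n_excluded = qc$report$n_excluded[
               qc$report$criterion == "total_excluded"])
}))
write.table(qc_summary, file.path(out, "qc_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("QC keeps %.1f%% of cells on average\n",
            100 * mean(qc_summary$n_kept / qc_summary$n_cells)))

write_gmt(list(sim$senescence_set,
               gene_set("PLANTED.EC.SENESCENCE", sim$planted),
               gene_set("PAN.LINEAGE.DECOYS", sim$decoys)),
          file.path(out, "gene_programs.gmt"))

bulk <- simulate_bulk(bulk_sim_config(seed = seed))
write_clinical(bulk$clinical, file.path(out, "bulk_clinical.tsv"))
cat(sprintf("bulk cohort: %d samples, %.1f%% censored\n",
            nrow(bulk$clinical), 100 * mean(1 - bulk$clinical$event)))
cat("summaries written to", out, "\n")
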