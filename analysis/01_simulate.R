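#!/usr/bin/env Rscript
# Build the synthetic study cohort: paired BS/oxBS EPIC-like beta matrices
# for 24 samples (8 non-tumor, 4 tumor types x 4), a probe annotation,
# cell-type compositions that differ between groups, gene counts with
# planted fold changes, and bulk + NSC-specific planted 5hmC effects.
# Outputs under results/cohort/ feed every later script.

library(ct5hmc)

outdir <- "results/cohort"
cfg <- pipeline_config(outdir = outdir, seed = 20260929 %% 100000,
                       n_probes = 4000, n_genes = 1000,
                       groups = c(NT = 12L, ATC = 12L, EMB = 12L, EPN = 12L, GNN = 12L),
                       measurement_precision = 1000, de_lfc = 2,
                       stages = "simulate")
run <- run_pipeline(cfg)
sim <- run$results$simulate

cat("cohort:", nrow(sim$samples$sheet), "samples,",
    nrow(sim$measurements$bs), "probes,", nrow(sim$counts$counts), "genes\n")
cat("planted modification effects:", nrow(sim$truth), "truth rows;",
    sum(rowSums(sim$counts$log2fc != 0) > 0), "genes with DE truth\n")
ratio <- mean(sim$profiles$h) / mean(sim$profiles$m)
cat(sprintf("true genome-wide 5hmC/5mC prevalence ratio: %.3f\n", ratio))
cat("files:", paste(run$manifest$file, collapse = ", "), "\n")
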