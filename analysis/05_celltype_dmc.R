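#!/usr/bin/env Rscript
# Which cell type drives the differential hydroxymethylation? Composition x
# phenotype interaction models with neuronal-like and aggregated
# progenitor-like (NSC+RGC+OPC+UBC) super-types, per tumor type, and
# recovery scoring against the planted truth.

library(ct5hmc)

sheet <- data.table::fread("results/cohort/sample_sheet.tsv", data.table = FALSE)
comp <- read_matrix_tsv("results/cohort/composition.tsv")
truth <- data.table::fread("results/cohort/truth_table.tsv", data.table = FALSE)
h <- read_matrix_tsv("results/5hmc.tsv.gz")

agg <- aggregate_celltypes(comp)
groups <- setdiff(unique(sheet$group), "NT")
fits <- list()
for (g in groups) {
  sub <- sheet[sheet$group %in% c(g, "NT"), ]
  covs <- cbind(sex = as.numeric(sub$sex == "M"),
                age = sub$age - mean(sub$age), purity = sub$purity)
  fits[[g]] <- fit_dmct(h[, sub$sample_id], agg[sub$sample_id, ],
                        as.numeric(sub$group == g), covariates = covs)
}

all_fits <- do.call(rbind, lapply(names(fits), function(g) cbind(group = g, fits[[g]])))
data.table::fwrite(all_fits, "results/dmct_fits.tsv.gz", sep = "\t", compress = "gzip")

classes <- classify_dmct(fits)
for (ct in names(classes)) {
  cat(ct, "hits per group:",
      paste(sprintf("%s=%d", classes[[ct]]$counts$group,
                    classes[[ct]]$counts$n_hits), collapse = " "),
      "| shared:", length(classes[[ct]]$shared), "\n")
}

# recovery of progenitor-restricted truth at super-type resolution
prog_truth <- unique(truth[truth$cell_type %in% c("NSC", "RGC", "OPC", "UBC"),
                           c("probe_id", "group")])
if (nrow(prog_truth)) {
  for (g in groups) {
    planted <- prog_truth$probe_id[prog_truth$group == g]
    if (!length(planted)) next
    pf <- fits[[g]][fits[[g]]$cell_type == "progenitor_like" &
                      fits[[g]]$probe_id %in% planted, ]
    cat(sprintf("%s: %d progenitor-planted probes, progenitor-like q<0.05 at %.0f%%\n",
                g, length(planted), 100 * mean(pf$q < 0.05)))
  }
}
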