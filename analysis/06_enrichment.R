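#!/usr/bin/env Rscript
# Genomic-context enrichment of the fully adjusted dhmCpG sets, stratified
# by Infinium probe design type (Mantel-Haenszel common odds ratio), split
# by direction of change.

library(ct5hmc)

ann <- data.table::fread("results/cohort/annotation.tsv", data.table = FALSE)
fits <- read_tsv_file("results/dmct_fits.tsv.gz")
h <- read_matrix_tsv("results/5hmc.tsv.gz")
universe <- rownames(h)

contexts <- c("TSS200", "TSS1500", "body", "exon1", "enhancer", "DHS", "TFBS")
rows <- list()
for (g in unique(fits$group)) {
  for (ct in c("neuronal_like", "progenitor_like")) {
    sub <- fits[fits$group == g & fits$cell_type == ct & fits$q < 0.05, ]
    for (dir in c("hyper", "hypo", "all")) {
      hitset <- if (dir == "all") sub$probe_id else sub$probe_id[sub$direction == dir]
      if (length(hitset) < 5) next
      for (ctx in contexts) {
        r <- tryCatch(context_enrichment(hitset, universe, ann, ctx),
                      error = function(e) NULL)
        if (is.null(r)) next
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, cell_type = ct, direction = dir, context = ctx,
          or_mh = r$or_mh, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
      }
    }
  }
}
if (length(rows)) {
  enr <- do.call(rbind, rows)
  data.table::fwrite(enr, "results/context_enrichment.tsv", sep = "\t")
  sig <- enr[enr$p < 0.05, ]
  cat(nrow(enr), "tests;", nrow(sig), "significant at p < 0.05\n")
  print(head(sig[order(sig$p), ], 10))
} else {
  cat("no cell-type hit set large enough for enrichment testing\n")
}
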