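#!/usr/bin/env Rscript
# Bulk EWAS of 5hmC per tumor type vs non-tumor tissue with stepwise
# cell-composition adjustment, plus hit sharing across tumor types and
# the adjustment-depth trend in context proportions.

library(ct5hmc)

sheet <- data.table::fread("results/cohort/sample_sheet.tsv", data.table = FALSE)
comp <- read_matrix_tsv("results/cohort/composition.tsv")
ann <- data.table::fread("results/cohort/annotation.tsv", data.table = FALSE)
h <- read_matrix_tsv("results/5hmc.tsv.gz")

groups <- setdiff(unique(sheet$group), "NT")
series <- list()
for (g in groups) {
  sub <- sheet[sheet$group %in% c(g, "NT"), ]
  series[[g]] <- stepwise_series(h[, sub$sample_id], sub, comp, g)
  cat(g, "hits by k:", series[[g]]$hit_counts$n_hits, "\n")
}

counts_tab <- do.call(rbind, lapply(groups, function(g)
  cbind(group = g, series[[g]]$hit_counts)))
data.table::fwrite(counts_tab, "results/ewas_hit_counts.tsv", sep = "\t")

full_sets <- lapply(series, function(s) s$hit_sets[["5"]])
if (sum(lengths(full_sets) > 0) >= 2) {
  share <- summarize_hits(full_sets)
  cat(sprintf("union of fully adjusted dhmCpGs: %d; shared across all: %d (%.1f%%)\n",
              share$n_union, length(share$shared_all),
              100 * share$shared_all_fraction))
  data.table::fwrite(share$venn, "results/ewas_sharing.tsv", sep = "\t")
}

# does the context composition of hits drift as adjustment deepens?
trends <- do.call(rbind, lapply(groups, function(g) {
  do.call(rbind, lapply(c("TSS200", "body", "DHS", "enhancer"), function(ctx) {
    tr <- context_trend(series[[g]]$hit_sets, ann, ctx)
    data.frame(group = g, context = ctx, rho = tr$rho, p = tr$p)
  }))
}))
data.table::fwrite(trends, "results/ewas_context_trend.tsv", sep = "\t")
print(trends[!is.na(trends$rho) & trends$p < 0.05, ])
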