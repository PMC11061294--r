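#!/usr/bin/env Rscript
# Methylation dysregulation index: per-sample deviation from the non-tumor
# reference for 5mC and 5hmC, overall and per genomic context, with the
# accompanying KS, Kruskal-Wallis, Spearman and Grubbs statistics.

library(ct5hmc)

sheet <- data.table::fread("results/cohort/sample_sheet.tsv", data.table = FALSE)
ann <- data.table::fread("results/cohort/annotation.tsv", data.table = FALSE)
m <- read_matrix_tsv("results/5mc.tsv.gz")
h <- read_matrix_tsv("results/5hmc.tsv.gz")
nt_ids <- sheet$sample_id[sheet$group == "NT"]

recs <- list()
tests <- list()
for (assay in c("5mC", "5hmC")) {
  mat <- if (assay == "5mC") m else h
  ref <- reference_medians(mat, nt_ids)
  rec <- compute_mdi(mat, ref, assay = assay)
  rec$group <- sheet$group[match(rec$sample_id, sheet$sample_id)]
  recs[[assay]] <- rec

  tum <- rec[rec$group != "NT", ]
  kw <- rank_tests(tum$mdi, tum$group)
  med_t <- apply(mat[, setdiff(colnames(mat), nt_ids)], 1, median)
  med_n <- apply(mat[, nt_ids], 1, median)
  ks <- distribution_shift(med_t, med_n)
  gr <- grubbs_outlier(tum$mdi)
  tests[[assay]] <- data.frame(
    assay = assay, ks_D = ks$D, ks_p = ks$p,
    kruskal_stat = kw$kruskal$statistic, kruskal_p = kw$kruskal$p,
    grubbs_outlier = gr$outlier)
  cat(sprintf("%s: KS D=%.3f (p=%.2g); KW across tumor types p=%.3f; outlier=%s\n",
              assay, ks$D, ks$p, kw$kruskal$p, gr$outlier))

  ctx <- mdi_by_context(mat, ref, ann,
                        c("TSS200", "TSS1500", "body", "enhancer", "DHS"),
                        assay = assay)
  ctx$group <- sheet$group[match(ctx$sample_id, sheet$sample_id)]
  recs[[paste0(assay, "_ctx")]] <- ctx
}

mdi_all <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
data.table::fwrite(mdi_all, "results/mdi.tsv", sep = "\t")
data.table::fwrite(do.call(rbind, tests), "results/mdi_tests.tsv", sep = "\t")

both <- merge(recs[["5mC"]], recs[["5hmC"]], by = "sample_id")
sp <- spearman_cor(both$mdi.x, both$mdi.y)
cat(sprintf("Spearman rho between 5mC and 5hmC MDI: %.2f (p=%.3g)\n", sp$rho, sp$p))
cat(sprintf("mean tumor 5hmC MDI is %.0f%% of mean tumor 5mC MDI\n",
            100 * mean(recs[["5hmC"]]$mdi[recs[["5hmC"]]$group != "NT"]) /
              mean(recs[["5mC"]]$mdi[recs[["5mC"]]$group != "NT"])))
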