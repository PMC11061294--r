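#!/usr/bin/env Rscript
# Differential expression by NB regression with cell-composition covariates,
# integration of dhmCpG effects with expression fold changes, promoter/
# gene-body odds by expression direction, and binned-control module scores.

library(ct5hmc)

sheet <- data.table::fread("results/cohort/sample_sheet.tsv", data.table = FALSE)
comp <- read_matrix_tsv("results/cohort/composition.tsv")
counts <- read_matrix_tsv("results/cohort/counts.tsv.gz")
ann <- data.table::fread("results/cohort/annotation.tsv", data.table = FALSE)
ewas_hits <- read_tsv_file("results/dmct_fits.tsv.gz")

groups <- setdiff(unique(sheet$group), "NT")
de_fits <- list()
for (g in groups) {
  sub <- sheet[sheet$group %in% c(g, "NT"), ]
  de <- fit_nb_de(counts, sub, g, composition = comp,
                  cell_types = intersect(colnames(comp),
                                         c("NEU", "NSC", "RGC", "OPC", "UBC")))
  de_fits[[g]] <- de$fits
  cat(sprintf("%s: %d DE genes at p_adj < 0.05\n", g,
              sum(de$fits$p_adj < 0.05, na.rm = TRUE)))
}
de_all <- do.call(rbind, lapply(names(de_fits), function(g)
  cbind(group = g, de_fits[[g]])))
data.table::fwrite(de_all, "results/de_fits.tsv.gz", sep = "\t", compress = "gzip")

# pair dhmCpGs with mapped-gene fold changes
for (g in groups) {
  dm <- ewas_hits[ewas_hits$group == g & ewas_hits$q < 0.05 &
                    ewas_hits$cell_type == "progenitor_like", ]
  if (nrow(dm) < 3) next
  out <- tryCatch(hm_expression_correlation(dm, de_fits[[g]], ann),
                  error = function(e) NULL)
  if (is.null(out)) next
  cat(sprintf("%s: %d (CpG, gene) pairs; Pearson r=%.2f (p=%.2g)\n",
              g, nrow(out$pairs), out$r_all, out$p_all))
  sig_pairs <- out$pairs[!is.na(out$pairs$p_adj) & out$pairs$p_adj < 0.05, ]
  if (nrow(sig_pairs) && length(unique(sign(sig_pairs$log2fc))) == 2) {
    odds <- promoter_genebody_odds(sig_pairs, ann)
    print(odds)
  }
}

# pseudo single-cell matrix for module scores: per-cell noisy expression
set.seed(77)
lognorm <- log1p(t(t(counts) / estimate_size_factors(counts)))
cells_per_sample <- 5
cell_expr <- do.call(rbind, lapply(colnames(lognorm), function(s)
  matrix(rep(lognorm[, s], each = cells_per_sample), cells_per_sample,
         dimnames = list(sprintf("%s_c%d", s, 1:cells_per_sample), NULL)) +
    rnorm(cells_per_sample * nrow(lognorm), 0, 0.2)))
colnames(cell_expr) <- rownames(lognorm)
meta <- data.frame(
  cell_type = "OPC",
  group = rep(ifelse(sheet$group == "NT", "NT", "TUM"), each = cells_per_sample))

gene_set <- unique(unlist(strsplit(ann$genes[ann$DHS == 1 & ann$genes != ""], ",")))
gene_set <- intersect(gene_set, colnames(cell_expr))
if (length(gene_set) >= 5) {
  ms <- module_score(cell_expr, gene_set, cell_meta = meta, seed = 78)
  cat(sprintf("module score over %d genes: mean %.3f\n",
              length(gene_set), mean(ms$scores)))
  if (!is.null(ms$comparisons)) print(ms$comparisons)
}
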