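#!/usr/bin/env Rscript
# Infer per-probe per-sample 5mC and 5hmC from the paired BS/oxBS betas by
# constrained maximum likelihood (BS reads 5mC+5hmC, oxBS reads 5mC) and
# summarize how prevalent 5hmC is relative to 5mC.

library(ct5hmc)

bs <- read_matrix_tsv("results/cohort/bs.tsv.gz")
ox <- read_matrix_tsv("results/cohort/oxbs.tsv.gz")
est <- estimate_modifications(bs, ox)

write_matrix_tsv(est$m, "results/5mc.tsv.gz")
write_matrix_tsv(est$h, "results/5hmc.tsv.gz")

cat(sprintf("boundary (h = 0) fraction: %.3f\n", mean(est$boundary)))
cat(sprintf("genome-wide mean 5hmC = %.4f, mean 5mC = %.4f (ratio %.3f)\n",
            mean(est$h), mean(est$m), mean(est$h) / mean(est$m)))
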