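# ct5hmc

Cell-type-aware analysis of DNA methylation (5mC) and hydroxymethylation
(5hmC) in bulk tissue measured with paired bisulfite (BS) and
oxidative-bisulfite (oxBS) arrays.

Bulk methylation studies of heterogeneous tissue — here, pediatric CNS
tumors against non-tumor brain — confound two very different things: probes
whose cytosine modifications actually change within cells, and probes that
only appear to change because the cell-type composition of the tissue
shifts. `ct5hmc` implements the full analysis chain needed to separate
them, for both 5mC and the rarer 5hmC mark (genome-wide, 5hmC runs at
roughly 6% of 5mC in brain):

1. **Modification inference.** BS conversion reads m + h (5mC + 5hmC),
   oxBS reads m alone. Per probe and sample, `(m, h)` are estimated by
   maximizing the binomial pseudo-count likelihood

   L(m, h) = n_bs [β_bs log(m+h) + (1−β_bs) log(1−m−h)]
           + n_ox [β_ox log m + (1−β_ox) log(1−m)]

   subject to m ≥ 0, h ≥ 0, m + h ≤ 1. The solution is closed-form:
   m̂ = β_ox, ĥ = β_bs − β_ox when β_bs ≥ β_ox, otherwise ĥ = 0 with the
   assays pooled by pseudo-count.
2. **Methylation dysregulation index (MDI).** Per-sample mean absolute
   deviation of betas from the per-probe non-tumor median, overall or per
   genomic context, with KS, Kruskal-Wallis, Wilcoxon, Spearman and Grubbs
   statistics around it.
3. **Bulk EWAS.** Per-probe linear models of beta on tumor-type contrast +
   sex + age + purity, with empirical-Bayes variance moderation (scaled
   inverse-chi-square prior fitted by moments on log residual variances)
   and stepwise addition of cell-type proportions (NEU, NSC, OPC, RGC,
   UBC) to expose composition confounding; BH q-values.
4. **Cell-type attribution.** Interaction model
   β_i = Σ_k w_ik a_k + Σ_k (w_ik x_i) b_k + γ′z_i + ε_i (no global
   intercept) over neuronal-like and aggregated progenitor-like
   (NSC+RGC+OPC+UBC) super-types: b_k is the modification change inside
   cell type k.
5. **Context enrichment.** Mantel-Haenszel common odds ratio over strata
   defined by Infinium probe design type (I/II), with
   Robins-Breslow-Greenland confidence intervals.
6. **Expression integration.** Gamma-Poisson (NB) GLMs with
   median-of-ratios size factors and composition covariates; Pearson
   correlation of dhmCpG effects with log2 fold changes; promoter/gene-body
   odds by expression direction; binned-control gene-set module scores.
7. **Single-nucleus support.** Feature/mitochondrial QC and integrative
   HTO + genotype demultiplex consolidation.
8. **Synthetic cohorts.** A generator with planted, auditable ground truth
   (per-cell-type profiles, Dirichlet compositions, Beta measurement noise,
   NB counts, nucleus records) so every stage is testable at desk scale.

## Worked example

```r
library(ct5hmc)

bs <- matrix(c(0.62, 0.48, 0.15), 3, 1,
             dimnames = list(c("cg01", "cg02", "cg03"), "S1"))
ox <- matrix(c(0.55, 0.50, 0.10), 3, 1,
             dimnames = list(c("cg01", "cg02", "cg03"), "S1"))
est <- estimate_modifications(bs, ox, n_bs = 100, n_ox = 100)
cbind(`5mC` = est$m[, 1], `5hmC` = est$h[, 1], boundary = est$boundary[, 1])
#>       5mC 5hmC boundary
#> cg01 0.55 0.07        0
#> cg02 0.49 0.00        1
#> cg03 0.10 0.05        0
```

cg01 and cg03 are interior solutions (ĥ is the BS − oxBS difference);
cg02 has β_bs < β_ox, so ĥ = 0 and m̂ pools the two assays (boundary = 1).

```r
ref <- c(cg01 = 0.50, cg02 = 0.45, cg03 = 0.12)   # non-tumor medians
compute_mdi(est$m + est$h, ref, assay = "5mC+5hmC")
#>   sample_id    assay context        mdi n_probes_used
#> 1        S1 5mC+5hmC     all 0.06333333             3
```

The MDI is the mean absolute deviation from the reference:
(0.12 + 0.04 + 0.03) / 3 ≈ 0.063.

```r
tabs <- list(I  = list(a = 12, b = 30, c = 18, d = 40, n = 100),
             II = list(a = 7,  b = 11, c = 9,  d = 23, n = 50))
mh <- mantel_haenszel(tabs)
sprintf("OR_MH = %.3f (95%% CI %.3f-%.3f), p = %.3f",
        mh$or_mh, mh$ci_low, mh$ci_high, mh$p)
#> "OR_MH = 1.087 (95% CI 0.537-2.201), p = 0.818"
```

## The analysis workflow

`analysis/01_simulate.R` … `analysis/08_nuclei.R` are thin narrative
drivers over the package: simulate a 60-sample cohort with planted bulk and
progenitor-restricted 5hmC effects, infer modifications, compute MDI, run
the stepwise EWAS (bulk hit counts collapse from hundreds to the planted
set as cell-type covariates are added), attribute effects to super-types,
test context enrichment, fit differential expression and integrate, and
demultiplex simulated nuclei. Each script prints what it found and writes
tidy TSVs under `results/`. Run them in order from the repository root
after installing the package.

`run_pipeline()` performs the same chain programmatically from a single
`pipeline_config()`, writing every stage output plus an md5-hashed manifest
for reproducibility.

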