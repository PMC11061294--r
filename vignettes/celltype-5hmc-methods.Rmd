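---
title: "Models and design choices in ct5hmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in ct5hmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ct5hmc)
```

`ct5hmc` analyzes paired bisulfite (BS) and oxidative-bisulfite (oxBS)
array measurements of bulk tissue in a cell-type-aware way. This vignette
is the package's own account of its models, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable option existed. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## 1. Inferring 5mC and 5hmC from paired measurements

BS conversion leaves both 5mC and 5hmC unconverted, so a BS beta value
measures m + h; oxBS first oxidizes 5hmC so its beta measures m alone.
We model the paired betas as binomial fractions with pseudo-count depths
`n_bs` and `n_ox` and maximize

$$L(m,h) = n_{bs}\left[\beta_{bs}\log(m{+}h) + (1{-}\beta_{bs})\log(1{-}m{-}h)\right]
         + n_{ox}\left[\beta_{ox}\log m + (1{-}\beta_{ox})\log(1{-}m)\right]$$

over the constraint set $m \ge 0$, $h \ge 0$, $m + h \le 1$, with the
convention $0\log 0 = 0$. The likelihood is concave, and the maximizer is
closed-form: when $\beta_{bs} \ge \beta_{ox}$ the unconstrained optimum
$\hat m = \beta_{ox}$, $\hat h = \beta_{bs} - \beta_{ox}$ is feasible;
otherwise the constraint $h \ge 0$ binds and
$\hat m = (n_{bs}\beta_{bs} + n_{ox}\beta_{ox})/(n_{bs}+n_{ox})$, $\hat h = 0$,
flagged in the `boundary` matrix. The published array-based MLE this step
follows does not print its formulas or its effective depths; we make the
pseudo-counts explicit with a default of 100 per assay, which reproduces
the known closed form and lets the user encode differing assay precision.
`oxbs_grid_oracle()` is an independent brute-force check: a coarse-to-fine
grid search (final step $10^{-4}$; refinement around the coarse maximum is
exact up to grid resolution because the likelihood is concave) that the
test suite compares against the closed form on 1,000 random instances.

A consequence worth knowing: because $\hat h = 0$ whenever
$\beta_{bs} \le \beta_{ox}$, genome-wide summaries of $\hat h$ are slightly
inflated relative to truth at low measurement precision (negative noise
excursions are truncated at zero while positive ones are kept). The
consistency test verifies this bias shrinks as precision grows.

## 2. Methylation dysregulation index

The MDI of sample $s$ is the mean absolute deviation of its betas from the
per-probe median of the non-tumor samples:
$\mathrm{MDI}_s = \frac{1}{|P|}\sum_{c \in P} |\beta_{sc} - \mathrm{ref}_c|$.
The source describing this index cites an external definition without
printing it; we fixed the mean-absolute-deviation form because it matches
the index's verbal description (a summary of epigenome-wide alteration
against non-tumor tissue), is bounded in [0, 1], and satisfies an exact
partition identity — the overall MDI equals the probe-count-weighted mean
of MDIs over any partition of probes — which the tests exploit. A
median-of-deviations aggregation is available via `aggregate = "median"`.
Missing betas are excluded pairwise and `n_probes_used` is recorded;
nothing is imputed.

Accompanying statistics delegate to base R (`ks.test`, `kruskal.test`,
`wilcox.test`, `cor.test`, `lm`); the Grubbs outlier test is implemented
directly (base R has none): two-sided, single outlier, applied once without
iterative removal, with the t-based critical value
$\frac{n-1}{\sqrt n}\sqrt{t^2_{\alpha/(2n),\,n-2}/(n-2+t^2)}$.

## 3. Bulk EWAS with moderation and stepwise adjustment

Each tumor type is contrasted against non-tumor tissue in its own model on
the samples of that group plus the reference — never a joint all-groups
model — mirroring how the cell-type-specific models are also run. The
design is intercept, 0/1 group, 0/1 sex, mean-centered age, tumor purity,
then k cell-type fractions added cumulatively in the order NEU, NSC, OPC,
RGC, UBC (configurable). Tumor location is deliberately not a covariate
(sample sizes do not support it). Purity is included in all models by
default; because descriptions of the "unadjusted" model are ambiguous on
this point, `covariates =` lets the user drop it. Constant columns (e.g.
sex in a single-sex subset) are dropped with a warning rather than left to
destroy the fit.

Per-probe OLS residual variances $s^2_i$ with $d$ df are shrunk toward a
scaled inverse-chi-square prior $(d_0, s_0^2)$ estimated by method of
moments on $\log s^2_i$ (digamma/trigamma bias corrections, trigamma
inverted by Newton iteration). The moderated statistic is
$t_i = \hat\beta_i / (\mathrm{se}_i \cdot s_{post,i}/s_i)$ on $d + d_0$ df
with $s^2_{post} = (d_0 s_0^2 + d s^2)/(d_0 + d)$. This is the standard
empirical-Bayes squeeze; the test suite checks it coefficient-for-
coefficient against the reference implementation in `limma` when that
package is present, and the estimator itself against a normal-equations
oracle at $10^{-10}$. Two deliberate degenerate behaviors: `prior_df = 0`
reproduces ordinary t-tests exactly, and when the observed log-variance
spread is no larger than chi-square sampling noise the prior df is
infinite with $s_0^2$ equal to the pooled mean variance, so equal input
variances pass through unchanged.

"q-value" means Benjamini-Hochberg throughout: the original analyses name a
q-value threshold without naming an estimator, and BH is deterministic and
conservative; a Storey-type estimator was considered and rejected because
its π₀ smoothing adds a tuning surface the rest of the pipeline never uses.
Betas are modeled directly (no M-value transform), matching the upstream
choice of modeling fractional values.

## 4. Cell-type attribution

With composition $w_{ik}$ on the simplex and tumor indicator $x_i$, the
interaction model is
$$\beta_i = \sum_k w_{ik} a_k + \sum_k (w_{ik} x_i)\, b_k + \gamma' z_i + \varepsilon_i$$
without a global intercept — the composition block spans it once a
remainder column tops the fractions up to 1, and adding an intercept would
make the block collinear. $b_k$ is the within-cell-type modification
change; each is t-tested and BH-adjusted within cell type. Granular types
are first aggregated to neuronal-like (NEU) and progenitor-like
(NSC + RGC + OPC + UBC) super-types, limiting parameters at cohort-scale n.
Covariates (sex, age, purity) enter additively, not interacted; whether
the original cell-type models carried covariates is unstated, so this is a
flag (`covariates =`, default on). Estimates are unconstrained OLS and may
leave [0, 1]; they are estimates, not measurements, and clipping them would
bias recovery scoring. A single constant composition column (K = 1,
$w \equiv 1$) is allowed and reduces exactly to the bulk group model;
zero-variance columns with K > 1 are rejected by name because the
interaction block is then unidentifiable. Complete-case fitting per probe
handles missing betas.

## 5. Context enrichment

Enrichment of a hit set against a genomic context uses the Mantel-Haenszel
common odds ratio over strata defined by Infinium design type (I/II), whose
differing chemistry makes pooled 2×2 tables misleading:
$\mathrm{OR}_{MH} = \sum_s (a_s d_s / n_s) \big/ \sum_s (b_s c_s / n_s)$,
with the Robins-Breslow-Greenland variance for the 95% CI and the MH
chi-square for the p-value, no continuity correction by default (none is
described; `correct = TRUE` is available). The probe universe is the
analyzable probe set for the assay, not the array manifest — hits can only
arise from tested probes, and using the manifest would manufacture
enrichment. Direction-stratified tests filter the hit set by hyper/hypo
before tabulation. The implementation is checked against
`stats::mantelhaen.test` and hand-evaluated tables, and its null
calibration is measured over 2,000 simulated replicates.

## 6. Expression integration

The NB differential-expression fit is authored here as a direct
gamma-Poisson GLM rather than delegated, keeping the surface
oracle-checkable: log link, log size-factor offsets (median-of-ratios over
genes positive in all samples, rescaled to geometric mean 1), per-gene
dispersion by Pearson moments around a Poisson fit — squared residuals
inflated by $n/(n-p)$ to undo coefficient shrinkage — with optional
shrinkage toward the mean dispersion (`dispersion_shrink`, default 0.2),
then a Wald test on the group coefficient. Deviations from the widely used
count package this emulates are documented behaviors, not bugs: no
independent filtering, no LFC shrinkage, moment dispersions instead of the
full empirical-Bayes treatment. One calibration choice matters at cohort
n: the Wald statistic is referred to a t distribution with residual df
rather than the normal, because plug-in moment dispersions otherwise make
the smallest of a few thousand p-values anticonservative (the test suite
measures the null false-discovery behavior directly). `dispersion =`
accepts a known value, which is also how the Poisson-limit equivalence is
tested.

Integration pairs each significant CpG with its mapped genes (one row per
CpG, the default; collapsing many CpGs to one gene row is not offered
because the upstream convention is unstated) and reports Pearson r overall
and among significantly differentially expressed genes. Promoter
(TSS200 ∪ TSS1500) and gene-body odds ratios use the plain cross-product
with Haldane-Anscombe correction only when a zero cell forces it, Woolf
CIs, and Fisher exact p.

Module scores follow the binned-control construction: genes are ranked by
average expression into `n_bins = 24` bins; each set gene draws
`n_ctrl = 100` controls from its bin (set genes excluded); the per-cell
score is mean(set) − mean(controls). The normalization feeding it is
log1p of depth-normalized counts by default. Both parameters and the
normalization are conventions — the original score method is unnamed — and
are exposed as arguments. Note that a large uniform shift planted on set
genes also shifts those genes' bin assignments, biasing the absolute score;
recovery is therefore assessed on the between-group score contrast, where
control selection cancels.

## 7. Nucleus QC and demultiplex consolidation

QC keeps nuclei with 2000 ≤ features ≤ 10000 and mitochondrial percentage
≤ 5, boundaries inclusive, because the removal rule is stated with strict
inequalities. Consolidation trusts an HTO singlet only when the genotype
agrees (R1), discards disagreements (R2), falls back to the genotype for
HTO doublets/negatives (R3), and discards double failures (R4). The case
of an HTO singlet with an uninformative genotype (R5) is not covered by
the quoted rules; the default discards it, symmetric with R2, and
`trust_hto = TRUE` keeps the HTO call. The rule table is exhaustive over
both call vocabularies and exercised combination-by-combination in the
tests.

## 8. What the synthetic cohort emulates — and what it does not

`cohort_config()` fixes the study conditions: EPIC-like probe counts, a
bimodal 5mC compartment (60% high, Beta(8,2); 40% low, Beta(2,8)) with
per-cell-type logit jitter (sd 0.5) so deconvolution has signal; 5hmC as a
fraction of the unmethylated headroom, $h = (1-m)f$ with
$E[f]$ calibrated so genome-wide mean(h)/mean(m) equals
`hmc_to_mc_ratio` (default 0.06, the prevalence regime of brain tissue) —
the construction guarantees $m + h \le 1$ without clipping; Dirichlet
compositions per group; Beta measurement noise with a single precision
pseudo-count shared by BS and oxBS (default 200; bounded support is the
reason a Beta model was chosen — no array noise model is published); NB
counts with dispersion 0.1; and planted effects recorded in an auditable
truth table, with clipping (never rejection) reported entry-by-entry when
a requested delta leaves the simplex.

The pipeline's default group concentrations
(`default_group_concentrations()`) encode neuron-rich non-tumor tissue
against progenitor-leaning tumors with modest totals, so per-sample
compositional spread is realistic and group labels are not fully
determined by composition. Composition differences between groups are
reported only qualitatively in the source material, so these
concentrations are structural placeholders, not estimates. Covariates
(sex, age, purity) are independent of group unless
`confound_covariates = TRUE`, giving both clean and confounded regimes.

Not emulated: raw intensities and dye bias, probe cross-reactivity and
masking, spatial genome structure, read-level sequencing, cell clustering.
Passing tests therefore demonstrate correctness of the statistical chain
under the stated generative assumptions, not robustness to array
artifacts that upstream preprocessing is supposed to remove.

Two interactions discovered with this generator are worth flagging because
they affect real analyses too. First, one-sided differential expression
contaminates median-of-ratios size factors (a 25% one-direction DE fraction
shifts every log2FC by ~0.2); recovery simulations plant
direction-balanced truth for this reason. Second, adjusting for
compositions that strongly separate groups inflates the variance of the
group coefficient (the usual price of adjusting a confounder); at tight
Dirichlet concentrations the group label becomes nearly a linear function
of composition and bulk power collapses — visible in the stepwise series
as hit counts falling toward the planted set.

## 9. Problem sizes and determinism

The test suite runs at desk scale: 10,000-probe EWAS calibration and
recovery (n = 10 + 10, precision 200, planted Δβ = 0.2), 20 replicates of
the composition-confounding series at 800 probes, cell-type attribution at
2,000 probes (n = 20 + 20, precision 1000, Δβ = 0.3 in all progenitor
members), 2,000 Mantel-Haenszel null replicates, 20 NB null replicates at
2,000 genes, and an end-to-end 24-sample pipeline at 2,000 probes / 500
genes. The analysis drivers use a 60-sample, 4,000-probe, 1,000-gene
cohort at precision 1000 — the regime in which super-type attribution is
well-powered — and note that at precision 200 with 12 samples per group
attribution is honest but weak. All generators derive per-stage sub-seeds
from a single master seed (`derive_seed()`), restore the caller's RNG
state, and are bit-reproducible; `run_pipeline()` writes an md5 manifest
over every output so reproducibility is checkable from the file system
alone.

## 10. Known limitations

- The boundary-truncation bias of $\hat h$ at low precision propagates
  into prevalence summaries (estimates overshoot a 6% target ratio by
  roughly a percentage point of ratio at precision 200).
- Moment dispersions are noisy at n ≈ 20; the t reference compensates for
  calibration but sacrifices a little power relative to a full
  empirical-Bayes treatment.
- The MDI reference requires non-tumor samples; with a single reference
  sample the "median" is that sample and MDI inherits its noise.
- Attribution resolution stops at the super-type level by design; effects
  planted in one granular progenitor type dilute by the ratio of its
  fraction to the super-type fraction and are correspondingly harder to
  detect.
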