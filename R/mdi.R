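# Methylation dysregulation index (MDI) and accompanying statistics.
#
# MDI summarizes per-sample epigenome-wide deviation from non-tumor tissue:
# for sample s, MDI_s = mean over probes of |beta_{s,c} - ref_c| where ref_c
# is the per-probe median beta of the non-tumor samples. It is computed
# overall or restricted to probes carrying a genomic-context flag.

#' Per-probe non-tumor reference medians
#'
#' @param betas probes x samples beta matrix
#' @param nontumor_ids sample ids forming the non-tumor reference
#' @return list with `reference` (named numeric vector of per-probe medians
#'   over non-tumor samples, NAs ignored) and `dropped` (probes with no
#'   non-tumor observation)
#' @export
reference_medians <- function(betas, nontumor_ids) {
  assert_beta_matrix(betas, "betas")
  if (length(nontumor_ids) == 0) stop_validation("non-tumor sample set is empty")
  missing_ids <- setdiff(nontumor_ids, colnames(betas))
  if (length(missing_ids))
    stop_validation(sprintf("non-tumor ids absent from betas: %s",
                            paste(missing_ids, collapse = ", ")))
  sub <- betas[, nontumor_ids, drop = FALSE]
  med <- apply(sub, 1, stats::median, na.rm = TRUE)
  dropped <- names(med)[is.nan(med) | is.na(med)]
  med <- med[!(names(med) %in% dropped)]
  list(reference = med, dropped = dropped)
}

#' Per-sample methylation dysregulation index
#'
#' Mean absolute deviation of a sample's betas from the reference medians,
#' over non-missing probes in an optional subset. `aggregate = "median"`
#' switches to the median of absolute deviations.
#'
#' @param betas probes x samples beta matrix
#' @param reference output of [reference_medians()] (or a named vector)
#' @param probe_subset optional probe ids to restrict to
#' @param assay label recorded in the output ("5mC" or "5hmC", free-form)
#' @param context label recorded in the output (default "all")
#' @param aggregate "mean" (default) or "median"
#' @return data.frame: sample_id, assay, context, mdi, n_probes_used
#' @export
compute_mdi <- function(betas, reference, probe_subset = NULL,
                        assay = "5hmC", context = "all", aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  ref <- if (is.list(reference)) reference$reference else reference
  probes <- intersect(rownames(betas), names(ref))
  if (!is.null(probe_subset)) probes <- intersect(probes, probe_subset)
  if (length(probes) == 0) stop_validation("no probes with reference values in subset")
  dev <- abs(betas[probes, , drop = FALSE] - ref[probes])
  agg <- if (aggregate == "mean") colMeans(dev, na.rm = TRUE) else
    apply(dev, 2, stats::median, na.rm = TRUE)
  n_used <- colSums(!is.na(dev))
  if (any(n_used == 0)) stop_validation("a sample has no non-missing probes in subset")
  data.frame(sample_id = colnames(betas), assay = assay, context = context,
             mdi = unname(agg), n_probes_used = unname(n_used),
             stringsAsFactors = FALSE)
}

#' MDI per genomic context
#'
#' One MDI record per sample x context, computed on probes carrying the
#' context flag in the annotation. Contexts with zero flagged probes are
#' omitted with a warning.
#'
#' @param betas probes x samples beta matrix
#' @param reference output of [reference_medians()]
#' @param annotation probe annotation with `probe_id` and 0/1 context columns
#' @param contexts context column names to evaluate
#' @inheritParams compute_mdi
#' @return data.frame as in [compute_mdi()], one block per context
#' @export
mdi_by_context <- function(betas, reference, annotation, contexts,
                           assay = "5hmC", aggregate = "mean") {
  bad <- setdiff(contexts, colnames(annotation))
  if (length(bad))
    stop_validation(sprintf("contexts absent from annotation: %s",
                            paste(bad, collapse = ", ")))
  out <- list()
  for (ctx in contexts) {
    probes <- annotation$probe_id[annotation[[ctx]] == 1]
    probes <- intersect(probes, rownames(betas))
    if (length(probes) == 0) {
      warning(sprintf("context '%s' has no probes; omitted", ctx))
      next
    }
    out[[ctx]] <- compute_mdi(betas, reference, probe_subset = probes,
                              assay = assay, context = ctx, aggregate = aggregate)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-sample Kolmogorov-Smirnov shift between beta distributions
#'
#' @param tumor_medians,nontumor_medians numeric vectors in \[0,1\]
#' @return list with `D` and `p` (asymptotic two-sample KS)
#' @export
distribution_shift <- function(tumor_medians, nontumor_medians) {
  if (!length(tumor_medians) || !length(nontumor_medians))
    stop_validation("both vectors must be non-empty")
  if (any(c(tumor_medians, nontumor_medians) < 0 | c(tumor_medians, nontumor_medians) > 1,
          na.rm = TRUE))
    stop_validation("beta medians must lie in [0,1]")
  kt <- suppressWarnings(stats::ks.test(tumor_medians, nontumor_medians))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Rank-based group tests for MDI values
#'
#' Kruskal-Wallis across >= 2 groups; Wilcoxon rank-sum when exactly 2
#' groups are present (reported alongside).
#'
#' @param values numeric vector (e.g. MDI per sample)
#' @param grouping group labels, same length
#' @return list with `kruskal` (statistic, p), and `wilcoxon` (statistic, p)
#'   when there are exactly two groups; degenerate all-tied input is flagged
#'   with p = 1
#' @export
rank_tests <- function(values, grouping) {
  grouping <- as.factor(grouping)
  if (nlevels(grouping) < 2) stop_validation("need at least 2 groups")
  if (length(unique(values)) == 1) {
    res <- list(kruskal = list(statistic = 0, p = 1, degenerate = TRUE))
    if (nlevels(grouping) == 2)
      res$wilcoxon <- list(statistic = NA_real_, p = 1, degenerate = TRUE)
    return(res)
  }
  kw <- stats::kruskal.test(values, grouping)
  res <- list(kruskal = list(statistic = unname(kw$statistic), p = kw$p.value,
                             degenerate = FALSE))
  if (nlevels(grouping) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(values ~ grouping))
    res$wilcoxon <- list(statistic = unname(wt$statistic), p = wt$p.value,
                         degenerate = FALSE)
  }
  res
}

#' Spearman rank correlation between two paired vectors
#'
#' @param x,y paired numeric vectors (>= 3 pairs)
#' @return list with `rho` and `p`
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_validation("need >= 3 complete pairs")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Grubbs test for a single two-sided outlier
#'
#' G = max |x - mean(x)| / sd(x), compared with the t-based critical value
#' G_crit = ((n-1)/sqrt(n)) sqrt(t^2 / (n - 2 + t^2)) where t is the upper
#' alpha/(2n) quantile of t with n-2 df. Applied once, no iterative removal.
#'
#' @param values numeric vector (>= 3 values)
#' @param alpha significance level (default 0.05)
#' @return list: `index` of the most extreme value, `G`, `critical`,
#'   `outlier` (logical decision), `p` (approximate two-sided p)
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop_validation("Grubbs test needs >= 3 values")
  s <- stats::sd(values)
  if (s == 0) return(list(index = NA_integer_, G = 0, critical = NA_real_,
                          outlier = FALSE, p = 1))
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  G <- dev[idx] / s
  tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  # invert the critical-value map for an approximate p
  t2 <- (G^2 * n * (n - 2)) / ((n - 1)^2 - G^2 * n)
  p <- if (t2 <= 0 || !is.finite(t2)) 1 else
    min(1, 2 * n * stats::pt(sqrt(t2), df = n - 2, lower.tail = FALSE))
  list(index = idx, G = unname(G), critical = crit, outlier = G > crit, p = p)
}

#' Linear model of MDI on genomic context and tumor type
#'
#' OLS of MDI on context indicators (vs a reference context) plus tumor-type
#' indicators, as used to ask whether dysregulation concentrates in specific
#' contexts after adjusting for tumor type.
#'
#' @param mdi data.frame from [mdi_by_context()] with a `context` column
#' @param tumor_type per-record tumor-type labels (recycled by sample if
#'   named) or a vector aligned with `mdi` rows
#' @param reference_context context level used as baseline
#' @return data.frame of per-term coefficient, se, t, p (context terms only
#'   flagged in `is_context`)
#' @export
context_model <- function(mdi, tumor_type, reference_context = NULL) {
  if (length(unique(mdi$context)) < 2)
    stop_validation("need >= 2 contexts")
  ctx <- factor(mdi$context)
  if (!is.null(reference_context)) ctx <- stats::relevel(ctx, reference_context)
  dat <- data.frame(mdi = mdi$mdi, context = ctx,
                    tumor_type = factor(tumor_type))
  X <- stats::model.matrix(~ context + tumor_type, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_validation(sprintf("rank-deficient design; aliased: %s",
                            paste(aliased, collapse = ", ")))
  }
  fit <- stats::lm(mdi ~ context + tumor_type, dat)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], p = sm[, 4],
             is_context = grepl("^context", rownames(sm)),
             row.names = NULL, stringsAsFactors = FALSE)
}
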