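# Differential expression by negative-binomial regression with composition
# covariates, integration of modification changes with expression changes,
# and binned-control gene-set expression scores.
#
# The gamma-Poisson GLM is fit directly (log link, size-factor offsets,
# per-gene moment dispersion with optional shrinkage toward the mean trend,
# Wald test on the group coefficient, BH adjustment). This keeps the fit
# oracle-checkable against a Poisson GLM in the small-dispersion limit.

#' Median-of-ratios size factors
#'
#' Per-sample median of count ratios to the per-gene geometric mean,
#' restricted to genes with all-positive counts; factors are rescaled to
#' geometric mean 1.
#'
#' @param counts genes x samples non-negative integer matrix
#' @return named numeric vector of positive size factors
#' @export
estimate_size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos))
    stop_validation("no gene has positive counts in every sample; consider a pseudo-reference")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)                  # log geometric mean per gene
  sf <- exp(apply(lg - ref, 2, stats::median))
  sf / exp(mean(log(sf)))
}

# Moment estimator of the NB dispersion alpha for one gene given fitted
# means mu: solves E[(y - mu)^2] = mu + alpha mu^2. Squared residuals are
# inflated by n/(n - p) to undo the shrinkage from fitting p coefficients.
moment_dispersion <- function(y, mu, n_coef = 0) {
  n <- length(y)
  infl <- if (n > n_coef) n / (n - n_coef) else 1
  num <- sum((y - mu)^2 * infl - mu)
  den <- sum(mu^2)
  max(1e-8, num / den)
}

#' Negative-binomial differential expression
#'
#' Per-gene gamma-Poisson GLM of counts on the tumor-type contrast with
#' covariate adjustment, log link and log(size factor) offsets. Dispersions
#' come from Pearson-style moments around a Poisson fit, optionally shrunk
#' toward the trend mean; the group coefficient is Wald-tested and BH
#' adjusted. All-zero genes are reported with missing statistics.
#'
#' @param counts genes x samples non-negative integer matrix
#' @param sheet sample sheet restricted to contrast group + non-tumor
#' @param contrast_group group label coded 1
#' @param composition optional samples x cell-types matrix; included
#'   cell-type fraction columns are added as covariates
#' @param cell_types composition columns to adjust for
#' @param covariates subset of c("sex", "age") added from the sheet
#' @param size_factors optional; estimated by median-of-ratios when NULL
#' @param dispersion_shrink weight in \[0,1\] pulling per-gene dispersion
#'   toward the mean dispersion (0 = none)
#' @param dispersion optional known common dispersion; skips the moment
#'   estimator (useful for calibration studies and the Poisson limit)
#' @return list: `fits` (gene_id, log2fc, se, wald_p, p_adj, mean_expression,
#'   dispersion, flagged), `size_factors`
#' @export
fit_nb_de <- function(counts, sheet, contrast_group, composition = NULL,
                      cell_types = character(), covariates = c("sex", "age"),
                      size_factors = NULL, dispersion_shrink = 0.2,
                      dispersion = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop_validation("counts must be non-negative integers")
  counts <- counts[, sheet$sample_id, drop = FALSE]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  off <- log(size_factors)
  X <- cbind(intercept = 1, group = as.numeric(sheet$group == contrast_group))
  if ("sex" %in% covariates) X <- cbind(X, sex = as.numeric(sheet$sex == "M"))
  if ("age" %in% covariates) X <- cbind(X, age = sheet$age - mean(sheet$age))
  if (length(cell_types)) {
    if (is.null(composition)) stop_validation("composition required for cell-type covariates")
    X <- cbind(X, composition[sheet$sample_id, cell_types, drop = FALSE])
  }
  drop_const <- apply(X[, -1, drop = FALSE], 2, function(v) stats::var(v) == 0)
  if (any(drop_const)) X <- X[, c(TRUE, !drop_const), drop = FALSE]
  if (nrow(X) <= ncol(X)) stop_validation("need more samples than coefficients")
  n_genes <- nrow(counts)

  log2fc <- se <- wald_p <- disp <- rep(NA_real_, n_genes)
  flagged <- rep(FALSE, n_genes)
  mean_expr <- rowMeans(sweep(counts, 2, size_factors, "/"))

  # pass 1: Poisson fits for mean structure -> moment dispersions
  alphas <- rep(NA_real_, n_genes)
  pois_fits <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    y <- counts[g, ]
    if (all(y == 0)) { flagged[g] <- TRUE; next }
    f <- tryCatch(suppressWarnings(
      stats::glm.fit(X, y, family = stats::poisson(), offset = off)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged) { flagged[g] <- TRUE; next }
    pois_fits[[g]] <- f
    alphas[g] <- if (is.null(dispersion))
      moment_dispersion(y, f$fitted.values, n_coef = ncol(X)) else dispersion
  }
  if (is.null(dispersion)) {
    mean_alpha <- mean(alphas, na.rm = TRUE)
    alphas <- (1 - dispersion_shrink) * alphas + dispersion_shrink * mean_alpha
  }

  # pass 2: NB Wald fits at the fixed per-gene dispersion
  for (g in seq_len(n_genes)) {
    if (flagged[g] || is.na(alphas[g])) next
    y <- counts[g, ]
    disp[g] <- alphas[g]
    fam <- if (alphas[g] < 1e-6) stats::poisson() else
      MASS::negative.binomial(theta = 1 / alphas[g])
    f <- tryCatch(suppressWarnings(
      stats::glm.fit(X, y, family = fam, offset = off,
                     start = pois_fits[[g]]$coefficients)),
      error = function(e) NULL)
    if (is.null(f) || !f$converged || f$rank < ncol(X)) { flagged[g] <- TRUE; next }
    # Wald SE from the unscaled GLM covariance (dispersion parameter 1)
    Xw <- X * sqrt(f$weights)
    cov_u <- tryCatch(solve(crossprod(Xw)), error = function(e) NULL)
    if (is.null(cov_u)) { flagged[g] <- TRUE; next }
    j <- match("group", colnames(X))
    beta <- f$coefficients[j]
    se_b <- sqrt(cov_u[j, j])
    log2fc[g] <- beta / log(2)
    se[g] <- se_b / log(2)
    # t reference with residual df: the plug-in dispersion makes the normal
    # reference anticonservative at cohort-scale n
    wald_p[g] <- 2 * stats::pt(-abs(beta / se_b), df = nrow(X) - ncol(X))
  }
  p_adj <- rep(NA_real_, n_genes)
  ok <- !is.na(wald_p)
  p_adj[ok] <- stats::p.adjust(wald_p[ok], method = "BH")
  list(fits = data.frame(
    gene_id = rownames(counts), log2fc = log2fc, se = se, wald_p = wald_p,
    p_adj = p_adj, mean_expression = mean_expr, dispersion = disp,
    flagged = flagged, row.names = NULL, stringsAsFactors = FALSE),
    size_factors = size_factors)
}

#' Pair modification hits with expression changes and correlate
#'
#' One row per (CpG hit, mapped gene) pair; Pearson correlation between the
#' modification coefficient and the expression log2 fold change, overall and
#' among significantly differentially expressed genes.
#'
#' @param dm_fits data.frame with `probe_id`, `coefficient` (EWAS) or `b`
#'   (cell-type fits); only rows passed in are paired, so filter to hits first
#' @param de_fits data.frame from [fit_nb_de()]
#' @param annotation probe annotation with a `genes` column
#'   (comma-separated symbols)
#' @param p_adj_threshold significance cut for the significant-gene subset
#' @return list: `pairs` (data.frame), `r_all`, `p_all`, `r_sig`, `p_sig`
#'   (NA with `reason` when undefined)
#' @export
hm_expression_correlation <- function(dm_fits, de_fits, annotation,
                                      p_adj_threshold = 0.05) {
  eff_col <- if ("coefficient" %in% names(dm_fits)) "coefficient" else "b"
  genes_str <- annotation$genes[match(dm_fits$probe_id, annotation$probe_id)]
  rows <- list()
  for (i in seq_along(genes_str)) {
    if (is.na(genes_str[i]) || genes_str[i] == "") next
    for (gene in strsplit(genes_str[i], ",")[[1]]) {
      j <- match(gene, de_fits$gene_id)
      if (is.na(j) || is.na(de_fits$log2fc[j])) next
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = dm_fits$probe_id[i], gene_id = gene,
        dm_effect = dm_fits[[eff_col]][i], log2fc = de_fits$log2fc[j],
        p_adj = de_fits$p_adj[j], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) < 3) stop_validation("fewer than 3 mapped (CpG, gene) pairs")
  pairs <- do.call(rbind, rows)
  cor_or_na <- function(x, y) {
    if (length(x) < 3) return(list(r = NA_real_, p = NA_real_, reason = "n < 3"))
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r = NA_real_, p = NA_real_, reason = "zero variance"))
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, reason = NA_character_)
  }
  all_ct <- cor_or_na(pairs$dm_effect, pairs$log2fc)
  sig <- pairs[!is.na(pairs$p_adj) & pairs$p_adj < p_adj_threshold, ]
  sig_ct <- cor_or_na(sig$dm_effect, sig$log2fc)
  list(pairs = pairs, r_all = all_ct$r, p_all = all_ct$p,
       r_sig = sig_ct$r, p_sig = sig_ct$p,
       reason = c(all = all_ct$reason, sig = sig_ct$reason))
}

#' Odds ratio for a 2x2 table with Woolf CI and Fisher exact p
#'
#' The point estimate is the cross-product `(a d)/(b c)`; a zero cell
#' triggers the Haldane-Anscombe correction (+0.5 everywhere) for both the
#' estimate and the CI.
#'
#' @param a,b,c,d cell counts (rows: group 1/2; columns: in/out of context)
#' @param conf confidence level
#' @return list: `or`, `ci` (length 2), `p` (Fisher exact, two-sided)
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf = 0.95) {
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  if (min(a, b, c, d) == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), p = p)
}

#' Promoter / gene-body odds for expression-direction-split hits
#'
#' 2x2 odds ratio of context membership (promoter = TSS200 or TSS1500;
#' gene body = body flag, both configurable) between CpGs whose mapped gene
#' expression increased vs decreased; Woolf CI with Haldane-Anscombe
#' correction on zero cells and Fisher exact p. The raw OR is the
#' uncorrected cross-product unless a zero cell forces the correction.
#'
#' @param pairs data.frame with `probe_id` and `log2fc` (e.g. the
#'   significant subset of [hm_expression_correlation()] pairs)
#' @param annotation probe annotation
#' @param promoter_cols,body_cols annotation flag columns defining contexts
#' @return data.frame: context, a, b, c, d, or, ci_low, ci_high, p
#' @export
promoter_genebody_odds <- function(pairs, annotation,
                                   promoter_cols = c("TSS200", "TSS1500"),
                                   body_cols = "body") {
  up <- pairs[pairs$log2fc > 0, ]
  down <- pairs[pairs$log2fc < 0, ]
  if (!nrow(up) || !nrow(down))
    stop_validation("both expression-direction groups must be non-empty")
  in_ctx <- function(probes, cols) {
    idx <- match(probes, annotation$probe_id)
    flags <- rowSums(annotation[idx, cols, drop = FALSE]) > 0
    flags
  }
  one <- function(cols, label) {
    a <- sum(in_ctx(up$probe_id, cols));  b <- nrow(up) - a
    c <- sum(in_ctx(down$probe_id, cols)); d <- nrow(down) - c
    o <- odds_ratio_2x2(a, b, c, d)
    data.frame(context = label, a = a, b = b, c = c, d = d, or = o$or,
               ci_low = o$ci[1], ci_high = o$ci[2], p = o$p,
               stringsAsFactors = FALSE)
  }
  rbind(one(promoter_cols, "promoter"), one(body_cols, "gene_body"))
}

#' Binned-control gene-set expression scores
#'
#' Genes are binned by average expression; each set gene is matched with
#' `n_ctrl` control genes sampled from its bin (set genes excluded). The
#' per-cell score is mean(set expression) - mean(control expression).
#' Group differences per cell type are tested with Wilcoxon rank-sum.
#'
#' @param expression cells x genes normalized matrix (e.g. log1p CPM-scaled)
#' @param gene_set character vector of gene ids
#' @param cell_meta optional data.frame with `cell_type` and `group` per cell
#'   (rows aligned with `expression`); enables group comparisons
#' @param n_bins number of average-expression bins
#' @param n_ctrl controls sampled per set gene (must be >= 1)
#' @param seed RNG seed for control sampling
#' @return list: `scores` (per cell), `comparisons` (per cell type Wilcoxon
#'   p of tumor vs reference group, when `cell_meta` given)
#' @export
module_score <- function(expression, gene_set, cell_meta = NULL,
                         n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (n_ctrl < 1) stop_validation("n_ctrl must be >= 1")
  if (n_bins < 1) stop_validation("n_bins must be >= 1")
  genes <- colnames(expression)
  set_genes <- intersect(gene_set, genes)
  if (!length(set_genes)) stop_validation("gene set has no expressed genes")
  avg <- colMeans(expression)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bins) <- genes
  ctrl <- with_seed(seed, {
    unlist(lapply(set_genes, function(g) {
      pool <- genes[bins == bins[g] & !(genes %in% set_genes)]
      if (!length(pool)) return(character())
      sample(pool, min(n_ctrl, length(pool)))
    }))
  })
  ctrl <- unique(ctrl)
  if (!length(ctrl)) stop_validation("no control genes available outside the set")
  scores <- rowMeans(expression[, set_genes, drop = FALSE]) -
    rowMeans(expression[, ctrl, drop = FALSE])
  res <- list(scores = scores, set_genes = set_genes, n_ctrl_genes = length(ctrl))
  if (!is.null(cell_meta)) {
    groups <- unique(cell_meta$group)
    ref <- groups[1]
    comp <- list()
    for (ct in unique(cell_meta$cell_type)) {
      for (g in setdiff(groups, ref)) {
        x <- scores[cell_meta$cell_type == ct & cell_meta$group == g]
        y <- scores[cell_meta$cell_type == ct & cell_meta$group == ref]
        if (length(x) >= 2 && length(y) >= 2) {
          wt <- suppressWarnings(stats::wilcox.test(x, y))
          comp[[length(comp) + 1L]] <- data.frame(
            cell_type = ct, group = g, reference = ref,
            mean_score = mean(x), mean_ref = mean(y), p = wt$p.value)
        }
      }
    }
    res$comparisons <- if (length(comp)) do.call(rbind, comp) else NULL
  }
  res
}
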