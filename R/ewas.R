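# Covariate-adjusted epigenome-wide association models with empirical-Bayes
# variance moderation and stepwise cell-composition adjustment.
#
# Each tumor type is contrasted against non-tumor tissue in its own model
# (samples restricted to that group plus the non-tumor reference). Per-probe
# OLS of beta on group + sex + centered age + purity (+ k cell-type
# fractions); residual variances are shrunk toward a scaled inverse-chi-square
# prior whose parameters (d0, s0^2) are estimated by method of moments on the
# log residual variances, and the moderated t uses d_residual + d0 degrees of
# freedom. Probes with missing values are fit on complete cases with
# per-probe df.

#' Build the EWAS design matrix
#'
#' Columns: intercept, group indicator (non-tumor = 0), sex indicator (M = 1),
#' mean-centered age, tumor purity, then the included cell-type fractions in
#' the stated order. Constant columns (e.g. sex in a single-sex cohort) are
#' dropped with a warning.
#'
#' @param sheet sample sheet (`sample_id`, `group`, `sex`, `age`, `purity`)
#'   already restricted to the contrast group plus non-tumor samples
#' @param composition samples x cell-types matrix (rows indexed by sample id)
#' @param contrast_group tumor-type label coded 1 in the group column
#' @param covariates subset of c("sex", "age", "purity") to adjust for
#' @param cell_types ordered subset of composition columns to include (k = 0..5)
#' @param condition_threshold condition-number limit before erroring
#' @return list: `X` (design matrix), `column_map`, `contrast` (column name)
#' @export
build_design <- function(sheet, composition, contrast_group,
                         covariates = c("sex", "age", "purity"),
                         cell_types = character(),
                         condition_threshold = 1e10) {
  if (!contrast_group %in% sheet$group)
    stop_validation(sprintf("contrast group '%s' not in sample sheet", contrast_group))
  bad_ct <- setdiff(cell_types, colnames(composition))
  if (length(bad_ct))
    stop_validation(sprintf("cell types absent from composition: %s",
                            paste(bad_ct, collapse = ", ")))
  n <- nrow(sheet)
  X <- cbind(intercept = rep(1, n),
             group = as.numeric(sheet$group == contrast_group))
  if ("sex" %in% covariates) X <- cbind(X, sex = as.numeric(sheet$sex == "M"))
  if ("age" %in% covariates) X <- cbind(X, age = sheet$age - mean(sheet$age))
  if ("purity" %in% covariates) X <- cbind(X, purity = sheet$purity)
  if (length(cell_types))
    X <- cbind(X, composition[sheet$sample_id, cell_types, drop = FALSE])
  rownames(X) <- sheet$sample_id
  const <- apply(X[, -1, drop = FALSE], 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning(sprintf("dropping constant design columns: %s",
                    paste(names(const)[const], collapse = ", ")))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  d <- svd(scale(X[, -1, drop = FALSE], center = FALSE, scale = FALSE))$d
  if (length(d) > 1 && d[1] / max(d[length(d)], .Machine$double.eps) > condition_threshold)
    stop_validation("design is numerically collinear; inspect cell-type and covariate columns")
  list(X = X, column_map = colnames(X), contrast = "group")
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used by the method-of-moments prior fit.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# Method-of-moments fit of the scaled inverse-chi-square prior (d0, s0^2) to
# per-probe residual variances s2 with df degrees of freedom, on the log
# scale: e = log s2 - digamma(df/2) + log(df/2) has mean log s0^2 -
# digamma(d0/2) + log(d0/2) and variance trigamma(df/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok)) return(list(d0 = 0, s0_sq = 0))
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2) return(list(d0 = Inf, s0_sq = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  resid_var <- sum((e - ebar)^2) / (length(e) - 1) - mean(trigamma(df / 2))
  if (resid_var <= 0) {
    # no excess spread beyond chi-square sampling noise: infinite prior df;
    # the pooled variance keeps equal inputs as an exact fixed point
    d0 <- Inf
    s0_sq <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(resid_var)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Per-probe moderated linear-model fits
#'
#' OLS per probe with a shared design; residual variances are squeezed toward
#' the empirical prior and the contrast coefficient is tested with a
#' moderated t on `df_residual + d0` df. BH q-values and hyper/hypo
#' direction are attached.
#'
#' @param betas probes x samples matrix (values in \[0,1\], NAs allowed)
#' @param design output of [build_design()] (or a list with `X`, `contrast`)
#' @param prior_df override for d0: `NULL` (estimate; default), `0` (no
#'   moderation: ordinary t), or `Inf` (full shrinkage to the pooled prior)
#' @return list: `fits` (data.frame: probe_id, coefficient, se, t_mod,
#'   df_total, p, q, direction, n_used), `moderation` (d0, s0_sq)
#' @export
fit_moderated <- function(betas, design, prior_df = NULL) {
  X <- design$X
  jc <- match(design$contrast, colnames(X))
  n <- ncol(betas); p <- ncol(X)
  if (n <= p) stop_validation("need more samples than design columns")
  if (!identical(colnames(betas), rownames(X)))
    betas <- betas[, rownames(X), drop = FALSE]

  complete <- !rowSums(is.na(betas))
  coef <- se_unscaled <- s2 <- rep(NA_real_, nrow(betas))
  df <- rep(NA_real_, nrow(betas))
  n_used <- integer(nrow(betas))

  if (any(complete)) {
    XtXi <- solve(crossprod(X))
    H <- X %*% XtXi                       # n x p
    B <- betas[complete, , drop = FALSE] %*% H      # probes x p coefficients
    R <- betas[complete, , drop = FALSE] - B %*% t(X)
    rss <- rowSums(R^2)
    dfc <- n - p
    coef[complete] <- B[, jc]
    s2[complete] <- rss / dfc
    se_unscaled[complete] <- sqrt(XtXi[jc, jc])
    df[complete] <- dfc
    n_used[complete] <- n
  }
  for (i in which(!complete)) {
    ok <- !is.na(betas[i, ])
    n_used[i] <- sum(ok)
    if (sum(ok) <= p) next                # flagged missing, not dropped
    f <- stats::lm.fit(X[ok, , drop = FALSE], betas[i, ok])
    if (f$rank < p) next
    coef[i] <- f$coefficients[jc]
    df[i] <- sum(ok) - p
    s2[i] <- sum(f$residuals^2) / df[i]
    se_unscaled[i] <- sqrt(solve(crossprod(X[ok, , drop = FALSE]))[jc, jc])
  }

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, df)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_sq = mean(s2, na.rm = TRUE))
  } else {
    prior <- list(d0 = prior_df, s0_sq = exp(mean(log(s2[s2 > 0]), na.rm = TRUE)))
  }
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s0_sq, length(s2)) else
    (d0 * prior$s0_sq + df * s2) / (d0 + df)
  df_total <- df + d0
  t_mod <- coef / (se_unscaled * sqrt(s2_post))
  pval <- 2 * stats::pt(-abs(t_mod), df_total)
  q <- rep(NA_real_, length(pval))
  ok <- !is.na(pval)
  q[ok] <- stats::p.adjust(pval[ok], method = "BH")
  fits <- data.frame(
    probe_id = rownames(betas), coefficient = coef,
    se = se_unscaled * sqrt(s2_post), t_mod = t_mod, df_total = df_total,
    p = pval, q = q,
    direction = ifelse(is.na(coef), NA, ifelse(coef >= 0, "hyper", "hypo")),
    n_used = n_used, row.names = NULL, stringsAsFactors = FALSE)
  list(fits = fits, moderation = list(d0 = d0, s0_sq = prior$s0_sq))
}

#' Stepwise cell-composition adjustment series
#'
#' Fits the contrast model with k = 0..K cell-type fraction covariates added
#' cumulatively in the stated order and records per-k significant-hit counts.
#'
#' @param betas probes x samples matrix
#' @param sheet sample sheet restricted to contrast group + non-tumor
#' @param composition samples x cell-types matrix
#' @param contrast_group tumor-type label
#' @param cell_type_order inclusion order (default NEU, NSC, OPC, RGC, UBC)
#' @param covariates passed to [build_design()]
#' @param q_threshold hit threshold on BH q
#' @param prior_df passed to [fit_moderated()]
#' @return list: `fits` (per-k list), `hit_counts` (data.frame k, n_hits),
#'   `hit_sets` (per-k probe-id vectors)
#' @export
stepwise_series <- function(betas, sheet, composition, contrast_group,
                            cell_type_order = c("NEU", "NSC", "OPC", "RGC", "UBC"),
                            covariates = c("sex", "age", "purity"),
                            q_threshold = 0.05, prior_df = NULL) {
  bad <- setdiff(cell_type_order, colnames(composition))
  if (length(bad))
    stop_validation(sprintf("cell types absent from composition: %s",
                            paste(bad, collapse = ", ")))
  fits <- list(); hit_sets <- list()
  ks <- 0:length(cell_type_order)
  for (k in ks) {
    des <- build_design(sheet, composition, contrast_group,
                        covariates = covariates,
                        cell_types = cell_type_order[seq_len(k)])
    fm <- fit_moderated(betas, des, prior_df = prior_df)
    key <- as.character(k)
    fits[[key]] <- fm$fits
    hit_sets[[key]] <- fm$fits$probe_id[!is.na(fm$fits$q) & fm$fits$q < q_threshold]
  }
  list(fits = fits,
       hit_counts = data.frame(k = ks, n_hits = vapply(fits, function(f)
         sum(f$q < q_threshold, na.rm = TRUE), 0L)),
       hit_sets = hit_sets)
}

#' Cross-group hit sharing summary
#'
#' Exact set algebra over per-group significant probe sets: pairwise and
#' higher-order intersections, probes shared across all groups, and
#' group-specific fractions relative to the union of all hits.
#'
#' @param fits_per_group named list of fit data.frames (from
#'   [fit_moderated()]) or of probe-id vectors
#' @param q_threshold hit threshold when fit tables are supplied
#' @return list: `hit_sets`, `shared_all`, `n_union`, `specific_fraction`
#'   (per group), `shared_all_fraction`, `venn` (region cardinalities from
#'   [sharing_sets()])
#' @export
summarize_hits <- function(fits_per_group, q_threshold = 0.05) {
  if (length(fits_per_group) < 2) stop_validation("need >= 2 groups")
  hit_sets <- lapply(fits_per_group, function(f) {
    if (is.data.frame(f)) f$probe_id[!is.na(f$q) & f$q < q_threshold] else f
  })
  universe <- Reduce(union, hit_sets)
  shared_all <- Reduce(intersect, hit_sets)
  specific <- vapply(names(hit_sets), function(g) {
    others <- Reduce(union, hit_sets[setdiff(names(hit_sets), g)])
    length(setdiff(hit_sets[[g]], others))
  }, 0L)
  n_union <- length(universe)
  list(hit_sets = hit_sets, shared_all = shared_all, n_union = n_union,
       specific_fraction = if (n_union) specific / n_union else specific * NA_real_,
       shared_all_fraction = if (n_union) length(shared_all) / n_union else NA_real_,
       venn = sharing_sets(hit_sets))
}
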