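# Cell-type-specific differential modification via composition-phenotype
# interaction models.
#
# Per probe i the model is
#   beta_i = sum_k w_ik a_k + sum_k (w_ik x_i) b_k + gamma' z_i + eps_i
# with no global intercept (the composition block spans it, since the w_ik
# sum to 1 once a remainder column is appended). x is the 0/1 tumor
# indicator; b_k is the change in cell type k and is tested per cell type
# with a two-sided t-test, BH-adjusted within cell type. The default
# aggregation collapses the granular progenitor-like types (NSC, RGC, OPC,
# UBC) into one super-type alongside the neuronal-like type (NEU), limiting
# model size at small n.

#' Default neuronal-like / progenitor-like aggregation scheme
#'
#' @return named character vector mapping granular type -> super-type
#' @export
default_aggregation_scheme <- function() {
  c(NEU = "neuronal_like", NSC = "progenitor_like", RGC = "progenitor_like",
    OPC = "progenitor_like", UBC = "progenitor_like", other = "other")
}

#' Aggregate a composition matrix to super-types
#'
#' Super-type fractions are sums of member fractions; row sums (the simplex)
#' are preserved exactly.
#'
#' @param composition samples x granular-cell-types matrix
#' @param scheme named character vector granular -> super-type
#' @return samples x super-types matrix
#' @export
aggregate_celltypes <- function(composition, scheme = default_aggregation_scheme()) {
  unmapped <- setdiff(colnames(composition), names(scheme))
  if (length(unmapped))
    stop_validation(sprintf("cell types not covered by scheme: %s",
                            paste(unmapped, collapse = ", ")))
  supers <- unique(unname(scheme[colnames(composition)]))
  out <- sapply(supers, function(s) {
    members <- colnames(composition)[scheme[colnames(composition)] == s]
    rowSums(composition[, members, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(composition),
                                       dimnames = list(rownames(composition), supers))
  out
}

#' Fit the cell-type interaction model per probe
#'
#' @param betas probes x samples matrix
#' @param composition samples x super-types matrix; if rows sum to < 1 a
#'   remainder `"other"` column is appended so the block spans the intercept
#' @param phenotype 0/1 tumor indicator per sample (named or aligned)
#' @param covariates optional samples x covariates numeric matrix added
#'   additively (not interacted); default NULL
#' @param q_threshold used only to annotate, hits are thresholded downstream
#' @return data.frame: probe_id, cell_type, b, se, t, p, q, direction
#' @export
fit_dmct <- function(betas, composition, phenotype, covariates = NULL,
                     q_threshold = 0.05) {
  W <- as.matrix(composition)
  if (any(W < -1e-9)) stop_validation("composition fractions must be non-negative")
  rs <- rowSums(W)
  if (any(rs > 1 + 1e-6)) stop_validation("composition rows exceed the simplex")
  if (any(rs < 1 - 1e-9)) W <- cbind(W, other = pmax(0, 1 - rs))
  K <- ncol(W)
  vars <- apply(W, 2, stats::var)
  # a single constant column is the intercept-free bulk model; with K > 1 a
  # zero-variance column makes the interaction block unidentifiable
  if (K > 1 && any(vars < 1e-12))
    stop_validation(sprintf("near-degenerate composition for: %s",
                            paste(colnames(W)[vars < 1e-12], collapse = ", ")))
  x <- as.numeric(phenotype)
  n <- nrow(W)
  inter <- W * x
  colnames(inter) <- paste0(colnames(W), ":group")
  X <- cbind(W, inter)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  p <- ncol(X)
  if (n <= p) stop_validation("need n > 2K + covariates samples")
  if (!is.null(colnames(betas)) && !is.null(rownames(W)))
    betas <- betas[, rownames(W), drop = FALSE]

  XtXi <- solve(crossprod(X))
  B <- betas %*% X %*% XtXi
  R <- betas - B %*% t(X)
  df <- n - p
  s2 <- rowSums(R^2) / df
  jidx <- K + seq_len(K)        # interaction columns
  out <- list()
  for (j in seq_along(jidx)) {
    col <- jidx[j]
    b <- B[, col]
    se <- sqrt(s2 * XtXi[col, col])
    tstat <- b / se
    pval <- 2 * stats::pt(-abs(tstat), df)
    out[[j]] <- data.frame(
      probe_id = rownames(betas), cell_type = colnames(W)[j],
      b = unname(b), se = unname(se), t = unname(tstat), p = unname(pval),
      q = stats::p.adjust(pval, method = "BH"),
      direction = ifelse(b >= 0, "hyper", "hypo"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Threshold and share cell-type-specific hits
#'
#' @param fits_per_group named list of [fit_dmct()] outputs (one per tumor
#'   type), or a single fit data.frame
#' @param q_threshold significance threshold on q
#' @return list per cell type: `hits` (per-group probe-id lists split by
#'   direction), `shared` (probes in every group's hit set), `counts`
#' @export
classify_dmct <- function(fits_per_group, q_threshold = 0.05) {
  if (is.data.frame(fits_per_group)) fits_per_group <- list(all = fits_per_group)
  cell_types <- unique(fits_per_group[[1]]$cell_type)
  res <- list()
  for (ct in cell_types) {
    sets <- lapply(fits_per_group, function(f) {
      sub <- f[f$cell_type == ct & !is.na(f$q) & f$q < q_threshold, ]
      list(all = sub$probe_id,
           hyper = sub$probe_id[sub$direction == "hyper"],
           hypo = sub$probe_id[sub$direction == "hypo"])
    })
    all_sets <- lapply(sets, `[[`, "all")
    res[[ct]] <- list(
      hits = sets,
      shared = Reduce(intersect, all_sets),
      counts = data.frame(group = names(sets),
                          n_hits = vapply(all_sets, length, 0L),
                          row.names = NULL))
  }
  res
}
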