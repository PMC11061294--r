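# Synthetic-cohort generator.
#
# Emulates the statistical structure of a paired BS/oxBS EPIC-style study of
# pediatric CNS tumors with matched cell-composition, expression-count and
# single-nucleus fixtures: low-prevalence 5hmC (about 6% of 5mC genome-wide),
# beta-distributed measurement noise, Dirichlet cell compositions that differ
# between groups, cell-type-specific planted modification effects, and
# NB-distributed gene counts. Every operation is deterministic given the
# config seed, and planted truth is retained for recovery scoring.

DEFAULT_CELL_TYPES <- c("NEU", "NSC", "OPC", "RGC", "UBC", "other")

DEFAULT_CONTEXTS <- c("TSS200", "TSS1500", "body", "exon1", "UTR5", "UTR3",
                      "exon_bnd", "enhancer", "DHS", "TFBS", "open_chromatin")

#' Configuration for the synthetic cohort generator
#'
#' Bundles cohort dimensions, composition structure, the genome-wide
#' 5hmC/5mC prevalence ratio, measurement precision and NB dispersion.
#'
#' @param n_probes number of CpG probes
#' @param cell_types character vector of cell-type labels; a trailing
#'   remainder type is conventional
#' @param groups named integer vector: samples per group; the first group is
#'   treated as the non-tumor reference by downstream defaults
#' @param dirichlet_concentrations named list (one positive numeric vector of
#'   length `length(cell_types)` per group); `NULL` uses a common flat prior
#' @param hmc_to_mc_ratio target genome-wide mean(5hmC)/mean(5mC), in (0, 1]
#' @param measurement_precision Beta pseudo-count controlling array noise
#' @param nb_dispersion NB dispersion (alpha; variance = mu + alpha mu^2)
#' @param n_genes number of genes for the counts module
#' @param confound_covariates if TRUE, age/purity are shifted by group so the
#'   confounded regime can be exercised
#' @param seed integer master seed
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_probes = 10000,
                          cell_types = DEFAULT_CELL_TYPES,
                          groups = c(NT = 4L, ATC = 8L, EMB = 6L, EPN = 10L, GNN = 8L),
                          dirichlet_concentrations = NULL,
                          hmc_to_mc_ratio = 0.06,
                          measurement_precision = 200,
                          nb_dispersion = 0.1,
                          n_genes = 2000,
                          confound_covariates = FALSE,
                          seed = 1L) {
  if (!is.numeric(n_probes) || n_probes < 1)
    stop_config("must be a positive count", "n_probes")
  if (length(cell_types) < 1 || anyDuplicated(cell_types))
    stop_config("must be unique labels", "cell_types")
  if (is.null(names(groups)) || any(groups < 1))
    stop_config("must be a named vector of positive counts", "groups")
  if (!is.numeric(hmc_to_mc_ratio) || hmc_to_mc_ratio <= 0 || hmc_to_mc_ratio > 1)
    stop_config("must lie in (0, 1]", "hmc_to_mc_ratio")
  if (measurement_precision <= 0)
    stop_config("must be positive", "measurement_precision")
  if (nb_dispersion <= 0)
    stop_config("must be positive", "nb_dispersion")
  if (is.null(dirichlet_concentrations)) {
    K <- length(cell_types)
    dirichlet_concentrations <- lapply(names(groups), function(g) rep(10, K))
    names(dirichlet_concentrations) <- names(groups)
  }
  if (!setequal(names(dirichlet_concentrations), names(groups)))
    stop_config("must name every group", "dirichlet_concentrations")
  for (g in names(groups)) {
    a <- dirichlet_concentrations[[g]]
    if (length(a) != length(cell_types) || any(a <= 0))
      stop_config(sprintf("group '%s' needs %d positive values", g, length(cell_types)),
                  "dirichlet_concentrations")
  }
  structure(list(
    n_probes = as.integer(n_probes), cell_types = cell_types,
    groups = groups, dirichlet_concentrations = dirichlet_concentrations,
    hmc_to_mc_ratio = hmc_to_mc_ratio,
    measurement_precision = measurement_precision,
    nb_dispersion = nb_dispersion, n_genes = as.integer(n_genes),
    confound_covariates = isTRUE(confound_covariates),
    seed = as.integer(seed)), class = "cohort_config")
}

probe_ids <- function(n) sprintf("cg%08d", seq_len(n))

#' Default group-differing Dirichlet concentrations
#'
#' Emulates the compositional contrast between non-tumor brain (neuron-rich)
#' and tumors (progenitor-leaning), with mild variation across tumor types.
#' Assumes the standard cell-type panel (NEU, NSC, OPC, RGC, UBC, other) and
#' treats the first group as the non-tumor reference.
#'
#' @param groups named sample counts as in [cohort_config()]
#' @return named list of concentration vectors, one per group
#' @export
default_group_concentrations <- function(groups) {
  # totals kept modest so within-group compositional spread is realistic
  # and group labels are not fully determined by composition
  ref <- c(12, 2, 2, 2, 2, 4)                 # neuron-rich non-tumor tissue
  tumor_base <- list(c(4, 6, 5, 4, 3, 4), c(3, 7, 4, 5, 3, 4),
                     c(5, 4, 6, 3, 4, 4), c(6, 4, 3, 5, 3, 4))
  out <- vector("list", length(groups))
  names(out) <- names(groups)
  out[[1]] <- ref
  for (i in seq_along(out)[-1])
    out[[i]] <- tumor_base[[(i - 2) %% length(tumor_base) + 1]]
  out
}

#' Simulate per-cell-type true 5mC and 5hmC profiles
#'
#' 5mC is drawn from a bimodal Beta mixture (mostly-methylated and
#' mostly-unmethylated compartments, as on real arrays). 5hmC is a small
#' fraction of the unmethylated headroom, `h = (1 - m) * f`, with `f`
#' calibrated so the genome-wide mean(h)/mean(m) matches
#' `config$hmc_to_mc_ratio`; the construction guarantees m + h <= 1.
#'
#' @param config a [cohort_config()]
#' @return list with `m` and `h`: probes x cell-types matrices
#' @export
simulate_reference_profiles <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "profiles"), {
    n <- config$n_probes
    K <- length(config$cell_types)
    # bimodal 5mC compartment shared across cell types, with per-cell-type
    # jitter so deconvolution has signal to work with
    hi <- stats::runif(n) < 0.6
    m_base <- ifelse(hi, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
    mean_m <- 0.6 * (8 / 10) + 0.4 * (2 / 10)      # mixture mean, 0.56
    # target E[h] = ratio * E[m]; h = (1-m) * f with f ~ Beta(mean = mu_f)
    mu_f <- config$hmc_to_mc_ratio * mean_m / (1 - mean_m)
    mu_f <- min(mu_f, 0.95)
    f_prec <- 30
    m <- h <- matrix(NA_real_, n, K, dimnames = list(probe_ids(n), config$cell_types))
    for (k in seq_len(K)) {
      jitter <- stats::rnorm(n, 0, 0.5)
      mk <- stats::plogis(stats::qlogis(clamp01(m_base, 1e-6)) + jitter)
      fk <- stats::rbeta(n, mu_f * f_prec, (1 - mu_f) * f_prec)
      m[, k] <- mk
      h[, k] <- (1 - mk) * fk
    }
    list(m = m, h = h)
  })
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  sw <- rowSums(x)
  # all-zero rows can only arise from degenerate alpha; renormalize safely
  x / ifelse(sw > 0, sw, 1)
}

#' Simulate the sample sheet and cell-composition matrix
#'
#' Compositions are Dirichlet draws with per-group concentrations; sex, age
#' at diagnosis, tumor purity and grade are drawn independently of group
#' unless `config$confound_covariates` is set.
#'
#' @param config a [cohort_config()]
#' @return list with `sheet` (data.frame) and `composition`
#'   (samples x cell-types matrix, rows on the simplex)
#' @export
simulate_samples <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(config$groups) < 2)
    stop_config("need at least 2 groups", "groups")
  with_seed(derive_seed(config$seed, "samples"), {
    groups <- config$groups
    n <- sum(groups)
    grp <- rep(names(groups), groups)
    ids <- sprintf("S%03d", seq_len(n))
    comp <- matrix(NA_real_, n, length(config$cell_types),
                   dimnames = list(ids, config$cell_types))
    for (g in names(groups)) {
      idx <- which(grp == g)
      comp[idx, ] <- rdirichlet(length(idx), config$dirichlet_concentrations[[g]])
    }
    age <- stats::runif(n, 1, 18)
    purity <- stats::rbeta(n, 8, 2)
    if (config$confound_covariates) {
      shift <- as.numeric(factor(grp, levels = names(groups))) - 1
      age <- pmin(18, age + shift)
      purity <- clamp01(purity + 0.03 * shift)
    }
    sheet <- data.frame(
      sample_id = ids, group = grp,
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = age, purity = purity,
      grade = sample(paste0("G", 1:4), n, replace = TRUE),
      stringsAsFactors = FALSE)
    list(sheet = sheet, composition = comp)
  })
}

#' Build a planted-effect truth table
#'
#' @param probe_id,cell_type,group,delta_5hmC,delta_5mC vectors recycled to a
#'   common length; `cell_type` may be `"bulk"` (effect in every cell type)
#' @return data.frame of class `truth_table`
#' @export
truth_table <- function(probe_id = character(), cell_type = character(),
                        group = character(), delta_5hmC = numeric(),
                        delta_5mC = numeric()) {
  tt <- data.frame(probe_id = probe_id, cell_type = cell_type, group = group,
                   delta_5hmC = delta_5hmC, delta_5mC = delta_5mC,
                   stringsAsFactors = FALSE)
  if (nrow(tt) && any(abs(tt$delta_5hmC) > 1 | abs(tt$delta_5mC) > 1))
    stop_validation("planted deltas must lie in [-1, 1]")
  if (anyDuplicated(tt[, c("probe_id", "cell_type", "group")]))
    stop_validation("duplicate (probe, cell_type, group) rows in truth table")
  class(tt) <- c("truth_table", "data.frame")
  tt
}

#' Apply planted effects to reference profiles
#'
#' Returns one modified profile pair per group. Deltas are added to the true
#' (m, h) values and then clipped to keep m >= 0, h >= 0, m + h <= 1; entries
#' whose realized delta differs from the request are listed in the clip
#' report so truth tables stay auditable.
#'
#' @param truth a [truth_table()]
#' @param profiles output of [simulate_reference_profiles()]
#' @param groups group labels to instantiate (default: groups in `truth`)
#' @return list with `profiles` (named list per group of `list(m, h)`) and
#'   `clip_report` (data.frame of entries that were clipped)
#' @export
plant_effects <- function(truth, profiles, groups = NULL) {
  if (is.null(groups)) groups <- unique(truth$group)
  cts <- colnames(profiles$m)
  bad <- setdiff(truth$probe_id, rownames(profiles$m))
  if (length(bad)) stop_validation(sprintf("unknown probes in truth table: %s",
                                           paste(utils::head(bad, 3), collapse = ", ")))
  bad_ct <- setdiff(setdiff(truth$cell_type, "bulk"), cts)
  if (length(bad_ct)) stop_validation(sprintf("unknown cell types in truth table: %s",
                                              paste(bad_ct, collapse = ", ")))
  out <- list()
  clips <- list()
  for (g in groups) {
    m <- profiles$m; h <- profiles$h
    rows <- truth[truth$group == g, , drop = FALSE]
    if (nrow(rows)) {
      for (i in seq_len(nrow(rows))) {
        p <- rows$probe_id[i]
        targets <- if (rows$cell_type[i] == "bulk") cts else rows$cell_type[i]
        for (ct in targets) {
          m_new <- m[p, ct] + rows$delta_5mC[i]
          h_new <- h[p, ct] + rows$delta_5hmC[i]
          m_clip <- min(max(m_new, 0), 1)
          h_clip <- min(max(h_new, 0), 1 - m_clip)
          if (abs(m_clip - m_new) > 1e-12 || abs(h_clip - h_new) > 1e-12)
            clips[[length(clips) + 1L]] <- data.frame(
              probe_id = p, cell_type = ct, group = g,
              requested_dm = rows$delta_5mC[i], requested_dh = rows$delta_5hmC[i],
              realized_dm = m_clip - profiles$m[p, ct],
              realized_dh = h_clip - profiles$h[p, ct])
          m[p, ct] <- m_clip
          h[p, ct] <- h_clip
        }
      }
    }
    out[[g]] <- list(m = m, h = h)
  }
  clip_report <- if (length(clips)) do.call(rbind, clips) else
    data.frame(probe_id = character(), cell_type = character(), group = character(),
               requested_dm = numeric(), requested_dh = numeric(),
               realized_dm = numeric(), realized_dh = numeric())
  list(profiles = out, clip_report = clip_report)
}

#' Render noisy BS and oxBS measurements from mixed cell-type profiles
#'
#' The bulk truth for sample i is the composition-weighted mixture of its
#' group's cell-type profiles; BS measures m + h, oxBS measures m, and the
#' observed betas are Beta draws with those expectations and precision
#' `config$measurement_precision` (shape = mean * precision).
#'
#' @param group_profiles named list per group of `list(m, h)` (see
#'   [plant_effects()]); a single `list(m, h)` is recycled to every group
#' @param composition samples x cell-types matrix on the simplex
#' @param sheet sample sheet with `sample_id` and `group`
#' @param config a [cohort_config()]
#' @return list with matrices `bs`, `ox` (observed) and `true_m`, `true_h`
#'   (noise-free bulk expectations), probes x samples
#' @export
render_measurements <- function(group_profiles, composition, sheet, config) {
  if (!is.null(group_profiles$m)) {
    gp <- lapply(unique(sheet$group), function(g) group_profiles)
    names(gp) <- unique(sheet$group)
    group_profiles <- gp
  }
  bad <- rowSums(composition)
  if (any(abs(bad - 1) > 1e-6))
    stop_validation("composition rows must sum to 1 (tolerance 1e-6)")
  ref <- group_profiles[[1]]
  if (!identical(colnames(composition), colnames(ref$m)))
    stop_validation("composition columns must align with profile cell types")
  n_probes <- nrow(ref$m)
  samples <- sheet$sample_id
  true_m <- true_h <- matrix(NA_real_, n_probes, length(samples),
                             dimnames = list(rownames(ref$m), samples))
  for (i in seq_along(samples)) {
    g <- sheet$group[i]
    if (is.null(group_profiles[[g]]))
      stop_validation(sprintf("no profiles for group '%s'", g))
    w <- composition[samples[i], ]
    true_m[, i] <- group_profiles[[g]]$m %*% w
    true_h[, i] <- group_profiles[[g]]$h %*% w
  }
  with_seed(derive_seed(config$seed, "measurements"), {
    prec <- config$measurement_precision
    draw <- function(mu) {
      v <- clamp01(as.vector(mu), 1e-9)
      matrix(stats::rbeta(length(v), v * prec, (1 - v) * prec),
             nrow = nrow(mu), dimnames = dimnames(mu))
    }
    list(bs = draw(true_m + true_h), ox = draw(true_m),
         true_m = true_m, true_h = true_h)
  })
}

#' Simulate an NB gene-by-sample counts matrix
#'
#' Counts are NB with mean `baseline * 2^(log2FC[gene, group]) * size_factor`
#' and dispersion `config$nb_dispersion`.
#'
#' @param config a [cohort_config()]
#' @param sheet sample sheet with `sample_id`, `group`
#' @param de_truth optional genes x groups matrix of planted log2 fold
#'   changes (missing groups mean 0)
#' @param size_factors optional per-sample positive scalars (default 1)
#' @param baseline_mean lognormal location for per-gene baselines
#' @return list with `counts` (integer matrix), `baseline`, `log2fc` truth
#' @export
simulate_counts <- function(config, sheet, de_truth = NULL,
                            size_factors = NULL, baseline_mean = 100) {
  if (baseline_mean <= 0) stop_config("must be positive", "baseline_mean")
  n_genes <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(n_genes))
  samples <- sheet$sample_id
  if (is.null(size_factors)) size_factors <- stats::setNames(rep(1, length(samples)), samples)
  if (any(size_factors <= 0)) stop_config("must be positive", "size_factors")
  with_seed(derive_seed(config$seed, "counts"), {
    baseline <- stats::rlnorm(n_genes, log(baseline_mean), 1)
    names(baseline) <- genes
    lfc <- matrix(0, n_genes, length(unique(sheet$group)),
                  dimnames = list(genes, unique(sheet$group)))
    if (!is.null(de_truth)) {
      shared_g <- intersect(colnames(de_truth), colnames(lfc))
      shared_r <- intersect(rownames(de_truth), genes)
      lfc[shared_r, shared_g] <- de_truth[shared_r, shared_g]
    }
    counts <- matrix(0L, n_genes, length(samples),
                     dimnames = list(genes, samples))
    size <- 1 / config$nb_dispersion
    for (i in seq_along(samples)) {
      mu <- baseline * 2^(lfc[, sheet$group[i]]) * size_factors[i]
      counts[, i] <- stats::rnbinom(n_genes, mu = mu, size = size)
    }
    list(counts = counts, baseline = baseline, log2fc = lfc)
  })
}

#' Simulate single-nucleus QC and demultiplexing records
#'
#' Each nucleus carries a true sample of origin; the HTO call is corrupted to
#' `"Doublet"`/`"Negative"`/a wrong sample and the genotype call to
#' `"Doublet"`/`"Unassigned"` at the configured rates.
#'
#' @param n number of nuclei
#' @param samples sample ids to draw truth from
#' @param error_rates named list: `hto_doublet`, `hto_negative`, `hto_wrong`,
#'   `geno_doublet`, `geno_unassigned` (all in \[0,1\])
#' @param seed integer
#' @return data.frame with truth and corrupted calls plus QC covariates
#' @export
simulate_nuclei <- function(n, samples,
                            error_rates = list(hto_doublet = 0.05, hto_negative = 0.05,
                                               hto_wrong = 0.01, geno_doublet = 0.02,
                                               geno_unassigned = 0.05),
                            seed = 1L) {
  rates <- unlist(error_rates)
  if (any(rates < 0 | rates > 1)) stop_config("rates must lie in [0,1]", "error_rates")
  with_seed(seed, {
    truth <- sample(samples, n, replace = TRUE)
    u <- stats::runif(n)
    hto <- truth
    hto[u < rates["hto_doublet"]] <- "Doublet"
    sel <- u >= rates["hto_doublet"] & u < rates["hto_doublet"] + rates["hto_negative"]
    hto[sel] <- "Negative"
    sel <- u >= rates["hto_doublet"] + rates["hto_negative"] &
      u < rates["hto_doublet"] + rates["hto_negative"] + rates["hto_wrong"]
    if (any(sel) && length(samples) > 1)
      hto[sel] <- vapply(truth[sel], function(s) sample(setdiff(samples, s), 1), "")
    v <- stats::runif(n)
    geno <- truth
    geno[v < rates["geno_doublet"]] <- "Doublet"
    sel <- v >= rates["geno_doublet"] & v < rates["geno_doublet"] + rates["geno_unassigned"]
    geno[sel] <- "Unassigned"
    data.frame(
      barcode = sprintf("BC%06d", seq_len(n)),
      n_features = as.integer(round(stats::rlnorm(n, log(4000), 0.5))),
      pct_mito = 100 * stats::rbeta(n, 1.2, 30),
      hto_call = hto, genotype_call = geno, true_sample = truth,
      stringsAsFactors = FALSE)
  })
}

#' Simulate an EPIC-like probe annotation table
#'
#' @param config a [cohort_config()]
#' @param context_probs named Bernoulli probabilities per functional context
#'   (defaults cover TSS200/TSS1500/body/exon1/UTRs/enhancer/DHS/TFBS/...)
#' @param gene_pool gene identifiers probes may map to; defaults to the
#'   gene ids used by [simulate_counts()] so modification and expression
#'   results integrate
#' @return data.frame: probe_id, chrom, pos, design_type, island_relation,
#'   one 0/1 column per context, gene symbols (comma-separated, 0-2)
#' @export
simulate_annotation <- function(config, context_probs = NULL, gene_pool = NULL) {
  defaults <- c(TSS200 = 0.08, TSS1500 = 0.10, body = 0.35, exon1 = 0.05,
                UTR5 = 0.08, UTR3 = 0.04, exon_bnd = 0.03, enhancer = 0.12,
                DHS = 0.15, TFBS = 0.20, open_chromatin = 0.10)
  if (!is.null(context_probs)) defaults[names(context_probs)] <- unlist(context_probs)
  with_seed(derive_seed(config$seed, "annotation"), {
    n <- config$n_probes
    ann <- data.frame(
      probe_id = probe_ids(n),
      chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
      pos = sample.int(2e8, n, replace = TRUE),
      design_type = sample(c("I", "II"), n, replace = TRUE, prob = c(0.16, 0.84)),
      island_relation = sample(c("Island", "Shore", "Shelf", "OpenSea"),
                               n, replace = TRUE, prob = c(0.31, 0.22, 0.10, 0.37)),
      stringsAsFactors = FALSE)
    for (ctx in names(defaults))
      ann[[ctx]] <- as.integer(stats::runif(n) < defaults[[ctx]])
    pool <- if (is.null(gene_pool))
      sprintf("gene%05d", seq_len(config$n_genes)) else gene_pool
    n_sym <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.55, 0.15))
    ann$genes <- vapply(n_sym, function(k)
      paste(sample(pool, k), collapse = ","), "")
    ann
  })
}
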