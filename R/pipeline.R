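# Configuration-driven orchestration: simulate (or load) a cohort, infer
# 5mC/5hmC, compute MDI, run the stepwise EWAS, the cell-type interaction
# model, context enrichment and NB differential expression, writing tidy
# TSV outputs and a hashed run manifest.

#' Default pipeline configuration
#'
#' @param outdir output directory
#' @param seed master seed; per-stage sub-seeds are derived from it
#' @param n_probes,n_genes cohort dimensions for the simulate stage
#' @param groups named sample counts; first group is the non-tumor reference
#' @param q_threshold,p_adj_threshold significance thresholds
#' @param measurement_precision Beta pseudo-count for array noise
#' @param de_lfc magnitude of planted log2 fold changes (balanced up/down)
#' @param stages character vector of stages to run, in dependency order
#' @return named list of class `pipeline_config`
#' @export
pipeline_config <- function(outdir = tempfile("ct5hmc_run_"), seed = 1L,
                            n_probes = 2000, n_genes = 500,
                            groups = c(NT = 8L, ATC = 4L, EMB = 4L, EPN = 4L, GNN = 4L),
                            q_threshold = 0.05, p_adj_threshold = 0.05,
                            measurement_precision = 200, de_lfc = 1,
                            stages = c("simulate", "infer", "mdi", "ewas",
                                       "dmct", "enrichment", "de")) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_probes = n_probes, n_genes = n_genes, groups = groups,
                 q_threshold = q_threshold, p_adj_threshold = p_adj_threshold,
                 measurement_precision = measurement_precision, de_lfc = de_lfc,
                 stages = stages), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields as in [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$groups)) raw$groups <- unlist(raw$groups)
  cfg <- pipeline_config()
  cfg[names(raw)] <- raw
  cfg
}

#' Validate a pipeline configuration
#'
#' Collects every failure (thresholds outside (0,1), bad stage names, bad
#' group counts, missing referenced files) rather than stopping at the
#' first.
#'
#' @param config a `pipeline_config` or plain named list (e.g. from a YAML
#'   file read with [yaml::read_yaml()])
#' @return list: `ok` (logical), `failures` (character vector)
#' @export
validate_config <- function(config) {
  failures <- character()
  thr <- c("q_threshold", "p_adj_threshold")
  for (t in thr) {
    v <- config[[t]]
    if (is.null(v) || !is.numeric(v) || v <= 0 || v >= 1)
      failures <- c(failures, sprintf("%s must lie in (0,1)", t))
  }
  known <- c("simulate", "infer", "mdi", "ewas", "dmct", "enrichment", "de")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    failures <- c(failures, sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (!is.null(config$groups) &&
      (is.null(names(config$groups)) || any(config$groups < 1)))
    failures <- c(failures, "groups must be a named vector of positive counts")
  for (f in c("bs_path", "ox_path", "annotation_path", "counts_path")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      failures <- c(failures, sprintf("%s: file not found (%s)", f, config[[f]]))
  }
  list(ok = length(failures) == 0, failures = failures)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on a simulated cohort
#' with planted bulk and cell-type-specific 5hmC effects, writes each
#' stage's outputs as TSV/JSON under `config$outdir`, and returns a manifest
#' with the md5 hash of every output file. Re-running with the same config
#' reproduces identical hashes.
#'
#' @param config a [pipeline_config()]
#' @return list: `manifest` (data.frame stage/file/md5), `results` (in-memory
#'   stage outputs), `config`
#' @export
run_pipeline <- function(config) {
  val <- validate_config(config)
  if (!val$ok) stop_validation(paste(val$failures, collapse = "; "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(); results <- list()
  emit <- function(stage, name, writer) {
    path <- file.path(config$outdir, name)
    writer(path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = name, md5 = unname(tools::md5sum(path)))
  }
  groups <- config$groups
  nontumor <- names(groups)[1]
  cc <- cohort_config(n_probes = config$n_probes, groups = groups,
                      dirichlet_concentrations = default_group_concentrations(groups),
                      measurement_precision = config$measurement_precision,
                      n_genes = config$n_genes, seed = config$seed)

  if ("simulate" %in% config$stages) {
    profiles <- simulate_reference_profiles(cc)
    samp <- simulate_samples(cc)
    ann <- simulate_annotation(cc)
    # planted truth per tumor type: bulk 5hmC gains on one probe block and
    # progenitor-restricted gains (all NSC/RGC/OPC/UBC members, so the
    # effect is resolvable at super-type resolution) on another; probes are
    # chosen with (1 - m - h) headroom so the shift is not clipped
    n_eff <- max(10L, round(config$n_probes * 0.02))
    tumor_groups <- setdiff(names(groups), nontumor)
    prog_members <- intersect(c("NSC", "RGC", "OPC", "UBC"), colnames(profiles$m))
    headroom <- apply(1 - profiles$m - profiles$h, 1, min)
    eligible <- rownames(profiles$m)[headroom > 0.35]
    tt <- do.call(rbind, lapply(seq_along(tumor_groups), function(i) {
      idx <- ((i - 1) * n_eff + 1):(i * n_eff)
      probes <- eligible[((idx - 1) %% length(eligible)) + 1]
      bulk_p <- probes[seq_len(n_eff %/% 2)]
      prog_p <- probes[(n_eff %/% 2 + 1):n_eff]
      rbind(
        data.frame(probe_id = bulk_p, cell_type = "bulk",
                   group = tumor_groups[i], delta_5hmC = 0.15, delta_5mC = 0),
        data.frame(probe_id = rep(prog_p, each = length(prog_members)),
                   cell_type = rep(prog_members, length(prog_p)),
                   group = tumor_groups[i], delta_5hmC = 0.3, delta_5mC = 0))
    }))
    class(tt) <- c("truth_table", "data.frame")
    planted <- plant_effects(tt, profiles, groups = names(groups))
    meas <- render_measurements(planted$profiles, samp$composition, samp$sheet, cc)
    # direction-balanced DE truth so median-of-ratios normalization holds
    de_truth <- matrix(0, cc$n_genes, length(tumor_groups),
                       dimnames = list(sprintf("gene%05d", seq_len(cc$n_genes)),
                                       tumor_groups))
    n_de <- max(6, cc$n_genes %/% 20)
    de_truth[seq_len(n_de %/% 2), ] <- config$de_lfc
    de_truth[(n_de %/% 2 + 1):n_de, ] <- -config$de_lfc
    cnt <- simulate_counts(cc, samp$sheet, de_truth = de_truth)
    results$simulate <- list(profiles = profiles, samples = samp, annotation = ann,
                             truth = tt, measurements = meas, counts = cnt,
                             de_truth = de_truth)
    emit("simulate", "bs.tsv.gz", function(p) write_matrix_tsv(meas$bs, p))
    emit("simulate", "oxbs.tsv.gz", function(p) write_matrix_tsv(meas$ox, p))
    emit("simulate", "sample_sheet.tsv", function(p)
      data.table::fwrite(samp$sheet, p, sep = "\t"))
    emit("simulate", "composition.tsv", function(p)
      write_matrix_tsv(samp$composition, p))
    emit("simulate", "annotation.tsv", function(p)
      data.table::fwrite(ann, p, sep = "\t"))
    emit("simulate", "counts.tsv.gz", function(p) write_matrix_tsv(cnt$counts, p))
    emit("simulate", "truth_table.tsv", function(p)
      data.table::fwrite(tt, p, sep = "\t"))
  }

  sim <- results$simulate
  if ("infer" %in% config$stages) {
    est <- estimate_modifications(sim$measurements$bs, sim$measurements$ox)
    results$infer <- est
    emit("infer", "5mc.tsv.gz", function(p) write_matrix_tsv(est$m, p))
    emit("infer", "5hmc.tsv.gz", function(p) write_matrix_tsv(est$h, p))
  }

  sheet <- sim$samples$sheet
  comp <- sim$samples$composition
  nt_ids <- sheet$sample_id[sheet$group == nontumor]
  if ("mdi" %in% config$stages) {
    mdi_out <- list()
    for (assay in c("5mC", "5hmC")) {
      mat <- if (assay == "5mC") results$infer$m else results$infer$h
      ref <- reference_medians(mat, nt_ids)
      rec <- compute_mdi(mat, ref, assay = assay)
      rec$group <- sheet$group[match(rec$sample_id, sheet$sample_id)]
      mdi_out[[assay]] <- rec
    }
    mdi_all <- do.call(rbind, c(mdi_out, list(make.row.names = FALSE)))
    results$mdi <- mdi_all
    emit("mdi", "mdi.tsv", function(p) data.table::fwrite(mdi_all, p, sep = "\t"))
  }

  if ("ewas" %in% config$stages) {
    ewas_out <- list()
    for (g in setdiff(names(groups), nontumor)) {
      sub <- sheet[sheet$group %in% c(g, nontumor), ]
      sw <- stepwise_series(results$infer$h[, sub$sample_id], sub, comp, g,
                            q_threshold = config$q_threshold)
      ewas_out[[g]] <- sw
    }
    results$ewas <- ewas_out
    counts_tab <- do.call(rbind, lapply(names(ewas_out), function(g)
      cbind(group = g, ewas_out[[g]]$hit_counts)))
    emit("ewas", "ewas_hit_counts.tsv", function(p)
      data.table::fwrite(counts_tab, p, sep = "\t"))
    k_full <- as.character(max(as.integer(names(ewas_out[[1]]$hit_sets))))
    share <- summarize_hits(lapply(ewas_out, function(sw) sw$hit_sets[[k_full]]),
                            q_threshold = config$q_threshold)
    results$ewas_sharing <- share
    emit("ewas", "ewas_sharing.json", function(p)
      jsonlite::write_json(list(n_union = share$n_union,
                                shared_all = share$shared_all,
                                shared_all_fraction = share$shared_all_fraction,
                                specific_fraction = as.list(share$specific_fraction)),
                           p, auto_unbox = TRUE, pretty = TRUE))
  }

  if ("dmct" %in% config$stages) {
    agg <- aggregate_celltypes(comp)
    dmct_out <- list()
    for (g in setdiff(names(groups), nontumor)) {
      sub <- sheet[sheet$group %in% c(g, nontumor), ]
      covs <- cbind(sex = as.numeric(sub$sex == "M"),
                    age = sub$age - mean(sub$age), purity = sub$purity)
      dmct_out[[g]] <- fit_dmct(results$infer$h[, sub$sample_id],
                                agg[sub$sample_id, ],
                                as.numeric(sub$group == g), covariates = covs)
    }
    results$dmct <- dmct_out
    emit("dmct", "dmct_fits.tsv.gz", function(p)
      data.table::fwrite(do.call(rbind, lapply(names(dmct_out), function(g)
        cbind(group = g, dmct_out[[g]]))), p, sep = "\t", compress = "gzip"))
    results$dmct_classes <- classify_dmct(dmct_out, config$q_threshold)
  }

  if ("enrichment" %in% config$stages) {
    ann <- sim$annotation
    universe <- rownames(results$infer$h)
    enr <- list()
    for (g in names(results$ewas)) {
      k_full <- as.character(max(as.integer(names(results$ewas[[g]]$hit_sets))))
      hits <- results$ewas[[g]]$hit_sets[[k_full]]
      if (length(hits) < 2) next
      for (ctx in c("TSS200", "body", "DHS", "enhancer")) {
        r <- context_enrichment(hits, universe, ann, ctx)
        enr[[length(enr) + 1L]] <- data.frame(
          group = g, context = ctx, or_mh = r$or_mh, ci_low = r$ci_low,
          ci_high = r$ci_high, p = r$p)
      }
    }
    results$enrichment <- if (length(enr)) do.call(rbind, enr) else NULL
    if (!is.null(results$enrichment))
      emit("enrichment", "enrichment.tsv", function(p)
        data.table::fwrite(results$enrichment, p, sep = "\t"))
  }

  if ("de" %in% config$stages) {
    de_out <- list()
    for (g in setdiff(names(groups), nontumor)) {
      sub <- sheet[sheet$group %in% c(g, nontumor), ]
      de_out[[g]] <- fit_nb_de(sim$counts$counts, sub, g, composition = comp,
                               cell_types = intersect(colnames(comp),
                                                      c("NEU", "NSC", "RGC", "OPC", "UBC")))
    }
    results$de <- de_out
    emit("de", "de_fits.tsv.gz", function(p)
      data.table::fwrite(do.call(rbind, lapply(names(de_out), function(g)
        cbind(group = g, de_out[[g]]$fits))), p, sep = "\t", compress = "gzip"))
  }

  manifest_df <- do.call(rbind, manifest)
  emit_cfg <- file.path(config$outdir, "run_config.json")
  jsonlite::write_json(config[setdiff(names(config), "outdir")], emit_cfg,
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  list(manifest = manifest_df, results = results, config = config)
}
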