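# Fixture builders shared across test files. Everything is generated in
# code from the package's own synthetic-cohort module; no stored data.

# Two-group cohort with optional planted bulk 5hmC effects, rendered to
# noisy BS/oxBS and inferred back to (m, h). Returns everything recovery
# tests need.
make_ewas_sim <- function(n_probes = 2000, n_per_group = 10, precision = 200,
                          delta = 0, n_planted = 0, seed = 1L,
                          concentrations = NULL) {
  groups <- c(NT = n_per_group, TUM = n_per_group)
  cfg <- cohort_config(
    n_probes = n_probes, groups = groups,
    dirichlet_concentrations = concentrations,
    measurement_precision = precision, seed = seed)
  profiles <- simulate_reference_profiles(cfg)
  samp <- simulate_samples(cfg)
  planted <- character()
  if (n_planted > 0 && delta != 0) {
    # plant where every cell type has headroom so the bulk shift is exact
    head_ok <- apply(1 - profiles$m - profiles$h, 1, min) > abs(delta) + 0.02
    low_ok <- apply(profiles$h, 1, min) > abs(delta) + 0.02
    eligible <- if (delta > 0) which(head_ok) else which(low_ok)
    planted <- rownames(profiles$m)[utils::head(eligible, n_planted)]
    tt <- truth_table(probe_id = planted, cell_type = "bulk", group = "TUM",
                      delta_5hmC = delta, delta_5mC = 0)
    pl <- plant_effects(tt, profiles, groups = names(groups))
    gp <- pl$profiles
  } else {
    gp <- list(NT = profiles, TUM = profiles)
  }
  meas <- render_measurements(gp, samp$composition, samp$sheet, cfg)
  est <- estimate_modifications(meas$bs, meas$ox)
  list(cfg = cfg, sheet = samp$sheet, composition = samp$composition,
       profiles = profiles, meas = meas, est = est, planted = planted)
}

# Cohort where tumor and non-tumor differ only through cell-type
# composition (no planted effects): the confounding regime.
make_confounded_sim <- function(n_probes = 2000, n_per_group = 10,
                                precision = 200, seed = 1L) {
  conc <- list(NT = c(30, 4, 4, 4, 4, 8), TUM = c(6, 12, 12, 6, 6, 8))
  make_ewas_sim(n_probes = n_probes, n_per_group = n_per_group,
                precision = precision, seed = seed, concentrations = conc)
}

# Cohort with 5hmC effects planted in every progenitor-like granular type,
# for cell-type attribution tests.
make_dmct_sim <- function(n_probes = 2000, n_per_group = 20, precision = 1000,
                          delta = 0.3, n_planted = 100, seed = 1L) {
  groups <- c(NT = n_per_group, TUM = n_per_group)
  cfg <- cohort_config(n_probes = n_probes, groups = groups,
                       measurement_precision = precision, seed = seed)
  profiles <- simulate_reference_profiles(cfg)
  samp <- simulate_samples(cfg)
  prog <- c("NSC", "RGC", "OPC", "UBC")
  head_ok <- apply(1 - profiles$m[, prog] - profiles$h[, prog], 1, min) > delta + 0.02
  planted <- rownames(profiles$m)[utils::head(which(head_ok), n_planted)]
  tt <- truth_table(
    probe_id = rep(planted, each = length(prog)),
    cell_type = rep(prog, length(planted)),
    group = "TUM", delta_5hmC = delta, delta_5mC = 0)
  pl <- plant_effects(tt, profiles, groups = names(groups))
  meas <- render_measurements(pl$profiles, samp$composition, samp$sheet, cfg)
  est <- estimate_modifications(meas$bs, meas$ox)
  agg <- aggregate_celltypes(samp$composition)
  list(cfg = cfg, sheet = samp$sheet, composition = agg, est = est,
       planted = planted, clip_report = pl$clip_report)
}

expect_on_simplex <- function(x, tol = 1e-9) {
  expect_true(all(x >= -tol & x <= 1 + tol))
  expect_true(all(abs(rowSums(x) - 1) < tol))
}
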