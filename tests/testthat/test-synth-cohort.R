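# Synthetic-cohort generator: determinism, simplex invariants, prevalence
# calibration and planted-truth bookkeeping.

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_probes = 0), class = "ct5hmc_config_error")
  expect_error(cohort_config(hmc_to_mc_ratio = 0), "hmc_to_mc_ratio")
  expect_error(cohort_config(measurement_precision = -1), "measurement_precision")
  expect_error(cohort_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(cohort_config(groups = c(5, 5)), "groups")
})

test_that("reference profiles respect constraints and hit the prevalence ratio", {
  cfg <- cohort_config(n_probes = 10000, hmc_to_mc_ratio = 0.06, seed = 1)
  pr <- simulate_reference_profiles(cfg)
  expect_true(all(pr$m >= 0 & pr$h >= 0 & pr$m + pr$h <= 1))
  ratio <- mean(pr$h) / mean(pr$m)
  expect_gt(ratio, 0.048)
  expect_lt(ratio, 0.072)

  # vanishing ratio: h effectively zero, constraints intact
  cfg0 <- cohort_config(n_probes = 500, hmc_to_mc_ratio = 1e-9, seed = 1)
  pr0 <- simulate_reference_profiles(cfg0)
  expect_lt(max(pr0$h), 1e-6)
  expect_true(all(pr0$m + pr0$h <= 1))

  # determinism: same config, same seed, bit-identical
  expect_identical(pr, simulate_reference_profiles(cfg))
})

test_that("sample simulation yields simplex compositions and honors limits", {
  cfg <- cohort_config(n_probes = 10, groups = c(A = 12L, B = 8L), seed = 3)
  s <- simulate_samples(cfg)
  expect_equal(nrow(s$sheet), 20)
  expect_equal(nrow(s$composition), 20)
  expect_on_simplex(s$composition)
  expect_identical(s, simulate_samples(cfg))

  # concentration limit: huge alpha pins rows at the mean
  cfg2 <- cohort_config(n_probes = 10, cell_types = c("a", "b"),
                        groups = c(A = 5L, B = 5L),
                        dirichlet_concentrations = list(A = c(1e6, 1e6),
                                                        B = c(1e6, 1e6)))
  s2 <- simulate_samples(cfg2)
  expect_true(all(abs(s2$composition - 0.5) < 1e-2))

  # single cell type: compositions exactly 1
  cfg1 <- cohort_config(n_probes = 10, cell_types = "only",
                        groups = c(A = 3L, B = 3L),
                        dirichlet_concentrations = list(A = 5, B = 5))
  expect_true(all(simulate_samples(cfg1)$composition == 1))

  expect_error(simulate_samples(cohort_config(groups = c(A = 5L))),
               class = "ct5hmc_config_error")
})

test_that("plant_effects shifts, clips and reports faithfully", {
  cfg <- cohort_config(n_probes = 50, seed = 5)
  pr <- simulate_reference_profiles(cfg)

  # empty truth: unchanged
  empty <- plant_effects(truth_table(), pr, groups = "TUM")
  expect_identical(empty$profiles$TUM, pr)
  expect_equal(nrow(empty$clip_report), 0)

  # controlled arithmetic on a hand-built profile
  prof <- list(m = matrix(0.3, 1, 1, dimnames = list("cg1", "NEU")),
               h = matrix(0.1, 1, 1, dimnames = list("cg1", "NEU")))
  tt <- truth_table("cg1", "NEU", "TUM", delta_5hmC = 0.2, delta_5mC = 0)
  out <- plant_effects(tt, prof)
  expect_equal(out$profiles$TUM$h[1, 1], 0.3)
  expect_equal(out$profiles$TUM$m[1, 1], 0.3)
  expect_equal(nrow(out$clip_report), 0)

  # forced clip: h = 0.2 - 0.3 -> 0, entry reported
  prof$h[1, 1] <- 0.2
  tt2 <- truth_table("cg1", "NEU", "TUM", delta_5hmC = -0.3, delta_5mC = 0)
  out2 <- plant_effects(tt2, prof)
  expect_equal(out2$profiles$TUM$h[1, 1], 0)
  expect_equal(nrow(out2$clip_report), 1)
  expect_equal(out2$clip_report$realized_dh, -0.2)

  expect_error(plant_effects(truth_table("nope", "NEU", "T", 0.1, 0), prof),
               class = "ct5hmc_validation_error")
  expect_error(truth_table("cg1", "NEU", "T", 1.5, 0),
               class = "ct5hmc_validation_error")
})

test_that("render_measurements mixes profiles and respects the noise model", {
  cfg <- cohort_config(n_probes = 20, cell_types = c("a", "b"),
                       groups = c(NT = 2L, TUM = 2L),
                       dirichlet_concentrations = list(NT = c(1, 1), TUM = c(1, 1)),
                       measurement_precision = 1e9, seed = 2)
  m <- matrix(c(0.2, 0.6), 1, 2, dimnames = list("cg1", c("a", "b")))
  h <- matrix(c(0.05, 0.1), 1, 2, dimnames = list("cg1", c("a", "b")))
  prof <- list(m = m, h = h)
  sheet <- data.frame(sample_id = c("s1", "s2"), group = c("NT", "NT"))
  comp <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("a", "b")))
  out <- render_measurements(list(NT = prof), comp, sheet, cfg)

  # degenerate mixture: bulk truth equals cell type a's profile
  expect_equal(out$true_m["cg1", "s1"], 0.2)
  # arithmetic: (0.2 + 0.6)/2
  expect_equal(out$true_m["cg1", "s2"], 0.4)
  # noise-free limit: observed within 1e-3 of expectations
  expect_lt(max(abs(out$bs - (out$true_m + out$true_h))), 1e-3)
  expect_lt(max(abs(out$ox - out$true_m)), 1e-3)

  bad <- comp; bad[1, ] <- c(0.6, 0.6)
  expect_error(render_measurements(list(NT = prof), bad, sheet, cfg),
               class = "ct5hmc_validation_error")
})

test_that("planted bulk deltas are recoverable from BS - oxBS averages", {
  sim <- make_ewas_sim(n_probes = 800, n_per_group = 25, precision = 2000,
                       delta = 0.15, n_planted = 60, seed = 9)
  tum <- sim$sheet$sample_id[sim$sheet$group == "TUM"]
  nt <- sim$sheet$sample_id[sim$sheet$group == "NT"]
  dh <- rowMeans(sim$meas$bs[, tum] - sim$meas$ox[, tum]) -
    rowMeans(sim$meas$bs[, nt] - sim$meas$ox[, nt])
  expect_lt(abs(mean(dh[sim$planted]) - 0.15), 0.02)
  expect_lt(abs(mean(dh[setdiff(names(dh), sim$planted)])), 0.01)
})

test_that("counts are NB with the configured structure", {
  cfg <- cohort_config(n_probes = 10, groups = c(A = 6L, B = 6L),
                       n_genes = 5000, nb_dispersion = 1e-4, seed = 13)
  sheet <- simulate_samples(cfg)$sheet
  out <- simulate_counts(cfg, sheet)
  expect_true(all(out$counts >= 0) && all(out$counts == round(out$counts)))
  expect_identical(out, simulate_counts(cfg, sheet))

  # dispersion -> 0 approximates Poisson: variance/mean near 1
  ratio <- apply(out$counts, 1, var) / rowMeans(out$counts)
  expect_lt(abs(median(ratio) - 1), 0.1)

  # size factor 2 doubles expected counts
  sf <- setNames(rep(1, nrow(sheet)), sheet$sample_id)
  sf[1] <- 2
  out2 <- simulate_counts(cfg, sheet, size_factors = sf)
  expect_lt(abs(mean(out2$counts[, 1]) / mean(out2$counts[, 2]) - 2), 0.1)
})

test_that("nuclei simulation respects error rates and counts", {
  recs <- simulate_nuclei(100, c("S1", "S2"),
                          error_rates = list(hto_doublet = 0, hto_negative = 0,
                                             hto_wrong = 0, geno_doublet = 0,
                                             geno_unassigned = 0), seed = 4)
  expect_equal(nrow(recs), 100)
  expect_identical(recs$hto_call, recs$true_sample)
  expect_identical(recs$genotype_call, recs$true_sample)

  all_doublet <- simulate_nuclei(50, c("S1", "S2"),
                                 error_rates = list(hto_doublet = 1, hto_negative = 0,
                                                    hto_wrong = 0, geno_doublet = 0,
                                                    geno_unassigned = 0), seed = 4)
  expect_true(all(all_doublet$hto_call == "Doublet"))
  expect_error(simulate_nuclei(10, "S1", error_rates = list(hto_doublet = 2)),
               class = "ct5hmc_config_error")
})

test_that("annotation flags follow the configured probabilities", {
  cfg <- cohort_config(n_probes = 400, seed = 6)
  ann0 <- simulate_annotation(cfg, context_probs = list(DHS = 0))
  expect_equal(sum(ann0$DHS), 0)
  ann1 <- simulate_annotation(cfg, context_probs = list(body = 1))
  expect_equal(sum(ann1$body), 400)
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  expect_true(all(ann1$design_type %in% c("I", "II")))
  expect_true(all(ann1$island_relation %in% c("Island", "Shore", "Shelf", "OpenSea")))
})
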