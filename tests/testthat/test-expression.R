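# Size factors, NB differential expression, integration with modification
# changes, and module scores.

make_de_sheet <- function(n_per_group = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(sample_id = sprintf("d%02d", 1:n),
             group = rep(c("NT", "TUM"), each = n_per_group),
             sex = sample(c("F", "M"), n, TRUE), age = runif(n, 1, 18),
             stringsAsFactors = FALSE)
}

test_that("size factors are median-of-ratios and scale-equivariant", {
  set.seed(6)
  base <- matrix(rnbinom(2000, mu = 100, size = 10), 500, 4,
                 dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:4)))
  base <- base + 1                                  # all-positive

  # sample B exactly double of sample A: factors in ratio 2:1
  ab <- cbind(A = base[, 1], B = 2 * base[, 1])
  sf_ab <- estimate_size_factors(ab)
  expect_equal(unname(sf_ab["B"] / sf_ab["A"]), 2, tolerance = 1e-12)

  # scale equivariance: doubling one sample doubles its relative factor
  doubled <- base
  doubled[, 2] <- base[, 2] * 2
  sf0 <- estimate_size_factors(base)
  sf <- estimate_size_factors(doubled)
  expect_equal(unname(sf[2] / sf[1]), unname(2 * sf0[2] / sf0[1]),
               tolerance = 1e-12)

  same <- estimate_size_factors(cbind(base[, 1], base[, 1], base[, 1]))
  expect_equal(unname(same), rep(1, 3), tolerance = 1e-12)

  # direct median-of-ratios oracle
  sf_all <- estimate_size_factors(base)
  lg <- log(base)
  raw <- exp(apply(lg - rowMeans(lg), 2, median))
  expect_equal(unname(sf_all), unname(raw / exp(mean(log(raw)))), tolerance = 1e-12)

  zero <- base; zero[, 1] <- 0
  expect_error(estimate_size_factors(zero), class = "ct5hmc_validation_error")
})

test_that("NB fit recovers planted fold changes with small bias", {
  sheet <- make_de_sheet(10)
  cfg <- cohort_config(n_probes = 10, groups = c(NT = 10L, TUM = 10L),
                       n_genes = 1000, nb_dispersion = 0.1, seed = 33)
  # direction-balanced truth keeps median-of-ratios normalization honest
  lfc <- matrix(0, 1000, 1, dimnames = list(sprintf("gene%05d", 1:1000), "TUM"))
  lfc[1:50, 1] <- 1
  lfc[51:100, 1] <- -1
  sim <- simulate_counts(cfg, sheet, de_truth = lfc)
  fit <- fit_nb_de(sim$counts, sheet, "TUM", covariates = character())
  expect_lt(abs(mean(fit$fits$log2fc[1:50], na.rm = TRUE) - 1), 0.1)
  expect_lt(abs(mean(fit$fits$log2fc[51:100], na.rm = TRUE) + 1), 0.1)
  expect_gt(mean(fit$fits$p_adj[1:100] < 0.05, na.rm = TRUE), 0.8)
  expect_lt(abs(mean(fit$fits$log2fc[101:1000], na.rm = TRUE)), 0.05)
})

test_that("near-zero dispersion matches a Poisson GLM oracle", {
  sheet <- make_de_sheet(8, seed = 2)
  set.seed(44)
  mu <- 1000
  counts <- matrix(rpois(50 * 16, mu * rep(c(1, 1.3), each = 8)), 50, 16,
                   byrow = TRUE,
                   dimnames = list(sprintf("g%02d", 1:50), sheet$sample_id))
  sf <- setNames(rep(1, 16), sheet$sample_id)
  fit <- fit_nb_de(counts, sheet, "TUM", covariates = character(),
                   size_factors = sf, dispersion = 1e-8)
  x <- as.numeric(sheet$group == "TUM")
  for (i in c(1, 25, 50)) {
    pf <- glm(counts[i, ] ~ x, family = poisson())
    z_pois <- summary(pf)$coefficients["x", "z value"]
    z_ours <- (fit$fits$log2fc[i] / fit$fits$se[i])
    expect_lt(abs(z_ours - z_pois) / abs(z_pois), 0.05)
  }
})

test_that("all-zero genes are reported with missing statistics", {
  sheet <- make_de_sheet(5, seed = 3)
  set.seed(5)
  counts <- matrix(rnbinom(30 * 10, mu = 50, size = 10) + 1, 30, 10,
                   dimnames = list(sprintf("g%02d", 1:30), sheet$sample_id))
  counts[7, ] <- 0
  fit <- fit_nb_de(counts, sheet, "TUM", covariates = character())
  expect_true(fit$fits$flagged[7])
  expect_true(is.na(fit$fits$log2fc[7]))
  expect_equal(nrow(fit$fits), 30)
  expect_error(fit_nb_de(counts + 0.5, sheet, "TUM"),
               class = "ct5hmc_validation_error")
})

test_that("modification-expression pairing and Pearson correlation are exact", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    genes = c("g1", "g2", "g3", "g4"))
  dm <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                   coefficient = c(-0.2, -0.1, 0.1, 0.2))
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   log2fc = c(1, 0.5, -0.5, -1), p_adj = c(0.01, 0.2, 0.01, 0.01))
  out <- hm_expression_correlation(dm, de, ann)
  expect_equal(out$r_all, -1)                      # exactly anti-linear
  expect_equal(nrow(out$pairs), 4)

  de$log2fc <- 2                                   # constant: undefined r
  out2 <- hm_expression_correlation(dm, de, ann)
  expect_true(is.na(out2$r_all))
  expect_match(out2$reason[["all"]], "zero variance")

  # multiple CpGs per gene contribute one row per CpG
  ann2 <- data.frame(probe_id = c("p1", "p2", "p3"), genes = c("g1", "g1", "g1,g2"))
  de3 <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1, 2), p_adj = c(0.5, 0.5))
  out3 <- hm_expression_correlation(dm[1:3, ], de3, ann2)
  expect_equal(nrow(out3$pairs), 4)
})

test_that("2x2 odds ratios match hand computation incl. Haldane correction", {
  expect_equal(odds_ratio_2x2(5, 5, 5, 5)$or, 1)
  expect_equal(odds_ratio_2x2(2, 8, 8, 2)$or, 0.0625)
  z <- odds_ratio_2x2(0, 10, 5, 5)
  expect_equal(z$or, (0.5 * 5.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_true(z$ci[1] < z$or && z$or < z$ci[2])
})

test_that("promoter/gene-body odds split hits by expression direction", {
  ann <- data.frame(probe_id = sprintf("p%02d", 1:20),
                    TSS200 = rep(c(1, 0), each = 10),
                    TSS1500 = 0, body = rep(c(0, 1), each = 10))
  pairs <- data.frame(probe_id = sprintf("p%02d", 1:20),
                      log2fc = rep(c(1, -1), 10))
  out <- promoter_genebody_odds(pairs, ann)
  expect_setequal(out$context, c("promoter", "gene_body"))
  pr <- out[out$context == "promoter", ]
  expect_equal(pr$a + pr$b, 10)                    # 10 up-regulated pairs
  expect_equal(pr$or, (pr$a * pr$d) / (pr$b * pr$c))
  expect_error(promoter_genebody_odds(pairs[pairs$log2fc > 0, ], ann),
               class = "ct5hmc_validation_error")
})

test_that("module scores are centered, recover shifts and are deterministic", {
  set.seed(55)
  n_cells <- 150; n_genes <- 600
  expr <- matrix(rnorm(n_cells * n_genes, 2, 1), n_cells, n_genes,
                 dimnames = list(sprintf("c%03d", 1:n_cells),
                                 sprintf("g%03d", 1:n_genes)))
  gene_set <- sprintf("g%03d", 1:30)

  # background set: mean score near zero
  sc <- module_score(expr, gene_set, n_bins = 10, n_ctrl = 50, seed = 9)
  expect_lt(abs(mean(sc$scores)), 0.05)
  sc2 <- module_score(expr, gene_set, n_bins = 10, n_ctrl = 50, seed = 9)
  expect_identical(sc$scores, sc2$scores)

  # +1 shift on set genes in half the cells is recovered there
  shifted <- expr
  shifted[1:75, gene_set] <- shifted[1:75, gene_set] + 1
  meta <- data.frame(cell_type = rep("OPC", n_cells),
                     group = rep(c("TUM", "NT"), each = 75))
  sc3 <- module_score(shifted, gene_set, cell_meta = meta,
                      n_bins = 10, n_ctrl = 50, seed = 9)
  # score contrast between shifted and unshifted cells recovers the shift
  # (controls are shared, so bin-selection offsets cancel)
  expect_lt(abs(mean(sc3$scores[1:75]) - mean(sc3$scores[76:150]) - 1), 0.1)
  expect_lt(sc3$comparisons$p[1], 0.01)

  expect_error(module_score(expr, gene_set, n_ctrl = 0),
               class = "ct5hmc_validation_error")
  expect_error(module_score(expr, "absent"), class = "ct5hmc_validation_error")
})
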