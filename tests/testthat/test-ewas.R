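# Bulk EWAS: design construction, moderated fits, stepwise adjustment and
# hit sharing.

make_sheet <- function(n_nt = 6, n_tum = 6, seed = 1) {
  set.seed(seed)
  n <- n_nt + n_tum
  data.frame(sample_id = sprintf("s%02d", 1:n),
             group = rep(c("NT", "TUM"), c(n_nt, n_tum)),
             sex = sample(c("F", "M"), n, TRUE),
             age = runif(n, 1, 18), purity = runif(n, 0.5, 1),
             stringsAsFactors = FALSE)
}

make_comp <- function(sheet, seed = 2) {
  set.seed(seed)
  cts <- c("NEU", "NSC", "OPC", "RGC", "UBC", "other")
  x <- matrix(rgamma(nrow(sheet) * 6, 5), nrow(sheet))
  x <- x / rowSums(x)
  dimnames(x) <- list(sheet$sample_id, cts)
  x
}

test_that("design matrix has the documented columns", {
  sheet <- make_sheet(); comp <- make_comp(sheet)
  d0 <- build_design(sheet, comp, "TUM")
  expect_identical(colnames(d0$X), c("intercept", "group", "sex", "age", "purity"))
  expect_equal(sum(d0$X[, "group"]), 6)      # non-tumor coded 0
  expect_equal(mean(d0$X[, "age"]), 0)       # centered

  d5 <- build_design(sheet, comp, "TUM",
                     cell_types = c("NEU", "NSC", "OPC", "RGC", "UBC"))
  expect_equal(ncol(d5$X), 10)

  allf <- sheet; allf$sex <- "F"
  expect_warning(df <- build_design(allf, comp, "TUM"), "sex")
  expect_false("sex" %in% colnames(df$X))

  expect_error(build_design(sheet, comp, "nope"), class = "ct5hmc_validation_error")
})

test_that("per-probe coefficients and SEs match the normal-equations oracle", {
  sheet <- make_sheet(8, 8); comp <- make_comp(sheet)
  des <- build_design(sheet, comp, "TUM", cell_types = c("NEU", "NSC"))
  set.seed(5)
  betas <- matrix(runif(200 * 16), 200, 16,
                  dimnames = list(sprintf("p%03d", 1:200), sheet$sample_id))
  fm <- fit_moderated(betas, des, prior_df = 0)
  X <- des$X
  XtXi <- solve(crossprod(X))
  for (i in c(1, 57, 200)) {
    b <- XtXi %*% crossprod(X, betas[i, ])
    r <- betas[i, ] - X %*% b
    s2 <- sum(r^2) / (16 - ncol(X))
    expect_equal(fm$fits$coefficient[i], unname(b["group", 1]), tolerance = 1e-10)
    expect_equal(fm$fits$se[i], sqrt(s2 * XtXi["group", "group"]),
                 tolerance = 1e-10)
  }
  # prior_df = 0: moderated t equals ordinary t
  i <- 42
  fit_lm <- lm(betas[i, ] ~ X - 1)
  t_ord <- summary(fit_lm)$coefficients["Xgroup", "t value"]
  expect_equal(fm$fits$t_mod[i], t_ord, tolerance = 1e-8)
})

test_that("variance moderation matches limma's empirical Bayes machinery", {
  skip_if_not_installed("limma")
  sheet <- make_sheet(10, 10); comp <- make_comp(sheet)
  des <- build_design(sheet, comp, "TUM")
  set.seed(8)
  # heterogeneous residual variances so there is real shrinkage to estimate
  sds <- sqrt(1 / rgamma(300, 5, 0.05))
  betas <- matrix(rnorm(300 * 20, 0.5, rep(sds, 20)), 300, 20,
                  dimnames = list(sprintf("p%03d", 1:300), sheet$sample_id))
  fm <- fit_moderated(betas, des)
  lf <- limma::lmFit(betas, des$X)
  eb <- limma::eBayes(lf)
  expect_equal(fm$moderation$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(fm$moderation$s0_sq, eb$s2.prior, tolerance = 1e-6)
  expect_equal(fm$fits$t_mod, eb$t[, "group"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fm$fits$p, eb$p.value[, "group"], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("equal residual variances are a moderation fixed point", {
  sheet <- make_sheet(4, 4)
  X <- cbind(intercept = 1, group = as.numeric(sheet$group == "TUM"))
  rownames(X) <- sheet$sample_id
  des <- list(X = X, contrast = "group")
  # residuals identical across probes -> identical s2
  base <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  betas <- rbind(p1 = base, p2 = base + 0.1, p3 = base - 0.05)
  colnames(betas) <- sheet$sample_id
  fm <- fit_moderated(betas, des)
  s2 <- unique(round(fm$fits$se^2 / solve(crossprod(X))["group", "group"], 12))
  expect_length(s2, 1)
  expect_equal(fm$moderation$s0_sq, s2, tolerance = 1e-8)
})

test_that("probes with missing values are fit on complete cases", {
  sheet <- make_sheet(6, 6)
  X <- cbind(intercept = 1, group = as.numeric(sheet$group == "TUM"))
  rownames(X) <- sheet$sample_id
  set.seed(10)
  betas <- matrix(runif(5 * 12), 5, 12,
                  dimnames = list(sprintf("p%d", 1:5), sheet$sample_id))
  betas[2, 3] <- NA
  betas[3, 1:11] <- NA             # too few cases: flagged, not dropped
  fm <- fit_moderated(betas, list(X = X, contrast = "group"))
  expect_equal(fm$fits$n_used[2], 11L)
  expect_true(is.na(fm$fits$coefficient[3]))
  expect_equal(nrow(fm$fits), 5)
  ok <- !is.na(betas[2, ])
  oracle <- lm(betas[2, ok] ~ X[ok, "group"])
  expect_equal(fm$fits$coefficient[2], unname(coef(oracle)[2]), tolerance = 1e-10)
})

test_that("stepwise adjustment removes composition-driven hits", {
  sim <- make_confounded_sim(n_probes = 1500, n_per_group = 12, seed = 17)
  sw <- stepwise_series(sim$est$h, sim$sheet, sim$composition, "TUM")
  expect_equal(sw$hit_counts$k, 0:5)
  # composition is the only group difference: adjustment shrinks the hit set
  expect_gt(sw$hit_counts$n_hits[1], sw$hit_counts$n_hits[6])

  # null cohort: near-zero hits at every k
  null_sim <- make_ewas_sim(n_probes = 1500, n_per_group = 12, seed = 18)
  sw0 <- stepwise_series(null_sim$est$h, null_sim$sheet, null_sim$composition, "TUM")
  expect_lt(max(sw0$hit_counts$n_hits), 1500 * 0.005 + 1)

  # identical betas across samples: zero hits for every k
  flat <- matrix(0.4, 50, nrow(null_sim$sheet),
                 dimnames = list(sprintf("p%02d", 1:50), null_sim$sheet$sample_id))
  swf <- stepwise_series(flat, null_sim$sheet, null_sim$composition, "TUM")
  expect_true(all(swf$hit_counts$n_hits == 0))
})

test_that("hit sharing set algebra is exact", {
  sets <- list(g1 = c("A", "B", "C"), g2 = c("B", "C"), g3 = "C", g4 = "C")
  sh <- summarize_hits(sets)
  expect_equal(sh$shared_all, "C")
  expect_equal(sh$n_union, 3)
  expect_equal(sh$shared_all_fraction, 1 / 3)
  expect_equal(unname(sh$specific_fraction["g1"]), 1 / 3)  # only "A"

  same <- summarize_hits(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same$shared_all_fraction, 1)
  disj <- summarize_hits(list(a = "x", b = "y"))
  expect_equal(disj$shared_all, character())
  expect_error(summarize_hits(list(a = "x")), class = "ct5hmc_validation_error")
})
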