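test_that("residual weights follow (1 - r2)/r2 with a floored noiseless case", {
  w <- residual_weights(c(0.5, 0.4, 1))
  expect_equal(w$d, c(1, 1.5, 1e-6))
  expect_identical(w$near_noiseless, c(FALSE, FALSE, TRUE))
  expect_error(residual_weights(0), "reliabilit")
  expect_error(residual_weights(-0.2), "reliabilit")
})

test_that("the fixed-component solver matches a dense conditional-mean oracle", {
  pop <- make_test_population(n = 120, chrs = 2, m_chr = 80, n_qtl = 10, seed = 71)
  G <- grm_vanraden1(pop$geno)
  y <- pop$pheno$drp
  w <- residual_weights(pop$pheno$reliability)
  sol <- gblup_solve(y, G, components = 0.35, sigma2_e = 0.6, weights = w)

  V <- 0.35 * G$matrix + 0.6 * diag(w$d)
  Vinv <- solve(V)
  mu <- sum(Vinv %*% y) / sum(Vinv)
  gebv <- drop(0.35 * G$matrix %*% Vinv %*% (y - mu))
  expect_equal(sol$mu, mu, tolerance = 1e-10)
  expect_equal(sol$gebv, gebv, tolerance = 1e-8)
})

test_that("in the noiseless limit GEBVs converge to centered phenotypes", {
  pop <- make_test_population(n = 80, chrs = 1, m_chr = 120, n_qtl = 10, seed = 72)
  G <- grm_vanraden1(pop$geno)
  y <- pop$pheno$drp
  sol <- gblup_solve(y, G, components = 0.5, sigma2_e = 1e-10)
  expect_equal(unname(sol$gebv), y - sol$mu, tolerance = 1e-5)
})

test_that("AI-REML recovers one-matrix variance components", {
  pop <- make_test_population(n = 400, chrs = 2, m_chr = 200, n_qtl = 0, seed = 73)
  G <- grm_vanraden1(pop$geno)
  est <- vapply(1:3, function(s) {
    y <- draw_y_from_grm(G$matrix, 0.3, 0.7, seed = 200 + s)
    fit <- aireml_fit(y, G)
    expect_true(fit$converged)
    c(unname(fit$components), fit$sigma2_e)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.3), 0.1)
  expect_lt(abs(mean(est[2, ]) - 0.7), 0.1)
})

test_that("a relationship matrix carrying no signal gets a near-zero component", {
  hits <- vapply(1:5, function(s) {
    pop <- make_test_population(n = 300, chrs = 2, m_chr = 150, n_qtl = 15,
                                seed = 700 + s, h2 = 0.5)
    qtl_chr <- pop$geno$map$chr[pop$truth$qtl_indices]
    # all QTL on chromosome 1 are captured by G1; G2 uses chromosome 2 only
    g1 <- grm_vanraden1(pop$geno, which(pop$geno$map$chr == 1))
    g2 <- grm_vanraden1(pop$geno, which(pop$geno$map$chr == 2))
    if (!any(qtl_chr == 1)) return(NA)   # need signal in G1 for the contrast
    y <- setNames(pop$pheno$drp, pop$pheno$id)
    # rebuild the trait so chromosome 2 carries no QTL at all
    keep <- pop$truth$qtl_indices[qtl_chr == 1]
    X <- scale(pop$geno$codes[, keep, drop = FALSE], scale = FALSE)
    tbv <- drop(X %*% pop$truth$qtl_effects[qtl_chr == 1])
    tbv <- tbv / sd(tbv) * sqrt(0.5)
    y <- tbv + withr::with_seed(s, rnorm(300, sd = sqrt(0.5)))
    fit <- suppressWarnings(aireml_fit(y, list(signal = g1, empty = g2)))
    total <- sum(fit$components) + fit$sigma2_e
    fit$components[["empty"]] / total < 0.05
  }, logical(1))
  expect_gte(sum(hits, na.rm = TRUE), 3)
})

test_that("hitting the iteration cap reports non-convergence without raising", {
  pop <- make_test_population(n = 100, chrs = 2, m_chr = 60, n_qtl = 10, seed = 75)
  g1 <- grm_vanraden1(pop$geno)
  g2 <- g1
  g2$matrix <- g1$matrix + 1e-8 * diag(100)   # nearly identical: confounded
  y <- setNames(pop$pheno$drp, pop$pheno$id)
  expect_warning(
    fit <- aireml_fit(y, list(a = g1, b = g2), max_iter = 3),
    "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 3)
})

test_that("REML log-likelihood is monotone under pure EM updates", {
  pop <- make_test_population(n = 150, chrs = 2, m_chr = 80, n_qtl = 10, seed = 76)
  G <- grm_vanraden1(pop$geno)
  y <- draw_y_from_grm(G$matrix, 0.4, 0.6, seed = 5)
  fit <- suppressWarnings(aireml_fit(y, G, method = "em", max_iter = 50, tol = 1e-10))
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("a two-matrix model with one component at zero reduces to one matrix", {
  pop <- make_test_population(n = 100, chrs = 2, m_chr = 60, n_qtl = 10, seed = 77)
  chip <- make_chip_panel(pop$geno, 40, seed = 1)
  g_chip <- grm_vanraden1(pop$geno, chip)
  g_fs <- grm_vanraden1(pop$geno, setdiff(colnames(pop$geno$codes), chip)[1:30])
  y <- pop$pheno$drp
  two <- gblup_solve(y, list(fs = g_fs, chip = g_chip),
                     components = c(0, 0.4), sigma2_e = 0.5)
  one <- gblup_solve(y, g_chip, components = 0.4, sigma2_e = 0.5)
  expect_equal(two$gebv, one$gebv, tolerance = 1e-10)
  expect_equal(unname(two$components_blup$fs), rep(0, 100))
  # components decompose additively
  full <- gblup_solve(y, list(fs = g_fs, chip = g_chip),
                      components = c(0.2, 0.3), sigma2_e = 0.5)
  expect_equal(full$components_blup$fs + full$components_blup$chip, full$gebv)
})

test_that("GEBVs are location-equivariant in the phenotype", {
  pop <- make_test_population(n = 120, chrs = 2, m_chr = 60, n_qtl = 10, seed = 78)
  G <- grm_vanraden1(pop$geno)
  y <- setNames(pop$pheno$drp, pop$pheno$id)
  f1 <- aireml_fit(y, G)
  f2 <- aireml_fit(y + 10, G)
  expect_equal(f2$mu, f1$mu + 10, tolerance = 1e-5)
  expect_equal(f2$gebv$gebv, f1$gebv$gebv, tolerance = 1e-5)
  expect_equal(unname(f2$components), unname(f1$components), tolerance = 1e-5)
})

test_that("prediction projects reference information onto new individuals", {
  pop <- make_test_population(n = 200, chrs = 2, m_chr = 100, n_qtl = 15,
                              seed = 79, h2 = 0.5)
  G <- grm_vanraden1(pop$geno)
  split <- partition_population(pop$pheno)
  ref <- split$reference
  ph_ref <- pop$pheno[match(ref, pop$pheno$id), ]
  y <- setNames(ph_ref$drp, ph_ref$id)
  G_ref <- G; G_ref$matrix <- G$matrix[ref, ref]
  fit <- aireml_fit(y, G_ref)
  pred <- predict(fit, G, split$validation)
  expect_identical(pred$id, split$validation)
  # direct oracle: sigma2_a G[val, ref] V_ref^-1 (y_ref - mu)
  V <- fit$components[[1]] * G$matrix[ref, ref] + fit$sigma2_e * diag(length(ref))
  manual <- drop(fit$components[[1]] * G$matrix[split$validation, ref] %*%
                   solve(V, y - fit$mu))
  expect_equal(pred$gebv, manual, tolerance = 1e-8)
  # in-sample prediction reproduces the fitted GEBVs
  self <- predict(fit, G, ref)
  expect_equal(self$gebv, fit$gebv$gebv, tolerance = 1e-8)
})
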