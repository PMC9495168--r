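test_that("penalties at or above lambda_max zero every coefficient", {
  pop <- make_test_population(n = 80, chrs = 1, m_chr = 40, n_qtl = 5, seed = 61)
  X <- pop$geno$codes
  y <- pop$pheno$drp
  for (a in c(1, 0.5)) {
    Xs <- scale(X, scale = apply(X, 2, function(x) sqrt(mean((x - mean(x))^2))))
    lmax <- max(abs(crossprod(Xs, y - mean(y)))) / (nrow(X) * a)
    fit <- enet_fit(X, y, alpha = a, lambda = lmax * 1.0001)
    expect_identical(unname(fit$beta), rep(0, ncol(X)))
    expect_equal(fit$intercept, mean(y))
    fit2 <- enet_fit(X, y, alpha = a, lambda = lmax * 0.95)
    expect_gt(sum(fit2$beta != 0), 0)
  }
})

test_that("LASSO on an orthonormal design equals the soft-threshold closed form", {
  n <- 100; m <- 12
  X <- make_orthonormal_design(n, m, seed = 62)
  beta_true <- c(3, -2, 1.5, rep(0, m - 3))
  y <- withr::with_seed(63, drop(X %*% beta_true) + rnorm(n, sd = 0.5))
  b_ols <- drop(crossprod(X, y - mean(y))) / n
  for (lam in c(0.1, 0.5, 1.5)) {
    fit <- enet_fit(X, y, alpha = 1, lambda = lam, standardize = FALSE)
    expect_equal(unname(fit$beta),
                 sign(b_ols) * pmax(abs(b_ols) - lam, 0),
                 tolerance = 1e-8)
  }
})

test_that("every elastic-net solution satisfies the KKT conditions", {
  pop <- make_test_population(n = 150, chrs = 2, m_chr = 60, n_qtl = 10, seed = 64)
  X <- pop$geno$codes
  y <- pop$pheno$drp
  for (a in c(1, 0.55, 0.05)) {
    for (lam in c(0.005, 0.05, 0.2)) {
      fit <- enet_fit(X, y, alpha = a, lambda = lam, standardize = FALSE)
      expect_lt(enet_kkt_violation(X, y, fit$intercept, fit$beta, a, lam), 1e-6)
    }
  }
})

test_that("warm-started path solutions match cold starts", {
  pop <- make_test_population(n = 100, chrs = 1, m_chr = 80, n_qtl = 8, seed = 65)
  X <- pop$geno$codes
  y <- pop$pheno$drp
  lams <- exp(seq(log(0.5), log(0.005), length.out = 8))
  path <- enet_fit(X, y, alpha = 0.5, lambda = lams)
  for (i in seq_along(lams)) {
    cold <- enet_fit(X, y, alpha = 0.5, lambda = lams[i])
    expect_lt(max(abs(path$beta[, i] - cold$beta)), 1e-6)
  }
})

test_that("solutions agree with an independent solver (glmnet)", {
  pop <- make_test_population(n = 120, chrs = 1, m_chr = 50, n_qtl = 6, seed = 66)
  X <- pop$geno$codes
  # glmnet standardizes the response internally, which rescales the ridge
  # part of the penalty; a unit-variance response puts both solvers on the
  # same objective
  y <- pop$pheno$drp
  y <- y / sqrt(mean((y - mean(y))^2))
  for (a in c(1, 0.3)) {
    lam <- 0.05
    ours <- enet_fit(X, y, alpha = a, lambda = lam, standardize = FALSE)
    # glmnet solves single-lambda requests poorly; give it a path ending at lam
    lams_g <- c(exp(seq(log(2), log(lam), length.out = 20)))
    ref <- glmnet::glmnet(X, y, alpha = a, lambda = lams_g, standardize = FALSE,
                          thresh = 1e-14)
    expect_equal(unname(ours$beta), ref$beta[, 20][colnames(X)],
                 ignore_attr = TRUE, tolerance = 1e-5)
    expect_equal(ours$intercept, ref$a0[[20]], tolerance = 1e-5)
  }
})

test_that("cross-validated selection is deterministic given the fold seed", {
  pop <- make_test_population(n = 120, chrs = 1, m_chr = 60, n_qtl = 8, seed = 67)
  X <- pop$geno$codes
  y <- pop$pheno$drp
  cfg <- regularization_config(fold_seed = 5, lambda_path_length = 40,
                               lambda_min_ratio = 0.01)
  s1 <- cv_select_1se(X, y, cfg, mode = "lasso")
  s2 <- cv_select_1se(X, y, cfg, mode = "lasso")
  expect_identical(tidy(s1), tidy(s2))
  expect_identical(s1$cv, s2$cv)
})

test_that("the chosen penalty satisfies the 1SE definition on the stored curve", {
  pop <- make_test_population(n = 150, chrs = 1, m_chr = 70, n_qtl = 10, seed = 68)
  sel <- cv_select_1se(pop$geno$codes, pop$pheno$drp,
                       regularization_config(lambda_path_length = 30,
                                             lambda_min_ratio = 0.01,
                                             n_folds = 5),
                       mode = "en")
  for (a in unique(sel$cv$alpha)) {
    curve <- sel$cv[sel$cv$alpha == a, ]
    i_min <- which.min(curve$mean_cv_error)
    bound <- curve$mean_cv_error[i_min] + curve$se_cv_error[i_min]
    eligible <- curve$lambda[curve$mean_cv_error <= bound]
    expect_equal(curve$lambda[curve$chosen], max(eligible))
  }
  g <- glance(sel)
  expect_equal(g$n_selected, nrow(tidy(sel)))
  expect_true(all(tidy(sel)$coefficient != 0))
})

test_that("pure-noise responses usually yield an empty selection", {
  empties <- vapply(1:10, function(s) {
    X <- withr::with_seed(s, matrix(rbinom(200 * 500, 2, 0.3), 200, 500))
    y <- withr::with_seed(1000 + s, rnorm(200))
    sel <- suppressWarnings(
      cv_select_1se(X, y, regularization_config(fold_seed = s,
                                                lambda_path_length = 40,
                                                lambda_min_ratio = 0.01),
                    mode = "lasso"))
    sel$n_selected == 0
  }, logical(1))
  expect_gte(sum(empties), 8)
})

test_that("near-ridge mixing selects at least as many SNPs as the LASSO", {
  pop <- make_test_population(n = 200, chrs = 2, m_chr = 100, n_qtl = 20,
                              seed = 69, h2 = 0.5)
  X <- pop$geno$codes
  y <- pop$pheno$drp
  cfg <- regularization_config(lambda_path_length = 40, fold_seed = 2,
                               lambda_min_ratio = 0.01, n_folds = 5)
  n_lasso <- cv_select_1se(X, y, cfg, mode = "lasso")$n_selected
  n_en <- cv_select_1se(X, y, cfg, mode = "en")$n_selected
  expect_gte(n_en, n_lasso)
})

test_that("top-N selection orders by p-value with deterministic tie-breaks", {
  res <- tibble::tibble(snp_id = c("a", "b", "c", "d"),
                        beta = c(0.1, 0.9, -0.5, 0.2),
                        p_value = c(0.5, 0.01, 0.03, NA))
  top <- top_n_by_pvalue(res, 2, strategy = "LMM_LASSO")
  expect_identical(top$snp_id, c("b", "c"))
  expect_identical(top$strategy, rep("LMM_LASSO", 2))

  tied <- tibble::tibble(snp_id = c("a", "b", "c"),
                         beta = c(0.1, -0.9, 0.5),
                         p_value = c(0.02, 0.02, 0.02))
  t1 <- top_n_by_pvalue(tied, 2)
  expect_identical(t1$snp_id, c("b", "c"))   # larger |beta| wins, then map order
  expect_identical(top_n_by_pvalue(tied, 2)$snp_id, t1$snp_id)

  expect_error(top_n_by_pvalue(res, 0), "positive")
  expect_error(top_n_by_pvalue(res, 4), "exceeds")
})
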