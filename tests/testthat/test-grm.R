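test_that("allele frequencies average counted-allele copies with missing dropped", {
  codes <- cbind(a = c(0, 1, 2), b = c(0, 1, NA), c = c(0, 0, 0))
  rownames(codes) <- paste0("i", 1:3)
  f <- allele_frequencies(codes)
  expect_equal(unname(f), c(0.5, 0.25, 0))
  expect_error(allele_frequencies(cbind(x = c(NA, NA))), "missing")
})

test_that("VanRaden-1 reproduces the hand-computed two-individual example", {
  codes <- matrix(c(0, 2, 2, 0), 2, 2,
                  dimnames = list(c("i1", "i2"), c("s1", "s2")))
  g <- grm_vanraden1(geno_matrix(codes))
  expect_identical(g$matrix, matrix(c(2, -2, -2, 2), 2, 2,
                                    dimnames = list(c("i1", "i2"), c("i1", "i2"))))
  expect_equal(g$scale_constant, 1)
})

test_that("monomorphic markers are excluded from construction and scaling", {
  codes <- cbind(s1 = c(0, 1, 2, 1), s2 = c(2, 2, 2, 2), s3 = c(0, 0, 1, 1))
  rownames(codes) <- paste0("i", 1:4)
  g <- geno_matrix(codes)
  expect_warning(gv <- grm_vanraden1(g), "monomorphic")
  expect_setequal(gv$snp_ids, c("s1", "s3"))
  expect_error(grm_vanraden1(g, snp_subset = "s2"), "monomorphic")
})

test_that("the per-SNP standardized diagonal matches its defining formula", {
  # single SNP at p = 0.5: heterozygote diagonal is 1 + (1 - 2 + 0.5)/0.5 = 0
  codes <- cbind(s1 = c(0, 1, 1, 2))
  rownames(codes) <- paste0("i", 1:4)
  g <- grm_gcta(geno_matrix(codes))
  expect_equal(diag(g$matrix)[c(2, 3)], c(i2 = 0, i3 = 0))
  # homozygotes at p = 0.5: 1 + (0 - 0 + 0.5)/0.5 = 2
  expect_equal(diag(g$matrix)[c(1, 4)], c(i1 = 2, i4 = 2))
})

test_that("an individual at the mean code has zero off-diagonal relationships", {
  codes <- cbind(s1 = c(1, 0, 2, 1), s2 = c(1, 2, 0, 1))  # p = 0.5, i1 = 2p everywhere
  rownames(codes) <- paste0("i", 1:4)
  g <- grm_gcta(geno_matrix(codes))
  expect_equal(unname(g$matrix[1, -1]), rep(0, 3))
})

test_that("with equal frequencies both constructions agree off the diagonal", {
  # every column is a shuffle of the same code multiset, so all realized
  # frequencies are exactly equal and the two estimators coincide off-diagonal
  base <- c(rep(0, 12), rep(1, 16), rep(2, 12))
  codes <- withr::with_seed(6, sapply(1:25, function(j) sample(base)))
  rownames(codes) <- paste0("i", seq_along(base))
  colnames(codes) <- paste0("s", 1:25)
  g <- geno_matrix(codes)
  gv <- grm_vanraden1(g)
  gg <- grm_gcta(g)
  off <- upper.tri(gv$matrix)
  expect_equal(gg$matrix[off], gv$matrix[off], tolerance = 1e-12)
})

test_that("both constructions are symmetric, near-PSD and allele-flip invariant", {
  pop <- make_test_population(n = 60, chrs = 2, m_chr = 400, n_qtl = 0,
                              seed = 17, ld_rho = 0.2)
  flipped <- geno_matrix(2 - pop$geno$codes, pop$geno$map)
  for (builder in list(grm_vanraden1, grm_gcta)) {
    g <- builder(pop$geno)
    expect_identical(g$matrix, t(g$matrix))
    gf <- builder(flipped)
    expect_equal(gf$matrix, g$matrix, tolerance = 1e-12)
  }
  # VanRaden-1 is a Gram matrix: PSD to machine precision
  ev_v <- eigen(grm_vanraden1(pop$geno)$matrix, symmetric = TRUE,
                only.values = TRUE)$values
  expect_gt(min(ev_v), -1e-8)
  # the per-SNP standardized form is singular along the ones vector before
  # its diagonal is replaced by the unbiased estimator, so its smallest
  # eigenvalue sits at the diagonal's sampling-noise scale, not at zero
  ev_g <- eigen(grm_gcta(pop$geno)$matrix, symmetric = TRUE,
                only.values = TRUE)$values
  expect_gt(min(ev_g), -0.02)
})

test_that("mean diagonal is near 1 in an unstructured population", {
  pop <- make_test_population(n = 100, chrs = 2, m_chr = 300, n_qtl = 0,
                              seed = 23, ld_rho = 0)
  expect_equal(mean(diag(grm_vanraden1(pop$geno)$matrix)), 1, tolerance = 0.05)
  expect_equal(mean(diag(grm_gcta(pop$geno)$matrix)), 1, tolerance = 0.05)
})

test_that("LOCO equals construction from the remaining chromosomes", {
  pop <- make_test_population(n = 50, chrs = 2, m_chr = 40, n_qtl = 0, seed = 3)
  chr2 <- pop$geno$map$snp_id[pop$geno$map$chr == 2]
  loco <- grm_loco(pop$geno, exclude_chr = 1, method = "vanraden1")
  direct <- grm_vanraden1(pop$geno, snp_subset = chr2)
  expect_equal(loco$matrix, direct$matrix)
  expect_identical(loco$loco_excluded, 1)
})

test_that("VanRaden per-chromosome matrices recombine to the full matrix", {
  pop <- make_test_population(n = 40, chrs = 3, m_chr = 30, n_qtl = 0, seed = 19)
  full <- grm_vanraden1(pop$geno)
  parts <- lapply(1:3, function(ch) {
    grm_vanraden1(pop$geno, snp_subset = which(pop$geno$map$chr == ch))
  })
  s <- vapply(parts, `[[`, numeric(1), "scale_constant")
  recombined <- Reduce(`+`, Map(function(g, w) g$matrix * w, parts, s)) / sum(s)
  expect_equal(recombined, full$matrix, tolerance = 1e-12)
})

test_that("LOCO degenerate cases: empty exclusion warns, one chromosome errors", {
  pop1 <- make_test_population(n = 30, chrs = 1, m_chr = 30, n_qtl = 0, seed = 4)
  expect_error(grm_loco(pop1$geno, 1), "two chromosomes")
  pop2 <- make_test_population(n = 30, chrs = 2, m_chr = 30, n_qtl = 0, seed = 4)
  expect_warning(g <- grm_loco(pop2$geno, exclude_chr = 99), "no SNPs")
  expect_equal(g$matrix, grm_gcta(pop2$geno)$matrix)
})
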