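# Independent oracles and small fixture builders shared across tests.
# Everything here is deliberately naive: direct formulas and dense linear
# algebra, no reuse of the package's computational paths.

# direct log-factorial probability of a heterozygote count conditional on
# allele counts; the enumeration oracle for the exact HWE test
hwe_enum_pvalues <- function(nr, n) {
  if (nr == 0) return(stats::setNames(1, "0"))
  hets <- seq.int(nr %% 2, nr, by = 2)
  hets <- hets[(nr - hets) / 2 <= n - hets]
  lp <- vapply(hets, function(h) {
    n_rare <- (nr - h) / 2
    n_comm <- n - h - n_rare
    lfactorial(n) - lfactorial(n_rare) - lfactorial(h) - lfactorial(n_comm) +
      h * log(2) + lfactorial(nr) + lfactorial(2 * n - nr) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  p <- vapply(seq_along(hets), function(i) {
    sum(probs[probs <= probs[i] * (1 + 1e-10)])
  }, numeric(1))
  stats::setNames(pmin(p, 1), as.character(hets))
}

# dense restricted log-likelihood of y = 1 mu + g + e, g ~ N(0, G s2g),
# e ~ N(0, I s2e), evaluated with generic determinants and solves
dense_reml_loglik <- function(y, G, s2g, s2e) {
  n <- length(y)
  V <- s2g * G + s2e * diag(n)
  X <- matrix(1, n, 1)
  Vinv <- solve(V)
  XtVX <- drop(t(X) %*% Vinv %*% X)
  mu <- drop(t(X) %*% Vinv %*% y) / XtVX
  r <- y - mu
  -0.5 * (as.numeric(determinant(V)$modulus) + log(XtVX) + drop(t(r) %*% Vinv %*% r) +
            (n - 1) * log(2 * pi))
}

# KKT subgradient residual for the elastic-net objective
# (1/(2n)) ||y - mu - X b||^2 + lambda ((1-alpha)/2 ||b||^2 + alpha ||b||_1);
# returns the largest violation across coordinates
enet_kkt_violation <- function(X, y, intercept, beta, alpha, lambda) {
  n <- nrow(X)
  r <- y - intercept - drop(X %*% beta)
  g <- drop(crossprod(X, r)) / n - lambda * (1 - alpha) * beta
  active <- beta != 0
  viol_active <- if (any(active)) {
    max(abs(g[active] - lambda * alpha * sign(beta[active])))
  } else 0
  viol_zero <- if (any(!active)) max(0, abs(g[!active]) - lambda * alpha) else 0
  max(viol_active, viol_zero)
}

# small quality-controlled population for mid-level tests
make_test_population <- function(n = 300, chrs = 2, m_chr = 150, n_qtl = 20,
                                 h2 = 0.4, seed = 42, ld_rho = 0.3, ...) {
  cfg <- sim_config(n_individuals = n, n_chromosomes = chrs,
                    snps_per_chromosome = m_chr, n_qtl = n_qtl, h2 = h2,
                    ld_rho = ld_rho, seed = seed, ...)
  simulate_population(cfg)
}

# draw y with known variance components on a fixed relationship matrix
draw_y_from_grm <- function(G, s2g, s2e, seed) {
  n <- nrow(G)
  eg <- eigen(G, symmetric = TRUE)
  withr::with_seed(seed, {
    g <- drop(eg$vectors %*% (sqrt(pmax(eg$values, 0) * s2g) * rnorm(n)))
    g + rnorm(n, sd = sqrt(s2e))
  })
}

# center and scale to unit variance
sd_unit <- function(x) (x - mean(x)) / stats::sd(x)

# n-scaled orthonormal design: columns centered, x_j'x_j / n = 1, x_j'x_k = 0
make_orthonormal_design <- function(n, m, seed) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(scale(matrix(rnorm(n * (m + 1)), n, m + 1), scale = FALSE)))[, 1:m]
    sweep(Q, 2, sqrt(colMeans(Q^2)), `/`)
  })
}
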