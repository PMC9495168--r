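#' Fit the polygenic null model by REML on the GRM eigenbasis
#'
#' Model `y = 1 mu + g + e` with `g ~ N(0, G sigma2_g)` and
#' `e ~ N(0, I sigma2_e)`. After rotating by the eigenvectors of `G`, the
#' covariance is diagonal and the restricted likelihood profiles down to a
#' one-dimensional optimization over the heritability ratio
#' `h = sigma2_g / (sigma2_g + sigma2_e)`, solved with Brent's method. The
#' spectral decomposition is stored for reuse by the association scan.
#'
#' @param y Numeric phenotype vector (de-regressed proofs), optionally named
#'   with individual ids matching the GRM.
#' @param grm A `grm` object (or plain symmetric matrix).
#' @return A `null_model_fit`: `sigma2_g`, `sigma2_e`, `loglik_reml`,
#'   `boundary` flag (variance ratio pinned near 0 or 1), eigen pair
#'   (`values`, `vectors`) and rotated phenotype/intercept.
#' @export
fit_null_reml <- function(y, grm) {
  G <- if (inherits(grm, "grm")) grm$matrix else as.matrix(grm)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stop_gsfs("need at least 3 individuals")
  if (nrow(G) != n) stop_gsfs("GRM dimension does not match phenotype length")
  if (sd(y) == 0) stop_gsfs("phenotype is constant")
  eg <- eigen(G, symmetric = TRUE)
  # the per-SNP standardized GRM's unbiased diagonal can leave it very
  # slightly indefinite; clip small negative eigenvalues, reject real ones
  if (min(eg$values) < -0.05 * max(abs(eg$values))) {
    stop_gsfs("GRM is not positive semi-definite")
  }
  s <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  # profiled restricted log-likelihood in h = sigma2_g / sigma2_p
  rll <- function(h) {
    v <- h * s + (1 - h)
    w <- 1 / v
    mu <- sum(w * xt * yt) / sum(w * xt^2)
    rss <- sum(w * (yt - xt * mu)^2)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + sum(log(v)) + log(sum(w * xt^2)))
  }
  opt <- optimize(rll, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-10)
  h <- opt$maximum
  v <- h * s + (1 - h)
  w <- 1 / v
  mu <- sum(w * xt * yt) / sum(w * xt^2)
  s2p <- sum(w * (yt - xt * mu)^2) / (n - 1)
  structure(
    list(sigma2_g = h * s2p, sigma2_e = (1 - h) * s2p,
         h2 = h, mu = mu,
         loglik_reml = opt$objective,
         boundary = h < 1e-3 || h > 1 - 1e-3,
         values = s, vectors = U, y_rot = yt, x_rot = xt,
         chromosome = if (inherits(grm, "grm")) grm$loco_excluded %||% NA else NA),
    class = "null_model_fit"
  )
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat("<null_model_fit> sigma2_g =", signif(x$sigma2_g, 4),
      "sigma2_e =", signif(x$sigma2_e, 4),
      if (x$boundary) "(boundary)" else "", "\n")
  invisible(x)
}

#' Fit leave-one-chromosome-out null models for every chromosome
#'
#' For each chromosome, builds the per-SNP standardized GRM from all other
#' chromosomes and fits the polygenic null model once; the association scan
#' then holds these variance components fixed for every SNP on that
#' chromosome.
#'
#' @param geno A `geno_matrix` with at least two chromosomes.
#' @param y Phenotype vector aligned with the rows of `geno`.
#' @param method GRM construction for the polygenic term.
#' @return Named list of `null_model_fit`, one per chromosome.
#' @export
fit_loco_nulls <- function(geno, y, method = "gcta") {
  chrs <- unique(geno$map$chr)
  fits <- lapply(chrs, function(ch) {
    fit_null_reml(y, grm_loco(geno, ch, method = method))
  })
  names(fits) <- as.character(chrs)
  fits
}

#' Single-marker mixed-model association scan
#'
#' For each SNP, generalized least squares of the phenotype on an intercept
#' and the additive genotype code under the covariance
#' `sigma2_g G_loco + sigma2_e I` of the chromosome-matched null model,
#' with variance components held fixed across all SNPs of that chromosome.
#' The Wald statistic `(b / se)^2` is referred to the chi-square
#' distribution with 1 df. Monomorphic SNPs and SNPs collinear with the
#' intercept are flagged `"untestable"` rather than dropped.
#'
#' @param geno A `geno_matrix`.
#' @param y Phenotype vector aligned with the rows of `geno`.
#' @param null_fits Named list of `null_model_fit` per chromosome (e.g. from
#'   [fit_loco_nulls()]); a single unnamed fit is recycled for all
#'   chromosomes.
#' @param trait Optional trait label stored in the result.
#' @return A `gwas_result` tibble: `snp_id`, `chr`, `pos`, `beta`, `se`,
#'   `statistic`, `p_value`, `status`.
#' @export
wald_scan <- function(geno, y, null_fits, trait = "trait") {
  stopifnot(inherits(geno, "geno_matrix"))
  y <- as.numeric(y)
  if (length(y) != nrow(geno$codes)) stop_gsfs("phenotype length does not match genotypes")
  if (inherits(null_fits, "null_model_fit")) null_fits <- list(null_fits)
  chrs <- as.character(unique(geno$map$chr))
  if (length(null_fits) == 1L && is.null(names(null_fits))) {
    null_fits <- setNames(rep(null_fits, length(chrs)), chrs)
  }
  if (!all(chrs %in% names(null_fits))) {
    stop_gsfs("missing null model fit for chromosome(s): ",
              paste(setdiff(chrs, names(null_fits)), collapse = ", "))
  }
  m <- ncol(geno$codes)
  beta <- se <- stat <- pval <- rep(NA_real_, m)
  status <- rep("ok", m)
  p_all <- geno$freqs
  for (ch in chrs) {
    fit <- null_fits[[ch]]
    idx <- which(as.character(geno$map$chr) == ch)
    w <- 1 / (fit$sigma2_g * fit$values + fit$sigma2_e)
    X <- geno$codes[, idx, drop = FALSE]
    X[is.na(X)] <- 0
    for (j in seq_along(idx)) {           # mean-impute missing per SNP
      nas <- is.na(geno$codes[, idx[j]])
      if (any(nas)) X[nas, j] <- 2 * p_all[idx[j]]
    }
    Xt <- crossprod(fit$vectors, X)
    yt <- fit$y_rot
    ot <- fit$x_rot
    a11 <- sum(w * ot^2)
    a12 <- drop(crossprod(Xt * w, ot))
    a22 <- colSums(Xt^2 * w)
    b1 <- sum(w * ot * yt)
    b2 <- drop(crossprod(Xt * w, yt))
    det <- a11 * a22 - a12^2
    bad <- p_all[idx] <= 0 | p_all[idx] >= 1 | det <= 1e-10 * a11 * pmax(a22, 1e-300)
    b_hat <- (a11 * b2 - a12 * b1) / det
    v_hat <- a11 / det
    beta[idx] <- ifelse(bad, NA_real_, b_hat)
    se[idx] <- ifelse(bad, NA_real_, sqrt(v_hat))
    st <- b_hat^2 / v_hat
    stat[idx] <- ifelse(bad, NA_real_, st)
    pval[idx] <- ifelse(bad, NA_real_, pchisq(st, df = 1, lower.tail = FALSE))
    status[idx][bad] <- "untestable"
  }
  out <- tibble(snp_id = colnames(geno$codes),
                chr = geno$map$chr, pos = geno$map$pos,
                beta = beta, se = se, statistic = stat, p_value = pval,
                status = status)
  attr(out, "trait") <- trait
  attr(out, "n") <- length(y)
  class(out) <- c("gwas_result", class(out))
  out
}

#' Pre-select SNPs by nominal association p-value
#'
#' Keeps SNPs with `p_value` strictly below the threshold (default 0.05,
#' the nominal pre-selection used upstream of regularized-regression
#' feature selection), preserving map order. Untestable SNPs never pass.
#'
#' @param result A `gwas_result`.
#' @param threshold P-value threshold; retention is strict (`p < threshold`).
#' @return Character vector of selected SNP ids (possibly empty, with a
#'   warning).
#' @export
preselect_by_threshold <- function(result, threshold = 0.05) {
  stopifnot(is.data.frame(result), all(c("snp_id", "p_value") %in% names(result)))
  sel <- result$snp_id[!is.na(result$p_value) & result$p_value < threshold]
  if (!length(sel)) warn("no SNPs pass the pre-selection threshold")
  as.character(sel)
}

#' @export
autoplot.gwas_result <- function(object, threshold = 0.05, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$p_value))
  df$chr <- factor(df$chr)
  ggplot2::ggplot(df, ggplot2::aes(x = seq_along(.data$snp_id),
                                   y = -log10(.data$p_value),
                                   colour = .data$chr)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = 2) +
    ggplot2::labs(x = "SNP index", y = expression(-log[10](p)),
                  title = attr(object, "trait")) +
    ggplot2::theme_minimal()
}
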