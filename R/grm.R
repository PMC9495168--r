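#' Per-SNP allele frequencies with mean imputation
#'
#' Frequency of the counted allele (the allele whose copies the 0/1/2 codes
#' tally): `p_i = (sum of copies) / (2 x non-missing individuals)`. Both
#' relationship-matrix constructions below are provably invariant to which
#' allele is counted, so no minor/major designation is needed. Missing codes
#' are imputed as `2 p_i` (the mean code) when matrices are built.
#'
#' @param geno A `geno_matrix` or a plain individuals x SNPs code matrix.
#' @return Named numeric vector of per-SNP frequencies.
#' @export
allele_frequencies <- function(geno) {
  codes <- if (inherits(geno, "geno_matrix")) geno$codes else as.matrix(geno)
  n_obs <- colSums(!is.na(codes))
  if (any(n_obs == 0L)) {
    stop_gsfs("SNP(s) with all calls missing; remove them before computing frequencies")
  }
  colMeans(codes, na.rm = TRUE) / 2
}

# centered (and optionally standardized) code matrix with mean imputation;
# monomorphic columns are the caller's responsibility
.center_codes <- function(codes, p, standardize = FALSE) {
  Z <- sweep(codes, 2L, 2 * p, `-`)
  Z[is.na(Z)] <- 0    # missing = mean code 2p, centered to 0
  if (standardize) Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), `/`)
  Z
}

.resolve_subset <- function(geno, snp_subset) {
  ids <- colnames(geno$codes)
  if (is.null(snp_subset)) return(seq_along(ids))
  if (is.character(snp_subset)) {
    idx <- match(snp_subset, ids)
    if (anyNA(idx)) stop_gsfs("unknown SNP id(s) in `snp_subset`")
    return(idx)
  }
  idx <- as.integer(snp_subset)
  if (any(idx < 1L | idx > length(ids))) stop_gsfs("SNP subset index out of range")
  idx
}

.new_grm <- function(mat, method, snp_ids, scale_constant) {
  structure(list(matrix = mat, method = method, snp_ids = snp_ids,
                 scale_constant = scale_constant),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm>", nrow(x$matrix), "x", ncol(x$matrix), "individuals, method =",
      x$method, "from", length(x$snp_ids), "SNPs\n")
  invisible(x)
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' `G = Z Z' / (2 sum p_i (1 - p_i))` where `Z` holds column-centered codes
#' `x_ij - 2 p_i`. The Gram form makes `G` symmetric positive semi-definite
#' by construction, and centering makes it invariant to recoding any SNP by
#' the opposite allele. Monomorphic SNPs contribute nothing and are excluded
#' from both numerator and scale (with a warning).
#'
#' @param geno A `geno_matrix`.
#' @param snp_subset SNP ids or column indices to use; default all.
#' @return A `grm` object.
#' @export
grm_vanraden1 <- function(geno, snp_subset = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  idx <- .resolve_subset(geno, snp_subset)
  if (!length(idx)) stop_gsfs("empty SNP subset")
  p <- geno$freqs[idx]
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_gsfs("all SNPs in subset are monomorphic; GRM scale is zero")
  if (any(!poly)) {
    warn(sprintf("%d monomorphic SNP(s) excluded from GRM", sum(!poly)))
    idx <- idx[poly]
    p <- p[poly]
  }
  Z <- .center_codes(geno$codes[, idx, drop = FALSE], p)
  sc <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / sc
  .new_grm(G, "vanraden1", colnames(geno$codes)[idx], sc)
}

#' Genomic relationship matrix, per-SNP standardized form
#'
#' The GCTA-style estimator: off-diagonal entries average
#' `(x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1 - p_i))` over SNPs, while the
#' diagonal uses the distinct unbiased form
#' `1 + mean((x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p)))`. This is the
#' matrix used for the mixed-model association scan; GBLUP uses
#' [grm_vanraden1()].
#'
#' @inheritParams grm_vanraden1
#' @return A `grm` object.
#' @export
grm_gcta <- function(geno, snp_subset = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  idx <- .resolve_subset(geno, snp_subset)
  if (!length(idx)) stop_gsfs("empty SNP subset")
  p <- geno$freqs[idx]
  poly <- p > 0 & p < 1
  if (!any(poly)) stop_gsfs("all SNPs in subset are monomorphic; GRM scale is zero")
  if (any(!poly)) {
    warn(sprintf("%d monomorphic SNP(s) excluded from GRM", sum(!poly)))
    idx <- idx[poly]
    p <- p[poly]
  }
  X <- geno$codes[, idx, drop = FALSE]
  W <- .center_codes(X, p, standardize = TRUE)
  N <- length(idx)
  G <- tcrossprod(W) / N
  # replace the diagonal with the dedicated estimator
  Ximp <- X
  for (j in seq_len(ncol(Ximp))) {             # mean-impute missing codes
    nas <- is.na(Ximp[, j])
    if (any(nas)) Ximp[nas, j] <- 2 * p[j]
  }
  num <- Ximp^2 - sweep(Ximp, 2L, 1 + 2 * p, `*`) +
    matrix(2 * p^2, nrow(Ximp), N, byrow = TRUE)
  diag(G) <- 1 + rowMeans(sweep(num, 2L, 2 * p * (1 - p), `/`))
  .new_grm(G, "gcta", colnames(geno$codes)[idx], N)
}

#' Leave-one-chromosome-out genomic relationship matrix
#'
#' Builds the GRM from all SNPs *not* on the excluded chromosome, the
#' standard device for mixed-model association scans: the polygenic term
#' must not absorb the tested SNP or its neighbours in LD.
#'
#' @param geno A `geno_matrix`.
#' @param exclude_chr Chromosome label to leave out.
#' @param method `"gcta"` (default, the scan matrix) or `"vanraden1"`.
#' @return A `grm` object.
#' @export
grm_loco <- function(geno, exclude_chr, method = c("gcta", "vanraden1")) {
  stopifnot(inherits(geno, "geno_matrix"))
  method <- match.arg(method)
  chrs <- unique(geno$map$chr)
  if (length(chrs) < 2L) {
    stop_gsfs("leave-one-chromosome-out needs at least two chromosomes")
  }
  keep <- which(geno$map$chr != exclude_chr)
  if (length(keep) == ncol(geno$codes)) {
    warn(sprintf("chromosome '%s' has no SNPs; LOCO GRM equals the full GRM",
                 as.character(exclude_chr)))
  }
  if (!length(keep)) stop_gsfs("no SNPs left after excluding chromosome")
  builder <- if (method == "vanraden1") grm_vanraden1 else grm_gcta
  g <- builder(geno, snp_subset = keep)
  g$loco_excluded <- exclude_chr
  g
}
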