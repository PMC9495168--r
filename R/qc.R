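#' Quality-control thresholds
#'
#' Retention is strict: an individual or SNP is kept only when its statistic
#' is strictly greater than the corresponding threshold (call rates, MAF,
#' HWE p-value). Defaults reproduce a standard chip-QC protocol for dairy
#' cattle: individual call rate > 0.95, SNP call rate > 0.95, MAF > 0.01,
#' HWE exact-test p > 1e-6.
#'
#' @param ind_call_rate Minimum (exclusive) individual call rate.
#' @param snp_call_rate Minimum (exclusive) SNP call rate.
#' @param maf_min Minimum (exclusive) minor allele frequency.
#' @param hwe_p_min Minimum (exclusive) Hardy-Weinberg exact-test p-value.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(ind_call_rate = 0.95, snp_call_rate = 0.95,
                          maf_min = 0.01, hwe_p_min = 1e-6) {
  vals <- c(ind_call_rate, snp_call_rate, maf_min, hwe_p_min)
  if (any(vals < 0) || any(vals > 1)) {
    stop_gsfs("all QC thresholds must lie in [0, 1]", class = "gsfs_config_error")
  }
  structure(list(ind_call_rate = ind_call_rate, snp_call_rate = snp_call_rate,
                 maf_min = maf_min, hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

# p-values of the conditional exact HWE test for every possible heterozygote
# count, given n diploid individuals carrying nr copies of the rarer allele.
# Probabilities conditional on the allele counts are computed by the stable
# mid-to-tails recurrence; the two-sided p-value for an observed het count
# sums the probabilities of all configurations no more likely than it.
.hwe_pvalues_all <- function(nr, n) {
  if (nr == 0L) return(setNames(1, "0"))
  hets <- seq.int(nr %% 2L, nr, by = 2L)       # parity of nr
  hets <- hets[(nr - hets) / 2L <= n - hets]   # rare homs must fit in n
  nh <- length(hets)
  probs <- numeric(nh)
  # start at the mode-ish midpoint and apply the ratio recurrence outwards:
  # P(h-2)/P(h) = h (h-1) / (4 n_aa(h-2) n_AA(h-2)) etc.
  mid <- which.min(abs(hets - nr * (2 * n - nr) / (2 * n - 1)))
  probs[mid] <- 1
  if (mid < nh) {
    for (i in mid:(nh - 1L)) {
      h <- hets[i]
      n_rare_hom <- (nr - h) / 2
      n_comm_hom <- n - h - n_rare_hom
      # moving h -> h + 2
      probs[i + 1L] <- probs[i] * 4 * n_rare_hom * n_comm_hom / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1L) {
    for (i in mid:2L) {
      h <- hets[i]
      n_rare_hom <- (nr - h) / 2
      n_comm_hom <- n - h - n_rare_hom
      # moving h -> h - 2
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (n_rare_hom + 1) * (n_comm_hom + 1))
    }
  }
  probs <- probs / sum(probs)
  p <- vapply(seq_len(nh), function(i) {
    sum(probs[probs <= probs[i] * (1 + 1e-10)])
  }, numeric(1))
  setNames(pmin(p, 1), as.character(hets))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test on one biallelic marker: conditional on
#' the observed allele counts, the p-value is the total probability of all
#' heterozygote counts whose probability does not exceed that of the
#' observed count. This is the exact test chip-QC tools apply by default;
#' unlike the chi-square test it is well behaved at low minor allele
#' frequency. Vectorized over genotype-count triples.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return P-values in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(50, 0, 50)   # extreme heterozygote deficit
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), k)
  n_Aa <- rep_len(as.integer(n_Aa), k)
  n_aa <- rep_len(as.integer(n_aa), k)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) stop_gsfs("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0L)) stop_gsfs("at least one genotype count must be positive")
  nr <- pmin(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)   # rarer-allele copies
  out <- numeric(k)
  for (key in unique(paste(n, nr))) {
    sel <- which(paste(n, nr) == key)
    pv <- .hwe_pvalues_all(nr[sel[1L]], n[sel[1L]])
    out[sel] <- pv[as.character(n_Aa[sel])]
  }
  out
}

#' Apply marker and individual quality control
#'
#' Single-pass filtering in a fixed, documented order: (1) SNPs on
#' non-autosomal chromosomes are dropped unconditionally; (2) individuals
#' with call rate not exceeding `ind_call_rate` are removed; (3) remaining
#' SNPs are tested, in order, for call rate, minor allele frequency and
#' Hardy-Weinberg equilibrium (exact test), each with strict retention.
#' Allele frequencies and HWE are computed after individual removal, as QC
#' tools do.
#'
#' @param geno A `geno_matrix`.
#' @param thresholds A [qc_thresholds()].
#' @param autosomes Chromosome labels regarded as autosomal; by default every
#'   chromosome whose label parses as a number. SNPs on other chromosomes
#'   (e.g. `"X"`, `"Y"`, `"MT"`) are excluded.
#' @return List with `geno` (filtered `geno_matrix`) and `report`, a tibble
#'   of removals with columns `item`, `type` (`"individual"`/`"snp"`),
#'   `reason` and `value` (the offending statistic).
#' @export
run_qc <- function(geno, thresholds = qc_thresholds(), autosomes = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(thresholds, "qc_thresholds"))
  codes <- geno$codes
  map <- geno$map
  report <- list()

  chr_lab <- as.character(map$chr)
  if (is.null(autosomes)) {
    auto <- !is.na(suppressWarnings(as.numeric(chr_lab)))
  } else {
    auto <- chr_lab %in% as.character(autosomes)
  }
  if (any(!auto)) {
    report$sex <- tibble(item = map$snp_id[!auto], type = "snp",
                         reason = "non_autosomal", value = NA_real_)
    codes <- codes[, auto, drop = FALSE]
    map <- map[auto, , drop = FALSE]
  }
  if (ncol(codes) == 0L) stop_gsfs("all SNPs removed by QC", class = "gsfs_empty_result")

  ind_cr <- rowMeans(!is.na(codes))
  bad_ind <- ind_cr <= thresholds$ind_call_rate
  if (any(bad_ind)) {
    report$ind <- tibble(item = rownames(codes)[bad_ind], type = "individual",
                         reason = "call_rate", value = ind_cr[bad_ind])
    codes <- codes[!bad_ind, , drop = FALSE]
  }
  if (nrow(codes) == 0L) stop_gsfs("all individuals removed by QC", class = "gsfs_empty_result")

  snp_cr <- colMeans(!is.na(codes))
  bad_cr <- snp_cr <= thresholds$snp_call_rate
  keep <- !bad_cr
  if (any(bad_cr)) {
    report$snp_cr <- tibble(item = colnames(codes)[bad_cr], type = "snp",
                            reason = "call_rate", value = snp_cr[bad_cr])
  }

  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad_maf <- keep & (maf <= thresholds$maf_min | is.nan(maf))
  if (any(bad_maf)) {
    report$maf <- tibble(item = colnames(codes)[bad_maf], type = "snp",
                         reason = "maf", value = maf[bad_maf])
    keep <- keep & !bad_maf
  }

  idx <- which(keep)
  if (length(idx)) {
    n_aa <- colSums(codes[, idx, drop = FALSE] == 0, na.rm = TRUE)
    n_ab <- colSums(codes[, idx, drop = FALSE] == 1, na.rm = TRUE)
    n_bb <- colSums(codes[, idx, drop = FALSE] == 2, na.rm = TRUE)
    hwe_p <- hwe_exact_test(n_aa, n_ab, n_bb)
    bad_hwe <- hwe_p <= thresholds$hwe_p_min
    if (any(bad_hwe)) {
      report$hwe <- tibble(item = colnames(codes)[idx[bad_hwe]], type = "snp",
                           reason = "hwe", value = hwe_p[bad_hwe])
      keep[idx[bad_hwe]] <- FALSE
    }
  }

  if (!any(keep)) stop_gsfs("all SNPs removed by QC", class = "gsfs_empty_result")
  codes <- codes[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]

  report <- if (length(report)) dplyr::bind_rows(report) else
    tibble(item = character(), type = character(),
           reason = character(), value = numeric())
  list(geno = geno_matrix(codes, map), report = report)
}
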