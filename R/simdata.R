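#' Configuration for the synthetic breeding population
#'
#' Collects, and validates, every knob of the synthetic-data generator:
#' population size, genome layout, linkage disequilibrium, trait
#' architecture and the de-regressed-proof (DRP) reliability spectrum.
#' The generator emulates a post-imputation dairy-cattle dataset: complete
#' multi-chromosome genotypes with adjacent-marker LD, a sparse set of
#' additive QTL producing heritability `h2` (total phenotypic variance is
#' normalized to 1, so `h2` equals the additive genetic variance), and DRPs
#' equal to the true breeding value plus noise with per-individual variance
#' `sigma2_a * (1 - r2) / r2` for reliability `r2`.
#'
#' @param n_individuals Number of individuals.
#' @param n_chromosomes Number of chromosomes.
#' @param snps_per_chromosome Markers simulated on each chromosome.
#' @param n_qtl Number of causal loci (sampled genome-wide without
#'   replacement); may be 0 for a null trait.
#' @param h2 Narrow-sense heritability in (0, 1); equals the additive
#'   variance because phenotypic variance is fixed at 1.
#' @param maf_range Length-2 interval within (0, 0.5]; per-marker allele
#'   frequencies are drawn uniformly from it.
#' @param ld_rho First-order correlation of the latent gamete chain in
#'   [0, 1); 0 gives linkage equilibrium, larger values stronger adjacent-
#'   marker LD decaying geometrically with distance.
#' @param reliability_range Length-2 interval within (0, 1]; per-individual
#'   DRP reliabilities are drawn uniformly from it.
#' @param birth_year_range Length-2 integer interval; birth years are drawn
#'   uniformly from it (the default brackets a 2013 reference/validation
#'   cutoff).
#' @param missing_rate Fraction of genotype calls set missing, to exercise
#'   quality control. Default 0: the emulated data are post-imputation.
#' @param seed Integer seed; identical configurations yield bit-identical
#'   populations.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 50, n_chromosomes = 2,
#'                   snps_per_chromosome = 20, n_qtl = 5, h2 = 0.3, seed = 1)
sim_config <- function(n_individuals,
                       n_chromosomes,
                       snps_per_chromosome,
                       n_qtl,
                       h2,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.6,
                       reliability_range = c(0.5, 0.95),
                       birth_year_range = c(2008L, 2015L),
                       missing_rate = 0,
                       seed = 1L) {
  n_individuals <- as.integer(n_individuals)
  n_chromosomes <- as.integer(n_chromosomes)
  snps_per_chromosome <- as.integer(snps_per_chromosome)
  n_qtl <- as.integer(n_qtl)
  if (n_individuals < 1L) stop_gsfs("`n_individuals` must be >= 1", class = "gsfs_config_error")
  if (n_chromosomes < 1L || snps_per_chromosome < 1L) {
    stop_gsfs("genome must have at least one chromosome and one SNP per chromosome",
              class = "gsfs_config_error")
  }
  total_snps <- n_chromosomes * snps_per_chromosome
  if (n_qtl < 0L || n_qtl > total_snps) {
    stop_gsfs("`n_qtl` must lie in [0, total number of SNPs]", class = "gsfs_config_error")
  }
  if (!(h2 > 0 && h2 < 1)) stop_gsfs("`h2` must lie in (0, 1)", class = "gsfs_config_error")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop_gsfs("`maf_range` must be an interval within (0, 0.5]", class = "gsfs_config_error")
  }
  if (!(ld_rho >= 0 && ld_rho < 1)) stop_gsfs("`ld_rho` must lie in [0, 1)", class = "gsfs_config_error")
  if (length(reliability_range) != 2L || reliability_range[1] > reliability_range[2] ||
      reliability_range[1] <= 0 || reliability_range[2] > 1) {
    stop_gsfs("`reliability_range` must be an interval within (0, 1]", class = "gsfs_config_error")
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    stop_gsfs("`missing_rate` must lie in [0, 1)", class = "gsfs_config_error")
  }
  structure(
    list(
      n_individuals = n_individuals,
      n_chromosomes = n_chromosomes,
      snps_per_chromosome = snps_per_chromosome,
      n_qtl = n_qtl,
      h2 = h2,
      maf_range = as.numeric(maf_range),
      ld_rho = as.numeric(ld_rho),
      reliability_range = as.numeric(reliability_range),
      birth_year_range = as.integer(birth_year_range),
      missing_rate = as.numeric(missing_rate),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_individuals, "individuals,",
      x$n_chromosomes, "chr x", x$snps_per_chromosome, "SNPs,",
      x$n_qtl, "QTL, h2 =", x$h2, "\n")
  invisible(x)
}

# one gamete: latent AR(1) Gaussian chain thresholded at qnorm(p) so the
# marginal allele frequency is exactly p while adjacent markers share a
# first-order correlation governed by ld_rho
.sim_gamete <- function(n_ind, p, ld_rho) {
  m <- length(p)
  z <- matrix(rnorm(n_ind * m), n_ind, m)
  if (ld_rho > 0 && m > 1L) {
    s <- sqrt(1 - ld_rho^2)
    for (i in 2:m) z[, i] <- ld_rho * z[, i - 1L] + s * z[, i]
  }
  thr <- qnorm(p)
  (z < matrix(thr, n_ind, m, byrow = TRUE)) + 0
}

#' Simulate a multi-chromosome genotype matrix
#'
#' Draws per-marker allele frequencies uniformly from `maf_range`, then for
#' each chromosome simulates two independent gametes as latent first-order
#' autoregressive Gaussian chains thresholded at the allele frequency, and
#' sums them to additive codes 0/1/2. Chromosomes are independent, so LD
#' exists only within chromosomes and decays geometrically with marker
#' distance.
#'
#' @param config A [sim_config()].
#' @return A `geno_matrix`: list with `codes` (individuals x SNPs matrix of
#'   0/1/2, `NA` for missing), `map` (tibble with `snp_id`, `chr`, `pos`) and
#'   `freqs` (observed counted-allele frequencies, see
#'   [allele_frequencies()]).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_individuals
    m_chr <- config$snps_per_chromosome
    codes <- vector("list", config$n_chromosomes)
    maps <- vector("list", config$n_chromosomes)
    for (chr in seq_len(config$n_chromosomes)) {
      p <- runif(m_chr, config$maf_range[1], config$maf_range[2])
      g <- .sim_gamete(n, p, config$ld_rho) + .sim_gamete(n, p, config$ld_rho)
      pos <- cumsum(sample.int(90000L, m_chr, replace = TRUE) + 10000L)
      colnames(g) <- sprintf("snp_%d_%d", chr, seq_len(m_chr))
      codes[[chr]] <- g
      maps[[chr]] <- tibble(snp_id = colnames(g), chr = chr, pos = pos)
    }
    codes <- do.call(cbind, codes)
    rownames(codes) <- sprintf("ind_%d", seq_len(n))
    if (config$missing_rate > 0) {
      miss <- runif(length(codes)) < config$missing_rate
      codes[miss] <- NA_real_
    }
    geno_matrix(codes, dplyr::bind_rows(maps))
  })
}

#' Construct a genotype-matrix object
#'
#' @param codes Numeric matrix, individuals x SNPs, values 0/1/2 or `NA`;
#'   row names are individual ids, column names SNP ids.
#' @param map Data frame with columns `snp_id`, `chr`, `pos` aligned with the
#'   columns of `codes` (generated if omitted).
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(codes, map = NULL) {
  codes <- as.matrix(codes)
  if (nrow(codes) == 0L || ncol(codes) == 0L) {
    stop_gsfs("genotype matrix must have at least one individual and one SNP",
              class = "gsfs_config_error")
  }
  ok <- codes[!is.na(codes)]
  if (length(ok) && !all(ok %in% c(0, 1, 2))) {
    stop_gsfs("genotype codes must be 0, 1, 2 or missing")
  }
  if (is.null(rownames(codes))) rownames(codes) <- sprintf("ind_%d", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("snp_%d", seq_len(ncol(codes)))
  if (is.null(map)) {
    map <- tibble(snp_id = colnames(codes), chr = 1L, pos = seq_len(ncol(codes)))
  }
  map <- as_tibble(map)
  stopifnot(all(c("snp_id", "chr", "pos") %in% names(map)))
  if (nrow(map) != ncol(codes) || !identical(as.character(map$snp_id), colnames(codes))) {
    stop_gsfs("SNP map does not align with genotype columns")
  }
  structure(
    list(codes = codes, map = map, freqs = allele_frequencies(codes)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix>", nrow(x$codes), "individuals x", ncol(x$codes), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s);",
      sum(is.na(x$codes)), "missing call(s)\n")
  invisible(x)
}

#' Dimensions of a genotype matrix
#' @param x A `geno_matrix`.
#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Simulate a sparse additive trait architecture
#'
#' Samples `n_qtl` causal markers without replacement, draws their allele-
#' substitution effects iid normal, computes true breeding values from
#' column-centered genotype codes, and rescales effects so that the
#' empirical variance of the breeding values equals `h2` (phenotypic
#' variance is 1 by convention, so `sigma2_a = h2`).
#'
#' @param geno A `geno_matrix`.
#' @param config The [sim_config()] that generated it.
#' @return A `true_state`: list with `qtl_indices`, `qtl_ids`, `qtl_effects`,
#'   `tbv` (named per-individual true breeding values) and `sigma2_a`.
#' @export
simulate_true_effects <- function(geno, config) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  m <- ncol(geno$codes)
  if (config$n_qtl > m) stop_gsfs("more QTL requested than SNPs available")
  n <- nrow(geno$codes)
  withr::with_seed(config$seed + 1L, {
    if (config$n_qtl == 0L) {
      state <- list(qtl_indices = integer(0), qtl_ids = character(0),
                    qtl_effects = numeric(0),
                    tbv = setNames(numeric(n), rownames(geno$codes)),
                    sigma2_a = 0)
      return(structure(state, class = "true_state"))
    }
    idx <- sort(sample.int(m, config$n_qtl))
    beta <- rnorm(config$n_qtl)
    X <- geno$codes[, idx, drop = FALSE]
    X[is.na(X)] <- 0
    X <- scale(X, center = TRUE, scale = FALSE)
    g <- drop(X %*% beta)
    v <- var(g)
    if (v <= 0) stop_gsfs("QTL genotypes carry no variance; increase MAF or n")
    k <- sqrt(config$h2 / v)
    structure(
      list(qtl_indices = idx,
           qtl_ids = colnames(geno$codes)[idx],
           qtl_effects = beta * k,
           tbv = setNames(g * k, rownames(geno$codes)),
           sigma2_a = config$h2),
      class = "true_state"
    )
  })
}

#' Simulate de-regressed proofs from true breeding values
#'
#' A DRP is the true breeding value plus noise whose variance reflects the
#' proof's reliability: `var(DRP_j - tbv_j) = sigma2_a (1 - r2_j) / r2_j`,
#' the classical de-regression noise model, so that `cor(DRP, tbv)` tends to
#' `sqrt(r2)`. Birth years are drawn uniformly from `birth_year_range`.
#'
#' @param state A `true_state` from [simulate_true_effects()].
#' @param reliabilities Per-individual reliabilities in (0, 1]; scalar values
#'   are recycled.
#' @param birth_year_range Length-2 integer interval to draw birth years from.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `drp`, `reliability`, `birth_year`.
#' @export
simulate_drp <- function(state, reliabilities,
                         birth_year_range = c(2008L, 2015L),
                         seed = 1L) {
  stopifnot(inherits(state, "true_state"))
  n <- length(state$tbv)
  r2 <- rep_len(as.numeric(reliabilities), n)
  if (any(!is.finite(r2)) || any(r2 <= 0) || any(r2 > 1)) {
    stop_gsfs("reliabilities must lie in (0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    noise_sd <- sqrt(state$sigma2_a * (1 - r2) / r2)
    drp <- state$tbv + rnorm(n, 0, noise_sd)
    years <- sample(seq(birth_year_range[1], birth_year_range[2]), n, replace = TRUE)
    tibble(id = names(state$tbv), drp = as.numeric(drp),
           reliability = r2, birth_year = as.integer(years))
  })
}

#' Simulate a complete population: genotypes, trait architecture and DRPs
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_true_effects()] and [simulate_drp()] with seeds derived from the
#' configuration seed, the one-call entry point for scenario runs and tests.
#'
#' @param config A [sim_config()].
#' @return List with elements `geno` (`geno_matrix`), `truth` (`true_state`)
#'   and `pheno` (DRP tibble).
#' @export
simulate_population <- function(config) {
  geno <- simulate_genotypes(config)
  truth <- simulate_true_effects(geno, config)
  r2 <- withr::with_seed(config$seed + 2L, {
    runif(config$n_individuals, config$reliability_range[1], config$reliability_range[2])
  })
  pheno <- simulate_drp(truth, r2, config$birth_year_range, seed = config$seed + 3L)
  list(geno = geno, truth = truth, pheno = pheno)
}
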