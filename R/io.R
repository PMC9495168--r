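#' Write and read genotypes as a tab-delimited additive matrix
#'
#' The layout is individuals x SNPs with codes 0/1/2 (`NA` for missing),
#' preceded by three header rows carrying the SNP map (id, chromosome,
#' position); the first column holds individual ids.
#'
#' @param geno A `geno_matrix`.
#' @param path Output file.
#' @export
write_genotypes_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", geno$map$snp_id), collapse = "\t"), con)
  writeLines(paste(c("chr", geno$map$chr), collapse = "\t"), con)
  writeLines(paste(c("pos", geno$map$pos), collapse = "\t"), con)
  utils::write.table(geno$codes, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @return `read_genotypes_tsv()` returns a `geno_matrix`.
#' @export
read_genotypes_tsv <- function(path) {
  hdr <- readLines(path, n = 3L)
  parts <- strsplit(hdr, "\t", fixed = TRUE)
  map <- tibble(snp_id = parts[[1]][-1],
                chr = parts[[2]][-1],
                pos = as.numeric(parts[[3]][-1]))
  chr_num <- suppressWarnings(as.integer(map$chr))
  if (!anyNA(chr_num)) map$chr <- chr_num
  body <- utils::read.table(path, sep = "\t", skip = 3L, row.names = 1L,
                            na.strings = "NA")
  codes <- as.matrix(body)
  colnames(codes) <- map$snp_id
  geno_matrix(codes, map)
}

#' Write genotypes as a diploid VCF
#'
#' Encodes additive codes as unphased diploid genotypes (`0/0`, `0/1`,
#' `1/1`, `./.`) with placeholder REF/ALT alleles, via the vcfR package.
#' Note `vcfR::write.vcf` gzip-compresses its output.
#'
#' @param geno A `geno_matrix`.
#' @param path Output file (conventionally `.vcf.gz`).
#' @export
write_genotypes_vcf <- function(geno, path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_gsfs("the vcfR package is required to write VCF")
  }
  stopifnot(inherits(geno, "geno_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", ncol(geno$codes), nrow(geno$codes))
  ok <- !is.na(t(geno$codes))
  gt[ok] <- gt_code[t(geno$codes)[ok] + 1L]
  gt <- cbind(FORMAT = "GT", gt)
  colnames(gt) <- c("FORMAT", rownames(geno$codes))
  fix <- cbind(CHROM = as.character(geno$map$chr),
               POS = as.character(geno$map$pos),
               ID = geno$map$snp_id,
               REF = "A", ALT = "B", QUAL = ".", FILTER = "PASS", INFO = ".")
  vcf <- methods::new("vcfR",
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read additive genotype codes from a VCF
#'
#' Parses diploid GT fields with vcfR and counts alternate-allele copies to
#' additive 0/1/2 codes (missing genotypes become `NA`).
#'
#' @param path VCF file (optionally gzipped).
#' @return A `geno_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_gsfs("the vcfR package is required to read VCF")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  g <- gsub("|", "/", gt, fixed = TRUE)   # biallelic, single-digit alleles
  codes <- (substr(g, 1L, 1L) == "1") + (substr(g, 3L, 3L) == "1")
  codes[is.na(g) | substr(g, 1L, 1L) == "."] <- NA_real_
  codes <- t(matrix(as.numeric(codes), nrow(gt), ncol(gt),
                    dimnames = dimnames(gt)))
  chrs <- vcfR::getCHROM(vcf)
  chr_num <- suppressWarnings(as.integer(chrs))
  map <- tibble(snp_id = rownames(gt),
                chr = if (!anyNA(chr_num)) chr_num else chrs,
                pos = vcfR::getPOS(vcf))
  geno_matrix(codes, map)
}

#' Write a phenotype table as TSV
#'
#' @param pheno Tibble with `id`, `drp`, `reliability`, `birth_year`.
#' @param path Output file.
#' @export
write_phenotypes_tsv <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
}

#' Write a genomic relationship matrix as labeled square TSV
#'
#' @param grm A `grm` object.
#' @param path Output file.
#' @export
write_grm_tsv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  utils::write.table(grm$matrix, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
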