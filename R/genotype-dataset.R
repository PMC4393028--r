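#' Construct a genotype dataset
#'
#' The central container for SNP-array genotypes: a samples-by-SNPs matrix of
#' minor-allele counts plus a variant map. Genotypes are coded 0/1/2 as the
#' count of `allele2` (oriented to the minor allele on import) and `NA` for
#' missing calls; missing is never conflated with the homozygous-reference
#' code 0.
#'
#' @param geno Integer matrix, samples x SNPs, values in `c(0L, 1L, 2L, NA)`.
#' @param map Variant map: a data frame with columns `snp_id`, `chrom`
#'   (character label; autosomes are positive integer labels, sex chromosomes
#'   are labels such as `"X"`), `bp` (1-based physical position) and
#'   `allele1`, `allele2` (allele labels; `allele2` is the counted allele).
#' @param sample_ids Character vector, one id per matrix row.
#'
#' @details Positions must be strictly increasing within each chromosome and
#' `(chrom, bp)` pairs unique. Intervals derived from the map are 1-based and
#' closed; the length of an interval is `end_bp - start_bp`.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(geno, map, sample_ids) {
  map <- tibble::as_tibble(map)
  stopifnot(is.matrix(geno))
  storage.mode(geno) <- "integer"
  needed <- c("snp_id", "chrom", "bp", "allele1", "allele2")
  if (!all(needed %in% names(map))) {
    stop("variant map must have columns: ", paste(needed, collapse = ", "))
  }
  map$chrom <- as.character(map$chrom)
  map$bp <- as.integer(map$bp)
  if (nrow(map) != ncol(geno)) {
    stop("map has ", nrow(map), " variants but genotype matrix has ",
         ncol(geno), " columns")
  }
  if (length(sample_ids) != nrow(geno)) {
    stop("sample_ids length does not match genotype matrix rows")
  }
  bad <- setdiff(unique(as.vector(geno)), c(0L, 1L, 2L, NA))
  if (length(bad) > 0) {
    stop("genotype codes outside {0,1,2,NA}: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(map[c("chrom", "bp")])) {
    stop("duplicate (chrom, bp) positions in variant map")
  }
  inc <- unlist(lapply(split(map$bp, factor(map$chrom, unique(map$chrom))),
                       function(x) diff(x) > 0))
  if (length(inc) && !all(inc)) {
    stop("bp must be strictly increasing within each chromosome")
  }
  dimnames(geno) <- list(sample_ids, map$snp_id)
  structure(list(sample_ids = as.character(sample_ids),
                 map = map, geno = geno),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", n_samples(x), " samples x ", n_snps(x),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat("  missing calls: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' Number of samples / SNPs in a dataset
#' @param ds A `genotype_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) length(ds$sample_ids)

#' @rdname n_samples
#' @export
n_snps <- function(ds) nrow(ds$map)

#' Is a chromosome label autosomal?
#'
#' Autosomes are positive integer labels; `0`, `X`, `Y`, `XY` and `MT` (case
#' insensitive) are non-autosomal. Numerically coded sex chromosomes can be
#' excluded explicitly via the `sex_chroms` argument of
#' [drop_sex_chromosomes()].
#'
#' @param chrom Character vector of chromosome labels.
#' @return Logical vector.
#' @export
is_autosome <- function(chrom) {
  chrom <- as.character(chrom)
  suppressWarnings(num <- as.integer(chrom))
  !is.na(num) & num > 0 & !(toupper(chrom) %in% c("X", "Y", "XY", "MT"))
}

keep_snps <- function(ds, idx) {
  genotype_dataset(ds$geno[, idx, drop = FALSE], ds$map[idx, , drop = FALSE],
                   ds$sample_ids)
}

#' Per-SNP allele-2 frequency in the sample
#'
#' @param ds A `genotype_dataset`.
#' @return Numeric vector of length `n_snps(ds)`; `NaN` for SNPs with no
#'   calls.
#' @export
allele2_freq <- function(ds) {
  colMeans(ds$geno, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#' @param ds A `genotype_dataset`.
#' @return Numeric vector in `[0, 0.5]`.
#' @export
snp_maf <- function(ds) {
  p <- allele2_freq(ds)
  pmin(p, 1 - p)
}

#' Total autosome length covered by SNPs
#'
#' Sum over chromosomes of the distance between the first and last mapped SNP
#' (closed-interval convention: `last_bp - first_bp`). This is the default
#' denominator of [froh()].
#'
#' @param ds A `genotype_dataset`.
#' @return Length in bp.
#' @export
snp_covered_length <- function(ds) {
  ds$map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$bp) - min(.data$bp), .groups = "drop") |>
    dplyr::pull(.data$len) |>
    sum()
}
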