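# Per-SNP quality filters. The call-rate rule is strict (fraction of
# non-missing calls must exceed `min_rate`), matching "genotyping rate >0.90".

#' Filter SNPs on genotyping call rate
#'
#' Keeps SNPs whose fraction of non-missing genotypes across samples is
#' strictly greater than `min_rate` (fully called SNPs always pass); SNP
#' order is preserved.
#'
#' @param ds A `genotype_dataset`.
#' @param min_rate Minimum genotyping rate in `[0, 1]`.
#' @return Filtered `genotype_dataset`.
#' @export
filter_call_rate <- function(ds, min_rate = 0.9) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  rate <- colMeans(!is.na(ds$geno))
  keep_snps(ds, which(rate > min_rate | rate >= 1 |
                        (min_rate == 0 & rate == 0)))
}

#' Drop sex-chromosome SNPs
#'
#' Removes SNPs on non-autosomal chromosomes (see [is_autosome()]); the
#' sample set is unchanged.
#'
#' @param ds A `genotype_dataset`.
#' @param sex_chroms Optional extra chromosome labels to treat as sex
#'   chromosomes (for species that code them numerically, e.g. `"39"` in
#'   dog-coded PLINK files).
#' @return Filtered `genotype_dataset`.
#' @export
drop_sex_chromosomes <- function(ds, sex_chroms = character()) {
  keep <- is_autosome(ds$map$chrom) & !(ds$map$chrom %in% as.character(sex_chroms))
  keep_snps(ds, which(keep))
}

#' Filter SNPs on minor allele frequency
#'
#' Removes SNPs with MAF strictly below `min_maf`. Frequencies come either
#' from the dataset itself or from an external per-SNP table (standing in for
#' an across-breed reference panel).
#'
#' @param ds A `genotype_dataset`.
#' @param min_maf MAF threshold; SNPs with `maf < min_maf` are dropped.
#' @param freq_source `"sample"` (default) to use the dataset's own allele
#'   frequencies, or a data frame with columns `snp_id` and `maf`.
#' @return Filtered `genotype_dataset`.
#' @export
filter_maf <- function(ds, min_maf = 0.01, freq_source = "sample") {
  if (is.character(freq_source) && identical(freq_source, "sample")) {
    maf <- snp_maf(ds)
  } else {
    tab <- tibble::as_tibble(freq_source)
    stopifnot(all(c("snp_id", "maf") %in% names(tab)))
    idx <- match(ds$map$snp_id, tab$snp_id)
    if (anyNA(idx)) {
      stop("frequency table is missing SNPs: ",
           paste(utils::head(ds$map$snp_id[is.na(idx)], 10), collapse = ", "))
    }
    maf <- tab$maf[idx]
  }
  keep_snps(ds, which(!(maf < min_maf) | is.na(maf) & min_maf <= 0))
}

# Per-SNP expected probability of a homozygous genotype under random mating,
# with the unbiased small-sample correction 2pq * 2N/(2N-1); shared by
# summarize_diversity() and fis().
expected_hom_by_snp <- function(ds, small_sample_correction = TRUE) {
  called <- !is.na(ds$geno)
  nj <- colSums(called)
  p <- allele2_freq(ds)
  q <- 1 - p
  corr <- if (small_sample_correction) {
    ifelse(nj > 0, (2 * nj) / pmax(2 * nj - 1, 1), NA_real_)
  } else rep(1, length(nj))
  e <- 1 - 2 * p * q * corr
  e[nj < 2] <- NA_real_
  list(e = e, nj = nj, called = called)
}

#' Summarize SNP diversity
#'
#' Sample-wide summary of allele-frequency spectrum and homozygosity: mean
#' minor allele frequency, the fraction of informative (polymorphic in
#' sample) SNPs, mean observed and expected homozygous SNP counts per
#' individual, and the mean per-individual fixation index F_IS.
#'
#' @param ds A `genotype_dataset` with at least 2 samples.
#' @param small_sample_correction Use the `2N/(2N-1)` correction on expected
#'   heterozygosity (default `TRUE`).
#' @return One-row tibble with columns `n_samples`, `n_snps`, `mean_maf`,
#'   `prop_informative`, `mean_obs_hom`, `mean_exp_hom`, `mean_fis`.
#' @export
summarize_diversity <- function(ds, small_sample_correction = TRUE) {
  stopifnot(n_samples(ds) >= 2)
  maf <- snp_maf(ds)
  rec <- fis(ds, small_sample_correction = small_sample_correction)
  tibble::tibble(
    n_samples = n_samples(ds),
    n_snps = n_snps(ds),
    mean_maf = mean(maf, na.rm = TRUE),
    prop_informative = mean(maf > 0, na.rm = TRUE),
    mean_obs_hom = mean(rec$obs_hom),
    mean_exp_hom = mean(rec$exp_hom),
    mean_fis = mean(rec$f_is)
  )
}

#' Per-individual fixation index F_IS
#'
#' For individual *i*, `F_IS = (O_i - E_i) / (n_i - E_i)` where `O_i` is the
#' observed number of homozygous SNPs among the `n_i` SNPs genotyped in *i*,
#' and `E_i` is the expected homozygous count under random mating given the
#' sample allele frequencies, `E_i = sum_j (1 - 2 p_j q_j * 2N_j/(2N_j-1))`
#' over those SNPs (`N_j` = samples called at SNP *j*). SNPs called in fewer
#' than 2 samples are excluded from both counts.
#'
#' @param ds A `genotype_dataset` with at least 2 samples.
#' @param small_sample_correction Apply the `2N/(2N-1)` factor (default
#'   `TRUE`); set `FALSE` for the uncorrected `1 - 2pq` expectation.
#' @return Tibble with columns `sample_id`, `n_genotyped`, `obs_hom`,
#'   `exp_hom`, `f_is`.
#' @export
fis <- function(ds, small_sample_correction = TRUE) {
  stopifnot(n_samples(ds) >= 2)
  eh <- expected_hom_by_snp(ds, small_sample_correction)
  usable <- !is.na(eh$e)
  called <- eh$called[, usable, drop = FALSE]
  g <- ds$geno[, usable, drop = FALSE]
  hom <- (!is.na(g)) & (g == 0L | g == 2L)
  obs <- unname(rowSums(hom))
  expc <- as.vector(called %*% ifelse(is.na(eh$e[usable]), 0, eh$e[usable]))
  n_gt <- unname(rowSums(called))
  tibble::tibble(
    sample_id = ds$sample_ids,
    n_genotyped = n_gt,
    obs_hom = obs,
    exp_hom = expc,
    f_is = (obs - expc) / (n_gt - expc)
  )
}
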