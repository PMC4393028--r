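#' Construct a phased haplotype set
#'
#' Phased 0/1 haplotypes aligned to a variant map: two rows per sample
#' (maternal/paternal), columns in variant-map order. The long-range
#' haplotype scan requires fully called phased input, so missing alleles are
#' rejected here.
#'
#' @param haps Integer matrix of 0/1 alleles, `2 * n_samples` rows.
#' @param map Variant map as in [genotype_dataset()].
#' @param sample_ids Character vector of sample ids (one per diploid).
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(haps, map, sample_ids) {
  stopifnot(is.matrix(haps))
  storage.mode(haps) <- "integer"
  map <- tibble::as_tibble(map)
  map$chrom <- as.character(map$chrom)
  if (nrow(haps) != 2 * length(sample_ids)) {
    stop("haplotype matrix must have 2 rows per sample")
  }
  if (ncol(haps) != nrow(map)) {
    stop("haplotype matrix columns must match variant map rows")
  }
  if (anyNA(haps) || !all(haps %in% c(0L, 1L))) {
    stop("phased haplotypes must be fully called 0/1 alleles")
  }
  rownames(haps) <- paste0(rep(sample_ids, each = 2), c("_1", "_2"))
  structure(list(sample_ids = as.character(sample_ids), map = map,
                 haps = haps),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", length(x$sample_ids), " samples (",
      nrow(x$haps), " haplotypes) x ", nrow(x$map), " SNPs\n", sep = "")
  invisible(x)
}

#' Collapse phased haplotypes to genotype codes
#'
#' Sums the two haplotypes of each sample; by construction the result equals
#' the 0/1/2 genotype codes of the matching [genotype_dataset()].
#'
#' @param hs A `haplotype_set`.
#' @return A `genotype_dataset`.
#' @export
haps_to_genotypes <- function(hs) {
  n <- length(hs$sample_ids)
  g <- hs$haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    hs$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  map <- hs$map
  if (!all(c("allele1", "allele2") %in% names(map))) {
    map$allele1 <- "A"
    map$allele2 <- "B"
  }
  genotype_dataset(g, map, hs$sample_ids)
}

#' Read / write a phased haplotype table
#'
#' Plain TSV with columns `hap_id` then one column per SNP (named by
#' `snp_id`), two rows per sample with suffixes `_1`/`_2`; the variant map
#' travels in a sidecar `<path>.map.tsv`.
#'
#' @param hs A `haplotype_set`.
#' @param path Output TSV path.
#' @return `path` (write) or a `haplotype_set` (read).
#' @export
write_haplotypes_tsv <- function(hs, path) {
  tab <- tibble::as_tibble(hs$haps, .name_repair = "minimal")
  names(tab) <- hs$map$snp_id
  tab <- dplyr::bind_cols(tibble::tibble(hap_id = rownames(hs$haps)), tab)
  readr::write_tsv(tab, path)
  readr::write_tsv(hs$map, paste0(path, ".map.tsv"))
  invisible(path)
}

#' @rdname write_haplotypes_tsv
#' @export
read_haplotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  map <- readr::read_tsv(paste0(path, ".map.tsv"), show_col_types = FALSE)
  ids <- unique(sub("_[12]$", "", tab$hap_id))
  haps <- as.matrix(tab[-1])
  haplotype_set(haps, map, ids)
}
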