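#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genotype dataset into a per-SNP summary
#'
#' @param x A `genotype_dataset`.
#' @param ... Unused.
#' @return Tibble with one row per SNP: the variant map plus `call_rate`,
#'   `freq_allele2` and `maf`.
#' @method tidy genotype_dataset
#' @export
tidy.genotype_dataset <- function(x, ...) {
  x$map |>
    dplyr::mutate(call_rate = colMeans(!is.na(x$geno)),
                  freq_allele2 = allele2_freq(x),
                  maf = snp_maf(x))
}

#' @rdname tidy.genotype_dataset
#' @return `glance()`: one-row tibble with `n_samples`, `n_snps`,
#'   `n_chrom`, `missing_rate`, `mean_maf`.
#' @method glance genotype_dataset
#' @export
glance.genotype_dataset <- function(x, ...) {
  tibble::tibble(n_samples = n_samples(x), n_snps = n_snps(x),
                 n_chrom = length(unique(x$map$chrom)),
                 missing_rate = mean(is.na(x$geno)),
                 mean_maf = mean(snp_maf(x), na.rm = TRUE))
}

#' Tidy a Wright-Fisher simulation
#'
#' @param x A `wf_sim` from [simulate_wf()].
#' @param ... Unused.
#' @return Tibble per generation: `generation`, `ne` (true size) and the
#'   realised mean expected heterozygosity.
#' @method tidy wf_sim
#' @export
tidy.wf_sim <- function(x, ...) {
  tibble::tibble(generation = x$het_trajectory$generation,
                 ne = c(x$true_ne[1], x$true_ne),
                 exp_het = x$het_trajectory$exp_het)
}

#' @rdname tidy.wf_sim
#' @return `glance()`: one-row tibble summarising the simulated sample.
#' @method glance wf_sim
#' @export
glance.wf_sim <- function(x, ...) {
  tibble::tibble(n_sampled = length(x$haplotypes$sample_ids),
                 n_snps = nrow(x$haplotypes$map),
                 n_generations = length(x$true_ne),
                 final_exp_het = utils::tail(x$het_trajectory$exp_het, 1),
                 has_sweep = !is.null(x$selected_site))
}

#' Tidy a pedigree
#'
#' @param x A [pedigree()].
#' @param max_depth Truncation depth for the reported coefficients
#'   (default `Inf`... capped at 12 for completeness).
#' @param ... Unused.
#' @return Tibble per individual: `id`, `sire`, `dam`, `f_ped`,
#'   `completeness`.
#' @method tidy pedigree
#' @export
tidy.pedigree <- function(x, max_depth = Inf, ...) {
  dep <- if (is.finite(max_depth)) max_depth else 12L
  tibble::tibble(id = x$id, sire = x$sire, dam = x$dam,
                 f_ped = f_ped(x, x$id, max_depth),
                 completeness = completeness(x, x$id, dep))
}

#' @rdname tidy.pedigree
#' @method glance pedigree
#' @export
glance.pedigree <- function(x, ...) {
  tibble::tibble(n_individuals = nrow(x),
                 n_founders = sum(is.na(x$sire) & is.na(x$dam)),
                 prop_sire_known = mean(!is.na(x$sire)),
                 prop_dam_known = mean(!is.na(x$dam)))
}
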