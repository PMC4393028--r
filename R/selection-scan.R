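# Long-range haplotype test: extended haplotype homozygosity (EHH) of core
# haplotypes, the recombination-rate-corrected relative EHH (REHH), and
# frequency-binned log-normal significance scores.

#' Tile chromosomes into core regions
#'
#' Fixed-size, non-overlapping windows of `core_snps` consecutive SNPs per
#' chromosome (a trailing remainder shorter than `core_snps` is dropped).
#' Each distinct allele string over a window's SNPs is a core haplotype.
#'
#' @param haps A `haplotype_set` (phased, fully called).
#' @param core_snps SNPs per core (default 10).
#' @param step_snps Step between core starts (default `core_snps`:
#'   non-overlapping tiling).
#' @return Tibble with columns `core_id`, `chrom`, `snp_lo`, `snp_hi`
#'   (column indices into the haplotype matrix, inclusive), `start_bp`,
#'   `end_bp`, `n_haplotypes`.
#' @export
define_cores <- function(haps, core_snps = 10L, step_snps = core_snps) {
  stopifnot(core_snps >= 1, step_snps >= 1)
  map <- haps$map
  out <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    m <- length(idx)
    if (m < core_snps) return(NULL)
    starts <- seq(1L, m - core_snps + 1L, by = step_snps)
    tibble::tibble(chrom = ch,
                   snp_lo = idx[starts],
                   snp_hi = idx[starts + core_snps - 1L])
  })
  out <- dplyr::bind_rows(out)
  out |>
    dplyr::mutate(core_id = dplyr::row_number(),
                  start_bp = map$bp[.data$snp_lo],
                  end_bp = map$bp[.data$snp_hi],
                  n_haplotypes = vapply(seq_len(dplyr::n()), function(i) {
                    length(unique(hap_strings(haps, out$snp_lo[i],
                                              out$snp_hi[i])))
                  }, integer(1))) |>
    dplyr::select("core_id", "chrom", "snp_lo", "snp_hi", "start_bp",
                  "end_bp", "n_haplotypes")
}

# allele strings of all chromosomes over columns [lo, hi]
hap_strings <- function(haps, lo, hi) {
  sub <- haps$haps[, lo:hi, drop = FALSE]
  apply(sub, 1, paste0, collapse = "")
}

#' Core haplotypes and their carrier counts
#'
#' @param haps A `haplotype_set`.
#' @param core One row of [define_cores()] output (or a list with `snp_lo`,
#'   `snp_hi`).
#' @return Tibble with columns `haplotype`, `n_carriers`, `frequency`,
#'   sorted by decreasing frequency.
#' @export
core_haplotypes <- function(haps, core) {
  s <- hap_strings(haps, core$snp_lo, core$snp_hi)
  tab <- sort(table(s), decreasing = TRUE)
  tibble::tibble(haplotype = names(tab),
                 n_carriers = as.integer(tab),
                 frequency = as.integer(tab) / length(s))
}

#' Extended haplotype homozygosity
#'
#' Among the chromosomes carrying `haplotype` at the core, EHH at a given
#' physical distance and direction is the fraction of carrier pairs that
#' are identical at every SNP from the core edge out to the last SNP within
#' `distance_bp`: `sum_groups C(n_g, 2) / C(n_h, 2)`. At distance 0 EHH is
#' 1; a single-carrier haplotype has undefined pair homozygosity, reported
#' as 0 with `n_carriers = 1` as the flag.
#'
#' @param haps A `haplotype_set`.
#' @param core A row of [define_cores()] output.
#' @param haplotype Core allele string.
#' @param distance_bp Test distance from the core edge, bp.
#' @param direction `"up"` (increasing bp) or `"down"`.
#' @return EHH in `[0, 1]`.
#' @export
ehh <- function(haps, core, haplotype, distance_bp, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(distance_bp >= 0)
  s <- hap_strings(haps, core$snp_lo, core$snp_hi)
  carriers <- which(s == haplotype)
  n_h <- length(carriers)
  if (n_h == 0) stop("haplotype not present at this core")
  if (n_h == 1) return(0)
  map <- haps$map
  chrom_idx <- which(map$chrom == core$chrom)
  if (direction == "up") {
    lim <- map$bp[core$snp_hi] + distance_bp
    ext <- chrom_idx[chrom_idx > core$snp_hi & map$bp[chrom_idx] <= lim]
  } else {
    lim <- map$bp[core$snp_lo] - distance_bp
    ext <- chrom_idx[chrom_idx < core$snp_lo & map$bp[chrom_idx] >= lim]
  }
  if (length(ext) == 0) return(1)
  sub <- haps$haps[carriers, ext, drop = FALSE]
  grp <- table(apply(sub, 1, paste0, collapse = ""))
  sum(choose(as.integer(grp), 2)) / choose(n_h, 2)
}

#' Relative extended haplotype homozygosity
#'
#' EHH of the tested core haplotype divided by the pair-count-weighted mean
#' EHH of all other haplotypes at the same core:
#' `REHH = EHH(h) / (sum_{h' != h} C(n_h', 2) EHH(h') / sum_{h' != h}
#' C(n_h', 2))`. This normalises out local recombination-rate variation.
#' Undefined (`NA`) when the others contribute no pairs or decay to 0.
#'
#' @inheritParams ehh
#' @return REHH (positive), or `NA` when undefined.
#' @export
rehh_stat <- function(haps, core, haplotype, distance_bp,
                      direction = c("up", "down")) {
  direction <- match.arg(direction)
  ch <- core_haplotypes(haps, core)
  others <- ch[ch$haplotype != haplotype, , drop = FALSE]
  w <- choose(others$n_carriers, 2)
  if (nrow(others) == 0 || sum(w) == 0) return(NA_real_)
  e_others <- vapply(others$haplotype, function(h) {
    ehh(haps, core, h, distance_bp, direction)
  }, numeric(1))
  ebar <- sum(w * e_others) / sum(w)
  if (ebar == 0) return(NA_real_)
  ehh(haps, core, haplotype, distance_bp, direction) / ebar
}

#' Score every core haplotype with EHH and REHH
#'
#' Runs [ehh()] and [rehh_stat()] in both directions for every haplotype of
#' every core at a fixed test distance. The reported `rehh` is the larger of
#' the two directions.
#'
#' @param haps A `haplotype_set`.
#' @param cores Tibble from [define_cores()].
#' @param distance_bp Test distance per direction (default 1 Mb).
#' @param min_carriers Haplotypes with fewer carriers are skipped
#'   (default 2; single carriers have no pair homozygosity).
#' @return Tibble with one row per (core, haplotype): `core_id`, `chrom`,
#'   `start_bp`, `end_bp`, `haplotype`, `n_carriers`, `frequency`,
#'   `ehh_up`, `ehh_down`, `rehh_up`, `rehh_down`, `rehh`.
#' @export
scan_ehh <- function(haps, cores, distance_bp = 1e6, min_carriers = 2L) {
  res <- lapply(seq_len(nrow(cores)), function(i) {
    core <- cores[i, ]
    ch <- core_haplotypes(haps, core)
    ch <- ch[ch$n_carriers >= min_carriers, , drop = FALSE]
    if (nrow(ch) == 0) return(NULL)
    # EHH of every haplotype in both directions, then weighted means
    e_up <- vapply(ch$haplotype, ehh, numeric(1), haps = haps, core = core,
                   distance_bp = distance_bp, direction = "up")
    e_dn <- vapply(ch$haplotype, ehh, numeric(1), haps = haps, core = core,
                   distance_bp = distance_bp, direction = "down")
    all_h <- core_haplotypes(haps, core)
    w_all <- choose(all_h$n_carriers, 2)
    e_all_up <- vapply(all_h$haplotype, function(h) {
      if (h %in% ch$haplotype) e_up[[h]]
      else ehh(haps, core, h, distance_bp, "up")
    }, numeric(1))
    e_all_dn <- vapply(all_h$haplotype, function(h) {
      if (h %in% ch$haplotype) e_dn[[h]]
      else ehh(haps, core, h, distance_bp, "down")
    }, numeric(1))
    rehh_dir <- function(e_self, e_all, h) {
      oth <- all_h$haplotype != h
      wsum <- sum(w_all[oth])
      if (wsum == 0) return(NA_real_)
      ebar <- sum(w_all[oth] * e_all[oth]) / wsum
      if (ebar == 0) return(NA_real_)
      e_self / ebar
    }
    r_up <- vapply(seq_len(nrow(ch)), function(k) {
      rehh_dir(e_up[[k]], e_all_up, ch$haplotype[k])
    }, numeric(1))
    r_dn <- vapply(seq_len(nrow(ch)), function(k) {
      rehh_dir(e_dn[[k]], e_all_dn, ch$haplotype[k])
    }, numeric(1))
    tibble::tibble(core_id = core$core_id, chrom = core$chrom,
                   start_bp = core$start_bp, end_bp = core$end_bp,
                   haplotype = ch$haplotype, n_carriers = ch$n_carriers,
                   frequency = ch$frequency,
                   ehh_up = unname(e_up), ehh_down = unname(e_dn),
                   rehh_up = r_up, rehh_down = r_dn,
                   rehh = pmax(r_up, r_dn))
  })
  dplyr::bind_rows(res)
}

#' Frequency-binned REHH significance scores
#'
#' Groups scored haplotypes into `n_bins` equal-width frequency bins over
#' (0, 1]; within each bin the log-transformed REHH values are standardised
#' (`z = (ln REHH - mean) / sd` over bin members) and converted to
#' one-sided upper-tail normal P-values, reported as `-log10 P`. Members of
#' bins with fewer than 2 defined REHH values or zero spread are flagged
#' `scored = FALSE`. Haplotypes below frequency 0.1 keep their scores but
#' are flagged `low_freq`, since the test has little power for rare
#' haplotypes.
#'
#' @param results Tibble from [scan_ehh()].
#' @param n_bins Number of frequency bins (default 20).
#' @return `results` with added columns `bin_id` (1-based), `z`,
#'   `neg_log10_p`, `scored`, `low_freq`.
#' @export
score_rehh <- function(results, n_bins = 20L) {
  results |>
    dplyr::mutate(bin_id = pmin(ceiling(.data$frequency * n_bins),
                                n_bins)) |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::mutate(
      ln_rehh = log(.data$rehh),
      n_defined = sum(is.finite(.data$ln_rehh)),
      bin_mean = mean(.data$ln_rehh[is.finite(.data$ln_rehh)]),
      bin_sd = stats::sd(.data$ln_rehh[is.finite(.data$ln_rehh)]),
      scored = is.finite(.data$ln_rehh) & .data$n_defined >= 2 &
        !is.na(.data$bin_sd) & .data$bin_sd > 0,
      z = dplyr::if_else(.data$scored,
                         (.data$ln_rehh - .data$bin_mean) / .data$bin_sd,
                         NA_real_),
      neg_log10_p = dplyr::if_else(
        .data$scored,
        -stats::pnorm(.data$z, lower.tail = FALSE, log.p = TRUE) / log(10),
        NA_real_),
      low_freq = .data$frequency < 0.1
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"ln_rehh", -"n_defined", -"bin_mean", -"bin_sd")
}

#' Candidate selected regions
#'
#' Filters scored core haplotypes to those with core-haplotype frequency at
#' least `min_freq` and `-log10 P` above `min_score`.
#'
#' @param results Tibble from [score_rehh()].
#' @param min_freq Minimum core-haplotype frequency (default 0.50).
#' @param min_score Significance threshold on `-log10 P` (default 3,
#'   roughly the top 5% of haplotypes under strong LD).
#' @return Tibble with columns `chrom`, `start_bp`, `end_bp`, `frequency`,
#'   `neg_log10_p` (plus `core_id`, `haplotype`).
#' @export
significant_regions <- function(results, min_freq = 0.5, min_score = 3) {
  results |>
    dplyr::filter(.data$scored, .data$frequency >= min_freq,
                  .data$neg_log10_p > min_score) |>
    dplyr::select("core_id", "chrom", "start_bp", "end_bp", "haplotype",
                  "frequency", "neg_log10_p")
}

#' Export candidate regions as BED with flanks
#'
#' Extends each region by `flank_bp` on both sides (clipped at position 1
#' and at the chromosome end when lengths are supplied) and writes BED
#' (0-based half-open). Overlapping extended regions are deliberately not
#' merged: adjacent cores may represent one sweep but are reported
#' separately.
#'
#' @param table Tibble from [significant_regions()].
#' @param path Output BED path.
#' @param flank_bp Flank added to each side (default 0.5 Mb).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-clipping.
#' @return The extended tibble, invisibly; the BED file is written to
#'   `path`.
#' @export
export_regions_bed <- function(table, path, flank_bp = 5e5,
                               chrom_lengths = NULL) {
  stopifnot(flank_bp >= 0)
  ext <- table |>
    dplyr::mutate(start_bp = pmax(1, .data$start_bp - flank_bp),
                  end_bp = .data$end_bp + flank_bp)
  if (!is.null(chrom_lengths)) {
    ext <- dplyr::mutate(
      ext, end_bp = pmin(.data$end_bp,
                         unname(chrom_lengths[as.character(.data$chrom)])))
  }
  bed <- tibble::tibble(chrom = ext$chrom, start = ext$start_bp - 1,
                        end = ext$end_bp,
                        name = sprintf("core%s_f%.2f", ext$core_id,
                                       ext$frequency),
                        score = round(ext$neg_log10_p, 3))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(ext)
}
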