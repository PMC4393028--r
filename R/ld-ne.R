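# Linkage-disequilibrium decay and the LD-based effective-population-size
# trajectory. The physical-to-genetic scale defaults to 1e-8 Morgan/bp
# (100 Mb = 1 Morgan); distance c Morgan probes ancestry about g = 1/(2c)
# generations back, and the Sved equilibrium relation r2 = 1/(1 + 4 Ne c) is
# inverted to Ne = (1 - r2) / (4 c r2), with dF = 1/(2 Ne) per generation.

#' Pairwise r-squared between SNPs
#'
#' Computes within-chromosome r-squared for all SNP pairs with physical
#' distance in `[min_dist_bp, max_dist_bp]`. Given phased haplotypes, r2 is
#' the haplotype-frequency measure `D^2 / (p1 q1 p2 q2)`, identical to the
#' squared Pearson correlation of the 0/1 haplotype indicators; given
#' genotypes it is the squared complete-case Pearson correlation of genotype
#' codes (composite LD). Monomorphic SNPs are excluded; pairs with fewer
#' than two jointly called samples are skipped.
#'
#' @param x A `genotype_dataset` or `haplotype_set`.
#' @param min_dist_bp,max_dist_bp Distance window in bp (default 1 kb -
#'   50 Mb).
#' @return Tibble with columns `chrom`, `snp_a`, `snp_b`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(x, min_dist_bp = 1e3, max_dist_bp = 50e6) {
  if (inherits(x, "haplotype_set")) {
    mat <- x$haps
    map <- x$map
    pairwise <- FALSE
  } else {
    mat <- x$geno
    map <- x$map
    pairwise <- TRUE
  }
  out <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) return(NULL)
    sub <- mat[, idx, drop = FALSE]
    v <- apply(sub, 2, stats::var, na.rm = TRUE)
    poly <- !is.na(v) & v > 0
    idx <- idx[poly]
    if (length(idx) < 2) return(NULL)
    sub <- mat[, idx, drop = FALSE]
    cc <- if (pairwise) {
      suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    } else {
      stats::cor(sub)
    }
    bp <- map$bp[idx]
    ut <- which(upper.tri(cc), arr.ind = TRUE)
    d <- bp[ut[, 2]] - bp[ut[, 1]]
    keep <- d >= min_dist_bp & d <= max_dist_bp & !is.na(cc[ut])
    if (!any(keep)) return(NULL)
    tibble::tibble(chrom = ch,
                   snp_a = map$snp_id[idx][ut[keep, 1]],
                   snp_b = map$snp_id[idx][ut[keep, 2]],
                   dist_bp = d[keep],
                   r2 = cc[ut][keep]^2)
  })
  dplyr::bind_rows(out)
}

#' Bin LD pairs by physical distance
#'
#' Groups SNP pairs into half-open distance bins `[k w, (k+1) w)` and
#' averages r2 per bin (unweighted over pairs); empty bins are omitted.
#'
#' @param pairs Tibble from [pairwise_r2()].
#' @param bin_width_bp Bin width in bp (default 0.1 Mb).
#' @return Tibble with columns `lo_bp`, `hi_bp`, `n_pairs`, `mean_r2`.
#' @export
bin_ld <- function(pairs, bin_width_bp = 1e5) {
  stopifnot(bin_width_bp > 0)
  pairs |>
    dplyr::mutate(bin = floor(.data$dist_bp / bin_width_bp)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2),
                     .groups = "drop") |>
    dplyr::transmute(lo_bp = .data$bin * bin_width_bp,
                     hi_bp = (.data$bin + 1) * bin_width_bp,
                     n_pairs = .data$n_pairs, mean_r2 = .data$mean_r2) |>
    dplyr::arrange(.data$lo_bp)
}

#' Effective population size from binned LD
#'
#' For each distance bin, sets the genetic distance `c` to the bin midpoint
#' scaled by `recomb_scale`, inverts the Sved relation to
#' `ne = (1 - mean_r2) / (4 c mean_r2)`, maps the bin to
#' `g = round(1 / (2 c))` generations in the past, and computes the
#' per-generation inbreeding increase `delta_f = 1 / (2 ne)`. Bins with
#' `mean_r2` of exactly 0 or 1 are flagged (`estimable = FALSE`) and carry
#' `NA` estimates.
#'
#' @param bins Tibble from [bin_ld()].
#' @param recomb_scale Morgan per bp (default `1e-8`, i.e. 100 Mb = 1
#'   Morgan).
#' @return `bins` with added columns `c_morgan`, `ne`, `g`, `delta_f`,
#'   `estimable`.
#' @export
estimate_ne <- function(bins, recomb_scale = 1e-8) {
  if (nrow(bins) == 0) stop("no LD bins to estimate from")
  bins |>
    dplyr::mutate(
      c_morgan = (.data$lo_bp + .data$hi_bp) / 2 * recomb_scale,
      estimable = .data$mean_r2 > 0 & .data$mean_r2 < 1,
      ne = dplyr::if_else(.data$estimable,
                          (1 - .data$mean_r2) / (4 * .data$c_morgan * .data$mean_r2),
                          NA_real_),
      g = as.integer(round(1 / (2 * .data$c_morgan))),
      delta_f = 1 / (2 * .data$ne)
    )
}

#' Collapse an Ne estimate to one value per generation
#'
#' Several distance bins can round to the same generation `g`; the
#' trajectory reports the pair-count-weighted mean Ne (and its `delta_f`)
#' per generation.
#'
#' @param est Tibble from [estimate_ne()].
#' @return Tibble with columns `g`, `ne`, `n_pairs`, `delta_f`, sorted by
#'   `g`.
#' @export
ne_trajectory <- function(est) {
  est |>
    dplyr::filter(.data$estimable) |>
    dplyr::group_by(g = .data$g) |>
    dplyr::summarise(ne = stats::weighted.mean(.data$ne, .data$n_pairs),
                     n_pairs = sum(.data$n_pairs),
                     .groups = "drop") |>
    dplyr::mutate(delta_f = 1 / (2 * .data$ne)) |>
    dplyr::arrange(.data$g)
}

#' Generations in the past probed by a marker distance
#'
#' `g = round(1 / (2 d s))` with `d` in bp and `s` in Morgan/bp: IBD
#' segments inherited from a common ancestor g generations back have mean
#' length 1/(2g) Morgan, so LD at genetic distance c reflects ancestry about
#' 1/(2c) generations ago. Results below 1 are clamped to 1 with a warning.
#'
#' @param dist_bp Physical distance in bp (vectorised).
#' @param recomb_scale Morgan per bp (default `1e-8`).
#' @return Integer vector of generations.
#' @export
generations_for_distance <- function(dist_bp, recomb_scale = 1e-8) {
  stopifnot(all(dist_bp > 0))
  g <- as.integer(round(1 / (2 * dist_bp * recomb_scale)))
  if (any(g < 1)) {
    warning("distance(s) beyond the one-generation horizon; clamping g to 1")
    g[g < 1] <- 1L
  }
  g
}
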