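# Run-of-homozygosity detection and genomic inbreeding coefficients.
#
# A ROH is a maximal stretch of consecutive autosomal SNPs in one individual
# with no heterozygous call, at most `max_missing` missing calls, and
# homozygous calls at both ends (missing SNPs never anchor a segment). A
# stretch is reported iff it spans at least `min_snps` SNPs and its physical
# length (last bp - first bp, closed-interval convention) is at least
# `min_length_bp`. This is an exact run-based scan, not a sliding-window
# heuristic: maximality means no valid stretch is contained in another.

#' Minimum SNP count for calling a ROH
#'
#' Derives the number of consecutive homozygous SNPs needed so that the
#' expected number of chance (non-autozygous) runs across the whole dataset
#' stays below the error rate `alpha`:
#' `l = log(alpha / (n_snp * n_ind)) / log(hom)`, rounded to the nearest
#' integer. `hom` is the mean SNP homozygosity, `n_snp` the mean number of
#' genotyped SNPs per individual and `n_ind` the number of individuals.
#'
#' @param alpha Tolerated false-positive rate, in (0, 1).
#' @param n_snp Mean genotyped SNPs per individual.
#' @param n_ind Number of individuals.
#' @param hom Mean per-SNP homozygosity, in (0, 1).
#' @return Integer SNP-count threshold.
#' @export
min_snp_threshold <- function(alpha, n_snp, n_ind, hom) {
  stopifnot(alpha > 0, alpha < 1, n_snp * n_ind >= 1, hom > 0)
  if (hom >= 1) stop("hom must be < 1: threshold undefined at hom = 1")
  as.integer(round(log(alpha / (n_snp * n_ind)) / log(hom)))
}

#' ROH calling parameters
#'
#' @param min_snps Minimum SNPs per run (the classic 50/65, or a derived
#'   value from [min_snp_threshold()]).
#' @param min_length_bp Minimum physical length in bp (default 1,000 kb).
#' @param max_missing Maximum missing calls tolerated inside a run (default
#'   5). Heterozygous calls are never tolerated.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 50L, min_length_bp = 1e6, max_missing = 5L) {
  stopifnot(min_snps >= 2, min_length_bp >= 0, max_missing >= 0)
  structure(list(min_snps = as.integer(min_snps),
                 min_length_bp = as.numeric(min_length_bp),
                 max_missing = as.integer(max_missing)),
            class = "roh_params")
}

# Maximal valid runs in one call vector (0/1/2/NA) with positions bp.
# Returns a data.frame of start/end SNP indices. Candidate endpoints are
# homozygous calls; a run [i, j] is valid iff no het inside and at most
# max_missing missing calls; maximal iff not contained in another valid run.
scan_runs <- function(calls, max_missing) {
  n <- length(calls)
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  hom <- !het & !mis
  out_s <- integer(0)
  out_e <- integer(0)
  # split at hets; enumerate maximal windows inside each het-free stretch
  bounds <- c(0L, which(het), n + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L
    hi <- bounds[b + 1L] - 1L
    if (hi < lo) next
    homs <- which(hom[lo:hi]) + lo - 1L
    if (length(homs) == 0) next
    cmis <- cumsum(mis[lo:hi])
    miss_between <- function(i, j) {
      # missing calls strictly inside [i, j] (i, j are hom anyway)
      cmis[j - lo + 1L] - cmis[i - lo + 1L]
    }
    k <- length(homs)
    jmax <- integer(k)
    j <- 1L
    for (i in seq_len(k)) {
      if (j < i) j <- i
      while (j < k && miss_between(homs[i], homs[j + 1L]) <= max_missing) {
        j <- j + 1L
      }
      jmax[i] <- j
    }
    # maximality: keep starts where the reachable end strictly advances
    keep <- c(TRUE, diff(jmax) > 0)
    out_s <- c(out_s, homs[keep])
    out_e <- c(out_e, homs[jmax[keep]])
  }
  data.frame(s = out_s, e = out_e)
}

#' Detect runs of homozygosity
#'
#' Scans every sample (or one) for maximal homozygous runs per chromosome
#' and applies the SNP-count and physical-length thresholds. Runs never span
#' chromosomes, never contain a heterozygous call, tolerate at most
#' `max_missing` missing calls, and are trimmed to homozygous SNPs at both
#' ends.
#'
#' @param ds A `genotype_dataset` (autosomes; SNPs sorted by chrom, bp).
#' @param params A [roh_params()] object.
#' @param sample_id Optional single sample to scan (default: all).
#' @return Tibble with columns `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps` (SNPs spanned, including missing), `n_missing`, `length_bp`.
#' @export
detect_roh <- function(ds, params = roh_params(), sample_id = NULL) {
  ids <- if (is.null(sample_id)) ds$sample_ids else sample_id
  stopifnot(all(ids %in% ds$sample_ids))
  chroms <- unique(ds$map$chrom)
  res <- lapply(ids, function(id) {
    row <- ds$geno[match(id, ds$sample_ids), ]
    per_chrom <- lapply(chroms, function(ch) {
      idx <- which(ds$map$chrom == ch)
      runs <- scan_runs(row[idx], params$max_missing)
      if (nrow(runs) == 0) return(NULL)
      bp <- ds$map$bp[idx]
      calls <- row[idx]
      tibble::tibble(
        sample_id = id, chrom = ch,
        start_bp = bp[runs$s], end_bp = bp[runs$e],
        n_snps = runs$e - runs$s + 1L,
        n_missing = vapply(seq_len(nrow(runs)), function(r) {
          sum(is.na(calls[runs$s[r]:runs$e[r]]))
        }, integer(1))
      )
    })
    dplyr::bind_rows(per_chrom)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start_bp = integer(), end_bp = integer(),
                          n_snps = integer(), n_missing = integer(),
                          length_bp = numeric()))
  }
  out |>
    dplyr::mutate(length_bp = as.numeric(.data$end_bp - .data$start_bp)) |>
    dplyr::filter(.data$n_snps >= params$min_snps,
                  .data$length_bp >= params$min_length_bp)
}

#' Consensus ROHs across all samples
#'
#' Intersects ROH coverage over every sample on SNP support: a SNP is
#' covered for a sample if it lies inside one of that sample's segments, and
#' consensus ROHs are the maximal runs of SNPs covered in all samples. No
#' minimum length is applied; endpoints are SNP positions.
#'
#' @param segments Tibble from [detect_roh()] covering every sample.
#' @param ds The `genotype_dataset` the segments were called on (supplies
#'   the SNP map and the sample set).
#' @return Tibble with columns `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_bp`.
#' @export
consensus_roh <- function(segments, ds) {
  map <- ds$map
  covered_all <- rep(TRUE, nrow(map))
  for (id in ds$sample_ids) {
    seg <- segments[segments$sample_id == id, , drop = FALSE]
    cov <- rep(FALSE, nrow(map))
    if (nrow(seg) > 0) {
      for (r in seq_len(nrow(seg))) {
        cov <- cov | (map$chrom == seg$chrom[r] &
                        map$bp >= seg$start_bp[r] & map$bp <= seg$end_bp[r])
      }
    }
    covered_all <- covered_all & cov
    if (!any(covered_all)) break
  }
  out <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    cv <- covered_all[idx]
    if (!any(cv)) return(NULL)
    r <- rle(cv)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    tibble::tibble(chrom = ch,
                   start_bp = map$bp[idx][starts[on]],
                   end_bp = map$bp[idx][ends[on]],
                   n_snps = r$lengths[on])
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), start_bp = integer(),
                          end_bp = integer(), n_snps = integer(),
                          length_bp = numeric()))
  }
  dplyr::mutate(out, length_bp = as.numeric(.data$end_bp - .data$start_bp))
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Per sample, the summed length of ROH segments at least `min_length_bp`
#' long divided by the denominator genome length. The default denominator is
#' the SNP-covered autosome length of the dataset; pass a constant (e.g.
#' `2.29e9` for the CanFam3.1 autosomes) to reproduce whole-genome fractions.
#'
#' @param segments Tibble from [detect_roh()].
#' @param denominator_bp Genome length in bp, or a `genotype_dataset` whose
#'   [snp_covered_length()] is used.
#' @param min_length_bp Only segments at least this long contribute
#'   (default 0: all detected segments).
#' @param sample_ids Samples to report (default: those present in
#'   `segments`; pass the full cohort to get explicit zeros).
#' @return Tibble with columns `sample_id`, `roh_bp`, `f_roh`.
#' @export
froh <- function(segments, denominator_bp, min_length_bp = 0,
                 sample_ids = NULL) {
  if (inherits(denominator_bp, "genotype_dataset")) {
    if (is.null(sample_ids)) sample_ids <- denominator_bp$sample_ids
    denominator_bp <- snp_covered_length(denominator_bp)
  }
  stopifnot(denominator_bp > 0)
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  kept <- segments[segments$length_bp >= min_length_bp, , drop = FALSE]
  tot <- vapply(sample_ids, function(id) {
    sum(kept$length_bp[kept$sample_id == id])
  }, numeric(1), USE.NAMES = FALSE)
  tibble::tibble(sample_id = sample_ids, roh_bp = tot,
                 f_roh = tot / denominator_bp)
}

#' Generations of inbreeding captured by a minimum ROH length
#'
#' IBD segments from a common ancestor g generations back have mean length
#' `1/(2g)` Morgan, so restricting ROHs to at least `min_length_bp` focuses
#' F_ROH on roughly the last `round(1 / (2 L s))` generations.
#'
#' @param min_length_bp Minimum ROH length in bp (vectorised).
#' @param recomb_scale Morgan per bp (default `1e-8`).
#' @return Integer vector of generations.
#' @export
roh_generations <- function(min_length_bp, recomb_scale = 1e-8) {
  stopifnot(all(min_length_bp > 0))
  as.integer(round(1 / (2 * min_length_bp * recomb_scale)))
}

#' ROH length-category histogram
#'
#' Counts segments per length category; a boundary value falls in the lower
#' category.
#'
#' @param segments Tibble from [detect_roh()].
#' @param edges_bp Category edges (default 5 and 10 Mb, giving categories
#'   `<=5 Mb`, `5-10 Mb`, `>10 Mb`).
#' @return Tibble with columns `category`, `n`.
#' @export
roh_length_histogram <- function(segments, edges_bp = c(5e6, 10e6)) {
  edges <- sort(edges_bp)
  brk <- c(-Inf, edges, Inf)
  labs <- c(paste0("<=", edges[1] / 1e6, " Mb"),
            if (length(edges) > 1) {
              paste0(edges[-length(edges)] / 1e6, "-", edges[-1] / 1e6, " Mb")
            },
            paste0(">", edges[length(edges)] / 1e6, " Mb"))
  cat_ <- cut(segments$length_bp, breaks = brk, labels = labs, right = TRUE)
  tibble::tibble(category = labs,
                 n = as.integer(table(factor(cat_, levels = labs))))
}

#' Pairwise Pearson correlation between inbreeding measures
#'
#' @param records Data frame of per-sample measures (one column per
#'   measure, plus optionally `sample_id`).
#' @param pairs Optional 2-column character matrix/data frame of measure
#'   name pairs; default: all distinct pairs.
#' @return Tibble with columns `measure_a`, `measure_b`, `r`, `p_value`,
#'   `n`; `r` is `NA` (flagged via `zero_variance`) when a measure does not
#'   vary.
#' @export
correlate_measures <- function(records, pairs = NULL) {
  num <- records[vapply(records, is.numeric, logical(1))]
  stopifnot(nrow(num) >= 3)
  if (is.null(pairs)) {
    cmb <- utils::combn(names(num), 2)
    pairs <- tibble::tibble(a = cmb[1, ], b = cmb[2, ])
  } else {
    pairs <- tibble::as_tibble(as.data.frame(pairs, stringsAsFactors = FALSE))
    names(pairs) <- c("a", "b")
  }
  purrr::pmap_dfr(pairs, function(a, b) {
    x <- num[[a]]
    y <- num[[b]]
    ok <- stats::complete.cases(x, y)
    zv <- stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0
    if (zv) {
      tibble::tibble(measure_a = a, measure_b = b, r = NA_real_,
                     p_value = NA_real_, n = sum(ok), zero_variance = TRUE)
    } else {
      ct <- stats::cor.test(x[ok], y[ok])
      tibble::tibble(measure_a = a, measure_b = b, r = unname(ct$estimate),
                     p_value = ct$p.value, n = sum(ok),
                     zero_variance = FALSE)
    }
  })
}

#' Write ROH or consensus segments as BED
#'
#' Converts the internal 1-based closed intervals to BED's 0-based
#' half-open convention (`start_bp - 1`, `end_bp`).
#'
#' @param segments Tibble with `chrom`, `start_bp`, `end_bp` (and optional
#'   `sample_id`, written as the BED name column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- tibble::tibble(chrom = segments$chrom,
                        start = segments$start_bp - 1L,
                        end = segments$end_bp,
                        name = if ("sample_id" %in% names(segments)) {
                          segments$sample_id
                        } else ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
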