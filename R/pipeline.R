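# Configuration-driven end-to-end run: filters -> diversity -> LD/Ne ->
# ROH/inbreeding -> pedigree F -> selection scan, with a consolidated set of
# TSV outputs and a structured filter log.

default_config <- function() {
  list(
    input = list(ped = NULL, map = NULL, bed = NULL, bim = NULL, fam = NULL,
                 haps = NULL, pedigree = NULL),
    filters = list(min_call_rate = 0.9, min_maf = 0, sex_chroms = list()),
    ld = list(min_dist_bp = 1e3, max_dist_bp = 50e6, bin_width_bp = 1e5),
    recomb_scale = 1e-8,
    roh = list(min_snps = list(50, 65, "auto"), min_length_bp = 1e6,
               max_missing = 5, alpha = 0.05,
               froh_min_lengths_bp = list(0),
               denominator_bp = NULL),
    scan = list(core_snps = 10, distance_bp = 1e6, n_bins = 20,
                min_freq = 0.5, min_score = 3, flank_bp = 5e5),
    pedigree = list(depths = list(5, 11), monoecious = FALSE),
    out_dir = "pipeline_out",
    seed = 1
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list) and validates it against the known
#' configuration schema; unknown keys are rejected. Missing keys fall back
#' to defaults.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_config()
  merge_checked <- function(user, def, path = "") {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    }
    for (nm in names(user)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_checked(user[[nm]], def[[nm]],
                                   paste0(path, nm, "."))
      } else {
        def[[nm]] <- user[[nm]]
      }
    }
    def
  }
  cfg <- merge_checked(config, def)
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(log, stage, n_in, n_kept) {
  dplyr::bind_rows(log, tibble::tibble(stage = stage, n_in = n_in,
                                       n_kept = n_kept,
                                       n_filtered = n_in - n_kept))
}

#' Run the full analysis pipeline
#'
#' Executes the standard sequence on a genotype dataset: call-rate filter,
#' sex-chromosome exclusion, optional MAF filter, diversity summary, LD
#' decay and the Ne/deltaF trajectory, ROH detection at each configured
#' SNP-count threshold (with `"auto"` resolved through
#' [min_snp_threshold()]), consensus ROHs, F_ROH / F_IS and their
#' correlations, pedigree inbreeding at the configured depths, and the
#' EHH/REHH selection scan when phased haplotypes are supplied. All tables
#' are written as TSV under `out_dir` and returned; a structured log
#' accounts for every SNP at every filter stage. Deterministic given the
#' config (the seed covers every stochastic step).
#'
#' @param config A [pipeline_config()], path to a YAML file, or list.
#' @return A list of class `pipeline_report` with the result tables.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- list(config = cfg)
  log <- tibble::tibble()
  tryCatch({
    ds <- if (!is.null(cfg$input$ped)) {
      read_plink_text(cfg$input$ped, cfg$input$map)
    } else if (!is.null(cfg$input$bed)) {
      read_plink_binary(cfg$input$bed, cfg$input$bim, cfg$input$fam)
    } else stop("config must name a .ped/.map or .bed/.bim/.fam input")
    if (n_samples(ds) == 0) stop("input has no samples")

    stage <- "filters"
    n0 <- n_snps(ds)
    ds <- filter_call_rate(ds, cfg$filters$min_call_rate)
    log <- log_stage(log, "call_rate", n0, n_snps(ds))
    n1 <- n_snps(ds)
    ds <- drop_sex_chromosomes(ds, unlist(cfg$filters$sex_chroms))
    log <- log_stage(log, "autosomes", n1, n_snps(ds))
    n2 <- n_snps(ds)
    if (cfg$filters$min_maf > 0) {
      ds <- filter_maf(ds, cfg$filters$min_maf)
    }
    log <- log_stage(log, "maf", n2, n_snps(ds))

    stage <- "diversity"
    res$diversity <- summarize_diversity(ds)

    stage <- "ld_ne"
    pairs <- pairwise_r2(ds, cfg$ld$min_dist_bp, cfg$ld$max_dist_bp)
    res$ld_bins <- bin_ld(pairs, cfg$ld$bin_width_bp)
    res$ne_estimates <- estimate_ne(res$ld_bins, cfg$recomb_scale)
    res$ne_trajectory <- ne_trajectory(res$ne_estimates)

    stage <- "roh"
    thresholds <- lapply(cfg$roh$min_snps, function(t) {
      if (identical(t, "auto")) {
        eh <- expected_hom_by_snp(ds)
        hom_bar <- mean(1 - 2 * allele2_freq(ds) * (1 - allele2_freq(ds)),
                        na.rm = TRUE)
        min_snp_threshold(cfg$roh$alpha, mean(rowSums(!is.na(ds$geno))),
                          n_samples(ds), hom_bar)
      } else as.integer(t)
    })
    seg_sets <- lapply(thresholds, function(t) {
      detect_roh(ds, roh_params(t, cfg$roh$min_length_bp,
                                cfg$roh$max_missing))
    })
    names(seg_sets) <- paste0("snp", thresholds)
    res$roh_segments <- dplyr::bind_rows(seg_sets, .id = "threshold")
    denom <- if (is.null(cfg$roh$denominator_bp)) snp_covered_length(ds)
             else cfg$roh$denominator_bp
    res$table1 <- report_table1(seg_sets, denom, ds)
    res$roh_histogram <- dplyr::bind_rows(
      lapply(seg_sets, roh_length_histogram), .id = "threshold")

    stage <- "inbreeding"
    fis_tab <- fis(ds)
    fmat <- tibble::tibble(sample_id = ds$sample_ids, f_is = fis_tab$f_is)
    for (i in seq_along(seg_sets)) {
      fr <- froh(seg_sets[[i]], denom, sample_ids = ds$sample_ids)
      fmat[[paste0("f_roh_", names(seg_sets)[i])]] <- fr$f_roh
    }
    res$inbreeding <- fmat
    res$fis <- fis_tab
    res$correlations <- correlate_measures(fmat[-1])

    stage <- "pedigree"
    if (!is.null(cfg$input$pedigree)) {
      ped <- read_pedigree_csv(cfg$input$pedigree,
                               monoecious = cfg$pedigree$monoecious)
      ids <- intersect(ds$sample_ids, ped$id)
      ptab <- tibble::tibble(sample_id = ids)
      for (d in unlist(cfg$pedigree$depths)) {
        ptab[[paste0("f_ped_", d)]] <- f_ped(ped, ids, d)
        ptab[[paste0("completeness_", d)]] <- completeness(ped, ids, d)
      }
      res$pedigree_f <- ptab
    }

    stage <- "scan"
    if (!is.null(cfg$input$haps)) {
      haps <- read_haplotypes_tsv(cfg$input$haps)
      cores <- define_cores(haps, cfg$scan$core_snps)
      scored <- score_rehh(scan_ehh(haps, cores, cfg$scan$distance_bp),
                           cfg$scan$n_bins)
      res$scan <- scored
      res$scan_hits <- significant_regions(scored, cfg$scan$min_freq,
                                           cfg$scan$min_score)
      export_regions_bed(res$scan_hits,
                         file.path(cfg$out_dir, "scan_hits.bed"),
                         cfg$scan$flank_bp)
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res$filter_log <- log
  for (nm in names(res)) {
    if (is.data.frame(res[[nm]])) {
      readr::write_tsv(res[[nm]], file.path(cfg$out_dir,
                                            paste0(nm, ".tsv")))
    }
  }
  class(res) <- "pipeline_report"
  res
}

#' ROH summary table across thresholds
#'
#' One row per SNP-count threshold with the per-individual ROH counts and
#' lengths, consensus ROH statistics and the mean F_ROH - the canonical
#' ROH summary-table shape for a multi-threshold analysis.
#'
#' @param seg_sets Named list of segment tibbles (one per threshold) from
#'   [detect_roh()].
#' @param denominator_bp F_ROH denominator in bp.
#' @param ds The `genotype_dataset` segments were called on.
#' @return Tibble with columns `min_snps`, `mean_n_roh`,
#'   `shortest_roh_mb`, `mean_length_mb`, `total_length_gb`, `n_consensus`,
#'   `mean_consensus_mb`, `total_consensus_gb`, `mean_froh` (9 columns).
#' @export
report_table1 <- function(seg_sets, denominator_bp, ds) {
  purrr::imap_dfr(seg_sets, function(seg, nm) {
    n_ind <- n_samples(ds)
    cons <- consensus_roh(seg, ds)
    fr <- froh(seg, denominator_bp, sample_ids = ds$sample_ids)
    tibble::tibble(
      min_snps = sub("^snp", "", nm),
      mean_n_roh = nrow(seg) / n_ind,
      shortest_roh_mb = if (nrow(seg)) min(seg$length_bp) / 1e6 else 0,
      mean_length_mb = if (nrow(seg)) mean(seg$length_bp) / 1e6 else 0,
      total_length_gb = sum(seg$length_bp) / n_ind / 1e9,
      n_consensus = nrow(cons),
      mean_consensus_mb = if (nrow(cons)) mean(cons$length_bp) / 1e6 else 0,
      total_consensus_gb = sum(cons$length_bp) / 1e9,
      mean_froh = mean(fr$f_roh)
    )
  })
}
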