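# Forward-in-time diploid Wright-Fisher simulator with recombination,
# infinite-sites mutation, an optional admixture pulse and an optional
# additively selected locus. Discrete generations, monoecious random mating
# with selfing excluded; a single seeded RNG stream drives every draw, so a
# fixed seed reproduces the result byte for byte.

#' Describe a Wright-Fisher scenario
#'
#' @param ne_history Integer vector of per-generation diploid population
#'   sizes, oldest to newest; its length is the number of bred generations.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Chromosome length in bp.
#' @param recomb_morgan_per_bp Recombination rate (default `1e-8`,
#'   i.e. 100 Mb = 1 Morgan).
#' @param mutation_rate Per-bp per-generation mutation rate (infinite
#'   sites). Default 0: variation comes from founder standing variation.
#' @param n_founder_sites Standing-variation sites at generation 0
#'   (founder allele frequencies drawn from Beta(0.5, 0.5)).
#' @param n_segsites_target SNPs to retain after chip-like ascertainment
#'   (`NULL`: disable ascertainment and keep all sites polymorphic in the
#'   final sample). Ascertained panels mimic a genotyping chip designed on
#'   an outbred reference pool: sites are chosen by spacing and *panel*
#'   minor allele frequency, so sites fixed in the bottlenecked sample are
#'   retained, as on a real array.
#' @param ascertain_maf_floor Minimum panel MAF for an ascertained site
#'   (default 0.05).
#' @param admixture Optional `list(generation =, fraction =)`: at
#'   `generation` generations before the end, each gamete is replaced with
#'   probability `fraction` by a migrant gamete drawn from an outbred
#'   migrant allele-frequency pool.
#' @param selected_locus Optional
#'   `list(chrom =, bp =, s =, onset =, mode =)`: from `onset` generations
#'   before the end, parents are sampled with additive fitness 1, 1 + s/2,
#'   1 + s at the selected site. `mode = "standing"` (default) selects on
#'   the segregating site nearest (chrom, bp) with current frequency in
#'   0.2-0.4 (a soft sweep from intermediate standing variation: the
#'   allele typically rides several haplotype backgrounds). `mode = "de_novo"` introduces a new derived allele on
#'   one random chromosome at the monomorphic site nearest (chrom, bp) and
#'   conditions on its survival by rewinding to the onset generation
#'   whenever it is lost (a hard sweep on a single haplotype background -
#'   the classic long-range-haplotype signal).
#' @param sample_size Diploids sampled (without replacement) from the final
#'   generation.
#' @param seed Integer seed.
#' @return A list of class `wf_scenario`.
#' @export
wf_scenario <- function(ne_history = rep(15L, 100L), n_chrom = 2L,
                        chrom_length_bp = 50e6, recomb_morgan_per_bp = 1e-8,
                        mutation_rate = 0, n_founder_sites = 400L,
                        n_segsites_target = NULL, ascertain_maf_floor = 0.05,
                        admixture = NULL, selected_locus = NULL,
                        sample_size = 28L, seed = 1L) {
  stopifnot(all(ne_history >= 2), n_chrom >= 1, chrom_length_bp > 1,
            sample_size >= 1, n_founder_sites >= 1)
  if (!is.null(admixture)) {
    stopifnot(admixture$fraction >= 0, admixture$fraction <= 1,
              admixture$generation >= 1)
  }
  if (!is.null(selected_locus)) stopifnot(selected_locus$s >= 0)
  structure(list(ne_history = as.integer(ne_history),
                 n_chrom = as.integer(n_chrom),
                 chrom_length_bp = chrom_length_bp,
                 recomb_morgan_per_bp = recomb_morgan_per_bp,
                 mutation_rate = mutation_rate,
                 n_founder_sites = as.integer(n_founder_sites),
                 n_segsites_target = n_segsites_target,
                 ascertain_maf_floor = ascertain_maf_floor,
                 admixture = admixture, selected_locus = selected_locus,
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "wf_scenario")
}

# one gamete from a parent's two haplotypes, one chromosome at a time;
# chrom_idx is a precomputed list of site indices per chromosome
meiose <- function(hap_a, hap_b, site_bp, chrom_idx, chrom_length_bp,
                   morgan_per_bp) {
  gam <- hap_a
  for (idx in chrom_idx) {
    n_x <- stats::rpois(1, chrom_length_bp * morgan_per_bp)
    start <- stats::rbinom(1, 1, 0.5)
    if (n_x == 0) {
      phase <- rep(start, length(idx))
    } else {
      brk <- sort(stats::runif(n_x, 0, chrom_length_bp))
      phase <- (start + findInterval(site_bp[idx], brk)) %% 2L
    }
    take_b <- phase == 1L
    gam[idx[take_b]] <- hap_b[idx[take_b]]
  }
  gam
}

#' Run a Wright-Fisher forward simulation
#'
#' Breeds `length(ne_history)` discrete generations from unrelated founders
#' carrying standing variation, with per-meiosis Poisson crossovers,
#' optional infinite-sites mutation (implemented on a pre-allocated reserve
#' of unused positions), an optional admixture pulse, and optional additive
#' selection at one locus. Parentage is recorded for every simulated
#' individual, and mean expected heterozygosity is tracked per generation.
#'
#' @param scenario A [wf_scenario()].
#' @return A list of class `wf_sim` with elements `haplotypes`
#'   (`haplotype_set` of the final sample at sites segregating in it, or at
#'   the ascertained subset), `genotypes` (matching `genotype_dataset`),
#'   `pedigree` (a [pedigree()] with a `generation` column covering every
#'   simulated individual), `true_ne` (the input `ne_history`),
#'   `het_trajectory` (tibble: generation, mean expected heterozygosity),
#'   `selected_site` (tibble with chrom, bp and final sample frequency, or
#'   `NULL`) and `scenario`.
#' @export
simulate_wf <- function(scenario) {
  stopifnot(inherits(scenario, "wf_scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  n_gen <- length(sc$ne_history)
  # site table: founder standing variation plus a mutation reserve
  exp_mut <- if (sc$mutation_rate > 0) {
    ceiling(1.5 * sc$mutation_rate * sc$n_chrom * sc$chrom_length_bp *
              2 * sum(sc$ne_history)) + 50L
  } else 0L
  n_sites <- sc$n_founder_sites + exp_mut
  site_chrom <- sort(sample(rep_len(seq_len(sc$n_chrom), n_sites)))
  site_bp <- integer(0)
  for (ch in seq_len(sc$n_chrom)) {
    k <- sum(site_chrom == ch)
    bp <- sort(sample.int(sc$chrom_length_bp - 1L, k))
    site_bp <- c(site_bp, bp)
  }
  is_reserve <- rep(FALSE, n_sites)
  if (exp_mut > 0) {
    is_reserve[sample.int(n_sites, exp_mut)] <- TRUE
  }
  founder_p <- stats::rbeta(n_sites, 0.5, 0.5)
  founder_p[is_reserve] <- 0
  chrom_idx <- lapply(seq_len(sc$n_chrom), function(ch) which(site_chrom == ch))

  n0 <- sc$ne_history[1]
  haps <- matrix(stats::rbinom(2L * n0 * n_sites, 1L,
                               rep(founder_p, each = 2L * n0)),
                 nrow = 2L * n0, ncol = n_sites)
  ids <- paste0("G0_", seq_len(n0))
  ped <- list(tibble::tibble(id = ids, sire = NA_character_,
                             dam = NA_character_, generation = 0L))
  het <- numeric(n_gen + 1L)
  het[1] <- mean(2 * colMeans(haps) * (1 - colMeans(haps)))
  reserve_idx <- which(is_reserve)
  reserve_used <- 0L

  migrant_p <- NULL
  if (!is.null(sc$admixture)) {
    migrant_p <- stats::rbeta(n_sites, 0.8, 0.8)
    migrant_p[is_reserve] <- 0
  }
  sel_site <- NA_integer_
  sel_mode <- if (!is.null(sc$selected_locus)) {
    if (is.null(sc$selected_locus$mode)) "standing" else sc$selected_locus$mode
  } else "none"
  sweep_snap <- NULL
  sweep_retries <- 0L
  max_sweep_retries <- 200L
  mig_counter <- 0L

  g <- 1L
  while (g <= n_gen) {
    gen_left <- n_gen - g          # generations before the end, after breeding
    n_next <- if (g < n_gen) sc$ne_history[g + 1L] else sc$ne_history[n_gen]
    n_par <- length(ids)

    # activate selection at onset
    fit <- rep(1, n_par)
    if (!is.null(sc$selected_locus)) {
      on_now <- gen_left < sc$selected_locus$onset
      if (on_now && is.na(sel_site)) {
        p_now <- colMeans(haps)
        if (sel_mode == "de_novo") {
          # hard sweep: new derived allele on one chromosome at the nearest
          # currently monomorphic site
          cand <- which(site_chrom == sc$selected_locus$chrom &
                          !is_reserve & p_now == 0)
          if (length(cand) == 0) {
            cand <- which(site_chrom == sc$selected_locus$chrom & !is_reserve)
            cand <- cand[order(p_now[cand])][1]
          }
          sel_site <- cand[which.min(abs(site_bp[cand] -
                                           sc$selected_locus$bp))]
          haps[, sel_site] <- 0L
          haps[sample.int(nrow(haps), 1L), sel_site] <- 1L
          sweep_snap <- list(haps = haps, ids = ids, n_ped = length(ped),
                             het = het, mig_counter = mig_counter,
                             reserve_used = reserve_used, g = g)
        } else {
          cand <- which(site_chrom == sc$selected_locus$chrom &
                          p_now >= 0.2 & p_now <= 0.4)
          if (length(cand) == 0) {
            cand <- which(site_chrom == sc$selected_locus$chrom &
                            p_now > 0 & p_now < 1)
          }
          if (length(cand) == 0) {
            stop("no segregating site available for the selected locus")
          }
          sel_site <- cand[which.min(abs(site_bp[cand] -
                                           sc$selected_locus$bp))]
        }
      }
      if (!is.na(sel_site)) {
        gcnt <- haps[seq(1, 2 * n_par, 2), sel_site] +
          haps[seq(2, 2 * n_par, 2), sel_site]
        fit <- 1 + sc$selected_locus$s * gcnt / 2
      }
    }

    new_haps <- matrix(0L, 2L * n_next, n_sites)
    sires <- integer(n_next)
    dams <- integer(n_next)
    adm_frac <- if (!is.null(sc$admixture) &&
                    gen_left == (sc$admixture$generation - 1L)) {
      sc$admixture$fraction
    } else 0
    new_ids <- paste0("G", g, "_", seq_len(n_next))
    sire_ids <- character(n_next)
    dam_ids <- character(n_next)
    for (k in seq_len(n_next)) {
      pr <- sample.int(n_par, 2, replace = FALSE, prob = fit)
      sires[k] <- pr[1]
      dams[k] <- pr[2]
      sire_ids[k] <- ids[pr[1]]
      dam_ids[k] <- ids[pr[2]]
      for (side in 1:2) {
        p <- pr[side]
        if (adm_frac > 0 && stats::runif(1) < adm_frac) {
          gam <- stats::rbinom(n_sites, 1L, migrant_p)
          mig_counter <- mig_counter + 1L
          if (side == 1) sire_ids[k] <- paste0("MIG_", mig_counter)
          else dam_ids[k] <- paste0("MIG_", mig_counter)
        } else {
          gam <- meiose(haps[2L * p - 1L, ], haps[2L * p, ], site_bp,
                        chrom_idx, sc$chrom_length_bp,
                        sc$recomb_morgan_per_bp)
        }
        new_haps[2L * k - 2L + side, ] <- gam
      }
    }
    # infinite-sites mutation on the reserve
    if (sc$mutation_rate > 0) {
      n_mut <- stats::rpois(1, 2 * n_next * sc$n_chrom *
                              sc$chrom_length_bp * sc$mutation_rate)
      for (mm in seq_len(n_mut)) {
        if (reserve_used >= length(reserve_idx)) {
          warning("mutation reserve exhausted; later mutations dropped")
          break
        }
        reserve_used <- reserve_used + 1L
        new_haps[sample.int(2L * n_next, 1L),
                 reserve_idx[reserve_used]] <- 1L
      }
    }
    # condition a de-novo sweep on survival (and, if requested, on a final
    # frequency band): rewind to the onset generation on failure
    sweep_failed <- FALSE
    if (!is.null(sweep_snap) && !is.na(sel_site)) {
      p_sel <- mean(new_haps[, sel_site])
      sweep_failed <- p_sel == 0
      if (!sweep_failed && g == n_gen &&
          !is.null(sc$selected_locus$condition_freq)) {
        band <- sc$selected_locus$condition_freq
        sweep_failed <- p_sel < band[1] || p_sel > band[2]
      }
    }
    if (sweep_failed && sweep_retries < max_sweep_retries) {
      sweep_retries <- sweep_retries + 1L
      haps <- sweep_snap$haps
      ids <- sweep_snap$ids
      ped <- ped[seq_len(sweep_snap$n_ped)]
      het <- sweep_snap$het
      mig_counter <- sweep_snap$mig_counter
      reserve_used <- sweep_snap$reserve_used
      g <- sweep_snap$g
      next
    }
    haps <- new_haps
    ids <- new_ids
    mig_unique <- unique(c(sire_ids, dam_ids))
    mig_unique <- mig_unique[startsWith(mig_unique, "MIG_")]
    if (length(mig_unique) > 0) {
      ped[[length(ped) + 1L]] <- tibble::tibble(
        id = mig_unique, sire = NA_character_, dam = NA_character_,
        generation = g - 1L)
    }
    ped[[length(ped) + 1L]] <- tibble::tibble(
      id = new_ids, sire = sire_ids, dam = dam_ids, generation = g)
    pbar <- colMeans(haps)
    het[g + 1L] <- mean(2 * pbar * (1 - pbar))
    g <- g + 1L
  }

  # sample final diploids
  n_final <- length(ids)
  take <- sort(sample.int(n_final, min(sc$sample_size, n_final)))
  rows <- as.vector(rbind(2L * take - 1L, 2L * take))
  samp <- haps[rows, , drop = FALSE]
  active <- !is_reserve
  if (reserve_used > 0) active[reserve_idx[seq_len(reserve_used)]] <- TRUE
  if (!is.null(sc$n_segsites_target)) {
    # chip-like panel ascertainment: sites fixed in the sample are kept
    keep0 <- which(active)
  } else {
    p_s <- colMeans(samp)
    keep0 <- which(active & p_s > 0 & p_s < 1)
  }
  if (length(keep0) == 0) {
    stop("no polymorphic sites in the final sample; increase ",
         "n_founder_sites or mutation_rate")
  }
  map <- tibble::tibble(
    snp_id = paste0("snp", keep0),
    chrom = as.character(site_chrom[keep0]),
    bp = site_bp[keep0], allele1 = "A", allele2 = "B")
  hs <- haplotype_set(samp[, keep0, drop = FALSE], map, ids[take])
  if (!is.null(sc$n_segsites_target) &&
      sc$n_segsites_target < nrow(hs$map)) {
    fk <- if (!is.na(sel_site)) match(sel_site, keep0) else integer(0)
    fk <- fk[!is.na(fk)]
    hs <- ascertain_snps(hs, sc$n_segsites_target,
                         maf_floor = sc$ascertain_maf_floor,
                         panel_freq = founder_p[keep0], force_keep = fk)
  }
  sel_out <- NULL
  if (!is.na(sel_site)) {
    sel_out <- tibble::tibble(chrom = as.character(site_chrom[sel_site]),
                              bp = site_bp[sel_site],
                              freq = mean(samp[, sel_site]))
  }
  ped_tbl <- pedigree(dplyr::bind_rows(ped), monoecious = TRUE)
  structure(list(haplotypes = hs, genotypes = haps_to_genotypes(hs),
                 pedigree = ped_tbl, true_ne = sc$ne_history,
                 het_trajectory = tibble::tibble(
                   generation = 0:n_gen, exp_het = het),
                 selected_site = sel_out, sampled_ids = ids[take],
                 scenario = sc),
            class = "wf_sim")
}

#' @export
print.wf_sim <- function(x, ...) {
  cat("<wf_sim> ", length(x$haplotypes$sample_ids), " sampled diploids, ",
      nrow(x$haplotypes$map), " segregating SNPs, ",
      length(x$true_ne), " generations (Ne ",
      min(x$true_ne), "-", max(x$true_ne), ")\n", sep = "")
  invisible(x)
}

#' Chip-like SNP ascertainment
#'
#' Thins segregating sites to `n_target`, preferring an even physical
#' spacing: per chromosome, evenly spaced target positions are matched
#' greedily to the nearest unused site with minor allele frequency at least
#' `maf_floor` in an (optionally supplied) reference panel; the sample
#' itself is the default panel. Mirrors the roughly uniform SNP spacing of
#' genotyping arrays.
#'
#' @param hs A `haplotype_set`.
#' @param n_target Number of SNPs to keep.
#' @param maf_floor Minimum panel MAF (default 0).
#' @param panel_freq Optional numeric vector of per-site panel allele
#'   frequencies aligned to `hs$map`.
#' @param force_keep Integer indices of sites that are always retained
#'   (e.g. a known trait locus placed on the chip), regardless of spacing
#'   or panel MAF.
#' @return A thinned `haplotype_set`.
#' @export
ascertain_snps <- function(hs, n_target, maf_floor = 0, panel_freq = NULL,
                           force_keep = integer(0)) {
  m <- nrow(hs$map)
  stopifnot(n_target >= 1)
  if (n_target > m) stop("n_target exceeds available segregating sites")
  p <- if (is.null(panel_freq)) colMeans(hs$haps) else panel_freq
  maf <- pmin(p, 1 - p)
  eligible <- maf >= maf_floor
  force_keep <- as.integer(force_keep)
  if (length(force_keep) > 0) {
    eligible[force_keep] <- FALSE      # handled outside the spacing quota
    n_target <- n_target - length(force_keep)
  }
  if (sum(eligible) < n_target) {
    stop("only ", sum(eligible), " sites pass maf_floor; cannot select ",
         n_target)
  }
  chroms <- unique(hs$map$chrom)
  # apportion targets by chromosome share of eligible sites
  n_by <- table(factor(hs$map$chrom[eligible], levels = chroms))
  quota <- floor(n_target * as.numeric(n_by) / sum(n_by))
  rem <- n_target - sum(quota)
  if (rem > 0) {
    ord <- order(-(n_target * as.numeric(n_by) / sum(n_by) - quota))
    quota[ord[seq_len(rem)]] <- quota[ord[seq_len(rem)]] + 1L
  }
  keep <- integer(0)
  for (i in seq_along(chroms)) {
    idx <- which(hs$map$chrom == chroms[i] & eligible)
    q <- min(quota[i], length(idx))
    if (q == 0) next
    bp <- hs$map$bp[idx]
    targets <- seq(min(bp), max(bp), length.out = q)
    used <- rep(FALSE, length(idx))
    for (tg in targets) {
      free <- which(!used)
      pick <- free[which.min(abs(bp[free] - tg))]
      used[pick] <- TRUE
      keep <- c(keep, idx[pick])
    }
  }
  keep <- sort(unique(c(keep, force_keep)))
  haplotype_set(hs$haps[, keep, drop = FALSE], hs$map[keep, , drop = FALSE],
                hs$sample_ids)
}

#' Breed a full-sib mating line
#'
#' Starting from one pair of unrelated founders carrying standing
#' variation, breeds `n_generations` of strict full-sib matings (two
#' offspring per generation mate to produce the next) plus `n_extra`
#' additional offspring of the final mating, recording the pedigree.
#' Pedigree inbreeding rises along the classic full-sib series 0, 0.25,
#' 0.375, ... while ROH-based inbreeding of the genotypes tracks it.
#'
#' @param n_generations Generations of sib mating (0 = just the founders'
#'   offspring).
#' @param scenario A [wf_scenario()] supplying genome layout and founder
#'   variation (its `ne_history`/`sample_size` are ignored).
#' @param n_offspring Offspring genotyped per generation (default 2, the
#'   breeding pair).
#' @return A list with `genotypes`, `haplotypes`, `pedigree` for all bred
#'   individuals.
#' @export
simulate_sib_line <- function(n_generations, scenario = wf_scenario(),
                              n_offspring = 2L) {
  stopifnot(n_generations >= 0, n_offspring >= 2)
  sc <- scenario
  set.seed(sc$seed)
  n_sites <- sc$n_founder_sites
  site_chrom <- sort(sample(rep_len(seq_len(sc$n_chrom), n_sites)))
  site_bp <- integer(0)
  for (ch in seq_len(sc$n_chrom)) {
    k <- sum(site_chrom == ch)
    site_bp <- c(site_bp, sort(sample.int(sc$chrom_length_bp - 1L, k)))
  }
  founder_p <- stats::rbeta(n_sites, 2, 2)  # common variants: het founders
  chrom_idx <- lapply(seq_len(sc$n_chrom), function(ch) which(site_chrom == ch))
  founders <- matrix(stats::rbinom(4L * n_sites, 1L,
                                   rep(founder_p, each = 4L)), nrow = 4L)
  ped <- tibble::tibble(id = c("F1", "F2"), sire = NA_character_,
                        dam = NA_character_, generation = 0L)
  cur <- founders                 # rows 1:2 = parent A, 3:4 = parent B
  cur_ids <- c("F1", "F2")
  all_haps <- NULL
  all_ids <- character(0)
  for (g in 0:n_generations) {
    n_off <- n_offspring
    off <- matrix(0L, 2L * n_off, n_sites)
    off_ids <- paste0("S", g, "_", seq_len(n_off))
    for (k in seq_len(n_off)) {
      off[2L * k - 1L, ] <- meiose(cur[1, ], cur[2, ], site_bp, chrom_idx,
                                   sc$chrom_length_bp,
                                   sc$recomb_morgan_per_bp)
      off[2L * k, ] <- meiose(cur[3, ], cur[4, ], site_bp, chrom_idx,
                              sc$chrom_length_bp,
                              sc$recomb_morgan_per_bp)
    }
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      id = off_ids, sire = cur_ids[1], dam = cur_ids[2], generation = g + 1L))
    all_haps <- rbind(all_haps, off)
    all_ids <- c(all_ids, off_ids)
    cur <- off[1:4, , drop = FALSE]
    cur_ids <- off_ids[1:2]
  }
  map <- tibble::tibble(snp_id = paste0("snp", seq_len(n_sites)),
                        chrom = as.character(site_chrom), bp = site_bp,
                        allele1 = "A", allele2 = "B")
  hs <- haplotype_set(all_haps, map, all_ids)
  list(haplotypes = hs, genotypes = haps_to_genotypes(hs),
       pedigree = pedigree(ped))
}

#' Write a named simulation fixture to disk
#'
#' Generates one of the documented synthetic datasets and writes PLINK text
#' genotypes, a phased haplotype TSV, a pedigree CSV and a truth JSON (true
#' Ne history; selected site if any) under `dir`.
#'
#' * `tiny_toy`: 3 samples, at most 10 SNPs, hand-checkable.
#' * `bottleneck28`: 28 diploids after a long small-Ne bottleneck with a
#'   recent 1/16 admixture pulse; genome scaled down ~50x from a 38-autosome
#'   array design (3 chromosomes, ~50 Mb, ~3000 SNPs).
#' * `sweep_demo`: bottlenecked population with one additively selected
#'   locus (s = 0.8) swept over the last 12 generations.
#'
#' @param name One of `"tiny_toy"`, `"bottleneck28"`, `"sweep_demo"`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list with the `wf_sim` object and the file paths.
#' @export
make_fixture <- function(name, dir, seed = 1L) {
  scen <- switch(
    name,
    tiny_toy = wf_scenario(ne_history = rep(6L, 8L), n_chrom = 1L,
                           chrom_length_bp = 5e6, n_founder_sites = 30L,
                           n_segsites_target = 10L, sample_size = 3L,
                           seed = seed),
    bottleneck28 = wf_scenario(
      ne_history = c(rep(50L, 20L), rep(12L, 50L), rep(30L, 5L)),
      n_chrom = 3L, chrom_length_bp = 50e6, n_founder_sites = 4500L,
      n_segsites_target = 3000L,
      admixture = list(generation = 5L, fraction = 1 / 16),
      sample_size = 28L, seed = seed),
    sweep_demo = wf_scenario(
      ne_history = rep(50L, 40L),
      n_chrom = 2L, chrom_length_bp = 40e6, n_founder_sites = 2500L,
      n_segsites_target = 1500L,
      selected_locus = list(chrom = 1L, bp = 20e6, s = 0.8, onset = 12L,
                            mode = "de_novo",
                            condition_freq = c(0.5, 0.95)),
      sample_size = 28L, seed = seed),
    stop("unknown fixture name: ", name)
  )
  sim <- simulate_wf(scen)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, name)
  write_plink_text(sim$genotypes, prefix)
  write_haplotypes_tsv(sim$haplotypes, paste0(prefix, "_haps.tsv"))
  write_pedigree_csv(sim$pedigree, paste0(prefix, "_pedigree.csv"))
  truth <- list(name = name, seed = seed, true_ne = sim$true_ne,
                selected_site = sim$selected_site)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(truth, paste0(prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(sim = sim, prefix = prefix))
}
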