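# Core tiling, EHH against the all-pairs oracle, REHH weighting, the
# frequency-binned scores and region export.

test_that("core tiling floors partial windows and enumerates haplotypes by group-by", {
  set.seed(61)
  haps <- matrix(rbinom(8 * 25, 1, 0.5), nrow = 8)
  hs <- make_haps(haps, bp = seq_len(25) * 100000L)
  cores <- define_cores(hs, 10)
  expect_equal(nrow(cores), 2L) # 25 %/% 10, remainder dropped
  expect_equal(cores$snp_lo, c(1L, 11L))
  expect_equal(cores$snp_hi, c(10L, 20L))
  ch <- core_haplotypes(hs, cores[1, ])
  strings <- apply(haps[, 1:10], 1, paste0, collapse = "")
  expect_equal(sum(ch$n_carriers), 8L)
  expect_equal(sort(ch$haplotype), sort(unique(strings)))
  expect_equal(ch$n_carriers,
               as.integer(sort(table(strings), decreasing = TRUE)))
  # single-SNP cores: haplotypes are alleles
  c1 <- define_cores(hs, 1)
  expect_equal(nrow(c1), 25L)
  expect_setequal(core_haplotypes(hs, c1[1, ])$haplotype,
                  as.character(unique(haps[, 1])))
})

test_that("EHH anchors: distance zero, identical carriers, pair-group arithmetic", {
  # 6 carriers of core allele 1, extended groups of sizes 3, 2, 1
  ext <- rbind(c(0, 0), c(0, 0), c(0, 0), c(1, 0), c(1, 0), c(1, 1),
               c(0, 1), c(1, 1)) # last 2 rows carry core allele 0
  core_col <- c(1, 1, 1, 1, 1, 1, 0, 0)
  haps <- cbind(core_col, ext)
  hs <- make_haps(haps, bp = c(1e6, 2e6, 3e6))
  core <- define_cores(hs, 1)[1, ]
  expect_equal(ehh(hs, core, "1", 0), 1)
  expect_equal(ehh(hs, core, "1", 2.5e6, "up"),
               (choose(3, 2) + choose(2, 2)) / choose(6, 2))
  expect_equal(ehh(hs, core, "1", 2.5e6, "up"), 4 / 15)
  # two identical carriers -> 1; differing carriers -> 0
  expect_equal(ehh(hs, core, "0", 2.5e6, "up"), 0)
})

test_that("EHH equals the all-pairs oracle and never increases with distance", {
  set.seed(14)
  for (rep in 1:25) {
    n_hap <- 2 * sample(6:12, 1)
    m <- sample(15:30, 1)
    p <- runif(m, 0.2, 0.8)
    haps <- matrix(rbinom(n_hap * m, 1, rep(p, each = n_hap)), nrow = n_hap)
    bp <- sort(sample.int(5e6, m))
    hs <- make_haps(haps, bp = bp)
    lo <- sample(3:(m - 6), 1)
    hi <- lo + 2
    core <- list(chrom = "1", snp_lo = lo, snp_hi = hi)
    hap_tab <- core_haplotypes(hs, core)
    h <- hap_tab$haplotype[hap_tab$n_carriers >= 2][1]
    if (is.na(h)) next
    dists <- sort(sample.int(5e6, 4))
    prev_up <- prev_dn <- Inf
    for (d in dists) {
      for (dir in c("up", "down")) {
        got <- ehh(hs, core, h, d, dir)
        expect_equal(got, oracle_ehh(haps, bp, lo, hi, h, d, dir),
                     info = sprintf("rep %d d %d %s", rep, d, dir))
      }
      up <- ehh(hs, core, h, d, "up")
      dn <- ehh(hs, core, h, d, "down")
      expect_lte(up, prev_up + 1e-12)
      expect_lte(dn, prev_dn + 1e-12)
      prev_up <- up
      prev_dn <- dn
    }
  }
})

test_that("pair-weighted homozygosity is conserved at distance zero", {
  set.seed(55)
  haps <- matrix(rbinom(20 * 12, 1, 0.5), nrow = 20)
  hs <- make_haps(haps, bp = seq_len(12) * 50000L)
  core <- list(chrom = "1", snp_lo = 4L, snp_hi = 6L)
  tab <- core_haplotypes(hs, core)
  e0 <- vapply(tab$haplotype, function(h) ehh(hs, core, h, 0), numeric(1))
  lhs <- sum(choose(tab$n_carriers, 2) * ifelse(tab$n_carriers > 1, e0, 0))
  expect_equal(lhs, sum(choose(tab$n_carriers, 2)))
  expect_lte(lhs, choose(20, 2))
})

test_that("REHH is the pair-count-weighted ratio with its degenerate cases", {
  # identical decay for every haplotype -> REHH = 1
  haps <- rbind(matrix(c(1, 0, 0), 4, 3, byrow = TRUE),
                matrix(c(0, 1, 1), 4, 3, byrow = TRUE))
  hs <- make_haps(haps, bp = c(1e6, 2e6, 3e6))
  core <- define_cores(hs, 1)[1, ]
  expect_equal(rehh_stat(hs, core, "1", 1.5e6), 1)
  # single alternative haplotype: denominator collapses to its EHH
  ext <- rbind(c(1, 1), c(1, 1), c(1, 1),      # core 1: fully conserved
               c(0, 0), c(0, 1), c(1, 0), c(0, 0)) # core 0: partly decayed
  hs2 <- make_haps(cbind(c(1, 1, 1, 0, 0, 0, 0), ext)[c(1:7, 7), ],
                   bp = c(1e6, 2e6, 3e6))
  core2 <- define_cores(hs2, 1)[1, ]
  e1 <- ehh(hs2, core2, "1", 2.5e6, "up")
  e0 <- ehh(hs2, core2, "0", 2.5e6, "up")
  expect_equal(rehh_stat(hs2, core2, "1", 2.5e6, "up"), e1 / e0)
  # constructed ratio from oracle values
  expect_equal(e1, 1)
  expect_gt(rehh_stat(hs2, core2, "1", 2.5e6, "up"), 1)
  # all-singleton others -> no pairs -> undefined
  single <- make_haps(rbind(c(1, 0), c(1, 0), c(1, 1), c(0, 1)),
                      bp = c(1e6, 2e6))
  cs <- define_cores(single, 1)[1, ]
  expect_true(is.na(rehh_stat(single, cs, "1", 1e6)))
})

test_that("binned scores standardise ln REHH with one-sided upper-tail P", {
  res <- tibble::tibble(core_id = 1:6, chrom = "1", start_bp = 1,
                        end_bp = 2,
                        haplotype = letters[1:6], n_carriers = 4L,
                        frequency = c(.52, .53, .54, .12, .12, .95),
                        ehh_up = 1, ehh_down = 1, rehh_up = 1, rehh_down = 1,
                        rehh = c(exp(-1), exp(0), exp(1), 2, 2, 3))
  sc <- score_rehh(res, n_bins = 20)
  # symmetric {-a, 0, a}: middle member has z = 0, P = 0.5
  b11 <- sc[sc$frequency %in% c(.52, .53, .54), ]
  expect_equal(b11$z[2], 0)
  expect_equal(b11$neg_log10_p[2], -log10(0.5))
  expect_equal(b11$z[3], 1 / stats::sd(c(-1, 0, 1)))
  expect_gt(b11$neg_log10_p[3], b11$neg_log10_p[2])
  # equal members -> sd 0 -> unscored
  expect_false(any(sc$scored[sc$frequency == .12]))
  # lone member in its bin -> unscored; low-frequency flagging
  expect_false(sc$scored[sc$frequency == .95])
  expect_true(all(sc$low_freq == (sc$frequency < 0.1)))
})

test_that("significant-region filtering and BED export with flanks behave as specified", {
  scored <- tibble::tibble(core_id = 1:4, chrom = c("1", "1", "2", "2"),
                           start_bp = c(1e6, 5e6, 1e5, 8e6),
                           end_bp = c(1.5e6, 5.5e6, 2e5, 8.5e6),
                           haplotype = "h", n_carriers = 10L,
                           frequency = c(.8, .3, .7, .6),
                           rehh = 2, bin_id = 1L, z = 1,
                           neg_log10_p = c(4, 5, 1, 3.5),
                           scored = TRUE, low_freq = FALSE)
  hits <- significant_regions(scored, min_freq = 0.5, min_score = 3)
  expect_equal(hits$core_id, c(1L, 4L)) # 2 fails freq, 3 fails score
  expect_equal(nrow(significant_regions(scored[0, ])), 0L)
  path <- withr::local_tempfile(fileext = ".bed")
  ext <- export_regions_bed(hits, path, flank_bp = 5e5,
                            chrom_lengths = c("1" = 2e6, "2" = 40e6))
  bed <- utils::read.table(path)
  # flank applied both sides, 0-based start, clipped at chromosome ends
  expect_equal(bed$V2[1], 5e5 - 1)
  expect_equal(bed$V3[1], 2e6)      # right-clipped
  expect_equal(bed$V3[2], 9e6)
  # clipping at the left end
  low <- dplyr::mutate(hits[1, ], start_bp = 1e5, end_bp = 3e5)
  ext2 <- export_regions_bed(low, path, flank_bp = 5e5)
  expect_equal(ext2$start_bp, 1)
  # zero flank is the identity on intervals
  ext0 <- export_regions_bed(hits, path, flank_bp = 0)
  expect_equal(ext0$start_bp, hits$start_bp)
  expect_equal(ext0$end_bp, hits$end_bp)
  # overlapping extended regions are not merged
  near <- dplyr::bind_rows(hits[1, ],
                           dplyr::mutate(hits[1, ], core_id = 9L,
                                         start_bp = 1.6e6, end_bp = 1.7e6))
  ext3 <- export_regions_bed(near, path, flank_bp = 5e5)
  expect_equal(nrow(ext3), 2L)
})

test_that("scan_ehh tables agree with direct per-haplotype calls", {
  set.seed(91)
  # few distinct lineages so core haplotypes recur across chromosomes
  templates <- matrix(rbinom(4 * 40, 1, 0.5), nrow = 4)
  haps <- templates[sample(4, 16, TRUE), ]
  flip <- matrix(rbinom(16 * 40, 1, 0.03), nrow = 16)
  haps <- (haps + flip) %% 2
  hs <- make_haps(haps, bp = sort(sample.int(8e6, 40)))
  cores <- define_cores(hs, 8)
  res <- scan_ehh(hs, cores, 2e6)
  expect_true(all(res$n_carriers >= 2))
  expect_gt(nrow(res), 0)
  for (i in sample(nrow(res), min(5, nrow(res)))) {
    core <- cores[cores$core_id == res$core_id[i], ]
    expect_equal(res$ehh_up[i],
                 ehh(hs, core, res$haplotype[i], 2e6, "up"))
    expect_equal(res$rehh_down[i],
                 rehh_stat(hs, core, res$haplotype[i], 2e6, "down"))
    expect_equal(res$rehh[i], max(res$rehh_up[i], res$rehh_down[i]))
  }
})
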