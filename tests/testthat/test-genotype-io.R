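# PLINK text/binary round trips, genotype recoding and the SNP filters.

test_that("text round trip is lossless and minor-allele coding matches a hand-enumerated table", {
  # 2 samples x 3 SNPs; SNP1: A hom / A-B het -> B minor (1 copy vs 3)
  # SNP2: tie at p = 0.5 -> allele2 stays the later label B
  # SNP3: one missing, one A hom
  geno <- matrix(c(0L, 1L,  2L, 0L,  NA, 0L), nrow = 2)
  ds <- make_ds(geno, chrom = c("1", "1", "2"), bp = c(100L, 200L, 150L))
  dir <- withr::local_tempdir()
  write_plink_text(ds, file.path(dir, "toy"))
  back <- read_plink_text(file.path(dir, "toy.ped"), file.path(dir, "toy.map"))
  expect_identical(back$geno, ds$geno)
  expect_equal(back$map$bp, ds$map$bp)
  expect_identical(back$sample_ids, ds$sample_ids)

  # hand enumeration on a 6-genotype toy: alleles written as A/B tokens;
  # counts of B are 0,1,2 regardless of writing order
  lines <- c("f1 i1 0 0 0 -9 A A A B B B",
             "f2 i2 0 0 0 -9 A A B B 0 0")
  writeLines(lines, file.path(dir, "hand.ped"))
  writeLines(c("1 s1 0 10", "1 s2 0 20", "1 s3 0 30"),
             file.path(dir, "hand.map"))
  hd <- read_plink_text(file.path(dir, "hand.ped"), file.path(dir, "hand.map"))
  # s1: A,A,A,A -> B absent, monomorphic, codes 0,0 (B = lexicographically
  # later label on the tie-less all-A column is A itself -> both 0)
  expect_equal(unname(hd$geno[, 1]), c(0L, 0L))
  # s2: A B | B B -> B has 3 copies, A 1 -> minor is A; codes count A
  expect_equal(unname(hd$geno[, 2]), c(1L, 0L))
  expect_equal(hd$map$allele2[2], "A")
  # s3: B B | missing -> only B seen; missing preserved
  expect_equal(unname(hd$geno[, 3]), c(0L, NA_integer_))
})

test_that("missing genotype code 0 0 maps to NA and half-missing is rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("f1 i1 0 0 0 -9 0 0", "f2 i2 0 0 0 -9 A A"),
             file.path(dir, "m.ped"))
  writeLines("1 s1 0 10", file.path(dir, "m.map"))
  ds <- read_plink_text(file.path(dir, "m.ped"), file.path(dir, "m.map"))
  expect_true(is.na(ds$geno[1, 1]))
  expect_equal(ds$geno[2, 1], 0L)

  writeLines(c("f1 i1 0 0 0 -9 A 0"), file.path(dir, "h.ped"))
  expect_error(read_plink_text(file.path(dir, "h.ped"),
                               file.path(dir, "m.map")),
               "half-missing")
})

test_that("malformed ped lines and >2 alleles raise informative errors", {
  dir <- withr::local_tempdir()
  writeLines("f1 i1 0 0 0 -9 A", file.path(dir, "bad.ped"))
  writeLines("1 s1 0 10", file.path(dir, "bad.map"))
  expect_error(read_plink_text(file.path(dir, "bad.ped"),
                               file.path(dir, "bad.map")),
               "line 1")
  writeLines(c("f1 i1 0 0 0 -9 A C", "f2 i2 0 0 0 -9 G G"),
             file.path(dir, "tri.ped"))
  expect_error(read_plink_text(file.path(dir, "tri.ped"),
                               file.path(dir, "bad.map")),
               "more than 2 alleles")
})

test_that("binary reader equals text reader, detects truncation and rejects individual-major", {
  set.seed(42)
  geno <- matrix(sample(c(0L, 1L, 2L, NA), 5 * 7, TRUE), nrow = 5)
  ds <- make_ds(geno)
  dir <- withr::local_tempdir()
  write_plink_text(ds, file.path(dir, "x"))
  write_plink_binary(ds, file.path(dir, "x"))
  t_ds <- read_plink_text(file.path(dir, "x.ped"), file.path(dir, "x.map"))
  b_ds <- read_plink_binary(file.path(dir, "x.bed"), file.path(dir, "x.bim"),
                            file.path(dir, "x.fam"))
  expect_identical(b_ds$geno, t_ds$geno)
  expect_equal(b_ds$map$allele2, t_ds$map$allele2)

  raw <- readBin(file.path(dir, "x.bed"), "raw", 1e6)
  writeBin(raw[1:(length(raw) - 1)], file.path(dir, "trunc.bed"))
  expect_error(read_plink_binary(file.path(dir, "trunc.bed"),
                                 file.path(dir, "x.bim"),
                                 file.path(dir, "x.fam")),
               "truncated")
  raw[3] <- as.raw(0x00)
  writeBin(raw, file.path(dir, "im.bed"))
  expect_error(read_plink_binary(file.path(dir, "im.bed"),
                                 file.path(dir, "x.bim"),
                                 file.path(dir, "x.fam")),
               "individual-major")
})

test_that("both readers give the same F_IS vector on a simulated cohort", {
  sim <- simulate_wf(wf_scenario(ne_history = rep(20L, 12L), n_chrom = 1L,
                                 chrom_length_bp = 10e6,
                                 n_founder_sites = 120L, sample_size = 10L,
                                 seed = 11L))
  ds <- sim$genotypes
  dir <- withr::local_tempdir()
  write_plink_text(ds, file.path(dir, "c"))
  write_plink_binary(ds, file.path(dir, "c"))
  f_t <- fis(read_plink_text(file.path(dir, "c.ped"), file.path(dir, "c.map")))
  f_b <- fis(read_plink_binary(file.path(dir, "c.bed"), file.path(dir, "c.bim"),
                               file.path(dir, "c.fam")))
  expect_equal(f_b$f_is, f_t$f_is, tolerance = 1e-12)
})

test_that("call-rate filter is strict and matches a brute-force fraction check", {
  # SNP missing in 3/28 samples: 25/28 = 0.893 <= 0.90 -> dropped at 0.90
  g <- matrix(0L, 28, 2)
  g[1:3, 1] <- NA
  ds <- make_ds(g)
  kept <- filter_call_rate(ds, 0.90)
  expect_equal(n_snps(kept), 1L)
  expect_equal(kept$map$snp_id, "s2")
  expect_false(unname(colMeans(!is.na(ds$geno))[1] > 0.90))
  # boundary conventions
  expect_equal(n_snps(filter_call_rate(ds, 0)), 2L)
  expect_equal(n_snps(filter_call_rate(ds, 1)), 1L)
})

test_that("sex-chromosome exclusion keeps only autosomes and preserves samples", {
  g <- matrix(0L, 3, 4)
  ds <- make_ds(g, chrom = c("1", "2", "X", "39"),
                bp = c(10L, 10L, 10L, 10L))
  auto <- drop_sex_chromosomes(ds)
  expect_equal(unique(auto$map$chrom), c("1", "2", "39"))
  dog <- drop_sex_chromosomes(ds, sex_chroms = "39")
  expect_equal(unique(dog$map$chrom), c("1", "2"))
  expect_identical(dog$sample_ids, ds$sample_ids)
  expect_identical(drop_sex_chromosomes(dog)$map, dog$map)
})

test_that("MAF filter matches hand enumeration and honours an external panel", {
  set.seed(7)
  # 10 SNPs with controlled allele-2 counts over 10 samples
  counts <- c(0, 1, 2, 3, 5, 8, 10, 12, 15, 20) # of 20 chromosomes
  g <- sapply(counts, function(k) {
    v <- integer(10)
    v[seq_len(k %/% 2)] <- 2L
    if (k %% 2 == 1) v[k %/% 2 + 1] <- 1L
    v
  })
  ds <- make_ds(g)
  maf <- pmin(counts / 20, 1 - counts / 20)
  kept <- filter_maf(ds, 0.05)
  expect_equal(kept$map$snp_id, ds$map$snp_id[maf >= 0.05])
  expect_equal(n_snps(filter_maf(ds, 0)), 10L)
  # monomorphic SNP removed at 0.01
  expect_false("s1" %in% filter_maf(ds, 0.01)$map$snp_id)
  # external panel: reuse ids, shifted frequencies
  panel <- tibble::tibble(snp_id = ds$map$snp_id, maf = rep(c(0, 0.3), 5))
  keptp <- filter_maf(ds, 0.01, panel)
  expect_equal(n_snps(keptp), 5L)
  expect_error(filter_maf(ds, 0.01, panel[-1, ]), "missing SNPs")
})

test_that("filters commute on non-interacting fixtures and are idempotent", {
  set.seed(9)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 20 * 30, TRUE,
                     prob = c(.4, .2, .3, .1)), nrow = 20)
  ds <- make_ds(g, chrom = rep(c("1", "X"), each = 15),
                bp = rep(seq_len(15) * 1000L, 2))
  a <- filter_maf(filter_call_rate(ds, 0.8), 0.05)
  b <- filter_call_rate(filter_maf(ds, 0.05), 0.8)
  expect_identical(a$map$snp_id, b$map$snp_id)
  expect_identical(filter_call_rate(a, 0.8)$map$snp_id, a$map$snp_id)
})

test_that("diversity summary matches hand computation on a 3-SNP table", {
  # 3 samples x 3 SNPs, complete data
  g <- matrix(c(0L, 0L, 2L,   # p = 2/6
                1L, 1L, 0L,   # p = 2/6
                2L, 2L, 2L),  # monomorphic
              nrow = 3)
  ds <- make_ds(g)
  dv <- summarize_diversity(ds, small_sample_correction = FALSE)
  expect_equal(dv$mean_maf, mean(c(1 / 3, 1 / 3, 0)))
  expect_equal(dv$prop_informative, 2 / 3)
  expect_equal(dv$mean_obs_hom, mean(c(2, 2, 3)))
  # E per SNP (uncorrected): 1 - 2pq = 1 - 2*(1/3)*(2/3) twice, and 1
  e_snp <- c(1 - 4 / 9, 1 - 4 / 9, 1)
  expect_equal(dv$mean_exp_hom, sum(e_snp))
  f_hand <- (c(2, 2, 3) - sum(e_snp)) / (3 - sum(e_snp))
  expect_equal(dv$mean_fis, mean(f_hand))
})

test_that("mean F_IS is near zero under Hardy-Weinberg sampling", {
  set.seed(123)
  p <- runif(400, 0.1, 0.9)
  g <- sapply(p, function(pp) stats::rbinom(60, 2, pp))
  ds <- make_ds(g, bp = seq_len(400) * 1000L)
  expect_lt(abs(summarize_diversity(ds)$mean_fis), 0.05)
})

test_that("F_IS hits its algebraic anchors", {
  set.seed(5)
  g <- sapply(runif(50, .2, .8), function(pp) stats::rbinom(8, 2, pp))
  # an individual homozygous everywhere -> O = n -> F_IS = 1
  g[1, ] <- ifelse(g[1, ] == 1L, 0L, g[1, ])
  rec <- fis(make_ds(g, bp = seq_len(50) * 1000L))
  expect_equal(rec$f_is[1], 1)
  expect_true(all(rec$f_is >= -1 & rec$f_is <= 1))
})
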