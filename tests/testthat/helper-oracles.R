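# Fixture builders and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (exhaustive enumeration) and share
# no code with the package implementation.

# -- fixture builders --------------------------------------------------------

make_map <- function(chrom, bp) {
  tibble::tibble(snp_id = paste0("s", seq_along(bp)),
                 chrom = as.character(chrom), bp = as.integer(bp),
                 allele1 = "A", allele2 = "B")
}

make_ds <- function(geno, chrom = NULL, bp = NULL) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  genotype_dataset(geno, make_map(chrom, bp),
                   paste0("ind", seq_len(nrow(geno))))
}

make_haps <- function(haps, chrom = NULL, bp = NULL) {
  haps <- as.matrix(haps)
  m <- ncol(haps)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  haplotype_set(haps, make_map(chrom, bp),
                paste0("ind", seq_len(nrow(haps) / 2)))
}

# -- ROH oracle: exhaustive window enumeration ------------------------------
# calls: vector of 0/1/2/NA; valid window [i, j]: hom endpoints, no het
# inside, <= max_missing missing; maximal: not contained in another valid
# window; reported if SNP span >= min_snps and bp span >= min_len.
oracle_roh <- function(calls, bp, min_snps, min_len, max_missing) {
  n <- length(calls)
  hom <- !is.na(calls) & calls != 1L
  het <- !is.na(calls) & calls == 1L
  valid <- list()
  for (i in seq_len(n)) {
    if (!hom[i]) next
    for (j in i:n) {
      if (het[j]) break
      if (!hom[j]) next
      if (sum(is.na(calls[i:j])) > max_missing) break
      valid[[length(valid) + 1L]] <- c(i, j)
    }
  }
  if (length(valid) == 0) {
    return(data.frame(s = integer(0), e = integer(0)))
  }
  v <- do.call(rbind, valid)
  maximal <- vapply(seq_len(nrow(v)), function(k) {
    !any(v[, 1] <= v[k, 1] & v[, 2] >= v[k, 2] &
           (v[, 1] != v[k, 1] | v[, 2] != v[k, 2]))
  }, logical(1))
  v <- v[maximal, , drop = FALSE]
  keep <- (v[, 2] - v[, 1] + 1L) >= min_snps &
    (bp[v[, 2]] - bp[v[, 1]]) >= min_len
  v <- v[keep, , drop = FALSE]
  data.frame(s = v[, 1], e = v[, 2])
}

# -- EHH oracle: all-pairs string comparison --------------------------------
oracle_ehh <- function(hapmat, bp, core_lo, core_hi, haplotype, dist,
                       direction) {
  core_str <- apply(hapmat[, core_lo:core_hi, drop = FALSE], 1,
                    paste0, collapse = "")
  carriers <- which(core_str == haplotype)
  if (length(carriers) < 2) return(0)
  if (direction == "up") {
    ext <- which(seq_along(bp) > core_hi & bp <= bp[core_hi] + dist)
  } else {
    ext <- which(seq_along(bp) < core_lo & bp >= bp[core_lo] - dist)
  }
  if (length(ext) == 0) return(1)
  n_id <- 0L
  cmb <- utils::combn(carriers, 2)
  for (k in seq_len(ncol(cmb))) {
    if (all(hapmat[cmb[1, k], ext] == hapmat[cmb[2, k], ext])) {
      n_id <- n_id + 1L
    }
  }
  n_id / ncol(cmb)
}

# -- haplotype r2 oracle: D^2 / (p1 q1 p2 q2) -------------------------------
oracle_r2_haps <- function(h1, h2) {
  p1 <- mean(h1)
  p2 <- mean(h2)
  p11 <- mean(h1 == 1 & h2 == 1)
  d <- p11 - p1 * p2
  d^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

# -- pedigree F oracle: memoised recursive kinship --------------------------
# phi(a, a) = (1 + F_a) / 2; phi(a, b) = (phi(sire_b, a) + phi(dam_b, a)) / 2
# recursing on the younger individual; unknown parents are unrelated
# non-inbred founders. F(x) = phi(sire_x, dam_x).
oracle_f_ped <- function(ped_df, id) {
  par <- function(x) {
    i <- match(x, ped_df$id)
    if (is.na(i)) c(NA, NA) else c(ped_df$sire[i], ped_df$dam[i])
  }
  depth_memo <- new.env()
  depth <- function(x) {
    if (is.na(x)) return(-1L)
    if (!is.null(depth_memo[[x]])) return(depth_memo[[x]])
    p <- par(x)
    d <- 1L + max(depth(p[1]), depth(p[2]))
    depth_memo[[x]] <- d
    d
  }
  memo <- new.env()
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      p <- par(a)
      (1 + phi(p[1], p[2])) / 2
    } else {
      # recurse on the individual with greater pedigree depth
      if (depth(a) < depth(b)) { tmp <- a; a <- b; b <- tmp }
      p <- par(a)
      (phi(p[1], b) + phi(p[2], b)) / 2
    }
    memo[[key]] <- val
    val
  }
  p <- par(id)
  phi(p[1], p[2])
}

# random genotype vector with given het/missing rates
random_calls <- function(n, p_het = 0.15, p_miss = 0.1) {
  x <- sample(c(0L, 2L), n, replace = TRUE)
  r <- stats::runif(n)
  x[r < p_het] <- 1L
  x[r >= p_het & r < p_het + p_miss] <- NA_integer_
  x
}
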