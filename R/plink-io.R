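# PLINK text (.ped/.map) and binary (.bed/.bim/.fam) genotype I/O.
# Internal genotype codes count the minor allele (allele2); orientation is
# recomputed per dataset on import, with ties at p = 0.5 broken towards the
# lexicographically later allele label so both readers agree byte-for-byte.

read_map_file <- function(map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "snp_id", "cm", "bp")
  tibble::as_tibble(map)
}

orient_minor <- function(a1_tok, a2_tok) {
  # a1_tok/a2_tok: character vectors of the two allele tokens per sample at
  # one SNP ("0" = missing). Returns list(allele1, allele2, code) with
  # allele2 the minor allele.
  ok <- a1_tok != "0" & a2_tok != "0"
  alleles <- sort(unique(c(a1_tok[ok], a2_tok[ok])))
  if (length(alleles) > 2) {
    stop("more than 2 alleles observed at a SNP: ",
         paste(alleles, collapse = "/"))
  }
  if (length(alleles) == 0) alleles <- c("0", "0")
  if (length(alleles) == 1) {
    # monomorphic: the minor allele is absent, so every call carries 0
    # copies of it
    code <- rep(NA_integer_, length(a1_tok))
    code[ok] <- 0L
    return(list(allele1 = alleles, allele2 = alleles, code = code))
  }
  cnt2 <- sum(a1_tok[ok] == alleles[2]) + sum(a2_tok[ok] == alleles[2])
  cnt1 <- sum(a1_tok[ok] == alleles[1]) + sum(a2_tok[ok] == alleles[1])
  # allele2 = minor; tie -> lexicographically later label (alleles[2], since
  # `alleles` is sorted)
  if (cnt2 > cnt1) alleles <- rev(alleles)
  code <- rep(NA_integer_, length(a1_tok))
  code[ok] <- (a1_tok[ok] == alleles[2]) + (a2_tok[ok] == alleles[2])
  list(allele1 = alleles[1], allele2 = alleles[2], code = code)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses whitespace-delimited PLINK pedigree genotype files into a
#' [genotype_dataset()]. Alleles are recoded to 0/1/2 counts of the per-SNP
#' minor allele; the missing code `0 0` becomes `NA`.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A `genotype_dataset`.
#' @export
read_plink_text <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- read_map_file(map_path)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  sample_ids <- character(n)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != 6 + 2 * m) {
      stop("malformed .ped line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(tk))
    }
    sample_ids[i] <- tk[2]
    gt <- tk[-(1:6)]
    a1[i, ] <- gt[seq(1, 2 * m, by = 2)]
    a2[i, ] <- gt[seq(2, 2 * m, by = 2)]
  }
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    stop("half-missing genotype (one allele coded 0) at .ped line ",
         which(rowSums(half) > 0)[1], "; refusing to impute")
  }
  geno <- matrix(NA_integer_, n, m)
  al1 <- character(m)
  al2 <- character(m)
  for (j in seq_len(m)) {
    o <- orient_minor(a1[, j], a2[, j])
    geno[, j] <- o$code
    al1[j] <- o$allele1
    al2[j] <- o$allele2
  }
  map <- dplyr::mutate(map, allele1 = al1, allele2 = al2)
  genotype_dataset(geno, map[c("snp_id", "chrom", "bp", "allele1", "allele2")],
                   sample_ids)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Inverse of [read_plink_text()]: genotype code 0 becomes `allele1 allele1`,
#' 2 becomes `allele2 allele2`, and missing becomes `0 0`.
#'
#' @param ds A `genotype_dataset`.
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return `prefix`, invisibly.
#' @export
write_plink_text <- function(ds, prefix) {
  map <- ds$map
  readr::write_tsv(tibble::tibble(chrom = map$chrom, snp_id = map$snp_id,
                                  cm = 0, bp = map$bp),
                   paste0(prefix, ".map"), col_names = FALSE)
  n <- n_samples(ds)
  m <- n_snps(ds)
  tok <- function(g, a1, a2) {
    out <- rep("0 0", length(g))
    out[!is.na(g) & g == 0L] <- paste(a1, a1)
    out[!is.na(g) & g == 1L] <- paste(a1, a2)
    out[!is.na(g) & g == 2L] <- paste(a2, a2)
    out
  }
  body <- vapply(seq_len(m), function(j) {
    tok(ds$geno[, j], map$allele1[j], map$allele2[j])
  }, character(n))
  body <- matrix(body, nrow = n)
  lines <- vapply(seq_len(n), function(i) {
    paste(ds$sample_ids[i], ds$sample_ids[i], "0", "0", "0", "-9",
          paste(body[i, ], collapse = " "))
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Reads PLINK 1 binary files (magic bytes `0x6c 0x1b`, SNP-major layout).
#' The resulting dataset is identical to [read_plink_text()] on equivalent
#' content: minor-allele orientation is recomputed after decoding.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files.
#' @return A `genotype_dataset`.
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  stopifnot(file.exists(bed_path), file.exists(bim_path),
            file.exists(fam_path))
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "bp", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  sample_ids <- fam[[2]]
  n <- length(sample_ids)
  m <- nrow(bim)
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK v1 .bed file (bad magic bytes)")
  }
  if (raw[3] == as.raw(0x00)) {
    stop("individual-major .bed layout is not supported")
  }
  if (raw[3] != as.raw(0x01)) stop("unknown .bed mode byte")
  body <- raw[-(1:3)]
  if (length(body) != m * bytes_per_snp) {
    stop(".bed payload is ", length(body), " bytes; expected ",
         m * bytes_per_snp, " (truncated or corrupt file)")
  }
  # unpack 2-bit codes: 00=hom a1, 01=missing, 10=het, 11=hom a2
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8 * bytes_per_snp)
  lo <- bits[seq(1, 2 * n, by = 2), , drop = FALSE]
  hi <- bits[seq(2, 2 * n, by = 2), , drop = FALSE]
  code <- lo + 2L * hi                      # per-sample 2-bit value
  a2count <- matrix(NA_integer_, n, m)
  a2count[code == 0L] <- 0L                 # hom a1
  a2count[code == 2L] <- 1L                 # het
  a2count[code == 3L] <- 2L                 # hom a2
  # re-orient so allele2 is the minor allele (tie -> lexicographically later)
  geno <- a2count
  al1 <- bim$a1
  al2 <- bim$a2
  for (j in seq_len(m)) {
    g <- geno[, j]
    labs <- c(bim$a1[j], bim$a2[j])
    cnt2 <- sum(g, na.rm = TRUE)
    cnt1 <- sum(2L - g, na.rm = TRUE)
    flip <- cnt1 < cnt2 ||
      (cnt1 == cnt2 && labs[1] > labs[2] && labs[1] != labs[2])
    if (flip) {
      geno[, j] <- 2L - g
      al1[j] <- labs[2]
      al2[j] <- labs[1]
    }
  }
  map <- tibble::tibble(snp_id = bim$snp_id, chrom = bim$chrom, bp = bim$bp,
                        allele1 = al1, allele2 = al2)
  genotype_dataset(geno, map, sample_ids)
}

#' Write PLINK binary genotypes (.bed/.bim/.fam)
#'
#' @param ds A `genotype_dataset`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink_binary <- function(ds, prefix) {
  n <- n_samples(ds)
  m <- n_snps(ds)
  readr::write_tsv(tibble::tibble(chrom = ds$map$chrom, snp_id = ds$map$snp_id,
                                  cm = 0, bp = ds$map$bp,
                                  a1 = ds$map$allele1, a2 = ds$map$allele2),
                   paste0(prefix, ".bim"), col_names = FALSE)
  writeLines(paste(ds$sample_ids, ds$sample_ids, "0", "0", "0", "-9"),
             paste0(prefix, ".fam"))
  bytes_per_snp <- ceiling(n / 4)
  code <- matrix(1L, 4 * bytes_per_snp, m)  # pad with missing code 01
  g <- ds$geno
  cc <- matrix(1L, n, m)
  cc[!is.na(g) & g == 0L] <- 0L
  cc[!is.na(g) & g == 1L] <- 2L
  cc[!is.na(g) & g == 2L] <- 3L
  code[seq_len(n), ] <- cc
  lo <- as.raw(code %% 2L)
  hi <- as.raw(code %/% 2L)
  bits <- as.raw(rbind(as.integer(lo), as.integer(hi)))
  dim(bits) <- c(8L, bytes_per_snp * m)
  payload <- packBits(as.logical(bits), "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(payload, con)
  invisible(prefix)
}
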