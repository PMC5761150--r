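#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses a PED/MAP pair into a [genotype_matrix()]. At each locus the allele
#' with the lower sample frequency is designated the B allele and genotypes
#' are coded as B-allele dosage; at a 50/50 frequency tie the
#' lexicographically later allele label is taken as B, so the coding is
#' deterministic and invariant to which label the file lists first. `0`
#' allele codes mark missing; a genotype with either allele missing is
#' treated as missing.
#'
#' @param ped_path path to the PED file (6 leading columns, then two allele
#'   columns per locus).
#' @param map_path path to the MAP file (3 or 4 columns; chromosome, locus
#'   id, optional cM, bp position).
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  if (!ncol(map) %in% c(3L, 4L))
    stop("MAP file must have 3 or 4 columns, found ", ncol(map))
  loci <- data.frame(chr = map[[1L]], id = map[[2L]],
                     pos = as.numeric(map[[ncol(map)]]))
  L <- nrow(loci)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  expect <- 6L + 2L * L
  bad <- which(nf != expect)
  if (length(bad)) {
    if (length(unique(nf)) > 1L)
      stop("ragged PED line ", bad[1L], ": has ", nf[bad[1L]],
           " fields, expected ", expect)
    stop("PED/MAP locus-count mismatch: PED implies ",
         (nf[1L] - 6L) / 2, " loci, MAP lists ", L)
  }
  ped <- do.call(rbind, fields)
  samples <- data.frame(
    id = ped[, 2L],
    sex = c("male", "female")[match(ped[, 5L], c("1", "2"))]
  )
  samples$sex[is.na(samples$sex)] <- "unknown"

  N <- nrow(ped)
  a1 <- ped[, 6L + 2L * seq_len(L) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(L), drop = FALSE]
  calls <- matrix(NA_integer_, N, L)
  loci$allele_a <- NA_character_
  loci$allele_b <- NA_character_
  for (j in seq_len(L)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- x1 != "0" & x2 != "0"
    alleles <- sort(unique(c(x1[ok], x2[ok])))
    if (length(alleles) > 2L)
      stop("locus ", loci$id[j], " has ", length(alleles),
           " alleles; only biallelic loci are supported")
    if (length(alleles) == 0L) next  # fully missing column
    ref <- alleles[1L]
    dose <- ifelse(ok, (x1 == ref) + (x2 == ref), NA_integer_)
    alt <- if (length(alleles) == 2L) alleles[2L] else NA_character_
    o <- orient_minor(dose, ref, alt)
    calls[, j] <- o$dose
    loci$allele_b[j] <- o$b
    loci$allele_a[j] <- o$a
  }
  genotype_matrix(calls, samples, loci)
}

# Orient a dosage vector so it counts the minor (B) allele.
# `lab` is the counted allele's label, `other` the alternative (NA if the
# locus is monomorphic in the sample). Tie at 0.5: B is the
# lexicographically later label.
orient_minor <- function(dose, lab, other) {
  n_obs <- sum(!is.na(dose))
  if (n_obs == 0L)
    return(list(dose = dose, a = lab, b = other))
  f <- sum(dose, na.rm = TRUE) / (2 * n_obs)
  flip <- f > 0.5 ||
    (f == 0.5 && !is.na(other) && lab < other)
  if (flip)
    list(dose = 2L - dose, a = lab, b = other)
  else
    list(dose = dose, a = other, b = lab)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' Inverse of [read_plink_text()]: missing calls become `0 0`, the MAP file
#' lists loci in matrix order with chromosome and bp position. Allele labels
#' come from the locus map (`allele_a`/`allele_b`); loci without stored
#' labels are written with placeholder labels `A`/`B`.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(g, prefix) {
  lab <- io_allele_labels(g$loci)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  sex_code <- c(male = "1", female = "2", unknown = "0")[g$samples$sex]
  N <- n_ind(g); L <- n_loci(g)
  geno <- matrix("0 0", N, L)
  for (j in seq_len(L)) {
    a <- lab$a[j]; b <- lab$b[j]
    gj <- g$calls[, j]
    geno[, j] <- c(paste(a, a), paste(a, b), paste(b, b))[gj + 1L]
    geno[is.na(gj), j] <- "0 0"
  }
  lines <- paste(g$samples$id, g$samples$id, "0", "0", sex_code, "-9",
                 apply(geno, 1L, paste, collapse = " "))
  writeLines(lines, ped_path)
  map <- data.frame(g$loci$chr, g$loci$id, 0, format(g$loci$pos,
                                                     scientific = FALSE,
                                                     trim = TRUE))
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

io_allele_labels <- function(loci) {
  a <- if (!is.null(loci$allele_a)) loci$allele_a else
    rep(NA_character_, nrow(loci))
  b <- if (!is.null(loci$allele_b)) loci$allele_b else
    rep(NA_character_, nrow(loci))
  fill_b <- is.na(b)
  b[fill_b] <- ifelse(is.na(a[fill_b]) | a[fill_b] != "B", "B", "A")
  a[is.na(a)] <- ifelse(b[is.na(a)] != "A", "A", "B")
  list(a = a, b = b)
}

PLINK_BED_MAGIC <- as.raw(c(0x6c, 0x1b))

#' Read PLINK binary genotypes (BED/BIM/FAM)
#'
#' Decodes a SNP-major PLINK 1 binary fileset (magic bytes `0x6c 0x1b`,
#' mode byte `0x01`). Two-bit codes per individual: `00` homozygous A1,
#' `01` missing, `10` heterozygous, `11` homozygous A2. The result follows
#' the same coding contract as [read_plink_text()]: dosages count the
#' sample-minor allele regardless of which allele the BIM lists as A1.
#'
#' @param bed_path,bim_path,fam_path paths to the three files.
#' @return A [genotype_matrix()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  stopifnot(file.exists(bed_path), file.exists(bim_path),
            file.exists(fam_path))
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = "character")
  if (ncol(bim) != 6L) stop("BIM file must have 6 columns")
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  if (ncol(fam) != 6L) stop("FAM file must have 6 columns")
  N <- nrow(fam); L <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:2], PLINK_BED_MAGIC))
    stop("not a PLINK 1 BED file: bad magic bytes")
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major BED files (mode byte 0x01) are supported")
  bpl <- ceiling(N / 4)  # bytes per locus
  if (length(raw) != 3L + bpl * L)
    stop("BED file truncated or inconsistent: expected ", 3 + bpl * L,
         " bytes for ", N, " individuals x ", L, " loci, found ",
         length(raw))
  bits <- as.integer(rawToBits(raw[-(1:3)]))
  dim(bits) <- c(8L * bpl, L)
  lo <- bits[seq(1L, 2L * N, by = 2L), , drop = FALSE]
  hi <- bits[seq(2L, 2L * N, by = 2L), , drop = FALSE]
  code <- lo + 2L * hi                      # 0 homA1, 1 missing, 2 het, 3 homA2
  dose_a1 <- matrix(c(2L, NA, 1L, 0L)[code + 1L], N, L)

  samples <- data.frame(
    id = fam[[2L]],
    sex = c("male", "female")[match(fam[[5L]], c("1", "2"))]
  )
  samples$sex[is.na(samples$sex)] <- "unknown"
  loci <- data.frame(chr = bim[[1L]], id = bim[[2L]],
                     pos = as.numeric(bim[[4L]]))
  loci$allele_a <- NA_character_
  loci$allele_b <- NA_character_
  calls <- dose_a1
  for (j in seq_len(L)) {
    a1 <- bim[[5L]][j]; a2 <- bim[[6L]][j]
    if (a1 == "0") a1 <- NA_character_
    if (a2 == "0") a2 <- NA_character_
    o <- orient_minor(dose_a1[, j], a1, a2)
    calls[, j] <- o$dose
    loci$allele_a[j] <- o$a
    loci$allele_b[j] <- o$b
  }
  genotype_matrix(calls, samples, loci)
}

#' Write PLINK binary genotypes (BED/BIM/FAM)
#'
#' SNP-major PLINK 1 layout; A1 in the BIM is the counted (minor) allele.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix; writes `.bed`, `.bim` and `.fam`.
#' @return Invisibly, the three file paths.
#' @export
write_plink_binary <- function(g, prefix) {
  lab <- io_allele_labels(g$loci)
  N <- n_ind(g); L <- n_loci(g)
  bpl <- ceiling(N / 4)
  # dosage -> 2-bit code (counted allele is A1): 2->homA1(00), 1->het(10),
  # 0->homA2(11), NA->missing(01); padding individuals are 00
  code <- matrix(0L, 4L * bpl, L)
  d <- g$calls
  code[seq_len(N), ] <- ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  lo <- code %% 2L
  hi <- code %/% 2L
  bits <- matrix(0L, 8L * bpl, L)
  bits[seq(1L, 8L * bpl, by = 2L), ] <- lo
  bits[seq(2L, 8L * bpl, by = 2L), ] <- hi
  payload <- packBits(as.logical(bits), "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(c(PLINK_BED_MAGIC, as.raw(0x01)), con)
  writeBin(payload, con)
  close(con)

  bim <- data.frame(g$loci$chr, g$loci$id, 0,
                    format(g$loci$pos, scientific = FALSE, trim = TRUE),
                    ifelse(is.na(lab$b), "0", lab$b),
                    ifelse(is.na(lab$a), "0", lab$a))
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  sex_code <- c(male = "1", female = "2", unknown = "0")[g$samples$sex]
  fam <- data.frame(g$samples$id, g$samples$id, 0, 0, sex_code, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
              fam = paste0(prefix, ".fam")))
}
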