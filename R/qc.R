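#' Locus quality-control filters
#'
#' Applies the standard SNP-array locus filters in sequence: drop unmapped
#' loci, drop sex-chromosome loci (keeping the 38 canine autosomes), drop
#' loci with call rate below `min_call_rate`, then drop loci with minor
#' allele frequency below `min_maf` (computed on non-missing calls).
#' Thresholds are inclusive: a locus exactly at the threshold is kept.
#' Removal reasons are counted in that order, so each locus is attributed
#' to the first filter that would remove it.
#'
#' @param g a [genotype_matrix()].
#' @param min_call_rate minimum locus call rate (fraction), default 0.95.
#' @param min_maf minimum minor allele frequency, default 0.05.
#' @param autosomes_only drop unmapped and sex-chromosome loci, default
#'   `TRUE`.
#' @return A list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`).
#' @export
filter_loci <- function(g, min_call_rate = 0.95, min_maf = 0.05,
                        autosomes_only = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  cls <- chrom_class(g$loci$chr)
  keep <- rep(TRUE, n_loci(g))
  reason <- rep(NA_character_, n_loci(g))
  if (autosomes_only) {
    reason[keep & cls == "unmapped"] <- "unmapped"
    keep[cls == "unmapped"] <- FALSE
    reason[keep & cls == "sex"] <- "sex_chrom"
    keep[cls == "sex"] <- FALSE
  }
  n_obs <- colSums(!is.na(g$calls))
  call_rate <- n_obs / n_ind(g)
  fail_cr <- call_rate < min_call_rate
  reason[keep & fail_cr] <- "call_rate"
  keep <- keep & !fail_cr
  q <- ifelse(n_obs > 0, colSums(g$calls, na.rm = TRUE) / (2 * n_obs), NA)
  maf <- pmin(q, 1 - q)
  fail_maf <- is.na(maf) | maf < min_maf
  reason[keep & fail_maf] <- "maf"
  keep <- keep & !fail_maf
  if (!any(keep))
    stop("QC removed all loci (", n_loci(g), " in); nothing to analyse")
  report <- qc_report(
    n_loci_in = n_loci(g), n_loci_out = sum(keep),
    n_removed_unmapped = sum(reason == "unmapped", na.rm = TRUE),
    n_removed_sex_chrom = sum(reason == "sex_chrom", na.rm = TRUE),
    n_removed_callrate = sum(reason == "call_rate", na.rm = TRUE),
    n_removed_maf = sum(reason == "maf", na.rm = TRUE),
    n_individuals_in = n_ind(g), n_individuals_out = n_ind(g),
    n_individuals_removed = 0L,
    thresholds = list(min_call_rate = min_call_rate, min_maf = min_maf,
                      autosomes_only = autosomes_only)
  )
  list(genotypes = subset_genotypes(g, loci = which(keep)), report = report)
}

#' Individual quality-control filter
#'
#' Removes individuals with over `max_missing` missing genotypes across the
#' current loci. The rule is strictly "over": an individual with exactly
#' `max_missing` missingness is retained.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing maximum tolerated per-individual missing fraction,
#'   default 0.10.
#' @return A list with `genotypes` and `report` as in [filter_loci()].
#' @export
filter_individuals <- function(g, max_missing = 0.10) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- rowMeans(is.na(g$calls))
  keep <- miss <= max_missing
  if (!any(keep))
    stop("QC removed all ", n_ind(g), " individuals (missingness > ",
         max_missing, ")")
  report <- qc_report(
    n_loci_in = n_loci(g), n_loci_out = n_loci(g),
    n_removed_unmapped = 0L, n_removed_sex_chrom = 0L,
    n_removed_callrate = 0L, n_removed_maf = 0L,
    n_individuals_in = n_ind(g), n_individuals_out = sum(keep),
    n_individuals_removed = sum(!keep),
    thresholds = list(max_ind_missing = max_missing)
  )
  list(genotypes = subset_genotypes(g, individuals = which(keep)),
       report = report)
}

#' Full quality control: locus filters then individual filter
#'
#' Single pass, no iteration to convergence: locus filters are applied
#' first, then individual missingness is evaluated on the surviving loci.
#'
#' @inheritParams filter_loci
#' @inheritParams filter_individuals
#' @return A list with `genotypes` and a combined `report`.
#' @export
qc_filter <- function(g, min_call_rate = 0.95, min_maf = 0.05,
                      autosomes_only = TRUE, max_missing = 0.10) {
  l <- filter_loci(g, min_call_rate, min_maf, autosomes_only)
  i <- filter_individuals(l$genotypes, max_missing)
  rep <- l$report
  rep$n_individuals_out <- i$report$n_individuals_out
  rep$n_individuals_removed <- i$report$n_individuals_removed
  rep$thresholds$max_ind_missing <- max_missing
  list(genotypes = i$genotypes, report = rep)
}

qc_report <- function(...) {
  r <- list(...)
  stopifnot(r$n_loci_in - r$n_removed_unmapped - r$n_removed_sex_chrom -
              r$n_removed_callrate - r$n_removed_maf == r$n_loci_out)
  structure(r, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  loci: %d in -> %d out\n", x$n_loci_in, x$n_loci_out))
  cat(sprintf("    removed: unmapped=%d sex=%d call-rate=%d maf=%d\n",
              x$n_removed_unmapped, x$n_removed_sex_chrom,
              x$n_removed_callrate, x$n_removed_maf))
  cat(sprintf("  individuals: %d in -> %d out (removed %d)\n",
              x$n_individuals_in, x$n_individuals_out,
              x$n_individuals_removed))
  invisible(x)
}

#' @export
format.qc_report <- function(x, ...) {
  keys <- c("n_loci_in", "n_loci_out", "n_removed_unmapped",
            "n_removed_sex_chrom", "n_removed_callrate", "n_removed_maf",
            "n_individuals_in", "n_individuals_out",
            "n_individuals_removed")
  paste(keys, unlist(x[keys]), sep = "\t")
}
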