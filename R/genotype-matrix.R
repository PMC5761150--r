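#' Genotype matrix container
#'
#' Bundles a dosage matrix with its sample sheet and locus map. Calls count
#' copies of the B (minor) allele: 0, 1, 2, or `NA` for a missing genotype.
#'
#' @param calls integer matrix, individuals in rows and loci in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples data.frame with columns `id` (unique) and `sex`
#'   (`"male"`, `"female"` or `"unknown"`).
#' @param loci data.frame with columns `chr` (character label), `pos`
#'   (1-based bp, integer-valued), `id` (unique locus identifier) and
#'   optionally `allele_a`/`allele_b` (major/minor allele labels, used when
#'   writing PLINK files).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, samples, loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1L || ncol(calls) < 1L)
    stop("genotype matrix must have at least one individual and one locus")
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
    stop("calls must be 0, 1, 2 or NA")
  samples <- as.data.frame(samples)
  loci <- as.data.frame(loci)
  if (nrow(samples) != nrow(calls))
    stop("sample sheet rows (", nrow(samples), ") do not match call rows (",
         nrow(calls), ")")
  if (nrow(loci) != ncol(calls))
    stop("locus map rows (", nrow(loci), ") do not match call columns (",
         ncol(calls), ")")
  if (anyDuplicated(samples$id)) stop("sample ids must be unique")
  if (anyDuplicated(loci$id)) stop("locus ids must be unique")
  if (is.null(samples$sex)) samples$sex <- "unknown"
  samples$sex <- ifelse(samples$sex %in% c("male", "female"),
                        samples$sex, "unknown")
  loci$chr <- as.character(loci$chr)
  if (any(loci$pos < 1)) stop("locus positions must be >= 1 (1-based bp)")
  loci$pos <- as.numeric(loci$pos)
  dimnames(calls) <- list(samples$id, loci$id)
  structure(list(calls = calls, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "loci\n")
  tab <- table(chrom_class(x$loci$chr))
  cat("  loci by class:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Number of individuals / loci
#' @param g a [genotype_matrix()].
#' @return Integer count.
#' @export
n_ind <- function(g) nrow(g$calls)

#' @rdname n_ind
#' @export
n_loci <- function(g) ncol(g$calls)

#' Classify chromosome labels
#'
#' Canine autosomes are labelled 1-38; `X`/`Y` (and PLINK's numeric dog codes
#' 39/40) are sex chromosomes; anything else - including PLINK's `0` - is
#' treated as unmapped.
#'
#' @param chr character vector of chromosome labels.
#' @return Character vector with values `"autosome"`, `"sex"`, `"unmapped"`.
#' @export
chrom_class <- function(chr) {
  chr <- as.character(chr)
  out <- rep("unmapped", length(chr))
  out[chr %in% as.character(1:38)] <- "autosome"
  out[chr %in% c("X", "Y", "39", "40", "XY")] <- "sex"
  out
}

#' Subset a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param individuals logical/integer index or character ids of rows to keep.
#' @param loci logical/integer index or character ids of columns to keep.
#' @return The subset `genotype_matrix`.
#' @export
subset_genotypes <- function(g, individuals = NULL, loci = NULL) {
  ri <- if (is.null(individuals)) seq_len(n_ind(g)) else individuals
  if (is.character(ri)) ri <- match(ri, g$samples$id)
  ci <- if (is.null(loci)) seq_len(n_loci(g)) else loci
  if (is.character(ci)) ci <- match(ci, g$loci$id)
  genotype_matrix(g$calls[ri, ci, drop = FALSE],
                  g$samples[ri, , drop = FALSE],
                  g$loci[ci, , drop = FALSE])
}

#' Sort loci by chromosome and position
#'
#' Orders columns by chromosome label (numeric labels first, in numeric
#' order) and bp position within chromosome.
#'
#' @param g a [genotype_matrix()].
#' @return The `genotype_matrix` with loci sorted.
#' @export
sort_loci <- function(g) {
  key <- chrom_order_key(g$loci$chr)
  subset_genotypes(g, loci = order(key, g$loci$pos))
}

chrom_order_key <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  key <- ifelse(is.na(num), match(chr, sort(unique(chr[is.na(num)]))) + 1e6,
                num)
  key
}

loci_sorted <- function(loci) {
  all(unlist(lapply(split(loci$pos, loci$chr), function(p) !is.unsorted(p))))
}

#' Published genotyping survey of the Braque Francais, type Pyrenees breed
#'
#' Headline constants from the published genome-wide SNP survey of the
#' Braque Francais, type Pyrenees hunting dog (48 dogs on the Illumina
#' CanineHD array). Used as reference inputs for consistency checks and as
#' realistic defaults for the simulator: the ROH length-class table (counts
#' and mean length per class), the post-QC SNP count, sample size, mean
#' observed heterozygosity and the SNP-covered autosome length.
#'
#' @return A list with elements `n_dogs`, `n_snps_postqc`, `mean_h_o`,
#'   `l_auto_mb`, `alpha` and `roh_classes` (data.frame with `class_lo_mb`,
#'   `class_hi_mb`, `n_runs`, `mean_length_mb`).
#' @export
bfp_summary <- function() {
  list(
    n_dogs = 48L,
    n_snps_postqc = 94065L,
    mean_h_o = 0.371,
    l_auto_mb = 2268.83,
    alpha = 0.05,
    roh_classes = data.frame(
      class_lo_mb = c(1, 2, 4, 8),
      class_hi_mb = c(2, 4, 8, 16),
      n_runs = c(3390L, 1752L, 463L, 29L),
      mean_length_mb = c(1.43, 2.67, 5.16, 9.22)
    )
  )
}
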