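#' Per-locus diversity statistics
#'
#' For each locus, allele frequencies from non-missing calls, minor allele
#' frequency, observed heterozygosity (heterozygote count over non-missing
#' individuals) and Hardy-Weinberg expected heterozygosity
#' `h_e = 1 - p^2 - q^2`. Loci with zero non-missing calls are flagged
#' undefined (`defined = FALSE`, statistics `NA`) rather than propagating
#' `NaN`.
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with one row per locus: `locus_id`, `chr`, `pos`,
#'   `n_obs`, `n_het`, `p` (major), `q` (minor), `maf`, `h_o`, `h_e`,
#'   `defined`.
#' @export
locus_stats <- function(g) {
  n_obs <- colSums(!is.na(g$calls))
  n_het <- colSums(g$calls == 1L, na.rm = TRUE)
  fb <- ifelse(n_obs > 0, colSums(g$calls, na.rm = TRUE) / (2 * n_obs), NA)
  maf <- pmin(fb, 1 - fb)
  h_o <- ifelse(n_obs > 0, n_het / n_obs, NA)
  h_e <- 1 - (1 - maf)^2 - maf^2
  data.frame(
    locus_id = g$loci$id, chr = g$loci$chr, pos = g$loci$pos,
    n_obs = n_obs, n_het = n_het,
    p = 1 - maf, q = maf, maf = maf, h_o = h_o, h_e = h_e,
    defined = n_obs > 0,
    row.names = NULL
  )
}

#' Mean diversity indices over loci
#'
#' Unweighted means and population standard deviations (divisor `L`) of
#' per-locus observed heterozygosity, expected heterozygosity and MAF, plus
#' the population inbreeding index `F_IS`, the per-locus average of
#' `1 - h_o/h_e`. Loci monomorphic in the sample (`h_e == 0`) have an
#' undefined `F_IS` term and are excluded from the `F_IS` average only;
#' undefined loci are excluded from all averages.
#'
#' @param stats per-locus table from [locus_stats()].
#' @return A list of class `diversity_summary`: `mean_h_o`, `sd_h_o`,
#'   `mean_h_e`, `sd_h_e`, `mean_maf`, `sd_maf`, `f_is`, `n_loci`,
#'   `n_loci_f_is`.
#' @export
diversity_summary <- function(stats) {
  if (!nrow(stats)) stop("empty locus-stats table")
  s <- stats[stats$defined, , drop = FALSE]
  if (!nrow(s)) stop("no locus has defined statistics")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  fis_ok <- s$h_e > 0
  structure(list(
    mean_h_o = mean(s$h_o), sd_h_o = pop_sd(s$h_o),
    mean_h_e = mean(s$h_e), sd_h_e = pop_sd(s$h_e),
    mean_maf = mean(s$maf), sd_maf = pop_sd(s$maf),
    f_is = if (any(fis_ok)) mean(1 - s$h_o[fis_ok] / s$h_e[fis_ok]) else
      NA_real_,
    n_loci = nrow(s), n_loci_f_is = sum(fis_ok)
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("H_O  = %.4f (sd %.4f)\n", x$mean_h_o, x$sd_h_o))
  cat(sprintf("H_E  = %.4f (sd %.4f)\n", x$mean_h_e, x$sd_h_e))
  cat(sprintf("MAF  = %.4f (sd %.4f)\n", x$mean_maf, x$sd_maf))
  cat(sprintf("F_IS = %.4f (over %d loci)\n", x$f_is, x$n_loci_f_is))
  invisible(x)
}

#' Per-individual molecular inbreeding coefficient
#'
#' Method-of-moments estimator from the excess of observed over expected
#' homozygous genotypes:
#' `F_i = (O_hom - E_hom) / (L_i - E_hom)`, where `O_hom` is the observed
#' homozygote count over the individual's `L_i` non-missing loci and
#' `E_hom = sum_l (1 - 2 p_l q_l)` the Hardy-Weinberg expectation at the
#' cohort's sample allele frequencies. Negative values indicate
#' heterozygosity above expectation. Individuals with no usable loci get
#' `NA`.
#'
#' @param g a [genotype_matrix()], typically post-QC.
#' @return Named numeric vector of F, one entry per individual.
#' @export
per_individual_F <- function(g) {
  st <- locus_stats(g)
  exp_hom_l <- 1 - 2 * st$p * st$q   # per-locus P(homozygous) under HWE
  exp_hom_l[!st$defined] <- 0        # undefined loci contribute nothing
  obs <- !is.na(g$calls)
  usable <- obs & rep(st$defined, each = n_ind(g))
  L_i <- rowSums(usable)
  o_hom <- rowSums(g$calls != 1L & usable, na.rm = TRUE)
  e_hom <- as.vector(usable %*% exp_hom_l)
  f <- ifelse(L_i > 0 & (L_i - e_hom) != 0,
              (o_hom - e_hom) / (L_i - e_hom), NA_real_)
  stats::setNames(f, g$samples$id)
}

#' Per-group locus statistics on a chromosome subset
#'
#' Descriptive SNP statistics within sample groups (typically the sexes),
#' restricted to a chromosome subset (typically X and Y): proportion of
#' loci monomorphic within the group, mean MAF over loci with defined
#' frequencies, and overall missing rate.
#'
#' @param g a [genotype_matrix()].
#' @param grouping either the string `"sex"` (group by the sample sheet's
#'   sex column) or a vector of group labels, one per individual.
#' @param chromosome_subset chromosome labels to restrict to; `NULL` keeps
#'   all.
#' @return data.frame with columns `group`, `n_individuals`, `n_loci`,
#'   `prop_monomorphic`, `mean_maf`, `missing_rate`.
#' @export
per_group_locus_stats <- function(g, grouping = "sex",
                                  chromosome_subset = NULL) {
  labels <- if (identical(grouping, "sex")) g$samples$sex else grouping
  if (length(labels) != n_ind(g))
    stop("grouping must name one group per individual")
  if (!is.null(chromosome_subset)) {
    keep <- g$loci$chr %in% as.character(chromosome_subset)
    if (!any(keep)) stop("no loci on the requested chromosomes")
    g <- subset_genotypes(g, loci = which(keep))
  }
  groups <- unique(labels)
  rows <- lapply(groups, function(grp) {
    gi <- subset_genotypes(g, individuals = which(labels == grp))
    st <- locus_stats(gi)
    def <- st$defined
    data.frame(
      group = grp,
      n_individuals = n_ind(gi),
      n_loci = n_loci(gi),
      prop_monomorphic = mean(st$maf[def] == 0),
      mean_maf = mean(st$maf[def]),
      missing_rate = mean(is.na(gi$calls))
    )
  })
  do.call(rbind, rows)
}
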