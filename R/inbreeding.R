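#' SNP-covered autosome lengths
#'
#' Length of genome covered by SNPs, per chromosome (max minus min mapped
#' position plus one) and in total (`l_auto`), computed from a locus map.
#' By default only autosomes (labels 1-38) contribute, matching the
#' denominator convention of the ROH-based inbreeding coefficient.
#'
#' @param loci locus map data.frame (`chr`, `pos`) or a
#'   [genotype_matrix()].
#' @param autosomes_only restrict to autosomal labels, default `TRUE`.
#' @return A list of class `genome_info`: `autosome_lengths` (named bp
#'   vector) and `l_auto` (their sum).
#' @export
genome_info <- function(loci, autosomes_only = TRUE) {
  if (inherits(loci, "genotype_matrix")) loci <- loci$loci
  if (autosomes_only) {
    loci <- loci[chrom_class(loci$chr) == "autosome", , drop = FALSE]
    if (!nrow(loci)) stop("no autosomal loci in the map")
  }
  lens <- vapply(split(loci$pos, loci$chr),
                 function(p) max(p) - min(p) + 1, numeric(1))
  structure(list(autosome_lengths = lens, l_auto = sum(lens)),
            class = "genome_info")
}

#' ROH-based inbreeding coefficient per individual
#'
#' `F_ROH` is the summed length of an individual's ROH segments divided by
#' the SNP-covered autosome length `l_auto`. Individuals without segments
#' get `F_ROH = 0`.
#'
#' @param segments segment table from [call_roh()].
#' @param genome a [genome_info()].
#' @param individuals character vector of all individual ids (so that
#'   segment-free individuals are reported too).
#' @return data.frame `individual_id`, `n_segments`, `sum_l_roh` (bp),
#'   `f_roh`.
#' @export
f_roh_per_individual <- function(segments, genome, individuals) {
  stopifnot(genome$l_auto > 0)
  if (nrow(segments) && !all(segments$individual_id %in% individuals))
    stop("segments refer to individuals absent from `individuals`")
  if (nrow(segments)) {
    known <- segments$chr %in% names(genome$autosome_lengths)
    too_long <- known &
      segments$length_bp > genome$autosome_lengths[segments$chr]
    if (any(too_long))
      stop("segment longer than its chromosome's SNP-covered length: ",
           paste(segments$individual_id[too_long][1L],
                 segments$chr[too_long][1L]))
  }
  sum_l <- stats::setNames(numeric(length(individuals)), individuals)
  n_seg <- stats::setNames(integer(length(individuals)), individuals)
  if (nrow(segments)) {
    agg <- tapply(segments$length_bp, segments$individual_id, sum)
    sum_l[names(agg)] <- agg
    cnt <- table(segments$individual_id)
    n_seg[names(cnt)] <- as.integer(cnt)
  }
  data.frame(individual_id = individuals, n_segments = as.integer(n_seg),
             sum_l_roh = as.numeric(sum_l),
             f_roh = as.numeric(sum_l) / genome$l_auto, row.names = NULL)
}

#' Per-individual inbreeding table
#'
#' Joins ROH-based inbreeding (`f_roh`) with the marker-based
#' method-of-moments coefficient (`f_marker`, from [per_individual_F()])
#' for every individual in the matrix.
#'
#' @param g the post-QC [genotype_matrix()] the segments were called on.
#' @param segments segment table from [call_roh()].
#' @param genome a [genome_info()]; defaults to `genome_info(g)`.
#' @return data.frame `individual_id`, `n_segments`, `sum_l_roh`,
#'   `f_roh`, `f_marker`.
#' @export
inbreeding_table <- function(g, segments, genome = genome_info(g)) {
  tab <- f_roh_per_individual(segments, genome, g$samples$id)
  tab$f_marker <- as.numeric(per_individual_F(g)[tab$individual_id])
  tab
}

#' Pearson correlation between the two molecular inbreeding measures
#'
#' @param records table from [inbreeding_table()] (needs columns `f_roh`
#'   and `f_marker`) with at least 3 complete rows.
#' @return Pearson r, or `NA` (with a warning) when either measure has
#'   zero variance.
#' @export
correlate_inbreeding <- function(records) {
  ok <- stats::complete.cases(records[, c("f_roh", "f_marker")])
  x <- records$f_roh[ok]; y <- records$f_marker[ok]
  if (length(x) < 3L)
    stop("need at least 3 individuals with both inbreeding measures")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in an inbreeding measure; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
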