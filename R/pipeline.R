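#' Run the full diversity / ROH / Ne pipeline
#'
#' Orchestrates every stage on one genotype set: quality control, locus
#' and summary diversity statistics, per-individual marker inbreeding, ROH
#' calling with the derived minimum-SNP threshold, length-class table,
#' per-SNP incidence and island list, ROH-based inbreeding with the
#' correlation between the two molecular measures, VIF pruning and the
#' LD-based Ne estimate. All tabular outputs are written tab-separated to
#' `out_dir` (if given); figures are a convenience layer over tables that
#' are always also written. Any stage failure is re-signalled with the
#' stage name. The run is deterministic given the input (no stage draws
#' random numbers).
#'
#' @param g a [genotype_matrix()], or a PLINK path prefix (expects
#'   `.ped/.map` or `.bed/.bim/.fam`).
#' @param out_dir output directory for tables (and figures); `NULL` skips
#'   writing.
#' @param qc list of arguments for [qc_filter()].
#' @param roh a [roh_params()].
#' @param prune a [prune_params()]; set to `NULL` to skip pruning.
#' @param ne list of arguments for [estimate_ne()] (besides the data);
#'   set to `NULL` to skip the Ne stage.
#' @param island_threshold shared fraction defining ROH islands.
#' @param make_plots also write the incidence Manhattan plot and, for the
#'   chromosome with the strongest island (or the first chromosome), the
#'   per-individual ROH plot. Requires `out_dir`.
#' @return A list bundle: `qc_report`, `genotypes` (post-QC),
#'   `locus_stats`, `diversity`, `roh_segments`, `roh_classes`,
#'   `incidence`, `islands`, `inbreeding`, `inbreeding_correlation`,
#'   `pruned_ids`, `ne`.
#' @export
run_pipeline <- function(g, out_dir = NULL, qc = list(), roh = roh_params(),
                         prune = prune_params(), ne = list(),
                         island_threshold = 0.75, make_plots = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(g)) {
    g <- stage("input", {
      if (file.exists(paste0(g, ".bed")))
        read_plink_binary(paste0(g, ".bed"), paste0(g, ".bim"),
                          paste0(g, ".fam"))
      else
        read_plink_text(paste0(g, ".ped"), paste0(g, ".map"))
    })
  }
  qcres <- stage("qc", do.call(qc_filter, c(list(g), qc)))
  gq <- stage("qc", sort_loci(qcres$genotypes))
  st <- stage("diversity", locus_stats(gq))
  div <- stage("diversity", diversity_summary(st))
  segs <- stage("roh", call_roh(gq, roh))
  classes <- stage("roh", roh_length_classes(segs))
  inc <- stage("roh", snp_roh_incidence(segs, gq$loci, n_ind(gq)))
  isl <- stage("roh", roh_islands(inc, threshold = island_threshold))
  inb <- stage("inbreeding", inbreeding_table(gq, segs))
  corr <- stage("inbreeding",
                tryCatch(correlate_inbreeding(inb),
                         warning = function(w) NA_real_))
  pruned <- if (is.null(prune)) NULL else
    stage("prune", vif_prune(gq, prune))
  ne_est <- if (is.null(ne)) NULL else
    stage("ne", do.call(estimate_ne, c(list(gq, retained = pruned), ne)))
  bundle <- list(qc_report = qcres$report, genotypes = gq, locus_stats = st,
                 diversity = div, roh_segments = segs,
                 roh_classes = classes, incidence = inc, islands = isl,
                 inbreeding = inb, inbreeding_correlation = corr,
                 pruned_ids = pruned, ne = ne_est)
  if (!is.null(out_dir))
    stage("report", write_bundle(bundle, out_dir, make_plots))
  bundle
}

write_bundle <- function(b, out_dir, make_plots) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name)
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  writeLines(format(b$qc_report), file.path(out_dir, "qc_report.tsv"))
  tsv(b$locus_stats, "locus_stats.tsv")
  d <- b$diversity
  writeLines(paste(names(unclass(d)), unlist(unclass(d)), sep = "\t"),
             file.path(out_dir, "diversity_summary.tsv"))
  segs <- b$roh_segments
  segs$length_kb <- segs$length_bp / 1e3
  tsv(segs[, c("individual_id", "chr", "start_bp", "end_bp", "n_snps",
               "length_kb")], "roh_segments.tsv")
  write_segments_bed(b$roh_segments, file.path(out_dir, "roh_segments.bed"))
  tsv(b$roh_classes, "roh_length_classes.tsv")
  tsv(b$incidence, "roh_incidence.tsv")
  tsv(b$islands, "roh_islands.tsv")
  tsv(b$inbreeding, "inbreeding.tsv")
  writeLines(paste0("pearson_r\t", b$inbreeding_correlation),
             file.path(out_dir, "inbreeding_correlation.tsv"))
  if (!is.null(b$pruned_ids))
    writeLines(b$pruned_ids, file.path(out_dir, "pruned_loci.txt"))
  if (!is.null(b$ne)) {
    x <- b$ne
    writeLines(paste(names(unclass(x)), unlist(unclass(x)), sep = "\t"),
               file.path(out_dir, "ne_estimate.tsv"))
  }
  if (make_plots) {
    p <- plot_incidence(b$incidence)
    ggplot2::ggsave(file.path(out_dir, "roh_incidence.png"), p,
                    width = 9, height = 3.2, dpi = 150)
    chr <- if (nrow(b$islands)) {
      b$islands$chr[which.max(b$islands$peak_fraction)]
    } else unique(b$genotypes$loci$chr)[1L]
    p2 <- plot_roh_per_individual(b$roh_segments, chr,
                                  individuals = b$genotypes$samples$id)
    ggplot2::ggsave(file.path(out_dir,
                              paste0("roh_chr", chr, ".png")), p2,
                    width = 7, height = 5, dpi = 150)
  }
  invisible(NULL)
}

#' Export ROH segments as BED intervals
#'
#' BED uses 0-based half-open coordinates; the 1-based inclusive segment
#' `[start_bp, end_bp]` is written as `start_bp - 1, end_bp`.
#'
#' @param segments segment table from [call_roh()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(segments$chr,
                    format(segments$start_bp - 1, scientific = FALSE,
                           trim = TRUE),
                    format(segments$end_bp, scientific = FALSE, trim = TRUE),
                    segments$individual_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Manhattan plot of per-SNP ROH incidence
#'
#' Genome-wide scatter of the fraction of individuals whose ROH cover each
#' SNP, ordered by chromosome then position, with alternating chromosome
#' shading.
#'
#' @param incidence table from [snp_roh_incidence()].
#' @return A ggplot object.
#' @export
plot_incidence <- function(incidence) {
  if (!nrow(incidence)) stop("empty incidence track")
  key <- chrom_order_key(incidence$chr)
  d <- incidence[order(key, incidence$pos), , drop = FALSE]
  d$x <- seq_len(nrow(d))
  d$band <- factor(chrom_order_key(d$chr) %% 2)
  mids <- tapply(d$x, d$chr, stats::median)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$incidence,
                                  colour = .data$band)) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey25", "steelblue")) +
    ggplot2::scale_x_continuous(breaks = as.numeric(mids),
                                labels = names(mids)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "chromosome", y = "fraction of individuals in ROH") +
    ggplot2::theme_minimal()
}

#' Per-individual ROH plot for one chromosome
#'
#' One horizontal lane per individual (sorted by id), ROH drawn as bars at
#' bp coordinates.
#'
#' @param segments segment table from [call_roh()].
#' @param chromosome chromosome label to plot.
#' @param individuals ids to lay out as lanes; defaults to the ids present
#'   in `segments`.
#' @return A ggplot object.
#' @export
plot_roh_per_individual <- function(segments, chromosome,
                                    individuals = NULL) {
  if (is.null(individuals)) individuals <- unique(segments$individual_id)
  if (!nrow(segments[segments$chr == chromosome, , drop = FALSE]) &&
      !length(individuals))
    stop("unknown chromosome: ", chromosome)
  lanes <- sort(unique(as.character(individuals)))
  d <- segments[segments$chr == chromosome, , drop = FALSE]
  d$lane <- match(d$individual_id, lanes)
  if (nrow(d) && anyNA(d$lane))
    stop("segments contain individuals absent from `individuals`")
  p <- ggplot2::ggplot() +
    ggplot2::scale_y_continuous(breaks = seq_along(lanes), labels = lanes,
                                limits = c(0.5, length(lanes) + 0.5)) +
    ggplot2::labs(x = paste0("position on chromosome ", chromosome,
                             " (bp)"), y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(d))
    p <- p + ggplot2::geom_rect(
      data = d,
      ggplot2::aes(xmin = .data$start_bp, xmax = .data$end_bp,
                   ymin = .data$lane - 0.4, ymax = .data$lane + 0.4),
      fill = "firebrick")
  p
}
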