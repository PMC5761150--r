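#' Minimum SNP count for a run of homozygosity (Lencz threshold)
#'
#' The smallest run length `s` (in SNPs) such that the expected number of
#' chance runs across all `N` individuals and `L` loci stays below `alpha`:
#' `s = ceiling( ln(alpha / (N * L)) / ln(1 - mean_het) )`.
#'
#' @param alpha tolerated proportion of false-positive runs, default 0.05.
#' @param n_individuals sample size N.
#' @param n_loci number of SNP loci L.
#' @param mean_het mean observed heterozygosity across individuals and
#'   loci, strictly inside (0, 1).
#' @return Integer minimum SNP count, strictly positive.
#' @export
lencz_min_snps <- function(alpha = 0.05, n_individuals, n_loci, mean_het) {
  stopifnot(alpha > 0, alpha < 1, n_individuals >= 1, n_loci >= 1)
  if (!is.finite(mean_het) || mean_het <= 0 || mean_het >= 1)
    stop("mean_het must lie strictly between 0 and 1")
  s <- ceiling(log(alpha / (n_individuals * n_loci)) / log(1 - mean_het))
  max(1L, as.integer(s))
}

#' Parameters of the sliding-window ROH caller
#'
#' Defaults follow common SNP-array practice for canine HD data: a 50-SNP
#' scanning window, at most one heterozygous and two missing calls per
#' window, a SNP joins a run when at least 5% of the windows covering it
#' are homozygous, runs must span at least 1 Mb with at least one SNP per
#' 50 kb and no gap between consecutive SNPs above 100 kb.
#'
#' @param window_snps scanning window size in SNPs.
#' @param window_threshold minimum fraction of homozygous windows covering
#'   a SNP for it to enter a run (inclusive).
#' @param max_het_per_window heterozygous calls tolerated per window.
#' @param max_missing_per_window missing calls tolerated per window.
#' @param min_length_bp minimum run length in bp (inclusive).
#' @param min_snps minimum SNPs per run; `NULL` (default) computes the
#'   Lencz threshold from the data at call time.
#' @param min_density_bp_per_snp maximum bp per SNP inside a run
#'   (inclusive; 50000 means at least one SNP every 50 kb).
#' @param max_gap_bp maximum gap between consecutive in-run SNPs.
#' @param alpha false-positive tolerance used when `min_snps` is derived.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50L, window_threshold = 0.05,
                       max_het_per_window = 1L, max_missing_per_window = 2L,
                       min_length_bp = 1e6, min_snps = NULL,
                       min_density_bp_per_snp = 5e4, max_gap_bp = 1e5,
                       alpha = 0.05) {
  stopifnot(window_snps >= 1, window_threshold >= 0, window_threshold <= 1,
            max_het_per_window >= 0, max_missing_per_window >= 0,
            min_length_bp > 0, min_density_bp_per_snp > 0, max_gap_bp > 0,
            alpha > 0, alpha < 1)
  structure(list(window_snps = as.integer(window_snps),
                 window_threshold = window_threshold,
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 min_length_bp = min_length_bp, min_snps = min_snps,
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 max_gap_bp = max_gap_bp, alpha = alpha),
            class = "roh_params")
}

#' Per-SNP homozygous-window fractions for one chromosome
#'
#' Slides a `window_snps`-wide window over one individual's position-sorted
#' calls. A window is homozygous when it holds at most
#' `max_het_per_window` heterozygous and `max_missing_per_window` missing
#' calls. Each SNP's fraction is the number of homozygous windows covering
#' it over the number of windows covering it (edge SNPs are covered by
#' fewer windows). Chromosomes with fewer SNPs than the window are
#' uncallable: all fractions are `NA`.
#'
#' @param calls integer dosage vector (0/1/2/NA) for one individual on one
#'   chromosome, in map order.
#' @param params a [roh_params()].
#' @return Numeric vector of fractions, one per SNP (`NA` if uncallable).
#' @export
window_homozygosity_fractions <- function(calls, params = roh_params()) {
  n <- length(calls)
  w <- params$window_snps
  if (n < w) return(rep(NA_real_, n))
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  roll <- function(x) {
    cs <- cumsum(x)
    cs[w:n] - c(0, cs[seq_len(n - w)])
  }
  hom_win <- roll(het) <= params$max_het_per_window &
    roll(mis) <= params$max_missing_per_window
  H <- c(0, cumsum(hom_win))          # prefix sums over the n - w + 1 windows
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, n - w + 1L)
  (H[hi + 1L] - H[lo]) / (hi - lo + 1L)
}

#' Call runs of homozygosity
#'
#' Sliding-window ROH detection per individual and chromosome. A SNP is a
#' run candidate when its homozygous-window fraction is at least
#' `window_threshold` and its own call is not heterozygous (missing calls
#' already tolerated by the window rule may sit inside a run). Maximal
#' stretches of consecutive candidates are split wherever adjacent SNPs
#' are more than `max_gap_bp` apart, trimmed to the outermost homozygous
#' non-missing call, and kept when they hold at least `min_snps` SNPs,
#' span at least `min_length_bp`, and have at most
#' `min_density_bp_per_snp` bp per SNP. All thresholds are inclusive.
#'
#' When `params$min_snps` is `NULL` it is derived at call time with
#' [lencz_min_snps()] from the matrix dimensions and its mean observed
#' heterozygosity.
#'
#' @param g a post-QC [genotype_matrix()]; loci must be position-sorted
#'   within chromosomes.
#' @param params a [roh_params()].
#' @return data.frame of segments: `individual_id`, `chr`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`, sorted by individual, chromosome,
#'   start. The `min_snps` actually used is attached as attribute
#'   `min_snps`; chromosomes too short to window are listed in attribute
#'   `uncallable_chroms`.
#' @export
call_roh <- function(g, params = roh_params()) {
  if (!loci_sorted(g$loci))
    stop("loci are not position-sorted within chromosomes; ",
         "apply sort_loci() first")
  min_snps <- params$min_snps
  if (is.null(min_snps)) {
    mean_het <- mean(locus_stats(g)$h_o, na.rm = TRUE)
    min_snps <- lencz_min_snps(params$alpha, n_ind(g), n_loci(g), mean_het)
  }
  chroms <- unique(g$loci$chr)
  by_chr <- split(seq_len(n_loci(g)), factor(g$loci$chr, levels = chroms))
  uncallable <- character(0)
  out <- list()
  for (chr in chroms) {
    idx <- by_chr[[chr]]
    if (length(idx) < params$window_snps) {
      uncallable <- c(uncallable, chr)
      next
    }
    pos <- g$loci$pos[idx]
    gap_break <- c(FALSE, diff(pos) > params$max_gap_bp)
    for (i in seq_len(n_ind(g))) {
      calls <- g$calls[i, idx]
      frac <- window_homozygosity_fractions(calls, params)
      cand <- frac >= params$window_threshold &
        (is.na(calls) | calls != 1L)
      runs <- candidate_runs(cand, gap_break)
      for (r in runs) {
        seg <- trim_and_gate(r, calls, pos, min_snps, params)
        if (!is.null(seg))
          out[[length(out) + 1L]] <-
            data.frame(individual_id = g$samples$id[i], chr = chr,
                       start_bp = seg[1L], end_bp = seg[2L],
                       n_snps = seg[3L], length_bp = seg[2L] - seg[1L] + 1)
      }
    }
  }
  segs <- if (length(out)) do.call(rbind, out) else
    data.frame(individual_id = character(0), chr = character(0),
               start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), length_bp = numeric(0))
  segs <- segs[order(match(segs$individual_id, g$samples$id),
                     match(segs$chr, chroms), segs$start_bp), ,
               drop = FALSE]
  rownames(segs) <- NULL
  attr(segs, "min_snps") <- min_snps
  attr(segs, "uncallable_chroms") <- uncallable
  segs
}

# Maximal stretches of TRUE in `cand`, further split at positions where
# `gap_break` is TRUE (gap_break[i]: gap between SNP i-1 and i too large).
# Returns a list of index ranges c(from, to).
candidate_runs <- function(cand, gap_break) {
  brk <- cumsum(gap_break)
  grp <- brk[cand]
  idx <- which(cand)
  if (!length(idx)) return(list())
  # split consecutive candidate indices, then split again at gap breaks
  piece <- cumsum(c(1L, diff(idx) != 1L)) * 1e9 + grp
  unname(lapply(split(idx, piece), function(v) c(v[1L], v[length(v)])))
}

# Trim a candidate index range to the outermost homozygous non-missing
# call and apply the SNP-count, length and density gates. Returns
# c(start_bp, end_bp, n_snps) or NULL.
trim_and_gate <- function(range, calls, pos, min_snps, params) {
  v <- range[1L]:range[2L]
  hom <- which(!is.na(calls[v]) & calls[v] != 1L)
  if (!length(hom)) return(NULL)
  v <- v[hom[1L]:hom[length(hom)]]
  n_snps <- length(v)
  len <- pos[v[length(v)]] - pos[v[1L]] + 1
  if (n_snps < min_snps) return(NULL)
  if (len < params$min_length_bp) return(NULL)
  if (len / n_snps > params$min_density_bp_per_snp) return(NULL)
  c(pos[v[1L]], pos[v[length(v)]], n_snps)
}

#' Tabulate ROH by length class
#'
#' Bins segment lengths into left-closed, right-open Mb classes and
#' reports the count and unweighted mean length per class. Segments at or
#' beyond the last edge fall into an open-ended final class, reported only
#' when occupied.
#'
#' @param segments segment table from [call_roh()].
#' @param bin_edges_mb class edges in Mb, default `c(1, 2, 4, 8, 16)`.
#' @return data.frame with `class`, `n_runs`, `mean_length_mb`.
#' @export
roh_length_classes <- function(segments, bin_edges_mb = c(1, 2, 4, 8, 16)) {
  len_mb <- segments$length_bp / 1e6
  edges <- c(bin_edges_mb, Inf)
  lab <- c(paste0(utils::head(bin_edges_mb, -1L), "-",
                  utils::tail(bin_edges_mb, -1L)),
           paste0(">=", utils::tail(bin_edges_mb, 1L)))
  cls <- cut(len_mb, breaks = edges, right = FALSE, labels = lab)
  tab <- data.frame(
    class = lab,
    n_runs = as.integer(table(cls)[lab]),
    mean_length_mb = as.numeric(tapply(len_mb, cls, mean)[lab])
  )
  if (tab$n_runs[nrow(tab)] == 0L) tab <- tab[-nrow(tab), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-SNP ROH incidence across individuals
#'
#' For each locus, the fraction of individuals having at least one ROH
#' segment whose span contains the locus position on that chromosome.
#' Overlapping segments of the same individual count once.
#'
#' @param segments segment table from [call_roh()].
#' @param loci locus map (data.frame with `chr`, `pos`, `id`).
#' @param n_individuals number of individuals the segments were called on.
#' @return data.frame `locus_id`, `chr`, `pos`, `incidence`.
#' @export
snp_roh_incidence <- function(segments, loci, n_individuals) {
  stopifnot(n_individuals >= 1)
  inc <- numeric(nrow(loci))
  if (nrow(segments)) {
    for (chr in unique(segments$chr)) {
      li <- which(loci$chr == chr)
      if (!length(li)) next
      pos <- loci$pos[li]
      covered <- numeric(length(li))
      sc <- segments[segments$chr == chr, , drop = FALSE]
      for (ind in unique(sc$individual_id)) {
        si <- sc[sc$individual_id == ind, , drop = FALSE]
        hit <- rep(FALSE, length(li))
        for (k in seq_len(nrow(si)))
          hit <- hit | (pos >= si$start_bp[k] & pos <= si$end_bp[k])
        covered <- covered + hit
      }
      inc[li] <- covered / n_individuals
    }
  }
  data.frame(locus_id = loci$id, chr = loci$chr, pos = loci$pos,
             incidence = inc, row.names = NULL)
}

#' ROH islands: regions of elevated shared homozygosity
#'
#' Maximal runs of consecutive SNPs whose ROH incidence is at or above the
#' threshold, reported as bp intervals with the peak incidence reached
#' inside each.
#'
#' @param incidence table from [snp_roh_incidence()] (or a numeric vector
#'   aligned to `loci`).
#' @param loci locus map; defaults to the columns carried in `incidence`.
#' @param threshold minimum shared fraction, default 0.75.
#' @return data.frame `chr`, `start_bp`, `end_bp`, `n_snps`,
#'   `peak_fraction`.
#' @export
roh_islands <- function(incidence, loci = NULL, threshold = 0.75) {
  if (is.data.frame(incidence)) {
    if (is.null(loci)) loci <- incidence[, c("chr", "pos")]
    incidence <- incidence$incidence
  }
  stopifnot(length(incidence) == nrow(loci))
  out <- list()
  for (chr in unique(loci$chr)) {
    li <- which(loci$chr == chr)
    ok <- incidence[li] >= threshold
    if (!any(ok)) next
    idx <- which(ok)
    piece <- cumsum(c(1L, diff(idx) != 1L))
    for (v in split(idx, piece)) {
      out[[length(out) + 1L]] <- data.frame(
        chr = chr,
        start_bp = loci$pos[li[v[1L]]],
        end_bp = loci$pos[li[v[length(v)]]],
        n_snps = length(v),
        peak_fraction = max(incidence[li[v]])
      )
    }
  }
  if (!length(out))
    return(data.frame(chr = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      peak_fraction = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
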