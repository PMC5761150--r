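#' Parameters for variance-inflation-factor pruning
#'
#' @param window_snps window size in SNPs, default 50.
#' @param step_snps window step in SNPs, default 5.
#' @param vif_threshold maximum tolerated VIF, default 2.
#' @return A list of class `prune_params`.
#' @export
prune_params <- function(window_snps = 50L, step_snps = 5L,
                         vif_threshold = 2) {
  stopifnot(window_snps >= 1, step_snps >= 1, step_snps <= window_snps,
            vif_threshold > 1)
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps),
                 vif_threshold = vif_threshold),
            class = "prune_params")
}

#' Prune loci by variance inflation factor
#'
#' Slides a window along each chromosome in map order, advancing by
#' `step_snps`. Within each window the locus with the highest VIF
#' (`1/(1 - R^2)` from regressing its dosage on the other remaining window
#' loci, i.e. the diagonal of the inverted correlation matrix) is removed,
#' greedily, until every remaining locus has VIF at or below the
#' threshold. A locus removed in any window stays removed. Ties are broken
#' towards the locus with lower MAF, then earlier map order. Windows with
#' fewer than two usable loci pass through unchanged; loci with zero
#' dosage variance carry no collinearity information and are never
#' removed.
#'
#' @param g a post-QC [genotype_matrix()].
#' @param params a [prune_params()].
#' @return Character vector of retained locus ids, in map order.
#' @export
vif_prune <- function(g, params = prune_params()) {
  keep <- rep(TRUE, n_loci(g))
  st <- locus_stats(g)
  usable <- st$defined & st$maf > 0
  for (chr in unique(g$loci$chr)) {
    idx <- which(g$loci$chr == chr)
    Lc <- length(idx)
    for (ws in seq(1L, Lc, by = params$step_snps)) {
      we <- min(ws + params$window_snps - 1L, Lc)
      win <- idx[ws:we]
      win <- win[keep[win] & usable[win]]
      while (length(win) >= 2L) {
        X <- g$calls[, win, drop = FALSE]
        R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
        R[is.na(R)] <- 0
        vif <- window_vif(R)
        worst <- max(vif)
        if (worst <= params$vif_threshold) break
        cand <- which(vif >= worst - 1e-9)
        if (length(cand) > 1L) {
          cand <- cand[order(st$maf[win[cand]], win[cand])]
        }
        drop <- win[cand[1L]]
        keep[drop] <- FALSE
        win <- setdiff(win, drop)
      }
      if (we == Lc) break
    }
  }
  g$loci$id[keep]
}

# VIFs as the diagonal of the inverse correlation matrix; a tiny ridge
# keeps perfectly collinear windows invertible (their VIFs come out huge,
# which is what the greedy removal needs).
window_vif <- function(R) {
  inv <- tryCatch(chol2inv(chol(R)), error = function(e) NULL)
  if (is.null(inv))
    inv <- solve(R + diag(1e-8, nrow(R)))
  diag(inv)
}

#' Pairwise LD as squared dosage correlation
#'
#' `r^2` for each requested locus pair: the squared Pearson correlation of
#' the two dosage vectors over individuals complete for the pair (the
#' composite measure appropriate for unphased genotypes). Pairs where
#' either locus has zero variance are returned as `NA` and counted in the
#' `n_skipped` attribute.
#'
#' @param g a [genotype_matrix()].
#' @param locus_pairs two-column matrix of locus ids or column indices.
#' @return Numeric vector of r-squared values, attribute `n_skipped`.
#' @export
pairwise_r2 <- function(g, locus_pairs) {
  locus_pairs <- as.matrix(locus_pairs)
  if (is.character(locus_pairs))
    locus_pairs <- matrix(match(locus_pairs, g$loci$id),
                          ncol = 2L)
  r2 <- numeric(nrow(locus_pairs))
  skipped <- 0L
  for (k in seq_len(nrow(locus_pairs))) {
    x <- g$calls[, locus_pairs[k, 1L]]
    y <- g$calls[, locus_pairs[k, 2L]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L)
      stop("pair ", k, " has fewer than 2 individuals with complete calls")
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      r2[k] <- NA_real_
      skipped <- skipped + 1L
    } else {
      r2[k] <- stats::cor(x[ok], y[ok])^2
    }
  }
  attr(r2, "n_skipped") <- skipped
  r2
}

#' LD-based contemporary effective population size
#'
#' Mean squared dosage correlation over pairs of retained loci on
#' different chromosomes (physical linkage would otherwise inflate LD and
#' bias Ne downward), corrected for the finite sample with the standard
#' small-sample expectation, then inverted through the drift relation:
#' for `S >= 30` under random mating,
#' `E[r^2 | S] = 1/S + 3.19/S^2` and
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`
#' where `r2'` is the drift component `mean_r2 - E[r^2 | S]`; for
#' `S < 30`, `E[r^2 | S] = 0.0018 + 0.907/S + 4.44/S^2` with constants
#' `(0.308, 2.08)`; monogamous mating uses `(2/3, 7.2)` and
#' `(0.618, 5.24)`. `S` is the harmonic mean of per-pair complete sample
#' sizes. A drift component at or below zero is flagged `infinite` (the
#' data carry no drift signal); a negative discriminant is flagged
#' `undefined`.
#'
#' @param g a post-QC [genotype_matrix()].
#' @param retained locus ids to use, e.g. from [vif_prune()]; `NULL` uses
#'   all loci.
#' @param min_maf loci below this MAF at estimation time are excluded
#'   (the estimator is sensitive to rare alleles), default 0.05.
#' @param mating `"random"` or `"monogamy"`.
#' @param max_loci cap on the number of loci entering the pair matrix
#'   (memory grows with its square); above the cap, loci are evenly
#'   subsampled along the map, deterministically. Default 5000.
#' @return A list of class `ne_estimate`: `mean_r2`, `expected_r2`,
#'   `r2_drift`, `ne_hat`, `n_pairs`, `harmonic_mean_S`, `n_loci_used`,
#'   `status` (`"ok"`, `"infinite"` or `"undefined"`).
#' @export
estimate_ne <- function(g, retained = NULL, min_maf = 0.05,
                        mating = c("random", "monogamy"),
                        max_loci = 5000L) {
  mating <- match.arg(mating)
  idx <- if (is.null(retained)) seq_len(n_loci(g)) else
    match(retained, g$loci$id)
  if (anyNA(idx)) stop("retained ids not all present in the locus map")
  st <- locus_stats(g)
  ok <- st$defined[idx] & st$maf[idx] >= min_maf & st$maf[idx] > 0
  idx <- idx[ok]
  if (length(idx) < 2L) stop("need at least 2 usable retained loci")
  if (length(idx) > max_loci)
    idx <- idx[unique(round(seq(1L, length(idx), length.out = max_loci)))]
  X <- g$calls[, idx, drop = FALSE]
  chr <- g$loci$chr[idx]
  diff_chr <- outer(chr, chr, "!=")
  mask <- upper.tri(diff_chr) & diff_chr
  if (!any(mask))
    stop("no inter-chromosome locus pairs available")
  if (anyNA(X)) {
    C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
    Sp <- crossprod(!is.na(X))
  } else {
    C <- stats::cor(X)
    Sp <- matrix(nrow(X), length(idx), length(idx))
  }
  r2 <- C[mask]^2
  use <- !is.na(r2)
  r2 <- r2[use]
  n_pairs <- length(r2)
  mean_r2 <- mean(r2)
  S <- n_pairs / sum(1 / Sp[mask][use])
  expected <- if (S >= 30) 1 / S + 3.19 / S^2 else
    0.0018 + 0.907 / S + 4.44 / S^2
  r2d <- mean_r2 - expected
  cst <- if (S >= 30) {
    if (mating == "random") c(a = 1 / 3, b = 2.76) else c(a = 2 / 3, b = 7.2)
  } else {
    if (mating == "random") c(a = 0.308, b = 2.08) else
      c(a = 0.618, b = 5.24)
  }
  if (r2d <= 0) {
    ne <- Inf; status <- "infinite"
  } else {
    disc <- cst[["a"]]^2 - cst[["b"]] * r2d
    if (disc < 0) {
      ne <- NA_real_; status <- "undefined"
    } else {
      ne <- (cst[["a"]] + sqrt(disc)) / (2 * r2d)
      status <- "ok"
    }
  }
  structure(list(mean_r2 = mean_r2, expected_r2 = expected, r2_drift = r2d,
                 ne_hat = ne, n_pairs = n_pairs, harmonic_mean_S = S,
                 n_loci_used = length(idx), mating = mating,
                 status = status),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "LD Ne: n_pairs=%d S=%.1f mean_r2=%.5f r2_drift=%.5f ne_hat=%s (%s)\n",
    x$n_pairs, x$harmonic_mean_S, x$mean_r2, x$r2_drift,
    formatC(x$ne_hat, digits = 4), x$status))
  invisible(x)
}
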