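# Fixture builders and independent brute-force oracles. The oracles are
# deliberately written as plain nested loops, sharing no code with the
# package internals they check.

toy_genotypes <- function(calls, chr = "1", pos = NULL, sex = NULL,
                          ids = NULL) {
  calls <- as.matrix(calls)
  N <- nrow(calls); L <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(L) * 1e5
  if (length(chr) == 1L) chr <- rep(chr, L)
  if (is.null(sex)) sex <- rep("unknown", N)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(N))
  genotype_matrix(
    calls,
    data.frame(id = ids, sex = sex),
    data.frame(chr = chr, pos = pos, id = sprintf("L%04d", seq_len(L)))
  )
}

random_genotypes <- function(n, l, missing = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- runif(l, 0.05, 0.5)
  calls <- matrix(rbinom(n * l, 2, rep(q, each = n)), n, l)
  if (missing > 0) calls[runif(n * l) < missing] <- NA
  # canonicalise to the container convention: dosages count the
  # sample-minor allele (round-trip I/O is exact only up to that choice)
  freq <- colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
  flip <- !is.na(freq) & freq > 0.5
  calls[, flip] <- 2L - calls[, flip]
  toy_genotypes(calls)
}

# Brute-force diversity summary: explicit per-locus loop from raw calls.
oracle_diversity <- function(calls) {
  L <- ncol(calls)
  ho <- he <- maf <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    x <- calls[, l]
    x <- x[!is.na(x)]
    if (!length(x)) next
    q <- sum(x) / (2 * length(x))
    q <- min(q, 1 - q)
    maf[l] <- q
    ho[l] <- sum(x == 1) / length(x)
    he[l] <- 1 - (1 - q)^2 - q^2
  }
  ok <- !is.na(ho)
  fis_terms <- 1 - ho[ok & he > 0] / he[ok & he > 0]
  list(mean_h_o = mean(ho[ok]), mean_h_e = mean(he[ok]),
       mean_maf = mean(maf[ok]), f_is = mean(fis_terms))
}

# Brute-force ROH caller for one individual on one chromosome: direct
# window enumeration, linear scan with gap splitting, explicit trimming
# and gate checks.
oracle_roh_one <- function(calls, pos, params, min_snps) {
  n <- length(calls)
  w <- params$window_snps
  empty <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0))
  if (n < w) return(empty)
  W <- n - w + 1L
  homwin <- logical(W)
  for (s in seq_len(W)) {
    win <- calls[s:(s + w - 1L)]
    n_het <- 0L; n_mis <- 0L
    for (v in win) {
      if (is.na(v)) n_mis <- n_mis + 1L
      else if (v == 1L) n_het <- n_het + 1L
    }
    homwin[s] <- n_het <= params$max_het_per_window &&
      n_mis <= params$max_missing_per_window
  }
  cand <- logical(n)
  for (i in seq_len(n)) {
    n_cov <- 0L; n_hom <- 0L
    for (s in seq_len(W)) {
      if (s <= i && i <= s + w - 1L) {
        n_cov <- n_cov + 1L
        if (homwin[s]) n_hom <- n_hom + 1L
      }
    }
    own_ok <- is.na(calls[i]) || calls[i] != 1L
    cand[i] <- own_ok && (n_hom / n_cov) >= params$window_threshold
  }
  runs <- list()
  start <- NA_integer_
  for (i in seq_len(n + 1L)) {
    broken <- !is.na(start) && i <= n &&
      (pos[i] - pos[i - 1L]) > params$max_gap_bp
    if (i > n || !cand[i] || broken) {
      if (!is.na(start)) {
        runs[[length(runs) + 1L]] <- c(start, i - 1L)
        start <- NA_integer_
      }
      if (i <= n && cand[i] && broken) start <- i
    } else if (is.na(start)) {
      start <- i
    }
  }
  out <- empty
  for (r in runs) {
    a <- r[1L]; b <- r[2L]
    while (a <= b && (is.na(calls[a]) || calls[a] == 1L)) a <- a + 1L
    while (b >= a && (is.na(calls[b]) || calls[b] == 1L)) b <- b - 1L
    if (a > b) next
    n_snps <- b - a + 1L
    len <- pos[b] - pos[a] + 1
    if (n_snps >= min_snps && len >= params$min_length_bp &&
        len / n_snps <= params$min_density_bp_per_snp)
      out <- rbind(out, data.frame(start_bp = pos[a], end_bp = pos[b],
                                   n_snps = n_snps))
  }
  out
}

oracle_roh <- function(g, params, min_snps) {
  out <- list()
  for (i in seq_len(nrow(g$calls))) {
    for (chr in unique(g$loci$chr)) {
      li <- which(g$loci$chr == chr)
      segs <- oracle_roh_one(g$calls[i, li], g$loci$pos[li], params,
                             min_snps)
      if (nrow(segs)) {
        segs$individual_id <- g$samples$id[i]
        segs$chr <- chr
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(individual_id = character(0), chr = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(match(res$individual_id, g$samples$id),
                   match(res$chr, unique(g$loci$chr)), res$start_bp), ]
  rownames(res) <- NULL
  res[, c("individual_id", "chr", "start_bp", "end_bp", "n_snps")]
}
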