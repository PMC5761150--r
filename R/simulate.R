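#' Configuration for the genotype simulator
#'
#' Describes a synthetic SNP-array dataset with the statistical structure
#' the downstream analysis assumes: a Poisson-process marker map
#' (exponential inter-SNP gaps), Hardy-Weinberg genotypes with a chosen
#' MAF spectrum, call-level missingness and optional symmetric genotyping
#' error, and homozygous identical-by-descent tracts planted per
#' individual. The default scale (5 chromosomes of 100 Mb at 25 kb mean
#' spacing, ~20k SNPs, 3% missingness) is a reduced emulation of a canine
#' HD array; a `canine_hd = TRUE` configuration emulates the full
#' 38-autosome, ~2268.83 Mb, ~94k-SNP layout.
#'
#' @param n_individuals sample size.
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp chromosome length(s) in bp; scalar is recycled.
#' @param snp_spacing_bp mean inter-SNP distance in bp.
#' @param maf_distribution `"uniform"` (on `maf_range`) or `"beta"`
#'   (scaled to (0, 0.5]).
#' @param maf_range range for the uniform MAF spectrum.
#' @param beta_shape two shape parameters for the beta spectrum.
#' @param missing_rate per-call missingness probability.
#' @param genotype_error_rate probability a call is replaced by one of the
#'   other two states.
#' @param seed integer seed; each simulation stage derives its own stream
#'   from it (map: `seed`, genotypes: `seed + 1`, planting: `seed + 2`).
#' @param canine_hd if `TRUE`, override the map layout with 38
#'   chromosomes summing ~2268.83 Mb at 24 kb spacing (~94k SNPs).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_individuals = 48L, n_chromosomes = 5L,
                         chrom_length_bp = 100e6, snp_spacing_bp = 25e3,
                         maf_distribution = c("uniform", "beta"),
                         maf_range = c(0.05, 0.5), beta_shape = c(0.8, 1.6),
                         missing_rate = 0.03, genotype_error_rate = 0,
                         seed = 1L, canine_hd = FALSE) {
  maf_distribution <- match.arg(maf_distribution)
  if (canine_hd) {
    n_chromosomes <- 38L
    # autosome lengths decaying roughly like the canine assembly, scaled
    # to a 2268.83 Mb total
    raw <- seq(122, 26, length.out = 38)
    chrom_length_bp <- round(raw / sum(raw) * 2268.83e6)
    snp_spacing_bp <- 24e3
  }
  chrom_length_bp <- rep_len(chrom_length_bp, n_chromosomes)
  stopifnot(n_individuals >= 1, n_chromosomes >= 1,
            all(chrom_length_bp > 0), snp_spacing_bp > 0,
            missing_rate >= 0, missing_rate < 1,
            genotype_error_rate >= 0, genotype_error_rate < 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp,
                 snp_spacing_bp = snp_spacing_bp,
                 maf_distribution = maf_distribution,
                 maf_range = maf_range, beta_shape = beta_shape,
                 missing_rate = missing_rate,
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a marker map
#'
#' Positions per chromosome are cumulative exponential gaps (a Poisson
#' marker process) with the configured mean spacing, truncated at the
#' chromosome length; gaps are rounded up to at least 1 bp so positions
#' are strictly increasing. Deterministic under `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return Locus map data.frame (`chr`, `pos`, `id`).
#' @export
make_map <- function(cfg) {
  if (any(cfg$snp_spacing_bp >= cfg$chrom_length_bp))
    stop("mean SNP spacing must be smaller than every chromosome length")
  set.seed(cfg$seed)
  maps <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
    len <- cfg$chrom_length_bp[ci]
    pos <- numeric(0)
    last <- 0
    while (last < len) {
      n_draw <- max(50L, ceiling((len - last) / cfg$snp_spacing_bp * 1.3))
      gaps <- pmax(1, round(stats::rexp(n_draw, 1 / cfg$snp_spacing_bp)))
      pos <- c(pos, last + cumsum(gaps))
      last <- pos[length(pos)]
    }
    pos <- pos[pos <= len]
    data.frame(chr = as.character(ci), pos = pos,
               id = sprintf("snp_%d_%06d", ci, seq_along(pos)))
  })
  do.call(rbind, maps)
}

#' Simulate Hardy-Weinberg genotypes on a map
#'
#' Per locus, an allele frequency is drawn from the configured MAF
#' spectrum; per individual, the dosage is binomial(2, q) - exact
#' Hardy-Weinberg proportions. Missingness and symmetric genotype error
#' are then applied call-wise. Deterministic under `cfg$seed`.
#'
#' @param map locus map from [make_map()].
#' @param cfg a [synth_config()].
#' @return A [genotype_matrix()]; the simulated allele frequency of each
#'   locus is kept in the locus map column `sim_q`.
#' @export
simulate_genotypes <- function(map, cfg) {
  set.seed(cfg$seed + 1L)
  L <- nrow(map)
  N <- cfg$n_individuals
  q <- switch(cfg$maf_distribution,
    uniform = stats::runif(L, cfg$maf_range[1L], cfg$maf_range[2L]),
    beta = pmax(0.001, stats::rbeta(L, cfg$beta_shape[1L],
                                    cfg$beta_shape[2L]) / 2)
  )
  calls <- matrix(stats::rbinom(N * L, 2L, rep(q, each = N)), N, L)
  if (cfg$genotype_error_rate > 0) {
    err <- which(stats::runif(N * L) < cfg$genotype_error_rate)
    if (length(err))
      calls[err] <- (calls[err] +
                       sample(1:2, length(err), replace = TRUE)) %% 3L
  }
  if (cfg$missing_rate > 0)
    calls[stats::runif(N * L) < cfg$missing_rate] <- NA_integer_
  samples <- data.frame(
    id = sprintf("ind_%03d", seq_len(N)),
    sex = rep_len(c("female", "male"), N)
  )
  loci <- map
  loci$allele_a <- "A"
  loci$allele_b <- "B"
  loci$sim_q <- q
  genotype_matrix(calls, samples, loci)
}

#' Plant homozygous IBD tracts
#'
#' Overwrites an individual's calls inside each tract with homozygous
#' genotypes, choosing the allele by its population frequency
#' (dosage 0 with probability `p^2/(p^2+q^2)`, else 2) so within-tract
#' allele composition stays realistic; missingness is re-applied inside
#' tracts at `missing_rate`. Tracts can be given explicitly or generated
#' to hit per-individual `target_f_roh` values, with lengths drawn from
#' the published breed ROH length-class mix and placed uniformly without
#' overlap (tracts of one individual are kept at least
#' `min_separation_bp` apart so they are called as distinct runs). The
#' last generated tract is adjusted so the planted total matches the
#' target exactly against the SNP-covered genome span.
#'
#' @param g a [genotype_matrix()] from [simulate_genotypes()].
#' @param tracts data.frame (`individual_id`, `chr`, `start_bp`,
#'   `length_bp`) of explicit tracts, or `NULL`.
#' @param target_f_roh numeric vector of per-individual targets (named by
#'   individual id, or unnamed covering all individuals), or `NULL`.
#' @param missing_rate missingness re-applied inside tracts.
#' @param min_separation_bp minimum distance between tracts of one
#'   individual.
#' @param seed integer seed for tract generation and allele draws;
#'   defaults to reproducible derivation when the matrix came from a
#'   seeded config.
#' @return A list: `genotypes` (modified matrix) and `tracts` (ground
#'   truth: `individual_id`, `chr`, `start_bp`, `end_bp`, `length_bp`).
#' @export
plant_roh <- function(g, tracts = NULL, target_f_roh = NULL,
                      missing_rate = 0.03, min_separation_bp = 1e6,
                      seed = 1L) {
  if (is.null(tracts) == is.null(target_f_roh))
    stop("give exactly one of `tracts` or `target_f_roh`")
  set.seed(seed + 2L)
  bounds <- do.call(rbind, lapply(split(g$loci$pos, g$loci$chr), range))
  span <- bounds[, 2L] - bounds[, 1L] + 1
  chroms <- rownames(bounds)
  if (!is.null(target_f_roh)) {
    ids <- if (!is.null(names(target_f_roh))) names(target_f_roh) else
      g$samples$id[seq_along(target_f_roh)]
    tracts <- do.call(rbind, lapply(seq_along(ids), function(k) {
      draw_tracts(ids[k], target_f_roh[k], chroms, bounds, span,
                  min_separation_bp)
    }))
  } else {
    tracts <- as.data.frame(tracts)
    tracts$end_bp <- tracts$start_bp + tracts$length_bp - 1
    for (ind in unique(tracts$individual_id)) {
      ti <- tracts[tracts$individual_id == ind, , drop = FALSE]
      for (chr in unique(ti$chr)) {
        tc <- ti[ti$chr == chr, , drop = FALSE]
        o <- order(tc$start_bp)
        if (nrow(tc) > 1L &&
            any(tc$start_bp[o][-1L] <= tc$end_bp[o][-nrow(tc)]))
          stop("overlapping tracts for individual ", ind, " on chr ", chr)
      }
    }
  }
  q <- if (!is.null(g$loci$sim_q)) g$loci$sim_q else locus_stats(g)$q
  for (k in seq_len(nrow(tracts))) {
    ind <- match(tracts$individual_id[k], g$samples$id)
    li <- which(g$loci$chr == tracts$chr[k] &
                  g$loci$pos >= tracts$start_bp[k] &
                  g$loci$pos <= tracts$end_bp[k])
    if (!length(li)) next
    p2 <- (1 - q[li])^2
    prob2 <- q[li]^2 / (p2 + q[li]^2)
    draw <- 2L * stats::rbinom(length(li), 1L, prob2)
    if (missing_rate > 0)
      draw[stats::runif(length(li)) < missing_rate] <- NA_integer_
    g$calls[ind, li] <- draw
  }
  rownames(tracts) <- NULL
  list(genotypes = g, tracts = tracts)
}

# Draw non-overlapping tracts for one individual totalling
# target * sum(span) bp, with lengths from the published class mix.
draw_tracts <- function(id, target, chroms, bounds, span, min_sep) {
  mix <- bfp_summary()$roh_classes
  target_len <- target * sum(span)
  lens <- numeric(0)
  while (sum(lens) < target_len) {
    cls <- sample.int(nrow(mix), 1L, prob = mix$n_runs)
    lens <- c(lens, stats::runif(1, mix$class_lo_mb[cls],
                                 mix$class_hi_mb[cls]) * 1e6)
  }
  excess <- sum(lens) - target_len
  lens[length(lens)] <- lens[length(lens)] - excess
  if (length(lens) > 1L && lens[length(lens)] < 1e6) {
    lens[1L] <- lens[1L] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  placed <- data.frame(chr = character(0), start_bp = numeric(0),
                       end_bp = numeric(0))
  for (len in sort(lens, decreasing = TRUE)) {
    done <- FALSE
    for (try in 1:200) {
      ci <- sample.int(length(chroms), 1L, prob = span)
      lo <- bounds[ci, 1L]; hi <- bounds[ci, 2L] - len + 1
      if (hi <= lo) next
      start <- floor(stats::runif(1, lo, hi))
      end <- start + len - 1
      same <- placed[placed$chr == chroms[ci], , drop = FALSE]
      if (!nrow(same) ||
          all(start > same$end_bp + min_sep | end < same$start_bp - min_sep)) {
        placed <- rbind(placed, data.frame(chr = chroms[ci],
                                           start_bp = start, end_bp = end))
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not place a ", round(len / 1e6, 2),
           " Mb tract for individual ", id,
           "; genome too crowded for the requested target")
  }
  data.frame(individual_id = id, chr = placed$chr,
             start_bp = placed$start_bp, end_bp = placed$end_bp,
             length_bp = placed$end_bp - placed$start_bp + 1)
}

#' Simulate a whole dataset in one call
#'
#' [make_map()], [simulate_genotypes()] and optionally [plant_roh()] under
#' one seed.
#'
#' @param cfg a [synth_config()].
#' @param target_f_roh optional per-individual F_ROH targets passed to
#'   [plant_roh()].
#' @param tracts optional explicit tract table passed to [plant_roh()].
#' @return A list: `genotypes`, `tracts` (possibly empty), `map`, `cfg`.
#' @export
simulate_dataset <- function(cfg = synth_config(), target_f_roh = NULL,
                             tracts = NULL) {
  map <- make_map(cfg)
  g <- simulate_genotypes(map, cfg)
  planted <- NULL
  if (!is.null(target_f_roh) || !is.null(tracts)) {
    res <- plant_roh(g, tracts = tracts, target_f_roh = target_f_roh,
                     missing_rate = cfg$missing_rate, seed = cfg$seed)
    g <- res$genotypes
    planted <- res$tracts
  }
  list(genotypes = g, tracts = planted, map = map, cfg = cfg)
}

#' Simulate a drifting Wright-Fisher population
#'
#' Ground truth for the LD-based Ne estimator. A diploid population of
#' `true_ne` individuals evolves for `generations` generations of random
#' mating (each offspring from a random parent pair, one allele
#' transmitted per locus per parent); loci are unlinked with initial
#' frequencies uniform on (0.1, 0.9). The sample is then drawn as
#' `n_sampled` offspring of random parent pairs from the final pool. The
#' finite parent pool is what generates linkage disequilibrium among
#' unlinked loci (about `1/(3 Ne)` in expectation). For `true_ne` above
#' 10,000 the pedigree matrices are impractically large and the drift LD
#' is negligible against sampling noise, so allele frequencies drift by
#' binomial sampling and the sample is drawn in Hardy-Weinberg proportions
#' (an effectively infinite parent pool).
#'
#' @param true_ne effective (= census, idealised) population size.
#' @param n_sampled number of sampled individuals.
#' @param n_loci number of unlinked loci.
#' @param generations generations of drift before sampling, default 10.
#' @param n_chromosomes chromosome labels to spread loci over (pairs used
#'   by the estimator are inter-chromosome), default 38.
#' @param seed integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_drift_population <- function(true_ne, n_sampled, n_loci,
                                      generations = 10L,
                                      n_chromosomes = 38L, seed = 1L) {
  stopifnot(true_ne >= 2, n_sampled >= 2, n_loci >= 2, generations >= 1)
  set.seed(seed)
  chr <- sort(rep_len(seq_len(n_chromosomes), n_loci))
  pos <- stats::ave(seq_len(n_loci), chr, FUN = seq_along) * 1e6
  loci <- data.frame(chr = as.character(chr), pos = pos,
                     id = sprintf("wf_%05d", seq_len(n_loci)))
  q0 <- stats::runif(n_loci, 0.1, 0.9)
  if (true_ne > 1e4) {
    q <- q0
    for (gen in seq_len(generations))
      q <- stats::rbinom(n_loci, 2 * true_ne, q) / (2 * true_ne)
    calls <- matrix(stats::rbinom(n_sampled * n_loci, 2L,
                                  rep(q, each = n_sampled)),
                    n_sampled, n_loci)
  } else {
    A1 <- matrix(stats::rbinom(true_ne * n_loci, 1L, rep(q0, each = true_ne)),
                 true_ne, n_loci)
    A2 <- matrix(stats::rbinom(true_ne * n_loci, 1L, rep(q0, each = true_ne)),
                 true_ne, n_loci)
    transmit <- function(A1, A2, parents, n_off) {
      pick <- matrix(stats::runif(n_off * n_loci) < 0.5, n_off, n_loci)
      ifelse(pick, A1[parents, , drop = FALSE],
             A2[parents, , drop = FALSE])
    }
    for (gen in seq_len(generations)) {
      mothers <- sample.int(true_ne, true_ne, replace = TRUE)
      fathers <- sample.int(true_ne, true_ne, replace = TRUE)
      N1 <- transmit(A1, A2, mothers, true_ne)
      N2 <- transmit(A1, A2, fathers, true_ne)
      A1 <- N1; A2 <- N2
    }
    mothers <- sample.int(true_ne, n_sampled, replace = TRUE)
    fathers <- sample.int(true_ne, n_sampled, replace = TRUE)
    calls <- transmit(A1, A2, mothers, n_sampled) +
      transmit(A1, A2, fathers, n_sampled)
  }
  samples <- data.frame(id = sprintf("wf_ind_%04d", seq_len(n_sampled)),
                        sex = "unknown")
  genotype_matrix(calls, samples, loci)
}
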