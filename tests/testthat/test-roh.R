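test_that("Lencz minimum-SNP threshold matches direct evaluation", {
  # all four inputs as published for the breed survey
  expect_equal(lencz_min_snps(0.05, 48, 94065, 0.371), 40)
  # ceil(ln(0.05)/ln(0.5)) = ceil(4.32) = 5
  expect_equal(lencz_min_snps(0.05, 1, 1, 0.5), 5)
  # monotone in L
  expect_gt(lencz_min_snps(0.05, 48, 2 * 94065, 0.371),
            lencz_min_snps(0.05, 48, 94065, 0.371) - 1)
  expect_error(lencz_min_snps(0.05, 48, 94065, 0), "between 0 and 1")
  expect_error(lencz_min_snps(0.05, 48, 94065, 1), "between 0 and 1")
})

test_that("window fractions behave at the extremes and below window size", {
  p <- roh_params(window_snps = 50)
  expect_equal(window_homozygosity_fractions(rep(0L, 60), p), rep(1, 60))
  expect_equal(window_homozygosity_fractions(rep(1L, 60), p), rep(0, 60))
  expect_true(all(is.na(window_homozygosity_fractions(rep(0L, 49), p))))
})

test_that("a single het dips fractions only where every window sees it", {
  p <- roh_params(window_snps = 5, max_het_per_window = 0,
                  max_missing_per_window = 0)
  calls <- rep(0L, 100)
  calls[50] <- 1L
  frac <- window_homozygosity_fractions(calls, p)
  # brute-force window enumeration
  W <- 96
  homwin <- vapply(1:W, function(s) all(calls[s:(s + 4)] != 1L), logical(1))
  expected <- vapply(1:100, function(i) {
    cov <- max(1, i - 4):min(i, W)
    mean(homwin[cov])
  }, numeric(1))
  expect_equal(frac, expected)
  expect_equal(frac[50], 0)   # every window covering SNP 50 includes the het
  expect_equal(frac[44], 1)
})

test_that("a planted 1.2 Mb tract is recovered as one segment", {
  set.seed(2)
  n <- 200
  pos <- seq(20e3, by = 20e3, length.out = n)
  calls <- rep(1L, n)                      # het background blocks runs
  tract <- 71:130                          # 60 SNPs, span 1.18 Mb
  calls[tract] <- 0L
  g <- toy_genotypes(matrix(calls, 1), pos = pos)
  p <- roh_params(min_snps = 40)
  segs <- call_roh(g, p)
  expect_equal(nrow(segs), 1)
  # boundaries within one window-span of the tract
  expect_lte(abs(segs$start_bp - pos[71]), 50 * 20e3)
  expect_lte(abs(segs$end_bp - pos[130]), 50 * 20e3)
  expect_gte(segs$length_bp, 1e6)
  # windows holding 49 tract SNPs plus one flanking het still count as
  # homozygous (max_het = 1), so the run is 72..129: 58 SNPs; the
  # outermost tract SNPs fail the 5% window fraction
  expect_equal(segs$n_snps, 58)
})

test_that("a 0.9 Mb tract fails the minimum-length gate", {
  n <- 200
  pos <- seq(15e3, by = 15e3, length.out = n)
  calls <- rep(1L, n)
  calls[71:130] <- 0L                      # 60 SNPs, span 0.885 Mb < 1 Mb
  g <- toy_genotypes(matrix(calls, 1), pos = pos)
  segs <- call_roh(g, roh_params(min_snps = 40))
  expect_equal(nrow(segs), 0)
})

test_that("an internal 150 kb gap splits a tract into re-tested candidates", {
  n <- 240
  gaps <- rep(20e3, n - 1)
  gaps[120] <- 150e3                       # between SNPs 120 and 121
  pos <- cumsum(c(20e3, gaps))
  calls <- rep(1L, n)
  calls[41:200] <- 0L                      # 160-SNP tract spanning the gap
  g <- toy_genotypes(matrix(calls, 1), pos = pos)
  segs <- call_roh(g, roh_params(min_snps = 40))
  expect_equal(nrow(segs), 2)
  expect_lt(segs$end_bp[1], pos[121])
  expect_gt(segs$start_bp[2], pos[120])
  expect_true(all(segs$length_bp >= 1e6))
})

test_that("unsorted loci are rejected with advice", {
  g <- toy_genotypes(matrix(0L, 1, 60), pos = c(2e5, 1e5, 3:60 * 1e5))
  expect_error(call_roh(g, roh_params()), "sort_loci")
})

test_that("caller equals the brute-force oracle on random instances", {
  set.seed(99)
  n_cases <- 60
  for (k in seq_len(n_cases)) {
    n <- sample(60:200, 1)
    w <- sample(5:25, 1)
    p <- roh_params(
      window_snps = w,
      window_threshold = runif(1, 0, 0.3),
      max_het_per_window = sample(0:1, 1),
      max_missing_per_window = sample(0:2, 1),
      min_length_bp = sample(c(2e5, 5e5, 1e6), 1),
      min_snps = sample(5:30, 1),
      min_density_bp_per_snp = sample(c(3e4, 5e4, 8e4), 1),
      max_gap_bp = sample(c(6e4, 1e5, 2e5), 1)
    )
    gaps <- sample(c(5e3, 2e4, 4e4, 1.2e5), n - 1, replace = TRUE,
                   prob = c(.4, .4, .15, .05))
    pos <- cumsum(c(1e4, gaps))
    calls <- rbinom(n, 2, runif(1, 0.2, 0.5))
    # plant 0-2 homozygous stretches to exercise the gates
    for (t in seq_len(sample(0:2, 1))) {
      a <- sample(n - 20, 1); b <- min(n, a + sample(20:80, 1))
      calls[a:b] <- sample(c(0L, 2L), b - a + 1, replace = TRUE)
    }
    calls[runif(n) < 0.03] <- NA
    g <- toy_genotypes(matrix(calls, 1), pos = pos)
    got <- call_roh(g, p)
    want <- oracle_roh(g, p, p$min_snps)
    expect_equal(nrow(got), nrow(want), info = paste("case", k))
    if (nrow(want)) {
      expect_equal(got$start_bp, want$start_bp, info = paste("case", k))
      expect_equal(got$end_bp, want$end_bp, info = paste("case", k))
      expect_equal(got$n_snps, want$n_snps, info = paste("case", k))
    }
  }
})

test_that("every reported segment passes all four gates post hoc", {
  cfg <- synth_config(n_individuals = 10, n_chromosomes = 2,
                      chrom_length_bp = 40e6, snp_spacing_bp = 13e3,
                      missing_rate = 0.03, seed = 21)
  d <- simulate_dataset(cfg, target_f_roh = rep(0.15, 10))
  g <- sort_loci(d$genotypes)
  p <- roh_params(min_snps = 40)
  segs <- call_roh(g, p)
  expect_gt(nrow(segs), 0)
  for (k in seq_len(nrow(segs))) {
    li <- which(g$loci$chr == segs$chr[k] &
                  g$loci$pos >= segs$start_bp[k] &
                  g$loci$pos <= segs$end_bp[k])
    expect_equal(length(li), segs$n_snps[k])
    expect_gte(segs$n_snps[k], 40)
    expect_gte(segs$length_bp[k], p$min_length_bp)
    expect_lte(segs$length_bp[k] / segs$n_snps[k], p$min_density_bp_per_snp)
    expect_lte(max(diff(g$loci$pos[li])), p$max_gap_bp)
    calls <- g$calls[match(segs$individual_id[k], g$samples$id), li]
    expect_equal(sum(calls == 1L, na.rm = TRUE), 0)  # no hets inside runs
  }
})

test_that("length classes bin left-closed right-open with unweighted means", {
  segs <- data.frame(length_bp = c(1.5e6, 1.5e6, 2.5e6, 5e6, 9e6))
  tab <- roh_length_classes(segs)
  expect_equal(tab$n_runs, c(2, 1, 1, 1))
  expect_equal(tab$mean_length_mb, c(1.5, 2.5, 5, 9))
  # boundary value falls in the right-open upper class
  tab2 <- roh_length_classes(data.frame(length_bp = c(2e6, 17e6)))
  expect_equal(tab2$n_runs[tab2$class == "2-4"], 1)
  expect_equal(tab2$n_runs[tab2$class == ">=16"], 1)
})

test_that("incidence counts individuals once and islands are maximal runs", {
  loci <- data.frame(chr = "1", pos = c(1e6, 2e6, 3e6, 4e6),
                     id = paste0("L", 1:4))
  segs <- data.frame(
    individual_id = c("a", "a", "b", "c"),
    chr = "1",
    start_bp = c(0.5e6, 1.5e6, 0.5e6, 0.5e6),   # a overlaps itself on L2
    end_bp = c(2.5e6, 2.6e6, 1.5e6, 2.5e6)
  )
  inc <- snp_roh_incidence(segs, loci, 4)
  expect_equal(inc$incidence, c(3 / 4, 2 / 4, 0, 0))

  # islands: [0.8, 0.8, 0.1, 0.9] at threshold 0.75 -> two islands
  isl <- roh_islands(c(0.8, 0.8, 0.1, 0.9), loci, threshold = 0.75)
  expect_equal(nrow(isl), 2)
  expect_equal(isl$start_bp, c(1e6, 4e6))
  expect_equal(isl$end_bp, c(2e6, 4e6))
  expect_equal(isl$peak_fraction, c(0.8, 0.9))
  expect_equal(nrow(roh_islands(c(0.1, 0.2, 0.3, 0.4), loci)), 0)
  # constant incidence above threshold spans the whole chromosome
  one <- roh_islands(rep(0.8, 4), loci)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start_bp, one$end_bp), c(1e6, 4e6))
})
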