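test_that("per-locus statistics match hand counts", {
  g <- toy_genotypes(cbind(c(0L, 1L, 1L, 2L),   # q = 4/8 = 0.5
                           c(0L, 0L, 0L, 0L),   # monomorphic
                           c(1L, 1L, 1L, 1L),   # all heterozygous
                           c(NA, NA, NA, NA)))  # undefined
  st <- locus_stats(g)
  expect_equal(st$q[1], 0.5)
  expect_equal(st$h_o[1], 0.5)
  expect_equal(st$h_e[1], 0.5)
  expect_equal(st$maf[2], 0)
  expect_equal(st$h_o[2], 0)
  expect_equal(st$h_e[2], 0)
  expect_equal(st$h_o[3], 1)
  expect_equal(st$q[3], 0.5)
  expect_equal(st$h_e[3], 0.5)
  expect_false(st$defined[4])
  expect_true(all(is.na(st$h_o[4])))
  expect_true(all(abs(st$p + st$q - 1)[st$defined] < 1e-12))
})

test_that("F_IS averages per-locus deficits, skipping monomorphic loci", {
  st <- data.frame(h_o = c(0.5, 0.25), h_e = c(0.5, 0.5),
                   maf = c(0.5, 0.5), defined = TRUE)
  expect_equal(diversity_summary(st)$f_is, 0.25)

  st2 <- data.frame(h_o = c(0.4, 0.4), h_e = c(0.4, 0.4),
                    maf = 0.3, defined = TRUE)
  expect_equal(diversity_summary(st2)$f_is, 0)

  st3 <- data.frame(h_o = c(0, 0), h_e = c(0.5, 0),
                    maf = c(0.5, 0), defined = TRUE)
  s <- diversity_summary(st3)
  expect_equal(s$f_is, 1)           # monomorphic locus excluded
  expect_equal(s$n_loci_f_is, 1)
  expect_error(diversity_summary(st3[0, ]), "empty")
})

test_that("summary equals a brute-force per-locus loop on random matrices", {
  for (seed in 1:5) {
    g <- random_genotypes(10, 50, missing = 0.1, seed = seed)
    s <- diversity_summary(locus_stats(g))
    o <- oracle_diversity(g$calls)
    expect_equal(s$mean_h_o, o$mean_h_o)
    expect_equal(s$mean_h_e, o$mean_h_e)
    expect_equal(s$mean_maf, o$mean_maf)
    expect_equal(s$f_is, o$f_is)
  }
})

test_that("per-individual F matches hand evaluation and bounds", {
  # 2 loci with q = 0.5, individual het at both: F = (0 - 1)/(2 - 1) = -1
  g <- toy_genotypes(cbind(c(1L, 0L, 2L, 1L), c(1L, 2L, 0L, 1L)))
  f <- per_individual_F(g)
  expect_equal(unname(f["s01"]), -1)
  # fully homozygous individual -> F = 1
  g2 <- toy_genotypes(cbind(c(0L, 1L, 1L, 2L), c(2L, 1L, 1L, 0L)))
  expect_equal(unname(per_individual_F(g2)[1]), 1)
  # individual with zero usable loci -> NA
  g3 <- toy_genotypes(cbind(c(NA, 1L, 1L, 0L), c(NA, 1L, 1L, 2L)))
  expect_true(is.na(per_individual_F(g3)[1]))
})

test_that("HWE simulation gives F_IS and per-individual F near zero", {
  g <- random_genotypes(200, 5000, missing = 0, seed = 42)
  s <- diversity_summary(locus_stats(g))
  expect_lt(abs(s$f_is), 0.02)
  expect_lt(abs(mean(per_individual_F(g))), 0.02)
})

test_that("per-group statistics restrict to groups and chromosomes", {
  calls <- cbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 2L, 2L), c(1L, 1L, 0L, 0L))
  g <- toy_genotypes(calls, chr = c("X", "X", "1"),
                     pos = c(1e5, 2e5, 1e5),
                     sex = c("male", "male", "female", "female"))
  tab <- per_group_locus_stats(g, "sex", chromosome_subset = "X")
  m <- tab[tab$group == "male", ]
  f <- tab[tab$group == "female", ]
  expect_equal(m$n_loci, 2)
  expect_equal(m$prop_monomorphic, 1)    # males: 0/0 and 0/0
  expect_equal(f$prop_monomorphic, 0.5)  # females: 0/1 poly, 2/2 mono
  expect_equal(f$missing_rate, 0)
  expect_error(per_group_locus_stats(g, c("a", "b")), "one group")
  # two identical groups give identical rows
  g2 <- toy_genotypes(rbind(calls, calls),
                      chr = c("X", "X", "1"), pos = c(1e5, 2e5, 1e5),
                      sex = rep(c("male", "female"), each = 4))
  t2 <- per_group_locus_stats(g2, "sex", chromosome_subset = "X")
  expect_equal(t2$prop_monomorphic[1], t2$prop_monomorphic[2])
  expect_equal(t2$mean_maf[1], t2$mean_maf[2])
})
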