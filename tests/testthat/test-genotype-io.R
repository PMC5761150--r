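test_that("PED parsing codes genotypes as minor-allele dosage", {
  dir <- withr::local_tempdir()
  writeLines(c("f1 s1 0 0 1 -9 A A A G",
               "f2 s2 0 0 2 -9 G G G G"),
             file.path(dir, "t.ped"))
  writeLines(c("1\tL1\t0\t100", "1\tL2\t0\t200"), file.path(dir, "t.map"))
  g <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  # L1: freq(G) = 1/4 -> B = G; L2: freq(A) = 1/4 -> B = A
  expect_equal(unname(g$calls[1, ]), c(0L, 1L))
  expect_equal(unname(g$calls[2, ]), c(2L, 0L))
  expect_equal(g$loci$allele_b, c("G", "A"))
  expect_equal(g$samples$sex, c("male", "female"))
})

test_that("all-missing column stays missing and 50/50 tie picks the later label", {
  dir <- withr::local_tempdir()
  writeLines(c("f1 s1 0 0 1 -9 0 0 A G",
               "f2 s2 0 0 1 -9 0 0 G A"),
             file.path(dir, "t.ped"))
  writeLines(c("1\tL1\t0\t100", "1\tL2\t0\t200"), file.path(dir, "t.map"))
  g <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_true(all(is.na(g$calls[, 1])))
  expect_equal(g$loci$allele_b[2], "G")    # tie at 0.5: later label is B
  expect_equal(unname(g$calls[, 2]), c(1L, 1L))
})

test_that("ragged and mismatching PED files fail with an informative error", {
  dir <- withr::local_tempdir()
  writeLines(c("f1 s1 0 0 1 -9 A A A G",
               "f2 s2 0 0 2 -9 G G"),
             file.path(dir, "t.ped"))
  writeLines(c("1\tL1\t0\t100", "1\tL2\t0\t200"), file.path(dir, "t.map"))
  expect_error(read_plink_text(file.path(dir, "t.ped"),
                               file.path(dir, "t.map")),
               "ragged PED line 2")
  writeLines(c("f1 s1 0 0 1 -9 A A",
               "f2 s2 0 0 2 -9 G G"),
             file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"),
                               file.path(dir, "t.map")),
               "mismatch")
})

test_that("text round-trip preserves calls, ids, chromosomes and positions", {
  g <- random_genotypes(10, 100, missing = 0.1, seed = 5)
  dir <- withr::local_tempdir()
  write_plink_text(g, file.path(dir, "rt"))
  g2 <- read_plink_text(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_equal(unname(g2$calls), unname(g$calls))
  expect_equal(g2$samples$id, g$samples$id)
  expect_equal(g2$loci$chr, g$loci$chr)
  expect_equal(g2$loci$pos, g$loci$pos)
  # missing calls are written as "0 0"
  ped <- readLines(file.path(dir, "rt.ped"))
  n_zero <- sum(vapply(strsplit(ped, " "), function(f)
    sum(f[-(1:6)] == "0") / 2, numeric(1)))
  expect_equal(n_zero, sum(is.na(g$calls)))
})

test_that("dosage coding is invariant under allele-label swap", {
  dir <- withr::local_tempdir()
  writeLines(c("f1 s1 0 0 1 -9 A A",
               "f2 s2 0 0 1 -9 A G",
               "f3 s3 0 0 1 -9 A G"), file.path(dir, "a.ped"))
  writeLines(c("f1 s1 0 0 1 -9 G G",        # same data, labels swapped
               "f2 s2 0 0 1 -9 G A",
               "f3 s3 0 0 1 -9 G A"), file.path(dir, "b.ped"))
  writeLines("1\tL1\t0\t100", file.path(dir, "t.map"))
  ga <- read_plink_text(file.path(dir, "a.ped"), file.path(dir, "t.map"))
  gb <- read_plink_text(file.path(dir, "b.ped"), file.path(dir, "t.map"))
  expect_equal(unname(ga$calls), unname(gb$calls))
})

test_that("binary round-trip reproduces the matrix exactly", {
  g <- random_genotypes(13, 77, missing = 0.08, seed = 9)  # N %% 4 != 0
  dir <- withr::local_tempdir()
  write_plink_binary(g, file.path(dir, "rt"))
  g2 <- read_plink_binary(file.path(dir, "rt.bed"), file.path(dir, "rt.bim"),
                          file.path(dir, "rt.fam"))
  expect_equal(unname(g2$calls), unname(g$calls))
  expect_equal(g2$loci$pos, g$loci$pos)
  expect_equal(g2$samples$id, g$samples$id)
})

test_that("BED bytes decode per the 2-bit PLINK code", {
  dir <- withr::local_tempdir()
  # 4 individuals, 1 locus. Codes per individual (2 bits, LSB first):
  # ind1=00 (hom A1), ind2=01 (missing), ind3=10 (het), ind4=11 (hom A2)
  # byte (ind4..ind1) = 11 10 01 00 = 0xE4
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xe4)), file.path(dir, "h.bed"))
  writeLines("1\tL1\t0\t100\tC\tT", file.path(dir, "h.bim"))
  writeLines(sprintf("f%d s%d 0 0 1 -9", 1:4, 1:4), file.path(dir, "h.fam"))
  g <- read_plink_binary(file.path(dir, "h.bed"), file.path(dir, "h.bim"),
                         file.path(dir, "h.fam"))
  # A1 = C dosage: 2, NA, 1, 0. Sample frequency of C is exactly 0.5, so
  # the tie rule designates the later label T as B and flips the dosage.
  expect_equal(unname(g$calls[, 1]), c(0L, NA, 1L, 2L))
  expect_equal(g$loci$allele_b[1], "T")
})

test_that("corrupt binary files are rejected", {
  dir <- withr::local_tempdir()
  writeLines("1\tL1\t0\t100\tA\tG", file.path(dir, "h.bim"))
  writeLines("f1 s1 0 0 1 -9", file.path(dir, "h.fam"))
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0xe4)), file.path(dir, "h.bed"))
  expect_error(read_plink_binary(file.path(dir, "h.bed"),
                                 file.path(dir, "h.bim"),
                                 file.path(dir, "h.fam")), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0xe4, 0xff)), file.path(dir, "h.bed"))
  expect_error(read_plink_binary(file.path(dir, "h.bed"),
                                 file.path(dir, "h.bim"),
                                 file.path(dir, "h.fam")), "truncated")
})

test_that("one fully heterozygous individual reads as all-1 dosages", {
  g <- toy_genotypes(matrix(1L, 1, 3))
  dir <- withr::local_tempdir()
  write_plink_binary(g, file.path(dir, "het"))
  g2 <- read_plink_binary(file.path(dir, "het.bed"),
                          file.path(dir, "het.bim"),
                          file.path(dir, "het.fam"))
  expect_equal(unname(g2$calls[1, ]), c(1L, 1L, 1L))
})
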