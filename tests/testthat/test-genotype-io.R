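test_that("PLINK write/read round-trips genotypes bit-identically", {
  g <- random_genotypes(n = 9, m = 17, missing_rate = 0.15)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(g, prefix)
  g2 <- read_plink(paste0(prefix, ".bed"))
  expect_identical(unname(g2$calls), unname(g$calls))
  expect_identical(g2$sample_ids, g$sample_ids)
  expect_identical(g2$variants$pos, g$variants$pos)
  expect_identical(g2$variants$a1, g$variants$a1)
  expect_identical(g2$variants$a2, g$variants$a2)
})

test_that("hand-written bed fixture decodes to the expected calls", {
  ## 2 samples x 3 variants, SNP-major, 2-bit codes (low bits = sample 1):
  ## v1: s1=00 (0), s2=10 (1)      -> 0x08
  ## v2: s1=11 (2), s2=01 (miss)   -> 0x07
  ## v3: s1=10 (1), s2=11 (2)      -> 0x0e
  dir <- withr::local_tempdir()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x08, 0x07, 0x0e)),
           file.path(dir, "hand.bed"))
  writeLines(c("1\tv1\t0\t100\tA\tG", "1\tv2\t0\t200\tC\tT", "1\tv3\t0\t300\tA\tC"),
             file.path(dir, "hand.bim"))
  writeLines(c("f1\ts1\t0\t0\t0\t-9", "f2\ts2\t0\t0\t0\t-9"),
             file.path(dir, "hand.fam"))
  g <- read_plink(file.path(dir, "hand.bed"))
  expect_identical(unname(g$calls),
                   matrix(c(0L, 1L, 2L, NA, 1L, 2L), nrow = 2))
  expect_identical(sum(is.na(g$calls)), 1L)
})

test_that("bed with wrong payload size and bad magic are rejected", {
  dir <- withr::local_tempdir()
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x08, 0x07, 0x0e)), file.path(dir, "x.bed"))
  writeLines(c("1\tv1\t0\t100\tA\tG", "1\tv2\t0\t200\tC\tT", "1\tv3\t0\t300\tA\tC"),
             file.path(dir, "x.bim"))
  writeLines(sprintf("f%d\ts%d\t0\t0\t0\t-9", 1:5, 1:5), file.path(dir, "x.fam"))
  expect_error(read_plink(file.path(dir, "x.bed")), "payload")

  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0x08)), file.path(dir, "y.bed"))
  writeLines("1\tv1\t0\t100\tA\tG", file.path(dir, "y.bim"))
  writeLines("f1\ts1\t0\t0\t0\t-9", file.path(dir, "y.fam"))
  expect_error(read_plink(file.path(dir, "y.bed")), "magic")
})

test_that("phased VCF reads into haplotypes in row order h1,h2 per sample", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "p.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|0\t0|1\t1|1"
  ), vcf)
  h <- read_vcf(vcf, require_phased = TRUE)
  expect_s3_class(h, "haplotype_matrix")
  expect_identical(as.integer(h$haplotypes[, 1]), c(0L, 0L, 0L, 1L, 1L, 1L))
})

test_that("unphased call under require_phased errors naming record and sample", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "u.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|0\t0|1",
    "1\t200\tv2\tA\tG\t.\tPASS\t.\tGT\t0/1\t0|0"
  ), vcf)
  expect_error(read_vcf(vcf, require_phased = TRUE), "1:200.*sample a")
})

test_that("VCF round-trips preserve calls and phase", {
  dir <- withr::local_tempdir()
  g <- random_genotypes(n = 6, m = 11, missing_rate = 0.1)
  f <- file.path(dir, "g.vcf")
  write_vcf(g, f)
  g2 <- read_vcf(f)
  expect_identical(unname(g2$calls), unname(g$calls))

  set.seed(3)
  h <- toy_haplotypes(matrix(rbinom(8 * 9, 1, 0.4), 8, 9))
  f2 <- file.path(dir, "h.vcf")
  write_vcf(h, f2)
  h2 <- read_vcf(f2, require_phased = TRUE)
  expect_identical(unname(h2$haplotypes), unname(h$haplotypes))
})

test_that("multi-allelic records are skipped with a count", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "1\t100\tv1\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\tv2\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1"
  ), vcf)
  expect_message(g <- read_vcf(vcf), "1 non-biallelic")
  expect_identical(nrow(g$variants), 1L)
  expect_identical(g$variants$pos, 200L)
})

test_that("genetic-map interpolation is linear, extrapolated and monotone", {
  map <- genetic_map(c("1", "1"), c(100, 300), c(0, 2))
  v <- variant_table("1", c(100L, 200L, 300L, 400L), paste0("v", 1:4), "A", "G")
  out <- interpolate_cm(map, v)
  expect_equal(out$cm, c(0, 1, 2, 3))

  ## negative extrapolation floored at 0
  v2 <- variant_table("1", 10L, "v0", "A", "G")
  expect_equal(interpolate_cm(map, v2)$cm, 0)
  expect_error(interpolate_cm(map, variant_table("2", 100L, "x", "A", "G")),
               "absent")

  ## monotone in position for random anchor sets
  set.seed(21)
  for (i in 1:20) {
    bp <- sort(sample.int(10000, 5))
    cm <- cumsum(runif(5))
    m <- genetic_map(rep("1", 5), bp, cm)
    pos <- sort(sample.int(12000, 50))
    vv <- variant_table(rep("1", 50), pos, paste0("q", 1:50), "A", "G")
    got <- interpolate_cm(m, vv)$cm
    expect_true(all(diff(got) >= -1e-12))
  }
})

test_that("merge reconciles swapped and flipped alleles to a's orientation", {
  a <- genotype_matrix(
    matrix(c(0L, 1L, 2L), ncol = 1), c("x1", "x2", "x3"),
    variant_table("1", 100L, "v1", "A", "G")
  )
  ## same variant stored swapped (G/A): codes complement via 2 - g
  b <- genotype_matrix(
    matrix(c(2L, 1L, 0L), ncol = 1), c("y1", "y2", "y3"),
    variant_table("1", 100L, "v1", "G", "A")
  )
  m <- merge_datasets(a, b)
  expect_identical(unname(m$calls[, 1]), c(0L, 1L, 2L, 0L, 1L, 2L))
  expect_identical(m$variants$a1, "A")

  ## strand-flipped (T/C vs complement A/G)
  b2 <- genotype_matrix(
    matrix(c(0L, 1L, 2L), ncol = 1), c("z1", "z2", "z3"),
    variant_table("1", 100L, "v1", "T", "C")
  )
  m2 <- merge_datasets(a, b2)
  expect_identical(unname(m2$calls[4:6, 1]), c(0L, 1L, 2L))
})

test_that("palindromic variants are dropped and counted at merge", {
  a <- genotype_matrix(
    matrix(c(0L, 1L, 2L, 2L), ncol = 2), c("x1", "x2"),
    variant_table("1", c(100L, 200L), c("v1", "v2"), c("A", "C"), c("T", "G"))
  )
  b <- genotype_matrix(
    matrix(c(1L, 1L, 0L, 2L), ncol = 2), c("y1", "y2"),
    variant_table("1", c(100L, 200L), c("v1", "v2"), c("A", "C"), c("T", "G"))
  )
  m <- merge_datasets(a, b)
  expect_identical(nrow(m$variants), 0L)
  expect_identical(unname(attr(m, "merge_stats")["palindromic_dropped"]), 2L)

  expect_error(merge_datasets(a, a), "duplicated")
})

test_that("merge of disjoint variant sets warns and returns empty panel", {
  a <- toy_genotypes(matrix(0:2, 3, 1))
  b <- genotype_matrix(
    matrix(c(0L, 1L), ncol = 1), c("q1", "q2"),
    variant_table("2", 999L, "w1", "A", "G")
  )
  expect_warning(m <- merge_datasets(a, b), "no shared variants")
  expect_identical(nrow(m$variants), 0L)
})

test_that("merge content is symmetric up to allele orientation", {
  g1 <- random_genotypes(n = 4, m = 12, missing_rate = 0, seed = 5)
  g2 <- random_genotypes(n = 3, m = 12, missing_rate = 0, seed = 6)
  g2$sample_ids <- paste0("other", 1:3)
  rownames(g2$calls) <- g2$sample_ids
  g2$variants[c("a1", "a2")] <- g1$variants[c("a1", "a2")]
  ab <- merge_datasets(g1, g2)
  ba <- merge_datasets(g2, g1)
  expect_setequal(ab$variants$id, ba$variants$id)
  common <- intersect(ab$variants$id, ba$variants$id)
  for (s in ab$sample_ids) {
    expect_identical(ab$calls[s, common], ba$calls[s, common])
  }
})
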