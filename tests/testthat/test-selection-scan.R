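test_that("EHH decay follows the partition combinatorics", {
  ## 4 haplotypes; extending one SNP right splits them into groups {2,1,1}
  haps <- rbind(
    c(0, 0, 0),
    c(0, 0, 1),
    c(0, 1, 0),
    c(0, 1, 0)
  )
  h <- toy_haplotypes(haps, cm = c(0.01, 0.02, 0.03))
  curve <- ehh_curve(h, core = 1, direction = "downstream")
  expect_equal(curve$ehh[1], 1)                       # at the core
  expect_equal(curve$ehh[2], (choose(2, 2) + choose(2, 2)) / choose(4, 2)) # {2,2}
  expect_equal(curve$ehh[3], choose(2, 2) / choose(4, 2))                  # {2,1,1}

  ## identical haplotypes: ehh stays 1
  h1 <- toy_haplotypes(matrix(rep(c(0, 1, 0, 1), each = 6), nrow = 6,
                              byrow = FALSE))
  c1 <- ehh_curve(h1, core = 2, direction = "downstream")
  expect_true(all(c1$ehh == 1))
})

test_that("EHH is non-increasing with extension distance", {
  set.seed(61)
  for (i in 1:10) {
    haps <- matrix(rbinom(12 * 30, 1, 0.5), 12, 30)
    h <- toy_haplotypes(haps, cm = sort(runif(30, 0, 0.5)))
    for (dir in c("upstream", "downstream")) {
      curve <- ehh_curve(h, core = 15, direction = dir)
      expect_true(all(diff(curve$ehh) <= 1e-12))
    }
  }
})

test_that("iHH integrates a non-decaying window to its full width", {
  ## four identical haplotypes: ehh stays 1 over 0.1 cM each side
  pattern <- rep(c(0, 1), length.out = 11)
  haps <- matrix(rep(pattern, each = 4), nrow = 4)
  h <- toy_haplotypes(haps, cm = seq(0, 0.2, by = 0.02))
  expect_equal(ihh(h, core = 6), 0.2)
})

test_that("trapezoid iHH equals a fine-grid Riemann oracle on a toy decay", {
  set.seed(67)
  haps <- matrix(rbinom(10 * 41, 1, 0.3), 10, 41)
  cm <- seq(0, 0.8, by = 0.02)
  h <- toy_haplotypes(haps, cm = cm)
  cfg <- scan_config(ehh_cutoff = 1e-9)   # no cutoff truncation inside window
  got <- ihh(h, core = 21, cfg = cfg)
  ## Riemann sum over the piecewise-linear interpolation of the two curves
  riemann <- 0
  for (dir in c("upstream", "downstream")) {
    curve <- ehh_curve(h, core = 21, direction = dir, cfg = cfg)
    if (nrow(curve) < 2) next
    f <- approxfun(curve$cm_dist, curve$ehh)
    hi <- max(curve$cm_dist)
    xs <- seq(0, hi, length.out = 200001)
    mid <- (xs[-1] + xs[-length(xs)]) / 2
    riemann <- riemann + sum(f(mid)) * (hi / 200000)
  }
  expect_equal(got, riemann, tolerance = 1e-8)
})

test_that("C++ scan reproduces the R iHH implementation", {
  set.seed(71)
  haps_t <- matrix(rbinom(20 * 60, 1, 0.5), 20, 60)
  haps_r <- matrix(rbinom(16 * 60, 1, 0.5), 16, 60)
  cm <- sort(runif(60, 0, 1.2))
  ht <- toy_haplotypes(haps_t, cm = cm, sample_prefix = "t")
  hr <- toy_haplotypes(haps_r, cm = cm, sample_prefix = "r")
  cfg <- scan_config(maf_min = 0)
  pooled <- toy_haplotypes(rbind(haps_t, haps_r), cm = cm, sample_prefix = "p")
  res <- popgenpipe:::ihh_scan_cpp(
    rbind(haps_t, haps_r), 20L, cm, rep(1L, 60), as.numeric(ht$variants$pos),
    cfg$ehh_cutoff, cfg$max_gap_bp, c(9L, 29L, 49L)
  )
  all_ids <- pooled$sample_ids
  target_ids <- all_ids[1:10]               # rows 1..20 of the pooled matrix
  ref_ids <- all_ids[11:18]
  for (k in seq_along(c(10L, 30L, 50L))) {
    core <- c(10L, 30L, 50L)[k]
    expect_equal(res[k, 1],
                 ihh(pooled, core, samples = target_ids,
                     pool_samples = all_ids, cfg = cfg),
                 tolerance = 1e-9)
    expect_equal(res[k, 2],
                 ihh(pooled, core, samples = ref_ids,
                     pool_samples = all_ids, cfg = cfg),
                 tolerance = 1e-9)
  }
})

test_that("XP-EHH is antisymmetric and normalised", {
  sim <- split_sim(73, N = 300, T_split = 60, n_chrom = 2, n_loci = 1500,
                   sample_n = 40, burn_in = 300)
  ht <- sim$haplotypes$pop1
  hr <- sim$haplotypes$pop2
  ab <- xpehh_scan(ht, hr)
  ba <- xpehh_scan(hr, ht)
  expect_equal(ab$raw, -ba$raw, tolerance = 1e-12)
  expect_equal(mean(ab$z), 0, tolerance = 1e-9)
  expect_equal(sd(ab$z), 1, tolerance = 1e-9)

  ## identical haplotype matrices: raw identically 0
  same <- xpehh_scan(ht, ht)
  expect_true(all(abs(same$raw) < 1e-12))
  expect_true(all(same$z == 0))
})

test_that("region caller reproduces the hand-constructed toy track", {
  m <- 3000
  set.seed(79)
  z <- rnorm(m) * 0.5
  pos <- seq(1e5, by = 2e4, length.out = m)
  chrom <- rep("7", m)
  ## three top SNPs within 100 kb
  z[c(1500, 1502, 1504)] <- c(5, 6, 7)
  scores <- data.frame(chrom = chrom, pos = pos, id = paste0("s", 1:m), z = z,
                       stringsAsFactors = FALSE)
  fst_p <- rep(0.5, m)
  fst_p[1501] <- 0.005                      # interior SNP, not a top SNP
  regions <- call_regions(scores, fst_p, scan_config())
  expect_identical(nrow(regions), 1L)
  expect_identical(regions$n_top_snps, 3L)
  expect_identical(regions$start, pos[1500])
  expect_identical(regions$end, pos[1504])
  expect_equal(regions$min_fst_p, 0.005)

  ## without any sub-threshold fst p the region is vetoed
  expect_identical(nrow(call_regions(scores, rep(0.5, m), scan_config())), 0L)

  ## nothing above the xpehh floor: no regions
  expect_identical(nrow(call_regions(transform(scores, z = z / 10),
                                     fst_p, scan_config())), 0L)
})

test_that("region caller splits clusters beyond the merge window", {
  m <- 4000
  z <- rep(0, m)
  pos <- seq(1e5, by = 1e4, length.out = m)
  z[c(100, 110)] <- c(6, 6.5)               # 100 kb apart
  z[c(2000, 2002)] <- c(5.5, 5.1)
  z[3500] <- 7                              # singleton: never a region
  scores <- data.frame(chrom = "2", pos = pos, id = paste0("s", 1:m), z = z,
                       stringsAsFactors = FALSE)
  fst_p <- rep(0.001, m)
  regions <- call_regions(scores, fst_p, scan_config(top_quantile = 5 / m))
  expect_identical(nrow(regions), 2L)
  expect_identical(regions$n_top_snps, c(2L, 2L))
})

test_that("BED annotation labels overlapping genes in position order", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "genes.bed")
  writeLines(c(
    "1\t100\t500\tGENE_A",
    "1\t450\t900\tGENE_B",
    "1\t460\t470\tGENE_NESTED",
    "2\t100\t200\tGENE_C"
  ), bed)
  regions <- data.frame(chrom = c("1", "1", "2"), start = c(200L, 520L, 300L),
                        end = c(300L, 950L, 400L), stringsAsFactors = FALSE)
  out <- annotate_regions(regions, bed)
  expect_identical(out$genes[1], "GENE_A")
  expect_identical(out$genes[2], "GENE_B")
  expect_identical(out$genes[3], "")

  ## brute-force interval oracle on the nested case
  region <- c(455, 465)
  g <- read_bed(bed)
  hand <- g$name[g$chrom == "1" & g$start + 1 <= region[2] & g$end >= region[1]]
  out2 <- annotate_regions(data.frame(chrom = "1", start = region[1],
                                      end = region[2]), bed)
  expect_identical(out2$genes, paste(hand, collapse = ","))

  writeLines(c("1\t100\t500\tOK", "1\tnope\t600\tBAD"), file.path(dir, "bad.bed"))
  expect_error(read_bed(file.path(dir, "bad.bed")), "line 2")
})
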