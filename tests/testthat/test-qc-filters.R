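test_that("exact Hardy-Weinberg test matches enumeration on spot cases", {
  expect_equal(hwe_exact_test(7, 0, 0), 1)          # monomorphic
  expect_equal(hwe_exact_test(0, 0, 9), 1)
  ## frozen from the enumeration oracle: 10 copies of each allele in 10
  ## diploids, no heterozygotes
  expect_equal(hwe_exact_test(5, 0, 5), 0.00136396111628308, tolerance = 1e-12)
  expect_equal(hwe_exact_test(5, 0, 5), hwe_enum_oracle(5, 0, 5),
               tolerance = 1e-12)
  ## balanced configuration is the most probable one: p = 1 region includes it
  expect_gt(hwe_exact_test(2, 6, 2), 0.5)
})

test_that("exact test equals enumeration for all configurations, small n", {
  for (n in c(2, 5, 9, 14)) {
    for (naa in 0:n) {
      for (nab in 0:(n - naa)) {
        nbb <- n - naa - nab
        expect_equal(hwe_exact_test(naa, nab, nbb),
                     hwe_enum_oracle(naa, nab, nbb),
                     tolerance = 1e-10,
                     label = sprintf("hwe(%d,%d,%d)", naa, nab, nbb))
      }
    }
  }
})

test_that("variant filters apply missingness, MAF, HWE in order with counts", {
  ## 20 samples; v1 fails missingness (15%), v2 fails MAF (monomorphic),
  ## v3 fails HWE (strong het deficit), v4 passes all
  set.seed(1)
  v1 <- c(rep(NA, 3), sample(0:2, 17, replace = TRUE, prob = c(.25, .5, .25)))
  v2 <- rep(0L, 20)
  v3 <- c(rep(0L, 10), rep(2L, 10))
  v4 <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
  g <- toy_genotypes(cbind(v1, v2, v3, v4))
  out <- filter_variants(g, qc_config())
  expect_identical(unname(out$removed), c(1L, 1L, 1L))
  expect_identical(out$genotypes$variants$id, "v4")

  ## idempotence
  again <- filter_variants(out$genotypes, qc_config())
  expect_identical(unname(again$removed), c(0L, 0L, 0L))
  expect_identical(again$genotypes$calls, out$genotypes$calls)
})

test_that("sample missingness filter runs before variant filters", {
  ## sample 1 missing 2/10 calls (20%); variant v1 missing only via sample 1
  calls <- matrix(sample(0:2, 60, replace = TRUE, prob = c(.3, .4, .3)), 6, 10)
  calls[1, 1:2] <- NA
  g <- toy_genotypes(calls)
  g2 <- filter_samples_missingness(g, qc_config())
  expect_identical(attr(g2, "n_samples_removed"), 1L)
  expect_false("s1" %in% g2$sample_ids)
  ## after sample removal no variant exceeds missingness
  out <- filter_variants(g2, qc_config())
  expect_identical(unname(out$removed["missingness"]), 0L)
})

test_that("LD pruning removes duplicated columns and keeps independent ones", {
  set.seed(7)
  base <- sample(0:2, 40, replace = TRUE, prob = c(.25, .5, .25))
  ind <- replicate(4, sample(0:2, 40, replace = TRUE, prob = c(.25, .5, .25)))
  g <- toy_genotypes(cbind(base, base, ind))
  kept <- ld_prune(g, qc_config())
  expect_identical(sum(kept %in% 1:2), 1L)        # one of the duplicates
  expect_true(all(3:6 %in% kept))

  ## post-hoc invariant: no retained pair above the threshold
  r2 <- cor(g$calls[, kept])^2
  diag(r2) <- 0
  expect_lt(max(r2), 0.4 + 1e-12)
})

test_that("LD pruning equals a brute-force replay of its rule on a toy", {
  set.seed(11)
  n <- 60
  z <- sample(0:2, n, replace = TRUE, prob = c(.25, .5, .25))
  noisy <- function(p) ifelse(runif(n) < p, sample(0:2, n, TRUE), z)
  calls <- cbind(z, noisy(.1), noisy(.9), noisy(.2), noisy(.8),
                 noisy(.05), noisy(.95), noisy(.3), noisy(.7), noisy(.5))
  g <- toy_genotypes(calls)
  cfg <- qc_config(prune_window = 10L, prune_step = 5L, prune_r2 = 0.4)

  ## independent greedy replay (single window covers all 10 variants)
  maf <- apply(calls, 2, function(x) min(mean(x) / 2, 1 - mean(x) / 2))
  alive <- rep(TRUE, 10)
  repeat {
    idx <- which(alive)
    r2 <- cor(calls[, idx])^2
    diag(r2) <- 0
    if (max(r2) <= 0.4) break
    top <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    i <- idx[top[1]]; j <- idx[top[2]]
    drop_var <- if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
    alive[drop_var] <- FALSE
  }
  expect_identical(ld_prune(g, cfg), which(alive))
})

test_that("KING kinship hits its algebraic and simulated anchors", {
  set.seed(23)
  p <- runif(5000, 0.05, 0.5)
  gm <- function(geno) toy_genotypes(geno, sample_prefix = "k")

  ## duplicated sample: exactly 0.5
  a <- rbinom(5000, 2, p)
  g <- gm(rbind(a, a, rbinom(5000, 2, p)))
  expect_equal(king_kinship(g, 1, 2), 0.5)
  ## symmetry
  expect_identical(king_kinship(g, 1, 3), king_kinship(g, 3, 1))
  ## unrelated pair near 0
  expect_lt(abs(king_kinship(g, 1, 3)), 0.02)

  ## parent-offspring: one gamete inherited from the parent
  parent1 <- rbind(rbinom(5000, 1, p), rbinom(5000, 1, p))
  parent2 <- rbind(rbinom(5000, 1, p), rbinom(5000, 1, p))
  gam1 <- parent1[cbind(sample(1:2, 5000, TRUE), 1:5000)]
  gam2 <- parent2[cbind(sample(1:2, 5000, TRUE), 1:5000)]
  g2 <- gm(rbind(colSums(parent1), gam1 + gam2))
  phi <- king_kinship(g2, 1, 2)
  expect_gt(phi, 0.20)
  expect_lt(phi, 0.30)
})

test_that("relative removal drops the hub of a trio and nothing else", {
  set.seed(31)
  p <- runif(4000, 0.1, 0.5)
  hap <- function() rbinom(4000, 1, p)
  f1 <- rbind(hap(), hap()); f2 <- rbind(hap(), hap())
  child <- rbind(f1[sample(1:2, 1), ], f2[sample(1:2, 1), ])
  calls <- rbind(
    colSums(f1), colSums(f2), colSums(child),
    rbinom(4000, 2, p), rbinom(4000, 2, p)
  )
  g <- toy_genotypes(calls, sample_prefix = "t")
  panel <- population_panel(g$sample_ids, rep("popA", 5))
  ## threshold above the kinship noise floor of a 4000-locus panel, below
  ## the parent-offspring expectation of ~0.25
  cfg <- qc_config(kinship_threshold = 0.1)
  out <- remove_relatives(g, panel, cfg)
  ## the child is related to both parents: it is the unique hub
  expect_identical(attr(out, "removed_samples"), "t3")

  ## unrelated panel: identity
  g0 <- toy_genotypes(rbind(rbinom(4000, 2, p), rbinom(4000, 2, p)),
                      sample_prefix = "u")
  p0 <- population_panel(g0$sample_ids, rep("popA", 2))
  out0 <- remove_relatives(g0, p0, cfg)
  expect_length(attr(out0, "removed_samples"), 0)

  ## duplicated sample: exactly one copy removed
  a <- rbinom(4000, 2, p)
  gd <- toy_genotypes(rbind(a, a, rbinom(4000, 2, p)), sample_prefix = "d")
  pd <- population_panel(gd$sample_ids, rep("popA", 3))
  outd <- remove_relatives(gd, pd, cfg)
  expect_length(attr(outd, "removed_samples"), 1)
})
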