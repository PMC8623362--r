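## Shared fixture builders. All fixtures are constructed in code; no data
## files are read from disk except those a test writes itself.

## small genotype matrix with optional missingness
toy_genotypes <- function(calls, chrom = "1", start_pos = 100L,
                          sample_prefix = "s") {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  m <- ncol(calls)
  genotype_matrix(
    calls,
    paste0(sample_prefix, seq_len(n)),
    variant_table(rep(chrom, m), start_pos + seq_len(m) * 10L,
                  paste0("v", seq_len(m)), rep("A", m), rep("G", m))
  )
}

## haplotype matrix from an explicit (2n x m) 0/1 matrix with cm positions
toy_haplotypes <- function(haps, cm = seq_len(ncol(haps)) * 0.01,
                           chrom = "1", sample_prefix = "s") {
  haps <- as.matrix(haps)
  m <- ncol(haps)
  v <- variant_table(rep(chrom, m), round(cm * 1e6) + seq_len(m),
                     paste0("v", seq_len(m)), rep("A", m), rep("G", m), cm)
  haplotype_matrix(haps, paste0(sample_prefix, seq_len(nrow(haps) / 2)), v)
}

## random genotype matrix for round-trip tests
random_genotypes <- function(n = 7, m = 13, missing_rate = 0.1, seed = 99) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  calls[runif(n * m) < missing_rate] <- NA
  alleles <- matrix(c("A", "C", "G", "T")[sample.int(4, 2 * m, replace = TRUE)],
                    ncol = 2)
  ## ensure a1 != a2
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- ifelse(alleles[same, 1] == "A", "G", "A")
  genotype_matrix(
    calls, paste0("ind", seq_len(n)),
    variant_table(rep("1", m), seq_len(m) * 50L, paste0("rs", seq_len(m)),
                  alleles[, 1], alleles[, 2])
  )
}

## independent Weir & Cockerham (1984) transcription (general r-population
## form), used as the formula oracle
wc_oracle <- function(counts) {
  r <- length(counts)
  n <- sapply(counts, sum)
  p <- sapply(counts, function(x) (2 * x[3] + x[2]) / (2 * sum(x)))
  h <- sapply(counts, function(x) x[2] / sum(x))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

## exact Hardy-Weinberg enumeration oracle: weights proportional to the
## number of allele-to-genotype assignments, normalised numerically
hwe_enum_oracle <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na_ <- 2 * naa + nab
  hs <- c(); w <- c()
  for (h in 0:min(na_, 2 * n - na_)) {
    if ((na_ - h) %% 2 != 0) next
    aa <- (na_ - h) / 2
    bb <- n - aa - h
    if (aa < 0 || bb < 0) next
    hs <- c(hs, h)
    w <- c(w, exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2)))
  }
  p <- w / sum(w)
  obs <- p[hs == nab]
  sum(p[p <= obs * (1 + 1e-12)])
}

## cophenetic (tree) distance matrix from an upgma_tree, for comparison
## against hclust's cophenetic distances
upgma_cophenetic <- function(tree, labels) {
  k <- length(labels)
  d <- matrix(0, k, k, dimnames = list(labels, labels))
  for (m in tree$merges) {
    for (x in m$left) for (y in m$right) {
      d[x, y] <- d[y, x] <- 2 * m$height
    }
  }
  d
}

## two-population neutral split simulation used by several tests
split_sim <- function(seed, N = 1000, T_split = 100, n_chrom = 5,
                      n_loci = 2500, sample_n = 50, burn_in = 0) {
  cfg <- sim_config(
    pop_sizes = c(N, N), split_generations = c(NA, T_split),
    sample_sizes = c(sample_n, sample_n), n_chrom = n_chrom,
    n_loci = n_loci, chrom_length_cm = 50, burn_in = burn_in, seed = seed
  )
  suppressWarnings(simulate_panel(cfg))
}
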