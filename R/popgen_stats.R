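## Allele frequencies and the Weir-Cockerham (1984) fixation-index
## estimator: per-locus variance components, genome-wide weighted FST,
## the pairwise population matrix, and empirical per-SNP p-values.

#' Allele frequency of allele a2
#'
#' @param g a [genotype_matrix()].
#' @param sample_subset sample ids or indices; default all samples.
#' @return per-variant frequency of `a2` over non-missing calls; `NA`
#'   where no call is non-missing.
#' @export
allele_freq <- function(g, sample_subset = g$sample_ids) {
  if (!length(sample_subset)) stop("empty sample subset")
  sub <- subset_samples(g, sample_subset)
  colMeans(sub$calls, na.rm = TRUE) / 2
}

#' Weir-Cockerham variance components at one locus
#'
#' Two-population variance components from genotype count tables:
#' `a` (between populations), `b` (between individuals within populations)
#' and `c` (within individuals), with `theta = a / (a + b + c)`.
#'
#' @param counts1,counts2 length-3 genotype counts `(n_aa, n_ab, n_bb)` for
#'   the two populations.
#' @return a list `a, b, c, theta`; `theta` is `NA` when `a + b + c <= 0`
#'   (monomorphic across both populations). `theta` may be negative.
#' @export
wc_fst_locus <- function(counts1, counts2) {
  stopifnot(length(counts1) == 3, length(counts2) == 3)
  n1 <- sum(counts1); n2 <- sum(counts2)
  if (n1 < 2 || n2 < 2) stop("each population needs >= 2 genotypes")
  p1 <- (2 * counts1[3] + counts1[2]) / (2 * n1)
  p2 <- (2 * counts2[3] + counts2[2]) / (2 * n2)
  h1 <- counts1[2] / n1
  h2 <- counts2[2] / n2
  comp <- wc_components(n1, n2, p1, p2, h1, h2)
  s <- comp$a + comp$b + comp$c
  theta <- if (is.na(s) || s <= 0) NA_real_ else comp$a / s
  list(a = unname(comp$a), b = unname(comp$b), c = unname(comp$c),
       theta = unname(theta))
}

## Vectorised W&C (1984) components for r = 2 populations.
## n1, n2: diploid sample sizes; p1, p2: a2 frequencies; h1, h2: observed
## heterozygote proportions. All arguments recycled to common length.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  n_bar <- (n1 + n2) / 2
  nc <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  pq <- p_bar * (1 - p_bar)
  a <- (n_bar / nc) *
    (s2 - (pq - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (pq - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  c_ <- h_bar / 2
  list(a = a, b = b, c = c_)
}

## Per-locus components for a labelled population pair inside a panel.
## Returns a data.frame aligned with g$variants; loci where either
## population has < 2 non-missing genotypes get NA components.
wc_fst_pair_loci <- function(g, panel, pop1, pop2) {
  pops <- panel_lookup(panel, g$sample_ids)
  g1 <- g$calls[pops == pop1, , drop = FALSE]
  g2 <- g$calls[pops == pop2, , drop = FALSE]
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  h1 <- colMeans(g1 == 1L, na.rm = TRUE)
  h2 <- colMeans(g2 == 1L, na.rm = TRUE)
  comp <- wc_components(n1, n2, p1, p2, h1, h2)
  ok <- n1 >= 2 & n2 >= 2
  s <- comp$a + comp$b + comp$c
  theta <- ifelse(ok & !is.na(s) & s > 0, comp$a / s, NA_real_)
  data.frame(
    chrom = g$variants$chrom, pos = g$variants$pos, id = g$variants$id,
    a = ifelse(ok, comp$a, NA_real_),
    b = ifelse(ok, comp$b, NA_real_),
    c = ifelse(ok, comp$c, NA_real_),
    theta = theta,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide weighted FST for one population pair
#'
#' Weir-Cockerham ratio-of-sums estimator `sum(a) / sum(a + b + c)` over
#' loci with defined components.
#'
#' @param g a [genotype_matrix()].
#' @param panel a [population_panel()].
#' @param pop1,pop2 population labels.
#' @return a list: `theta` (genome-wide weighted estimate), `n_loci`
#'   (loci contributing), and `loci` (per-locus component table).
#' @export
genomewide_fst <- function(g, panel, pop1, pop2) {
  loci <- wc_fst_pair_loci(g, panel, pop1, pop2)
  s <- loci$a + loci$b + loci$c
  use <- !is.na(s) & s != 0
  theta <- sum(loci$a[use]) / sum(s[use])
  list(theta = theta, n_loci = sum(use), loci = loci)
}

#' Pairwise FST matrix across populations
#'
#' @inheritParams genomewide_fst
#' @return an `fst_matrix`: list with `populations`, `theta` (raw
#'   symmetric matrix, diagonal 0) and `theta_clamped` (negatives set to
#'   0, the version fed to divergence-time math). Populations with fewer
#'   than 2 samples are excluded with a warning.
#' @export
pairwise_fst <- function(g, panel) {
  pops <- panel_lookup(panel, g$sample_ids)
  tab <- table(pops)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("populations with < 2 samples excluded: ",
            paste(small, collapse = ", "))
  }
  labels <- names(tab)[tab >= 2]
  if (length(labels) < 2) stop("need >= 2 populations with >= 2 samples")
  k <- length(labels)
  theta <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      est <- genomewide_fst(g, panel, labels[i], labels[j])$theta
      theta[i, j] <- theta[j, i] <- est
    }
  }
  structure(
    list(populations = labels, theta = theta,
         theta_clamped = pmax(theta, 0)),
    class = "fst_matrix"
  )
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix> genome-wide Weir-Cockerham FST\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Empirical per-locus FST p-values
#'
#' Upper-tail rank p-value against the genome-wide per-locus distribution:
#' `p(locus) = #(theta_j >= theta_locus) / #defined`, inclusive of the
#' locus itself, so `p` lies in `(0, 1]`.
#'
#' @param theta per-locus Weir-Cockerham theta values (NA = undefined).
#' @return per-locus p-values aligned with `theta` (`NA` preserved).
#' @export
fst_empirical_pvalues <- function(theta) {
  ok <- !is.na(theta)
  m <- sum(ok)
  if (m < 1000) {
    warning("fewer than 1000 defined loci; empirical p-values coarser than 0.01")
  }
  p <- rep(NA_real_, length(theta))
  ## #(theta_j >= theta_i) = m - #(theta_j < theta_i)
  r <- rank(theta[ok], ties.method = "min")
  p[ok] <- (m - r + 1) / m
  p
}

#' Permutation p-values for per-locus FST
#'
#' The alternative to the empirical rank: population labels are permuted
#' across samples and the per-locus theta recomputed; the p-value is the
#' fraction of permutations (plus the observed arrangement) with theta at
#' least as large as observed.
#'
#' @param g a [genotype_matrix()].
#' @param panel a [population_panel()].
#' @param pop1,pop2 population labels.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @return per-locus p-values aligned with `g$variants` (`NA` where theta
#'   is undefined); p in `(0, 1]`.
#' @export
fst_permutation_pvalues <- function(g, panel, pop1, pop2, n_perm = 199L,
                                    seed = 1L) {
  pops <- panel_lookup(panel, g$sample_ids)
  members <- which(pops %in% c(pop1, pop2))
  labels <- pops[members]
  sub <- subset_samples(g, members)
  sub_panel <- population_panel(sub$sample_ids, labels)
  obs <- wc_fst_pair_loci(sub, sub_panel, pop1, pop2)$theta
  exceed <- integer(length(obs))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm_panel <- population_panel(sub$sample_ids, sample(labels))
    perm <- wc_fst_pair_loci(sub, perm_panel, pop1, pop2)$theta
    exceed <- exceed + as.integer(!is.na(perm) & !is.na(obs) & perm >= obs)
  }
  ifelse(is.na(obs), NA_real_, (exceed + 1) / (n_perm + 1))
}
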