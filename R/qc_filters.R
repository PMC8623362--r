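## Sample and variant quality control: missingness, MAF, exact
## Hardy-Weinberg test, window-based LD pruning, KING-robust kinship.

#' QC configuration
#'
#' Defaults reproduce an array-QC recipe: drop samples and variants with
#' >10% missing data, variants with MAF < 0.01 or Hardy-Weinberg exact
#' p < 1e-4; prune LD with a 200-variant window stepping 25 at r-squared
#' 0.4; remove within-population relatives above kinship 0.0084.
#'
#' @param max_missing_rate maximum tolerated missing-call fraction.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_alpha Hardy-Weinberg exact-test significance cutoff.
#' @param prune_window,prune_step LD-pruning window and step, in variants.
#' @param prune_r2 dosage r-squared threshold for pruning.
#' @param kinship_threshold KING-robust kinship above which a pair is
#'   treated as related (2nd degree and closer).
#'
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(max_missing_rate = 0.10, min_maf = 0.01,
                      hwe_alpha = 1e-4, prune_window = 200L,
                      prune_step = 25L, prune_r2 = 0.4,
                      kinship_threshold = 0.0084) {
  stopifnot(
    max_missing_rate >= 0, max_missing_rate <= 1,
    min_maf >= 0, min_maf <= 0.5,
    hwe_alpha > 0, hwe_alpha <= 1,
    prune_window > prune_step, prune_step > 0
  )
  structure(
    list(max_missing_rate = max_missing_rate, min_maf = min_maf,
         hwe_alpha = hwe_alpha, prune_window = as.integer(prune_window),
         prune_step = as.integer(prune_step), prune_r2 = prune_r2,
         kinship_threshold = kinship_threshold),
    class = "qc_config"
  )
}

#' Exact Hardy-Weinberg test
#'
#' Two-sided exact test on one biallelic variant's genotype counts: the
#' p-value is the total probability, under the hypergeometric null that
#' conditions on the observed allele counts, of every heterozygote
#' configuration whose probability does not exceed that of the observed
#' configuration.
#'
#' @param n_aa,n_ab,n_bb genotype counts (a1 homozygote, heterozygote,
#'   a2 homozygote).
#' @return p-value in (0, 1]. Monomorphic input gives 1.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("no genotypes")
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  ## log P(n_ab = h | n, n_a) up to a common constant
  logp <- lgamma(n + 1) -
    (lgamma((n_a - hets) / 2 + 1) + lgamma(hets + 1) + lgamma((n_b - hets) / 2 + 1)) +
    hets * log(2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

variant_missing_rate <- function(g) colMeans(is.na(g$calls))
sample_missing_rate <- function(g) rowMeans(is.na(g$calls))

variant_maf <- function(g) {
  f <- colMeans(g$calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Remove samples with excess missingness
#'
#' Applied before variant filters, mirroring the usual QC order.
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return the filtered [genotype_matrix()] with attribute
#'   `n_samples_removed`.
#' @export
filter_samples_missingness <- function(g, cfg = qc_config()) {
  keep <- sample_missing_rate(g) <= cfg$max_missing_rate
  out <- subset_samples(g, which(keep))
  attr(out, "n_samples_removed") <- sum(!keep)
  out
}

#' Variant QC filters
#'
#' Applied in order: missingness above `max_missing_rate`, then MAF (over
#' non-missing calls) below `min_maf`, then Hardy-Weinberg exact p below
#' `hwe_alpha`. Each variant is counted against the first filter it fails.
#'
#' @inheritParams filter_samples_missingness
#' @return a list: `genotypes` (the filtered [genotype_matrix()]) and
#'   `removed` (named counts for `missingness`, `maf`, `hwe`).
#' @export
filter_variants <- function(g, cfg = qc_config()) {
  stopifnot(nrow(g$variants) > 0)
  fail_miss <- variant_missing_rate(g) > cfg$max_missing_rate
  maf <- variant_maf(g)
  maf[is.nan(maf)] <- 0      # all-missing columns: caught by missingness rule
  fail_maf <- !fail_miss & maf < cfg$min_maf
  candidate <- !fail_miss & !fail_maf
  fail_hwe <- logical(ncol(g$calls))
  for (j in which(candidate)) {
    x <- g$calls[, j]
    x <- x[!is.na(x)]
    p <- hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
    fail_hwe[j] <- p < cfg$hwe_alpha
  }
  keep <- !(fail_miss | fail_maf | fail_hwe)
  list(
    genotypes = subset_variants(g, which(keep)),
    removed = c(missingness = sum(fail_miss), maf = sum(fail_maf),
                hwe = sum(fail_hwe))
  )
}

## dosage r^2 between two genotype columns (pairwise-complete)
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Window-based LD pruning
#'
#' Slides a `prune_window`-variant window along each chromosome advancing
#' `prune_step` variants at a time. Within a window, while any retained
#' pair has dosage r-squared above `prune_r2`, the pair with the highest
#' r-squared is resolved by removing its lower-MAF member (tie: the later
#' position). Removals persist across windows.
#'
#' @inheritParams filter_samples_missingness
#' @return integer vector of retained variant indices (into `g$variants`).
#' @export
ld_prune <- function(g, cfg = qc_config()) {
  check_variant_order(g$variants)
  maf <- variant_maf(g)
  retained <- rep(TRUE, ncol(g$calls))
  for (ch in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == ch)
    m <- length(idx)
    starts <- seq.int(1L, max(1L, m), by = cfg$prune_step)
    for (s in starts) {
      win <- idx[s:min(s + cfg$prune_window - 1L, m)]
      win <- win[retained[win]]
      if (length(win) < 2) next
      r2 <- cor(g$calls[, win, drop = FALSE], use = "pairwise.complete.obs")^2
      diag(r2) <- 0
      r2[is.na(r2)] <- 0
      while (max(r2) > cfg$prune_r2) {
        top <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        i <- win[top[1]]; j <- win[top[2]]
        drop_var <- if (maf[i] < maf[j]) i
          else if (maf[j] < maf[i]) j
          else max(i, j)                       # tie: later position
        retained[drop_var] <- FALSE
        k <- match(drop_var, win)
        r2[k, ] <- 0; r2[, k] <- 0
      }
    }
  }
  which(retained)
}

#' KING-robust kinship coefficient for one sample pair
#'
#' The between-family robust estimator from pairwise genotype counts over
#' jointly non-missing sites:
#' \deqn{\hat\varphi = \frac{N_{het,het} - 2 N_{opp}}{2\,\min(N^i_{het}, N^j_{het})}
#'   + \frac12 - \frac{N^i_{het} + N^j_{het}}{4\,\min(N^i_{het}, N^j_{het})}}
#' Duplicates score 0.5, parent-offspring about 0.25, unrelated about 0.
#'
#' @param g a [genotype_matrix()].
#' @param i,j sample indices or ids.
#' @return the kinship estimate, with attribute `low_confidence = TRUE`
#'   when fewer than 100 jointly non-missing variants were available;
#'   `NA` when either sample has no heterozygous site.
#' @export
king_kinship <- function(g, i, j) {
  if (is.character(i)) i <- match(i, g$sample_ids)
  if (is.character(j)) j <- match(j, g$sample_ids)
  gi <- g$calls[i, ]; gj <- g$calls[j, ]
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n_het_i <- sum(gi == 1L)
  n_het_j <- sum(gj == 1L)
  n_min <- min(n_het_i, n_het_j)
  if (n_min == 0L) return(NA_real_)
  n_hh <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  phi <- (n_hh - 2 * n_opp) / (2 * n_min) + 0.5 - (n_het_i + n_het_j) / (4 * n_min)
  if (sum(ok) < 100L) attr(phi, "low_confidence") <- TRUE
  phi
}

king_kinship_matrix <- function(g) {
  n <- length(g$sample_ids)
  k <- matrix(NA_real_, n, n, dimnames = list(g$sample_ids, g$sample_ids))
  if (n < 2) return(k)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k[i, j] <- k[j, i] <- as.numeric(king_kinship(g, i, j))
    }
  }
  k
}

#' Remove relatives within populations
#'
#' Computes KING-robust kinship within each population label and greedily
#' resolves pairs above `kinship_threshold`: while any over-threshold pair
#' remains, the member with more over-threshold partners is dropped (ties:
#' higher individual missingness, then later sample order).
#'
#' @inheritParams filter_samples_missingness
#' @param panel a [population_panel()] labelling every sample of `g`.
#' @return the filtered [genotype_matrix()] with attribute
#'   `removed_samples` (character vector, possibly empty).
#' @export
remove_relatives <- function(g, panel, cfg = qc_config()) {
  miss <- sample_missing_rate(g)
  pops <- panel_lookup(panel, g$sample_ids)
  dropped <- character(0)
  for (pop in unique(pops)) {
    members <- which(pops == pop)
    if (length(members) < 2) next
    sub <- subset_samples(g, members)
    km <- king_kinship_matrix(sub)
    over <- !is.na(km) & km > cfg$kinship_threshold
    active <- rep(TRUE, length(members))
    repeat {
      ov <- over
      ov[!active, ] <- FALSE
      ov[, !active] <- FALSE
      deg <- rowSums(ov)
      if (all(deg == 0L)) break
      cand <- which(deg == max(deg))
      if (length(cand) > 1) {
        mc <- miss[members[cand]]
        cand <- cand[mc == max(mc)]
      }
      victim <- max(cand)                      # tie: later sample order
      active[victim] <- FALSE
    }
    dropped <- c(dropped, g$sample_ids[members[!active]])
  }
  keep <- setdiff(g$sample_ids, dropped)
  out <- subset_samples(g, keep)
  attr(out, "removed_samples") <- dropped
  out
}
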