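## Effective population size over time from LD: mean dosage r-squared in
## sliding recombination-distance categories, inverted through
## E[r2] = 1/(alpha + 4*Ne*c) + 1/n, with the harmonic mean across
## categories as the long-term Ne.

#' Ne-estimation configuration
#'
#' Defaults generate sliding recombination-distance categories of width
#' 0.005 cM stepping 0.001 cM from 0.005 to 0.25 cM. A category at
#' recombination distance `c` Morgans indexes Ne roughly `1/(2c)`
#' generations ago; a generation is taken as 25 years.
#'
#' @param c_start,c_end,c_step,bin_width category grid, in cM.
#' @param alpha_const constant in the r-squared expectation
#'   (`1/(alpha + 4*Ne*c)`); 2 is the mutation-drift form, 1 the
#'   drift-only form.
#' @param sample_adjustment subtract the `1/n` finite-sample term from the
#'   mean r-squared before inversion (`n` = diploid sample size).
#' @param r2_maf_min minimum MAF for variants entering r-squared pairs.
#' @param min_pairs minimum SNP-pair count for a category to be usable.
#' @param generation_years years per generation.
#' @return a list of class `ne_config`.
#' @export
ne_config <- function(c_start = 0.005, c_end = 0.25, c_step = 0.001,
                      bin_width = 0.005, alpha_const = 2,
                      sample_adjustment = TRUE, r2_maf_min = 0.05,
                      min_pairs = 50L, generation_years = 25) {
  stopifnot(c_start > 0, c_start < c_end, c_step > 0, bin_width > 0,
            alpha_const %in% c(1, 2))
  structure(
    list(c_start = c_start, c_end = c_end, c_step = c_step,
         bin_width = bin_width, alpha_const = alpha_const,
         sample_adjustment = sample_adjustment, r2_maf_min = r2_maf_min,
         min_pairs = as.integer(min_pairs),
         generation_years = generation_years),
    class = "ne_config"
  )
}

#' Recombination-distance categories
#'
#' Sliding categories `[c_start + k*c_step, c_start + k*c_step + bin_width)`
#' for `k = 0, 1, ...` while the upper bound stays within
#' `c_end + bin_width`; consecutive categories overlap whenever
#' `bin_width > c_step`.
#'
#' @param cfg an [ne_config()].
#' @return a `data.frame` with columns `c_low`, `c_high` (cM) and
#'   `c_mid` (midpoint, Morgans — the scale used in the Ne formulas).
#' @export
make_bins <- function(cfg = ne_config()) {
  k <- 0:floor((cfg$c_end - cfg$c_start) / cfg$c_step + 1e-9)
  c_low <- cfg$c_start + k * cfg$c_step
  c_high <- c_low + cfg$bin_width
  data.frame(c_low = c_low, c_high = c_high,
             c_mid = (c_low + c_high) / 2 / 100)
}

#' Mean dosage r-squared per recombination-distance category
#'
#' Accumulates the squared Pearson correlation of genotype dosages over
#' every within-chromosome SNP pair whose cM separation falls in a
#' category (pairs count in every overlapping category they fall in).
#' Variants below `r2_maf_min` MAF are excluded first.
#'
#' @param g a [genotype_matrix()] with `variants$cm` filled.
#' @param cfg an [ne_config()].
#' @return the [make_bins()] table extended with `n_pairs`, `mean_r2`,
#'   `se_r2` (empty categories carry `n_pairs = 0`, `NA` statistics), plus
#'   an attribute `n_variants_used`.
#' @export
pairwise_r2_binned <- function(g, cfg = ne_config()) {
  if (anyNA(g$variants$cm)) stop("variants$cm must be filled (see interpolate_cm)")
  maf <- variant_maf(g)
  keep <- !is.na(maf) & maf >= cfg$r2_maf_min
  ord <- order(chrom_sort_key(g$variants$chrom[keep]), g$variants$cm[keep])
  idx <- which(keep)[ord]
  bins <- make_bins(cfg)
  res <- r2_binned_cpp(
    g$calls[, idx, drop = FALSE],
    g$variants$cm[idx],
    as.integer(factor(g$variants$chrom[idx])),
    cfg$c_start, cfg$c_step, cfg$bin_width, nrow(bins)
  )
  bins$n_pairs <- res$n_pairs
  bins$mean_r2 <- ifelse(res$n_pairs > 0, res$sum_r2 / res$n_pairs, NA_real_)
  var_r2 <- ifelse(res$n_pairs > 1,
                   (res$sum_r2_sq - res$n_pairs * bins$mean_r2^2) /
                     (res$n_pairs - 1),
                   NA_real_)
  bins$se_r2 <- sqrt(pmax(var_r2, 0) / res$n_pairs)
  attr(bins, "n_variants_used") <- length(idx)
  bins
}

## Invert E[r2] = 1/(alpha + 4*Ne*c) + 1/n for Ne; NA when the adjusted
## r2 or the resulting Ne is non-positive.
invert_r2 <- function(r2, c_m, n_samples, cfg) {
  adj <- if (cfg$sample_adjustment) r2 - 1 / n_samples else r2
  ne <- ifelse(adj > 0, (1 / adj - cfg$alpha_const) / (4 * c_m), NA_real_)
  ifelse(!is.na(ne) & ne > 0, ne, NA_real_)
}

#' Ne for one recombination-distance category
#'
#' @param bin a one-row slice of the [pairwise_r2_binned()] table.
#' @param n_samples diploid sample size used for the `1/n` adjustment.
#' @param cfg an [ne_config()].
#' @return a list `ne_hat, ci_low, ci_high, generations_ago, usable`.
#'   Categories with fewer than `min_pairs` pairs, or whose adjusted
#'   r-squared inverts to a non-positive Ne, are flagged unusable
#'   (`ne_hat = NA`). The 95% CI propagates `mean_r2 +/- 1.96 se` through
#'   the same inversion (endpoints ordered; an endpoint that fails to
#'   invert becomes 0 or `Inf`).
#' @export
ne_from_bin <- function(bin, n_samples, cfg = ne_config()) {
  gen <- 1 / (2 * bin$c_mid)
  if (is.na(bin$mean_r2) || bin$n_pairs < cfg$min_pairs) {
    return(list(ne_hat = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                generations_ago = gen, usable = FALSE))
  }
  ne <- invert_r2(bin$mean_r2, bin$c_mid, n_samples, cfg)
  lo_r2 <- bin$mean_r2 - 1.96 * bin$se_r2
  hi_r2 <- bin$mean_r2 + 1.96 * bin$se_r2
  ne_hi <- invert_r2(lo_r2, bin$c_mid, n_samples, cfg)   # smaller r2 -> larger Ne
  ne_lo <- invert_r2(hi_r2, bin$c_mid, n_samples, cfg)
  if (is.na(ne)) {
    return(list(ne_hat = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                generations_ago = gen, usable = FALSE))
  }
  ci <- sort(c(ifelse(is.na(ne_lo), 0, ne_lo), ifelse(is.na(ne_hi), Inf, ne_hi)))
  list(ne_hat = ne, ci_low = ci[1], ci_high = ci[2],
       generations_ago = gen, usable = TRUE)
}

#' Ne trajectory and long-term Ne from one genotype panel
#'
#' Runs [pairwise_r2_binned()] and inverts every category with
#' [ne_from_bin()], then summarises the long-term Ne as the harmonic mean
#' across usable categories.
#'
#' @param g a [genotype_matrix()] with cM positions.
#' @param cfg an [ne_config()].
#' @return an object of class `ne_trajectory`: the per-category
#'   `data.frame` (`c_low, c_high, c_mid, n_pairs, mean_r2, se_r2,
#'   generations_ago, ne_hat, ci_low, ci_high`) with attributes
#'   `long_term` (list `ne, ci_low, ci_high, n_bins`) and `n_samples`.
#' @export
estimate_ne <- function(g, cfg = ne_config()) {
  bins <- pairwise_r2_binned(g, cfg)
  n <- length(g$sample_ids)
  est <- lapply(seq_len(nrow(bins)), function(i) ne_from_bin(bins[i, ], n, cfg))
  bins$generations_ago <- vapply(est, `[[`, numeric(1), "generations_ago")
  bins$ne_hat <- vapply(est, `[[`, numeric(1), "ne_hat")
  bins$ci_low <- vapply(est, `[[`, numeric(1), "ci_low")
  bins$ci_high <- vapply(est, `[[`, numeric(1), "ci_high")
  lt <- long_term_ne(bins)
  structure(bins, long_term = lt, n_samples = n,
            class = c("ne_trajectory", "data.frame"))
}

#' Harmonic-mean long-term Ne
#'
#' `H = m / sum(1/ne_k)` over the `m` categories with a defined Ne. The CI
#' applies the same harmonic mean to the per-category CI envelopes
#' (categories with undefined endpoints are skipped for the envelope).
#'
#' @param trajectory a `data.frame` with columns `ne_hat`, `ci_low`,
#'   `ci_high` (as produced by [estimate_ne()]).
#' @return a list `ne, ci_low, ci_high, n_bins`.
#' @export
long_term_ne <- function(trajectory) {
  ne <- trajectory$ne_hat
  ok <- !is.na(ne)
  if (!any(ok)) stop("no recombination-distance category yields a defined Ne")
  m <- sum(ok)
  h <- m / sum(1 / ne[ok])
  lo <- trajectory$ci_low
  hi <- trajectory$ci_high
  ok_lo <- !is.na(lo) & lo > 0
  ok_hi <- !is.na(hi) & hi > 0
  list(
    ne = h,
    ci_low = if (any(ok_lo)) sum(ok_lo) / sum(1 / lo[ok_lo]) else NA_real_,
    ci_high = if (any(ok_hi)) sum(ok_hi) / sum(1 / hi[ok_hi]) else NA_real_,
    n_bins = m
  )
}

#' @export
print.ne_trajectory <- function(x, ...) {
  lt <- attr(x, "long_term")
  if (is.null(lt)) return(NextMethod())   # plain data.frame slice
  cat(sprintf(
    "<ne_trajectory> %d categories (%d usable); long-term Ne = %.0f [%.0f, %.0f]\n",
    nrow(x), lt$n_bins, lt$ne, lt$ci_low, lt$ci_high
  ))
  invisible(x)
}
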