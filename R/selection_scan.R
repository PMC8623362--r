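## EHH decay, integrated EHH, the cross-population XP-EHH statistic with
## genome-wide normalisation, and the joint XP-EHH/FST candidate-region
## caller.

#' Selection-scan configuration
#'
#' @param ehh_cutoff stop integrating a direction once the pooled
#'   two-population EHH falls below this value.
#' @param max_gap_bp truncate the EHH extension at inter-SNP gaps larger
#'   than this.
#' @param maf_min minimum pooled MAF for a core SNP to be scored.
#' @param top_quantile fraction of the empirical XP-EHH distribution
#'   defining "top" SNPs (0.001 = top 0.1%).
#' @param xpehh_min additional absolute threshold on the normalised score
#'   (top SNPs must also exceed this).
#' @param fst_p_max a candidate region must contain at least one SNP with
#'   empirical FST p below this.
#' @param merge_window_bp top SNPs at most this far apart are clustered
#'   into one region.
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(ehh_cutoff = 0.05, max_gap_bp = 200000,
                        maf_min = 0.05, top_quantile = 0.001,
                        xpehh_min = 2.0, fst_p_max = 0.01,
                        merge_window_bp = 500000) {
  stopifnot(top_quantile > 0, top_quantile < 1,
            ehh_cutoff > 0, ehh_cutoff < 1)
  structure(
    list(ehh_cutoff = ehh_cutoff, max_gap_bp = max_gap_bp,
         maf_min = maf_min, top_quantile = top_quantile,
         xpehh_min = xpehh_min, fst_p_max = fst_p_max,
         merge_window_bp = merge_window_bp),
    class = "scan_config"
  )
}

## Partition-based EHH: haplotypes start in one group at the core (both
## core alleles pooled) and are refined by each locus moving outward.
ehh_from_groups <- function(group) {
  n <- length(group)
  if (n < 2) return(NA_real_)
  cnt <- tabulate(group)
  sum(choose(cnt, 2)) / choose(n, 2)
}

#' EHH decay curve from a core SNP
#'
#' Extended haplotype homozygosity at extension `x`: the probability that
#' two random haplotypes from the subset are identical over all SNPs from
#' the core out to `x` (exclusive of the core allele itself, so EHH is 1
#' at the core). The curve is non-increasing and is truncated at the
#' chromosome end or at a bp gap above `max_gap_bp`.
#'
#' @param h a [haplotype_matrix()] with cM positions.
#' @param core variant index (column of `h`).
#' @param samples sample ids or indices defining the population subset.
#' @param direction `"upstream"` (decreasing position) or `"downstream"`.
#' @param cfg a [scan_config()].
#' @return a `data.frame` with columns `variant` (index), `cm_dist`
#'   (distance from core) and `ehh`, beginning with the core row
#'   (`ehh = 1`).
#' @export
ehh_curve <- function(h, core, samples = h$sample_ids,
                      direction = c("downstream", "upstream"),
                      cfg = scan_config()) {
  direction <- match.arg(direction)
  sub <- subset_samples(h, samples)
  if (nrow(sub$haplotypes) < 2) stop("need at least 2 haplotypes")
  v <- sub$variants
  step <- if (direction == "downstream") 1L else -1L
  group <- rep(1L, nrow(sub$haplotypes))
  out <- data.frame(variant = core, cm_dist = 0, ehh = 1)
  l <- core + step
  prev_bp <- v$pos[core]
  while (l >= 1 && l <= nrow(v) && v$chrom[l] == v$chrom[core]) {
    if (abs(v$pos[l] - prev_bp) > cfg$max_gap_bp) break
    group <- as.integer(factor(group * 2L + sub$haplotypes[, l]))
    out <- rbind(out, data.frame(
      variant = l, cm_dist = abs(v$cm[l] - v$cm[core]),
      ehh = ehh_from_groups(group)
    ))
    prev_bp <- v$pos[l]
    l <- l + step
  }
  out
}

#' Integrated EHH at a core SNP
#'
#' Trapezoid integral of the EHH decay over cM distance, both directions
#' from the core. Each direction is truncated at the first extension
#' where the EHH of the *pooled* haplotype set (`pool_samples`, normally
#' both populations of an XP-EHH comparison) drops below `ehh_cutoff`;
#' that extension's segment is included. If the pooled EHH never decays
#' below the cutoff the integral runs to the chromosome end.
#'
#' @inheritParams ehh_curve
#' @param pool_samples subset whose EHH controls truncation; defaults to
#'   `samples`.
#' @return the integrated EHH (cM units).
#' @export
ihh <- function(h, core, samples = h$sample_ids, pool_samples = samples,
                cfg = scan_config()) {
  total <- 0
  for (dir in c("upstream", "downstream")) {
    own <- ehh_curve(h, core, samples, dir, cfg)
    pool <- ehh_curve(h, core, pool_samples, dir, cfg)
    stopifnot(nrow(own) == nrow(pool))
    stop_at <- which(pool$ehh < cfg$ehh_cutoff)[1]
    last <- if (is.na(stop_at)) nrow(own) else stop_at
    if (last >= 2) {
      e <- own$ehh[1:last]
      x <- own$cm_dist[1:last]
      total <- total + sum(0.5 * (e[-1] + e[-last]) * diff(x))
    }
  }
  total
}

#' Cross-population XP-EHH scan
#'
#' For every core SNP with pooled MAF at least `maf_min`, computes the
#' integrated EHH in the target and reference populations (truncated
#' where the pooled EHH decays below `ehh_cutoff`), takes
#' `raw = ln(ihh_target / ihh_ref)`, and normalises genome-wide:
#' `z = (raw - mean(raw)) / sd(raw)`. Positive `z` means unusually long
#' haplotypes in the target population.
#'
#' @param h_target,h_ref [haplotype_matrix()] objects over an identical
#'   variant set (with cM filled).
#' @param cfg a [scan_config()].
#' @return a `data.frame` (class `xpehh_scores`) with one row per scored
#'   SNP: `chrom, pos, id, ihh_target, ihh_ref, raw, z`; attribute
#'   `n_skipped` counts cores failing MAF or with an undefined ratio.
#' @export
xpehh_scan <- function(h_target, h_ref, cfg = scan_config()) {
  vt <- h_target$variants
  if (!identical(vt[c("chrom", "pos")], h_ref$variants[c("chrom", "pos")])) {
    stop("target and reference must share the same variant set")
  }
  if (anyNA(vt$cm)) stop("variants$cm must be filled")
  haps <- rbind(h_target$haplotypes, h_ref$haplotypes)
  freq <- colMeans(haps)
  maf <- pmin(freq, 1 - freq)
  cores <- which(maf >= cfg$maf_min)
  n_skipped_maf <- ncol(haps) - length(cores)
  if (!length(cores)) stop("no core SNP passes the MAF filter")
  ih <- ihh_scan_cpp(
    haps, nrow(h_target$haplotypes), vt$cm,
    as.integer(factor(vt$chrom, levels = unique(vt$chrom))), as.numeric(vt$pos),
    cfg$ehh_cutoff, cfg$max_gap_bp, cores - 1L
  )
  ok <- ih[, 1] > 0 & ih[, 2] > 0
  n_skipped <- n_skipped_maf + sum(!ok)
  cores <- cores[ok]
  if (length(cores) < 100) {
    stop("fewer than 100 scored SNPs; refusing genome-wide normalisation")
  }
  raw <- log(ih[ok, 1] / ih[ok, 2])
  s <- sd(raw)
  z <- if (s > 0) (raw - mean(raw)) / s else rep(0, length(raw))
  out <- data.frame(
    chrom = vt$chrom[cores], pos = vt$pos[cores], id = vt$id[cores],
    ihh_target = ih[ok, 1], ihh_ref = ih[ok, 2], raw = raw, z = z,
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("xpehh_scores", "data.frame")
  out
}

#' Call candidate selection regions
#'
#' Top SNPs are those in the top `top_quantile` of the empirical z
#' distribution that also exceed `xpehh_min`. Top SNPs on a chromosome at
#' most `merge_window_bp` apart are clustered; clusters with at least two
#' top SNPs whose span contains at least one SNP (top or not) with
#' empirical FST p below `fst_p_max` become candidate regions.
#'
#' @param scores an [xpehh_scan()] table.
#' @param fst_p per-SNP empirical FST p-values aligned with `scores` rows
#'   (see [fst_empirical_pvalues()]).
#' @param cfg a [scan_config()].
#' @param comparison optional label (e.g. `"LT-LVL"`) copied onto regions.
#' @return a `data.frame` with one row per region: `chrom, start, end,
#'   n_top_snps, min_fst_p, snp_ids, comparison` (zero rows when nothing
#'   qualifies).
#' @export
call_regions <- function(scores, fst_p, cfg = scan_config(), comparison = NA_character_) {
  stopifnot(length(fst_p) == nrow(scores))
  m <- nrow(scores)
  k <- max(1L, floor(cfg$top_quantile * m))
  z_cut <- sort(scores$z, decreasing = TRUE)[k]
  top <- scores$z >= z_cut & scores$z > cfg$xpehh_min
  empty <- data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    n_top_snps = integer(0), min_fst_p = numeric(0),
    snp_ids = character(0), comparison = character(0),
    stringsAsFactors = FALSE
  )
  if (!any(top)) return(empty)
  regions <- empty
  for (ch in unique(scores$chrom[top])) {
    sel <- which(top & scores$chrom == ch)
    sel <- sel[order(scores$pos[sel])]
    cluster_id <- cumsum(c(1, diff(scores$pos[sel]) > cfg$merge_window_bp))
    for (cl in unique(cluster_id)) {
      members <- sel[cluster_id == cl]
      if (length(members) < 2) next
      span <- range(scores$pos[members])
      in_span <- scores$chrom == ch & scores$pos >= span[1] & scores$pos <= span[2]
      p_span <- fst_p[in_span]
      min_p <- suppressWarnings(min(p_span, na.rm = TRUE))
      if (!is.finite(min_p) || min_p >= cfg$fst_p_max) next
      regions <- rbind(regions, data.frame(
        chrom = ch, start = span[1], end = span[2],
        n_top_snps = length(members), min_fst_p = min_p,
        snp_ids = paste(scores$id[members], collapse = ","),
        comparison = comparison, stringsAsFactors = FALSE
      ))
    }
  }
  rownames(regions) <- NULL
  regions
}

#' Read a BED file of gene intervals
#'
#' @param path BED (0-based half-open) with at least 4 columns:
#'   chrom, start, end, name.
#' @return a `data.frame` `chrom, start, end, name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 4 || is.na(suppressWarnings(as.integer(p[2]))) ||
        is.na(suppressWarnings(as.integer(p[3])))) {
      stop("malformed BED line ", i, " in ", path)
    }
  }
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)),
    end = as.integer(vapply(parts, `[`, character(1), 3)),
    name = vapply(parts, `[`, character(1), 4),
    stringsAsFactors = FALSE
  )
}

#' Annotate regions with overlapping genes
#'
#' Gene intervals are BED-style 0-based half-open; region spans are
#' 1-based inclusive. A single overlapping base pair suffices.
#'
#' @param regions a [call_regions()] table.
#' @param gene_bed a [read_bed()] table (or a path to a BED file).
#' @return `regions` with an added `genes` column (comma-separated names
#'   in position order; `""` when none overlap).
#' @export
annotate_regions <- function(regions, gene_bed) {
  if (is.character(gene_bed)) gene_bed <- read_bed(gene_bed)
  genes <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    hit <- gene_bed$chrom == regions$chrom[i] &
      gene_bed$start + 1L <= regions$end[i] &
      gene_bed$end >= regions$start[i]
    g <- gene_bed[hit, , drop = FALSE]
    genes[i] <- paste(g$name[order(g$start)], collapse = ",")
  }
  regions$genes <- genes
  regions
}
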