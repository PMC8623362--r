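## Core data containers. Deliberately lightweight S3: a genotype panel is a
## samples x variants integer matrix plus a variant table, mirroring how
## array-genotype tools (PLINK and friends) model the data.

#' Variant table constructor
#'
#' Builds the variant metadata `data.frame` shared by [genotype_matrix()] and
#' [haplotype_matrix()]. One row per biallelic SNP.
#'
#' @param chrom chromosome labels (coerced to character).
#' @param pos 1-based base-pair positions.
#' @param id variant identifier strings.
#' @param a1,a2 allele strings; `a2` is the allele counted by genotype codes.
#' @param cm genetic-map positions in centiMorgan, or `NA` until a map has
#'   been interpolated (see [interpolate_cm()]).
#'
#' @return a `data.frame` with columns `chrom, pos, id, a1, a2, cm`.
#' @export
variant_table <- function(chrom, pos, id, a1, a2, cm = NA_real_) {
  v <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    id = as.character(id),
    a1 = as.character(a1),
    a2 = as.character(a2),
    cm = as.numeric(cm),
    stringsAsFactors = FALSE
  )
  if (any(v$pos < 1L)) stop("variant positions must be >= 1")
  if (any(v$a1 == v$a2)) stop("a1 and a2 must differ for every variant")
  v
}

check_variant_order <- function(variants) {
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0L)) {
      stop("variants must be strictly increasing in position within chromosome ", ch)
    }
  }
  invisible(TRUE)
}

#' Diploid genotype matrix
#'
#' @param calls samples x variants integer matrix of allele-a2 dosages in
#'   `{0, 1, 2}`, with `NA` for missing calls.
#' @param sample_ids unique sample identifiers (length `nrow(calls)`).
#' @param variants variant table from [variant_table()] (rows = `ncol(calls)`).
#'
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_ids, variants) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (nrow(calls) != length(sample_ids)) stop("calls rows must match sample_ids")
  if (ncol(calls) != nrow(variants)) stop("calls columns must match variants")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("non-missing genotype codes must be in {0, 1, 2}")
  }
  dimnames(calls) <- list(as.character(sample_ids), variants$id)
  structure(
    list(calls = calls, sample_ids = as.character(sample_ids), variants = variants),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d variants (%d chromosome%s), %.2f%% missing\n",
    length(x$sample_ids), nrow(x$variants), length(unique(x$variants$chrom)),
    if (length(unique(x$variants$chrom)) == 1L) "" else "s",
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Phased haplotype matrix
#'
#' Rows `2*i - 1` and `2*i` hold the two phased haplotypes of sample `i`.
#'
#' @param haplotypes (2 * samples) x variants binary matrix (0 = allele a1,
#'   1 = allele a2).
#' @inheritParams genotype_matrix
#'
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(haplotypes, sample_ids, variants) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (nrow(haplotypes) != 2L * length(sample_ids)) {
    stop("haplotypes must have 2 rows per sample")
  }
  if (ncol(haplotypes) != nrow(variants)) stop("haplotype columns must match variants")
  if (!all(haplotypes %in% c(0L, 1L))) stop("haplotype entries must be 0 or 1")
  structure(
    list(
      haplotypes = haplotypes,
      sample_ids = as.character(sample_ids),
      variants = variants
    ),
    class = "haplotype_matrix"
  )
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<haplotype_matrix> %d samples (%d haplotypes) x %d variants\n",
    length(x$sample_ids), nrow(x$haplotypes), nrow(x$variants)
  ))
  invisible(x)
}

#' Collapse phased haplotypes to diploid genotypes
#'
#' @param h a [haplotype_matrix()].
#' @return a [genotype_matrix()] whose codes are the column sums of each
#'   sample's two haplotype rows.
#' @export
as_genotype_matrix <- function(h) {
  stopifnot(inherits(h, "haplotype_matrix"))
  n <- length(h$sample_ids)
  calls <- h$haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h$haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(calls, h$sample_ids, h$variants)
}

#' Subset samples of a genotype or haplotype matrix
#'
#' @param x a `genotype_matrix` or `haplotype_matrix`.
#' @param samples character vector of sample ids (order preserved) or
#'   integer indices.
#' @return an object of the same class restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  if (is.character(samples)) {
    idx <- match(samples, x$sample_ids)
    if (anyNA(idx)) stop("unknown sample ids: ", paste(samples[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(samples)
  }
  if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$calls[idx, , drop = FALSE], x$sample_ids[idx], x$variants)
  } else if (inherits(x, "haplotype_matrix")) {
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    haplotype_matrix(x$haplotypes[rows, , drop = FALSE], x$sample_ids[idx], x$variants)
  } else {
    stop("unsupported class")
  }
}

#' Subset variants by column index
#'
#' @param x a `genotype_matrix` or `haplotype_matrix`.
#' @param idx integer or logical index into the variant table.
#' @return object of the same class with the selected variants.
#' @export
subset_variants <- function(x, idx) {
  v <- x$variants[idx, , drop = FALSE]
  rownames(v) <- NULL
  if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$calls[, idx, drop = FALSE], x$sample_ids, v)
  } else if (inherits(x, "haplotype_matrix")) {
    haplotype_matrix(x$haplotypes[, idx, drop = FALSE], x$sample_ids, v)
  } else {
    stop("unsupported class")
  }
}

#' Population panel
#'
#' A sample-to-population assignment used by all between-population
#' statistics.
#'
#' @param sample_id sample identifiers.
#' @param population population labels, one per sample.
#' @return a named character vector (names = sample ids) of class
#'   `population_panel`.
#' @export
population_panel <- function(sample_id, population) {
  if (length(sample_id) != length(population)) stop("lengths differ")
  if (anyDuplicated(sample_id)) stop("duplicated sample ids in panel")
  structure(setNames(as.character(population), as.character(sample_id)),
    class = "population_panel"
  )
}

panel_lookup <- function(panel, sample_ids) {
  pop <- unclass(panel)[sample_ids]
  if (anyNA(pop)) {
    stop(
      "samples missing from panel: ",
      paste(sample_ids[is.na(pop)], collapse = ", ")
    )
  }
  unname(pop)
}
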