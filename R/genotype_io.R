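## Genotype input/output: PLINK binary filesets, VCF, genetic maps, panels,
## and cross-dataset merging. VCF parsing is delegated to vcfR; the PLINK
## bed codec is implemented here (2-bit SNP-major, v1.00 magic).

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

## PLINK 2-bit codes -> allele-a2 dosage: 00 = hom a1 (0), 01 = missing,
## 10 = het (1), 11 = hom a2 (2).
BED_CODE_TO_DOSAGE <- c(0L, NA_integer_, 1L, 2L)
DOSAGE_TO_BED_CODE <- function(g) {
  code <- integer(length(g))
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 2L] <- 3L
  code
}

#' Read a PLINK binary fileset
#'
#' Reads a SNP-major PLINK 1 binary fileset (`.bed`/`.bim`/`.fam`) into a
#' [genotype_matrix()]. Genotype codes count copies of the `.bim` column-6
#' allele (`a2`); the PLINK missing code becomes `NA`.
#'
#' @param bed_path,bim_path,fam_path paths to the three files. `bim_path`
#'   and `fam_path` default to `bed_path` with the extension swapped.
#'
#' @return a [genotype_matrix()]; the `.bim` cM column (when non-zero) is
#'   carried into `variants$cm`.
#' @export
read_plink <- function(bed_path,
                       bim_path = sub("\\.bed$", ".bim", bed_path),
                       fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  fam <- read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  bim <- read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, what = "raw", n = file.size(bed_path))
  if (length(raw) < 3L || !identical(raw[1:3], BED_MAGIC)) {
    stop("bad bed magic bytes in ", bed_path, " (expected 6c 1b 01)")
  }
  bpv <- ceiling(n / 4)                     # bytes per variant, SNP-major
  payload <- raw[-(1:3)]
  if (length(payload) != bpv * m) {
    stop(sprintf(
      "bed payload is %d bytes but %d samples x %d variants requires %d",
      length(payload), n, m, bpv * m
    ))
  }
  bytes <- as.integer(payload)
  dim(bytes) <- c(bpv, m)
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  for (k in 0:3) {                          # sample within byte, low bits first
    rows <- seq.int(k + 1L, by = 4L, length.out = bpv)
    rows <- rows[rows <= n]
    if (!length(rows)) next
    byte_idx <- ((rows - 1L) %/% 4L) + 1L
    codes <- (bytes[byte_idx, , drop = FALSE] %/% (4L^k)) %% 4L
    calls[rows, ] <- BED_CODE_TO_DOSAGE[codes + 1L]
  }
  cm <- bim[[3]]
  cm[cm == 0] <- NA_real_
  variants <- variant_table(bim[[1]], bim[[4]], bim[[2]], bim[[5]], bim[[6]], cm)
  genotype_matrix(calls, fam[[2]], variants)
}

#' Write a PLINK binary fileset
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix; writes `prefix.bed`, `prefix.bim`,
#'   `prefix.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- length(g$sample_ids)
  m <- nrow(g$variants)
  bpv <- ceiling(n / 4)
  codes <- DOSAGE_TO_BED_CODE(g$calls)      # column-major: sample fastest
  dim(codes) <- c(n, m)
  bytes <- matrix(0L, nrow = bpv, ncol = m)
  for (k in 0:3) {
    rows <- seq.int(k + 1L, by = 4L, length.out = bpv)
    rows <- rows[rows <= n]
    if (!length(rows)) next
    byte_idx <- ((rows - 1L) %/% 4L) + 1L
    bytes[byte_idx, ] <- bytes[byte_idx, ] + codes[rows, , drop = FALSE] * (4L^k)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(bytes), con)
  v <- g$variants
  cm <- ifelse(is.na(v$cm), 0, v$cm)
  write.table(
    data.frame(v$chrom, v$id, cm, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  write.table(
    data.frame(g$sample_ids, g$sample_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Read genotypes or phased haplotypes from a VCF
#'
#' Biallelic SNP records are read into a [genotype_matrix()], or, with
#' `require_phased = TRUE`, into a [haplotype_matrix()]. Multi-allelic
#' records are skipped (their count is reported in a message). Under
#' `require_phased`, any retained record with a `/`-separated genotype is
#' an error naming the record and sample.
#'
#' @param path a VCF v4.x file (plain or bgzipped).
#' @param require_phased if `TRUE`, demand `|`-separated genotypes and
#'   return phased haplotypes.
#'
#' @return a [genotype_matrix()] or, when `require_phased`, a
#'   [haplotype_matrix()].
#' @export
read_vcf <- function(path, require_phased = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keep <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." & !is.na(fix[, "ALT"])
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic VCF record(s) skipped")
  }
  gt <- v@gt[keep, -1L, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (!nrow(fix)) stop("no biallelic records in ", path)
  sample_ids <- colnames(v@gt)[-1L]
  ## GT is the first colon-separated field per VCF spec
  gt <- sub(":.*$", "", gt)
  if (require_phased) {
    bad <- which(matrix(grepl("/", gt), nrow = nrow(gt)), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      i <- bad[1, 1]; j <- bad[1, 2]
      stop(sprintf(
        "unphased genotype '%s' at %s:%s for sample %s (require_phased = TRUE)",
        gt[i, j], fix[i, "CHROM"], fix[i, "POS"], sample_ids[j]
      ))
    }
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[is.na(ids) | ids == ".", "CHROM"], ":", fix[is.na(ids) | ids == ".", "POS"]
  )
  variants <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]), ids,
                            fix[, "REF"], fix[, "ALT"])
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^[^/|]*[/|]", "", gt)
  a1[a1 == "."] <- NA; a2[a2 == "."] <- NA
  a1 <- suppressWarnings(matrix(as.integer(a1), nrow = nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(a2), nrow = nrow(gt)))
  if (require_phased) {
    if (anyNA(a1) || anyNA(a2)) stop("missing genotypes not allowed in phased input")
    n <- length(sample_ids)
    haps <- matrix(0L, nrow = 2L * n, ncol = nrow(variants))
    haps[seq(1L, 2L * n, 2L), ] <- t(a1)
    haps[seq(2L, 2L * n, 2L), ] <- t(a2)
    haplotype_matrix(haps, sample_ids, variants)
  } else {
    genotype_matrix(t(a1 + a2), sample_ids, variants)
  }
}

#' Write genotypes or phased haplotypes to VCF v4.2
#'
#' @param x a [genotype_matrix()] (written unphased, `/`) or
#'   [haplotype_matrix()] (written phased, `|`). `a1` is used as REF and
#'   `a2` as ALT, consistent with the dosage convention.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  phased <- inherits(x, "haplotype_matrix")
  v <- x$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=popgenpipe",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_ids), collapse = "\t")
  )
  n <- length(x$sample_ids)
  if (phased) {
    h1 <- t(x$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE])
    h2 <- t(x$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE])
    gt <- matrix(paste0(h1, "|", h2), nrow = nrow(v))
  } else {
    g <- t(x$calls)
    gt <- matrix("./.", nrow = nrow(v), ncol = n)
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
  }
  body <- paste(
    v$chrom, v$pos, v$id, v$a1, v$a2, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genetic map
#'
#' @param path whitespace-delimited text with a header line and columns
#'   chromosome, base-pair position, cM position.
#' @return a `genetic_map`: a `data.frame` with columns `chrom, bp, cm`,
#'   validated per chromosome (bp strictly increasing, cM non-decreasing).
#' @export
read_genetic_map <- function(path) {
  m <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(m) < 3) stop("genetic map needs 3 columns: chrom, bp, cM")
  genetic_map(m[[1]], m[[2]], m[[3]])
}

#' Construct a genetic map
#'
#' @param chrom chromosome labels.
#' @param bp base-pair anchor positions.
#' @param cm cM positions at the anchors.
#' @return a `genetic_map` data.frame.
#' @export
genetic_map <- function(chrom, bp, cm) {
  m <- data.frame(chrom = as.character(chrom), bp = as.numeric(bp),
                  cm = as.numeric(cm), stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$bp), ]
  rownames(m) <- NULL
  for (ch in unique(m$chrom)) {
    sel <- m$chrom == ch
    if (any(diff(m$bp[sel]) <= 0)) stop("map bp not strictly increasing on ", ch)
    if (any(diff(m$cm[sel]) < 0)) stop("map cM decreasing on ", ch)
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Interpolate cM positions onto variants
#'
#' Linear interpolation between flanking map anchors; positions outside the
#' anchor range are extrapolated with the nearest interval's slope and
#' floored at 0 cM.
#'
#' @param map a [genetic_map()].
#' @param x a `genotype_matrix`, `haplotype_matrix`, or a variant table.
#' @return `x` with `variants$cm` (or the table's `cm`) filled.
#' @export
interpolate_cm <- function(map, x) {
  variants <- if (is.data.frame(x)) x else x$variants
  cm <- numeric(nrow(variants))
  for (ch in unique(variants$chrom)) {
    sel <- variants$chrom == ch
    anchors <- map[map$chrom == ch, ]
    if (!nrow(anchors)) stop("chromosome ", ch, " absent from genetic map")
    pos <- variants$pos[sel]
    if (nrow(anchors) == 1L) {
      cm[sel] <- anchors$cm
      next
    }
    val <- approx(anchors$bp, anchors$cm, xout = pos, rule = 1)$y
    ## extrapolate with the nearest interval's slope
    lo <- pos < anchors$bp[1]
    hi <- pos > anchors$bp[nrow(anchors)]
    s_lo <- (anchors$cm[2] - anchors$cm[1]) / (anchors$bp[2] - anchors$bp[1])
    k <- nrow(anchors)
    s_hi <- (anchors$cm[k] - anchors$cm[k - 1]) / (anchors$bp[k] - anchors$bp[k - 1])
    val[lo] <- anchors$cm[1] + s_lo * (pos[lo] - anchors$bp[1])
    val[hi] <- anchors$cm[k] + s_hi * (pos[hi] - anchors$bp[k])
    cm[sel] <- pmax(val, 0)
  }
  if (is.data.frame(x)) {
    x$cm <- cm
    x
  } else {
    x$variants$cm <- cm
    x
  }
}

#' Read a population panel file
#'
#' @param path two-column whitespace-delimited text (sample_id, population),
#'   no header.
#' @return a [population_panel()].
#' @export
read_panel <- function(path) {
  p <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  population_panel(p[[1]], p[[2]])
}

#' Write a population panel file
#'
#' @param panel a [population_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.table(data.frame(names(panel), unclass(panel)), path,
              quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Merge two genotype datasets on shared variants
#'
#' Intersects variants by (chromosome, position) and reconciles alleles to
#' the orientation of `a`: exact matches are kept, swapped A1/A2 are recoded
#' as `2 - g`, strand flips (base complement) are recoded likewise, and
#' palindromic A/T and C/G variants are dropped rather than strand-guessed.
#' Variants whose allele sets cannot be reconciled are also dropped.
#'
#' @param a,b [genotype_matrix()] objects with disjoint sample ids.
#' @return a [genotype_matrix()] over the union of samples and the
#'   reconciled variant intersection, sorted by (chrom, pos), with an
#'   attribute `merge_stats`: counts of variants dropped as palindromic or
#'   allele-mismatched.
#' @export
merge_datasets <- function(a, b) {
  if (length(intersect(a$sample_ids, b$sample_ids))) {
    stop("sample ids duplicated across datasets: ",
         paste(head(intersect(a$sample_ids, b$sample_ids)), collapse = ", "))
  }
  key_a <- paste(a$variants$chrom, a$variants$pos)
  key_b <- paste(b$variants$chrom, b$variants$pos)
  shared <- intersect(key_a, key_b)
  ia <- match(shared, key_a)
  ib <- match(shared, key_b)
  if (!length(shared)) {
    warning("no shared variants between datasets; merged panel is empty")
  }
  va <- a$variants[ia, , drop = FALSE]
  vb <- b$variants[ib, , drop = FALSE]
  pal <- is_palindromic(va$a1, va$a2) | is_palindromic(vb$a1, vb$a2)
  exact <- vb$a1 == va$a1 & vb$a2 == va$a2
  swap <- vb$a1 == va$a2 & vb$a2 == va$a1
  cb1 <- unname(COMPLEMENT[vb$a1]); cb2 <- unname(COMPLEMENT[vb$a2])
  flip <- !is.na(cb1) & !is.na(cb2) & cb1 == va$a1 & cb2 == va$a2
  flip_swap <- !is.na(cb1) & !is.na(cb2) & cb1 == va$a2 & cb2 == va$a1
  ok <- !pal & (exact | swap | flip | flip_swap)
  n_pal <- sum(pal)
  n_mismatch <- sum(!pal & !ok)
  ia <- ia[ok]; ib <- ib[ok]
  recode <- (swap | flip_swap)[ok]
  calls_b <- b$calls[, ib, drop = FALSE]
  if (any(recode)) {
    calls_b[, recode] <- 2L - calls_b[, recode, drop = FALSE]
  }
  calls <- rbind(a$calls[, ia, drop = FALSE], calls_b)
  variants <- a$variants[ia, , drop = FALSE]
  ord <- order(chrom_sort_key(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  g <- genotype_matrix(calls[, ord, drop = FALSE],
                       c(a$sample_ids, b$sample_ids), variants)
  attr(g, "merge_stats") <- c(palindromic_dropped = n_pal,
                              mismatch_dropped = n_mismatch)
  g
}

chrom_sort_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ifelse(is.na(num), rank(chrom) + 1e6, num)
}
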