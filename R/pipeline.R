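## Orchestrates the study-shaped workflow: QC -> FST -> Ne -> divergence
## -> selection scan, from one config, persisting plain-text artifacts
## and a run manifest.

#' Pipeline run configuration
#'
#' @param vcf path to a phased VCF holding all samples (phase is required
#'   by the selection scan).
#' @param map path to a genetic-map file (see [read_genetic_map()]).
#' @param panel path to a two-column panel file (sample, population).
#' @param pairs list of `c(target, reference)` population label pairs for
#'   the XP-EHH scan (may be empty).
#' @param out_dir output directory for stage artifacts.
#' @param qc a [qc_config()].
#' @param ne a [ne_config()].
#' @param scan a [scan_config()].
#' @param gene_bed optional BED file of gene intervals for region
#'   annotation.
#' @param min_pop_size_ne smallest population (post-QC) for which an Ne
#'   trajectory is attempted.
#' @param seed integer seed recorded in the manifest (the statistical
#'   stages are deterministic given identical inputs).
#' @return a list of class `run_config`.
#' @export
run_config <- function(vcf, map, panel, pairs = list(), out_dir,
                       qc = qc_config(), ne = ne_config(),
                       scan = scan_config(), gene_bed = NULL,
                       min_pop_size_ne = 10L, seed = 1L) {
  structure(
    list(vcf = vcf, map = map, panel = panel, pairs = pairs,
         out_dir = out_dir, qc = qc, ne = ne, scan = scan,
         gene_bed = gene_bed, min_pop_size_ne = as.integer(min_pop_size_ne),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

write_tsv <- function(x, path, row.names = FALSE) {
  write.table(x, path, quote = FALSE, sep = "\t", row.names = row.names,
              col.names = TRUE)
  path
}

#' Run the full pipeline
#'
#' Stages run in order (`qc`, `fst`, `ne`, `diverge`, `scan`), each
#' persisting its artifact as plain text under `out_dir` so that every
#' stage is independently re-runnable and diffable. Re-running with an
#' identical config and inputs reproduces identical statistical outputs.
#'
#' @param cfg a [run_config()].
#' @return the manifest: a `data.frame` with one row per completed stage
#'   (`stage`, `rows`, `seconds`, `artifact`), also written to
#'   `out_dir/manifest.tsv`.
#' @export
run_pipeline <- function(cfg) {
  inputs <- c(cfg$vcf, cfg$map, cfg$panel, cfg$gene_bed)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))
  for (pr in cfg$pairs) stopifnot(length(pr) == 2)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  manifest <- data.frame(stage = character(0), rows = integer(0),
                         seconds = numeric(0), artifact = character(0),
                         stringsAsFactors = FALSE)
  note <- function(stage, rows, t0, artifact) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, rows = rows,
      seconds = round(as.numeric(Sys.time()) - t0, 2),
      artifact = artifact, stringsAsFactors = FALSE
    ))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- qc ----
  t0 <- as.numeric(Sys.time())
  panel <- read_panel(cfg$panel)
  gmap <- read_genetic_map(cfg$map)
  st <- run_stage("qc", {
    haps <- read_vcf(cfg$vcf, require_phased = TRUE)
    g <- as_genotype_matrix(haps)
    g <- filter_samples_missingness(g, cfg$qc)
    vf <- filter_variants(g, cfg$qc)
    g <- vf$genotypes
    ## kinship on the LD-pruned variant set, removal applied to all data
    pruned <- subset_variants(g, ld_prune(g, cfg$qc))
    kept <- remove_relatives(pruned, panel, cfg$qc)
    g <- subset_samples(g, kept$sample_ids)
    haps <- subset_samples(haps, g$sample_ids)
    haps <- subset_variants(haps, match(g$variants$id, haps$variants$id))
    g <- interpolate_cm(gmap, g)
    haps$variants$cm <- g$variants$cm
    report <- data.frame(
      filter = c("variant_missingness", "variant_maf", "variant_hwe",
                 "samples_relatedness"),
      removed = c(vf$removed, length(attr(kept, "removed_samples")))
    )
    write_tsv(report, file.path(cfg$out_dir, "qc_report.tsv"))
    write_plink(g, file.path(cfg$out_dir, "qc_filtered"))
    list(g = g, haps = haps, report = report)
  })
  note("qc", nrow(st$g$variants), t0, "qc_filtered.bed")
  g <- st$g
  haps <- st$haps

  ## ---- fst ----
  t0 <- as.numeric(Sys.time())
  fst <- run_stage("fst", {
    fm <- pairwise_fst(g, panel)
    write_tsv(as.data.frame(fm$theta), file.path(cfg$out_dir, "fst_matrix.tsv"),
              row.names = TRUE)
    fm
  })
  note("fst", length(fst$populations), t0, "fst_matrix.tsv")

  ## ---- ne ----
  t0 <- as.numeric(Sys.time())
  pops <- panel_lookup(panel, g$sample_ids)
  ne_by_pop <- run_stage("ne", {
    res <- list()
    for (pop in unique(pops)) {
      members <- g$sample_ids[pops == pop]
      if (length(members) < cfg$min_pop_size_ne) next
      traj <- estimate_ne(subset_samples(g, members), cfg$ne)
      write_tsv(as.data.frame(traj),
                file.path(cfg$out_dir, paste0("ne_trajectory_", pop, ".tsv")))
      res[[pop]] <- attr(traj, "long_term")
    }
    if (length(res)) {
      summary <- data.frame(
        population = names(res),
        long_term_ne = vapply(res, `[[`, numeric(1), "ne"),
        ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
        ci_high = vapply(res, `[[`, numeric(1), "ci_high")
      )
      write_tsv(summary, file.path(cfg$out_dir, "ne_summary.tsv"))
    }
    res
  })
  note("ne", length(ne_by_pop), t0, "ne_summary.tsv")

  ## ---- diverge ----
  t0 <- as.numeric(Sys.time())
  div <- run_stage("diverge", {
    ne_vec <- vapply(ne_by_pop, `[[`, numeric(1), "ne")
    shared <- intersect(fst$populations, names(ne_vec))
    if (length(shared) >= 2) {
      fsub <- fst$theta_clamped[shared, shared, drop = FALSE]
      d <- divergence_matrix(fsub, ne_vec[shared],
                             generation_years = cfg$ne$generation_years)
      write_tsv(as.data.frame(d$T_years),
                file.path(cfg$out_dir, "divergence_years.tsv"), row.names = TRUE)
      if (!is.null(d$tree)) write_newick(d$tree, file.path(cfg$out_dir, "divergence.nwk"))
      d
    } else NULL
  })
  note("diverge", if (is.null(div)) 0L else length(div$populations), t0,
       "divergence_years.tsv")

  ## ---- scan ----
  t0 <- as.numeric(Sys.time())
  n_regions <- run_stage("scan", {
    all_regions <- list()
    hap_pops <- panel_lookup(panel, haps$sample_ids)
    for (pr in cfg$pairs) {
      target <- pr[1]; ref <- pr[2]
      ht <- subset_samples(haps, haps$sample_ids[hap_pops == target])
      hr <- subset_samples(haps, haps$sample_ids[hap_pops == ref])
      scores <- xpehh_scan(ht, hr, cfg$scan)
      loci <- wc_fst_pair_loci(g, panel, target, ref)
      theta <- loci$theta[match(scores$id, loci$id)]
      fst_p <- fst_empirical_pvalues(theta)
      scores$fst <- theta
      scores$fst_p <- fst_p
      label <- paste0(target, "-", ref)
      write_tsv(scores, file.path(cfg$out_dir, paste0("xpehh_", label, ".tsv")))
      regions <- call_regions(scores, fst_p, cfg$scan, comparison = label)
      if (!is.null(cfg$gene_bed) && nrow(regions)) {
        regions <- annotate_regions(regions, cfg$gene_bed)
      }
      all_regions[[label]] <- regions
    }
    if (length(all_regions)) {
      combined <- do.call(rbind, all_regions)
      rownames(combined) <- NULL
      write_tsv(combined, file.path(cfg$out_dir, "candidate_regions.tsv"))
      nrow(combined)
    } else 0L
  })
  note("scan", n_regions, t0, "candidate_regions.tsv")

  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  manifest
}
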