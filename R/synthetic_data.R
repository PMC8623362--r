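## Forward Wright-Fisher simulator: discrete generations, uniform parent
## choice (fitness-weighted under a sweep), Poisson recombination on a
## linear genetic map, population splits by pool copying, standing
## variation only (founder haplotypes drawn in linkage equilibrium).

#' Simulation configuration
#'
#' Populations are indexed 1..n; population 1 is the root. Every other
#' population splits from `parent` at `split_generations` generations
#' before present and evolves independently afterwards (no migration).
#' Loci are placed uniformly on a linear 1 cM/Mb map. Founder haplotypes
#' are in linkage equilibrium with allele frequencies drawn from
#' `founder_maf`; ancestral LD builds up during a burn-in before the
#' first split.
#'
#' @param pop_sizes diploid population sizes, one per population.
#' @param split_generations generations ago each population split from
#'   its parent (`NA` for the root).
#' @param parent parent population index per population (`NA` for root).
#'   Defaults to everyone splitting from the root.
#' @param sample_sizes diploids sampled per population at present.
#' @param pop_names population labels.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_cm chromosome length in cM (1 cM = 1 Mb).
#' @param n_loci founder loci per chromosome.
#' @param founder_maf range (low, high) of the uniform founder
#'   allele-frequency distribution.
#' @param sweep optional hard sweep: a list with `population` (index),
#'   `s` (additive selection coefficient; fitness 1, 1+s, 1+2s),
#'   `start_gen` (generations ago the sweep starts), `start_freq`
#'   (initial allele frequency), and optionally `chrom`, `cm` (placement,
#'   default middle of chromosome 1) and `min_end_freq` (default 0.8;
#'   simulations whose sweep allele ends below this are re-seeded and
#'   retried, conditioning on establishment).
#' @param burn_in generations of ancestral evolution before the deepest
#'   split; default `10 * max(pop_sizes)`. Shorter burn-ins are accepted
#'   with a warning that ancestral LD may not be fully equilibrated.
#' @param seed integer seed; identical seeds give identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(pop_sizes = c(500, 500),
                       split_generations = c(NA, 100),
                       parent = NULL,
                       sample_sizes = pmin(pop_sizes, 50),
                       pop_names = paste0("pop", seq_along(pop_sizes)),
                       n_chrom = 4L, chrom_length_cm = 50,
                       n_loci = 1000L,
                       founder_maf = c(0.05, 0.5),
                       sweep = NULL,
                       burn_in = NULL,
                       seed = 1L) {
  n_pops <- length(pop_sizes)
  if (is.null(parent)) parent <- c(NA_integer_, rep(1L, n_pops - 1L))
  stopifnot(
    all(pop_sizes >= 2),
    length(split_generations) == n_pops,
    length(parent) == n_pops,
    length(sample_sizes) == n_pops,
    all(sample_sizes <= pop_sizes),
    is.na(parent[1]), is.na(split_generations[1])
  )
  if (n_pops > 1) {
    stopifnot(all(!is.na(split_generations[-1])), all(parent[-1] >= 1))
    ## a child must not predate its parent
    for (p in 2:n_pops) {
      pp <- parent[p]
      if (pp != 1 && split_generations[p] > split_generations[pp]) {
        stop("population ", p, " splits before its parent exists")
      }
    }
  }
  if (!is.null(sweep)) {
    stopifnot(sweep$s > 0, sweep$s < 1,
              sweep$start_freq > 0, sweep$start_freq < 1)
    sweep$chrom <- if (is.null(sweep$chrom)) 1L else sweep$chrom
    sweep$cm <- if (is.null(sweep$cm)) chrom_length_cm / 2 else sweep$cm
    sweep$min_end_freq <- if (is.null(sweep$min_end_freq)) 0.8 else sweep$min_end_freq
    pop <- sweep$population
    if (pop != 1 && sweep$start_gen > split_generations[pop]) {
      stop("sweep starts before its population exists")
    }
  }
  if (is.null(burn_in)) burn_in <- 10L * max(pop_sizes)
  structure(
    list(n_pops = n_pops, pop_sizes = as.integer(pop_sizes),
         split_generations = split_generations, parent = as.integer(parent),
         sample_sizes = as.integer(sample_sizes), pop_names = pop_names,
         n_chrom = as.integer(n_chrom), chrom_length_cm = chrom_length_cm,
         n_loci = as.integer(n_loci), founder_maf = founder_maf,
         sweep = sweep, burn_in = as.integer(burn_in), seed = as.integer(seed)),
    class = "sim_config"
  )
}

## lineage location of population p at time t generations ago
ancestor_at <- function(cfg, p, t) {
  while (!is.na(cfg$parent[p]) && t >= cfg$split_generations[p]) {
    p <- cfg$parent[p]
  }
  p
}

## pairwise lineage-divergence times implied by the population tree
pair_divergence <- function(cfg) {
  n <- cfg$n_pops
  t_mat <- matrix(0, n, n, dimnames = list(cfg$pop_names, cfg$pop_names))
  times <- sort(unique(cfg$split_generations[!is.na(cfg$split_generations)]))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      t_div <- NA_real_
      for (t in times) {
        if (ancestor_at(cfg, i, t) == ancestor_at(cfg, j, t)) {
          t_div <- t
          break
        }
      }
      t_mat[i, j] <- t_mat[j, i] <- t_div
    }
  }
  t_mat
}

#' Simulate a multi-population SNP panel
#'
#' Runs the forward Wright-Fisher model of [sim_config()] and samples
#' phased haplotypes at present. Loci monomorphic across the pooled
#' sample are dropped from the output.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_result`:
#'   `haplotypes` (named list of [haplotype_matrix()], one per population),
#'   `map` (a [genetic_map()]), `panel` (a [population_panel()]), and
#'   `truth` — the config echoed back plus `expected_fst` (pairwise
#'   `1 - (1 - 1/(2N))^T` with `N` the harmonic mean of the pair's sizes
#'   and `T` the lineage divergence time), `divergence_gen`, and, under a
#'   sweep, `sweep_locus_id` and `sweep_end_freq` (realised frequency in
#'   the target population pool).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$burn_in < 10L * max(cfg$pop_sizes)) {
    warning("burn-in shorter than 10*N: ancestral LD may not be fully equilibrated")
  }
  max_retry <- 25L
  for (attempt in 0:max_retry) {
    ## distinct RNG stream per attempt, without colliding across base seeds
    set.seed((cfg$seed + attempt * 1000003L) %% .Machine$integer.max)
    out <- simulate_once(cfg)
    if (is.null(cfg$sweep)) return(out)
    if (!is.na(out$truth$sweep_end_freq) &&
        out$truth$sweep_end_freq >= cfg$sweep$min_end_freq) {
      out$truth$sweep_attempts <- attempt + 1L
      return(out)
    }
  }
  stop("sweep allele failed to establish in ", max_retry + 1L, " attempts")
}

simulate_once <- function(cfg) {
  L_chrom <- cfg$n_loci
  bp_len <- round(cfg$chrom_length_cm * 1e6)
  chrom <- rep(as.character(seq_len(cfg$n_chrom)), each = L_chrom)
  pos <- unlist(lapply(seq_len(cfg$n_chrom), function(i) {
    sort(sample.int(bp_len, L_chrom))
  }))
  cm <- pos / 1e6
  L <- length(pos)
  chrom_id <- rep(seq_len(cfg$n_chrom), each = L_chrom)
  variants <- variant_table(
    chrom, pos, paste0("c", chrom, "s", sequence(rep(L_chrom, cfg$n_chrom))),
    "A", "G", cm
  )
  map <- genetic_map(
    rep(as.character(seq_len(cfg$n_chrom)), each = 2),
    rep(c(1, bp_len), cfg$n_chrom),
    rep(c(0, cfg$chrom_length_cm), cfg$n_chrom)
  )

  sweep <- cfg$sweep
  sweep_locus <- NA_integer_
  if (!is.null(sweep)) {
    cand <- which(chrom_id == sweep$chrom)
    sweep_locus <- cand[which.min(abs(cm[cand] - sweep$cm))]
  }

  ## founder pool (root), loci x haplotypes, linkage equilibrium
  p0 <- runif(L, cfg$founder_maf[1], cfg$founder_maf[2])
  root_n <- cfg$pop_sizes[1]
  pool <- founder_pool_cpp(p0, 2L * root_n)
  if (!is.null(sweep)) pool[sweep_locus, ] <- as.raw(0L)  # sweep allele absent ancestrally

  pools <- vector("list", cfg$n_pops)
  pools[[1]] <- pool
  deepest <- if (cfg$n_pops > 1) max(cfg$split_generations[-1]) else 0
  t_now <- cfg$burn_in + deepest

  ## event times: splits, sweep start, present
  events <- sort(unique(c(
    cfg$split_generations[!is.na(cfg$split_generations)],
    if (!is.null(sweep)) sweep$start_gen,
    0
  )), decreasing = TRUE)
  events <- events[events <= t_now]

  sel_active <- rep(FALSE, cfg$n_pops)
  advance <- function(p, dt) {
    sel <- if (!is.null(sweep) && sel_active[p]) sweep_locus - 1L else -1L
    s <- if (sel >= 0) sweep$s else 0
    wf_evolve_cpp(pools[[p]], cm, chrom_id, cfg$pop_sizes[p], dt, sel, s)
  }

  for (ev in events) {
    dt <- t_now - ev
    for (p in seq_len(cfg$n_pops)) {
      if (!is.null(pools[[p]]) && dt > 0) pools[[p]] <- advance(p, dt)
    }
    t_now <- ev
    ## splits scheduled at this time: copy the parent pool (a size change
    ## takes effect with the first offspring generation)
    for (p in seq_len(cfg$n_pops)) {
      if (!is.na(cfg$split_generations[p]) && cfg$split_generations[p] == ev) {
        pools[[p]] <- pools[[cfg$parent[p]]]
      }
    }
    if (!is.null(sweep) && sweep$start_gen == ev) {
      ## hard single-origin sweep: all initial carriers share one ancestral
      ## haplotype over the sweep chromosome (the allele arose once and
      ## established); recombination during the sweep then erodes the tract
      tp <- sweep$population
      ncol_p <- ncol(pools[[tp]])
      n_car <- max(1L, round(ncol_p * sweep$start_freq))
      carriers <- sample.int(ncol_p, n_car)
      template <- carriers[1]
      chrom_rows <- which(chrom_id == sweep$chrom)
      pools[[tp]][chrom_rows, carriers] <-
        pools[[tp]][chrom_rows, rep(template, n_car)]
      pools[[tp]][sweep_locus, ] <- as.raw(0L)
      pools[[tp]][sweep_locus, carriers] <- as.raw(1L)
      sel_active[tp] <- TRUE
    }
  }

  ## sample diploids at present
  haps <- vector("list", cfg$n_pops)
  sample_ids_all <- character(0)
  pop_labels_all <- character(0)
  for (p in seq_len(cfg$n_pops)) {
    ids <- sample.int(cfg$pop_sizes[p], cfg$sample_sizes[p])
    colsel <- as.vector(rbind(2L * ids - 1L, 2L * ids))
    hm <- t(matrix(as.integer(pools[[p]][, colsel, drop = FALSE]), nrow = L))
    sids <- sprintf("%s_%03d", cfg$pop_names[p], seq_len(cfg$sample_sizes[p]))
    haps[[p]] <- hm
    sample_ids_all <- c(sample_ids_all, sids)
    pop_labels_all <- c(pop_labels_all, rep(cfg$pop_names[p], cfg$sample_sizes[p]))
  }
  pooled <- do.call(rbind, haps)
  poly <- colSums(pooled) > 0L & colSums(pooled) < nrow(pooled)
  variants_out <- variants[poly, , drop = FALSE]
  rownames(variants_out) <- NULL

  hap_objs <- list()
  offset <- 0L
  for (p in seq_len(cfg$n_pops)) {
    k <- cfg$sample_sizes[p]
    rows <- offset + seq_len(2L * k)
    hap_objs[[cfg$pop_names[p]]] <- haplotype_matrix(
      pooled[rows, poly, drop = FALSE],
      sample_ids_all[(offset / 2L) + seq_len(k)],
      variants_out
    )
    offset <- offset + 2L * k
  }

  t_mat <- if (cfg$n_pops > 1) pair_divergence(cfg) else NULL
  expected_fst <- NULL
  if (!is.null(t_mat)) {
    expected_fst <- t_mat
    for (i in seq_len(cfg$n_pops)) {
      for (j in seq_len(cfg$n_pops)) {
        if (i == j) next
        n_h <- 2 / (1 / cfg$pop_sizes[i] + 1 / cfg$pop_sizes[j])
        expected_fst[i, j] <- 1 - (1 - 1 / (2 * n_h))^t_mat[i, j]
      }
    }
  }
  sweep_end <- NA_real_
  if (!is.null(sweep)) {
    sweep_end <- mean(as.integer(pools[[sweep$population]][sweep_locus, ]))
  }

  structure(
    list(
      haplotypes = hap_objs,
      map = map,
      panel = population_panel(sample_ids_all, pop_labels_all),
      truth = list(
        config = cfg,
        divergence_gen = t_mat,
        expected_fst = expected_fst,
        sweep_locus_id = if (is.na(sweep_locus)) NA_character_ else variants$id[sweep_locus],
        sweep_locus_cm = if (is.na(sweep_locus)) NA_real_ else cm[sweep_locus],
        sweep_locus_chrom = if (is.na(sweep_locus)) NA_character_ else chrom[sweep_locus],
        sweep_end_freq = sweep_end
      )
    ),
    class = "sim_result"
  )
}

#' Pool the per-population haplotypes of a simulation
#'
#' @param sim a `sim_result` from [simulate_panel()].
#' @return one [haplotype_matrix()] over all sampled individuals.
#' @export
combine_haplotypes <- function(sim) {
  haps <- do.call(rbind, lapply(sim$haplotypes, function(h) h$haplotypes))
  ids <- unlist(lapply(sim$haplotypes, function(h) h$sample_ids), use.names = FALSE)
  haplotype_matrix(haps, ids, sim$haplotypes[[1]]$variants)
}

#' Export a simulated panel to standard file formats
#'
#' Writes the pooled panel as a phased VCF or a PLINK fileset, plus the
#' genetic map and the population panel file; reading the files back
#' through the genotype I/O layer reproduces the matrices exactly.
#'
#' @param sim a `sim_result`.
#' @param format `"vcf"` or `"plink"`.
#' @param out_dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return named character vector of the files written.
#' @export
export_fixture <- function(sim, format = c("vcf", "plink"), out_dir, prefix = "sim") {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pooled <- combine_haplotypes(sim)
  files <- c()
  if (format == "vcf") {
    f <- file.path(out_dir, paste0(prefix, ".vcf"))
    write_vcf(pooled, f)
    files["vcf"] <- f
  } else {
    pre <- file.path(out_dir, prefix)
    write_plink(as_genotype_matrix(pooled), pre)
    files["bed"] <- paste0(pre, ".bed")
    files["bim"] <- paste0(pre, ".bim")
    files["fam"] <- paste0(pre, ".fam")
  }
  map_f <- file.path(out_dir, paste0(prefix, ".map.txt"))
  write.table(
    data.frame(chrom = sim$map$chrom, bp = sim$map$bp, cm = sim$map$cm),
    map_f, quote = FALSE, sep = "\t", row.names = FALSE
  )
  files["map"] <- map_f
  panel_f <- file.path(out_dir, paste0(prefix, ".panel.txt"))
  write_panel(sim$panel, panel_f)
  files["panel"] <- panel_f
  files
}
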