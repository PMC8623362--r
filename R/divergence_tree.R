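## Divergence times from FST and long-term Ne, and an ultrametric UPGMA
## tree over the pairwise divergence-time matrix.

#' Divergence time from FST and Ne
#'
#' Under pure drift the fixation index after `T` generations of separation
#' satisfies `FST = 1 - (1 - 1/(2*Ne))^T`; inverting gives
#' `T = ln(1 - FST) / ln(1 - 1/(2*Ne))`.
#'
#' @param fst pairwise fixation index in `[0, 1)`; negative estimates must
#'   be clamped to 0 upstream.
#' @param ne effective population size (> 0.5).
#' @param generation_years years per generation.
#' @return a list `T_gen` (generations) and `T_years`; `fst >= 1` yields
#'   `NA` (infinite divergence).
#' @export
divergence_time <- function(fst, ne, generation_years = 25) {
  stopifnot(ne > 0.5)
  if (any(fst < 0, na.rm = TRUE)) stop("negative fst: clamp to 0 before calling")
  t_gen <- ifelse(fst >= 1, NA_real_, log(1 - fst) / log(1 - 1 / (2 * ne)))
  list(T_gen = t_gen, T_years = t_gen * generation_years)
}

#' Pairwise divergence-time matrix
#'
#' For each population pair the Ne entering the drift formula is the
#' harmonic mean of the two populations' long-term Ne.
#'
#' @param fst_matrix an `fst_matrix` from [pairwise_fst()] (its clamped
#'   matrix is used) or a plain symmetric matrix with dimnames.
#' @param long_term_ne named vector of long-term Ne per population.
#' @param generation_years years per generation.
#' @return an object of class `divergence_result`: list with
#'   `populations`, `T_gen`, `T_years` (symmetric matrices, diagonal 0,
#'   `NA` where a population's Ne is undefined) and `tree`, the
#'   [upgma()] tree over `T_years`.
#' @export
divergence_matrix <- function(fst_matrix, long_term_ne, generation_years = 25) {
  fst <- if (inherits(fst_matrix, "fst_matrix")) fst_matrix$theta_clamped
         else pmax(as.matrix(fst_matrix), 0)
  labels <- rownames(fst)
  ne <- long_term_ne[labels]
  if (is.null(labels) || anyNA(match(labels, names(long_term_ne)))) {
    stop("long_term_ne must name every population in the FST matrix")
  }
  k <- length(labels)
  t_gen <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (is.na(ne[i]) || is.na(ne[j])) {
        t_gen[i, j] <- t_gen[j, i] <- NA_real_
        next
      }
      ne_pair <- 2 / (1 / ne[i] + 1 / ne[j])
      t_gen[i, j] <- t_gen[j, i] <-
        divergence_time(fst[i, j], ne_pair, generation_years)$T_gen
    }
  }
  t_years <- t_gen * generation_years
  tree <- if (k >= 2 && !anyNA(t_years)) upgma(t_years, labels) else NULL
  structure(
    list(populations = labels, T_gen = t_gen, T_years = t_years, tree = tree),
    class = "divergence_result"
  )
}

#' @export
print.divergence_result <- function(x, ...) {
  cat("<divergence_result> divergence times (years)\n")
  print(round(x$T_years))
  if (!is.null(x$tree)) cat("tree:", x$tree$newick, "\n")
  invisible(x)
}

#' UPGMA tree
#'
#' Average-linkage agglomeration: repeatedly join the closest pair of
#' clusters (ties broken by the lexicographically smallest pair of
#' cluster labels, a cluster being labelled by its smallest leaf); the
#' joined node sits at half the join distance, and distances to the new
#' cluster are the size-weighted average of member distances. The result
#' is ultrametric by construction.
#'
#' @param dist symmetric non-negative matrix with zero diagonal.
#' @param labels leaf labels; defaults to `rownames(dist)`.
#' @return an object of class `upgma_tree`: list with `labels`, `merges`
#'   (per join: the two member label sets and the node height) and
#'   `newick` (branch lengths = height differences).
#' @export
upgma <- function(dist, labels = rownames(dist)) {
  dist <- as.matrix(dist)
  k <- length(labels)
  if (k < 2) stop("need at least 2 labels")
  if (!isTRUE(all.equal(dist, t(dist)))) stop("distance matrix must be symmetric")
  if (any(diag(dist) != 0)) stop("diagonal must be zero")
  if (any(dist < 0)) stop("distances must be non-negative")

  clusters <- lapply(seq_len(k), function(i) list(
    members = labels[i], size = 1L, height = 0, newick = labels[i],
    tag = labels[i]
  ))
  d <- dist
  dimnames(d) <- NULL
  merges <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        tags <- sort(c(clusters[[i]]$tag, clusters[[j]]$tag))
        cand <- list(i = i, j = j, d = d[i, j], tags = tags)
        if (is.null(best) || cand$d < best$d ||
            (cand$d == best$d &&
             (cand$tags[1] < best$tags[1] ||
              (cand$tags[1] == best$tags[1] && cand$tags[2] < best$tags[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    ## size-weighted distance update uses the positional clusters;
    ## serialization below orders children by tag for determinism
    d_new <- (clusters[[i]]$size * d[i, ] + clusters[[j]]$size * d[j, ]) /
      (clusters[[i]]$size + clusters[[j]]$size)
    ci <- clusters[[i]]; cj <- clusters[[j]]
    if (ci$tag > cj$tag) { tmp <- ci; ci <- cj; cj <- tmp }  # stable child order
    merged <- list(
      members = c(ci$members, cj$members),
      size = ci$size + cj$size,
      height = h,
      newick = sprintf("(%s:%.6f,%s:%.6f)",
                       ci$newick, h - ci$height, cj$newick, h - cj$height),
      tag = min(ci$tag, cj$tag)
    )
    merges[[length(merges) + 1]] <- list(
      left = ci$members, right = cj$members, height = h
    )
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    clusters <- c(clusters[keep], list(merged))
  }
  structure(
    list(labels = labels, merges = merges,
         height = clusters[[1]]$height,
         newick = paste0(clusters[[1]]$newick, ";")),
    class = "upgma_tree"
  )
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<upgma_tree>", x$newick, "\n")
  invisible(x)
}

#' Write a tree to a Newick file
#'
#' @param tree an [upgma()] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}
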