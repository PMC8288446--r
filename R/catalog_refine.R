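# Gene-catalog decluttering and co-abundance genome-bin refinement:
# co-exclusion merging within protein clusters, tiered bin dereplication,
# canopy integration, and marker-maximizing core-gene fishing.

# union-find with path compression
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

#' Declutter a gene-abundance matrix
#'
#' Within each protein cluster, gene pairs that co-occur in fewer than
#' `co_occ_max` of the samples where either is observed and whose
#' co-exclusion is supported by a one-sided Fisher's exact test at
#' `p < p_max` are merged (occurrence union, abundance sum), transitively
#' via union-find. Pairs in different protein clusters are never tested.
#'
#' @param mat Gene x sample abundance matrix (non-negative), rownames =
#'   gene ids.
#' @param clusters Named protein-cluster id per gene.
#' @param co_occ_max Maximum co-occurrence fraction for a pair to be tested.
#' @param p_max Fisher p-value cutoff for co-exclusion.
#' @return A list of class `declutter_result`: `matrix` (merged), `merges`
#'   (data frame `from`, `into`, `p`).
#' @export
declutter <- function(mat, clusters, co_occ_max = 0.10, p_max = 1e-5) {
  mat <- as.matrix(mat)
  stopifnot(!is.null(rownames(mat)), all(mat >= 0))
  genes <- rownames(mat)
  pres <- mat > 0
  uf <- .uf_new(length(genes))
  merges <- list()
  for (cl in unique(clusters[genes])) {
    members <- which(clusters[genes] == cl)
    if (length(members) < 2) next
    for (ii in seq_along(members)) {
      for (jj in seq_len(ii - 1L)) {
        i <- members[ii]; j <- members[jj]
        pi_ <- pres[i, ]; pj <- pres[j, ]
        both <- sum(pi_ & pj)
        either <- sum(pi_ | pj)
        if (either == 0 || both / either >= co_occ_max) next
        tab <- matrix(c(both, sum(pi_ & !pj), sum(!pi_ & pj), sum(!pi_ & !pj)), 2)
        p <- stats::fisher.test(tab, alternative = "less")$p.value
        if (p < p_max) {
          ri <- .uf_find(uf, i); rj <- .uf_find(uf, j)
          if (ri != rj) {
            uf[max(ri, rj)] <- min(ri, rj)
            merges[[length(merges) + 1L]] <- data.frame(
              from = genes[max(ri, rj)], into = genes[min(ri, rj)], p = p,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  root <- vapply(seq_along(genes), function(i) .uf_find(uf, i), 0L)
  out <- rowsum(mat, group = genes[root], reorder = FALSE)
  structure(list(
    matrix = out,
    merges = if (length(merges)) do.call(rbind, merges) else NULL
  ), class = "declutter_result")
}

#' Genome-bin quality tier
#'
#' Tier 1: completeness > 95 and contamination < 5; tier 2: > 90 / < 5;
#' tier 3: > 80 / < 5; tier 4: > 60 / < 10; otherwise `NA`.
#'
#' @param completeness,contamination Percentages (vectorized).
#' @return Integer tier (1 best) or `NA`.
#' @export
bin_quality_tier <- function(completeness, contamination) {
  tier <- rep(NA_integer_, length(completeness))
  tier[completeness > 60 & contamination < 10] <- 4L
  tier[completeness > 80 & contamination < 5] <- 3L
  tier[completeness > 90 & contamination < 5] <- 2L
  tier[completeness > 95 & contamination < 5] <- 1L
  tier
}

.bin_overlaps <- function(a, b, min_frac, min_genes) {
  shared <- length(intersect(a, b))
  shared >= min_frac * min(length(a), length(b)) || shared >= min_genes
}

#' Dereplicate genome bins across quality tiers
#'
#' Bins are processed best tier first (ties by completeness); a bin merges
#' into an already accepted, higher-quality bin when their shared genes
#' reach `min_frac` (of the smaller bin) or `min_genes` in absolute count.
#' The merged bin keeps the representative's identity and the union of
#' genes.
#'
#' @param bins List of bins, each a list with `id`, `genes` (character),
#'   `completeness`, `contamination`.
#' @param min_frac Fractional overlap threshold (default 30% of the smaller
#'   bin).
#' @param min_genes Absolute overlap threshold (default 300 genes).
#' @return List of merged bins (each with added `tier` and `members`).
#' @export
dereplicate_bins <- function(bins, min_frac = 0.30, min_genes = 300) {
  tiers <- vapply(bins, function(b) bin_quality_tier(b$completeness, b$contamination), 0L)
  comp <- vapply(bins, function(b) b$completeness, 0)
  ord <- order(tiers, -comp)
  accepted <- list()
  for (k in ord) {
    b <- bins[[k]]
    b$tier <- tiers[k]
    merged <- FALSE
    for (ai in seq_along(accepted)) {
      if (.bin_overlaps(accepted[[ai]]$genes, b$genes, min_frac, min_genes)) {
        accepted[[ai]]$genes <- union(accepted[[ai]]$genes, b$genes)
        accepted[[ai]]$members <- c(accepted[[ai]]$members, b$id)
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      b$members <- b$id
      accepted[[length(accepted) + 1L]] <- b
    }
  }
  accepted
}

#' Integrate canopy clusters with dereplicated bins
#'
#' Each canopy gene set merges into the most-overlapping bin when the
#' 30%-or-300-genes rule is met; otherwise it becomes an independent
#' species cluster only if at least `novel_frac` of its genes occur in no
#' bin, and is otherwise absorbed by the bin it overlaps most.
#'
#' @param canopies Named list of character gene sets (must be non-empty).
#' @param bins Output of [dereplicate_bins()].
#' @param min_frac,min_genes Merge thresholds, as in [dereplicate_bins()].
#' @param novel_frac Minimum fraction of bin-free genes for independence.
#' @return Updated bin list; canopy-derived bins carry `source =
#'   "canopy"`.
#' @export
merge_canopies <- function(canopies, bins, min_frac = 0.30, min_genes = 300,
                           novel_frac = 0.90) {
  for (nm in names(canopies)) {
    cg <- canopies[[nm]]
    if (length(cg) == 0) stop("empty canopy: ", nm)
    shared <- vapply(bins, function(b) length(intersect(b$genes, cg)), 0L)
    best <- if (length(shared)) which.max(shared) else integer(0)
    if (length(best) && .bin_overlaps(bins[[best]]$genes, cg, min_frac, min_genes)) {
      bins[[best]]$genes <- union(bins[[best]]$genes, cg)
      bins[[best]]$members <- c(bins[[best]]$members, nm)
      next
    }
    in_bins <- unique(unlist(lapply(bins, `[[`, "genes")))
    novel <- mean(!cg %in% in_bins)
    if (novel >= novel_frac || length(best) == 0 || shared[best] == 0) {
      bins[[length(bins) + 1L]] <- list(id = nm, genes = cg,
                                        completeness = NA, contamination = NA,
                                        tier = NA_integer_, members = nm,
                                        source = "canopy")
    } else {
      bins[[best]]$genes <- union(bins[[best]]$genes, cg)
      bins[[best]]$members <- c(bins[[best]]$members, nm)
    }
  }
  bins
}

#' Refine a bin to a metagenomic species gene set
#'
#' Fishes genes co-abundant with the bin's core: candidates must correlate
#' with the mean core profile at Pearson > `pearson_min` and Spearman >
#' `spearman_min` (both required). Candidates (union core) are clustered
#' hierarchically on correlation distance (average linkage; Spearman when
#' the median candidate occupancy is below `occupancy_switch`, else
#' Pearson), and the subcluster maximizing distinct single-copy marker
#' classes is selected, preferring subclusters without duplicated marker
#' classes, then marker count, then size.
#'
#' @param core_genes Character vector of core gene ids (in `mat`).
#' @param mat Gene x sample abundance matrix.
#' @param markers Named integer marker class (1..40) per gene; `NA` = not a
#'   marker.
#' @param pearson_min,spearman_min Correlation thresholds for fishing.
#' @param occupancy_switch Median occupancy below which Spearman distance is
#'   used for clustering.
#' @param cut_h Dendrogram cut height (correlation distance).
#' @return A list of class `mgs_refinement`: `genes` (selected set),
#'   `flavor`, `subcluster`, `n_markers`, `dup_markers`, `candidates`.
#' @export
refine_mgs <- function(core_genes, mat, markers, pearson_min = 0.75,
                       spearman_min = 0.85, occupancy_switch = 0.25,
                       cut_h = 0.5) {
  mat <- as.matrix(mat)
  stopifnot(all(core_genes %in% rownames(mat)))
  core_prof <- colMeans(mat[core_genes, , drop = FALSE])
  others <- setdiff(rownames(mat), core_genes)
  fished <- others[vapply(others, function(g) {
    x <- mat[g, ]
    if (stats::sd(x) == 0 || stats::sd(core_prof) == 0) return(FALSE)
    stats::cor(x, core_prof, method = "pearson") > pearson_min &&
      stats::cor(x, core_prof, method = "spearman") > spearman_min
  }, TRUE)]
  cand <- c(core_genes, fished)
  sub <- mat[cand, , drop = FALSE]
  occupancy <- rowMeans(sub > 0)
  flavor <- if (stats::median(occupancy) < occupancy_switch) "spearman" else "pearson"
  if (length(cand) > 2) {
    cm <- suppressWarnings(stats::cor(t(sub), method = flavor))
    cm[is.na(cm)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    cl <- stats::cutree(hc, h = cut_h)
  } else {
    cl <- stats::setNames(rep(1L, length(cand)), cand)
  }
  info <- lapply(split(names(cl), cl), function(gs) {
    mk <- markers[gs]
    mk <- mk[!is.na(mk)]
    list(genes = gs, n_markers = length(unique(mk)),
         dup = as.integer(any(duplicated(mk))), size = length(gs))
  })
  if (all(vapply(info, function(x) x$n_markers, 0L) == 0)) {
    stop("no single-copy markers in any subcluster: bin rejected")
  }
  ord <- order(vapply(info, function(x) x$dup, 0L),
               -vapply(info, function(x) x$n_markers, 0L),
               -vapply(info, function(x) x$size, 0L))
  sel <- info[[ord[1]]]
  structure(list(genes = sel$genes, flavor = flavor,
                 subcluster = names(info)[ord[1]],
                 n_markers = sel$n_markers, dup_markers = sel$dup == 1L,
                 candidates = cand),
            class = "mgs_refinement")
}

#' Remove near-duplicate samples before canopy clustering
#'
#' Utility prefilter: iteratively drops samples whose Spearman correlation
#' to an already kept sample exceeds `max_rho`, as used before
#' co-abundance clustering of longitudinal data.
#'
#' @param mat Gene x sample abundance matrix.
#' @param max_rho Correlation threshold (default 0.15).
#' @return Character vector of retained sample names.
#' @export
prefilter_samples <- function(mat, max_rho = 0.15) {
  mat <- as.matrix(mat)
  keep <- character(0)
  for (s in colnames(mat)) {
    ok <- TRUE
    for (k in keep) {
      if (suppressWarnings(stats::cor(mat[, s], mat[, k], method = "spearman")) > max_rho) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, s)
  }
  keep
}
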