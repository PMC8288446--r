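# Intraspecific phylogenies over per-sample genotypes and their partition
# into strains: neighbor-joining on pairwise p-distances, three delineation
# rules (fixed cutoff, tree quantile, within-host nearest neighbor), and ANI
# among recurrent strain groups.

#' Pairwise p-distance between consensus genotypes
#'
#' Proportion of mismatching sites over positions called (non-N) in both
#' sequences, computed with one-hot cross-products so large sample sets stay
#' fast.
#'
#' @param x A `consensus_set` or an integer matrix (samples x positions,
#'   0 = N).
#' @return Symmetric distance matrix; pairs with no shared called site are
#'   `NA`.
#' @export
pdist_consensus <- function(x) {
  m <- if (inherits(x, "consensus_set")) x$seqs else x
  storage.mode(m) <- "double"
  known <- (m > 0) * 1
  shared <- known %*% t(known)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in 1:4) {
    xb <- (m == b) * 1
    matches <- matches + xb %*% t(xb)
  }
  d <- 1 - matches / shared
  d[shared == 0] <- NA
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

# Three-leaf NJ special case: the unique unrooted star with branch lengths
# from the three-point formulas.
.nj3 <- function(d) {
  lab <- rownames(d)
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);", lab[1], max(v1, 0),
                 lab[2], max(v2, 0), lab[3], max(v3, 0))
  ape::read.tree(text = txt)
}

# Leaves at zero pairwise distance (identical genotypes over shared called
# sites) are grouped by single linkage; NJ runs on one representative per
# group and the remaining members are re-attached as a zero-length
# polytomy. Without this, NJ fits cancelling +/- branch pairs inside clone
# clusters, and clamping the negatives would inflate path lengths.
.dedup_groups <- function(d, tol = 1e-12) {
  n <- nrow(d)
  comp <- seq_len(n)
  hits <- which(d <= tol & lower.tri(d), arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    ci <- comp[hits[k, 1]]
    cj <- comp[hits[k, 2]]
    if (ci != cj) comp[comp == ci] <- cj
  }
  unname(split(seq_len(n), comp))
}

.graft_clones <- function(nwk, groups, labels) {
  for (g in groups) {
    if (length(g) < 2) next
    rex <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", labels[g[1]])
    star <- paste0("(", paste0(labels[g], ":0", collapse = ","), ")")
    nwk <- sub(paste0("(?<=[(,])", rex, "(?=:)"), star, nwk, perl = TRUE)
  }
  nwk
}

#' Build an intraspecific strain phylogeny
#'
#' Neighbor-joining on pairwise p-distances (sites uncalled in either
#' sequence are ignored). Identical genotypes are collapsed before NJ and
#' re-attached as zero-length polytomies; negative branch lengths are
#' clamped to zero and the tree is rooted at the midpoint unless an
#' outgroup leaf is named. Externally built trees can be wrapped via the
#' `tree` argument.
#'
#' @param x A `consensus_set`, an integer genotype matrix, or a symmetric
#'   distance matrix.
#' @param outgroup Optional leaf name to root on.
#' @param tree Optional pre-built `phylo` object; when supplied, `x` is only
#'   used for metadata.
#' @param min_branch Branch lengths below this value are collapsed to zero;
#'   defaults to half of one substitution over the alignment length
#'   (when known), removing the sub-resolution branch lengths
#'   neighbor-joining fits among effectively identical sequences.
#' @return A list of class `strain_phylo`: `tree` (rooted `phylo`), `dist`
#'   (input p-distances, when available) and `coph` (cophenetic tree
#'   distances).
#' @export
build_tree <- function(x, outgroup = NULL, tree = NULL, min_branch = NULL) {
  d <- NULL
  if (is.null(min_branch)) {
    L <- if (inherits(x, "consensus_set")) ncol(x$seqs)
    else if (is.matrix(x) && !isTRUE(all.equal(unname(x), unname(t(x))))) ncol(x)
    else NULL
    min_branch <- if (is.null(L)) 0 else 0.5 / L
  }
  if (is.null(tree)) {
    d <- if (is.matrix(x) && isTRUE(all.equal(unname(x), unname(t(x))))) x else pdist_consensus(x)
    if (nrow(d) < 3) stop("need at least 3 sequences to build a tree")
    if (any(is.na(d))) {
      mx <- max(d, na.rm = TRUE)
      d[is.na(d)] <- mx
      warning("pairs with no shared called sites; distance imputed with the maximum")
    }
    labels <- rownames(d)
    groups <- .dedup_groups(d)
    reps <- vapply(groups, `[`, 0L, 1L)
    if (length(reps) == 1L) {
      nwk <- paste0("(", paste0(labels, ":0", collapse = ","), ");")
      tree <- ape::read.tree(text = nwk)
    } else if (length(reps) == 2L) {
      half <- d[reps[1], reps[2]] / 2
      arm <- function(g) {
        if (length(g) == 1L) sprintf("%s:%.10f", labels[g], half)
        else sprintf("(%s):%.10f", paste0(labels[g], ":0", collapse = ","), half)
      }
      tree <- ape::read.tree(text = paste0("(", arm(groups[[1]]), ",",
                                           arm(groups[[2]]), ");"))
    } else {
      dr <- d[reps, reps, drop = FALSE]
      t0 <- if (length(reps) == 3) .nj3(dr) else ape::nj(stats::as.dist(dr))
      nwk <- .graft_clones(ape::write.tree(t0), groups, labels)
      tree <- ape::read.tree(text = nwk)
    }
  }
  tree$edge.length[tree$edge.length < min_branch] <- 0
  tree <- if (!is.null(outgroup)) {
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tree)
  }
  coph <- stats::cophenetic(tree)
  coph <- coph[tree$tip.label, tree$tip.label]
  structure(list(tree = tree, dist = d, coph = coph), class = "strain_phylo")
}

#' @export
print.strain_phylo <- function(x, ...) {
  cat(sprintf("strain phylogeny: %d leaves, max cophenetic distance %.4g\n",
              length(x$tree$tip.label), max(x$coph)))
  invisible(x)
}

#' Choose an outgroup from an inter-species phylogeny
#'
#' The closest neighbour of `species` that is further than `min_dist`
#' evolutionary distance in the supplied inter-species tree.
#'
#' @param interspecies_tree A `phylo` whose tips are species.
#' @param species Focal tip label.
#' @param min_dist Minimum cophenetic distance.
#' @return The chosen outgroup tip label (or `NA` if none qualifies).
#' @export
choose_outgroup <- function(interspecies_tree, species, min_dist = 0.1) {
  d <- stats::cophenetic(interspecies_tree)[species, ]
  d <- d[names(d) != species & d > min_dist]
  if (length(d) == 0) return(NA_character_)
  names(d)[which.min(d)]
}

# Per-node leaf sets and clade diameters (max within-clade cophenetic
# distance); strains are the maximal clades whose diameter stays within the
# cutoff. Diameter is non-decreasing towards the root, so each leaf has a
# unique maximal qualifying ancestor.
.clade_partition <- function(phylo, cutoff) {
  tree <- phylo$tree
  coph <- phylo$coph
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  kids <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  leafset <- vector("list", n_node)
  diam <- numeric(n_node)
  for (i in seq_len(n_tip)) {
    leafset[[i]] <- i
    diam[i] <- 0
  }
  post <- reorder(tree, "postorder")$edge[, 1]
  for (p in unique(post)) {
    ls <- integer(0)
    dm <- 0
    for (ch in kids[[p]]) {
      if (length(leafset[[ch]]) == 0) next
      if (length(ls) > 0) {
        cross <- max(coph[ls, leafset[[ch]], drop = FALSE])
        dm <- max(dm, cross)
      }
      dm <- max(dm, diam[ch])
      ls <- c(ls, leafset[[ch]])
    }
    leafset[[p]] <- ls
    diam[p] <- dm
  }
  eps <- 1e-12
  qual <- diam <= cutoff + eps
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  maximal <- which(qual & (seq_len(n_node) == root | !qual[pmax(parent, 1)]))
  maximal <- maximal[vapply(maximal, function(nd) nd == root || !qual[parent[nd]], TRUE)]
  strain <- integer(n_tip)
  sid <- 0L
  for (nd in sort(maximal)) {
    if (any(strain[leafset[[nd]]] != 0)) next
    sid <- sid + 1L
    strain[leafset[[nd]]] <- sid
  }
  # any leaf left unassigned (cannot happen for cutoff >= 0, kept as guard)
  for (i in which(strain == 0)) {
    sid <- sid + 1L
    strain[i] <- sid
  }
  stats::setNames(strain, tree$tip.label)
}

.assignment <- function(strain, method, cutoff) {
  out <- data.frame(sample = names(strain), strain = as.integer(strain),
                    stringsAsFactors = FALSE)
  structure(out, method = method, cutoff = cutoff, class = c("strain_assignment", "data.frame"))
}

#' @export
print.strain_assignment <- function(x, ...) {
  cat(sprintf("strain assignment (%s, cutoff %.4g): %d leaves, %d strains\n",
              attr(x, "method"), attr(x, "cutoff"), nrow(x),
              length(unique(x$strain))))
  invisible(x)
}

#' Delineate strains with a fixed evolutionary-distance cutoff
#'
#' Strains are the maximal monophyletic clades whose within-clade cophenetic
#' diameter does not exceed `cutoff` (default 0.01).
#'
#' @param phylo A `strain_phylo`.
#' @param cutoff Distance cutoff.
#' @return A `strain_assignment` data frame (`sample`, `strain`).
#' @export
delineate_fixed <- function(phylo, cutoff = 0.01) {
  .assignment(.clade_partition(phylo, cutoff), "fixed_cutoff", cutoff)
}

#' Delineate strains with a tree-specific quantile cutoff
#'
#' As [delineate_fixed()] with the cutoff set to the `q` quantile (linear
#' interpolation) of all pairwise cophenetic distances in the tree.
#'
#' @param phylo A `strain_phylo`.
#' @param q Quantile of all pairwise distances (default 10%).
#' @return A `strain_assignment`.
#' @export
delineate_quantile <- function(phylo, q = 0.10) {
  cutoff <- unname(stats::quantile(lower_tri(phylo$coph), q, type = 7))
  .assignment(.clade_partition(phylo, cutoff), "tree_quantile", cutoff)
}

#' Delineate strains from within-host nearest neighbors
#'
#' Seed pairs are leaves whose nearest neighbor (cophenetic) belongs to the
#' same host; the 95% quantile of those seed distances defines the
#' within-individual distance, and strains are the maximal monophyletic
#' clades within that diameter. Without any within-host pair the method
#' falls back to [delineate_quantile()] with a warning.
#'
#' @param phylo A `strain_phylo`.
#' @param hosts Named character vector mapping leaf (sample) to host.
#' @param q Quantile of seed-pair distances (default 95%).
#' @return A `strain_assignment`.
#' @export
delineate_phylo_nn <- function(phylo, hosts, q = 0.95) {
  tips <- phylo$tree$tip.label
  stopifnot(all(tips %in% names(hosts)))
  coph <- phylo$coph
  nn_d <- rep(NA_real_, length(tips))
  nn_same <- rep(FALSE, length(tips))
  for (i in seq_along(tips)) {
    d <- coph[i, -i]
    j <- which.min(d)
    nn_d[i] <- d[j]
    nn_same[i] <- hosts[[names(d)[j]]] == hosts[[tips[i]]]
  }
  if (!any(nn_same)) {
    warning("no within-host nearest-neighbor pairs; falling back to tree-quantile delineation")
    return(delineate_quantile(phylo))
  }
  d95 <- unname(stats::quantile(nn_d[nn_same], q, type = 7))
  .assignment(.clade_partition(phylo, d95), "phylo_nn", d95)
}

#' Average nucleotide identity within recurrent strain groups
#'
#' For every strain group observed in at least two samples, computes the
#' pairwise ANI (percent matching sites over sites called in both sequences
#' of the concatenated core genes) and summarizes each group by its mean.
#'
#' @param x A `consensus_set` or integer genotype matrix.
#' @param assignment A `strain_assignment` over the same samples.
#' @param by_host Optional named host vector; when given, groups are split
#'   by host so ANI is computed among recurrent samples of the same host.
#' @return A list of class `strain_ani`: `groups` (data frame `strain`,
#'   `n`, `ani`), `pairs`, and `summary` (`median`, `mean`, `iqr` over group
#'   ANIs).
#' @export
strain_ani <- function(x, assignment, by_host = NULL) {
  m <- if (inherits(x, "consensus_set")) x$seqs else x
  stopifnot(all(assignment$sample %in% rownames(m)))
  storage.mode(m) <- "double"
  known <- (m > 0) * 1
  shared <- known %*% t(known)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in 1:4) {
    xb <- (m == b) * 1
    matches <- matches + xb %*% t(xb)
  }
  dimnames(shared) <- dimnames(matches) <- list(rownames(m), rownames(m))
  grp <- as.character(assignment$strain)
  if (!is.null(by_host)) grp <- paste(grp, by_host[assignment$sample], sep = "@")
  groups <- split(assignment$sample, grp)
  groups <- groups[vapply(groups, length, 0L) >= 2]
  rows <- list()
  pair_rows <- list()
  for (g in names(groups)) {
    ss <- groups[[g]]
    anis <- c()
    for (i in seq_along(ss)) {
      for (j in seq_len(i - 1L)) {
        sh <- shared[ss[i], ss[j]]
        if (sh == 0) next  # no comparable sites
        ani <- 100 * matches[ss[i], ss[j]] / sh
        anis <- c(anis, ani)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          strain = g, a = ss[i], b = ss[j], ani = ani, sites = sh,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(anis) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      strain = g, n = length(ss), ani = mean(anis), stringsAsFactors = FALSE
    )
  }
  groups_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strain = character(0), n = integer(0), ani = numeric(0))
  structure(list(
    groups = groups_df,
    pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else NULL,
    summary = list(
      median = stats::median(groups_df$ani),
      mean = mean(groups_df$ani),
      iqr = stats::IQR(groups_df$ani)
    )
  ), class = "strain_ani")
}

#' @export
print.strain_ani <- function(x, ...) {
  cat(sprintf("strain ANI: %d recurrent groups, median %.4f%%, mean %.4f%%\n",
              nrow(x$groups), x$summary$median, x$summary$mean))
  invisible(x)
}
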