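# Population-genetic estimators on strain genotype alignments: site
# degeneracy classes, segregating sites, Watterson's theta, nucleotide
# diversity, Tajima's D (all sites and 4-fold/0-fold partitions),
# Nei-Gojobori dN/dS against an outgroup, the downsampling protocol and
# tree-shape statistics.

# Codon table (bacterial code; identical to the standard code over sense
# codons, start-codon differences do not matter here), built once from
# seqinr to avoid a hand-typed table.
codon_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      codons <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                            stringsAsFactors = FALSE)[, 3:1]
      key <- apply(codons, 1, paste, collapse = "")
      aa <- vapply(key, function(cd) {
        seqinr::translate(strsplit(tolower(cd), "")[[1]])
      }, "")
      tbl <<- stats::setNames(aa, key)
    }
    tbl
  }
})

# codon as integer triplet (1..4) -> amino acid
translate_codon <- function(co) {
  codon_table()[[paste(BASES[as.integer(co)], collapse = "")]]
}

# Coerce an alignment to the internal integer matrix (0 = N/gap).
aln_matrix <- function(aln) {
  if (inherits(aln, "consensus_set")) return(aln$seqs)
  if (is.character(aln)) {
    aln <- t(vapply(aln, function(s) seq_to_int(s), integer(nchar(aln[1])))) }
  if (is.matrix(aln) && is.character(aln[1])) {
    aln <- matrix(match(toupper(aln), BASES, nomatch = 0L), nrow = nrow(aln),
                  dimnames = dimnames(aln))
  }
  storage.mode(aln) <- "integer"
  aln
}

#' Classify codon-position degeneracy
#'
#' Using the consensus codon per column triplet, a position is 4-fold
#' degenerate when all three alternative bases leave the amino acid
#' unchanged, 0-fold when all three change it (a change to a stop codon
#' counts as a change); other positions are unclassified. Columns with an
#' uncalled base or gap in any retained sequence are excluded, as are the
#' columns of codons whose consensus is incomplete.
#'
#' @param aln In-frame alignment: integer matrix (0 = N), character matrix,
#'   or `consensus_set`; length must be a multiple of 3.
#' @return A list of class `site_classes`: `class` (factor per position:
#'   `fourfold`, `zerofold`, `other`, `excluded`) and `stop_codon` (`TRUE`
#'   when the consensus contains an internal stop; such genes should be
#'   excluded).
#' @export
classify_degeneracy <- function(aln) {
  m <- aln_matrix(aln)
  L <- ncol(m)
  if (L %% 3 != 0) stop("alignment length must be divisible by 3")
  complete <- colSums(m == 0) == 0
  cons <- vapply(seq_len(L), function(j) {
    x <- m[, j]
    x <- x[x > 0]
    if (length(x) == 0) return(0L)
    as.integer(which.max(tabulate(x, 4)))
  }, 0L)
  cls <- rep("excluded", L)
  stop_found <- FALSE
  for (c0 in seq(1, L, by = 3)) {
    cols <- c0:(c0 + 2)
    if (any(cons[cols] == 0)) next
    aa0 <- translate_codon(cons[cols])
    if (aa0 == "*") {
      stop_found <- TRUE
      next
    }
    if (!all(complete[cols])) next
    for (k in 1:3) {
      alt <- setdiff(1:4, cons[cols[k]])
      aas <- vapply(alt, function(b) {
        co <- cons[cols]
        co[k] <- b
        translate_codon(co)
      }, "")
      cls[cols[k]] <- if (all(aas == aa0)) "fourfold"
      else if (all(aas != aa0)) "zerofold"
      else "other"
    }
  }
  structure(list(
    class = factor(cls, levels = c("fourfold", "zerofold", "other", "excluded")),
    stop_codon = stop_found
  ), class = "site_classes")
}

.aln_sites <- function(m, sites) {
  complete <- colSums(m == 0) == 0
  use <- which(complete)
  if (!is.null(sites)) use <- intersect(use, sites)
  m[, use, drop = FALSE]
}

#' Segregating sites, Watterson's theta, nucleotide diversity
#'
#' Computed on complete columns (optionally restricted to a site subset):
#' `theta_W = S / (a1 * L)` with `a1 = sum(1/i, i < n)`, and `pi` the mean
#' pairwise difference per site.
#'
#' @param aln Alignment (see [classify_degeneracy()]).
#' @param sites Optional integer vector of columns to use (e.g. 4-fold
#'   positions).
#' @return A list: `S`, `theta_w`, `pi`, `n` (sequences), `L` (sites used).
#' @export
diversity_stats <- function(aln, sites = NULL) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  m <- .aln_sites(m, sites)
  L <- ncol(m)
  if (L == 0) return(list(S = 0L, theta_w = NA_real_, pi = NA_real_, n = n, L = 0L))
  seg <- 0L
  pair_diffs <- 0
  npairs <- n * (n - 1) / 2
  for (j in seq_len(L)) {
    tab <- tabulate(m[, j], 4)
    if (sum(tab > 0) > 1) {
      seg <- seg + 1L
      pair_diffs <- pair_diffs + (npairs - sum(choose(tab, 2)))
    }
  }
  a1 <- sum(1 / seq_len(n - 1))
  list(S = seg, theta_w = seg / (a1 * L), pi = pair_diffs / npairs / L,
       n = n, L = L)
}

#' Tajima's D
#'
#' The standardized difference between mean pairwise differences and the
#' scaled number of segregating sites, with the standard coefficients
#' derived from the sample size. `NA` when there are no segregating sites or
#' fewer than 4 sequences.
#'
#' @inheritParams diversity_stats
#' @return Numeric D (scalar, possibly `NA`).
#' @export
tajimas_d <- function(aln, sites = NULL) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 4) return(NA_real_)
  ds <- diversity_stats(m, sites)
  S <- ds$S
  if (is.na(ds$pi) || S == 0) return(NA_real_)
  k <- ds$pi * ds$L  # mean pairwise differences, absolute
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Nei-Gojobori (1986) dN/dS -------------------------------------------

# Synonymous site fraction of one codon: per position, the fraction of the
# three alternative bases that keep the amino acid. Changes to stop codons
# count as non-synonymous.
.ng86_sites <- function(co) {
  aa0 <- translate_codon(co)
  s <- 0
  for (k in 1:3) {
    for (b in setdiff(1:4, co[k])) {
      alt <- co
      alt[k] <- b
      if (translate_codon(alt) == aa0) s <- s + 1 / 3
    }
  }
  s
}

# All orderings of the differing positions between two codons; paths through
# stop codons are discarded and syn/nonsyn step counts averaged over the
# remaining paths. Returns c(syn, nonsyn) or NULL when no valid path exists.
.ng86_path_counts <- function(co1, co2) {
  diffs <- which(co1 != co2)
  k <- length(diffs)
  if (k == 0) return(c(0, 0))
  perms <- switch(as.character(k),
    "1" = list(diffs),
    "2" = list(diffs, rev(diffs)),
    "3" = {
      p <- list()
      for (i in 1:3) for (j in 1:3) {
        if (i == j) next
        p[[length(p) + 1L]] <- c(diffs[i], diffs[j], diffs[6 - i - j])
      }
      p
    })
  syn <- 0; nonsyn <- 0; valid <- 0L
  for (ord in perms) {
    cur <- co1
    s <- 0; ns <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- co2[pos]
      if (translate_codon(nxt) == "*") { ok <- FALSE; break }
      if (translate_codon(nxt) == translate_codon(cur)) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (ok) {
      syn <- syn + s; nonsyn <- nonsyn + ns; valid <- valid + 1L
    }
  }
  if (valid == 0L) return(NULL)
  c(syn / valid, nonsyn / valid)
}

jc_correct <- function(p) {
  arg <- 1 - 4 * p / 3
  if (is.na(p) || arg <= 0) return(NA_real_)
  -3 / 4 * log(arg)
}

#' Nei-Gojobori dN/dS between two aligned coding sequences
#'
#' Unweighted pathway counting with Jukes-Cantor correction. Codons with an
#' uncalled base, a gap, or a stop in either sequence are skipped, as are
#' codon pairs connected only through stop codons.
#'
#' @param seq1,seq2 Integer vectors (1..4, 0 = N), equal length divisible
#'   by 3.
#' @return A list: `dN`, `dS`, `dnds` (`NA` when `dS` is 0 or a correction
#'   saturates), `N_sites`, `S_sites`, `Nd`, `Sd`.
#' @export
ng86_pair <- function(seq1, seq2) {
  stopifnot(length(seq1) == length(seq2), length(seq1) %% 3 == 0)
  Ssites <- 0; Nd <- 0; Sd <- 0; ncod <- 0L
  for (c0 in seq(1, length(seq1), by = 3)) {
    co1 <- seq1[c0:(c0 + 2)]
    co2 <- seq2[c0:(c0 + 2)]
    if (any(co1 == 0) || any(co2 == 0)) next
    if (translate_codon(co1) == "*" || translate_codon(co2) == "*") next
    cnt <- .ng86_path_counts(co1, co2)
    if (is.null(cnt)) next
    Ssites <- Ssites + (.ng86_sites(co1) + .ng86_sites(co2)) / 2
    Sd <- Sd + cnt[1]
    Nd <- Nd + cnt[2]
    ncod <- ncod + 1L
  }
  if (ncod == 0L) {
    return(list(dN = NA_real_, dS = NA_real_, dnds = NA_real_,
                N_sites = 0, S_sites = 0, Nd = 0, Sd = 0))
  }
  Nsites <- 3 * ncod - Ssites
  pS <- Sd / Ssites
  pN <- Nd / Nsites
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  dnds <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  list(dN = dN, dS = dS, dnds = dnds, N_sites = Nsites, S_sites = Ssites,
       Nd = Nd, Sd = Sd)
}

#' Per-gene dN/dS against an outgroup
#'
#' Sequentially compares the outgroup to each ingroup sequence
#' (Nei-Gojobori counting, Jukes-Cantor corrected) and reports the medians
#' over ingroup sequences.
#'
#' @param aln Ingroup alignment (rows = sequences).
#' @param outgroup Outgroup sequence (integer vector or string), aligned to
#'   the same coordinates.
#' @return A list: `dN`, `dS`, `dnds` (medians; `dnds` `NA` when the median
#'   `dS` comparison is undefined), `per_sequence` data frame.
#' @export
dnds_vs_outgroup <- function(aln, outgroup) {
  m <- aln_matrix(aln)
  og <- if (is.character(outgroup)) seq_to_int(outgroup) else as.integer(outgroup)
  stopifnot(length(og) == ncol(m))
  per <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    r <- ng86_pair(m[i, ], og)
    data.frame(seq = rownames(m)[i] %||% i, dN = r$dN, dS = r$dS,
               dnds = r$dnds, stringsAsFactors = FALSE)
  }))
  list(
    dN = stats::median(per$dN, na.rm = TRUE),
    dS = stats::median(per$dS, na.rm = TRUE),
    dnds = stats::median(per$dnds, na.rm = TRUE),
    per_sequence = per
  )
}

#' Downsampling protocol for population-genetic estimates
#'
#' Randomly keeps one sample per host, then draws `n_genes` genes from the
#' QC-passed set; all estimators run on the subset so sample-number biases
#' cannot leak into between-species comparisons. Species with fewer genes
#' than requested keep all genes and are flagged.
#'
#' @param samples Character vector of sample ids.
#' @param hosts Named host per sample.
#' @param genes Character vector of available gene ids.
#' @param n_genes Number of genes to keep (default 20).
#' @param seed Integer seed.
#' @return A list: `samples`, `genes`, `n_genes_used`, `flagged`.
#' @export
downsample_protocol <- function(samples, hosts, genes, n_genes = 20, seed = 1) {
  with_seed(seed, {
    keep_s <- unname(vapply(split(samples, hosts[samples]), function(s) {
      s[sample.int(length(s), 1)]
    }, ""))
    flagged <- length(genes) < n_genes
    keep_g <- if (flagged) genes else sort(sample(genes, n_genes))
    list(samples = keep_s, genes = keep_g, n_genes_used = length(keep_g),
         flagged = flagged)
  })
}

#' Sackin's index with PDA normalization
#'
#' The sum of leaf depths (edges from the root), divided by `n^(3/2)`
#' (proportional-to-distinguishable-arrangements normalization), so tree
#' imbalance is comparable across tree sizes. Unrooted input is
#' midpoint-rooted with a warning.
#'
#' @param tree A `phylo` or `strain_phylo`.
#' @return Normalized Sackin index (scalar).
#' @export
sackin_pda <- function(tree) {
  if (inherits(tree, "strain_phylo")) tree <- tree$tree
  if (!ape::is.rooted(tree)) {
    warning("unrooted tree: midpoint-rooting before Sackin index")
    tree <- phangorn::midpoint(tree)
  }
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth_of <- function(i) {
    d <- 0L
    while (parent[i] != 0L) {
      d <- d + 1L
      i <- parent[i]
    }
    d
  }
  s <- sum(vapply(seq_len(n), depth_of, 0L))
  s / n^1.5
}

#' Median cophenetic distance of a tree
#'
#' @param tree A `phylo` or `strain_phylo`.
#' @return Median pairwise leaf distance.
#' @export
median_tree_distance <- function(tree) {
  if (inherits(tree, "strain_phylo")) return(stats::median(lower_tri(tree$coph)))
  stats::median(lower_tri(stats::cophenetic(tree)))
}

#' Population-genetic profile for one species
#'
#' Applies the downsampling protocol, computes per-gene Tajima's D (all
#' sites and 4-fold/0-fold partitions), Watterson's theta and nucleotide
#' diversity, and dN/dS against the outgroup, and reports the per-gene
#' medians alongside tree-shape statistics and the mean-abundance Nc proxy.
#' Genes whose consensus contains an internal stop are excluded.
#'
#' @param cs A filtered `consensus_set`.
#' @param hosts Named host per sample.
#' @param outgroup Optional outgroup genotype (integer vector over the same
#'   concatenated coordinates).
#' @param tree Optional `strain_phylo` for the tree-shape statistics.
#' @param abundance Optional per-sample relative abundance of the species
#'   (Nc proxy = mean of non-zero values).
#' @param n_genes Downsampling depth (default 20).
#' @param seed Integer seed.
#' @return A list of class `popgen_profile` with the per-gene medians
#'   (`TajimaD`, `TajimaD_S`, `TajimaD_N`, `theta`, `theta_S`, `theta_N`,
#'   `pi`, `pi_S`, `pi_N`, `dN`, `dS`, `dNdS`), `sackin_pda`,
#'   `median_tree_distance`, `Nc_proxy`, `n_samples`, `n_genes_used`,
#'   `flagged`, and the `per_gene` table.
#' @export
popgen_profile <- function(cs, hosts, outgroup = NULL, tree = NULL,
                           abundance = NULL, n_genes = 20, seed = 1) {
  stopifnot(inherits(cs, "consensus_set"))
  ds <- downsample_protocol(cs$samples, hosts, cs$genes$gene, n_genes, seed)
  rows <- list()
  for (g in which(cs$genes$gene %in% ds$genes)) {
    cols <- cs$genes$start[g]:cs$genes$end[g]
    m <- cs$seqs[ds$samples, cols, drop = FALSE]
    sc <- classify_degeneracy(m)
    if (sc$stop_codon) next
    s4 <- which(sc$class == "fourfold")
    s0 <- which(sc$class == "zerofold")
    all_s <- diversity_stats(m)
    st4 <- if (length(s4)) diversity_stats(m, s4) else NULL
    st0 <- if (length(s0)) diversity_stats(m, s0) else NULL
    dnds <- if (!is.null(outgroup)) {
      dnds_vs_outgroup(m, outgroup[cols])
    } else {
      list(dN = NA_real_, dS = NA_real_, dnds = NA_real_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = cs$genes$gene[g],
      TajimaD = tajimas_d(m), TajimaD_S = tajimas_d(m, s4),
      TajimaD_N = tajimas_d(m, s0),
      theta = all_s$theta_w, theta_S = if (is.null(st4)) NA else st4$theta_w,
      theta_N = if (is.null(st0)) NA else st0$theta_w,
      pi = all_s$pi, pi_S = if (is.null(st4)) NA else st4$pi,
      pi_N = if (is.null(st0)) NA else st0$pi,
      dN = dnds$dN, dS = dnds$dS, dNdS = dnds$dnds,
      stringsAsFactors = FALSE
    )
  }
  per_gene <- if (length(rows)) do.call(rbind, rows) else NULL
  med <- function(col) {
    if (is.null(per_gene)) NA_real_ else stats::median(per_gene[[col]], na.rm = TRUE)
  }
  structure(list(
    TajimaD = med("TajimaD"), TajimaD_S = med("TajimaD_S"),
    TajimaD_N = med("TajimaD_N"),
    theta = med("theta"), theta_S = med("theta_S"), theta_N = med("theta_N"),
    pi = med("pi"), pi_S = med("pi_S"), pi_N = med("pi_N"),
    dN = med("dN"), dS = med("dS"), dNdS = med("dNdS"),
    sackin_pda = if (is.null(tree)) NA_real_ else sackin_pda(tree),
    median_tree_distance = if (is.null(tree)) NA_real_ else median_tree_distance(tree),
    Nc_proxy = if (is.null(abundance)) NA_real_ else mean(abundance[abundance > 0]),
    n_samples = length(ds$samples), n_genes_used = ds$n_genes_used,
    flagged = ds$flagged, per_gene = per_gene
  ), class = "popgen_profile")
}

#' @export
print.popgen_profile <- function(x, ...) {
  cat(sprintf(
    "popgen profile: n = %d samples, %d genes%s | D = %.3f, D_S = %.3f, pi_S = %.4g, dN/dS = %.3g\n",
    x$n_samples, x$n_genes_used, if (x$flagged) " (fewer than requested)" else "",
    x$TajimaD, x$TajimaD_S, x$pi_S, x$dNdS
  ))
  invisible(x)
}
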