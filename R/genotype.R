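# Per-sample genotype reconstruction: consensus calling from allele-count
# pileups, conspecific-strain flagging, multi-copy gene exclusion, and
# alignment sanitation (frameshift masking, column trimming, gene/sample
# inclusion filters).

# Fast path: counts matrix (positions x 4, columns A,C,G,T) -> integer
# consensus (0 = N). The consensus is reference-free: the emitted allele is
# the one whose frequency reaches `threshold`, which is unique whenever
# threshold > 0.5, so column order cannot matter.
consensus_int <- function(counts, min_depth = 2, threshold = 0.501) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("allele counts must be non-negative")
  depth <- rowSums(counts)
  idx <- max.col(counts, ties.method = "first")
  mx <- counts[cbind(seq_len(nrow(counts)), idx)]
  ok <- depth >= min_depth & mx >= threshold * depth & depth > 0
  out <- integer(nrow(counts))
  out[ok] <- idx[ok]
  out
}

#' Call a consensus sequence from an allele-count pileup
#'
#' Per position, the allele whose frequency reaches `threshold` is emitted
#' when depth is at least `min_depth`; otherwise the position is `N`. The
#' defaults (minimum depth 2, 0.501 threshold) make a 50/50 split at depth 2
#' uncallable, which avoids reference bias and defers two-strain positions to
#' the conspecific filter.
#'
#' @param pileup Either an integer matrix (positions x 4, columns A,C,G,T) or
#'   a data frame with columns `countA`, `countC`, `countG`, `countT`
#'   (optionally `gene`, `pos`).
#' @param min_depth Minimum read depth to call a base.
#' @param threshold Minimum allele frequency to call a base.
#' @param gene_id Optional identifier attached to the result.
#' @return A list of class `consensus_gene`: `gene_id`, `seq` (single string
#'   over A,C,G,T,N) and `fraction_called`.
#' @export
call_consensus <- function(pileup, min_depth = 2, threshold = 0.501,
                           gene_id = NULL) {
  counts <- pileup_counts(pileup)
  ci <- consensus_int(counts, min_depth, threshold)
  structure(list(
    gene_id = gene_id %||% attr(pileup, "gene_id"),
    seq = int_to_seq(ci),
    fraction_called = mean(ci > 0)
  ), class = "consensus_gene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pileup_counts <- function(pileup) {
  if (is.matrix(pileup)) {
    stopifnot(ncol(pileup) == 4)
    return(pileup)
  }
  cols <- paste0("count", BASES)
  if (!all(cols %in% names(pileup))) {
    stop("pileup data frame must have columns countA, countC, countG, countT")
  }
  as.matrix(pileup[, cols])
}

#' @export
print.consensus_gene <- function(x, ...) {
  cat(sprintf("consensus gene %s: %d nt, %.1f%% called\n",
              x$gene_id %||% "?", nchar(x$seq), 100 * x$fraction_called))
  invisible(x)
}

#' Conspecific-strain scores for one species in one sample
#'
#' Fixed differences (minor-allele frequency below 0.20) only reflect
#' divergence from the reference and are ignored; positions with mid-range
#' minor-allele frequencies (0.20 to 0.80, inclusive) indicate a second
#' conspecific strain. `P_c` is the percentage of covered positions that are
#' mid-range across the whole sample; per gene,
#' `P_gc = P_c * N_midF * 100 / L_g`, and genes with `P_gc` above
#' `p_gc_max` are excluded for that sample.
#'
#' @param pileups A `strain_pileups` entry (positions x 4 matrix spanning all
#'   genes) plus a `genes` table, or a list of per-gene count matrices.
#' @param genes Data frame with `gene`, `start`, `end`, `length` when
#'   `pileups` is a single concatenated matrix.
#' @param min_depth Minimum depth for a position to count as covered.
#' @param maf_range Closed mid-range interval of minor-allele frequencies.
#' @param p_gc_max Exclusion cutoff on `P_gc`.
#' @return A list of class `conspecific_score`: `P_c` (sample-level percent,
#'   `NA` if nothing is covered) and `per_gene` (data frame: `gene`,
#'   `N_midF`, `L_g`, `P_gc`, `excluded`, `reason`).
#' @export
conspecific_probability <- function(pileups, genes = NULL, min_depth = 2,
                                    maf_range = c(0.20, 0.80),
                                    p_gc_max = 0.1) {
  if (is.list(pileups) && !is.matrix(pileups) && is.null(genes)) {
    lens <- vapply(pileups, nrow, 0L)
    genes <- data.frame(
      gene = names(pileups) %||% sprintf("g%03d", seq_along(pileups)),
      start = cumsum(c(1L, lens[-length(lens)])),
      end = cumsum(lens), length = lens, stringsAsFactors = FALSE
    )
    pileups <- do.call(rbind, pileups)
  }
  counts <- pileup_counts(pileups)
  depth <- rowSums(counts)
  mx <- counts[cbind(seq_len(nrow(counts)), max.col(counts, ties.method = "first"))]
  covered <- depth >= min_depth
  maf <- ifelse(covered, 1 - mx / depth, NA_real_)
  mid <- covered & !is.na(maf) & maf >= maf_range[1] & maf <= maf_range[2]
  n_cov <- sum(covered)
  p_c <- if (n_cov > 0) 100 * sum(mid) / n_cov else NA_real_
  per_gene <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
    rng <- genes$start[g]:genes$end[g]
    n_mid <- sum(mid[rng])
    cov_g <- sum(covered[rng])
    p_gc <- if (is.na(p_c)) NA_real_ else p_c * n_mid * 100 / genes$length[g]
    excluded <- cov_g == 0 || is.na(p_gc) || p_gc > p_gc_max
    data.frame(
      gene = genes$gene[g], N_midF = n_mid, L_g = genes$length[g],
      covered = cov_g, P_gc = p_gc, excluded = excluded,
      reason = if (cov_g == 0) "no_coverage" else if (excluded) "conspecific" else "",
      stringsAsFactors = FALSE
    )
  }))
  structure(list(P_c = p_c, per_gene = per_gene), class = "conspecific_score")
}

#' Exclude putatively multi-copy catalog genes
#'
#' A gene is dropped when it is represented by more than one copy within a
#' sample in strictly more than `max_multi_frac` of the samples where it is
#' present at all.
#'
#' @param occurrence Matrix or data frame of per-sample copy counts (genes x
#'   samples).
#' @param max_multi_frac Tolerated fraction of multi-copy samples (strict
#'   inequality; the default drops genes duplicated in > 5% of carrying
#'   samples).
#' @return Character vector of kept gene names.
#' @export
exclude_multicopy_genes <- function(occurrence, max_multi_frac = 0.05) {
  occ <- as.matrix(occurrence)
  present <- rowSums(occ >= 1)
  multi <- rowSums(occ > 1)
  frac <- ifelse(present > 0, multi / present, 0)
  rownames(occ)[frac <= max_multi_frac]
}

#' Expected identity threshold for frameshift masking
#'
#' `E[id] = IDi - (1 - IDi) * 0.25 - max(0.1, 3 * sigma)`: the mean identity
#' of a sequence to its alignment partners, discounted by a quarter of the
#' divergence (the chance agreement of unrelated windows) and by at least
#' 0.1 (or three standard deviations of the identity spread).
#'
#' @param IDi Mean identity of the sequence to all others (0..1).
#' @param sigma Standard deviation of those identities.
#' @return The window-identity threshold below which regions are masked.
#' @export
expected_identity_threshold <- function(IDi, sigma) {
  IDi - (1 - IDi) * 0.25 - pmax(0.1, sigma * 3)
}

# Pairwise identity of sequence i against all others over a column range.
# Entries not in A,C,G,T (N or gaps) are excluded from the comparison.
.seq_identity <- function(msa_num, i, others) {
  xi <- msa_num[i, ]
  vapply(others, function(j) {
    xj <- msa_num[j, ]
    comp <- xi > 0 & xj > 0
    n <- sum(comp)
    if (n == 0) return(NA_real_)
    sum(xi[comp] == xj[comp]) / n
  }, 0)
}

#' Mask frameshifted regions in a multiple sequence alignment
#'
#' For each sequence (in input order) the expected identity threshold is
#' `E[id] = IDi - (1 - IDi) * 0.25 - max(0.1, 3 * sigma)`, where `IDi` is the
#' sequence's mean identity to all others and `sigma` the standard deviation
#' of those identities. A sliding window (advanced one position at a time) is
#' scored by its mean identity to the other sequences; where windows fall
#' below `E[id]` over a run of at least `min_run` consecutive starts, the
#' spanned region is masked to `N`. Sequences with more than
#' `max_masked_frac` of their nucleotides masked are discarded. Identities
#' are recomputed after each sequence's masking pass, in one sweep over the
#' input order.
#'
#' @param msa Character matrix (sequences x positions) over A,C,G,T,N,-.
#' @param window Window width (nt).
#' @param min_run Minimum run of failing window starts before masking.
#' @param max_masked_frac Masked fraction above which a sequence is dropped.
#' @return A list of class `masked_msa`: `msa` (masked, discarded rows
#'   removed), `discarded`, `e_id` (per-sequence threshold used),
#'   `masked_frac`, and `masked` (logical matrix of masked cells, original
#'   row set).
#' @export
fix_frameshifts <- function(msa, window = 150, min_run = 50,
                            max_masked_frac = 0.60) {
  stopifnot(is.matrix(msa))
  if (nrow(msa) < 3) {
    warning("fewer than 3 sequences: identity spread undefined, returning input")
    return(structure(list(msa = msa, discarded = character(0),
                          e_id = rep(NA_real_, nrow(msa)),
                          masked_frac = rep(0, nrow(msa)),
                          masked = matrix(FALSE, nrow(msa), ncol(msa))),
                     class = "masked_msa"))
  }
  msa <- toupper(msa)
  num <- matrix(match(msa, BASES, nomatch = 0L), nrow = nrow(msa))
  dimnames(num) <- dimnames(msa)
  is_gap <- msa == "-"
  L <- ncol(msa)
  n <- nrow(msa)
  alive <- rep(TRUE, n)
  masked <- matrix(FALSE, n, L)
  e_ids <- rep(NA_real_, n)
  masked_frac <- rep(0, n)
  for (i in seq_len(n)) {
    others <- setdiff(which(alive), i)
    if (length(others) < 2 || L < window) next
    ids <- .seq_identity(num, i, others)
    ids <- ids[!is.na(ids)]
    if (length(ids) < 2) next
    IDi <- mean(ids)
    sigma <- stats::sd(ids)
    e_id <- expected_identity_threshold(IDi, sigma)
    e_ids[i] <- e_id
    # window identities via cumulative sums of matches/comparable positions
    xi <- num[i, ]
    win_id <- rep(0, L - window + 1L)
    win_n <- rep(0L, L - window + 1L)
    for (j in others) {
      xj <- num[j, ]
      comp <- as.integer(xi > 0 & xj > 0)
      mat <- as.integer(comp == 1L & xi == xj)
      cs_c <- c(0L, cumsum(comp))
      cs_m <- c(0L, cumsum(mat))
      s <- seq_len(L - window + 1L)
      wc <- cs_c[s + window] - cs_c[s]
      wm <- cs_m[s + window] - cs_m[s]
      use <- wc > 0
      win_id[use] <- win_id[use] + wm[use] / wc[use]
      win_n[use] <- win_n[use] + 1L
    }
    have <- win_n > 0
    fail <- have & (win_id / pmax(win_n, 1L)) < e_id
    r <- rle(fail)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      span <- starts[k]:(ends[k] + window - 1L)
      masked[i, span] <- TRUE
    }
    mi <- masked[i, ] & !is_gap[i, ]
    nt <- sum(!is_gap[i, ])
    masked_frac[i] <- if (nt > 0) sum(mi) / nt else 0
    num[i, mi] <- 0L
    msa[i, mi] <- "N"
    if (masked_frac[i] > max_masked_frac) alive[i] <- FALSE
  }
  structure(list(
    msa = msa[alive, , drop = FALSE],
    discarded = rownames(msa)[!alive] %||% which(!alive),
    e_id = e_ids, masked_frac = masked_frac, masked = masked
  ), class = "masked_msa")
}

#' Trim poorly occupied alignment columns
#'
#' Columns with fewer than `min_col_occupancy` non-gap residues are removed,
#' unless removal would keep fewer than `min_cols_kept_pct` percent of the
#' columns, in which case the most-occupied `min_cols_kept_pct` percent of
#' columns are retained (the conservation floor).
#'
#' @param msa Character matrix (sequences x positions); `-` marks gaps.
#' @param min_col_occupancy Minimum fraction of non-gap residues per column.
#' @param min_cols_kept_pct Minimum percentage of columns to keep.
#' @return The trimmed matrix, columns in original order.
#' @export
trim_alignment <- function(msa, min_col_occupancy = 0.1,
                           min_cols_kept_pct = 60) {
  stopifnot(is.matrix(msa))
  if (ncol(msa) == 0 || nrow(msa) == 0) stop("empty alignment")
  occ <- colMeans(msa != "-")
  keep <- occ >= min_col_occupancy
  floor_n <- ceiling(min_cols_kept_pct / 100 * ncol(msa))
  if (sum(keep) < floor_n) {
    ord <- order(occ, decreasing = TRUE)[seq_len(floor_n)]
    keep <- seq_len(ncol(msa)) %in% ord
  }
  msa[, keep, drop = FALSE]
}

#' Build a consensus set for one species
#'
#' Calls consensus for every sample of a species and stacks the results into
#' a positionally aligned matrix (genes share coordinates across samples by
#' construction), applying per-sample conspecific gene exclusion.
#'
#' @param pileups A `strain_pileups` from [emit_observations()] (or a named
#'   list of per-sample counts matrices plus `genes`).
#' @param genes Gene table when `pileups` is a plain list.
#' @param min_depth,threshold Consensus parameters, see [call_consensus()].
#' @param p_gc_max Conspecific exclusion cutoff, see
#'   [conspecific_probability()]; masked genes are set to `N` for that
#'   sample. Use `Inf` to disable.
#' @return A list of class `consensus_set`: `seqs` (integer matrix samples x
#'   positions, 0 = N), `genes`, `samples`, `qc` (per sample conspecific
#'   report).
#' @export
call_consensus_set <- function(pileups, genes = NULL, min_depth = 2,
                               threshold = 0.501, p_gc_max = 0.1) {
  if (inherits(pileups, "strain_pileups")) {
    genes <- pileups$genes
    counts <- pileups$counts
  } else {
    counts <- pileups
  }
  stopifnot(!is.null(genes), length(counts) > 0)
  L <- genes$end[nrow(genes)]
  m <- matrix(0L, nrow = length(counts), ncol = L,
              dimnames = list(names(counts), NULL))
  qc <- vector("list", length(counts))
  names(qc) <- names(counts)
  for (sid in names(counts)) {
    ci <- consensus_int(counts[[sid]], min_depth, threshold)
    if (is.finite(p_gc_max)) {
      sc <- conspecific_probability(counts[[sid]], genes, min_depth,
                                    p_gc_max = p_gc_max)
      qc[[sid]] <- sc
      for (g in which(sc$per_gene$excluded)) {
        ci[genes$start[g]:genes$end[g]] <- 0L
      }
    }
    m[sid, ] <- ci
  }
  structure(list(seqs = m, genes = genes, samples = names(counts), qc = qc),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus set: %d samples x %d nt (%d genes), %.1f%% called\n",
              nrow(x$seqs), ncol(x$seqs), nrow(x$genes),
              100 * mean(x$seqs > 0)))
  invisible(x)
}

#' Filter genes and samples before phylogeny building
#'
#' Genes are kept when they are at least `min_gene_len` nt long and at least
#' `min_gene_nonN` non-N across the whole set. Samples are then kept when at
#' least `min_sample_cov` of their concatenated nucleotides are non-N and at
#' least `min_sample_genes` of the retained genes are present (any called
#' base).
#'
#' @param cs A `consensus_set`.
#' @param min_gene_len Minimum gene length (nt).
#' @param min_gene_nonN Minimum non-N fraction per gene.
#' @param min_sample_cov Minimum non-N fraction per sample.
#' @param min_sample_genes Minimum fraction of retained genes present.
#' @return The filtered `consensus_set`; attributes `dropped_genes` and
#'   `dropped_samples` list exclusions.
#' @export
filter_genes_and_samples <- function(cs, min_gene_len = 400,
                                     min_gene_nonN = 0.75,
                                     min_sample_cov = 0.10,
                                     min_sample_genes = 0.20) {
  stopifnot(inherits(cs, "consensus_set"))
  g_nonN <- vapply(seq_len(nrow(cs$genes)), function(g) {
    mean(cs$seqs[, cs$genes$start[g]:cs$genes$end[g], drop = FALSE] > 0)
  }, 0)
  keep_g <- cs$genes$length >= min_gene_len & g_nonN >= min_gene_nonN
  genes <- cs$genes[keep_g, , drop = FALSE]
  cols <- unlist(lapply(which(keep_g), function(g) cs$genes$start[g]:cs$genes$end[g]))
  seqs <- cs$seqs[, cols, drop = FALSE]
  if (nrow(genes) > 0) {
    genes$start <- cumsum(c(1L, genes$length[-nrow(genes)]))
    genes$end <- cumsum(genes$length)
  }
  present <- vapply(seq_len(nrow(genes)), function(g) {
    rowSums(seqs[, genes$start[g]:genes$end[g], drop = FALSE] > 0) > 0
  }, logical(nrow(seqs)))
  if (is.null(dim(present))) present <- matrix(present, nrow = nrow(seqs))
  cov_s <- rowMeans(seqs > 0)
  gene_frac <- if (nrow(genes) > 0) rowMeans(present) else rep(0, nrow(seqs))
  keep_s <- cov_s >= min_sample_cov & gene_frac >= min_sample_genes
  out <- structure(list(
    seqs = seqs[keep_s, , drop = FALSE], genes = genes,
    samples = cs$samples[keep_s], qc = cs$qc[keep_s]
  ), class = "consensus_set")
  attr(out, "dropped_genes") <- cs$genes$gene[!keep_g]
  attr(out, "dropped_samples") <- cs$samples[!keep_s]
  out
}
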