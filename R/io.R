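# Readers and writers for the package's exchange formats: pileup TSV,
# FASTA consensus sets, strain-assignment and metric tables, and a minimal
# VCF (FORMAT/AD) pileup importer.

#' Write allele-count pileups to TSV
#'
#' Long format with columns `sample`, `gene`, `pos` (1-based within gene),
#' `countA`, `countC`, `countG`, `countT`.
#'
#' @param pileups A `strain_pileups`.
#' @param path Output file.
#' @export
write_pileup_tsv <- function(pileups, path) {
  stopifnot(inherits(pileups, "strain_pileups"))
  rows <- lapply(names(pileups$counts), function(sid) {
    cm <- pileups$counts[[sid]]
    g <- pileups$genes
    gene <- rep(g$gene, g$length)
    pos <- unlist(lapply(g$length, seq_len))
    data.frame(sample = sid, gene = gene, pos = pos,
               countA = cm[, 1], countC = cm[, 2], countG = cm[, 3],
               countT = cm[, 4], stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read allele-count pileups from TSV
#'
#' @param path File written by [write_pileup_tsv()] (columns `sample`,
#'   `gene`, `pos`, `countA..countT`; `sample` optional for single-sample
#'   files).
#' @return A `strain_pileups` (single-sample inputs get sample id
#'   `"sample1"`).
#' @export
read_pileup_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) df$sample <- "sample1"
  g0 <- df[df$sample == df$sample[1], ]
  lens <- vapply(split(g0$pos, g0$gene), max, 0)
  lens <- lens[unique(g0$gene)]
  genes <- data.frame(gene = names(lens),
                      start = cumsum(c(1, unname(lens[-length(lens)]))),
                      end = cumsum(unname(lens)), length = unname(lens),
                      stringsAsFactors = FALSE)
  counts <- lapply(split(df, df$sample), function(s) {
    s <- s[order(match(s$gene, genes$gene), s$pos), ]
    cm <- as.matrix(s[, c("countA", "countC", "countG", "countT")])
    dimnames(cm) <- list(NULL, BASES)
    storage.mode(cm) <- "integer"
    cm
  })
  counts <- counts[unique(df$sample)]
  structure(list(species_id = NA_character_, counts = counts, genes = genes,
                 conspecific = NULL), class = "strain_pileups")
}

#' Read a per-sample pileup from a sites-only VCF with an AD field
#'
#' Minimal importer: uses CHROM as gene, POS as position, and the first
#' sample's FORMAT/AD allele depths over REF/ALT alleles (SNVs only).
#'
#' @param path VCF file (uncompressed).
#' @return A `strain_pileups` with one sample.
#' @export
read_pileup_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  get <- function(row, col) row[match(col, hdr)]
  recs <- lapply(body, function(row) {
    fmt <- strsplit(get(row, "FORMAT"), ":")[[1]]
    smp <- strsplit(row[length(hdr)], ":")[[1]]
    ad <- as.integer(strsplit(smp[match("AD", fmt)], ",")[[1]])
    alleles <- c(get(row, "REF"), strsplit(get(row, "ALT"), ",")[[1]])
    keep <- nchar(alleles) == 1 & alleles %in% BASES
    counts <- integer(4)
    counts[match(alleles[keep], BASES)] <- ad[keep]
    list(gene = get(row, "CHROM"), pos = as.integer(get(row, "POS")),
         counts = counts)
  })
  gene <- vapply(recs, `[[`, "", "gene")
  pos <- vapply(recs, `[[`, 0L, "pos")
  lens <- vapply(split(pos, gene), max, 0L)
  lens <- lens[unique(gene)]
  genes <- data.frame(gene = names(lens),
                      start = cumsum(c(1L, unname(lens[-length(lens)]))),
                      end = cumsum(unname(lens)), length = unname(lens),
                      stringsAsFactors = FALSE)
  cm <- matrix(0L, nrow = genes$end[nrow(genes)], ncol = 4,
               dimnames = list(NULL, BASES))
  for (r in recs) {
    off <- genes$start[match(r$gene, genes$gene)] - 1L
    cm[off + r$pos, ] <- r$counts
  }
  structure(list(species_id = NA_character_,
                 counts = stats::setNames(list(cm), hdr[length(hdr)]),
                 genes = genes, conspecific = NULL),
            class = "strain_pileups")
}

#' Write a consensus set as FASTA
#'
#' One record per sample over the concatenated genes (N for uncalled).
#'
#' @param cs A `consensus_set`.
#' @param path Output file.
#' @export
write_consensus_fasta <- function(cs, path) {
  stopifnot(inherits(cs, "consensus_set"))
  seqs <- lapply(seq_len(nrow(cs$seqs)), function(i) {
    c("N", BASES)[cs$seqs[i, ] + 1L]
  })
  seqinr::write.fasta(seqs, names = rownames(cs$seqs), file.out = path,
                      nbchar = 80)
  invisible(path)
}

#' Read a FASTA alignment into a character matrix
#'
#' @param path FASTA file of equal-length (aligned) sequences.
#' @return Character matrix (sequences x positions), uppercase.
#' @export
read_alignment_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, forceDNAtolower = FALSE)
  lens <- vapply(fa, length, 0L)
  if (length(unique(lens)) != 1) stop("sequences are not aligned (unequal lengths)")
  m <- t(vapply(fa, function(s) toupper(as.character(s)), character(lens[1])))
  rownames(m) <- names(fa)
  m
}

#' Write a strain assignment table
#'
#' @param assignment A `strain_assignment`.
#' @param meta Optional metadata to join host information from.
#' @param path Output TSV.
#' @export
write_assignment_tsv <- function(assignment, path, meta = NULL) {
  df <- as.data.frame(assignment)
  if (!is.null(meta)) {
    df <- merge(df, meta[, intersect(c("sample_id", "host", "family", "day"),
                                     names(meta))],
                by.x = "sample", by.y = "sample_id", all.x = TRUE, sort = FALSE)
  }
  df$method <- attr(assignment, "method")
  df$cutoff <- attr(assignment, "cutoff")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulator truth tables as JSON
#'
#' Dumps the strain history (per-sample lineages, genealogy, acquisition
#' events) for test fixtures and parameter-recovery checks.
#'
#' @param histories A `strain_history`.
#' @param path Output JSON file.
#' @export
write_truth_json <- function(histories, path) {
  stopifnot(inherits(histories, "strain_history"))
  jsonlite::write_json(list(
    species_id = histories$species_id,
    history = histories$history,
    lineages = histories$lineages,
    events = histories$events
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
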