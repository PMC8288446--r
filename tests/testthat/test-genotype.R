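# Consensus calling, conspecific flagging, multi-copy exclusion, and
# alignment sanitation.

counts_row <- function(A = 0, C = 0, G = 0, T = 0) {
  matrix(c(A, C, G, T), nrow = 1, dimnames = list(NULL, c("A", "C", "G", "T")))
}

test_that("consensus emits the majority allele above threshold, N otherwise", {
  cg <- call_consensus(rbind(
    counts_row(A = 3, T = 1),   # 0.75 >= 0.501 -> A
    counts_row(G = 1),          # depth 1 -> N
    counts_row(A = 1, T = 1),   # 0.5 at depth 2 -> N (tie rule)
    counts_row(C = 2)           # unanimous at min depth -> C
  ))
  expect_equal(cg$seq, "ANNC")
  expect_equal(cg$fraction_called, 0.5)
  expect_error(call_consensus(counts_row(A = -1)), "non-negative")
})

test_that("consensus is reference-free: column permutations cannot matter", {
  set.seed(41)
  for (r in 1:20) {
    cm <- matrix(rpois(4 * 50, 3), ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    base <- straintrack:::consensus_int(cm)
    perm <- sample(4)
    permuted <- straintrack:::consensus_int(cm[, perm])
    # map permuted allele indices back to the original column space
    map <- c(0L, perm)
    expect_equal(map[permuted + 1L], base)
  }
})

test_that("noiseless consensus equals the simulated truth where covered", {
  co <- simulate_cohort(cohort_config(n_families = 2, seed = 42,
                                      countries = default_countries(2)))
  sp <- species_config("spX", n_genes = 2, gene_length_nt = 300, occupancy = 1)
  h <- simulate_strain_histories(co, sp, seed = 43)
  tr <- evolve_sequences(h, sp, seed = 44)
  pile <- emit_observations(tr, obs_config(mean_coverage = 15, error_rate = 0),
                            seed = 45)
  for (sid in names(pile$counts)[1:5]) {
    ci <- straintrack:::consensus_int(pile$counts[[sid]])
    called <- ci > 0
    expect_true(all(ci[called] == tr$seqs[[sid]][called]))
  }
})

test_that("conspecific scores follow the printed P_c and P_gc definitions", {
  # all positions unanimous: P_c = 0, nothing excluded
  cm <- matrix(0L, 100, 4); cm[, 1] <- 10L
  sc <- conspecific_probability(cm, genes = data.frame(
    gene = "g1", start = 1, end = 100, length = 100))
  expect_equal(sc$P_c, 0)
  expect_equal(sc$per_gene$P_gc, 0)
  expect_false(any(sc$per_gene$excluded))

  # 2 of 100 covered positions at 50% frequency: P_c = 2
  cm2 <- cm
  cm2[1:2, ] <- 0L; cm2[1:2, 1] <- 5L; cm2[1:2, 3] <- 5L
  sc2 <- conspecific_probability(cm2, genes = data.frame(
    gene = "g1", start = 1, end = 100, length = 100))
  expect_equal(sc2$P_c, 2)

  # P_c = 2 (2 of 100 covered positions mid-range), N_midF = 2, L_g = 1000:
  # P_gc = 2 * 2 * 100 / 1000 = 0.4 > 0.1 -> excluded
  cm3 <- matrix(0L, 1000, 4)
  cm3[1:100, 2] <- 10L                       # only 100 positions covered
  cm3[1:2, 2] <- 5L; cm3[1:2, 4] <- 5L
  sc3 <- conspecific_probability(cm3,
                                 genes = data.frame(gene = "g1", start = 1,
                                                    end = 1000, length = 1000))
  expect_equal(sc3$P_c, 2)
  expect_equal(sc3$per_gene$N_midF, 2)
  expect_equal(sc3$per_gene$P_gc, 0.4)
  expect_true(sc3$per_gene$excluded)
})

test_that("simulated conspecific mixtures are flagged with high sensitivity", {
  co <- simulate_cohort(cohort_config(
    n_families = 10, adults_per_family = 2, children_per_family = 0,
    countries = default_countries(10), sampling_days = 0, seed = 46))
  sp <- species_config("spY", replacement_rate = 0, p_family_source = 0,
                       geo_clustering = 0, p_novel = 1, occupancy = 1,
                       strain_divergence = 0.015,
                       n_genes = 10, gene_length_nt = 600)
  h <- simulate_strain_histories(co, sp, seed = 47)
  tr <- evolve_sequences(h, sp, seed = 48)
  mix <- emit_observations(tr, obs_config(mean_coverage = 20, error_rate = 0.005,
                                          p_conspecific = 1,
                                          conspecific_fraction = 0.5),
                           seed = 49)
  flagged <- unlist(lapply(names(mix$counts), function(sid) {
    conspecific_probability(mix$counts[[sid]], mix$genes)$per_gene$excluded
  }))
  expect_gte(mean(flagged), 0.95)   # >= 95% of 200 gene-samples
})

test_that("multi-copy genes are excluded by the strict 5% rule", {
  occ <- matrix(1L, 3, 100,
                dimnames = list(c("single", "dup6", "dup5"), NULL))
  occ["dup6", 1:6] <- 2L
  occ["dup5", 1:5] <- 2L
  kept <- exclude_multicopy_genes(occ)
  expect_true("single" %in% kept)
  expect_false("dup6" %in% kept)    # 6% > 5%
  expect_true("dup5" %in% kept)     # exactly 5%, strict inequality
})

test_that("the expected-identity threshold matches its definition", {
  expect_equal(expected_identity_threshold(1, 0), 0.9)
  expect_equal(expected_identity_threshold(0.95, 0.01), 0.8375)
})

test_that("frameshift masking hits shifted regions and is idempotent", {
  co <- simulate_cohort(cohort_config(
    n_families = 4, adults_per_family = 2, children_per_family = 0,
    countries = default_countries(4), sampling_days = 0, seed = 50))
  sp <- species_config("spZ", replacement_rate = 0, p_family_source = 1,
                       geo_clustering = 1, occupancy = 1,
                       strain_divergence = 0.003,
                       n_genes = 1, gene_length_nt = 600)
  h <- simulate_strain_histories(co, sp, seed = 51)
  tr <- evolve_sequences(h, sp, seed = 52)

  clean <- sim_raw_msa(tr, obs_config(p_frameshift_artifact = 0), seed = 53)
  fx <- fix_frameshifts(clean$msas[[1]])
  expect_equal(sum(fx$masked), 0)

  art <- sim_raw_msa(tr, obs_config(p_frameshift_artifact = 0.3,
                                    frameshift_len = 200), seed = 54)
  expect_false(is.null(art$shifted))
  fx2 <- fix_frameshifts(art$msas[[1]])
  for (k in seq_len(nrow(art$shifted))) {
    srow <- art$shifted[k, ]
    i <- match(srow$sample, rownames(art$msas[[1]]))
    span <- srow$from:srow$to
    expect_gte(mean(fx2$masked[i, span]), 0.95)
  }
  # idempotence: a second pass leaves the masked alignment unchanged
  fx3 <- fix_frameshifts(fx2$msa)
  expect_identical(fx3$msa, fx2$msa)
})

test_that("frameshift masking warns and no-ops below 3 sequences", {
  m <- rbind(a = rep("A", 200), b = rep("A", 200))
  expect_warning(out <- fix_frameshifts(m), "fewer than 3")
  expect_identical(out$msa, m)
})

test_that("column trimming removes gappy columns with a conservation floor", {
  m <- matrix("A", nrow = 20, ncol = 100)
  expect_identical(trim_alignment(m), m)

  m2 <- m
  m2[2:20, 1:5] <- "-"                       # 5 columns at occupancy 0.05
  expect_equal(ncol(trim_alignment(m2)), 95)

  m3 <- m
  m3[2:20, 1:50] <- "-"                      # half the columns below 10%
  expect_equal(ncol(trim_alignment(m3)), 60) # the 60% floor kicks in
  expect_error(trim_alignment(m[, 0, drop = FALSE]), "empty")
})

test_that("gene and sample inclusion filters apply the printed thresholds", {
  mk_cs <- function(seqs, lengths) {
    genes <- data.frame(gene = paste0("g", seq_along(lengths)),
                        start = cumsum(c(1, lengths[-length(lengths)])),
                        end = cumsum(lengths), length = lengths,
                        stringsAsFactors = FALSE)
    structure(list(seqs = seqs, genes = genes, samples = rownames(seqs),
                   qc = NULL), class = "consensus_set")
  }
  # a 399-nt gene is dropped regardless of coverage
  seqs <- matrix(1L, 2, 399 + 400, dimnames = list(c("s1", "s2"), NULL))
  cs <- mk_cs(seqs, c(399, 400))
  out <- filter_genes_and_samples(cs)
  expect_equal(out$genes$gene, "g2")

  # sample filters: >= 10% nucleotides and >= 20% genes both required
  lengths <- rep(500, 10)
  seqs <- matrix(0L, 3, 5000)
  rownames(seqs) <- c("keep", "few_nt", "ok")
  seqs["ok", ] <- 1L
  # 'keep': 25% of genes present (genes 1:3 fully + few bases), 12% of nt
  seqs["keep", 1:600] <- 1L
  # 'few_nt': genes 1..5 sparsely present -> 50% genes but 8% of nt
  for (g in 1:5) seqs["few_nt", (g - 1) * 500 + 1:80] <- 1L
  cs <- mk_cs(seqs, lengths)
  out <- filter_genes_and_samples(cs, min_gene_nonN = 0)
  expect_true("keep" %in% out$samples)
  expect_true("ok" %in% out$samples)
  expect_false("few_nt" %in% out$samples)
})
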