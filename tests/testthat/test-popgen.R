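# Site degeneracy, diversity estimators, Tajima's D, Nei-Gojobori dN/dS,
# downsampling, and tree-shape statistics.

aln_from <- function(...) {
  do.call(rbind, lapply(list(...), straintrack:::seq_to_int))
}

test_that("degeneracy classes follow the codon table", {
  # GGG (Gly): third position 4-fold
  sc <- classify_degeneracy(aln_from("GGG", "GGG"))
  expect_equal(as.character(sc$class), c("zerofold", "zerofold", "fourfold"))
  # ATG (Met): all three positions 0-fold
  sc2 <- classify_degeneracy(aln_from("ATG", "ATG"))
  expect_equal(as.character(sc2$class), rep("zerofold", 3))
  # TGG (Trp): second position 0-fold (TAG/TCG/TTG all change it)
  sc3 <- classify_degeneracy(aln_from("TGG", "TGG"))
  expect_equal(as.character(sc3$class)[2], "zerofold")
  # internal stop in the consensus flags the gene
  sc4 <- classify_degeneracy(aln_from("TAAGGG", "TAAGGG"))
  expect_true(sc4$stop_codon)
  # a column with N in any sequence is excluded
  sc5 <- classify_degeneracy(rbind(straintrack:::seq_to_int("GGG"),
                                   straintrack:::seq_to_int("GGN")))
  expect_equal(as.character(sc5$class)[3], "excluded")
})

test_that("diversity statistics match hand arithmetic and the oracle", {
  m <- aln_from(strrep("A", 100), strrep("A", 100))
  ds <- diversity_stats(m)
  expect_equal(ds$S, 0); expect_equal(ds$pi, 0); expect_equal(ds$theta_w, 0)

  m2 <- aln_from(paste0("G", strrep("A", 99)), strrep("A", 100))
  ds2 <- diversity_stats(m2)
  expect_equal(ds2$pi, 0.01)
  expect_equal(ds2$theta_w, 0.01)    # a1 = 1 for n = 2

  set.seed(90)
  for (r in 1:10) {
    m3 <- matrix(sample(1:4, 6 * 30, replace = TRUE, prob = c(.7, .1, .1, .1)),
                 nrow = 6)
    ds3 <- diversity_stats(m3)
    expect_equal(ds3$pi, oracle_pi(m3), tolerance = 1e-12)
    expect_equal(ds3$S, oracle_S(m3))
    expect_equal(ds3$theta_w, oracle_theta_w(m3), tolerance = 1e-12)
  }
})

test_that("Tajima's D equals the independent textbook evaluation", {
  m <- aln_from(strrep("A", 50), strrep("A", 50), strrep("A", 50),
                strrep("A", 50))
  expect_true(is.na(tajimas_d(m)))                     # S = 0

  # fixed 5-sequence alignment
  m5 <- aln_from(
    "AAAAAAAAAACCCCCCCCCC",
    "AAAAAAAAAACCCCCCCCCC",
    "AAAAAAAAAGCCCCCCCCCT",
    "AAAAAAAAAGCCCCCCCCCC",
    "TAAAAAAAAACCCCCCCCCC"
  )
  expect_equal(tajimas_d(m5), oracle_tajima(m5), tolerance = 1e-10)

  set.seed(91)
  for (r in 1:10) {
    m6 <- matrix(sample(1:2, 8 * 40, replace = TRUE, prob = c(.85, .15)),
                 nrow = 8)
    expect_equal(tajimas_d(m6), oracle_tajima(m6), tolerance = 1e-10)
    # sign identity: D <= 0 iff pi*L <= S/a1
    ds <- diversity_stats(m6)
    if (!is.na(tajimas_d(m6))) {
      expect_equal(tajimas_d(m6) <= 0,
                   ds$pi * ds$L <= ds$S / sum(1 / (1:7)))
    }
  }
})

test_that("Tajima's D responds to demographic structure in the right direction", {
  set.seed(92)
  # expansion-like genealogy: star alignments with private singletons
  d_star <- vapply(1:30, function(r) {
    m <- matrix(1L, 10, 200)
    for (i in 1:10) m[i, sample(200, 3)] <- 2L        # singletons only
    tajimas_d(m)
  }, 0)
  expect_lt(mean(d_star, na.rm = TRUE), 0)

  # two deep clades: intermediate-frequency variants
  d_bal <- vapply(1:30, function(r) {
    m <- matrix(1L, 10, 200)
    m[1:5, sample(200, 10)] <- 2L                     # shared by half
    tajimas_d(m)
  }, 0)
  expect_gt(mean(d_bal, na.rm = TRUE), 0)
})

test_that("NG86 dN/dS matches pathway-enumeration oracles", {
  # outgroup identical: no divergence, undefined ratio
  s <- straintrack:::seq_to_int("GGGATGTTT")
  r0 <- ng86_pair(s, s)
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0); expect_true(is.na(r0$dnds))

  # single synonymous difference: dN = 0, dS > 0, ratio 0
  a <- straintrack:::seq_to_int("GGGATGCCTCCTGACGACTTAGCA")
  b <- straintrack:::seq_to_int("GGAATGCCTCCTGACGACTTAGCA")
  r1 <- ng86_pair(a, b)
  expect_equal(r1$dN, 0)
  expect_gt(r1$dS, 0)
  expect_equal(dnds_vs_outgroup(matrix(a, nrow = 1), b)$dnds, 0)

  set.seed(93)
  for (r in 1:15) {
    n_cod <- sample(2:5, 1)
    s1 <- as.integer(sample(1:4, 3 * n_cod, replace = TRUE))
    s2 <- s1
    flip <- sample(length(s1), sample(1:3, 1))
    s2[flip] <- ((s2[flip] + sample(1:3, length(flip), replace = TRUE) - 1L) %% 4L) + 1L
    ok <- !is_stop_seq(s1) && !is_stop_seq(s2)
    if (!ok) next
    ours <- ng86_pair(s1, s2)
    orc <- oracle_ng86(s1, s2)
    if (is.na(ours$dS) || is.na(orc$dS)) {
      expect_equal(is.na(ours$dS), is.na(orc$dS))
    } else {
      expect_equal(ours$dS, orc$dS, tolerance = 1e-10)
    }
    if (!is.na(ours$dN) && !is.na(orc$dN)) {
      expect_equal(ours$dN, orc$dN, tolerance = 1e-10)
    }
  }
})

test_that("dN/dS calibrates to 1 under neutrality and drops under purifying selection", {
  set.seed(94)
  n_cod <- 10000
  anc <- straintrack:::random_root(1, 3 * n_cod)

  mutate_neutral <- function(s, n_mut) {
    pos <- sample(length(s), n_mut)
    s[pos] <- ((s[pos] + sample(1:3, n_mut, replace = TRUE) - 1L) %% 4L) + 1L
    s
  }
  der <- mutate_neutral(anc, round(0.05 * length(anc)))
  r <- ng86_pair(anc, der)
  expect_gt(r$dnds, 0.8); expect_lt(r$dnds, 1.2)

  # purifying: reject proposed nonsynonymous changes with probability 0.8
  purify <- function(s, n_prop, p_reject = 0.8) {
    for (k in seq_len(n_prop)) {
      pos <- sample(length(s), 1)
      new <- ((s[pos] + sample(1:3, 1) - 1L) %% 4L) + 1L
      cod0 <- s[3 * ((pos - 1) %/% 3) + 1:3]
      cod1 <- cod0; cod1[(pos - 1) %% 3 + 1] <- new
      aa0 <- straintrack:::translate_codon(cod0)
      aa1 <- straintrack:::translate_codon(cod1)
      if (aa1 == "*") next
      if (aa1 != aa0 && runif(1) < p_reject) next
      s[pos] <- new
    }
    s
  }
  der2 <- purify(anc, round(0.12 * length(anc)))
  r2 <- ng86_pair(anc, der2)
  expect_gt(r2$dnds, 0.15); expect_lt(r2$dnds, 0.25)
})

test_that("downsampling keeps one sample per host and n genes, reproducibly", {
  samples <- paste0("s", 1:12)
  hosts <- setNames(rep(paste0("h", 1:4), each = 3), samples)
  genes <- paste0("g", 1:30)
  ds <- downsample_protocol(samples, hosts, genes, n_genes = 20, seed = 5)
  expect_equal(length(ds$samples), 4)
  expect_equal(length(unique(hosts[ds$samples])), 4)
  expect_equal(ds$n_genes_used, 20)
  expect_false(ds$flagged)
  expect_identical(ds, downsample_protocol(samples, hosts, genes, 20, seed = 5))

  ds2 <- downsample_protocol(samples, hosts, paste0("g", 1:8), 20, seed = 5)
  expect_true(ds2$flagged)
  expect_equal(ds2$n_genes_used, 8)
})

test_that("Sackin index with PDA normalization matches hand computation", {
  catr <- ape::read.tree(text = "(a:1,(b:1,(c:1,d:1):1):1);")
  expect_equal(sackin_pda(catr), 9 / 4^1.5)           # 1 + 2 + 3 + 3 = 9
  bal <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(sackin_pda(bal), 8 / 4^1.5)            # 2 * 4 = 8
  expect_gt(sackin_pda(catr), sackin_pda(bal))
  expect_equal(median_tree_distance(bal), 4)
})

test_that("the popgen profile medianizes per-gene estimates", {
  co <- simulate_cohort(cohort_config(n_families = 6, seed = 95,
                                      countries = default_countries(6)))
  sp <- species_config("spP", strategy = "average", occupancy = 1,
                       strain_divergence = 0.02,
                       n_genes = 5, gene_length_nt = 600)
  h <- simulate_strain_histories(co, sp, seed = 96)
  tr <- evolve_sequences(h, sp, seed = 97)
  pile <- emit_observations(tr, obs_config(error_rate = 0), seed = 98)
  cs <- filter_genes_and_samples(call_consensus_set(pile))
  hosts <- setNames(h$history$host[match(cs$samples, h$history$sample_id)],
                    cs$samples)
  outg <- straintrack:::mutate_sites(tr$root, round(0.1 * length(tr$root)))
  phy <- build_tree(cs)
  prof <- popgen_profile(cs, hosts, outgroup = outg, tree = phy,
                         abundance = runif(length(cs$samples), 0.01, 0.2),
                         n_genes = 3, seed = 99)
  expect_true(prof$flagged == FALSE || prof$n_genes_used <= 3)
  expect_gte(prof$pi, 0)
  expect_gte(prof$theta, 0)
  expect_true(is.finite(prof$dNdS) || is.na(prof$dNdS))
  expect_equal(prof$pi, median(prof$per_gene$pi, na.rm = TRUE))
  expect_gt(prof$Nc_proxy, 0)
  expect_gt(prof$sackin_pda, 0)
})
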