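# Synthetic cohort generator: metadata structure, Markov strain
# replacement, neutral sequence evolution, and the observation model.

test_that("cohort metadata has the promised structure and determinism", {
  cfg <- cohort_config(n_families = 1, adults_per_family = 2,
                       children_per_family = 1,
                       countries = data.frame(name = "X", lat = 0, lon = 0,
                                              n_families = 1),
                       sampling_days = c(0, 30, 60), seed = 11)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 9)                       # 3 hosts x 3 samples
  expect_equal(length(unique(co$host)), 3)
  expect_equal(unique(co$family), "F001")
  expect_setequal(unique(co$role), c("mother", "father", "child"))
  expect_true(all(co$age[co$role == "child"] <= 3 + 60 / 365))

  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  all_ab <- simulate_cohort(cohort_config(n_families = 3, p_antibiotic = 1,
                                          countries = default_countries(3),
                                          seed = 2))
  expect_true(all(all_ab$antibiotic))

  expect_error(cohort_config(sampling_days = c(0, 10, 10)),
               "strictly increasing")
})

test_that("strain retention follows the exponential replacement model", {
  lambda <- -log(0.8) / 365
  co <- simulate_cohort(cohort_config(
    n_families = 500, adults_per_family = 1, children_per_family = 0,
    countries = data.frame(name = "X", lat = 0, lon = 0, n_families = 500),
    sampling_days = c(0, 365), seed = 3))
  sp <- species_config("spA", replacement_rate = lambda,
                       p_family_source = 0, geo_clustering = 0,
                       p_novel = 1, occupancy = 1)
  h <- simulate_strain_histories(co, sp, seed = 4)
  hh <- h$history
  first <- hh[hh$day == 0, ]
  second <- hh[hh$day == 365, ]
  retained <- mean(first$lineage[match(second$host, first$host)] == second$lineage)
  se <- sqrt(0.8 * 0.2 / 500)
  expect_lt(abs(retained - 0.8), 3 * se)
})

test_that("degenerate replacement and family sourcing behave as stated", {
  co <- simulate_cohort(cohort_config(n_families = 10, seed = 5,
                                      countries = default_countries(10)))
  sp0 <- species_config("sp0", replacement_rate = 0, occupancy = 1)
  h0 <- simulate_strain_histories(co, sp0, seed = 6)
  per_host <- tapply(h0$history$lineage, h0$history$host,
                     function(x) length(unique(x)))
  expect_true(all(per_host == 1))
  expect_equal(true_persistence(h0), 100)

  # p_family_source = 1: every acquisition after the family is colonized
  # traces to a family member
  sp1 <- species_config("sp1", replacement_rate = 0.02,
                        p_family_source = 1, occupancy = 1)
  h1 <- simulate_strain_histories(co, sp1, seed = 7)
  ev <- h1$events
  fam_of <- unique(co[, c("host", "family")])
  later <- ev[ev$day > 0, ]
  expect_true(all(later$source == "family"))
  # children are seeded from a parent on their first sample
  first_child <- ev[ev$day == 0 &
                    ev$host %in% co$host[co$role == "child"], ]
  adults_present <- vapply(first_child$host, function(hst) {
    fam <- fam_of$family[fam_of$host == hst]
    any(h1$history$host %in% setdiff(fam_of$host[fam_of$family == fam], hst))
  }, TRUE)
  expect_true(all(first_child$source[adults_present] == "family"))
})

test_that("sequence evolution is clonal, Poisson, and shared at transfer", {
  co <- simulate_cohort(cohort_config(
    n_families = 1, adults_per_family = 1, children_per_family = 1,
    countries = data.frame(name = "X", lat = 0, lon = 0, n_families = 1),
    sampling_days = c(0, 365), seed = 8))
  sp <- species_config("spB", replacement_rate = 0, mutation_rate = 0,
                       p_family_source = 1, occupancy = 1,
                       n_genes = 2, gene_length_nt = 300)
  h <- simulate_strain_histories(co, sp, seed = 9)
  tr <- evolve_sequences(h, sp, seed = 10)
  # zero mutation rate: every observation of a lineage is identical
  by_lin <- split(names(tr$lineage_of), tr$lineage_of)
  for (sids in by_lin) {
    for (s in sids[-1]) expect_identical(tr$seqs[[s]], tr$seqs[[sids[1]]])
  }
  # two hosts sharing a lineage have identical day-0 sequences
  d0 <- h$history[h$history$day == 0, ]
  shared <- split(d0$sample_id, d0$lineage)
  shared <- shared[vapply(shared, length, 0L) > 1]
  for (sids in shared) {
    expect_identical(tr$seqs[[sids[1]]], tr$seqs[[sids[2]]])
  }
})

test_that("mutation counts match the Poisson expectation", {
  co <- simulate_cohort(cohort_config(
    n_families = 1, adults_per_family = 1, children_per_family = 0,
    countries = data.frame(name = "X", lat = 0, lon = 0, n_families = 1),
    sampling_days = c(0, 365), seed = 12))
  sp <- species_config("spC", replacement_rate = 0, mutation_rate = 1e-5,
                       occupancy = 1, n_genes = 10, gene_length_nt = 1500)
  h <- simulate_strain_histories(co, sp, seed = 13)
  nrep <- 400
  diffs <- vapply(seq_len(nrep), function(r) {
    tr <- evolve_sequences(h, sp, seed = 1000 + r)
    sum(tr$seqs[[1]] != tr$seqs[[2]])
  }, 0)
  lambda <- 1e-5 * 1 * 15000   # rate x years x sites = 0.15
  se <- sqrt(lambda / nrep)
  expect_lt(abs(mean(diffs) - lambda), 3 * se)
})

test_that("observation model: noiseless unanimity, mixtures, Poisson depth", {
  co <- simulate_cohort(cohort_config(
    n_families = 2, adults_per_family = 1, children_per_family = 1,
    countries = data.frame(name = "X", lat = 0, lon = 0, n_families = 2),
    sampling_days = c(0, 100), seed = 14))
  # two one-parent families, no replacement, children seeded from the
  # parent: exactly two lineages, so the conspecific partner of any sample
  # is unambiguous
  sp <- species_config("spD", replacement_rate = 0, occupancy = 1,
                       p_family_source = 1, geo_clustering = 0, p_novel = 1,
                       n_genes = 2, gene_length_nt = 300)
  h <- simulate_strain_histories(co, sp, seed = 15)
  tr <- evolve_sequences(h, sp, seed = 16)

  clean <- emit_observations(tr, obs_config(mean_coverage = 20, error_rate = 0),
                             seed = 17)
  sid <- names(clean$counts)[1]
  cm <- clean$counts[[sid]]
  truth <- tr$seqs[[sid]]
  covered <- rowSums(cm) > 0
  expect_true(all(cm[cbind(which(covered), truth[covered])] ==
                  rowSums(cm)[covered]))

  # forced conspecific mixture: differing sites show intermediate freqs
  mix <- emit_observations(tr, obs_config(mean_coverage = 60, error_rate = 0,
                                          p_conspecific = 1,
                                          conspecific_fraction = 0.5),
                           seed = 18)
  lins <- tr$lineage_of
  s1 <- names(lins)[1]
  other <- names(lins)[lins != lins[[s1]]][1]
  diff_sites <- which(tr$seqs[[s1]] != tr$seqs[[other]])
  if (length(diff_sites) > 5) {
    cm <- mix$counts[[s1]]
    fr <- cm[cbind(diff_sites, tr$seqs[[s1]][diff_sites])] /
      rowSums(cm)[diff_sites]
    expect_lt(abs(mean(fr) - 0.5), 0.1)
  }

  depth10 <- emit_observations(tr, obs_config(mean_coverage = 10), seed = 19)
  depths <- rowSums(depth10$counts[[1]])
  se <- sqrt(10 / length(depths))
  expect_lt(abs(mean(depths) - 10), 3 * se)
})

test_that("the whole generator is deterministic under a fixed seed", {
  co <- simulate_cohort(cohort_config(n_families = 4, seed = 20,
                                      countries = default_countries(4)))
  sp <- species_config("spE", n_genes = 2, gene_length_nt = 300)
  run <- function() {
    h <- simulate_strain_histories(co, sp, seed = 21)
    tr <- evolve_sequences(h, sp, seed = 22)
    emit_observations(tr, obs_config(), seed = 23)
  }
  expect_identical(run(), run())
})

test_that("config validation rejects invalid probabilities and frames", {
  expect_error(species_config("x", gene_length_nt = 100), "divisible by 3")
  expect_error(species_config("x", geo_clustering = 1.5), "probability")
  expect_error(species_config("x", replacement_rate = -1), ">= 0")
  expect_error(obs_config(mean_coverage = 0), "> 0")
  expect_error(obs_config(conspecific_fraction = 0.9), "0.2, 0.8")
})
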