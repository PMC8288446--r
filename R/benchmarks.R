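# Study-design benchmarks: self-contained synthetic-cohort experiments that
# exercise the full pipeline and summarize it in one number each. Both are
# deterministic given their seed and sized to run on a single CPU in a few
# minutes.

#' Strain-precision benchmark: ANI within recurrent strain groups
#'
#' Simulates a longitudinal cohort of persisting strains under realistic
#' observation noise, runs consensus calling, phylogeny building and the
#' phylogeny-based strain delineation, and computes the median pairwise ANI
#' among consensus sequences within monophyletic same-host strain groups
#' recurring in at least two samples. With faithful genotype
#' reconstruction this median is 100%.
#'
#' @param seed Integer seed driving every random stage.
#' @param n_hosts Number of longitudinally sampled hosts.
#' @param n_timepoints Samples per host, evenly spread over `span_days`.
#' @param span_days Observation span per host (default two years).
#' @param n_genes,gene_length_nt Core-gene geometry.
#' @param coverage Mean sequencing depth per position.
#' @param error_rate Per-base miscall probability.
#' @param mutation_rate Within-lineage substitution rate (/site/year).
#' @param replacement_rate Per-day strain replacement rate (low: persisting
#'   strains).
#' @return A list: `value` (median group ANI, percent), `n` (number of
#'   recurrent strain groups compared), plus the intermediate objects.
#' @export
benchmark_strain_precision <- function(seed = 1,
                                       n_hosts = 50,
                                       n_timepoints = 5,
                                       span_days = 730,
                                       n_genes = 20,
                                       gene_length_nt = 1500,
                                       coverage = 10,
                                       error_rate = 0.005,
                                       mutation_rate = 1e-6,
                                       replacement_rate = 1e-4) {
  countries <- default_countries(n_hosts)
  cohort <- simulate_cohort(cohort_config(
    n_families = n_hosts, adults_per_family = 1, children_per_family = 0,
    countries = countries,
    sampling_days = round(seq(0, span_days, length.out = n_timepoints)),
    seed = substream_seed(seed, 1)))
  sp <- species_config("precision", replacement_rate = replacement_rate,
                       p_family_source = 0, geo_clustering = 0.3,
                       mutation_rate = mutation_rate, occupancy = 1,
                       n_genes = n_genes, gene_length_nt = gene_length_nt)
  hist <- simulate_strain_histories(cohort, sp, seed = substream_seed(seed, 2))
  truth <- evolve_sequences(hist, sp, seed = substream_seed(seed, 3))
  pile <- emit_observations(truth, obs_config(mean_coverage = coverage,
                                              error_rate = error_rate),
                            seed = substream_seed(seed, 4))
  cs <- filter_genes_and_samples(call_consensus_set(pile))
  phy <- build_tree(cs)
  hh <- hist$history
  hosts <- stats::setNames(hh$host[match(rownames(cs$seqs), hh$sample_id)],
                           rownames(cs$seqs))
  asg <- delineate_phylo_nn(phy, hosts)
  ani <- strain_ani(cs, asg, by_host = hosts)
  list(value = ani$summary$median, n = nrow(ani$groups),
       ani = ani, assignment = asg, history = hist)
}

#' Method-equivalence benchmark: quantile versus nearest-neighbor delineation
#'
#' Simulates a panel of species spanning replacement rates from zero to
#' high, runs the genotype and strain stages, computes per-species strain
#' persistence under the tree-quantile and the phylogeny-based
#' nearest-neighbor delineations, and reports the Spearman correlation of
#' the two per-species vectors.
#'
#' @param seed Integer seed.
#' @param n_species Number of simulated species.
#' @param n_hosts Number of hosts (paired adults in families).
#' @param sampling_days Collection days per host.
#' @param n_genes,gene_length_nt Core-gene geometry.
#' @param max_rate Highest replacement rate (/day) on the log-spaced grid.
#' @return A list: `value` (Spearman rho), `n` (species count), and the
#'   per-species persistence table.
#' @export
benchmark_method_equivalence <- function(seed = 1,
                                         n_species = 30,
                                         n_hosts = 100,
                                         sampling_days = c(0, 120, 240, 365),
                                         n_genes = 4,
                                         gene_length_nt = 900,
                                         max_rate = 0.03) {
  n_fam <- n_hosts / 2
  cohort <- simulate_cohort(cohort_config(
    n_families = n_fam, adults_per_family = 2, children_per_family = 0,
    countries = default_countries(n_fam), sampling_days = sampling_days,
    seed = substream_seed(seed, 1)))
  rates <- c(0, exp(seq(log(1e-5), log(max_rate),
                        length.out = n_species - 1)))
  rows <- list()
  for (si in seq_len(n_species)) {
    sp <- species_config(sprintf("eq%02d", si), replacement_rate = rates[si],
                         p_family_source = 0.3, geo_clustering = 0.3,
                         occupancy = 1, n_genes = n_genes,
                         gene_length_nt = gene_length_nt)
    hist <- simulate_strain_histories(cohort, sp,
                                      seed = substream_seed(seed, 2, si))
    truth <- evolve_sequences(hist, sp, seed = substream_seed(seed, 3, si))
    pile <- emit_observations(truth, obs_config(),
                              seed = substream_seed(seed, 4, si))
    cs <- filter_genes_and_samples(call_consensus_set(pile))
    if (nrow(cs$seqs) < 3) next
    phy <- build_tree(cs)
    hh <- hist$history
    mm <- hh[match(rownames(cs$seqs), hh$sample_id), ]
    hosts <- stats::setNames(mm$host, mm$sample_id)
    series_for <- function(asg) {
      data.frame(host = mm$host, day = mm$day,
                 strain = asg$strain[match(mm$sample_id, asg$sample)],
                 stringsAsFactors = FALSE)
    }
    p_q <- strain_persistence(series_for(delineate_quantile(phy)))$species
    p_nn <- strain_persistence(series_for(delineate_phylo_nn(phy, hosts)))$species
    rows[[length(rows) + 1L]] <- data.frame(
      species = sp$species_id, rate = rates[si],
      true_persistence = true_persistence(hist),
      persistence_quantile = p_q, persistence_nn = p_nn,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  rho <- stats::cor(tab$persistence_quantile, tab$persistence_nn,
                    method = "spearman")
  list(value = unname(rho), n = nrow(tab), table = tab)
}
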