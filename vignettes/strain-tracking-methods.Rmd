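---
title: "Strain-resolved tracking of gut bacteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-resolved tracking of gut bacteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straintrack)
```

## The problem

Shotgun metagenomes of fecal samples carry enough single-nucleotide
variation on a species' core genes to tell apart the *strains* colonizing
different hosts. Given longitudinal samples from hosts organised in
families across countries, one can then ask how long a strain persists in
its host, how often it is transmitted within families (parent-to-child
versus adult-to-adult), whether strains are geographically structured, and
what population-genetic regime (diversity, site-frequency spectrum,
purifying selection) goes with each of these dispersal styles.

`straintrack` implements this analysis chain — per-sample consensus
genotypes, strain delineation on intraspecific phylogenies,
persistence/transmission/phylogeography statistics, and population-genetic
estimators — together with a synthetic-cohort generator that provides
ground truth for every stage. Raw reads, assembly, mapping and variant
calling are out of scope: the package starts from per-sample per-gene
allele-count pileups (TSV or VCF with allele depths).

## Genotype reconstruction

**Consensus calling.** Per position, the allele with frequency at least
0.501 is emitted when depth is at least 2, otherwise `N`
(`call_consensus()`). The threshold just above one half makes a 50/50
split at depth 2 uncallable; this avoids reference bias, and defers
genuinely mixed positions to the conspecific filter. Consensus is
reference-free by construction: only counts enter, and no allele ordering
can break a tie because two alleles cannot both reach 50.1%.

**Conspecific filtering.** Two strains of one species in one sample leave
intermediate allele frequencies. Fixed differences (minor allele below
0.20) only reflect reference divergence and are ignored; the sample-level
score `P_c` is the percentage of covered positions with minor-allele
frequency in the closed interval [0.20, 0.80], and per gene
`P_gc = P_c * N_midF * 100 / L_g`, with genes above 0.1 masked for that
sample (`conspecific_probability()`). The formula is dimensionally odd
(a percentage times a count scaled by length) but is applied literally,
with the 0.1 cutoff on that literal value; `maf_range` and `p_gc_max` are
arguments for users who prefer a rescaled variant. The mid-range interval
is closed at both ends — the boundary choice is not decidable from the
definition and closed is the conservative (more exclusion) reading.

**Alignment sanitation.** Back-translated protein alignments occasionally
contain 3-nt register shifts over terminal gene segments.
`fix_frameshifts()` masks, per sequence, regions where 150-bp windows
(advanced one position at a time) fall below the expected identity
threshold `E[id] = IDi - (1 - IDi)/4 - max(0.1, 3*sigma)` over runs of at
least 50 consecutive window starts, and discards sequences more than 60%
masked. Identities are recomputed after each sequence's pass, in input
order, in a single sweep (no fixpoint iteration); a second application is
a no-op because masked cells leave the identity computation.
`trim_alignment()` removes columns below 10% occupancy, with a floor
keeping at least 60% of columns (the most occupied ones). Genes enter the
phylogeny only if at least 400 nt long and 75% non-N; samples only if at
least 10% of concatenated nucleotides are called and at least 20% of the
phylogeny genes are present (any called base counts as presence — the
package treats presence as "contributes signal", and the 10% nucleotide
rule dominates in practice).

## Strain delineation

Concatenated consensus genes (positionally aligned by construction) give
pairwise p-distances over sites called in both samples; `build_tree()`
runs neighbor-joining, clamps negative branch lengths to zero and
midpoint-roots unless an outgroup is named.

Two numerical choices matter on near-noiseless data. First, identical
genotypes are collapsed before NJ and re-attached as zero-length
polytomies: NJ otherwise resolves a clone cluster with cancelling
positive/negative branch pairs, and clamping only the negatives inflates
within-clone path lengths by orders of magnitude more than the data
support. Second, branches shorter than half of one substitution across
the alignment (`0.5 / L`) are collapsed — they are below the resolution
of the distance matrix.

Strains are maximal monophyletic clades whose cophenetic diameter stays
within a cutoff; because the diameter is non-decreasing towards the root,
every leaf has a unique maximal qualifying ancestor, so the three
delineation rules always produce a partition into monophyletic groups:

* `delineate_fixed()` — hard cutoff at 0.01 evolutionary distance;
* `delineate_quantile()` — cutoff at the 10% quantile (linear
  interpolation) of all pairwise distances in the species' tree;
* `delineate_phylo_nn()` — seed pairs are leaves whose nearest neighbor
  is of the same host; the 95% quantile of those seed distances is the
  within-individual distance used as the clade-diameter cutoff.

The clade-diameter reading reconciles the distance-threshold and
monophyly languages in which these rules are usually stated and makes
assignments unique; ties are broken by postorder traversal position. The
package treats the nearest-neighbor method as primary and checks that it
and the quantile method give practically identical per-species
persistence (Spearman rho at or above 0.99 on simulated cohorts — the
`benchmark_method_equivalence()` experiment).

`strain_ani()` summarizes reconstruction precision: pairwise ANI
(percent matching sites over sites called in both sequences) within
strain groups recurring in at least two samples, group-averaged.

## Persistence, survival, and transmission

With per-sample strain labels, each host is an ordered series; undetected
timepoints are excluded before pairing.

* **Persistence** (`strain_persistence()`): consecutive same-strain pairs
  add the full interval to `Dcts`; different-strain pairs assume the
  exchange happened midway and add half the interval to each accumulator.
  Species persistence pools day sums across hosts (time-weighted, the
  "summed across individuals" reading). Note the midpoint rule bounds
  persistence below by 50%. A longest-run variant
  (`persistence_longest_run()`) is provided for comparison.
* **Resilience** (`strain_resilience()`): the same with pair counts
  instead of days, reported as `100 * Ncts / (Ncts + Nctd)` so the
  statistic is a percentage bounded by 100.
* **Annual persistence** (`annual_persistence()`): Kaplan-Meier
  product-limit survival of each host's longest same-strain span, right
  censored at the last detected sample; runs ended by replacement get the
  midpoint event time, consistent with the persistence rule. S(365) is
  read from the step function (`survival::survfit`).
* **Exposure contrasts** (`antibiotic_impact()`): impact is the ratio of
  group means; enrichment is Fisher's exact test on (same, different) by
  exposure, with day sums rescaled to the resilience pair totals first so
  the test sees the effective number of independent observations.
  P-values are reported uncorrected by design (screening use). Odds
  ratios are conditional MLEs solved to machine precision from the
  noncentral hypergeometric score equation (`fisher_or()`), because the
  stock optimizer only reaches ~1e-5 and the package's tests hold its
  estimators to brute-force oracles at 1e-10.

Host ages are medians over samples; `age_window_profile()` averages
host-level metrics in age windows (smoothing is presentation-layer and
not part of the statistic). Adults are hosts at least 18 years old;
children/teens below that; family pairs are typed vertical
(adult + non-adult), horizontal (adult + adult), or sibling (excluded
from both).

## Phylogeography

For geographic tests the sample set is reduced to one carrying sample per
family (per host where no family links exist), chosen at random under a
seed, irrespective of strain multiplicity — repeated sampling of a
household must not masquerade as geographic signal.

* `mantel_geo()`: Spearman-based Mantel correlation between cophenetic
  and great-circle distances (Haversine, Earth radius 6,371 km), with
  permutation p-values using the add-one convention
  `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`, plus a correlogram over
  distance classes (first class [0, 150) km; further classes — 1,500 and
  5,000 km boundaries — are configuration, not anchored).
* `country_permanova()`: Gower sum-of-squares decomposition of squared
  cophenetic distances by country; `R2 = SS_between / SS_total`, pseudo-F,
  permutation p. Across species, significance is the joint rule p < 0.05
  and Benjamini-Hochberg q < 0.1 (`bh_significant()`).

Both tests are implemented directly (a few lines of linear algebra each)
and are cross-checked in the test suite against `vegan::mantel()` and
`vegan::adonis2()` as independent references, and against brute-force
sum-of-squares enumeration; their permutation calibration (type-I error
within [0.035, 0.065] at alpha = 0.05) is asserted over 1,000 null draws.

## Population genetics

All estimators run per gene on in-frame consensus alignments, restricted
to complete columns, after the downsampling protocol
(`downsample_protocol()`: one random sample per host, then 20 random
genes; species with fewer genes keep all and are flagged). Species values
are medians over genes.

* Site classes (`classify_degeneracy()`): using the consensus codon per
  column triplet (the definition is silent on polymorphic codons;
  consensus is the deterministic choice), a position is 4-fold degenerate
  if all three alternative bases are synonymous and 0-fold if none are; a
  change to a stop codon counts as non-synonymous, and genes with an
  internal stop in the consensus are excluded. "Synonymous sites" means
  4-fold positions only and "non-synonymous" 0-fold only.
* `diversity_stats()`: segregating sites, Watterson's theta per site
  (`S / (a1 L)`), nucleotide diversity as mean pairwise difference per
  site.
* `tajimas_d()`: the standard 1989 coefficients; `NA` below 4 sequences
  or without segregating sites. The sign identity (D <= 0 exactly when
  pi*L <= S/a1) is asserted as a property test, and neutral-coalescent
  calibration (mean D within [-0.15, 0.15] at n = 20, theta = 5) over 200
  replicates.
* `dnds_vs_outgroup()`: Nei-Gojobori (1986) counting with equal pathway
  weighting and Jukes-Cantor correction, outgroup against each ingroup
  sequence, medians over sequences then genes. Codons with N, gaps or
  stops in either sequence are skipped, as are codon pairs connected only
  through stop codons (both their sites and their differences — keeping
  the two sides of the ratio consistent). `dN/dS` is `NA` when `dS` is 0
  or a correction saturates. This estimator is deliberately simple and
  fully oracle-checked; it is not a codeml replacement.
* `sackin_pda()`: sum of leaf depths normalized by `n^1.5`;
  `median_tree_distance()` complements it. The mean non-zero relative
  abundance serves as the census-size proxy.

## Dispersal strategies

`assemble_profiles()` aggregates per-species metrics to genus means,
keeps the 50 most abundant genera and z-scores the columns.
`cluster_dispersal()` runs Ward (ward.D2) hierarchical clustering on the
z-scored persistence, family-association and phylogeography columns, cut
at k = 5, and names clusters from centroid rules: tenacious (all three
above +0.5 SD), heredipersistent (family above +0.5, geography below 0),
spatiopersistent (geography above +0.5, family below 0), non-persistent
(all below -0.5), remainder average persistent. The +/-0.5 SD rule is a
package decision (the original labeling of such clusters is by
inspection); k is a parameter, and k = 6 exposes a residual mixed group.
Rows are sorted by name before clustering so labels cannot depend on
input order, and nothing in the procedure is randomized.
`correlation_suite()` (pairwise Spearman, BH within the test family,
partial correlations as Pearson on rank residuals) and `group_tests()`
(Kruskal-Wallis across strategy groups, persistence-versus-gene-count
correlations) provide the accompanying statistics.

## Catalog and bin refinement

The co-abundance utilities operate on gene-by-sample matrices:
`declutter()` merges, within a protein cluster, gene pairs co-occurring
in under 10% of the samples where either occurs and co-excluding at
Fisher p < 1e-5 (one-sided, union-find transitive closure);
`dereplicate_bins()` merges bins best-quality-tier first when they share
30% of the smaller bin's genes or 300 genes ("30% of their genes" is
resolved as the smaller bin — the permissive reading that makes the
300-gene clause a large-bin escape hatch, and configurable);
`merge_canopies()` applies the same rule to canopy gene sets, keeping a
canopy independent only if at least 90% of its genes occur in no bin;
`refine_mgs()` fishes genes correlating with the mean core profile at
Pearson > 0.75 *and* Spearman > 0.85, clusters candidates on correlation
distance (average linkage; Spearman below 25% median occupancy, else
Pearson — the occupancy switch value is a package decision), and selects
the subcluster by (no duplicated marker classes, marker count, size),
lexicographically.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
not the sequencing process:

* **Cohort** (`simulate_cohort()`): families of adults (18-70 y) and
  children (0-3 y, matching the child definition used throughout) across
  four countries, fixed sampling days, Bernoulli antibiotic exposure and
  birth mode.
* **Strain histories** (`simulate_strain_histories()`): memoryless
  replacement — retention over `dt` days is `exp(-rate * dt)`; the
  simplest process with a tunable annual survival, since only the outcome,
  not the mechanism, is measured. On loss (and for a child's first
  colonization) the new lineage comes from the family pool with
  probability `p_family_source`; otherwise, with probability
  `geo_clustering`, the host adopts the country's endemic founder lineage
  — a deliberate model of the locally expanded clades real cohorts show,
  chosen after a uniform draw over all local lineages proved to give so
  convex a response that planted geographic gradients were statistically
  unrecoverable at realistic cohort sizes; otherwise a circulating global
  lineage or a novel immigrant (`p_novel`). Adults arrive with their own
  strains (family seeding at baseline applies to children only), so
  parent-child and adult-adult sharing can differ — the property the
  vertical/horizontal contrast measures.
* **Sequences** (`evolve_sequences()`): random sense-codon root genomes;
  founder lineages diverge from the root at about 1% (uniform 0.5-1.5x
  `strain_divergence`); within a lineage, Poisson(rate x years x length)
  neutral substitutions between observation days, with a single
  lineage-level sequence timeline so donor and recipient are identical on
  the transfer day. The default 1e-6 substitutions/site/year sits inside
  the plausible bacterial range (1e-8 to 1e-5).
* **Observations** (`emit_observations()`): Poisson depth per position,
  uniform miscalls, optional two-strain mixtures at a fixed conspecific
  fraction, and (`sim_raw_msa()`) optional 3-nt terminal register shifts
  for the masking tests.

Strategy presets place the five dispersal archetypes in parameter space
(replacement/day, family sourcing, geographic clustering): tenacious
(1e-4, 0.8, 0.8), heredipersistent (1e-3, 0.8, 0), spatiopersistent
(3e-4, 0.1, 0.8), average (1e-3, 0.4, 0.4), non-persistent (6e-3, 0.05,
0.05) — i.e., annual survivals of roughly 0.96, 0.69, 0.90, 0.69 and
0.11. Sporulation and oxygen-tolerance gene counts default to increasing
functions of the replacement rate, planting the anti-correlation with
persistence that the group tests should detect.

What the generator does *not* emulate: read-level errors correlated along
reads, GC/abundance bias, gene gain/loss, recombination, and
within-lineage selection. Passing tests therefore demonstrate that the
statistics recover the processes they claim to measure under the stated
model — not that the model captures every idiosyncrasy of real
metagenomes.

## Benchmarks and problem sizes

Two pipeline-level experiments summarize fidelity, both deterministic
given a seed (`scripts/acceptance.R` reruns them):

* `benchmark_strain_precision()` — 50 hosts, 5 timepoints over 2 years,
  20 genes of 1,500 nt, 10x coverage, 0.5% base error, mutation rate
  1e-6/site/year: the median pairwise ANI within recurrent same-host
  strain groups after the full genotype-tree-delineation chain. Faithful
  reconstruction gives exactly 100%.
* `benchmark_method_equivalence()` — 30 species spanning replacement
  rates 0 to 0.03/day over 100 hosts and 4 timepoints: Spearman
  correlation of per-species persistence between the quantile and
  nearest-neighbor delineations.

The test suite additionally recovers a planted annual retention of 0.80
by Kaplan-Meier (averaging 10 cohorts of 200 hosts — a single draw has
sampling sd ~0.028, wider than the tolerance deserves), and rank-recovers
planted family (30 species, family sourcing 0-1) and geographic (30
species, 200 leaves, clustering 0-1) gradients. Simulation sizes
throughout were chosen as the smallest that leave the planted effects
comfortably above sampling noise.

## Known limitations

* NJ trees are distance-based; no likelihood model, no rate
  heterogeneity, no support values. External newick trees can be supplied
  instead.
* The conspecific filter excludes; it does not deconvolve the secondary
  strain.
* The literal `P_gc` formula is aggressive for short genes at low
  coverage (a couple of noisy mid-frequency positions can mask a 600-nt
  gene); with the default 10-gene geometry this is rare, and with the
  intended ~1-kb genes at 10x it is negligible, but tiny demo
  configurations will occasionally blank genes.
* Polymorphism-based selection measures (pN/pS) are not computed; the
  profile field is populated only from externally supplied results.
* The per-species sample-number dependence of the estimators is reported
  (`n` alongside every estimate) but not modeled.
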