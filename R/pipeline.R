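# End-to-end orchestration: a single config drives simulation, genotyping,
# strain delineation, persistence/dispersal/population-genetic statistics
# and the strategy clustering, with seeded substreams per stage and a
# provenance manifest.

#' Pipeline configuration
#'
#' Collects all stage parameters with their standard defaults. Accepts a
#' YAML file path or a named list; supplied values override defaults after
#' validation.
#'
#' @param config Optional YAML path or list of overrides.
#' @param ... Further overrides (take precedence).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = NULL, ...) {
  defaults <- list(
    seed = 1,
    n_species = 3,
    strategies = NULL,           # defaults to cycling the five presets
    cohort = list(),             # cohort_config() overrides
    species = list(),            # species_config() overrides (shared)
    observation = list(),        # obs_config() overrides
    consensus = list(min_depth = 2, threshold = 0.501, p_gc_max = 0.1),
    filters = list(min_gene_len = 400, min_gene_nonN = 0.75,
                   min_sample_cov = 0.10, min_sample_genes = 0.20),
    delineation = list(method = "phylo_nn", fixed_cutoff = 0.01,
                       quantile = 0.10, nn_quantile = 0.95),
    geo = list(n_perm = 199, classes = c(0, 150, 1500, 5000, Inf)),
    popgen = list(n_genes = 20),
    outdir = NULL
  )
  if (is.character(config)) config <- yaml::read_yaml(config)
  ov <- utils::modifyList(config %||% list(), list(...))
  cfg <- utils::modifyList(defaults, ov)
  thr <- cfg$consensus$threshold
  if (!is.numeric(thr) || thr <= 0.5 || thr > 1) {
    stop("consensus threshold must lie in (0.5, 1]")
  }
  if (is.null(cfg$seed)) stop("seed is mandatory")
  structure(cfg, class = "pipeline_config")
}

#' Analyze one species from pileups to per-species statistics
#'
#' The per-species core of the pipeline: consensus calling with conspecific
#' exclusion, gene/sample filtering, neighbor-joining phylogeny, the three
#' strain delineations, persistence/resilience/annual survival, family and
#' geographic association, and the population-genetic profile.
#'
#' @param pileups A `strain_pileups` for one species.
#' @param meta Sample metadata (from [simulate_cohort()] or equivalent).
#' @param cfg A `pipeline_config`.
#' @param outgroup Optional outgroup genotype for dN/dS.
#' @param abundance Optional per-sample species abundance.
#' @param seed Seed for the seeded sub-steps (timepoint draws, subsetting,
#'   permutations).
#' @return A list of class `species_analysis` (or `NULL` when fewer than 3
#'   samples survive filtering): consensus set, tree, assignments, and the
#'   statistic blocks.
#' @export
analyze_species <- function(pileups, meta, cfg = pipeline_config(),
                            outgroup = NULL, abundance = NULL, seed = 1) {
  cs <- call_consensus_set(pileups,
                           min_depth = cfg$consensus$min_depth,
                           threshold = cfg$consensus$threshold,
                           p_gc_max = cfg$consensus$p_gc_max)
  cs <- filter_genes_and_samples(cs,
                                 min_gene_len = cfg$filters$min_gene_len,
                                 min_gene_nonN = cfg$filters$min_gene_nonN,
                                 min_sample_cov = cfg$filters$min_sample_cov,
                                 min_sample_genes = cfg$filters$min_sample_genes)
  if (nrow(cs$seqs) < 3) return(NULL)
  phy <- build_tree(cs)
  mm <- meta[match(rownames(cs$seqs), meta$sample_id), ]
  hosts <- stats::setNames(mm$host, mm$sample_id)
  asg <- list(
    fixed_cutoff = delineate_fixed(phy, cfg$delineation$fixed_cutoff),
    tree_quantile = delineate_quantile(phy, cfg$delineation$quantile),
    phylo_nn = delineate_phylo_nn(phy, hosts, cfg$delineation$nn_quantile)
  )
  main <- asg[[cfg$delineation$method]]
  series <- data.frame(host = mm$host, day = mm$day,
                       strain = main$strain[match(mm$sample_id, main$sample)],
                       stringsAsFactors = FALSE)
  pers <- strain_persistence(series)
  resi <- strain_resilience(series)
  ann <- tryCatch(annual_persistence(series), error = function(e) NULL)
  fam <- family_association(main, meta, seed = substream_seed(seed, 4))
  vh <- if (!is.null(fam$pairs)) vertical_horizontal(fam) else NULL
  geo <- NULL
  cty <- NULL
  sub <- subset_one_per_family(meta, rownames(cs$seqs),
                               seed = substream_seed(seed, 5))
  sub <- intersect(sub, rownames(phy$coph))
  if (length(sub) >= 4) {
    sm <- meta[match(sub, meta$sample_id), ]
    gd <- geo_dist_matrix(stats::setNames(sm$lat, sub), sm$lon)
    geo <- tryCatch(
      mantel_geo(phy$coph[sub, sub], gd, n_perm = cfg$geo$n_perm,
                 classes = cfg$geo$classes, seed = substream_seed(seed, 6)),
      error = function(e) NULL)
    if (length(unique(sm$country)) >= 2 &&
        min(table(sm$country)) >= 2) {
      cty <- tryCatch(
        country_permanova(phy$coph[sub, sub], sm$country,
                          n_perm = cfg$geo$n_perm,
                          seed = substream_seed(seed, 7)),
        error = function(e) NULL)
    }
  }
  pg <- popgen_profile(cs, hosts, outgroup = outgroup, tree = phy,
                       abundance = abundance,
                       n_genes = cfg$popgen$n_genes,
                       seed = substream_seed(seed, 8))
  structure(list(
    consensus = cs, tree = phy, assignments = asg, series = series,
    persistence = pers, resilience = resi, annual = ann,
    family = fam, vertical_horizontal = vh, mantel = geo, permanova = cty,
    popgen = pg
  ), class = "species_analysis")
}

# Flatten one species_analysis into a profile row.
.species_row <- function(species_id, an, sp = NULL) {
  data.frame(
    species = species_id,
    persistence = an$persistence$species,
    resilience = an$resilience$species,
    annual_persistence = if (is.null(an$annual)) NA else 100 * an$annual$surv,
    family_association = an$family$percent,
    vertical = if (is.null(an$vertical_horizontal)) NA else an$vertical_horizontal$vertical,
    horizontal = if (is.null(an$vertical_horizontal)) NA else an$vertical_horizontal$horizontal,
    mantel_r = if (is.null(an$mantel)) NA else an$mantel$r,
    mantel_p = if (is.null(an$mantel)) NA else an$mantel$p,
    permanova_R2 = if (is.null(an$permanova)) NA else an$permanova$R2,
    permanova_p = if (is.null(an$permanova)) NA else an$permanova$p,
    TajimaD_S = an$popgen$TajimaD_S, pi_S = an$popgen$pi_S,
    dNdS = an$popgen$dNdS,
    sackin_pda = an$popgen$sackin_pda,
    n_samples = nrow(an$consensus$seqs),
    n_hosts = length(unique(an$series$host)),
    sporulation_ko = if (is.null(sp)) NA else sp$sporulation_ko_count,
    oxygen_ko = if (is.null(sp)) NA else sp$oxygen_ko_count,
    abundance = if (is.null(sp)) NA else sp$occupancy,
    stringsAsFactors = FALSE
  )
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in dependency order on a simulated cohort:
#' `simulate` (cohort, strain histories, sequences, observations),
#' `genotype`+`strains`+`persistence`+`dispersal`+`popgen` (per species via
#' [analyze_species()]), and `patterns` (profile assembly and strategy
#' clustering, when enough species are available). All randomness derives
#' from the root seed through fixed per-stage substreams, so rerunning with
#' the same config is byte-identical; a provenance manifest records seeds
#' and thresholds.
#'
#' @param config A [pipeline_config()], YAML path, or override list.
#' @param stages Character vector of stages to run.
#' @return A list of class `pipeline_result`: `cohort`, `species`
#'   (per-species analyses and truths), `profiles` (per-species table),
#'   `patterns`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "genotype", "strains",
                                    "persistence", "dispersal", "popgen",
                                    "patterns")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cfg <- config
  preset_names <- c("tenacious", "heredipersistent", "spatiopersistent",
                    "average", "non-persistent")
  strategies <- cfg$strategies %||%
    preset_names[(seq_len(cfg$n_species) - 1L) %% 5L + 1L]
  if (!"simulate" %in% stages) stop("the pipeline is simulation-driven: include 'simulate'")
  cohort <- simulate_cohort(do.call(cohort_config, utils::modifyList(
    list(seed = substream_seed(cfg$seed, 1)), cfg$cohort)))
  obs <- do.call(obs_config, cfg$observation)
  species <- list()
  profiles <- list()
  for (si in seq_along(strategies)) {
    sp <- do.call(species_config, utils::modifyList(
      list(species_id = sprintf("sp%02d", si), strategy = strategies[si]),
      cfg$species))
    hist <- simulate_strain_histories(cohort, sp,
                                      seed = substream_seed(cfg$seed, 2, si))
    truth <- evolve_sequences(hist, sp, seed = substream_seed(cfg$seed, 3, si))
    pile <- emit_observations(truth, obs, seed = substream_seed(cfg$seed, 4, si))
    rec <- list(config = sp, history = hist, truth = truth, pileups = pile)
    if (any(c("genotype", "strains", "persistence") %in% stages) &&
        length(pile$counts) >= 3) {
      an <- analyze_species(pile, cohort, cfg, outgroup = NULL,
                            seed = substream_seed(cfg$seed, 5, si))
      rec$analysis <- an
      if (!is.null(an)) {
        profiles[[length(profiles) + 1L]] <- .species_row(sp$species_id, an, sp)
      }
    }
    species[[sp$species_id]] <- rec
  }
  profiles <- if (length(profiles)) do.call(rbind, profiles) else NULL
  patterns <- NULL
  if ("patterns" %in% stages && !is.null(profiles) && nrow(profiles) >= 5) {
    genus <- stats::setNames(profiles$species, profiles$species)
    prof <- assemble_profiles(profiles, genus, top_n = nrow(profiles))
    patterns <- tryCatch(cluster_dispersal(prof), error = function(e) NULL)
  }
  manifest <- list(
    package = as.character(utils::packageVersion("straintrack")),
    seed = cfg$seed,
    stages = stages,
    thresholds = cfg[c("consensus", "filters", "delineation", "geo", "popgen")],
    n_species = length(species)
  )
  out <- structure(list(cohort = cohort, species = species,
                        profiles = profiles, patterns = patterns,
                        manifest = manifest), class = "pipeline_result")
  if (!is.null(cfg$outdir)) write_pipeline_outputs(out, cfg$outdir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d samples, %d species analysed\n",
              nrow(x$cohort),
              if (is.null(x$profiles)) 0L else nrow(x$profiles)))
  if (!is.null(x$profiles)) {
    print(x$profiles[, c("species", "persistence", "resilience",
                         "family_association", "mantel_r")])
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Metadata, per-species strain assignments and the profile table as TSV,
#' plus the provenance manifest as JSON.
#'
#' @param result A `pipeline_result`.
#' @param outdir Output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$cohort, file.path(outdir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$profiles)) {
    utils::write.table(result$profiles, file.path(outdir, "species_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (sid in names(result$species)) {
    an <- result$species[[sid]]$analysis
    if (is.null(an)) next
    write_assignment_tsv(an$assignments$phylo_nn,
                         file.path(outdir, sprintf("%s_strains.tsv", sid)),
                         meta = result$cohort)
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
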