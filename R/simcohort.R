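# Synthetic cohort simulator: families of hosts across countries, longitudinal
# sampling, Markov strain replacement with family/geographic transmission,
# neutral sequence evolution on strain genealogies, and read-level sampling
# noise. The generator provides ground truth against which every downstream
# stage of the package can be validated.

#' Default country panel
#'
#' Four countries with representative coordinates; families are split as
#' evenly as possible.
#'
#' @param n_families Total families to distribute.
#' @return Data frame with `name`, `lat`, `lon`, `n_families`.
#' @export
default_countries <- function(n_families = 20) {
  base <- data.frame(
    name = c("Denmark", "Spain", "Kazakhstan", "Peru"),
    lat  = c(55.68, 40.42, 51.17, -12.05),
    lon  = c(12.57, -3.70, 71.43, -77.04),
    stringsAsFactors = FALSE
  )
  n <- nrow(base)
  base$n_families <- diff(round(seq(0, n_families, length.out = n + 1)))
  base
}

#' Cohort configuration
#'
#' Describes the host population to simulate: families of adults and children
#' distributed over countries, longitudinal sampling days, host ages and
#' clinical covariates.
#'
#' @param n_families Number of families.
#' @param adults_per_family,children_per_family Hosts per family. Adults are
#'   assigned roles `mother`/`father` (additional adults become `adult`).
#' @param countries Data frame with columns `name`, `lat`, `lon` (degrees) and
#'   `n_families`; families are dealt out in order. Defaults to four countries
#'   splitting `n_families` evenly.
#' @param sampling_days Strictly increasing collection days (day 0 = host's
#'   first sample), applied to every host, or a list with one such vector per
#'   host.
#' @param adult_age_range,child_age_range Age ranges in years; children are
#'   at most 3 years old by default, matching the child definition used
#'   throughout the package.
#' @param p_antibiotic Per-host probability of antibiotic exposure.
#' @param p_csection Per-child probability of caesarean delivery.
#' @param seed Mandatory integer seed; identical config + seed gives
#'   byte-identical output.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 20,
                          adults_per_family = 2,
                          children_per_family = 1,
                          countries = default_countries(n_families),
                          sampling_days = c(0, 120, 240, 365),
                          adult_age_range = c(18, 70),
                          child_age_range = c(0, 3),
                          p_antibiotic = 0.1,
                          p_csection = 0.2,
                          seed = 1) {
  if (sum(countries$n_families) != n_families) {
    stop("countries$n_families must sum to n_families")
  }
  days_ok <- function(d) length(d) >= 1 && !is.unsorted(d, strictly = TRUE)
  if (is.list(sampling_days)) {
    if (!all(vapply(sampling_days, days_ok, TRUE))) {
      stop("sampling days must be strictly increasing within a host")
    }
  } else if (!days_ok(sampling_days)) {
    stop("sampling days must be strictly increasing within a host")
  }
  stopifnot_prob(p_antibiotic, "p_antibiotic")
  stopifnot_prob(p_csection, "p_csection")
  structure(list(
    n_families = n_families,
    adults_per_family = adults_per_family,
    children_per_family = children_per_family,
    countries = countries,
    sampling_days = sampling_days,
    adult_age_range = adult_age_range,
    child_age_range = child_age_range,
    p_antibiotic = p_antibiotic,
    p_csection = p_csection,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate a host cohort
#'
#' Generates the sample metadata table: one row per collected sample with
#' host, family, role, age at sampling, country and coordinates, collection
#' day, antibiotic exposure and birth mode.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per sample (`sample_id`, `host`,
#'   `family`, `role`, `age`, `country`, `lat`, `lon`, `day`, `antibiotic`,
#'   `birth_mode`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    fam_country <- rep(seq_len(nrow(config$countries)), config$countries$n_families)
    hosts <- list()
    h <- 0L
    for (f in seq_len(config$n_families)) {
      ci <- fam_country[f]
      roles <- c(
        c("mother", "father", rep("adult", max(0, config$adults_per_family - 2)))[
          seq_len(config$adults_per_family)],
        rep("child", config$children_per_family)
      )
      for (r in roles) {
        h <- h + 1L
        age <- if (r == "child") {
          stats::runif(1, config$child_age_range[1], config$child_age_range[2])
        } else {
          stats::runif(1, config$adult_age_range[1], config$adult_age_range[2])
        }
        hosts[[h]] <- data.frame(
          host = sprintf("H%04d", h),
          family = sprintf("F%03d", f),
          role = r,
          age0 = age,
          country = config$countries$name[ci],
          lat = config$countries$lat[ci],
          lon = config$countries$lon[ci],
          antibiotic = stats::runif(1) < config$p_antibiotic,
          birth_mode = if (r == "child") {
            if (stats::runif(1) < config$p_csection) "csection" else "vaginal"
          } else {
            NA_character_
          },
          stringsAsFactors = FALSE
        )
      }
    }
    hosts <- do.call(rbind, hosts)
    rows <- lapply(seq_len(nrow(hosts)), function(i) {
      days <- if (is.list(config$sampling_days)) {
        config$sampling_days[[((i - 1L) %% length(config$sampling_days)) + 1L]]
      } else {
        config$sampling_days
      }
      data.frame(
        sample_id = sprintf("%s_T%02d", hosts$host[i], seq_along(days)),
        host = hosts$host[i], family = hosts$family[i], role = hosts$role[i],
        age = hosts$age0[i] + days / 365,
        country = hosts$country[i], lat = hosts$lat[i], lon = hosts$lon[i],
        day = days, antibiotic = hosts$antibiotic[i],
        birth_mode = hosts$birth_mode[i],
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Strategy presets: replacement (per day), family sourcing and geographic
# clustering chosen so the five archetypes span the qualitative space the
# dispersal clustering expects. Annual strain survival is exp(-365 * rate).
strategy_presets <- function(strategy) {
  presets <- list(
    tenacious          = list(replacement_rate = 1e-4, p_family_source = 0.8, geo_clustering = 0.8),
    heredipersistent   = list(replacement_rate = 1e-3, p_family_source = 0.8, geo_clustering = 0.0),
    spatiopersistent   = list(replacement_rate = 3e-4, p_family_source = 0.1, geo_clustering = 0.8),
    average            = list(replacement_rate = 1e-3, p_family_source = 0.4, geo_clustering = 0.4),
    `non-persistent`   = list(replacement_rate = 6e-3, p_family_source = 0.05, geo_clustering = 0.05)
  )
  if (!strategy %in% names(presets)) {
    stop("unknown strategy: ", strategy)
  }
  presets[[strategy]]
}

#' Species configuration
#'
#' Parameters of one simulated species: Markov strain-replacement rate,
#' family/geographic transmission, neutral mutation rate, core-gene geometry
#' and host occupancy. A `strategy` preset fills `replacement_rate`,
#' `p_family_source` and `geo_clustering` unless they are given explicitly.
#'
#' @param species_id Identifier.
#' @param strategy One of `"tenacious"`, `"heredipersistent"`,
#'   `"spatiopersistent"`, `"average"`, `"non-persistent"`.
#' @param replacement_rate Per-day probability rate of strain loss; strain
#'   retention over an interval of `dt` days is `exp(-replacement_rate * dt)`.
#' @param p_family_source Probability a newly acquired strain is drawn from
#'   the family pool (also the probability a child is initially colonized
#'   from a parent).
#' @param geo_clustering Concentration of strain lineages within a country,
#'   0 = global panmixia, 1 = fully local.
#' @param mutation_rate Substitutions/site/year within a lineage.
#' @param n_genes,gene_length_nt Core-gene geometry; `gene_length_nt` must be
#'   a multiple of 3.
#' @param occupancy Probability the species is detectable in a host.
#' @param strain_divergence Expected p-distance of a novel founder lineage
#'   from the species root sequence (inter-strain divergence scale).
#' @param p_novel Probability that a non-family, non-pool acquisition founds
#'   a novel immigrant lineage.
#' @param sporulation_ko_count,oxygen_ko_count Gene-function counts carried
#'   along as species covariates; by default scaled with the replacement rate
#'   so poorly persisting species carry more sporulation/oxygen-tolerance
#'   genes.
#' @return A list of class `species_config`.
#' @export
species_config <- function(species_id,
                           strategy = "average",
                           replacement_rate = NULL,
                           p_family_source = NULL,
                           geo_clustering = NULL,
                           mutation_rate = 1e-6,
                           n_genes = 10,
                           gene_length_nt = 900,
                           occupancy = 0.8,
                           strain_divergence = 0.01,
                           p_novel = 0.3,
                           sporulation_ko_count = NULL,
                           oxygen_ko_count = NULL) {
  preset <- strategy_presets(strategy)
  if (is.null(replacement_rate)) replacement_rate <- preset$replacement_rate
  if (is.null(p_family_source)) p_family_source <- preset$p_family_source
  if (is.null(geo_clustering)) geo_clustering <- preset$geo_clustering
  if (replacement_rate < 0) stop("replacement_rate must be >= 0")
  stopifnot_prob(p_family_source, "p_family_source")
  stopifnot_prob(geo_clustering, "geo_clustering")
  stopifnot_prob(occupancy, "occupancy")
  if (gene_length_nt %% 3 != 0) stop("gene_length_nt must be divisible by 3")
  if (is.null(sporulation_ko_count)) {
    sporulation_ko_count <- as.integer(round(5 + 8000 * replacement_rate))
  }
  if (is.null(oxygen_ko_count)) {
    oxygen_ko_count <- as.integer(round(2 + 3000 * replacement_rate))
  }
  structure(list(
    species_id = species_id, strategy = strategy,
    replacement_rate = replacement_rate,
    p_family_source = p_family_source,
    geo_clustering = geo_clustering,
    mutation_rate = mutation_rate,
    n_genes = as.integer(n_genes),
    gene_length_nt = as.integer(gene_length_nt),
    occupancy = occupancy,
    strain_divergence = strain_divergence,
    p_novel = p_novel,
    sporulation_ko_count = sporulation_ko_count,
    oxygen_ko_count = oxygen_ko_count
  ), class = "species_config")
}

#' Simulate strain histories for one species over a cohort
#'
#' Walks every host's sampling timeline. Over an inter-sample interval of
#' `dt` days the resident strain is retained with probability
#' `exp(-replacement_rate * dt)`; on loss a new lineage is drawn from the
#' family pool with probability `p_family_source`, otherwise from a
#' country-weighted pool of circulating lineages (weight `geo_clustering`),
#' with a residual probability of founding a novel immigrant lineage.
#' Children are initially colonized from a parent with probability
#' `p_family_source`.
#'
#' @param cohort Sample metadata from [simulate_cohort()].
#' @param sp A [species_config()].
#' @param seed Integer seed.
#' @return A list of class `strain_history`: `history` (one row per sample:
#'   `sample_id`, `host`, `family`, `country`, `day`, `lineage`; `NA` lineage
#'   marks hosts the species does not occupy), `lineages` (genealogy:
#'   `lineage`, `origin_host`, `origin_day`, `origin_country`, `divergence`)
#'   and `events` (acquisitions: `host`, `day`, `lineage`, `source`).
#' @export
simulate_strain_histories <- function(cohort, sp, seed = 1) {
  stopifnot(nrow(cohort) > 0, inherits(sp, "species_config"))
  with_seed(seed, {
    hosts <- unique(cohort[, c("host", "family", "role", "country")])
    occupied <- hosts$host[stats::runif(nrow(hosts)) < sp$occupancy]
    samp <- cohort[cohort$host %in% occupied, , drop = FALSE]
    # adults first within a day, so children can be seeded from parents
    samp <- samp[order(samp$day, samp$role == "child", samp$host), , drop = FALSE]

    current <- list()       # host -> lineage id currently carried
    lineages <- list()      # registry rows
    events <- list()
    n_lin <- 0L

    new_founder <- function(host, day, country) {
      n_lin <<- n_lin + 1L
      div <- sp$strain_divergence * stats::runif(1, 0.5, 1.5)
      lineages[[n_lin]] <<- data.frame(
        lineage = n_lin, origin_host = host, origin_day = day,
        origin_country = country, divergence = div, stringsAsFactors = FALSE
      )
      n_lin
    }

    draw_lineage <- function(host, family, country, day, use_family = TRUE) {
      fam_hosts <- hosts$host[hosts$family == family & hosts$host != host]
      fam_pool <- unlist(current[intersect(fam_hosts, names(current))], use.names = FALSE)
      if (use_family && length(fam_pool) > 0 && stats::runif(1) < sp$p_family_source) {
        return(list(lin = fam_pool[sample.int(length(fam_pool), 1)], source = "family"))
      }
      # geographic clustering: each country carries a locally dominant
      # (endemic) lineage -- the first founded there -- adopted with
      # probability geo_clustering, mirroring the local clonal expansions
      # seen in real cohorts
      if (stats::runif(1) < sp$geo_clustering) {
        reg <- do.call(rbind, lineages[seq_len(n_lin)])
        endemic <- if (is.null(reg)) integer(0) else
          reg$lineage[reg$origin_country == country]
        if (length(endemic) > 0) {
          return(list(lin = endemic[1], source = "country"))
        }
        return(list(lin = new_founder(host, day, country), source = "novel"))
      }
      carried <- unlist(current[setdiff(names(current), host)], use.names = FALSE)
      if (length(carried) > 0 && stats::runif(1) >= sp$p_novel) {
        return(list(lin = carried[sample.int(length(carried), 1)], source = "global"))
      }
      list(lin = new_founder(host, day, country), source = "novel")
    }

    last_day <- list()
    hist_rows <- vector("list", nrow(samp))
    for (i in seq_len(nrow(samp))) {
      s <- samp[i, ]
      lin <- NA_integer_
      if (is.null(current[[s$host]])) {
        # initial colonization: only children seed from the family (their
        # parents); adults arrive with their own strains
        acq <- draw_lineage(s$host, s$family, s$country, s$day,
                            use_family = s$role == "child")
        lin <- acq$lin
        events[[length(events) + 1L]] <- data.frame(
          host = s$host, day = s$day, lineage = lin, source = acq$source,
          stringsAsFactors = FALSE
        )
      } else {
        dt <- s$day - last_day[[s$host]]
        if (stats::runif(1) < exp(-sp$replacement_rate * dt)) {
          lin <- current[[s$host]]
        } else {
          acq <- draw_lineage(s$host, s$family, s$country, s$day)
          lin <- acq$lin
          events[[length(events) + 1L]] <- data.frame(
            host = s$host, day = s$day, lineage = lin, source = acq$source,
            stringsAsFactors = FALSE
          )
        }
      }
      current[[s$host]] <- lin
      last_day[[s$host]] <- s$day
      hist_rows[[i]] <- data.frame(
        sample_id = s$sample_id, host = s$host, family = s$family,
        country = s$country, day = s$day, lineage = lin,
        stringsAsFactors = FALSE
      )
    }
    history <- do.call(rbind, hist_rows)
    if (!is.null(history)) history <- history[order(history$host, history$day), ]
    rownames(history) <- NULL
    structure(list(
      species_id = sp$species_id,
      history = history,
      lineages = if (n_lin > 0) do.call(rbind, lineages[seq_len(n_lin)]) else NULL,
      events = if (length(events)) do.call(rbind, events) else NULL
    ), class = "strain_history")
  })
}

#' @export
print.strain_history <- function(x, ...) {
  cat(sprintf(
    "strain history: species %s, %d samples, %d hosts, %d lineages, %d acquisitions\n",
    x$species_id, nrow(x$history), length(unique(x$history$host)),
    if (is.null(x$lineages)) 0L else nrow(x$lineages),
    if (is.null(x$events)) 0L else nrow(x$events)
  ))
  invisible(x)
}

# Random root genome: codons drawn uniformly from the 61 sense codons so
# downstream dN/dS machinery always sees valid frames.
random_root <- function(n_genes, gene_length_nt) {
  codons <- expand.grid(1:4, 1:4, 1:4)
  aa <- apply(codons, 1, function(co) translate_codon(co))
  sense <- codons[aa != "*", , drop = FALSE]
  n_cod <- n_genes * gene_length_nt / 3
  pick <- sense[sample.int(nrow(sense), n_cod, replace = TRUE), ]
  as.integer(t(as.matrix(pick)))
}

mutate_sites <- function(seq, n_mut) {
  if (n_mut <= 0) return(seq)
  pos <- sample.int(length(seq), min(n_mut, length(seq)))
  shift <- sample.int(3, length(pos), replace = TRUE)
  seq[pos] <- ((seq[pos] - 1L + shift) %% 4L) + 1L
  seq
}

#' Evolve true genotype sequences along strain histories
#'
#' Each lineage receives a founder genome (the species root mutated at its
#' founder divergence) and then accrues Poisson(`mutation_rate` x years x
#' length) neutral substitutions between the days at which it is observed.
#' All hosts carrying a lineage on a given day see the same sequence, so a
#' transmitted strain is identical in donor and recipient on the transfer
#' day.
#'
#' @param histories A `strain_history` from [simulate_strain_histories()].
#' @param sp The matching [species_config()].
#' @param seed Integer seed.
#' @return A list of class `strain_truth`: `seqs` (named list, sample_id ->
#'   integer genotype over all concatenated genes), `genes` (data frame with
#'   `gene`, `start`, `end`, `length`), `root`, and `lineage_of` (named
#'   lineage per sample).
#' @export
evolve_sequences <- function(histories, sp, seed = 1) {
  stopifnot(inherits(histories, "strain_history"), inherits(sp, "species_config"))
  with_seed(seed, {
    L <- sp$n_genes * sp$gene_length_nt
    root <- random_root(sp$n_genes, sp$gene_length_nt)
    genes <- data.frame(
      gene = sprintf("%s_g%03d", sp$species_id, seq_len(sp$n_genes)),
      start = (seq_len(sp$n_genes) - 1L) * sp$gene_length_nt + 1L,
      end = seq_len(sp$n_genes) * sp$gene_length_nt,
      length = sp$gene_length_nt,
      stringsAsFactors = FALSE
    )
    h <- histories$history
    h <- h[!is.na(h$lineage), , drop = FALSE]
    seqs <- vector("list", nrow(h))
    names(seqs) <- h$sample_id
    lineage_of <- stats::setNames(h$lineage, h$sample_id)
    if (nrow(h) > 0) {
      reg <- histories$lineages
      for (lin in sort(unique(h$lineage))) {
        info <- reg[reg$lineage == lin, ]
        founder <- mutate_sites(root, stats::rbinom(1, L, info$divergence))
        days <- sort(unique(c(info$origin_day, h$day[h$lineage == lin])))
        cur <- founder
        prev_day <- days[1]
        for (d in days) {
          dt_years <- (d - prev_day) / 365
          cur <- mutate_sites(cur, stats::rpois(1, sp$mutation_rate * dt_years * L))
          prev_day <- d
          for (sid in h$sample_id[h$lineage == lin & h$day == d]) {
            seqs[[sid]] <- cur
          }
        }
      }
    }
    structure(list(
      species_id = sp$species_id, seqs = seqs, genes = genes, root = root,
      lineage_of = lineage_of
    ), class = "strain_truth")
  })
}

#' Observation-model configuration
#'
#' Read-sampling noise applied to true genotypes: per-position Poisson depth,
#' uniform base miscalls, optional conspecific strain mixtures and optional
#' frameshift artifacts injected into raw alignments.
#'
#' @param mean_coverage Mean reads per position (> 0).
#' @param error_rate Per-base miscall probability.
#' @param p_conspecific Probability a sample carries a second strain.
#' @param conspecific_fraction Relative abundance of the second strain,
#'   within (0.2, 0.8).
#' @param p_frameshift_artifact Per-gene probability of a 3-nt register shift
#'   over a terminal segment in the emitted raw alignment.
#' @param frameshift_len Length (nt) of the shifted terminal segment.
#' @return A list of class `obs_config`.
#' @export
obs_config <- function(mean_coverage = 10,
                       error_rate = 0.005,
                       p_conspecific = 0,
                       conspecific_fraction = 0.5,
                       p_frameshift_artifact = 0,
                       frameshift_len = 200) {
  if (mean_coverage <= 0) stop("mean_coverage must be > 0")
  stopifnot_prob(error_rate, "error_rate")
  stopifnot_prob(p_conspecific, "p_conspecific")
  stopifnot_prob(p_frameshift_artifact, "p_frameshift_artifact")
  if (conspecific_fraction <= 0.2 || conspecific_fraction >= 0.8) {
    stop("conspecific_fraction must lie in (0.2, 0.8)")
  }
  structure(list(
    mean_coverage = mean_coverage, error_rate = error_rate,
    p_conspecific = p_conspecific, conspecific_fraction = conspecific_fraction,
    p_frameshift_artifact = p_frameshift_artifact,
    frameshift_len = frameshift_len
  ), class = "obs_config")
}

# Add base-call errors of one strain component to a counts matrix.
add_component_counts <- function(counts, truth, reads, error_rate) {
  L <- length(truth)
  errs <- stats::rbinom(L, reads, error_rate)
  ok <- reads - errs
  idx <- cbind(seq_len(L), truth)
  counts[idx] <- counts[idx] + ok
  tot <- sum(errs)
  if (tot > 0) {
    pos <- rep.int(seq_len(L), errs)
    shift <- sample.int(3, tot, replace = TRUE)
    base <- ((truth[pos] - 1L + shift) %% 4L) + 1L
    tab <- tabulate(pos + (base - 1L) * L, nbins = 4L * L)
    counts <- counts + matrix(tab, nrow = L, ncol = 4L)
  }
  counts
}

#' Emit per-sample allele-count pileups from true genotypes
#'
#' Per position the depth is Poisson(`mean_coverage`); each read reports the
#' true base with probability `1 - error_rate`, otherwise a uniformly chosen
#' other base. With probability `p_conspecific` a sample is a two-strain
#' mixture: reads are split between the resident lineage and a second lineage
#' drawn from the other simulated lineages at `conspecific_fraction`.
#'
#' @param truth A `strain_truth` from [evolve_sequences()].
#' @param obs An [obs_config()].
#' @param seed Integer seed.
#' @return A list of class `strain_pileups`: `counts` (named list, sample ->
#'   integer matrix positions x 4 with columns A,C,G,T), `genes`,
#'   `conspecific` (named logical).
#' @export
emit_observations <- function(truth, obs, seed = 1) {
  stopifnot(inherits(truth, "strain_truth"), inherits(obs, "obs_config"))
  with_seed(seed, {
    sids <- names(truth$seqs)
    counts <- vector("list", length(sids))
    names(counts) <- sids
    consp <- stats::setNames(rep(FALSE, length(sids)), sids)
    for (sid in sids) {
      tr <- truth$seqs[[sid]]
      L <- length(tr)
      depth <- stats::rpois(L, obs$mean_coverage)
      cm <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
      second <- NULL
      if (obs$p_conspecific > 0 && stats::runif(1) < obs$p_conspecific) {
        other <- setdiff(unique(truth$lineage_of), truth$lineage_of[[sid]])
        if (length(other) > 0) {
          lin2 <- other[sample.int(length(other), 1)]
          sid2 <- names(truth$lineage_of)[truth$lineage_of == lin2][1]
          second <- truth$seqs[[sid2]]
        } else {
          second <- mutate_sites(tr, stats::rbinom(1, L, 0.015))
        }
        consp[sid] <- TRUE
      }
      if (is.null(second)) {
        cm <- add_component_counts(cm, tr, depth, obs$error_rate)
      } else {
        r2 <- stats::rbinom(L, depth, obs$conspecific_fraction)
        cm <- add_component_counts(cm, tr, depth - r2, obs$error_rate)
        cm <- add_component_counts(cm, second, r2, obs$error_rate)
      }
      storage.mode(cm) <- "integer"
      counts[[sid]] <- cm
    }
    structure(list(
      species_id = truth$species_id, counts = counts, genes = truth$genes,
      conspecific = consp
    ), class = "strain_pileups")
  })
}

#' Emit raw per-gene alignments with optional frameshift artifacts
#'
#' Builds per-gene multiple alignments of the true genotypes (positionally
#' aligned by construction) and, with probability `p_frameshift_artifact` per
#' gene and sequence, shifts the register of a terminal segment by 3 nt,
#' emulating the back-translation artifacts that alignment sanitation must
#' mask.
#'
#' @inheritParams emit_observations
#' @return A list of class `raw_msas`: `msas` (per gene, character matrix
#'   sequences x positions) and `shifted` (data frame of injected artifacts:
#'   `gene`, `sample`, `from`, `to`).
#' @export
sim_raw_msa <- function(truth, obs, seed = 1) {
  stopifnot(inherits(truth, "strain_truth"), inherits(obs, "obs_config"))
  with_seed(seed, {
    sids <- names(truth$seqs)
    shifted <- list()
    msas <- vector("list", nrow(truth$genes))
    names(msas) <- truth$genes$gene
    for (g in seq_len(nrow(truth$genes))) {
      rng <- truth$genes$start[g]:truth$genes$end[g]
      m <- t(vapply(sids, function(sid) {
        int_to_seq(truth$seqs[[sid]][rng], collapse = FALSE)
      }, character(length(rng))))
      rownames(m) <- sids
      Lg <- length(rng)
      for (i in seq_along(sids)) {
        if (stats::runif(1) < obs$p_frameshift_artifact) {
          seg_len <- min(obs$frameshift_len, Lg - 3L)
          p0 <- Lg - seg_len + 1L
          m[i, p0:Lg] <- m[i, (p0 - 3L):(Lg - 3L)]
          shifted[[length(shifted) + 1L]] <- data.frame(
            gene = truth$genes$gene[g], sample = sids[i], from = p0, to = Lg,
            stringsAsFactors = FALSE
          )
        }
      }
      msas[[g]] <- m
    }
    structure(list(
      species_id = truth$species_id, msas = msas,
      shifted = if (length(shifted)) do.call(rbind, shifted) else NULL
    ), class = "raw_msas")
  })
}

#' True persistence of simulated strain histories
#'
#' Computes ground-truth per-species strain persistence directly from the
#' simulated lineage labels (midpoint rule, same accumulator as
#' [strain_persistence()]), for parameter-recovery checks.
#'
#' @param histories A `strain_history`.
#' @return Percent persistence (scalar).
#' @export
true_persistence <- function(histories) {
  h <- histories$history
  strain_persistence(data.frame(
    host = h$host, day = h$day, strain = h$lineage, stringsAsFactors = FALSE
  ))$species
}
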