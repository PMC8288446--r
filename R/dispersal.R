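# Family association, vertical/horizontal transmission, and phylogeography:
# Mantel correlograms on great-circle distances and per-country perMANOVA.

ADULT_AGE <- 18  # years; hosts younger than this count as children/teens

#' Great-circle distance between coordinates
#'
#' Haversine distance with Earth radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (vectorized).
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("latitude must be in [-90, 90] and longitude in [-180, 180]")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}

#' Geographic distance matrix for a set of samples
#'
#' @param lat,lon Coordinate vectors (degrees), optionally named.
#' @return Symmetric matrix of great-circle distances in km.
#' @export
geo_dist_matrix <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  d <- (d + t(d)) / 2
  dimnames(d) <- list(names(lat), names(lat))
  d
}

#' Subset to one carrying sample per family (or host)
#'
#' Chooses, with a seeded draw, one species-carrying sample per family
#' (per host for hosts without family links), irrespective of how many
#' strains the sample carries, so repeated sampling of the same individual
#' or household cannot inflate geographic signals.
#'
#' @param meta Sample metadata (`sample_id`, `host`, `family`).
#' @param carrying Character vector of sample ids that carry the species.
#' @param seed Integer seed.
#' @return Character vector of retained sample ids.
#' @export
subset_one_per_family <- function(meta, carrying, seed = 1) {
  m <- meta[meta$sample_id %in% carrying, , drop = FALSE]
  if (nrow(m) == 0) return(character(0))
  grp <- ifelse(is.na(m$family) | m$family == "", m$host, m$family)
  with_seed(seed, {
    unname(vapply(split(m$sample_id, grp), function(s) {
      s[sample.int(length(s), 1)]
    }, ""))
  })
}

# Family host pairs with both members carrying the species; one seeded
# random carrying timepoint per host.
.family_pairs <- function(assignment, meta, seed = 1) {
  am <- merge(assignment, meta, by.x = "sample", by.y = "sample_id")
  picks <- with_seed(seed, {
    do.call(rbind, lapply(split(am, am$host), function(h) {
      h[sample.int(nrow(h), 1), , drop = FALSE]
    }))
  })
  rows <- list()
  for (fam in unique(picks$family)) {
    hp <- picks[picks$family == fam, , drop = FALSE]
    if (nrow(hp) < 2) next
    for (i in seq_len(nrow(hp))) {
      for (j in seq_len(i - 1L)) {
        adult_i <- hp$age[i] >= ADULT_AGE
        adult_j <- hp$age[j] >= ADULT_AGE
        type <- if (adult_i && adult_j) "horizontal"
        else if (adult_i || adult_j) "vertical"
        else "sibling"
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, host_a = hp$host[i], host_b = hp$host[j],
          type = type, shared = hp$strain[i] == hp$strain[j],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Conditional maximum-likelihood odds ratio of a 2x2 table
#'
#' The odds ratio under the noncentral hypergeometric model (the estimate
#' Fisher's exact test conditions on), solved from the score equation
#' `E[x11; psi] = x11` to near machine precision; 0 and infinity at the
#' support boundaries.
#'
#' @param tab 2x2 count matrix.
#' @return The conditional MLE odds ratio.
#' @export
fisher_or <- function(tab) {
  x <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(m, k)
  if (lo == hi) return(NA_real_)
  if (x == lo) return(0)
  if (x == hi) return(Inf)
  supp <- lo:hi
  lc <- lchoose(m, supp) + lchoose(n, k - supp)
  mean_x <- function(logpsi) {
    w <- lc + supp * logpsi
    w <- exp(w - max(w))
    sum(supp * w) / sum(w)
  }
  exp(stats::uniroot(function(lp) mean_x(lp) - x, c(-50, 50),
                     tol = .Machine$double.eps)$root)
}

#' Family strain association
#'
#' The percentage of within-family host pairs, both carrying the species
#' (one random timepoint per host), that share an identical strain
#' (same monophyletic group). Transmission direction is not inferred.
#'
#' @param assignment A `strain_assignment` for one species.
#' @param meta Sample metadata (`sample_id`, `host`, `family`, `age`).
#' @param seed Seed for the per-host timepoint draw.
#' @return A list of class `family_association`: `percent` (`NA` when no
#'   qualifying pair exists), `n_pairs`, `pairs` (typed pair table).
#' @export
family_association <- function(assignment, meta, seed = 1) {
  pairs <- .family_pairs(assignment, meta, seed)
  structure(list(
    percent = if (is.null(pairs)) NA_real_ else 100 * mean(pairs$shared),
    n_pairs = if (is.null(pairs)) 0L else nrow(pairs),
    pairs = pairs
  ), class = "family_association")
}

#' @export
print.family_association <- function(x, ...) {
  cat(sprintf("family association: %.1f%% over %d pairs\n", x$percent, x$n_pairs))
  invisible(x)
}

#' Vertical versus horizontal strain transmission
#'
#' Vertical pairs are adult + child/teen (< 18 y at sampling), horizontal
#' pairs adult + adult; sibling pairs are excluded. Sharing rates are
#' contrasted with Fisher's exact test on the (shared, not shared) x
#' (horizontal, vertical) table, so an odds ratio below 1 means
#' vertical-enriched sharing.
#'
#' @param pairs Pair table from [family_association()] (or the
#'   `family_association` object itself).
#' @return A list of class `vh_contrast`: `vertical`, `horizontal` (percent
#'   shared), `n_vertical`, `n_horizontal`, `or`, `p`.
#' @export
vertical_horizontal <- function(pairs) {
  if (inherits(pairs, "family_association")) pairs <- pairs$pairs
  v <- pairs[pairs$type == "vertical", , drop = FALSE]
  h <- pairs[pairs$type == "horizontal", , drop = FALSE]
  tab <- rbind(horizontal = c(sum(h$shared), sum(!h$shared)),
               vertical = c(sum(v$shared), sum(!v$shared)))
  colnames(tab) <- c("shared", "not_shared")
  or <- NA_real_; p <- NA_real_
  if (all(rowSums(tab) > 0)) {
    or <- fisher_or(tab)
    p <- stats::fisher.test(tab)$p.value
  }
  structure(list(
    vertical = if (nrow(v)) 100 * mean(v$shared) else NA_real_,
    horizontal = if (nrow(h)) 100 * mean(h$shared) else NA_real_,
    n_vertical = nrow(v), n_horizontal = nrow(h), or = or, p = p, table = tab
  ), class = "vh_contrast")
}

.mantel_stat <- function(a, b) {
  stats::cor(rank(a), rank(b))
}

#' Mantel test of genetic versus geographic distance
#'
#' Spearman-based Mantel statistic with permutation p-values using the
#' add-one convention `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`, plus a
#' correlogram: within each geographic distance class the genetic distances
#' are correlated with the class-membership indicator.
#'
#' @param gen_d Genetic (cophenetic) distance matrix.
#' @param geo_d Geographic distance matrix (km), same order.
#' @param n_perm Number of permutations.
#' @param classes Distance class boundaries in km; the first class is
#'   `[0, 150)` km by default.
#' @param seed Optional seed for the permutations.
#' @return A list of class `mantel_geo`: `r`, `p`, `n`, and `classes` (data
#'   frame `from`, `to`, `r`, `p`, `n_pairs`). `NA` statistics (with a
#'   warning) when either matrix is constant.
#' @export
mantel_geo <- function(gen_d, geo_d, n_perm = 999,
                       classes = c(0, 150, 1500, 5000, Inf), seed = NULL) {
  stopifnot(nrow(gen_d) == ncol(gen_d), all(dim(gen_d) == dim(geo_d)))
  n <- nrow(gen_d)
  if (n < 4) stop("need at least 4 leaves for a Mantel test")
  g <- lower_tri(gen_d)
  e <- lower_tri(geo_d)
  if (stats::sd(g) == 0 || stats::sd(e) == 0) {
    warning("constant distance matrix: Mantel statistic undefined")
    return(structure(list(r = NA_real_, p = NA_real_, n = n, classes = NULL),
                     class = "mantel_geo"))
  }
  do_perm <- function(target) {
    robs <- .mantel_stat(g, target)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      pm <- sample.int(n)
      rp <- .mantel_stat(g, target[.lt_index(pm, n)])
      if (rp >= robs) hits <- hits + 1L
    }
    c(r = robs, p = (1 + hits) / (1 + n_perm))
  }
  run <- function() {
    overall <- do_perm(e)
    cls <- NULL
    if (!is.null(classes) && length(classes) >= 2) {
      rows <- list()
      for (k in seq_len(length(classes) - 1L)) {
        ind <- as.numeric(e >= classes[k] & e < classes[k + 1L])
        if (stats::sd(ind) == 0) next
        res <- do_perm(ind)
        rows[[length(rows) + 1L]] <- data.frame(
          from = classes[k], to = classes[k + 1L],
          r = unname(res["r"]), p = unname(res["p"]), n_pairs = sum(ind)
        )
      }
      if (length(rows)) cls <- do.call(rbind, rows)
    }
    structure(list(r = unname(overall["r"]), p = unname(overall["p"]),
                   n = n, classes = cls), class = "mantel_geo")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Indices into the lower-triangle vector after permuting rows/cols of the
# underlying matrix.
.lt_index <- function(perm, n) {
  idx <- matrix(0L, n, n)
  idx[lower.tri(idx)] <- seq_len(n * (n - 1) / 2)
  idx <- idx + t(idx)
  idx[perm, perm][lower.tri(idx)]
}

#' @export
print.mantel_geo <- function(x, ...) {
  cat(sprintf("Mantel (Spearman): r = %.3f, p = %.4g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' perMANOVA of genetic distance by country
#'
#' Partitions the squared cophenetic distances by country label (Gower
#' decomposition): `R^2 = SS_between / SS_total`, pseudo-F with `a - 1` and
#' `n - a` degrees of freedom, and a permutation p-value with the add-one
#' convention.
#'
#' @param d Distance matrix.
#' @param groups Country label per row of `d`.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return A list of class `permanova`: `R2`, `F`, `p`, `n`, `n_groups`.
#' @export
country_permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  stopifnot(nrow(d) == length(groups))
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need at least 2 countries")
  n <- nrow(d)
  a <- length(unique(groups))
  d2 <- d^2
  ss_total <- sum(lower_tri(d2)) / n
  ssw <- function(g) {
    s <- 0
    for (lv in unique(g)) {
      i <- which(g == lv)
      if (length(i) < 2) next
      s <- s + sum(lower_tri(d2[i, i, drop = FALSE])) / length(i)
    }
    s
  }
  ss_within <- ssw(groups)
  ss_between <- ss_total - ss_within
  Fobs <- (ss_between / (a - 1)) / (ss_within / (n - a))
  run <- function() {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      gp <- groups[sample.int(n)]
      ssw_p <- ssw(gp)
      Fp <- ((ss_total - ssw_p) / (a - 1)) / (ssw_p / (n - a))
      if (Fp >= Fobs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(R2 = ss_between / ss_total, F = Fobs, p = p, n = n,
                 n_groups = a), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("perMANOVA: R2 = %.3f, F = %.3f, p = %.4g (%d leaves, %d groups)\n",
              x$R2, x$F, x$p, x$n, x$n_groups))
  invisible(x)
}

#' Benjamini-Hochberg significance across species
#'
#' Flags tests significant at raw `p < alpha` and BH `q < q_max`, the joint
#' rule used for the per-species country and geography tests.
#'
#' @param p Vector of p-values.
#' @param alpha Raw p cutoff.
#' @param q_max BH q cutoff.
#' @return Data frame `p`, `q`, `significant`.
#' @export
bh_significant <- function(p, alpha = 0.05, q_max = 0.1) {
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, significant = !is.na(p) & p < alpha & q < q_max)
}
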