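# Genus-level association profiles, dispersal-strategy clustering, and the
# correlation/enrichment statistics run across species.

#' Assemble genus-level association profiles
#'
#' Aggregates per-species association and population-genetic metrics to
#' genus means, keeps the `top_n` most abundant genera, and z-scores each
#' metric column for clustering. Genera whose metrics are entirely missing
#' are dropped with a warning.
#'
#' @param species_stats Data frame with a `species` column, an `abundance`
#'   column and one column per metric.
#' @param genus Named character vector mapping species to genus.
#' @param top_n Number of genera to retain (by mean abundance).
#' @return A list of class `association_profiles`: `raw` (genus means),
#'   `z` (z-scored matrix), `genera`.
#' @export
assemble_profiles <- function(species_stats, genus, top_n = 50) {
  stopifnot("species" %in% names(species_stats),
            "abundance" %in% names(species_stats))
  df <- species_stats
  df$genus <- genus[df$species]
  num_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], "species")
  agg <- stats::aggregate(df[num_cols], list(genus = df$genus),
                          function(x) mean(x, na.rm = TRUE))
  all_na <- apply(agg[num_cols], 1, function(r) all(is.nan(r) | is.na(r)))
  if (any(all_na)) {
    warning("dropping genera with all-missing metrics: ",
            paste(agg$genus[all_na], collapse = ", "))
    agg <- agg[!all_na, , drop = FALSE]
  }
  agg <- agg[order(-agg$abundance), , drop = FALSE]
  agg <- utils::head(agg, top_n)
  z <- scale(as.matrix(agg[setdiff(num_cols, "abundance")]))
  z[is.nan(z)] <- 0
  rownames(z) <- agg$genus
  structure(list(raw = agg, z = z, genera = agg$genus),
            class = "association_profiles")
}

# Default column mapping: which profile columns carry the persistence,
# family and geography signals used for strategy clustering.
DISPERSAL_COLS <- c(persistence = "persistence", family = "family_association",
                    geo = "mantel_r")

#' Cluster genera into dispersal strategies
#'
#' Ward hierarchical clustering (Euclidean distance) on the z-scored
#' persistence, family-association and phylogeography columns, cut at `k`
#' clusters. Clusters are named from their centroids: `tenacious` (all
#' three above +0.5 SD), `heredipersistent` (family above +0.5, geography
#' below 0), `spatiopersistent` (geography above +0.5, family below 0),
#' `non-persistent` (all below -0.5); the remainder are `average
#' persistent`. Entirely deterministic: no randomized initialization.
#'
#' @param profiles An `association_profiles`.
#' @param k Number of clusters (5 named strategies by default; use 6 to
#'   split out a residual mixed group).
#' @param cols Named vector mapping the roles `persistence`, `family`,
#'   `geo` to profile column names.
#' @return A list of class `dispersal_labels`: `labels` (named by genus),
#'   `clusters`, `centroids`, `hclust`.
#' @export
cluster_dispersal <- function(profiles, k = 5, cols = DISPERSAL_COLS) {
  z <- profiles$z[, cols, drop = FALSE]
  colnames(z) <- names(cols)
  if (nrow(z) < k) stop("need at least k rows to cut k clusters")
  ord <- order(rownames(z))  # row-order invariance of the final labels
  z <- z[ord, , drop = FALSE]
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(z)), cl), function(i) {
    colMeans(z[i, , drop = FALSE])
  }))
  label_for <- function(ce) {
    if (all(ce > 0.5)) "tenacious"
    else if (ce["family"] > 0.5 && ce["geo"] < 0) "heredipersistent"
    else if (ce["geo"] > 0.5 && ce["family"] < 0) "spatiopersistent"
    else if (all(ce < -0.5)) "non-persistent"
    else "average persistent"
  }
  cl_labels <- apply(centroids, 1, label_for)
  labels <- stats::setNames(cl_labels[as.character(cl)], rownames(z))
  structure(list(labels = labels, clusters = stats::setNames(cl, rownames(z)),
                 centroids = centroids, hclust = hc),
            class = "dispersal_labels")
}

#' @export
print.dispersal_labels <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}

#' Partial Spearman correlation
#'
#' Pearson correlation of rank-transformed residuals after regressing both
#' variables on the rank-transformed covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame or matrix of control variables.
#' @return A list: `rho`, `p`.
#' @export
partial_spearman <- function(x, y, covariates) {
  cv <- as.data.frame(lapply(as.data.frame(covariates), rank))
  rx <- stats::resid(stats::lm(rank(x) ~ ., data = cv))
  ry <- stats::resid(stats::lm(rank(y) ~ ., data = cv))
  ct <- stats::cor.test(rx, ry, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Pairwise Spearman correlation suite
#'
#' Spearman rho and p for every pair of metric columns, BH-corrected within
#' the family of tests, with optional partial correlations controlling for
#' covariates and significance stars at q < 0.05 / 0.01 / 0.001.
#'
#' @param df Data frame of metric columns (numeric).
#' @param covariates Optional covariate data frame for partial
#'   correlations.
#' @param min_n Minimum paired observations per test.
#' @return A list of class `correlation_suite`: `rho`, `p`, `q`, `stars`
#'   (matrices) and optionally `partial_rho`, `partial_p`.
#' @export
correlation_suite <- function(df, covariates = NULL, min_n = 5) {
  df <- as.data.frame(df)
  cols <- names(df)[vapply(df, is.numeric, TRUE)]
  m <- length(cols)
  rho <- p <- matrix(NA_real_, m, m, dimnames = list(cols, cols))
  diag(rho) <- 1; diag(p) <- 0
  pr <- pp <- if (is.null(covariates)) NULL else rho
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      ok <- stats::complete.cases(df[[cols[i]]], df[[cols[j]]])
      if (sum(ok) < min_n) next
      x <- df[[cols[i]]][ok]; y <- df[[cols[j]]][ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      if (!is.null(covariates)) {
        okc <- ok & stats::complete.cases(covariates)
        if (sum(okc) >= min_n) {
          ps <- partial_spearman(df[[cols[i]]][okc], df[[cols[j]]][okc],
                                 covariates[okc, , drop = FALSE])
          pr[i, j] <- pr[j, i] <- ps$rho
          pp[i, j] <- pp[j, i] <- ps$p
        }
      }
    }
  }
  q <- p
  up <- upper.tri(p)
  q[up] <- stats::p.adjust(p[up], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  stars <- matrix(cut(q, c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("***", "**", "*", "")),
                  m, m, dimnames = dimnames(q))
  structure(list(rho = rho, p = p, q = q, stars = stars,
                 partial_rho = pr, partial_p = pp),
            class = "correlation_suite")
}

#' Group tests across dispersal strategies
#'
#' Kruskal-Wallis tests of each population-genetic column across strategy
#' groups (groups with fewer than 2 members excluded), plus Spearman
#' correlations of persistence with sporulation and oxygen-tolerance gene
#' counts.
#'
#' @param profiles Data frame (e.g. `association_profiles$raw`) with the
#'   tested columns.
#' @param labels Named strategy label per row of `profiles` (names matching
#'   `profiles$genus` or rownames).
#' @param test_cols Columns to test across groups.
#' @param persistence_col,ko_cols Columns for the persistence/KO-count
#'   correlations.
#' @return A list of class `group_tests`: `kruskal` (data frame `metric`,
#'   `statistic`, `p`) and `ko_cor` (data frame `ko`, `rho`, `p`).
#' @export
group_tests <- function(profiles, labels,
                        test_cols = c("dNdS", "TajimaD_S", "pi_S", "abundance"),
                        persistence_col = "persistence",
                        ko_cols = c("sporulation_ko", "oxygen_ko")) {
  ids <- profiles$genus %||% rownames(profiles)
  lab <- labels[ids]
  keep_groups <- names(which(table(lab) >= 2))
  ok <- lab %in% keep_groups
  kr <- do.call(rbind, lapply(intersect(test_cols, names(profiles)), function(cc) {
    x <- profiles[[cc]][ok]
    g <- factor(lab[ok])
    if (length(unique(g)) < 2 || all(is.na(x))) return(NULL)
    kt <- stats::kruskal.test(x, g)
    data.frame(metric = cc, statistic = unname(kt$statistic), p = kt$p.value,
               stringsAsFactors = FALSE)
  }))
  ko <- do.call(rbind, lapply(intersect(ko_cols, names(profiles)), function(cc) {
    ct <- suppressWarnings(stats::cor.test(profiles[[persistence_col]],
                                           profiles[[cc]], method = "spearman"))
    data.frame(ko = cc, rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  structure(list(kruskal = kr, ko_cor = ko), class = "group_tests")
}
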