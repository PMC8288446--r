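# Strain persistence, resilience and Kaplan-Meier annual survival per host
# and species, plus age-window profiles and exposure contrasts.

# Sorted detected timepoints for one host; strains may be integer or
# character, NA marks non-detection (excluded from transition counting).
.detected_series <- function(series) {
  s <- series[!is.na(series$strain), , drop = FALSE]
  s[order(s$day), , drop = FALSE]
}

#' Strain persistence (time-weighted, midpoint rule)
#'
#' Consecutive detected sample pairs within a host accumulate days: a pair
#' carrying the same strain adds the full interval to `Dcts`; a pair with
#' different strains assumes the exchange happened midway and adds half the
#' interval to each of `Dcts` and `Dctd`. Species persistence pools the day
#' sums across hosts: `100 * sum(Dcts) / (sum(Dcts) + sum(Dctd))`.
#'
#' @param series Data frame with columns `host`, `day`, `strain` (`NA` =
#'   species not detected at that timepoint).
#' @return A list: `per_host` (data frame `host`, `Dcts`, `Dctd`, `n_pairs`,
#'   `persistence`) and `species` (pooled percent; `NA` when no host has two
#'   detected timepoints).
#' @export
strain_persistence <- function(series) {
  per_host <- lapply(split(series, series$host), function(s) {
    s <- .detected_series(s)
    if (nrow(s) < 2) return(NULL)
    dt <- diff(s$day)
    same <- s$strain[-1] == s$strain[-nrow(s)]
    dcts <- sum(dt[same]) + sum(dt[!same] / 2)
    dctd <- sum(dt[!same] / 2)
    data.frame(host = s$host[1], Dcts = dcts, Dctd = dctd,
               n_pairs = length(dt),
               persistence = 100 * dcts / (dcts + dctd),
               stringsAsFactors = FALSE)
  })
  per_host <- do.call(rbind, per_host)
  species <- if (is.null(per_host)) NA_real_ else
    100 * sum(per_host$Dcts) / sum(per_host$Dcts + per_host$Dctd)
  list(per_host = per_host, species = species)
}

#' Strain persistence, longest-run variant
#'
#' The fraction of each host's observed timespan covered by the longest run
#' of a single strain; provided for comparison with the accumulator-based
#' [strain_persistence()], which is the primary definition.
#'
#' @inheritParams strain_persistence
#' @return A list: `per_host` and `species` (mean over hosts).
#' @export
persistence_longest_run <- function(series) {
  per_host <- lapply(split(series, series$host), function(s) {
    s <- .detected_series(s)
    if (nrow(s) < 2) return(NULL)
    r <- rle(as.character(s$strain))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    spans <- s$day[ends] - s$day[starts]
    data.frame(host = s$host[1],
               persistence = 100 * max(spans) / (s$day[nrow(s)] - s$day[1]),
               stringsAsFactors = FALSE)
  })
  per_host <- do.call(rbind, per_host)
  list(per_host = per_host,
       species = if (is.null(per_host)) NA_real_ else mean(per_host$persistence))
}

#' Strain resilience
#'
#' The percentage of consecutive detected sample pairs within a host that
#' carry the same strain, with pair counts (`Ncts`, `Nctd`) summed across
#' hosts: `100 * sum(Ncts) / (sum(Ncts) + sum(Nctd))`. Timepoints where the
#' species is not detected are excluded before pairing.
#'
#' @inheritParams strain_persistence
#' @return A list: `per_host` (`host`, `Ncts`, `Nctd`, `resilience`) and
#'   `species`.
#' @export
strain_resilience <- function(series) {
  per_host <- lapply(split(series, series$host), function(s) {
    s <- .detected_series(s)
    if (nrow(s) < 2) return(NULL)
    same <- s$strain[-1] == s$strain[-nrow(s)]
    data.frame(host = s$host[1], Ncts = sum(same), Nctd = sum(!same),
               resilience = 100 * mean(same), stringsAsFactors = FALSE)
  })
  per_host <- do.call(rbind, per_host)
  species <- if (is.null(per_host)) NA_real_ else
    100 * sum(per_host$Ncts) / sum(per_host$Ncts + per_host$Nctd)
  list(per_host = per_host, species = species)
}

#' Longest same-strain spans with censoring flags
#'
#' For each host, the runs of one strain over detected timepoints. A run
#' ended by an observed replacement is an event whose duration extends to
#' the midpoint of the flanking interval (consistent with the persistence
#' midpoint rule); a run reaching the last detected sample is censored
#' there. Each host contributes its longest run (censored preferred on
#' ties).
#'
#' @inheritParams strain_persistence
#' @return Data frame `host`, `time` (days), `event` (1 = replacement).
#' @export
longest_strain_spans <- function(series) {
  rows <- lapply(split(series, series$host), function(s) {
    s <- .detected_series(s)
    if (nrow(s) < 2) return(NULL)
    r <- rle(as.character(s$strain))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    time <- numeric(length(ends))
    event <- integer(length(ends))
    for (k in seq_along(ends)) {
      t0 <- s$day[starts[k]]
      if (ends[k] < nrow(s)) {
        time[k] <- (s$day[ends[k]] + s$day[ends[k] + 1L]) / 2 - t0
        event[k] <- 1L
      } else {
        time[k] <- s$day[ends[k]] - t0
        event[k] <- 0L
      }
    }
    best <- order(-time, event)[1]
    data.frame(host = s$host[1], time = time[best], event = event[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier annual strain persistence
#'
#' Product-limit estimate of the probability that a strain survives `at`
#' days within a host, from per-host longest same-strain spans with right
#' censoring.
#'
#' @param spans Data frame `time`, `event` (see [longest_strain_spans()]),
#'   or a `series` data frame with `host`, `day`, `strain` which is
#'   converted first.
#' @param at Day at which to read the survival curve (default 365).
#' @return A list of class `annual_persistence`: `surv` (S(at)), `at`,
#'   `fit` (the `survfit` object), `n_hosts`.
#' @export
annual_persistence <- function(spans, at = 365) {
  if (all(c("host", "day", "strain") %in% names(spans)) && !"time" %in% names(spans)) {
    spans <- longest_strain_spans(spans)
  }
  if (is.null(spans) || nrow(spans) == 0) stop("no hosts with two detected timepoints")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = spans)
  sv <- summary(fit, times = at, extend = TRUE)$surv
  structure(list(surv = sv, at = at, fit = fit, n_hosts = nrow(spans)),
            class = "annual_persistence")
}

#' @export
print.annual_persistence <- function(x, ...) {
  cat(sprintf("Kaplan-Meier strain survival: S(%g d) = %.3f over %d hosts\n",
              x$at, x$surv, x$n_hosts))
  invisible(x)
}

#' Average a host-level metric in age windows
#'
#' Hosts are represented by their median age across samples; the metric is
#' averaged within the supplied age windows. Empty windows are omitted.
#'
#' @param values Data frame with `age` and `value` (one row per host).
#' @param breaks Window boundaries in years (left-closed).
#' @return Data frame `window`, `age_mid`, `mean`, `n`.
#' @export
age_window_profile <- function(values, breaks = c(0, 1, 3, 10, 18, 40, 65, 100)) {
  win <- cut(values$age, breaks = breaks, right = FALSE, include.lowest = TRUE)
  agg <- stats::aggregate(values$value, list(window = win), mean)
  n <- stats::aggregate(values$value, list(window = win), length)
  mid <- stats::aggregate(values$age, list(window = win), stats::median)
  data.frame(window = as.character(agg$window), age_mid = mid$x,
             mean = agg$x, n = n$x, stringsAsFactors = FALSE)
}

#' Exposure impact on persistence or resilience
#'
#' The impact of an exposure (antibiotics, caesarean birth) is the ratio of
#' mean metric values, exposed over unexposed. Enrichment is tested with
#' Fisher's exact test on the 2x2 table of (same, different) observations by
#' exposure; for day-based persistence accumulators the day sums of each
#' group are rescaled so their totals equal the resilience pair counts
#' before testing (so the test operates on the effective number of
#' independent observations). P-values are reported uncorrected.
#'
#' @param per_host Data frame with one row per host: `value` (metric),
#'   `same`, `diff` (accumulators), `exposed` (logical).
#' @param downscale Logical; rescale day sums to pair counts given in
#'   `pairs` before testing.
#' @param pairs Optional per-host total pair counts (required when
#'   `downscale = TRUE`).
#' @return A list of class `impact_contrast`: `impact`, `or`, `p`, `table`.
#' @export
antibiotic_impact <- function(per_host, downscale = FALSE, pairs = NULL) {
  stopifnot(all(c("value", "same", "diff", "exposed") %in% names(per_host)))
  grp_mean <- function(e) mean(per_host$value[per_host$exposed == e])
  if (!any(per_host$exposed) || all(per_host$exposed)) {
    stop("impact undefined: one exposure group is empty")
  }
  impact <- grp_mean(TRUE) / grp_mean(FALSE)
  cells <- function(e) {
    same <- sum(per_host$same[per_host$exposed == e])
    diff <- sum(per_host$diff[per_host$exposed == e])
    if (downscale) {
      stopifnot(!is.null(pairs))
      tot <- sum(pairs[per_host$exposed == e])
      sc <- if (same + diff > 0) tot / (same + diff) else 0
      same <- round(same * sc); diff <- round(diff * sc)
    }
    c(same, diff)
  }
  tab <- rbind(exposed = cells(TRUE), unexposed = cells(FALSE))
  colnames(tab) <- c("same", "different")
  structure(list(impact = impact, or = fisher_or(tab),
                 p = stats::fisher.test(tab)$p.value,
                 table = tab), class = "impact_contrast")
}

#' @export
print.impact_contrast <- function(x, ...) {
  cat(sprintf("impact %.3f, OR %.3g, Fisher p = %.3g\n", x$impact, x$or, x$p))
  invisible(x)
}
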