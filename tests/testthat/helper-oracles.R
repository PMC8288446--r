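# Independent brute-force oracles. These deliberately re-derive every
# quantity with the most literal (and slowest) formulation available, so
# they share no code path with the package implementation.

# --- diversity -----------------------------------------------------------

# mean pairwise difference per site, by explicit pair enumeration
oracle_pi <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      tot <- tot + sum(m[i, ] != m[j, ])
    }
  }
  tot / choose(n, 2) / L
}

oracle_S <- function(m) {
  sum(apply(m, 2, function(col) length(unique(col)) > 1))
}

oracle_theta_w <- function(m) {
  n <- nrow(m)
  oracle_S(m) / sum(1 / seq_len(n - 1)) / ncol(m)
}

# Tajima's D written directly from the published coefficient definitions,
# with pi computed by pair enumeration (not via diversity_stats).
oracle_tajima <- function(m) {
  n <- nrow(m)
  S <- oracle_S(m)
  if (S == 0 || n < 4) return(NA_real_)
  khat <- oracle_pi(m) * ncol(m)
  a1 <- sum(1 / 1:(n - 1))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (khat - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# --- Nei-Gojobori --------------------------------------------------------

oracle_translate <- local({
  tab <- NULL
  function(codon_int) {
    if (is.null(tab)) {
      b <- c("t", "c", "a", "g")
      aas <- strsplit(paste0(
        "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
        "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
      keys <- as.vector(t(outer(
        as.vector(t(outer(b, b, paste0))), b, paste0)))
      tab <<- stats::setNames(aas, keys)
    }
    tab[[tolower(paste(c("A", "C", "G", "T")[codon_int], collapse = ""))]]
  }
})

.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# syn/nonsyn sites and differences for one codon pair, by full enumeration
oracle_ng86_codon <- function(co1, co2) {
  site_frac <- function(co) {
    aa <- oracle_translate(co)
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(1:4, co[p])) {
        mut <- co
        mut[p] <- b
        if (oracle_translate(mut) == aa) s <- s + 1 / 3
      }
    }
    s
  }
  diffs <- which(co1 != co2)
  syn <- 0; non <- 0; valid <- 0
  for (ord in .perms(diffs)) {
    cur <- co1
    s <- 0; ns <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- co2[p]
      if (oracle_translate(nxt) == "*") { ok <- FALSE; break }
      if (oracle_translate(nxt) == oracle_translate(cur)) s <- s + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (ok) { syn <- syn + s; non <- non + ns; valid <- valid + 1 }
  }
  if (length(diffs) > 0 && valid == 0) return(NULL)
  list(S_sites = (site_frac(co1) + site_frac(co2)) / 2,
       Sd = if (length(diffs)) syn / valid else 0,
       Nd = if (length(diffs)) non / valid else 0)
}

oracle_ng86 <- function(s1, s2) {
  Ss <- 0; Sd <- 0; Nd <- 0; ncod <- 0
  for (c0 in seq(1, length(s1), by = 3)) {
    co1 <- s1[c0:(c0 + 2)]; co2 <- s2[c0:(c0 + 2)]
    if (any(co1 == 0) || any(co2 == 0)) next
    if (oracle_translate(co1) == "*" || oracle_translate(co2) == "*") next
    r <- oracle_ng86_codon(co1, co2)
    if (is.null(r)) next
    Ss <- Ss + r$S_sites; Sd <- Sd + r$Sd; Nd <- Nd + r$Nd
    ncod <- ncod + 1
  }
  Ns <- 3 * ncod - Ss
  pS <- Sd / Ss; pN <- Nd / Ns
  corr <- function(p) if (1 - 4 * p / 3 <= 0) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dS = corr(pS), dN = corr(pN))
}

# --- survival ------------------------------------------------------------

# hand product-limit estimator
oracle_km <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# --- perMANOVA -----------------------------------------------------------

oracle_permanova_r2 <- function(d, groups) {
  n <- nrow(d)
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(i - 1)) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    for (a in idx) for (b in idx) if (a < b) s <- s + d[a, b]^2
    ssw <- ssw + s / length(idx)
  }
  (sst - ssw) / sst
}

# --- Fisher's exact test -------------------------------------------------

# two-sided p by enumerating all tables with the observed margins and
# summing hypergeometric probabilities no larger than the observed one
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  hy <- function(x) stats::dhyper(x, r1, r2, c1)
  p_obs <- hy(tab[1, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(xs, hy, 0)[vapply(xs, hy, 0) <= p_obs * (1 + 1e-7)])
}

# --- coalescent ----------------------------------------------------------

# Kingman coalescent with infinite-sites mutations; returns a 0/1-coded
# alignment as bases A/C (enough for the diversity machinery)
sim_coalescent_aln <- function(n, theta, min_sites = 1) {
  nodes <- as.list(seq_len(n))
  times <- rep(0, n)
  lineages <- seq_len(n)
  parent_desc <- list()
  t_now <- 0
  branches <- list()  # list of (descendant tip set, length)
  active <- lapply(seq_len(n), function(i) i)
  blen <- rep(0, n)
  while (length(active) > 1) {
    k <- length(active)
    dt <- stats::rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + dt
    pick <- sample.int(k, 2)
    for (ii in sort(pick, decreasing = TRUE)) {
      branches[[length(branches) + 1L]] <- list(tips = active[[ii]],
                                                len = blen[ii])
    }
    merged <- c(active[[pick[1]]], active[[pick[2]]])
    active <- active[-pick]
    blen <- blen[-pick]
    active[[length(active) + 1L]] <- merged
    blen[length(active)] <- 0
  }
  cols <- list()
  for (br in branches) {
    nmut <- stats::rpois(1, theta / 2 * br$len)
    if (nmut > 0) {
      for (m in seq_len(nmut)) {
        col <- rep(1L, n)
        col[br$tips] <- 2L
        cols[[length(cols) + 1L]] <- col
      }
    }
  }
  while (length(cols) < min_sites) cols[[length(cols) + 1L]] <- rep(1L, n)
  do.call(cbind, cols)
}

# --- trees ---------------------------------------------------------------

# least-squares branch fit for a fixed 4-leaf unrooted topology ab|cd
.ls_fit4 <- function(d, a, b, c_, d_) {
  # design: 5 branches (ta, tb, tc, td, tm) against 6 distances
  X <- rbind(
    c(1, 1, 0, 0, 0),   # ab
    c(1, 0, 1, 0, 1),   # ac
    c(1, 0, 0, 1, 1),   # ad
    c(0, 1, 1, 0, 1),   # bc
    c(0, 1, 0, 1, 1),   # bd
    c(0, 0, 1, 1, 0)    # cd
  )
  y <- c(d[a, b], d[a, c_], d[a, d_], d[b, c_], d[b, d_], d[c_, d_])
  fit <- stats::lm.fit(X, y)
  list(rss = sum(fit$residuals^2), branches = fit$coefficients)
}

# best least-squares 4-leaf tree over the three topologies
oracle_ls_tree4 <- function(d) {
  tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  fits <- lapply(tops, function(tp) .ls_fit4(d, tp[1], tp[2], tp[3], tp[4]))
  best <- which.min(vapply(fits, `[[`, 0, "rss"))
  list(split = tops[[best]], fit = fits[[best]])
}

# --- misc ----------------------------------------------------------------

# sampled strain series from a simulated history, using true lineage labels
history_series <- function(hist) {
  h <- hist$history
  data.frame(host = h$host, day = h$day, strain = h$lineage,
             stringsAsFactors = FALSE)
}

is_stop_seq <- function(s) {
  any(vapply(seq(1, length(s), by = 3), function(c0) {
    oracle_translate(s[c0:(c0 + 2)]) == "*"
  }, TRUE))
}

# conditional MLE odds ratio by hand-rolled bisection on the monotone
# conditional expectation (independent of uniroot)
oracle_fisher_or <- function(tab) {
  x <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo_s <- max(0, k - n); hi_s <- min(m, k)
  if (x == lo_s) return(0)
  if (x == hi_s) return(Inf)
  supp <- lo_s:hi_s
  lc <- lchoose(m, supp) + lchoose(n, k - supp)
  f <- function(lp) {
    w <- exp(lc + supp * lp - max(lc + supp * lp))
    sum(supp * w) / sum(w) - x
  }
  lo <- -50; hi <- 50
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}
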