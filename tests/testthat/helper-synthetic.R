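# Shared fixtures: small, fast synthetic configurations built in code.

small_config <- function(seed = 101, cells = 300, n_good = 3, n_bad = 3,
                         n_hd = 2, ...) {
  syntheticCohortConfig(seed = seed, n_good = n_good, n_bad = n_bad,
                        n_hd = n_hd, cells_per_condition = cells, ...)
}

# Survival-only config: n patients split over two groups, binary hazard
# modifier with the given HR for high mitochondrial dependence.
surv_config <- function(seed, n = 100, hr = 1, cens = 0.2, threshold = 80) {
  syntheticCohortConfig(
    seed = seed, n_good = ceiling(n / 2), n_bad = floor(n / 2),
    cells_per_condition = 100,
    survival = list(baseline_hazard = 0.04, hr_high = hr,
                    threshold = threshold, censoring_rate = cens))
}

# Independent sort-based quantile-binning oracle: rank cells against the
# interpolated 25/50/75 percentiles computed from first principles (type-7
# definition written out), ties below a boundary stay in the lower bin.
bin_oracle <- function(x) {
  n <- length(x)
  v <- sort(x)
  qs <- vapply(c(0.25, 0.5, 0.75), function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }, numeric(1))
  vapply(x, function(xi) 1L + sum(xi > qs), integer(1))
}

# Independent product-limit oracle: direct enumeration over event times.
km_oracle <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t <= at) {
      n_risk <- sum(times >= t)
      d <- sum(times == t & events == 1)
      s <- s * (1 - d / n_risk)
    }
  }
  s
}

# Independent two-group log-rank oracle: explicit 2x2 tabulation per event
# time (counts written out, no shared code with the implementation).
logrank_oracle <- function(times, events, groups) {
  lev <- sort(unique(as.character(groups)))
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    in_risk <- times >= t
    tab <- table(factor(groups[in_risk], levels = lev),
                 factor(times[in_risk] == t & events[in_risk] == 1,
                        levels = c(FALSE, TRUE)))
    n <- sum(tab)
    n1 <- sum(tab[1, ])
    d <- sum(tab[, "TRUE"])
    d1 <- tab[1, "TRUE"]
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
  }
  list(chisq = if (v > 0) (o - e)^2 / v else 0,
       z = if (v > 0) (o - e) / sqrt(v) else 0)
}
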