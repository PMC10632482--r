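# Survival statistics implemented in-repo: Kaplan-Meier product-limit
# estimation, the two-group log-rank test, maximally selected rank-statistic
# cutpoint selection, and univariate Cox proportional hazards with Efron
# tie handling. These carry the headline outcome associations, so they are
# authored here and cross-checked against the survival package in tests.

.check_surv <- function(times, events) {
  if (any(times < 0)) stop("survival times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("event flags must be 0/1")
  if (length(times) != length(events)) stop("times/events length mismatch")
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over distinct event times t_j <= t of (1 - d_j / n_j), with
#' d_j deaths and n_j subjects at risk at t_j. Censored subjects leave the
#' risk set after their censoring time. With no censoring this equals the
#' empirical survival function.
#'
#' @param times non-negative follow-up times.
#' @param events 0 = censored, 1 = event.
#' @return list with `time` (distinct event times), `n_risk`, `n_event`,
#'   `surv` (S just after each event time), and `survfun`, a right-continuous
#'   step function S(t) with S(0) = 1.
#' @examples
#' km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' km$survfun(2.5)  # 0.5
#' @export
kmEstimate <- function(times, events) {
  .check_surv(times, events)
  if (!length(times)) stop("need at least one subject")
  ev_times <- sort(unique(times[events == 1]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  survfun <- if (length(ev_times))
    stats::stepfun(ev_times, c(1, surv), right = FALSE)
  else function(t) rep(1, length(t))
  list(time = ev_times, n_risk = n_risk, n_event = n_event, surv = surv,
       survfun = survfun)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected formulation: at each distinct event time, the
#' expected group-1 deaths under the null are d_j * n_1j / n_j with
#' hypergeometric variance d_j (n_1j/n_j)(1 - n_1j/n_j)(n_j - d_j)/(n_j - 1).
#' The chi-square statistic is (O - E)^2 / V on 1 degree of freedom; the
#' signed standardized form (O - E)/sqrt(V) is also returned (used by the
#' maxstat scan). Invariant under swapping group labels.
#'
#' @param times,events as in [kmEstimate()].
#' @param groups vector with exactly two distinct labels.
#' @return list with `chisq`, `df`, `p`, `z` (standardized statistic for
#'   the first group sorted by label), `observed`, `expected`.
#' @export
logrankTest <- function(times, events, groups) {
  .check_surv(times, events)
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("log-rank test requires exactly 2 groups, got ",
                             length(lev))
  g1 <- groups == lev[1]
  ev_times <- sort(unique(times[events == 1]))
  if (length(ev_times)) {
    riskmat <- outer(ev_times, times, "<=")      # at risk at each event time
    n_risk <- rowSums(riskmat)
    n1_risk <- riskmat %*% g1
    tie <- outer(ev_times, times, "==") & matrix(events == 1,
                                                 length(ev_times),
                                                 length(times), byrow = TRUE)
    d <- rowSums(tie)
    d1 <- tie %*% g1
    O <- sum(d1)
    E <- sum(d * n1_risk / n_risk)
    ok <- n_risk > 1
    V <- sum((d * (n1_risk / n_risk) * (1 - n1_risk / n_risk) *
                (n_risk - d) / pmax(n_risk - 1, 1))[ok])
  } else {
    O <- 0; E <- 0; V <- 0
  }
  if (V <= 0) {
    z <- 0; chisq <- 0
  } else {
    z <- (O - E) / sqrt(V)
    chisq <- z^2
  }
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       z = z, observed = O, expected = E)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans every distinct observed covariate value whose quantile rank lies
#' within `bounds`, dichotomizes the cohort at each candidate (high = value
#' above the candidate) and computes the standardized two-group log-rank
#' statistic; the selected cutpoint maximizes |z| (ties broken toward the
#' smaller cutpoint). The naive log-rank p at the selected cutpoint is
#' reported as `p_uncorrected` and labelled as such — selecting the maximum
#' inflates type I error, so a seeded permutation p-value is available via
#' `n_perm`.
#'
#' @param covariate numeric biomarker values.
#' @param times,events survival outcome.
#' @param bounds quantile window for candidate cutpoints (default
#'   `c(0.1, 0.9)`).
#' @param n_perm optional number of label permutations for a selection-aware
#'   p-value (0 = skip).
#' @param perm_seed seed for the permutation stream.
#' @return list with `cutpoint`, `statistic` (max |z|), `p_uncorrected`,
#'   `scan` (data.frame candidate/statistic), group sizes, and `p_perm`
#'   when requested.
#' @export
maxstatCutpoint <- function(covariate, times, events, bounds = c(0.1, 0.9),
                            n_perm = 0, perm_seed = 1L) {
  .check_surv(times, events)
  if (length(covariate) != length(times))
    stop("covariate/times length mismatch")
  if (length(covariate) < 10)
    stop("maxstat needs >= 10 subjects, got ", length(covariate))
  ranks <- vapply(covariate, function(v) mean(covariate <= v), numeric(1))
  cand <- sort(unique(covariate[ranks >= bounds[1] & ranks <= bounds[2]]))
  cand <- cand[cand < max(covariate)]  # a split must leave a high group
  if (length(cand) < 1)
    stop("no candidate cutpoints inside the quantile bounds")

  scan_stat <- function(tms, evs) vapply(cand, function(cut) {
    abs(logrankTest(tms, evs, covariate > cut)$z)
  }, numeric(1))

  stat <- scan_stat(times, events)
  best <- which(stat == max(stat))[1]  # ties -> smaller cutpoint
  cut <- cand[best]
  lr <- logrankTest(times, events, covariate > cut)
  out <- list(cutpoint = cut, statistic = stat[best],
              p_uncorrected = lr$p,
              scan = data.frame(candidate = cand, statistic = stat),
              n_high = sum(covariate > cut), n_low = sum(covariate <= cut))
  if (n_perm > 0) {
    old <- local_seed(perm_seed)
    on.exit(restore_seed(old))
    max_null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(times))
      max(scan_stat(times[idx], events[idx]))
    }, numeric(1))
    out$p_perm <- (1 + sum(max_null >= stat[best])) / (n_perm + 1)
  }
  out
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the Efron partial likelihood for a single numeric or binary
#' covariate by Newton-Raphson. The hazard ratio is exp(beta); the 95%
#' confidence interval and Wald p come from the observed information.
#' Monotone likelihood (complete separation) is detected and reported as a
#' non-estimable coefficient rather than a huge number.
#'
#' @param times,events survival outcome; >= 2 events required.
#' @param covariate numeric covariate, non-constant.
#' @param max_iter Newton iteration cap (default 25).
#' @param tol convergence tolerance on the score (default 1e-9).
#' @return list with `coef` (log HR), `hr`, `se`, `ci` (length-2, HR
#'   scale), `p` (Wald), `converged`, `iterations`, `estimable`.
#' @export
coxUnivariate <- function(times, events, covariate, max_iter = 25,
                          tol = 1e-9) {
  .check_surv(times, events)
  if (sum(events) < 2) stop("need >= 2 events")
  x <- as.numeric(covariate)
  if (length(unique(x)) < 2) stop("covariate is constant")
  xc <- x - mean(x)  # centering leaves beta unchanged, improves conditioning

  ev_times <- sort(unique(times[events == 1]))
  # Precompute risk/death index sets per event time
  risk_sets <- lapply(ev_times, function(t) which(times >= t))
  death_sets <- lapply(ev_times, function(t) which(times == t & events == 1))

  derivs <- function(beta) {
    ll <- 0; U <- 0; I <- 0
    exb <- exp(beta * xc)
    for (j in seq_along(ev_times)) {
      R <- risk_sets[[j]]; D <- death_sets[[j]]
      d <- length(D)
      s0R <- sum(exb[R]); s1R <- sum(xc[R] * exb[R])
      s2R <- sum(xc[R]^2 * exb[R])
      s0D <- sum(exb[D]); s1D <- sum(xc[D] * exb[D])
      s2D <- sum(xc[D]^2 * exb[D])
      ll <- ll + beta * sum(xc[D])
      for (l in seq_len(d) - 1) {
        f <- l / d
        phi0 <- s0R - f * s0D
        phi1 <- s1R - f * s1D
        phi2 <- s2R - f * s2D
        ll <- ll - log(phi0)
        U <- U - phi1 / phi0
        I <- I + phi2 / phi0 - (phi1 / phi0)^2
      }
      U <- U + sum(xc[D])
    }
    list(ll = ll, U = U, I = I)
  }

  beta <- 0; converged <- FALSE; iter <- 0; estimable <- TRUE
  for (iter in seq_len(max_iter)) {
    d <- derivs(beta)
    if (!is.finite(d$U) || !is.finite(d$I) || d$I <= 0) {
      estimable <- FALSE
      break
    }
    step <- d$U / d$I
    beta <- beta + step
    if (abs(beta) > 15) {  # monotone likelihood: beta runs away
      estimable <- FALSE
      break
    }
    if (abs(d$U) < tol || abs(step) < 1e-12) {
      converged <- TRUE
      break
    }
  }
  if (!estimable)
    return(list(coef = NA_real_, hr = NA_real_, se = NA_real_,
                ci = c(NA_real_, NA_real_), p = NA_real_,
                converged = FALSE, iterations = iter, estimable = FALSE))
  d <- derivs(beta)
  se <- sqrt(1 / d$I)
  zq <- stats::qnorm(0.975)
  list(coef = beta, hr = exp(beta), se = se,
       ci = exp(c(beta - zq * se, beta + zq * se)),
       p = 2 * stats::pnorm(-abs(beta / se)),
       converged = converged, iterations = iter, estimable = TRUE)
}

#' Dichotomize, fit and tabulate survival associations for many biomarkers
#'
#' For each covariate column: select a maxstat cutpoint, dichotomize into
#' high/low, fit the univariate Cox model on the indicator and run the
#' log-rank test — producing a forest-plot-ready table.
#'
#' @param records data.frame with `os_months`/`os_event` (or
#'   `pfs_months`/`pfs_event`) and the covariate columns.
#' @param covariates character vector of biomarker column names.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param bounds maxstat quantile window.
#' @return data.frame: covariate, cutpoint, n_high, n_low, hr, ci_low,
#'   ci_high, p_wald, p_logrank.
#' @export
survivalAssociationTable <- function(records, covariates, endpoint = "OS",
                                     bounds = c(0.1, 0.9)) {
  endpoint <- match.arg(endpoint, c("OS", "PFS"))
  tcol <- if (endpoint == "OS") "os_months" else "pfs_months"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  tms <- records[[tcol]]; evs <- records[[ecol]]
  rows <- lapply(covariates, function(cv) {
    x <- records[[cv]]
    ms <- maxstatCutpoint(x, tms, evs, bounds = bounds)
    high <- as.numeric(x > ms$cutpoint)
    cx <- coxUnivariate(tms, evs, high)
    data.frame(covariate = cv, endpoint = endpoint, cutpoint = ms$cutpoint,
               n_high = ms$n_high, n_low = ms$n_low,
               hr = cx$hr, ci_low = cx$ci[1], ci_high = cx$ci[2],
               p_wald = cx$p, p_logrank = ms$p_uncorrected)
  })
  do.call(rbind, rows)
}
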