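test_that("Kaplan-Meier equals the empirical survival function without
           censoring", {
  km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survfun(2.5), 0.5)
  expect_equal(km$survfun(0), 1)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  set.seed(51)
  times <- rexp(40)
  km2 <- kmEstimate(times, rep(1, 40))
  for (t in c(0.1, 0.5, 1, 2))
    expect_equal(km2$survfun(t), mean(times > t))
})

test_that("all-censored data keep S(t) = 1 and negative times error", {
  km <- kmEstimate(c(1, 5, 9), c(0, 0, 0))
  expect_equal(km$survfun(c(0, 4, 100)), c(1, 1, 1))
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), ">= 0")
})

test_that("product-limit estimate matches direct enumeration and the
           survival package", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    times <- round(rexp(n, 0.2), 1)
    events <- rbinom(n, 1, 0.7)
    if (!sum(events)) events[1] <- 1
    km <- kmEstimate(times, events)
    for (at in sample(times, 3))
      expect_equal(km$survfun(at), km_oracle(times, events, at))
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    expect_equal(km$surv, sf$surv[sf$n.event > 0], tolerance = 1e-12)
  }
})

test_that("log-rank: null on duplicated groups, label-swap and ordering
           invariance, oracle equality", {
  times <- c(1, 3, 5, 7, 9)
  events <- c(1, 1, 0, 1, 1)
  lr0 <- logrankTest(rep(times, 2), rep(events, 2),
                     rep(c("a", "b"), each = 5))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)

  set.seed(53)
  for (i in 1:10) {
    n <- 30
    tms <- rexp(n, 0.1)
    evs <- rbinom(n, 1, 0.8)
    grp <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(grp)) < 2) next
    lr <- logrankTest(tms, evs, grp)
    orc <- logrank_oracle(tms, evs, grp)
    expect_equal(lr$chisq, orc$chisq, tolerance = 1e-9)
    # swap and permutation invariance
    swap <- logrankTest(tms, evs, ifelse(grp == "x", "y", "x"))
    expect_equal(swap$chisq, lr$chisq, tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(logrankTest(tms[perm], evs[perm], grp[perm])$chisq,
                 lr$chisq, tolerance = 1e-9)
    sd <- survival::survdiff(survival::Surv(tms, evs) ~ grp)
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-9)
  }
  expect_error(logrankTest(times, events, rep("a", 5)), "2 groups")
})

test_that("perfectly separated groups reject at n = 20/20", {
  set.seed(54)
  tms <- c(runif(20, 0, 1), runif(20, 5, 6))
  evs <- rep(1, 40)
  grp <- rep(c("early", "late"), each = 20)
  expect_lt(logrankTest(tms, evs, grp)$p, 0.05)
})

test_that("maxstat equals an exhaustive brute-force scan", {
  set.seed(55)
  for (i in 1:5) {
    n <- 40
    x <- rnorm(n, 50, 10)
    tms <- rexp(n, 0.05 * exp(0.02 * (x - 50)))
    evs <- rbinom(n, 1, 0.8)
    ms <- maxstatCutpoint(x, tms, evs)
    # independent scan: all interior distinct values, oracle log-rank
    qs <- quantile(x, c(0.1, 0.9), type = 1)
    cand <- sort(unique(x))
    cand <- cand[vapply(cand, function(v) mean(x <= v), numeric(1)) >= 0.1 &
                 vapply(cand, function(v) mean(x <= v), numeric(1)) <= 0.9]
    cand <- cand[cand < max(x)]
    stats <- vapply(cand, function(cut)
      abs(logrank_oracle(tms, evs, ifelse(x > cut, "hi", "lo"))$z),
      numeric(1))
    expect_equal(ms$cutpoint, cand[which.max(stats)])
    expect_equal(ms$statistic, max(stats), tolerance = 1e-9)
    expect_equal(nrow(ms$scan), length(cand))
  }
})

test_that("maxstat finds a clean separation point and stays inside the
           candidate range", {
  set.seed(101)
  x <- c(1:10, 21:30)
  tms <- c(runif(10, 0.1, 1), runif(10, 10, 20))  # high x -> late events
  evs <- rep(1, 20)
  ms <- maxstatCutpoint(x, tms, evs)
  expect_equal(ms$cutpoint, 10)
  expect_gt(ms$statistic, 3)
  expect_error(maxstatCutpoint(x[1:5], tms[1:5], evs[1:5]), ">= 10")
})

test_that("cutpoint selection inflates the uncorrected type-I error and
           the permutation p corrects it", {
  set.seed(56)
  n <- 30
  reject <- logical(200)
  for (r in 1:200) {
    x <- rnorm(n)
    tms <- rexp(n, 0.1)          # independent of x: null is true
    evs <- rbinom(n, 1, 0.85)
    ms <- try(maxstatCutpoint(x, tms, evs), silent = TRUE)
    reject[r] <- !inherits(ms, "try-error") && ms$p_uncorrected < 0.05
  }
  expect_gt(mean(reject), 0.10)  # substantially above the nominal 5%

  set.seed(57)
  x <- rnorm(n); tms <- rexp(n, 0.1); evs <- rbinom(n, 1, 0.85)
  ms <- maxstatCutpoint(x, tms, evs, n_perm = 99, perm_seed = 7)
  expect_gte(ms$p_perm, ms$p_uncorrected)
})

test_that("Cox: identical groups give HR 1; Efron fit matches the survival
           package", {
  times <- rep(c(2, 4, 6, 8, 10), 2)
  events <- rep(c(1, 1, 0, 1, 1), 2)
  x <- rep(c(0, 1), each = 5)
  cx <- coxUnivariate(times, events, x)
  expect_equal(cx$hr, 1, tolerance = 1e-6)

  set.seed(58)
  for (i in 1:5) {
    n <- 60
    z <- rnorm(n)
    tms <- rexp(n, 0.1 * exp(0.6 * z))
    evs <- rbinom(n, 1, 0.8)
    cx <- coxUnivariate(tms, evs, z)
    ref <- survival::coxph(survival::Surv(tms, evs) ~ z, ties = "efron")
    expect_equal(cx$coef, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(cx$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-6)
    expect_true(cx$converged)
  }
})

test_that("tie-free partial likelihood matches brute-force maximization", {
  set.seed(59)
  n <- 6
  tms <- sample(seq(1, 60, by = 3), n)  # distinct times, no ties
  evs <- rep(1, n)
  x <- rnorm(n)
  cx <- coxUnivariate(tms, evs, x)
  # independent oracle: direct partial-likelihood grid + golden refinement
  pl <- function(beta) {
    ll <- 0
    ord <- order(tms)
    for (j in seq_len(n)) {
      i <- ord[j]
      risk <- which(tms >= tms[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  opt <- optimize(pl, c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(cx$coef, opt$maximum, tolerance = 1e-4)
})

test_that("Cox recovers a simulated log hazard ratio of ln 2", {
  cfg <- surv_config(seed = 4242, n = 500, hr = 2.0, cens = 0.2,
                     threshold = 80)
  rec <- generateSurvivalCohort(cfg)
  cx <- coxUnivariate(rec$os_months, rec$os_event, rec$high_mito)
  expect_lt(abs(cx$coef - log(2)), 0.15)
})

test_that("complete separation is flagged non-estimable, not a huge
           coefficient", {
  tms <- c(1, 2, 3, 4, 10, 11, 12, 13)
  evs <- rep(1, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)  # all x=1 events precede all x=0 events
  cx <- coxUnivariate(tms, evs, x)
  expect_false(cx$estimable)
  expect_true(is.na(cx$coef))
  expect_error(coxUnivariate(tms, evs, rep(1, 8)), "constant")
  expect_error(coxUnivariate(c(1, 2), c(1, 0), c(0, 1)), ">= 2 events")
})

test_that("association table dichotomizes at the maxstat cutpoint and
           reports a forest-ready row", {
  cfg <- surv_config(seed = 31, n = 120, hr = 0.4)
  rec <- generateSurvivalCohort(cfg)
  tab <- survivalAssociationTable(rec, "mitochondrial_dependence",
                                  endpoint = "OS")
  expect_equal(nrow(tab), 1)
  expect_true(tab$n_high + tab$n_low == nrow(rec))
  expect_true(tab$ci_low < tab$hr & tab$hr < tab$ci_high)
  pfs <- survivalAssociationTable(rec, "mitochondrial_dependence",
                                  endpoint = "PFS")
  expect_equal(pfs$endpoint, "PFS")
})
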