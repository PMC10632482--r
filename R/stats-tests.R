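# Group-comparison statistics: normality-routed two-group tests,
# multiple-testing correction (authored in-repo), per-marker differential
# linear models, Spearman correlation matrices, ANOVA + Tukey.

#' Normality-routed two-group test
#'
#' Shapiro-Wilk is run on each group at `alpha`; when both groups look
#' normal the comparison uses the two-tailed Student's t-test, otherwise
#' the two-tailed Wilcoxon test. Unpaired data route to the rank-sum test;
#' `paired = TRUE` uses the signed-rank/paired-t variants. The routing
#' decision and test used are recorded in the output.
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @param alpha Shapiro-Wilk rejection level per group (default 0.05).
#' @param paired paired design (default FALSE).
#' @param var_equal classical equal-variance t-test (default TRUE,
#'   "Student's"); set FALSE for Welch.
#' @return list with `test` ("t" or "wilcoxon"), `statistic`, `p`,
#'   `shapiro_p` (length 2), `normal` (routing decision).
#' @export
twoGroupTest <- function(values_a, values_b, alpha = 0.05, paired = FALSE,
                         var_equal = TRUE) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs >= 3 values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
    stop("zero variance in both groups: test not computable")

  shapiro_p <- vapply(list(values_a, values_b), function(v) {
    if (length(unique(v)) < 3) return(0)  # constant-ish: clearly non-normal
    if (length(v) > 5000)  # Shapiro-Wilk is defined for n <= 5000
      v <- v[round(seq(1, length(v), length.out = 5000))]
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(shapiro_p > alpha)

  if (normal) {
    ht <- stats::t.test(values_a, values_b, paired = paired,
                        var.equal = var_equal)
    test <- "t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = paired, exact = FALSE))
    test <- "wilcoxon"
  }
  list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
       shapiro_p = shapiro_p, normal = normal)
}

#' Holm and Benjamini-Hochberg p-value adjustment
#'
#' Step-down Holm (family-wise error) and step-up Benjamini-Hochberg
#' (false discovery rate) with monotonicity enforcement; input order is
#' preserved in the output. Authored here because the adjusted p-values
#' carry the marker-level claims; tests cross-check against
#' `stats::p.adjust`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"holm"` or `"bh"`.
#' @return adjusted p-values, same order as input.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh")   # all 0.04
#' adjustPvalues(c(0.01, 0.04), "holm")             # 0.02 0.04
#' @export
adjustPvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (!n) return(numeric())
  ord <- order(p)
  ps <- p[ord]
  adj <- if (method == "holm") {
    pmin(cummax((n - seq_len(n) + 1) * ps), 1)
  } else {
    rev(pmin(cummin(rev(n / seq_len(n) * ps)), 1))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Per-marker differential expression on sample medians
#'
#' Fits, per marker, a group-indicator linear model on (by default
#' log2-transformed) per-sample median intensities. The group coefficient
#' is the log fold change; p-values are BH-adjusted across markers,
#' producing a volcano-ready table. Constant markers are flagged rather
#' than dropped.
#'
#' @param medians data.frame/matrix, samples x markers, positive values
#'   when `log2` is TRUE.
#' @param groups factor/character of length nrow(medians) with exactly two
#'   levels; the fold change is level 2 over level 1 (alphabetical).
#' @param log2 log2-transform medians before fitting (default TRUE).
#' @return data.frame: marker, logFC, p, p_bh, flag.
#' @export
differentialMarkerTest <- function(medians, groups, log2 = TRUE) {
  medians <- as.data.frame(medians)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 3) stop("need >= 3 samples per group")
  g <- as.numeric(groups) - 1
  rows <- lapply(names(medians), function(mk) {
    v <- medians[[mk]]
    if (log2) {
      if (any(v <= 0)) stop("log2 transform requires positive medians (",
                            mk, ")")
      v <- base::log2(v)
    }
    if (stats::var(v) == 0)
      return(data.frame(marker = mk, logFC = 0, p = NA_real_,
                        flag = "constant_marker"))
    fit <- stats::lm(v ~ g)
    sm <- summary(fit)$coefficients
    data.frame(marker = mk, logFC = unname(sm["g", "Estimate"]),
               p = unname(sm["g", "Pr(>|t|)"]), flag = NA_character_)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  ok <- !is.na(out$p)
  out$p_bh[ok] <- adjustPvalues(out$p[ok], "bh")
  out
}

#' Pairwise Spearman correlation between two variable sets
#'
#' Rank correlation (average ranks for ties) with asymptotic p-values for
#' every column pair of `x` and `y`, e.g. supernatant lactate against
#' metabolic-transporter expression. Constant columns are reported as not
#' computable.
#'
#' @param x,y data.frames/matrices with the same number of (paired) rows,
#'   n >= 4.
#' @return data.frame: x, y, rho, p, n, flag.
#' @export
spearmanMatrix <- function(x, y) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  if (nrow(x) != nrow(y)) stop("x and y must have paired rows")
  if (nrow(x) < 4) stop("need n >= 4 pairs")
  rows <- list()
  for (cx in names(x)) for (cy in names(y)) {
    ok <- stats::complete.cases(x[[cx]], y[[cy]])
    vx <- x[[cx]][ok]; vy <- y[[cy]][ok]
    if (length(unique(vx)) < 2 || length(unique(vy)) < 2) {
      rows[[length(rows) + 1L]] <- data.frame(
        x = cx, y = cy, rho = NA_real_, p = NA_real_, n = sum(ok),
        flag = "constant_vector")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(vx, vy, method = "spearman", exact = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      x = cx, y = cy, rho = unname(ct$estimate), p = ct$p.value,
      n = sum(ok), flag = NA_character_)
  }
  do.call(rbind, rows)
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Multi-group comparison (>= 3 groups) via `aov` followed by Tukey's
#' honestly-significant-difference pairwise contrasts.
#'
#' @param values numeric response.
#' @param groups group labels (>= 3 levels, >= 2 values each).
#' @return list with `anova_p`, `anova_F`, and `tukey` (data.frame of
#'   pairwise contrasts: diff, ci_low, ci_high, p_adj).
#' @export
anovaTukey <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 3) stop("ANOVA+Tukey here is for >= 3 groups; ",
                                "use twoGroupTest for 2")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova_F = an[1, "F value"], anova_p = an[1, "Pr(>F)"], tukey = tukey)
}
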