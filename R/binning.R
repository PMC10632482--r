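# Single-cell glycolytic/mitochondrial state binning.
#
# After oligomycin, cells that sustain high protein synthesis (high
# puromycin) are running on aerobic glycolysis; cells whose translation
# collapses are mitochondrial-dependent. Binning the oligomycin-condition
# puromycin distribution into quartiles therefore orders cells from
# mitochondrial-dependent (bin 1, lowest) to glycolytic (bin 4, highest).

#' Assign oligomycin-treated cells to metabolic quantile bins
#'
#' Bins the puromycin intensity of oligomycin-condition cells into four
#' quantiles. Boundaries are the 25/50/75 empirical percentiles (linear
#' interpolation) of the pooled distribution — pooled across the whole
#' cohort by default so that bin occupancy can be compared across samples —
#' or per sample for sensitivity analysis. Boundary ties go to the lower
#' bin (deterministic and order-independent).
#'
#' @param events an [EventTable-class]; only rows with `condition == "O"`
#'   are used (at least 8 such cells are required).
#' @param scope `"cohort"` (default, shared boundaries) or `"sample"`.
#' @return data.frame with columns `cell` (row index into the
#'   oligomycin-restricted table), `sample_id`, `puromycin`, `bin` (1-4)
#'   and `scope`; quantile boundaries attached as attribute `boundaries`.
#' @export
assignOligomycinQuantiles <- function(events, scope = c("cohort", "sample")) {
  scope <- match.arg(scope)
  df <- if (is(events, "EventTable")) events@events else events
  puro_ch <- if (is(events, "EventTable")) puromycinChannel(events)
             else "puromycin"
  df <- df[df$condition == "O", , drop = FALSE]
  if (nrow(df) < 8)
    stop("quantile binning needs >= 8 oligomycin-condition cells, got ",
         nrow(df))
  x <- df[[puro_ch]]

  bin_one <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    if (q[1] == q[3])
      warning("degenerate puromycin distribution: quantile boundaries ",
              "coincide; ties assigned to the lower bin")
    # ties at a boundary stay below it
    1L + (v > q[1]) + (v > q[2]) + (v > q[3])
  }

  if (scope == "cohort") {
    bins <- bin_one(x)
    bounds <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  } else {
    bins <- integer(nrow(df))
    for (s in unique(df$sample_id)) {
      sel <- df$sample_id == s
      if (sum(sel) < 8)
        stop("sample ", s, " has < 8 oligomycin cells for per-sample binning")
      bins[sel] <- bin_one(x[sel])
    }
    bounds <- NULL
  }
  out <- data.frame(cell = seq_len(nrow(df)), sample_id = df$sample_id,
                    puromycin = x, bin = bins, scope = scope)
  attr(out, "boundaries") <- bounds
  out
}

#' Bin occupancy per clinical group
#'
#' Proportion of each group's cells falling in each metabolic quantile bin.
#' Proportions within a group sum to 1.
#'
#' @param assignment output of [assignOligomycinQuantiles()].
#' @param groups named character vector mapping `sample_id` to a group
#'   label (e.g. HD / good / bad).
#' @return data.frame `group`, `bin`, `n`, `proportion`.
#' @export
binProportionsByGroup <- function(assignment, groups) {
  unmapped <- setdiff(unique(assignment$sample_id), names(groups))
  if (length(unmapped))
    stop("samples without a group mapping: ",
         paste(unmapped, collapse = ", "))
  g <- unname(groups[assignment$sample_id])
  tab <- table(group = g, bin = factor(assignment$bin, levels = 1:4))
  prop <- prop.table(tab, margin = 1)
  out <- as.data.frame(tab, responseName = "n")
  out$proportion <- as.data.frame(prop, responseName = "p")$p
  out$bin <- as.integer(as.character(out$bin))
  out$group <- as.character(out$group)
  out[order(out$group, out$bin), c("group", "bin", "n", "proportion")]
}

#' Per-bin marker comparison against a reference group
#'
#' Within each metabolic bin, compares each marker's intensity between every
#' group and a reference group (e.g. healthy donors) using the
#' normality-routed two-group test ([twoGroupTest()]), then Holm-adjusts
#' the p-values across all comparisons within a marker. Contrasts with
#' fewer than `min_cells` cells on either side, or with zero variance in
#' both groups, are flagged `not_computable` rather than dropped.
#'
#' @param events [EventTable-class] the assignment was derived from
#'   (oligomycin condition rows, same order as `assignment$cell`).
#' @param assignment output of [assignOligomycinQuantiles()].
#' @param markers character vector of marker channel names to test.
#' @param groups named vector mapping `sample_id` to group label.
#' @param reference_group group label to compare against.
#' @param min_cells minimum cells per side per contrast (default 2).
#' @param test routing for the two-group comparison: `"auto"`
#'   (Shapiro-routed, default) or `"t"` (Student's t throughout).
#' @return data.frame with one row per (bin, marker, group): group and
#'   reference medians, test used, raw and Holm-adjusted p, `flag`.
#' @export
perBinMarkerComparison <- function(events, assignment, markers, groups,
                                   reference_group, min_cells = 2,
                                   test = c("auto", "t")) {
  test <- match.arg(test)
  df <- if (is(events, "EventTable")) events@events else events
  df <- df[df$condition == "O", , drop = FALSE]
  if (nrow(df) != nrow(assignment))
    stop("assignment does not match the oligomycin rows of events")
  miss <- setdiff(markers, names(df))
  if (length(miss)) stop("markers absent: ", paste(miss, collapse = ", "))
  g <- unname(groups[assignment$sample_id])
  if (anyNA(g)) stop("samples without a group mapping present")
  if (!reference_group %in% g)
    stop("reference group '", reference_group, "' has no cells")

  rows <- list()
  for (mk in markers) {
    for (b in sort(unique(assignment$bin))) {
      in_bin <- assignment$bin == b
      ref_v <- df[[mk]][in_bin & g == reference_group]
      for (grp in setdiff(unique(g), reference_group)) {
        v <- df[[mk]][in_bin & g == grp]
        row <- data.frame(marker = mk, bin = b, group = grp,
                          reference = reference_group,
                          median_group = stats::median(v),
                          median_reference = stats::median(ref_v),
                          n_group = length(v), n_reference = length(ref_v),
                          test = NA_character_, p = NA_real_,
                          flag = NA_character_)
        if (length(v) < min_cells || length(ref_v) < min_cells) {
          row$flag <- "not_computable:insufficient_cells"
        } else if (stats::var(v) == 0 && stats::var(ref_v) == 0) {
          row$flag <- "not_computable:zero_variance"
        } else {
          tt <- if (test == "t")
            list(test = "t", p = stats::t.test(v, ref_v)$p.value)
          else twoGroupTest(v, ref_v)
          row$test <- tt$test
          row$p <- tt$p
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  # Holm across the comparisons within each marker
  out$p_holm <- NA_real_
  for (mk in unique(out$marker)) {
    sel <- out$marker == mk & !is.na(out$p)
    out$p_holm[sel] <- adjustPvalues(out$p[sel], method = "holm")
  }
  out
}
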