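# SCENITH percent-scale metabolic parameters.
#
# Per population and sample, the median anti-puromycin MFI under each
# inhibitor condition summarises protein synthesis:
#   C control, 2DG glycolysis block, O ATP-synthase block, Eto FAO block,
#   Tele glutaminase block, DGO full block (2DG + oligomycin).
# Dependencies are translation lost under an inhibitor relative to the full
# dynamic range C - DGO:
#   glucose dep       = 100 (C - 2DG)  / (C - DGO)
#   mitochondrial dep = 100 (C - O)    / (C - DGO)
#   FAO dep           = 100 (C - Eto)  / (C - DGO)
#   glutaminolysis dep= 100 (C - Tele) / (C - DGO)
#   glycolytic capacity = 100 - mitochondrial dep
#   FAAO capacity       = 100 - glucose dep
# Harringtonine (H) is a translation-arrest anchor: it appears in the
# condition list but in no formula; we only check H <= other conditions.

.scenith_required <- c("C", "2DG", "O", "DGO")

#' QC-validate an inhibitor panel summary
#'
#' Checks the per-condition median puromycin MFIs that feed the SCENITH
#' formulas. Hard-errors when the denominator `C - DGO` is non-positive (no
#' translation dynamic range); flags `low_dynamic_range` when
#' `(C - DGO)/C < min_dynamic_range`, and `missing_inhibitor` for absent
#' optional conditions (Eto, Tele).
#'
#' @param panel named numeric vector or one-row data.frame/list of median
#'   puromycin MFIs keyed by condition (`C`, `2DG`, `O`, `DGO` mandatory;
#'   `Eto`, `Tele`, `H` optional). All values must be >= 0.
#' @param min_dynamic_range minimum acceptable `(C - DGO)/C` fraction
#'   (default 0.2).
#' @return list with `pass` (logical) and `flags` (character vector).
#' @export
validatePanel <- function(panel, min_dynamic_range = 0.2) {
  p <- unlist(panel)
  miss <- setdiff(.scenith_required, names(p))
  if (length(miss))
    stop("mandatory SCENITH conditions absent: ", paste(miss, collapse = ", "))
  if (any(p < 0, na.rm = TRUE)) stop("puromycin MFIs must be >= 0")
  if (p[["C"]] <= p[["DGO"]])
    stop("no translation dynamic range: C (", p[["C"]],
         ") <= DGO (", p[["DGO"]], ")")
  flags <- character()
  if ((p[["C"]] - p[["DGO"]]) / p[["C"]] < min_dynamic_range)
    flags <- c(flags, "low_dynamic_range")
  for (opt in c("Eto", "Tele"))
    if (!opt %in% names(p) || is.na(p[[opt]]))
      flags <- c(flags, "missing_inhibitor")
  if ("H" %in% names(p) && !is.na(p[["H"]])) {
    others <- p[setdiff(intersect(names(p), SCENITH_CONDITIONS), "H")]
    if (any(p[["H"]] > others, na.rm = TRUE))
      warning("harringtonine MFI exceeds an inhibitor condition; ",
              "translation-arrest anchor failed")
  }
  list(pass = !"low_dynamic_range" %in% flags, flags = unique(flags))
}

#' Compute the SCENITH metabolic profile for one panel
#'
#' Applies the percent-scale dependence/capacity formulas to a panel of
#' per-condition median puromycin MFIs. Raw (unclamped) values are always
#' retained; with `clamp = TRUE` (default) dependencies are truncated to
#' \[0, 100\] with `clamped_low`/`clamped_high` flags and the capacities are
#' recomputed from the clamped dependencies, so the complement identities
#' `glucose + FAAO = 100` and `mitochondrial + glycolytic capacity = 100`
#' hold exactly on the reported values.
#'
#' @inheritParams validatePanel
#' @param clamp truncate reported dependencies to \[0, 100\] (default TRUE).
#' @return list with `profile` (named numeric, reported values), `raw`
#'   (named numeric, unclamped), and `qc_flags`.
#' @examples
#' computeScenithProfile(c(C = 1200, `2DG` = 400, O = 300, DGO = 200))
#' @export
computeScenithProfile <- function(panel, clamp = TRUE,
                                  min_dynamic_range = 0.2) {
  qc <- validatePanel(panel, min_dynamic_range)
  p <- unlist(panel)
  denom <- p[["C"]] - p[["DGO"]]
  dep <- function(cond)
    if (cond %in% names(p) && !is.na(p[[cond]]))
      100 * (p[["C"]] - p[[cond]]) / denom else NA_real_

  raw <- c(
    glucose_dependence       = dep("2DG"),
    mitochondrial_dependence = dep("O"),
    fao_dependence           = dep("Eto"),
    glutaminolysis_dependence = dep("Tele")
  )
  flags <- qc$flags
  rep_dep <- raw
  if (clamp) {
    if (any(raw < 0, na.rm = TRUE)) flags <- c(flags, "clamped_low")
    if (any(raw > 100, na.rm = TRUE)) flags <- c(flags, "clamped_high")
    rep_dep <- pmin(pmax(raw, 0), 100)
  }
  raw_full <- c(raw,
    glycolytic_capacity = 100 - raw[["mitochondrial_dependence"]],
    faao_capacity = 100 - raw[["glucose_dependence"]])
  profile <- c(rep_dep,
    glycolytic_capacity = 100 - rep_dep[["mitochondrial_dependence"]],
    faao_capacity = 100 - rep_dep[["glucose_dependence"]])
  list(profile = profile, raw = raw_full, qc_flags = unique(flags))
}

#' SCENITH profiles for a cohort of panels
#'
#' Computes one metabolic profile per (sample, population) key. Per-key
#' failures (e.g. zero dynamic range) are recorded and do not abort the
#' batch.
#'
#' @param panels data.frame in long format with columns `sample_id`,
#'   `population`, `condition`, `median_puromycin` (and optionally
#'   `n_cells`), as produced by [populationMedian()] or read from CSV.
#' @inheritParams computeScenithProfile
#' @return data.frame with one row per key: reported and `raw_*` parameter
#'   columns, `qc_flags` (semicolon-joined) and `error` (NA when computed).
#' @export
profileCohort <- function(panels, clamp = TRUE, min_dynamic_range = 0.2) {
  need <- c("sample_id", "population", "condition", "median_puromycin")
  miss <- setdiff(need, names(panels))
  if (length(miss)) stop("panels lack columns: ", paste(miss, collapse = ", "))
  if (!nrow(panels)) {
    warning("empty panel input; returning empty profile table")
    return(data.frame())
  }
  keys <- unique(panels[c("sample_id", "population")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- panels$sample_id == keys$sample_id[i] &
      panels$population == keys$population[i]
    sub <- panels[sel, ]
    vec <- stats::setNames(sub$median_puromycin, sub$condition)
    base <- data.frame(sample_id = keys$sample_id[i],
                       population = keys$population[i])
    res <- tryCatch(
      computeScenithProfile(vec, clamp = clamp,
                            min_dynamic_range = min_dynamic_range),
      error = function(e) e)
    if (inherits(res, "error")) {
      base$error <- conditionMessage(res)
      return(base)
    }
    prof <- as.data.frame(as.list(res$profile))
    names(prof) <- names(res$profile)
    rawv <- as.data.frame(as.list(res$raw))
    names(rawv) <- paste0("raw_", names(res$raw))
    out <- cbind(base, prof, rawv)
    out$qc_flags <- paste(res$qc_flags, collapse = ";")
    out$error <- NA_character_
    out
  })
  all_names <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  n_flagged <- sum(nzchar(out$qc_flags), na.rm = TRUE)
  if (n_flagged)
    message(n_flagged, " profile(s) carry QC flags")
  out
}

#' Summarise an EventTable into inhibitor-panel medians
#'
#' Convenience bridge from gated per-cell events to the long-format panel
#' table [profileCohort()] consumes: median puromycin MFI per
#' (sample, population, condition) with cell counts.
#'
#' @param events an [EventTable-class].
#' @param statistic summary statistic, `"median"` (default) or `"mean"`.
#' @return data.frame with columns `sample_id`, `population`, `condition`,
#'   `median_puromycin`, `n_cells`.
#' @export
summarisePanel <- function(events, statistic = "median") {
  med <- populationMedian(events, puromycinChannel(events),
                          statistic = statistic)
  names(med)[names(med) == "value"] <- "median_puromycin"
  med[c("sample_id", "population", "condition", "median_puromycin",
        "n_cells")]
}
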