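# Bioenergetic indices from mitochondrial/glycolysis stress-test traces.
#
# Segment labels follow the injection schedule: pre-Oligo (before the first
# injection), post-oligomycin, post-FCCP, post-rotenone/antimycinA. With
# agg() the configured per-segment aggregator:
#   basal respiration   = agg(OCR pre-Oligo)   - agg(OCR post-RA)
#   maximal O2 consumption = agg(OCR post-FCCP) - agg(OCR post-RA)
#   spare capacity      = maximal - basal  (== post-FCCP - pre-Oligo)
#   proton leak         = agg(OCR post-Oligo)  - agg(OCR post-RA)
#   ATP-linked respiration = basal - proton leak
#   exogenous FAO max   = control post-FCCP - palmitate/etomoxir post-FCCP
#   basal glycolysis    = agg(ECAR pre-Oligo)  - agg(ECAR post-RA)
#   glycolytic capacity = agg(ECAR post-Oligo) - agg(ECAR post-RA)

#' Default per-segment aggregators
#'
#' The pre-oligomycin segment is averaged; maximal respiration takes the
#' highest post-FCCP measurement; the suppressed OCR segments (post-oligo,
#' post-rotenone/antimycin A) take the minimum; ECAR rises after oligomycin
#' so its post-oligo aggregator is the maximum. All are configurable and
#' the configuration used is recorded on the output.
#'
#' @param ocr,ecar named lists overriding entries `pre_oligo`,
#'   `post_oligomycin`, `post_FCCP`, `post_RA` with one of
#'   `"mean"`, `"min"`, `"max"`, `"median"`.
#' @return nested list of aggregator names.
#' @export
seahorseAggregators <- function(ocr = list(), ecar = list()) {
  base_ocr <- list(pre_oligo = "mean", post_oligomycin = "min",
                   post_FCCP = "max", post_RA = "min")
  base_ecar <- list(pre_oligo = "mean", post_oligomycin = "max",
                    post_RA = "min")
  utils::modifyList(list(ocr = utils::modifyList(base_ocr, ocr),
                         ecar = utils::modifyList(base_ecar, ecar)),
                    list())
}

.seg_labels <- c(oligomycin = "post_oligomycin", FCCP = "post_FCCP",
                 "2DG" = "post_2DG", "rotenone/antimycinA" = "post_RA")

#' Partition a kinetic trace by injection
#'
#' Splits timepoints into pre-oligomycin and post-injection segments; every
#' measurement belongs to exactly one segment. Empty segments (two
#' injections with no measurement between them) are an error naming the
#' injection, as is an injection outside the trace span.
#'
#' @param trace a [SeahorseTrace-class].
#' @return named list of segments, each a list with `time`, `ocr`, `ecar`.
#' @export
segmentTrace <- function(trace) {
  stopifnot(is(trace, "SeahorseTrace"))
  inj <- trace@injections
  if (!nrow(inj)) stop("trace has no injections to segment by")
  if (max(inj$time) >= max(trace@time) || min(inj$time) <= min(trace@time))
    stop("injection at t=", inj$time[which.max(inj$time)],
         " lies outside the measured span")
  cuts <- c(-Inf, inj$time, Inf)
  idx <- findInterval(trace@time, cuts, left.open = FALSE)
  labels <- c("pre_oligo", unname(.seg_labels[inj$label]))
  segs <- list()
  for (i in seq_along(labels)) {
    sel <- idx == i
    if (!any(sel))
      stop("empty segment after injection '",
           c("(start)", inj$label)[i], "'")
    segs[[labels[i]]] <- list(time = trace@time[sel], ocr = trace@ocr[sel],
                              ecar = trace@ecar[sel])
  }
  segs
}

.agg_fun <- function(name) {
  switch(name,
         mean = mean, min = min, max = max, median = stats::median,
         stop("unknown aggregator: ", name))
}

#' Compute bioenergetic indices from a stress-test trace
#'
#' Derives the OCR indices (basal, maximal, spare, proton leak, ATP-linked)
#' and ECAR indices (basal glycolysis, glycolytic capacity) from the
#' segmented trace, and — when a paired palmitate + etomoxir trace is
#' supplied — the maximal respiration attributable to exogenous fatty
#' acids (control post-FCCP minus palmitate/etomoxir post-FCCP).
#' Negative indices are reported with a QC warning, never clipped.
#'
#' @param trace a [SeahorseTrace-class] (control or palmitate condition).
#' @param paired optional paired [SeahorseTrace-class] measured with
#'   palmitate + etomoxir, for the exogenous-FAO contrast. Pairing is
#'   explicit; wells are never paired implicitly by position.
#' @param aggregators per-segment aggregator config from
#'   [seahorseAggregators()].
#' @return one-row data.frame of indices (units follow the source rates);
#'   the aggregator config is attached as attribute `aggregators`.
#' @examples
#' tr <- SeahorseTrace("A1", time = 1:12,
#'                     ocr = rep(c(100, 30, 160, 10), each = 3),
#'                     ecar = rep(c(20, 35, 30, 5), each = 3),
#'                     injections = data.frame(
#'                       label = c("oligomycin", "FCCP",
#'                                 "rotenone/antimycinA"),
#'                       time = c(3.5, 6.5, 9.5)))
#' computeSeahorseIndices(tr)
#' @export
computeSeahorseIndices <- function(trace, paired = NULL,
                                   aggregators = seahorseAggregators()) {
  segs <- segmentTrace(trace)
  need <- c("pre_oligo", "post_oligomycin", "post_FCCP", "post_RA")
  miss <- setdiff(need, names(segs))
  if (length(miss))
    stop("required segment(s) missing: ", paste(miss, collapse = ", "))
  aocr <- function(seg) .agg_fun(aggregators$ocr[[seg]])(segs[[seg]]$ocr)
  aecar <- function(seg) .agg_fun(aggregators$ecar[[seg]])(segs[[seg]]$ecar)

  basal <- aocr("pre_oligo") - aocr("post_RA")
  maximal <- aocr("post_FCCP") - aocr("post_RA")
  leak <- aocr("post_oligomycin") - aocr("post_RA")
  idx <- data.frame(
    well = trace@well,
    basal_respiration = basal,
    maximal_oxygen_consumption = maximal,
    spare_respiratory_capacity = maximal - basal,
    proton_leak = leak,
    atp_linked_respiration = basal - leak,
    basal_glycolysis = aecar("pre_oligo") - aecar("post_RA"),
    glycolytic_capacity = aecar("post_oligomycin") - aecar("post_RA"),
    exogenous_fao_max = NA_real_
  )
  if (!is.null(paired)) {
    stopifnot(is(paired, "SeahorseTrace"))
    psegs <- segmentTrace(paired)
    if (!"post_FCCP" %in% names(psegs))
      stop("paired trace lacks a post-FCCP segment")
    idx$exogenous_fao_max <- aocr("post_FCCP") -
      .agg_fun(aggregators$ocr$post_FCCP)(psegs$post_FCCP$ocr)
  }
  num <- vapply(idx, is.numeric, logical(1))
  if (any(unlist(idx[num]) < 0, na.rm = TRUE))
    warning("negative bioenergetic index for well ", trace@well,
            "; reported unclipped for QC")
  attr(idx, "aggregators") <- aggregators
  idx
}

#' Average indices over replicate wells
#'
#' Triplicate (or any replicate) wells are averaged at the index level;
#' because every index is a linear difference of segment aggregates, the
#' mean of per-well indices equals the index of the mean trace when the
#' aggregators are linear.
#'
#' @param indices data.frame of per-well indices (rows from
#'   [computeSeahorseIndices()]).
#' @return one-row data.frame of index means (well column dropped).
#' @export
averageReplicateIndices <- function(indices) {
  num <- vapply(indices, is.numeric, logical(1))
  as.data.frame(lapply(indices[num], mean))
}

#' Scale per-sample index values
#'
#' Column-wise z-score (mean 0, SD 1) or min-max (\[0, 1\]) scaling across
#' samples, for heatmap-style comparison of bioenergetic profiles.
#' Zero-variance indices are flagged and returned unscaled.
#'
#' @param values data.frame/matrix, samples x indices, >= 2 rows.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return data.frame of scaled values; attribute `flagged` lists
#'   zero-variance columns.
#' @export
scaleIndices <- function(values, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  values <- as.data.frame(values)
  if (nrow(values) < 2) stop("scaling needs >= 2 samples")
  flagged <- character()
  out <- values
  for (nm in names(values)) {
    v <- values[[nm]]
    if (!is.numeric(v)) next
    rng <- range(v)
    if (rng[1] == rng[2]) {
      flagged <- c(flagged, nm)
      next
    }
    out[[nm]] <- if (method == "zscore") (v - mean(v)) / stats::sd(v)
                 else (v - rng[1]) / (rng[2] - rng[1])
  }
  if (length(flagged))
    warning("zero-variance index left unscaled: ",
            paste(flagged, collapse = ", "))
  attr(out, "flagged") <- flagged
  attr(out, "method") <- method
  if (method == "zscore")
    attr(out, "center_scale") <- lapply(values, function(v)
      if (is.numeric(v)) c(center = mean(v), scale = stats::sd(v)))
  else attr(out, "center_scale") <- lapply(values, function(v)
      if (is.numeric(v)) c(center = min(v), scale = diff(range(v))))
  out
}
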