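#' @import methods
NULL

#' Closed vocabulary of SCENITH inhibitor conditions
#'
#' Treatment conditions used in the SCENITH protein-synthesis assay:
#' `C` control (DMSO), `2DG` 2-deoxy-glucose, `O` oligomycin, `Eto` etomoxir,
#' `Tele` CB-839 (glutaminase inhibitor), `DGO` 2DG + oligomycin combined,
#' `H` harringtonine (translation-arrest anchor).
#'
#' @export
SCENITH_CONDITIONS <- c("C", "2DG", "O", "Eto", "Tele", "DGO", "H")

#' EventTable: per-cell cytometry events with assay annotations
#'
#' Holds one acquisition's worth of single-cell events. Each row is a cell;
#' annotation columns carry the sample, inhibitor condition, gated population
#' label and a per-cell viability flag, and the remaining columns are channel
#' intensities (arbitrary fluorescence/mass units).
#'
#' @slot events data.frame with columns `sample_id`, `condition`,
#'   `population`, `viability_pass` plus one numeric column per channel.
#' @slot channels character vector of channel column names.
#' @slot puromycinChannel name of the anti-puromycin channel (the per-cell
#'   protein-synthesis readout every SCENITH computation keys on).
#'
#' @export
setClass("EventTable",
  representation(
    events = "data.frame",
    channels = "character",
    puromycinChannel = "character"
  )
)

setValidity("EventTable", function(object) {
  ev <- object@events
  msgs <- character()
  need <- c("sample_id", "condition", "population", "viability_pass")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    msgs <- c(msgs, paste("missing annotation columns:",
                          paste(miss, collapse = ", ")))
  if (anyDuplicated(object@channels))
    msgs <- c(msgs, "duplicated channel names")
  if (length(object@puromycinChannel) != 1L)
    msgs <- c(msgs, "exactly one puromycin channel must be named")
  chmiss <- setdiff(object@channels, names(ev))
  if (length(chmiss))
    msgs <- c(msgs, paste("channels absent from event data:",
                          paste(chmiss, collapse = ", ")))
  if (!length(msgs) && !(object@puromycinChannel %in% object@channels))
    msgs <- c(msgs, sprintf("puromycin channel '%s' not among channels",
                            object@puromycinChannel))
  if (!length(msgs)) {
    puro <- ev[[object@puromycinChannel]]
    if (!is.numeric(puro) || any(!is.finite(puro)))
      msgs <- c(msgs, "puromycin intensities must all be finite")
    bad <- setdiff(unique(as.character(ev$condition)), SCENITH_CONDITIONS)
    if (length(bad))
      msgs <- c(msgs, paste("conditions outside the inhibitor vocabulary:",
                            paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EventTable
#'
#' @param events data.frame of per-cell rows. Must contain `sample_id`,
#'   `condition`, `population` and `viability_pass`; every other numeric
#'   column is treated as a channel unless `channels` is given.
#' @param puromycinChannel channel name holding anti-puromycin intensity.
#' @param channels optional explicit channel names; defaults to all
#'   non-annotation columns.
#' @return An [EventTable-class] object.
#' @examples
#' ev <- data.frame(sample_id = "s1", condition = "C", population = "mDC",
#'                  viability_pass = TRUE, Puro = c(100, 200, 300))
#' EventTable(ev, puromycinChannel = "Puro")
#' @export
EventTable <- function(events, puromycinChannel, channels = NULL) {
  annot <- c("sample_id", "condition", "population", "viability_pass")
  if (is.null(channels))
    channels <- setdiff(names(events), annot)
  events$condition <- as.character(events$condition)
  new("EventTable", events = as.data.frame(events), channels = channels,
      puromycinChannel = puromycinChannel)
}

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d cells, %d channels (puromycin: %s)\n",
              nrow(object@events), length(object@channels),
              object@puromycinChannel))
  cat(" conditions:", paste(sort(unique(object@events$condition)),
                            collapse = " "), "\n")
  cat(" populations:", paste(sort(unique(object@events$population)),
                             collapse = " "), "\n")
})

#' @describeIn EventTable number of cells (rows)
#' @param x,object an `EventTable`
#' @export
setMethod("nrow", "EventTable", function(x) nrow(x@events))

#' Accessors for EventTable
#'
#' `eventData()` returns the per-cell data.frame, `channelNames()` the channel
#' columns, `puromycinChannel()` the name of the protein-synthesis readout
#' channel.
#'
#' @param object an [EventTable-class]
#' @return data.frame, character vector, or single channel name.
#' @name eventData
#' @export
eventData <- function(object) object@events

#' @rdname eventData
#' @export
channelNames <- function(object) object@channels

#' @rdname eventData
#' @export
puromycinChannel <- function(object) object@puromycinChannel

#' GateSpec: rectangular threshold gates
#'
#' An ordered list of per-channel intervals; a cell passes the gate when it
#' lies inside every interval and its viability flag is TRUE. Mirrors
#' manual rectangle gating (e.g. CD14- HLA-DR+ CD86+ mature DC): thresholds
#' are explicit, no automated gating.
#'
#' @slot gates data.frame with columns `channel`, `lower`, `upper`
#'   (`-Inf`/`Inf` allowed, `lower < upper`).
#' @export
setClass("GateSpec", representation(gates = "data.frame"))

setValidity("GateSpec", function(object) {
  g <- object@gates
  if (!all(c("channel", "lower", "upper") %in% names(g)))
    return("gates need columns channel, lower, upper")
  if (nrow(g) && any(!(g$lower < g$upper)))
    return("each gate needs lower < upper")
  if (nrow(g) && any(is.na(g$lower) | is.na(g$upper)))
    return("gate bounds must be numbers or +/-Inf, not NA")
  TRUE
})

#' Construct a GateSpec
#'
#' @param channel character vector of channel names, one per rectangle.
#' @param lower,upper numeric bounds (use `-Inf`/`Inf` for open sides).
#' @return A [GateSpec-class].
#' @examples
#' GateSpec(channel = c("CD14", "HLA-DR"), lower = c(-Inf, 500),
#'          upper = c(300, Inf))
#' @export
GateSpec <- function(channel = character(), lower = numeric(),
                     upper = numeric()) {
  new("GateSpec", gates = data.frame(channel = as.character(channel),
                                     lower = as.numeric(lower),
                                     upper = as.numeric(upper)))
}

setMethod("show", "GateSpec", function(object) {
  cat(sprintf("GateSpec with %d rectangle(s)\n", nrow(object@gates)))
  if (nrow(object@gates)) print(object@gates)
})

#' SeahorseTrace: kinetic extracellular-flux measurements for one well
#'
#' Oxygen consumption (OCR, pmol O2/min) and extracellular acidification
#' (ECAR, mpH/min) measured at increasing times, with the ordered injection
#' schedule of the mitochondrial stress test (oligomycin, FCCP, 2DG,
#' rotenone/antimycin A).
#'
#' @slot well well identifier.
#' @slot condition one of `control`, `palmitate`, `palmitate+etomoxir`,
#'   `BSA-control`.
#' @slot time numeric minutes, strictly increasing.
#' @slot ocr,ecar numeric rates, one per timepoint, finite.
#' @slot injections data.frame with columns `label`, `time`; times strictly
#'   increasing and inside the trace span.
#' @export
setClass("SeahorseTrace",
  representation(
    well = "character",
    condition = "character",
    time = "numeric",
    ocr = "numeric",
    ecar = "numeric",
    injections = "data.frame"
  )
)

SEAHORSE_INJECTIONS <- c("oligomycin", "FCCP", "2DG", "rotenone/antimycinA")
SEAHORSE_CONDITIONS <- c("control", "palmitate", "palmitate+etomoxir",
                         "BSA-control")

setValidity("SeahorseTrace", function(object) {
  msgs <- character()
  n <- length(object@time)
  if (length(object@ocr) != n || length(object@ecar) != n)
    msgs <- c(msgs, "time, ocr and ecar must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    msgs <- c(msgs, "timepoints must be strictly increasing")
  if (any(!is.finite(object@ocr)) || any(!is.finite(object@ecar)))
    msgs <- c(msgs, "OCR/ECAR must be finite")
  if (!(object@condition %in% SEAHORSE_CONDITIONS))
    msgs <- c(msgs, sprintf("unknown condition '%s'", object@condition))
  inj <- object@injections
  if (!all(c("label", "time") %in% names(inj))) {
    msgs <- c(msgs, "injections need columns label, time")
  } else if (nrow(inj)) {
    if (any(diff(inj$time) <= 0))
      msgs <- c(msgs, "injection times must be strictly increasing")
    bad <- setdiff(inj$label, SEAHORSE_INJECTIONS)
    if (length(bad))
      msgs <- c(msgs, paste("unknown injection labels:",
                            paste(bad, collapse = ", ")))
    if (n && (min(inj$time) <= min(object@time) ||
              max(inj$time) >= max(object@time)))
      msgs <- c(msgs, "injections must fall strictly inside the trace span")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SeahorseTrace
#'
#' @param well well identifier.
#' @param time minutes, strictly increasing.
#' @param ocr,ecar rates per timepoint.
#' @param injections data.frame (`label`, `time`) with labels among
#'   oligomycin, FCCP, 2DG, rotenone/antimycinA.
#' @param condition assay condition (default `"control"`).
#' @return A [SeahorseTrace-class].
#' @export
SeahorseTrace <- function(well, time, ocr, ecar, injections,
                          condition = "control") {
  new("SeahorseTrace", well = as.character(well), condition = condition,
      time = as.numeric(time), ocr = as.numeric(ocr),
      ecar = as.numeric(ecar), injections = as.data.frame(injections))
}

setMethod("show", "SeahorseTrace", function(object) {
  cat(sprintf("SeahorseTrace well %s (%s): %d timepoints, injections: %s\n",
              object@well, object@condition, length(object@time),
              paste(object@injections$label, collapse = " -> ")))
})
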