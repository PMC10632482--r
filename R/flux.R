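# Supernatant glucose/lactate flux and ELISPOT response calls.

#' Interval glucose consumption and lactate production
#'
#' Computes per-interval fluxes from a supernatant concentration series.
#' For each interval between consecutive observation days, consumption is
#' the start concentration minus the end concentration; when a media change
#' opens the interval the start is reset to the fresh-media concentration
#' (culture media are typically replaced mid-differentiation, e.g. at day
#' 3, which makes the measured glucose rise without any cellular
#' production). Lactate production is the same computation with the sign
#' reversed. Totals are sums over intervals.
#'
#' @param series data.frame with columns `day` (strictly increasing),
#'   `glucose`, `lactate` (mM, >= 0).
#' @param media_changes optional data.frame with columns `day`,
#'   `fresh_glucose` and (optionally) `fresh_lactate` (defaults 0 mM).
#'   A change on day d resets the start concentrations of the interval
#'   beginning at (or spanning) d.
#' @return list with `intervals` (data.frame: `day_start`, `day_end`,
#'   `glucose_consumed`, `lactate_produced`, `media_change`) and totals
#'   `total_glucose_consumed`, `total_lactate_produced` (mM).
#' @examples
#' s <- data.frame(day = c(0, 3, 5), glucose = c(11, 7, 8),
#'                 lactate = c(0, 6, 4))
#' mc <- data.frame(day = 3, fresh_glucose = 11, fresh_lactate = 0)
#' intervalFluxes(s, mc)
#' @export
intervalFluxes <- function(series, media_changes = NULL) {
  stopifnot(all(c("day", "glucose", "lactate") %in% names(series)))
  if (is.unsorted(series$day, strictly = TRUE))
    stop("observation days must be strictly increasing")
  if (any(series$glucose < 0 | series$lactate < 0))
    stop("concentrations must be >= 0")
  if (!is.null(media_changes)) {
    if (!"day" %in% names(media_changes))
      stop("media_changes needs a 'day' column")
    if (!"fresh_glucose" %in% names(media_changes) ||
        anyNA(media_changes$fresh_glucose))
      stop("media change without specified fresh_glucose")
    if (!"fresh_lactate" %in% names(media_changes))
      media_changes$fresh_lactate <- 0
  }
  n <- nrow(series)
  if (n < 2) stop("need at least two observations")
  rows <- lapply(seq_len(n - 1), function(i) {
    d0 <- series$day[i]; d1 <- series$day[i + 1]
    g0 <- series$glucose[i]; l0 <- series$lactate[i]
    changed <- FALSE
    if (!is.null(media_changes)) {
      hit <- media_changes$day >= d0 & media_changes$day < d1
      if (any(hit)) {
        mc <- media_changes[which(hit)[sum(hit)], ]  # last change applies
        g0 <- mc$fresh_glucose
        l0 <- mc$fresh_lactate
        changed <- TRUE
      }
    }
    data.frame(day_start = d0, day_end = d1,
               glucose_consumed = g0 - series$glucose[i + 1],
               lactate_produced = series$lactate[i + 1] - l0,
               media_change = changed)
  })
  intervals <- do.call(rbind, rows)
  list(intervals = intervals,
       total_glucose_consumed = sum(intervals$glucose_consumed),
       total_lactate_produced = sum(intervals$lactate_produced))
}

#' Fraction of consumed glucose converted to lactate
#'
#' Under the glycolytic yield of 2 lactate per glucose, the conversion
#' fraction is `lactate_produced / (2 * glucose_consumed)`. Values above 1
#' are returned with a QC flag (exogenous lactate source or measurement
#' error). The raw ratio `lactate/glucose` is also reported since either
#' convention appears in practice.
#'
#' @param glucose_consumed mM, must be > 0 for the fraction to be defined.
#' @param lactate_produced mM.
#' @return list with `fraction_stoich`, `ratio_raw`, `computable`, `flag`.
#' @examples
#' glucoseToLactateFraction(2, 4)  # full conversion: 1.0
#' @export
glucoseToLactateFraction <- function(glucose_consumed, lactate_produced) {
  if (!is.finite(glucose_consumed) || glucose_consumed <= 0)
    return(list(fraction_stoich = NA_real_, ratio_raw = NA_real_,
                computable = FALSE, flag = "non_positive_consumption"))
  frac <- lactate_produced / (2 * glucose_consumed)
  list(fraction_stoich = frac,
       ratio_raw = lactate_produced / glucose_consumed,
       computable = TRUE,
       flag = if (frac > 1) "stoichiometry_exceeded" else NA_character_)
}

#' ELISPOT positive-response call
#'
#' Antigen-specific IFN-gamma responses: the empty-vector (AdVLacZ)
#' background is subtracted from the antigen response at each timepoint and
#' truncated at zero; the post-vaccine response is called positive when the
#' net count exceeds `min_spots` per well AND is at least `min_fold` times
#' the baseline net count (baseline floored at 1 net spot so a zero
#' baseline cannot make the fold criterion vacuous).
#'
#' @param baseline,post lists/one-row data.frames with fields
#'   `spots_antigen`, `spots_AdVLacZ`, and matching `patient`, `antigen`,
#'   `compartment` (matching is checked when the fields are present).
#' @param min_spots spot floor per well (default 10, strict inequality).
#' @param min_fold minimum fold increase over baseline (default 2).
#' @return list with `call` ("positive"/"negative"), `net_baseline`,
#'   `net_post`.
#' @examples
#' elispotCall(list(spots_antigen = 10, spots_AdVLacZ = 2),
#'             list(spots_antigen = 35, spots_AdVLacZ = 5))
#' @export
elispotCall <- function(baseline, post, min_spots = 10, min_fold = 2) {
  for (key in c("patient", "antigen", "compartment")) {
    b <- baseline[[key]]; p <- post[[key]]
    if (!is.null(b) && !is.null(p) && !identical(as.character(b),
                                                 as.character(p)))
      stop("mismatched records: baseline ", key, " '", b,
           "' vs post '", p, "'")
  }
  net <- function(r) {
    s <- r[["spots_antigen"]]; z <- r[["spots_AdVLacZ"]]
    if (s < 0 || z < 0) stop("spot counts must be >= 0")
    max(s - z, 0)
  }
  nb <- net(baseline); np <- net(post)
  positive <- (np > min_spots) && (np >= min_fold * max(nb, 1))
  list(call = if (positive) "positive" else "negative",
       net_baseline = nb, net_post = np)
}

#' Convert meter readings from mg/dL to mM
#'
#' Clinical glucose/lactate meters report mg/dL; internal units are mM.
#' Molar masses: glucose 180.16 g/mol, lactate 90.08 g/mol, so
#' mM = mg/dL * 10 / molar mass.
#'
#' @param mgdl numeric vector in mg/dL.
#' @param analyte `"glucose"` or `"lactate"`.
#' @return numeric vector in mM.
#' @export
mgdlToMm <- function(mgdl, analyte = c("glucose", "lactate")) {
  analyte <- match.arg(analyte)
  mgdl * 10 / switch(analyte, glucose = 180.16, lactate = 90.08)
}
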