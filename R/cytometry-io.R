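#' Read single-cell events into an EventTable
#'
#' Ingests one acquisition from either an FCS 3.0/3.1 file or a tabular CSV
#' (one row per cell, header row, UTF-8, comma-separated). Panel names are
#' mapped to file channel names through `channel_map` so that panel renames
#' do not break analysis configs; unknown channels are preserved verbatim.
#'
#' @param path input file.
#' @param format `"fcs"` or `"tabular"`.
#' @param channel_map named character vector/list mapping panel names (e.g.
#'   `"puromycin"`) to channel names in the file. Must cover `"puromycin"`.
#' @param sample_id sample identifier to stamp on every cell; defaults to the
#'   file name. Tabular files may instead carry their own `sample_id` column.
#' @param condition inhibitor condition for the acquisition (one of
#'   `r paste(SCENITH_CONDITIONS, collapse = ", ")`); tabular files may carry
#'   a `condition` column.
#' @param population population label (default `"ungated"`); tabular files
#'   may carry a `population` column.
#' @return An [EventTable-class] whose row count equals the event count in
#'   the file, with the puromycin channel resolved through `channel_map`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(Puro = c(1, 2, 3), CD86 = c(9, 8, 7)), f,
#'           row.names = FALSE)
#' ev <- readEvents(f, format = "tabular",
#'                  channel_map = c(puromycin = "Puro"),
#'                  sample_id = "s1", condition = "C")
#' nrow(ev)
#' @export
readEvents <- function(path, format = c("tabular", "fcs"), channel_map,
                       sample_id = basename(path), condition = "C",
                       population = "ungated") {
  format <- match.arg(format)
  channel_map <- unlist(channel_map)
  if (!"puromycin" %in% names(channel_map))
    stop("channel_map must map the 'puromycin' panel name to a channel")
  if (!file.exists(path)) stop("input file not found: ", path)

  if (format == "fcs") {
    fcs <- readFCS(path)
    df <- as.data.frame(fcs$data)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
  }

  puro_ch <- unname(channel_map[["puromycin"]])
  if (!puro_ch %in% names(df))
    stop("puromycin channel '", puro_ch, "' not present in ", path)

  annot <- c("sample_id", "condition", "population", "viability_pass")
  if (!"sample_id" %in% names(df)) df$sample_id <- sample_id
  if (!"condition" %in% names(df)) df$condition <- condition
  if (!"population" %in% names(df)) df$population <- population
  if (!"viability_pass" %in% names(df)) df$viability_pass <- TRUE
  channels <- setdiff(names(df), annot)
  EventTable(df[, c(annot, channels)], puromycinChannel = puro_ch,
             channels = channels)
}

#' Arcsinh-transform intensities
#'
#' Standard variance-stabilizing transform for mass/spectral cytometry:
#' elementwise `asinh(x / cofactor)`. Strictly monotone and invertible for
#' any positive cofactor; the conventional cofactor for mass cytometry is 5.
#'
#' @param values numeric vector of intensities.
#' @param cofactor positive scale divisor (default 5).
#' @param inverse if TRUE, apply the inverse (`sinh(x) * cofactor`).
#' @return transformed numeric vector.
#' @examples
#' arcsinhTransform(5)        # asinh(1) = 0.8814
#' arcsinhTransform(arcsinhTransform(5), inverse = TRUE)
#' @export
arcsinhTransform <- function(values, cofactor = 5, inverse = FALSE) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("cofactor must be a single positive number")
  if (inverse) sinh(values) * cofactor else asinh(values / cofactor)
}

#' Apply rectangular gates to an EventTable
#'
#' Keeps cells lying inside every gate rectangle (closed intervals) whose
#' viability flag is TRUE. Gating is idempotent and never increases the
#' event count; an empty gate list keeps all viable cells.
#'
#' @param events an [EventTable-class].
#' @param spec a [GateSpec-class]; every gated channel must exist.
#' @return gated [EventTable-class].
#' @export
applyGates <- function(events, spec) {
  stopifnot(is(events, "EventTable"), is(spec, "GateSpec"))
  df <- events@events
  keep <- as.logical(df$viability_pass)
  g <- spec@gates
  if (nrow(g)) {
    missing_ch <- setdiff(g$channel, events@channels)
    if (length(missing_ch))
      stop("gate references absent channel(s): ",
           paste(missing_ch, collapse = ", "))
    for (i in seq_len(nrow(g))) {
      v <- df[[g$channel[i]]]
      keep <- keep & v >= g$lower[i] & v <= g$upper[i]
    }
  }
  out <- events
  out@events <- df[keep, , drop = FALSE]
  rownames(out@events) <- NULL
  out
}

#' Per-population summary intensity
#'
#' Median (the default summary; mean available) of one channel per group,
#' the per-population "median MFI" used throughout downstream analysis.
#' Empty groups are reported as missing (`NA`), never as zero.
#'
#' @param events an [EventTable-class] or plain data.frame.
#' @param channel channel name to summarise.
#' @param group_by character vector of grouping columns
#'   (default `c("sample_id", "population", "condition")`).
#' @param statistic `"median"` (default) or `"mean"`.
#' @return data.frame with the grouping keys, `value` and `n_cells`.
#' @export
populationMedian <- function(events, channel,
                             group_by = c("sample_id", "population",
                                          "condition"),
                             statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  df <- if (is(events, "EventTable")) events@events else events
  if (!channel %in% names(df)) stop("channel not found: ", channel)
  miss <- setdiff(group_by, names(df))
  if (length(miss)) stop("grouping columns absent: ",
                         paste(miss, collapse = ", "))
  fun <- if (statistic == "median") stats::median else mean
  key <- interaction(df[group_by], drop = TRUE, lex.order = TRUE)
  split_vals <- split(df[[channel]], key)
  split_keys <- split(df[group_by], key)
  out <- do.call(rbind, lapply(names(split_vals), function(k) {
    v <- split_vals[[k]]
    row <- split_keys[[k]][1, , drop = FALSE]
    row$value <- if (length(v)) fun(v) else NA_real_
    row$n_cells <- length(v)
    row
  }))
  rownames(out) <- NULL
  out
}
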