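# Minimal FCS 3.0/3.1 reader and fixture writer.
#
# Supports list-mode ($MODE/L) float ($DATATYPE/F) and double ($DATATYPE/D)
# data in little- or big-endian byte order, which covers files exported by
# modern spectral/mass cytometry unmixing software as well as the fixtures
# written by writeFCS(). Integer data, analysis segments and multi-dataset
# files are out of scope.

#' Read an FCS 3.0/3.1 file
#'
#' Parses the TEXT segment keywords and the list-mode DATA segment and
#' returns the event matrix with channels as named columns.
#'
#' @param path path to an FCS file.
#' @return list with `data` (numeric matrix, events x channels) and
#'   `keywords` (named character vector of TEXT keywords).
#' @seealso [writeFCS()] for the fixture writer, [readEvents()] for the
#'   annotated [EventTable-class] entry point.
#' @export
readFCS <- function(path) {
  if (!file.exists(path)) stop("FCS file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (nchar(header, type = "bytes") < 58)
    stop("malformed FCS header: file shorter than 58 bytes (offset 0)")
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("malformed FCS header at byte offset 0: expected FCS3.0/FCS3.1, ",
         "found '", version, "'")
  offs <- suppressWarnings(as.numeric(c(
    substr(header, 11, 18), substr(header, 19, 26),
    substr(header, 27, 34), substr(header, 35, 42))))
  if (any(is.na(offs[1:2])))
    stop("malformed FCS header at byte offset 10: unreadable TEXT offsets")
  text_start <- offs[1]; text_end <- offs[2]
  seek(con, text_start)
  raw_text <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(raw_text, 1, 1)
  parts <- strsplit(substring(raw_text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- parts[seq(2, length(parts), by = 2)]
  names(kw) <- parts[seq(1, length(parts), by = 2)]

  need <- function(key) {
    v <- kw[[key]]
    if (is.null(v) || !nzchar(v)) stop("FCS TEXT segment lacks ", key)
    v
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("F", "D"))
    stop("unsupported $DATATYPE '", dtype, "' (only F and D)")
  if (toupper(need("$MODE")) != "L")
    stop("unsupported $MODE (only list mode L)")
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"

  data_start <- offs[3]; data_end <- offs[4]
  if (is.na(data_start) || data_start == 0)
    data_start <- as.numeric(need("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0)
    data_end <- as.numeric(need("$ENDDATA"))
  size <- if (dtype == "F") 4L else 8L
  expected <- npar * ntot
  avail <- (data_end - data_start + 1) %/% size
  if (avail < expected)
    stop("malformed FCS DATA segment at byte offset ", data_start,
         ": holds ", avail, " values, need ", expected)
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = expected, size = size, endian = endian)
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE)
  ch <- vapply(seq_len(npar), function(i) {
    v <- kw[[sprintf("$P%dN", i)]]
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1))
  colnames(mat) <- ch
  list(data = mat, keywords = kw)
}

#' Write a minimal FCS 3.0 file
#'
#' Writes list-mode single-precision float data with the mandatory keywords.
#' Intended for generating synthetic fixtures and for round-trip testing of
#' [readFCS()]; not a general-purpose exporter.
#'
#' @param data numeric matrix (events x channels) with column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFCS <- function(data, path) {
  data <- as.matrix(data)
  if (is.null(colnames(data))) stop("data must have channel column names")
  npar <- ncol(data); ntot <- nrow(data)
  delim <- "/"
  size <- 4L
  nbytes <- npar * ntot * size

  build_text <- function(begin_data, end_data) {
    kv <- c(
      "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
      "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
      "$BEGINDATA" = as.character(begin_data),
      "$ENDDATA" = as.character(end_data),
      "$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
      "$NEXTDATA" = "0",
      "$PAR" = as.character(npar), "$TOT" = as.character(ntot))
    for (i in seq_len(npar)) {
      kv[sprintf("$P%dN", i)] <- colnames(data)[i]
      kv[sprintf("$P%dB", i)] <- "32"
      kv[sprintf("$P%dE", i)] <- "0,0"
      kv[sprintf("$P%dR", i)] <- format(max(1, ceiling(max(data[, i], 0))),
                                        scientific = FALSE)
    }
    paste0(delim, paste0(names(kv), delim, kv, delim, collapse = ""))
  }

  # TEXT length depends on the data offsets it quotes; iterate to fixpoint
  text_start <- 58
  text <- build_text(0, 0)
  for (iter in 1:5) {
    data_start <- text_start + nchar(text, type = "bytes")
    data_end <- data_start + nbytes - 1
    text2 <- build_text(data_start, data_end)
    if (nchar(text2, type = "bytes") == nchar(text, type = "bytes")) {
      text <- text2
      break
    }
    text <- text2
  }
  data_start <- text_start + nchar(text, type = "bytes")
  data_end <- data_start + nbytes - 1
  text_end <- data_start - 1

  pad8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.0    ", pad8(text_start), pad8(text_end),
                   pad8(data_start), pad8(data_end), pad8(0), pad8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.numeric(t(data)), con, size = size, endian = "little")
  invisible(path)
}
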