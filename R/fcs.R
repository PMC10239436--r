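# Minimal FCS 3.0/3.1 list-mode reader.
#
# Supports the subset of the standard produced by bench cytometers in list
# mode: $MODE L, $DATATYPE F (32-bit float), D (64-bit float) or I
# (16/32-bit unsigned integers of uniform width), $BYTEORD 1,2,3,4 or
# 4,3,2,1. Analysis segments, escaped delimiters inside keyword values and
# multi-dataset files are out of scope.

.fcsReadHeader <- function(con, path) {
  hdr <- readChar(con, 58L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 58L)
    stop("malformed FCS file (header): '", path, "' is truncated", call. = FALSE)
  version <- substr(hdr, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("malformed FCS file (header): unsupported version '", version, "'",
         call. = FALSE)
  off <- function(a, b) suppressWarnings(as.integer(trimws(substr(hdr, a, b))))
  offsets <- c(textBegin = off(11, 18), textEnd = off(19, 26),
               dataBegin = off(27, 34), dataEnd = off(35, 42))
  if (any(is.na(offsets[c("textBegin", "textEnd")])))
    stop("malformed FCS file (header): non-numeric TEXT segment offsets",
         call. = FALSE)
  list(version = version, offsets = offsets)
}

.fcsReadText <- function(con, offsets, path) {
  seek(con, offsets["textBegin"])
  nTxt <- offsets["textEnd"] - offsets["textBegin"] + 1L
  txt <- readChar(con, nTxt, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2L)
    stop("malformed FCS file (TEXT): no keyword/value pairs", call. = FALSE)
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- parts[seq(1, length(parts), 2)]
  val <- trimws(parts[seq(2, length(parts), 2)])
  stats::setNames(val, trimws(kw))
}

.fcsKeyword <- function(keywords, name, path) {
  v <- keywords[[name]]
  if (is.null(v) || is.na(v))
    stop("malformed FCS file (TEXT): required keyword ", name, " missing",
         call. = FALSE)
  v
}

#' Read an FCS 3.0/3.1 file into a matrix
#'
#' Internal workhorse behind [readEventTable()] for `format = "fcs"`.
#' Returns the raw event matrix with `$PnN` channel names.
#'
#' @param path path to the FCS file.
#' @return numeric matrix (events x channels), channel names from `$PnN`.
#' @keywords internal
.readFCS <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .fcsReadHeader(con, path)
  keywords <- .fcsReadText(con, hdr$offsets, path)

  if (toupper(.fcsKeyword(keywords, "$MODE", path)) != "L")
    stop("malformed FCS file (TEXT): only list mode ($MODE L) is supported",
         call. = FALSE)
  nPar <- as.integer(.fcsKeyword(keywords, "$PAR", path))
  nTot <- as.integer(.fcsKeyword(keywords, "$TOT", path))
  dtype <- toupper(.fcsKeyword(keywords, "$DATATYPE", path))
  byteord <- .fcsKeyword(keywords, "$BYTEORD", path)
  endian <- if (grepl("^1", byteord)) "little" else "big"

  dataBegin <- hdr$offsets["dataBegin"]
  dataEnd <- hdr$offsets["dataEnd"]
  if (is.na(dataBegin) || dataBegin == 0L) {  # FCS3.1 large-file convention
    dataBegin <- as.integer(.fcsKeyword(keywords, "$BEGINDATA", path))
    dataEnd <- as.integer(.fcsKeyword(keywords, "$ENDDATA", path))
  }

  bits <- as.integer(keywords[paste0("$P", seq_len(nPar), "B")])
  chn <- as.character(keywords[paste0("$P", seq_len(nPar), "N")])
  if (any(is.na(chn)))
    stop("malformed FCS file (TEXT): missing $PnN channel names", call. = FALSE)

  seek(con, dataBegin)
  nVals <- nPar * nTot
  values <- switch(dtype,
    F = readBin(con, "numeric", n = nVals, size = 4L, endian = endian),
    D = readBin(con, "numeric", n = nVals, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1L || !unique(bits) %in% c(16L, 32L))
        stop("malformed FCS file (DATA): only uniform 16- or 32-bit integer data supported",
             call. = FALSE)
      sz <- unique(bits) / 8L
      if (sz == 2L)
        as.numeric(readBin(con, "integer", n = nVals, size = 2L,
                           signed = FALSE, endian = endian))
      else
        as.numeric(readBin(con, "integer", n = nVals, size = 4L, endian = endian))
    },
    stop("malformed FCS file (DATA): unsupported $DATATYPE '", dtype, "'",
         call. = FALSE))
  if (length(values) < nVals)
    stop("malformed FCS file (DATA): expected ", nVals, " values, read ",
         length(values), call. = FALSE)
  matrix(values, nrow = nTot, ncol = nPar, byrow = TRUE,
         dimnames = list(NULL, chn))
}
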