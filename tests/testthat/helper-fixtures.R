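# fixtures are built in code at test time; nothing binary lives in the repo

# small deterministic event table with scatter + one fluorescence channel
makeEventTable <- function(n = 200, seed = 1, channel = "mCherry-A") {
  withr::with_seed(seed, {
    fsc <- 10^rnorm(n, 5, 0.08)
    m <- cbind(`FSC-A` = fsc,
               `SSC-A` = 10^rnorm(n, 4.3, 0.1),
               `FSC-H` = 0.9 * fsc,
               10^rnorm(n, 2.5, 0.3))
    colnames(m)[4] <- channel
    EventTable(m, sampleId = sprintf("fix%d", seed))
  })
}

# minimal FCS 3.0 writer (float32 little-endian list mode) used to exercise
# the reader; written fresh into tempdir at test time
writeFcsFixture <- function(path, mat) {
  nPar <- ncol(mat); nTot <- nrow(mat)
  d <- "/"
  kw <- c("$MODE", "L", "$DATATYPE", "F", "$BYTEORD", "1,2,3,4",
          "$PAR", nPar, "$TOT", nTot)
  for (i in seq_len(nPar))
    kw <- c(kw, sprintf("$P%dN", i), colnames(mat)[i],
            sprintf("$P%dB", i), 32, sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), 262144)
  text <- paste0(d, paste(kw, collapse = d), d)
  textBegin <- 58L
  textEnd <- textBegin + nchar(text) - 1L
  dataBegin <- textEnd + 1L
  dataEnd <- dataBegin + 4L * nPar * nTot - 1L
  hdr <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d", textBegin, textEnd,
                 dataBegin, dataEnd, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

# independent KDE oracle: explicit Gaussian kernel sum evaluated on a grid
bruteForceModeCount <- function(values, h, bounds = NULL, gridSize = 512) {
  x <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = gridSize)
  y <- vapply(x, function(g) mean(dnorm((g - values) / h)) / h, numeric(1))
  k <- length(y)
  isMax <- c(FALSE, y[2:(k - 1)] > y[1:(k - 2)] & y[2:(k - 1)] > y[3:k], FALSE)
  if (!is.null(bounds)) isMax <- isMax & x >= bounds[1] & x <= bounds[2]
  sum(isMax)
}
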