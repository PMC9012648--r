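#' @include AllClasses.R simulate.R
NULL

# fixed-width ASCII field helpers (EDF headers are plain ASCII)
.edfField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

.edfNum <- function(x, width = 8) {
  for (digits in 7:1) {
    s <- formatC(x, width = 1, format = "g", digits = digits)
    if (nchar(s) <= width) return(.edfField(s, width))
  }
  stop("cannot format ", x, " into ", width, " ASCII characters")
}

#' Write a recording as EDF+
#'
#' Minimal EDF+C writer: one 16-bit signal per channel in physical
#' microvolts plus an annotations signal holding every stimulus onset as a
#' `stim` annotation. Physical scaling is per channel (symmetric around
#' zero). The reference descriptor travels in the recording-identification
#' field and the exact sample count in the reserved header field, so
#' [readEdf()] round-trips both. Header dates are fixed so identical
#' recordings produce byte-identical files.
#'
#' @param recording a [Recording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdf <- function(recording, path) {
  data <- recording@data
  fs <- recording@fsHz
  nch <- nrow(data)
  n <- ncol(data)
  # per-record samples: integer per record, record size under 61440 bytes
  cand <- c(1, 0.5, 0.2, 0.1, 0.05, 0.025, 0.01, 0.005, 0.002, 0.001)
  dr <- NA
  for (d in cand) {
    ns <- fs * d
    if (abs(ns - round(ns)) < 1e-9 && (round(ns) * nch + 64) * 2 <= 61440) {
      dr <- d; break
    }
  }
  if (is.na(dr)) stop("cannot tile fs = ", fs, " into EDF records")
  ns <- round(fs * dr)
  nRec <- ceiling(n / ns)
  nAnn <- 64L                          # annotation int16 samples per record

  # physical scaling: symmetric, consistent with the printed header value
  physMax <- pmax(apply(abs(data), 1, max), 1e-6)
  physMaxStr <- vapply(physMax, function(v) .edfNum(v), "")
  physMax <- as.numeric(physMaxStr)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  nsig <- nch + 1L
  wr(.edfField("0", 8))
  wr(.edfField("X X X X", 80))
  wr(.edfField(paste0("Startdate 01-JAN-2000 X X X ref:",
                      recording@reference), 80))
  wr(.edfField("01.01.00", 8)); wr(.edfField("00.00.00", 8))
  wr(.edfField(256 * (nsig + 1), 8))
  wr(.edfField(paste0("EDF+C n=", n), 44))
  wr(.edfField(nRec, 8))
  wr(.edfNum(dr, 8))
  wr(.edfField(nsig, 4))
  labels <- c(recording@channelNames, "EDF Annotations")
  for (l in labels) wr(.edfField(l, 16))
  for (i in seq_len(nsig)) wr(.edfField("", 80))              # transducer
  wr(paste(vapply(c(rep("uV", nch), ""), .edfField, "", width = 8),
           collapse = ""))
  for (v in c(-physMax, -1)) wr(.edfNum(v, 8))                # physical min
  for (v in c(physMax, 1)) wr(.edfNum(v, 8))                  # physical max
  for (i in seq_len(nsig)) wr(.edfField("-32767", 8))
  for (i in seq_len(nsig)) wr(.edfField("32767", 8))
  for (i in seq_len(nsig)) wr(.edfField("", 80))              # prefiltering
  for (v in c(rep(ns, nch), nAnn)) wr(.edfField(v, 8))
  for (i in seq_len(nsig)) wr(.edfField("", 32))

  evT <- (recording@events - 1) / fs    # onset seconds, 0-based
  for (r in seq_len(nRec)) {
    i0 <- (r - 1L) * ns
    take <- seq_len(min(ns, n - i0)) + i0
    block <- matrix(0L, ns, nch)
    dig <- round(t(data[, take, drop = FALSE]) /
                   matrix(physMax, length(take), nch, byrow = TRUE) * 32767)
    block[seq_along(take), ] <- as.integer(pmax(-32767, pmin(32767, dig)))
    writeBin(as.vector(block), con, size = 2, endian = "little")
    # annotations: record timestamp TAL, then one TAL per stimulus onset
    t0 <- (r - 1) * dr
    tal <- sprintf("+%.6g\x14\x14", t0)
    inRec <- which(evT >= t0 - 1e-12 & evT < t0 + dr - 1e-12)
    for (e in inRec) tal <- paste0(tal, sprintf("+%.9g\x14stim\x14", evT[e]))
    raw <- utf8ToInt(tal)
    raw <- c(raw, rep(0L, 2L * nAnn - length(raw)))
    if (length(raw) > 2L * nAnn) stop("annotation overflow in record ", r)
    writeBin(as.integer(raw[seq(1, 2 * nAnn, 2)] +
                        256L * raw[seq(2, 2 * nAnn, 2)]),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Reads a multichannel EDF file with equal sampling rates into a
#' [Recording-class]; `stim` annotations (any annotation text, except the
#' record timestamps) become stimulus events. Files written by
#' [writeEdf()] round-trip exactly up to the 16-bit quantisation.
#'
#' @param path EDF file path.
#' @return a [Recording-class] in the file's physical units.
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  rd(8)
  rd(80)                                  # patient
  recId <- rd(80)
  rd(8); rd(8); rd(8)
  reserved <- rd(44)
  nRec <- as.integer(rd(8))
  dr <- as.numeric(rd(8))
  nsig <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(nsig), function(i) rd(16), ""))
  for (i in seq_len(nsig)) rd(80)
  for (i in seq_len(nsig)) rd(8)          # units
  pMin <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  pMax <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  dMin <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  dMax <- as.numeric(vapply(seq_len(nsig), function(i) rd(8), ""))
  for (i in seq_len(nsig)) rd(80)
  spr <- as.integer(vapply(seq_len(nsig), function(i) rd(8), ""))
  for (i in seq_len(nsig)) rd(32)

  isAnn <- labels == "EDF Annotations"
  chIdx <- which(!isAnn)
  if (!length(chIdx)) stop("no data signals in ", path)
  fs <- spr[chIdx] / dr
  if (length(unique(fs)) > 1)
    stop("channels with unequal sampling rates are not supported")
  fs <- fs[1]
  nTot <- nRec * spr[chIdx[1]]
  data <- matrix(0, length(chIdx), nTot)
  annBytes <- raw(0)
  for (r in seq_len(nRec)) {
    for (s in seq_len(nsig)) {
      v <- readBin(con, "integer", spr[s], size = 2, endian = "little")
      if (isAnn[s]) {
        b <- writeBin(as.integer(v), raw(), size = 2, endian = "little")
        annBytes <- c(annBytes, b)
      } else {
        ci <- match(s, chIdx)
        sc <- (pMax[s] - pMin[s]) / (dMax[s] - dMin[s])
        cols <- ((r - 1) * spr[s] + 1):(r * spr[s])
        data[ci, cols] <- pMin[s] + (v - dMin[s]) * sc
      }
    }
  }
  events <- integer()
  if (length(annBytes)) {
    txt <- rawToChar(annBytes[annBytes != as.raw(0)], multiple = FALSE)
    tals <- strsplit(txt, "\x14\x14|\x14", fixed = FALSE)[[1]]
    # onsets followed by non-empty text are annotations (not timestamps)
    i <- 1
    while (i < length(tals)) {
      if (grepl("^[+-][0-9.]+$", tals[i]) && nzchar(tals[i + 1]) &&
          !grepl("^[+-][0-9.]", tals[i + 1])) {
        events <- c(events, as.integer(round(as.numeric(tals[i]) * fs)) + 1L)
        i <- i + 2
      } else i <- i + 1
    }
  }
  reference <- sub(".*ref:([^ ]+).*", "\\1", recId)
  if (identical(reference, recId)) reference <- "unknown"
  nMark <- suppressWarnings(as.integer(sub(".*n=([0-9]+).*", "\\1", reserved)))
  if (!is.na(nMark) && nMark <= nTot) data <- data[, seq_len(nMark), drop = FALSE]
  events <- events[events >= 1 & events <= ncol(data)]
  Recording(data, fsHz = fs, events = sort(unique(events)),
            reference = trimws(reference), channelNames = labels[chIdx])
}
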