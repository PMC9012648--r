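#' @include AllClasses.R
NULL

# base search windows (ms) at 80 dB nHL and 25/s; shifted by the documented
# level law (all waves) and rate law (wave V only)
.BASE_WINDOWS <- data.frame(wave = c("I", "III", "V"),
                            lo_ms = c(1.0, 3.0, 4.8),
                            hi_ms = c(2.4, 4.4, 7.2))

.searchWindows <- function(ratePerS, levelDbNhl, levelSlope = 0.3,
                           rateSlope = 0.2, refLevel = 80, refRate = 25) {
  w <- .BASE_WINDOWS
  shift <- levelSlope * (refLevel - levelDbNhl) / 10
  w$lo_ms <- w$lo_ms + shift
  w$hi_ms <- w$hi_ms + shift
  isV <- w$wave == "V"
  rshift <- rateSlope * log2(ratePerS / refRate)
  w$lo_ms[isV] <- w$lo_ms[isV] + rshift
  w$hi_ms[isV] <- w$hi_ms[isV] + rshift
  w
}

# parabolic (three-point) interpolation of a local maximum
.parabolicPeak <- function(y, i, dt) {
  if (i <= 1L || i >= length(y)) return(list(t = (i - 1) * dt, v = y[i]))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  delta <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
  delta <- max(-0.5, min(0.5, delta))
  list(t = (i - 1 + delta) * dt,
       v = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
}

#' Detect ABR waves I, III and V
#'
#' Scores an averaged waveform at one channel the way a clinician reads an
#' ABR trace, made explicit: within a rate/level-adjusted search window per
#' wave, the largest positive local maximum is the peak; its latency is
#' refined by parabolic (sub-sample) interpolation; the amplitude is peak
#' minus the lowest point within the following 1.5 ms (peak-to-trough,
#' offset-invariant) or, with `convention = "baseline_peak"`, the peak
#' value itself. A wave is flagged not-found when no local maximum exceeds
#' twice the RMS of the 8.5-10 ms tail of the trace -- an explicit stand-in
#' for the visual detectability judgement.
#'
#' @param avg an [AveragedWaveform-class] covering 0-10 ms.
#' @param channel channel label to score (default `"Cz"`).
#' @param ratePerS,levelDbNhl stimulus condition, used to place the search
#'   windows.
#' @param convention amplitude convention, `"peak_trough"` (default) or
#'   `"baseline_peak"`.
#' @return a [WavePeaks-class].
#' @export
detectWaves <- function(avg, channel = "Cz", ratePerS = 25, levelDbNhl = 75,
                        convention = c("peak_trough", "baseline_peak")) {
  convention <- match.arg(convention)
  ci <- match(channel, avg@channelNames)
  if (is.na(ci)) stop("identity error: channel ", channel, " not present")
  # detection works on the demeaned trace so a constant offset can neither
  # mask nor fabricate a wave; latencies and peak-to-trough amplitudes are
  # offset-invariant by construction
  y <- avg@data[ci, ]
  y <- y - mean(y)
  fs <- avg@fsHz
  dtMs <- 1000 / fs
  tMs <- (seq_along(y) - 1) * dtMs
  lateIdx <- tMs >= 8.5 & tMs <= 10
  late <- y[lateIdx]
  thresh <- 2 * sqrt(mean((late - mean(late))^2))
  win <- .searchWindows(ratePerS, levelDbNhl)
  res <- data.frame(wave = win$wave, latency_ms = NA_real_,
                    amplitude_uv = NA_real_, found = FALSE)
  # strict rise / non-strict fall so plateau peaks register once
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
             FALSE)
  for (w in seq_len(nrow(win))) {
    inWin <- which(isMax & tMs >= win$lo_ms[w] & tMs <= win$hi_ms[w])
    if (!length(inWin)) next
    i <- inWin[which.max(y[inWin])]
    if (y[i] <= thresh) next
    pk <- .parabolicPeak(y, i, dtMs)
    troughIdx <- which(tMs > tMs[i] & tMs <= tMs[i] + 1.5)
    amp <- if (convention == "peak_trough" && length(troughIdx))
      pk$v - min(y[troughIdx]) else pk$v
    res$latency_ms[w] <- pk$t
    res$amplitude_uv[w] <- max(amp, 0)
    res$found[w] <- TRUE
  }
  new("WavePeaks", peaks = res, channel = channel, searchWindows = win)
}

#' Interwave latencies
#'
#' Latency differences I-III and III-V, the conduction-time indices that
#' are independent of the reference choice. A pair involving an undetected
#' wave is reported `NA` (absent), never zero.
#'
#' @param peaks a [WavePeaks-class].
#' @return named numeric: `I_III` and `III_V` in ms (NA when a wave is
#'   absent).
#' @export
interwaveLatencies <- function(peaks) {
  p <- peaks@peaks
  lat <- stats::setNames(p$latency_ms, p$wave)
  fnd <- stats::setNames(p$found, p$wave)
  out <- c(I_III = if (fnd["I"] && fnd["III"]) lat[["III"]] - lat[["I"]] else NA_real_,
           III_V = if (fnd["III"] && fnd["V"]) lat[["V"]] - lat[["III"]] else NA_real_)
  out
}

#' Waveform repeatability across duplicate trials
#'
#' Pearson correlation of two averaged waveforms at one channel over the
#' analysis window -- the duplicate-trial consistency check used to accept
#' an ABR recording.
#'
#' @param avg1,avg2 [AveragedWaveform-class] objects of identical shape.
#' @param channel channel label.
#' @return correlation in `[-1, 1]`.
#' @export
repeatability <- function(avg1, avg2, channel = "Cz") {
  i1 <- match(channel, avg1@channelNames)
  i2 <- match(channel, avg2@channelNames)
  if (is.na(i1) || is.na(i2)) stop("identity error: channel not present")
  if (ncol(avg1@data) != ncol(avg2@data))
    stop("waveform lengths differ")
  stats::cor(avg1@data[i1, ], avg2@data[i2, ])
}

#' Summarize wave measurements across subjects
#'
#' Cross-subject mean and sample SD (n - 1 denominator) of wave amplitudes
#' per reference method, and of the I-III / III-V interwave latencies,
#' mirroring the clinical table layout. Waves not detected in a subject
#' are excluded from that cell, with the contributing count reported.
#'
#' @param peaksTable data.frame with columns `subject`, `method`, `wave`,
#'   `latency_ms`, `amplitude_uv`, `found` (one row per subject x method x
#'   wave; duplicate trials may be included and are pooled).
#' @return an [AbrSummary-class].
#' @export
summarizePeaks <- function(peaksTable) {
  if (!nrow(peaksTable)) stop("empty input")
  if (length(unique(peaksTable$subject)) < 2)
    stop("need at least 2 subjects to summarize")
  ok <- peaksTable[peaksTable$found, , drop = FALSE]
  amp <- do.call(rbind, lapply(split(ok, ok[c("method", "wave")], drop = TRUE),
    function(d) data.frame(method = d$method[1], wave = d$wave[1],
                           mean_uv = mean(d$amplitude_uv),
                           sd_uv = stats::sd(d$amplitude_uv),
                           n = length(unique(d$subject)))))
  pairs <- list(I_III = c("I", "III"), III_V = c("III", "V"))
  iw <- list()
  for (m in unique(peaksTable$method)) {
    for (pn in names(pairs)) {
      ws <- pairs[[pn]]
      d <- ok[ok$method == m & ok$wave %in% ws, ]
      # per subject (and trial, if present) both waves must be found
      key <- interaction(d$subject, if (!is.null(d$trial)) d$trial else 0)
      diffs <- unlist(lapply(split(d, key, drop = TRUE), function(g) {
        if (all(ws %in% g$wave))
          g$latency_ms[g$wave == ws[2]] - g$latency_ms[g$wave == ws[1]]
        else NULL
      }))
      if (length(diffs))
        iw[[length(iw) + 1L]] <- data.frame(
          method = m, pair = pn, mean_ms = mean(diffs),
          sd_ms = stats::sd(diffs), n = length(diffs))
    }
  }
  new("AbrSummary", amplitudes = amp,
      interwave = if (length(iw)) do.call(rbind, iw) else
        data.frame(method = character(), pair = character(),
                   mean_ms = numeric(), sd_ms = numeric(), n = integer()),
      nEars = length(unique(peaksTable$subject)))
}
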