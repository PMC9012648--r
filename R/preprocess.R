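#' @include AllClasses.R simulate.R
NULL

# zero-phase (forward-backward) IIR filtering with odd-reflection padding,
# so transients decay inside the pads rather than the data
.zeroPhase <- function(b, a, x) {
  npad <- min(length(x) - 1L, 1000L)
  front <- 2 * x[1] - x[(npad + 1):2]
  back <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  xp <- c(front, x, back)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(npad + 1):(npad + length(x))]
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass applied per channel, zero-phase
#' (forward-backward), so peak latencies are not shifted. The defaults are
#' the ABR analysis band: 3rd-order 100-1500 Hz (effective 6th-order
#' magnitude after the two passes). Offline zero-phase filtering differs
#' from the causal filters of clinical hardware, which delay peaks.
#'
#' @param recording a [Recording-class].
#' @param lowHz high-pass cutoff (Hz).
#' @param highHz low-pass cutoff (Hz), strictly below Nyquist.
#' @param order Butterworth order per pass (>= 1).
#' @return a filtered [Recording-class]; events and reference unchanged.
#' @export
bandpassFilter <- function(recording, lowHz = 100, highHz = 1500, order = 3) {
  fs <- recording@fsHz
  if (highHz >= fs / 2) stop("configuration error: cutoff must be below Nyquist")
  if (order < 1) stop("configuration error: order must be >= 1")
  bw <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  data <- recording@data
  for (i in seq_len(nrow(data)))
    data[i, ] <- .zeroPhase(bw$b, bw$a, data[i, ])
  Recording(data, fsHz = fs, events = recording@events,
            reference = recording@reference,
            channelNames = recording@channelNames)
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per stimulus event over the half-open window
#' `[onset, onset + n)` where `n = window * fs` (200 samples for the
#' default 0-10 ms window at 20 kHz). Events whose full window does not fit
#' in the record are dropped with a warning.
#'
#' @param recording a [Recording-class] with events.
#' @param windowMs numeric(2), epoch window in ms relative to onset
#'   (default `c(0, 10)`).
#' @return an [EpochSet-class].
#' @export
extractEpochs <- function(recording, windowMs = c(0, 10)) {
  ev <- recording@events
  if (!length(ev)) stop("empty-epochs error: the recording has no events")
  fs <- recording@fsHz
  nWin <- round((windowMs[2] - windowMs[1]) / 1000 * fs)
  start <- ev + round(windowMs[1] / 1000 * fs)
  ok <- start >= 1L & (start + nWin - 1L) <= ncol(recording@data)
  if (any(!ok))
    warning(sum(!ok), " epoch(s) dropped: window outside the record")
  start <- start[ok]
  if (!length(start)) stop("empty-epochs error: no epoch fits in the record")
  nch <- nrow(recording@data)
  idx <- outer(seq_len(nWin) - 1L, start, "+")      # samples x epochs
  ep <- array(0, c(nch, nWin, length(start)))
  for (c in seq_len(nch))
    ep[c, , ] <- recording@data[c, ][idx]
  new("EpochSet", epochs = ep, channelNames = recording@channelNames,
      fsHz = fs, reference = recording@reference)
}

# Filtered stimulus-locked epoch average without touching the full
# continuous record per method: band-pass filtering (linear,
# time-invariant) commutes with epoch averaging, so the filtered epoch
# average equals the raw epoch average over an extended window, filtered,
# with the pads trimmed. Record edges are reflection-extended, matching
# the zero-phase filter's own edge rule. Numerically equivalent to
# filter-then-epoch-then-average, at a fraction of the cost.
.filteredEpochAverage <- function(recording, lowHz = 100, highHz = 1500,
                                  order = 3, windowMs = c(0, 10),
                                  padMs = 50) {
  ev <- recording@events
  if (!length(ev)) stop("empty-epochs error: the recording has no events")
  fs <- recording@fsHz
  if (highHz >= fs / 2) stop("configuration error: cutoff must be below Nyquist")
  n <- ncol(recording@data)
  nWin <- round((windowMs[2] - windowMs[1]) / 1000 * fs)
  padN <- min(as.integer(round(padMs / 1000 * fs)), n - 1L)
  start <- ev + as.integer(round(windowMs[1] / 1000 * fs))
  ok <- start >= 1L & (start + nWin - 1L) <= n
  if (any(!ok))
    warning(sum(!ok), " epoch(s) dropped: window outside the record")
  start <- start[ok]
  if (!length(start)) stop("empty-epochs error: no epoch fits in the record")
  len <- nWin + 2L * padN
  nEp <- length(start)
  # regular click trains admit an exact strided mean via cumulative sums;
  # irregular event lists fall back to a full index gather
  s <- if (nEp > 1L) start[2] - start[1] else 0L
  regular <- nEp > 1L && s > 0L && all(diff(start) == s)
  idx <- if (!regular) outer(seq_len(len) - 1L, start, "+") else NULL
  if (regular) {
    q <- (seq_len(len) - 1L) %/% s        # per-offset stride block
    r <- (seq_len(len) - 1L) %% s + 1L    # per-offset phase
    nBlk <- max(q) + nEp
  }
  nch <- nrow(recording@data)
  bw <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  avg <- matrix(0, nch, nWin)
  core <- (padN + 1L):(padN + nWin)
  for (ci in seq_len(nch)) {
    x <- recording@data[ci, ]
    xx <- c(2 * x[1] - x[(padN + 1):2], x, 2 * x[n] - x[(n - 1):(n - padN)])
    if (regular) {
      v <- xx[start[1]:min(length(xx), start[1] + nBlk * s - 1L)]
      v <- c(v, numeric(nBlk * s - length(v)))   # zero-pad the tail block
      C <- matrix(v, s, nBlk)
      for (j in seq_len(nBlk - 1L) + 1L)       # running sums along blocks
        C[, j] <- C[, j - 1L] + C[, j]
      C <- cbind(0, C)                          # phases x (blocks + 1)
      a <- (C[cbind(r, q + nEp + 1L)] - C[cbind(r, q + 1L)]) / nEp
    } else {
      y <- xx[idx]
      dim(y) <- c(len, nEp)
      a <- rowMeans(y)
    }
    avg[ci, ] <- .zeroPhase(bw$b, bw$a, a)[core]
  }
  rownames(avg) <- recording@channelNames
  new("AveragedWaveform", data = avg, channelNames = recording@channelNames,
      fsHz = fs, nAveraged = length(start), reference = recording@reference)
}

#' Average epochs into an evoked waveform
#'
#' Per-channel arithmetic mean across epochs -- the averaging step that
#' raises the sub-microvolt evoked response out of the background EEG
#' (independent noise shrinks as 1/sqrt(N)).
#'
#' @param epochs an [EpochSet-class] with >= 1 epoch.
#' @return an [AveragedWaveform-class] with `nAveraged` recorded.
#' @export
averageEpochs <- function(epochs) {
  d <- dim(epochs@epochs)
  if (d[3] < 1L) stop("cannot average an empty epoch set")
  avg <- rowMeans(epochs@epochs, dims = 2)
  rownames(avg) <- epochs@channelNames
  new("AveragedWaveform", data = avg, channelNames = epochs@channelNames,
      fsHz = epochs@fsHz, nAveraged = as.integer(d[3]),
      reference = epochs@reference)
}
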