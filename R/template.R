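#' @include AllClasses.R
NULL

#' Default click-evoked ABR source template
#'
#' Each wave is a Gaussian-derivative (biphasic) wavelet whose positive peak
#' sits at the component latency and whose trough follows two sigma later
#' (`width_ms` = 2 sigma). Base latencies are quoted at 80 dB nHL and the
#' default 25/s stimulus rate: wave I at 1.60 ms with the clinical interwave
#' spacings I-III = 2.05 ms and III-V = 1.95 ms; waves II and IV sit midway
#' between their neighbours at half amplitude. All brainstem waves share a
#' 0.5 ms width: equal widths mean the band-pass filter displaces every
#' scored peak by the same small amount, so interwave spacings survive
#' filtering unbiased. A middle-latency (MLR) component at 21.25 ms,
#' generated by a more superficial source, follows the brainstem waves. Its
#' width (7.5 ms, the slowest biphasic shape whose open 4-sigma support of
#' 10-40 ms both starts after the 10 ms ABR window and fits the 40 ms
#' inter-stimulus interval at 25/s) keeps its energy below the 100 Hz
#' analysis band, so the previous click's MLR trough does not cancel the
#' current wave V at moderate and high rates -- matching the clinical
#' picture in which wave V remains scoreable across the rate series. At
#' 50-100/s the MLR still overlaps the following epochs and raises the
#' averaged waveform's floor, reproducing the contamination that degrades
#' high-rate ABR.
#'
#' Stimulus-dependence laws (documented constants):
#' * every latency increases by `levelLatencySlope` = 0.3 ms per 10 dB below
#'   80 dB nHL;
#' * every amplitude halves per `levelAmpHalvingDb` = 20 dB below 80;
#' * the wave V latency additionally grows by `rateLatencySlope` = 0.2 ms
#'   per doubling of the stimulus rate relative to 25/s (so it shortens at
#'   10/s and lengthens towards 100/s).
#'
#' Amplitudes are peak equivalent-dipole moments in nA.m, scaled so the
#' clean vertex (Cz) wave V peak-to-trough response is just under 1 uV --
#' the upper end of the clinically typical ABR range.
#'
#' @param waveVAmplitude peak wave V dipole moment (nA.m, default 20).
#' @return an [AbrTemplate-class].
#' @export
defaultAbrTemplate <- function(waveVAmplitude = 20) {
  latI <- 1.60; latIII <- latI + 2.05; latV <- latIII + 1.95
  cmp <- data.frame(
    name = c("I", "II", "III", "IV", "V", "MLR"),
    latency_ms = c(latI, (latI + latIII) / 2, latIII, (latIII + latV) / 2,
                   latV, 21.25),
    amplitude = waveVAmplitude *
      c(0.30, 0.5 * (0.30 + 0.35) / 2, 0.35, 0.5 * (0.35 + 1) / 2, 1, 2.0),
    width_ms = c(0.5, 0.5, 0.5, 0.5, 0.5, 7.5),
    polarity = c(1, 1, 1, 1, 1, 1),
    source = c(rep("abr", 5), "mlr"),
    stringsAsFactors = FALSE)
  new("AbrTemplate",
      components = cmp,
      sources = list(
        abr = list(location = c(0, 0.02, 0.02), orientation = c(0, 0, 1)),
        mlr = list(location = c(0, 0.03, 0.045), orientation = c(0, 0, 1))),
      levelLatencySlope = 0.3, levelAmpHalvingDb = 20,
      rateLatencySlope = 0.2, refLevelDb = 80, refRatePerS = 25)
}

# component latencies/amplitudes adjusted for a stimulus condition
.adjustComponents <- function(template, ratePerS, levelDbNhl) {
  cmp <- template@components
  dLevel <- template@refLevelDb - levelDbNhl
  cmp$latency_ms <- cmp$latency_ms + template@levelLatencySlope * dLevel / 10
  isV <- cmp$name == "V"
  cmp$latency_ms[isV] <- cmp$latency_ms[isV] +
    template@rateLatencySlope * log2(ratePerS / template@refRatePerS)
  cmp$amplitude <- cmp$amplitude * 2^(-dLevel / template@levelAmpHalvingDb)
  cmp
}

#' Ground-truth wave latencies for a stimulus condition
#'
#' Component peak latencies of the template after applying the documented
#' level and rate laws -- the values peak detection should recover from a
#' noiseless simulation.
#'
#' @param template an [AbrTemplate-class].
#' @param ratePerS stimulus rate (per s).
#' @param levelDbNhl stimulus level (dB nHL).
#' @param waves which components to report (default I, III, V).
#' @return named numeric vector of latencies in ms.
#' @export
trueWaveLatencies <- function(template, ratePerS, levelDbNhl,
                              waves = c("I", "III", "V")) {
  cmp <- .adjustComponents(template, ratePerS, levelDbNhl)
  stats::setNames(cmp$latency_ms[match(waves, cmp$name)], waves)
}

# single-stimulus kernel for one generator source, hard-truncated at 4 sigma
# so that epochs at rates <= 25/s see exactly one response
.templateKernel <- function(template, ratePerS, levelDbNhl, fsHz,
                            source = "abr") {
  cmp <- .adjustComponents(template, ratePerS, levelDbNhl)
  cmp <- cmp[cmp$source == source, , drop = FALSE]
  sig <- cmp$width_ms / 2
  tEnd <- max(cmp$latency_ms + sig + 4 * sig)
  n <- ceiling(tEnd / 1000 * fsHz) + 1L
  t <- (seq_len(n) - 1) / fsHz * 1000   # ms
  y <- numeric(n)
  for (i in seq_len(nrow(cmp))) {
    ctr <- cmp$latency_ms[i] + sig[i]   # peak at latency, trough 2 sigma later
    u <- (t - ctr) / sig[i]
    w <- -u * exp(0.5 - u^2 / 2)
    w[abs(u) >= 4] <- 0          # open support: the 4-sigma edge is zero
    y <- y + cmp$polarity[i] * cmp$amplitude[i] * w
  }
  y
}

#' Stimulus train constructor
#'
#' @param ratePerS stimulus rate, one of 10, 25, 50, 100 per second.
#' @param levelDbNhl level in dB nHL, 45 to 80 in 5 dB steps.
#' @param nStimuli number of clicks (default 4000).
#' @param onsetJitterMs uniform onset jitter in ms (default 0).
#' @return a [StimulusTrain-class].
#' @export
stimulusTrain <- function(ratePerS = 25, levelDbNhl = 75, nStimuli = 4000,
                          onsetJitterMs = 0) {
  new("StimulusTrain", ratePerS = as.numeric(ratePerS),
      levelDbNhl = as.numeric(levelDbNhl), nStimuli = as.integer(nStimuli),
      onsetJitterMs = onsetJitterMs)
}

#' Render the source time course of a stimulus train
#'
#' Places the level- and rate-adjusted single-stimulus kernel of one
#' generator source at every click onset (convolution of the kernel with
#' the impulse train). When the inter-stimulus interval is shorter than the
#' kernel support -- 10 ms at 100/s against an 18 ms middle-latency
#' component -- consecutive responses overlap, reproducing the MLR
#' contamination of high-rate ABR.
#'
#' @param template an [AbrTemplate-class].
#' @param train a [StimulusTrain-class].
#' @param fsHz sampling rate, >= 4000 Hz.
#' @param source which generator source to render (`"abr"` or `"mlr"`).
#' @param events optional onset sample indices (1-based); defaults to a
#'   regular train at `1/ratePerS` starting at sample 1.
#' @return list with `wave` (numeric vector, nA.m), `events` (onset sample
#'   indices) and `nSamples`.
#' @export
renderSourceTimecourse <- function(template, train, fsHz = 20000,
                                   source = "abr", events = NULL) {
  if (fsHz < 4000) stop("fsHz must be >= 4000")
  isi <- round(fsHz / train@ratePerS)
  if (is.null(events)) {
    events <- 1L + (seq_len(train@nStimuli) - 1L) * isi
    if (train@onsetJitterMs > 0) {
      jit <- round(stats::runif(train@nStimuli, -train@onsetJitterMs / 2,
                                train@onsetJitterMs / 2) * fsHz / 1000)
      events <- pmax(1L, events + as.integer(jit))
    }
  }
  ker <- .templateKernel(template, train@ratePerS, train@levelDbNhl, fsHz,
                         source)
  nk <- length(ker)
  n <- max(events) + max(nk, isi) - 1L
  y <- numeric(n)
  for (e in events) {
    idx <- e:(e + nk - 1L)
    y[idx] <- y[idx] + ker
  }
  list(wave = y, events = as.integer(events), nSamples = n)
}
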