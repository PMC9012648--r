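#' @import methods
NULL

.ELECTRODE_ROLES <- c("scalp", "mastoid_left", "mastoid_right",
                      "physical_reference", "ground")

#' Electrode montage
#'
#' Named electrodes with unit-sphere 3D positions and roles. The coordinate
#' convention is head-centred with x = right, y = anterior, z = superior;
#' positions are unit-normalised (the physical scalp radius lives in
#' [HeadModel-class]).
#'
#' @slot labels character vector of unique electrode names.
#' @slot positions numeric matrix (electrodes x 3) of unit vectors.
#' @slot roles character vector, one of `scalp`, `mastoid_left`,
#'   `mastoid_right`, `physical_reference`, `ground`.
#' @seealso [standardMontage()], [readMontageFile()]
#' @export
setClass("Montage",
  representation(labels = "character", positions = "matrix",
                 roles = "character"))

setValidity("Montage", function(object) {
  n <- length(object@labels)
  if (anyDuplicated(object@labels)) return("electrode labels must be unique")
  if (!is.numeric(object@positions) || ncol(object@positions) != 3 ||
      nrow(object@positions) != n)
    return("positions must be an n x 3 numeric matrix")
  nrm <- sqrt(rowSums(object@positions^2))
  if (any(abs(nrm - 1) > 1e-9))
    return("electrode positions must be unit vectors (|pos| = 1 within 1e-9)")
  if (length(object@roles) != n || !all(object@roles %in% .ELECTRODE_ROLES))
    return("roles must match electrodes and be valid role names")
  TRUE
})

#' Three-shell spherical head model
#'
#' Concentric brain / skull / scalp shells. Radii are expressed as fractions
#' of the outer scalp radius (outermost = 1); conductivities are relative
#' (the default skull is 1/80 of brain and scalp).
#'
#' @slot radii numeric(3), strictly increasing, `radii[3] == 1`.
#' @slot conductivities numeric(3), positive.
#' @slot scalpRadiusM physical scalp radius in metres.
#' @export
setClass("HeadModel",
  representation(radii = "numeric", conductivities = "numeric",
                 scalpRadiusM = "numeric"))

setValidity("HeadModel", function(object) {
  r <- object@radii
  if (length(r) != 3 || any(diff(r) <= 0) || abs(r[3] - 1) > 1e-12)
    return("radii must be three strictly increasing fractions with outermost = 1")
  if (length(object@conductivities) != 3 || any(object@conductivities <= 0))
    return("conductivities must be three positive scalars")
  if (length(object@scalpRadiusM) != 1 || object@scalpRadiusM <= 0)
    return("scalpRadiusM must be a positive scalar")
  TRUE
})

#' Equivalent dipole source layer
#'
#' Quasi-uniform dipole locations on a sphere strictly inside the innermost
#' (brain) shell, each carrying three orthonormal dipole orientations.
#'
#' @slot locations numeric matrix (sources x 3) in metres, all at the same
#'   radius.
#' @slot orientations numeric array (sources x 3 x 3); `orientations[i, , k]`
#'   is the k-th unit orientation of source i (radial plus two tangentials).
#' @export
setClass("SourceLayer",
  representation(locations = "matrix", orientations = "array"))

setValidity("SourceLayer", function(object) {
  loc <- object@locations
  if (ncol(loc) != 3) return("locations must be n x 3")
  r <- sqrt(rowSums(loc^2))
  if (any(abs(r - r[1]) > 1e-9 * max(r[1], 1)))
    return("all source locations must lie on a common sphere (within 1e-9)")
  d <- dim(object@orientations)
  if (length(d) != 3 || d[1] != nrow(loc) || d[2] != 3 || d[3] != 3)
    return("orientations must be an n x 3 x 3 array")
  for (k in 1:3) {
    n2 <- rowSums(object@orientations[, , k, drop = FALSE]^2)
    if (any(abs(n2 - 1) > 1e-9)) return("orientations must be unit vectors")
  }
  TRUE
})

#' Infinity-referenced lead field
#'
#' Channels x (3 x n_sources) matrix of scalp potentials per unit dipole
#' moment for every source-layer dipole, referenced at infinity (no
#' centering applied). Columns are grouped by source: the three columns of
#' source i correspond to its three orientations.
#'
#' @slot matrix numeric matrix, channels x (3 * n_sources), volts per A.m.
#' @slot channels channel names (row order).
#' @slot positions channels x 3 unit electrode directions (row order), kept
#'   so forward gains at arbitrary dipoles can be evaluated later.
#' @slot montageKey identity string of the montage/head model it was built
#'   for; used to detect stale caches and montage mismatches.
#' @slot head the [HeadModel-class] used.
#' @slot layer the [SourceLayer-class] used.
#' @slot nTerms Legendre series truncation order.
#' @export
setClass("LeadField",
  representation(matrix = "matrix", channels = "character",
                 positions = "matrix", montageKey = "character",
                 head = "HeadModel", layer = "SourceLayer",
                 nTerms = "integer"))

setValidity("LeadField", function(object) {
  if (!all(is.finite(object@matrix))) return("lead field entries must be finite")
  if (nrow(object@matrix) != length(object@channels))
    return("lead field rows must match channel names")
  if (ncol(object@matrix) != 3 * nrow(object@layer@locations))
    return("lead field must have 3 columns per source")
  TRUE
})

#' ABR source template
#'
#' Parametric description of the click-evoked response: one
#' Gaussian-derivative (biphasic) component per wave, plus the latency and
#' amplitude laws that shift the template with stimulus level and rate.
#' Component latencies are quoted at `refLevelDb` dB nHL and `refRatePerS`
#' per second.
#'
#' @slot components data.frame with columns `name` (I, II, III, IV, V, MLR),
#'   `latency_ms`, `amplitude` (peak equivalent-dipole moment, nA.m),
#'   `width_ms` (2 x the Gaussian sigma), `polarity` (+/- 1) and `source`
#'   ("abr" or "mlr").
#' @slot sources named list of generator dipoles, each `list(location,
#'   orientation)` in head coordinates (metres / unit vector).
#' @slot levelLatencySlope latency increase (ms) per 10 dB below `refLevelDb`,
#'   applied to every component.
#' @slot levelAmpHalvingDb level drop (dB) that halves every amplitude.
#' @slot rateLatencySlope wave V latency increase (ms) per doubling of the
#'   stimulus rate relative to `refRatePerS`.
#' @slot refLevelDb reference level (dB nHL).
#' @slot refRatePerS reference stimulus rate (per s).
#' @export
setClass("AbrTemplate",
  representation(components = "data.frame", sources = "list",
                 levelLatencySlope = "numeric", levelAmpHalvingDb = "numeric",
                 rateLatencySlope = "numeric", refLevelDb = "numeric",
                 refRatePerS = "numeric"))

setValidity("AbrTemplate", function(object) {
  cmp <- object@components
  need <- c("name", "latency_ms", "amplitude", "width_ms", "polarity", "source")
  if (!all(need %in% names(cmp))) return("components is missing columns")
  if (any(cmp$width_ms <= 0)) return("component widths must be positive")
  ord <- match(c("I", "II", "III", "IV", "V", "MLR"), cmp$name)
  lat <- cmp$latency_ms[ord[!is.na(ord)]]
  if (any(diff(lat) <= 0))
    return("component latencies must increase in the order I..V < MLR")
  if (!all(cmp$source %in% names(object@sources)))
    return("every component must map to a known source dipole")
  TRUE
})

#' Click stimulus train
#'
#' @slot ratePerS stimulus rate, one of 10, 25, 50, 100 per second.
#' @slot levelDbNhl stimulus level, 45-80 dB nHL in 5 dB steps.
#' @slot nStimuli number of clicks; the inter-stimulus interval is
#'   `1/ratePerS` exactly.
#' @slot onsetJitterMs uniform onset jitter (ms), 0 by default.
#' @export
setClass("StimulusTrain",
  representation(ratePerS = "numeric", levelDbNhl = "numeric",
                 nStimuli = "integer", onsetJitterMs = "numeric"))

.STIM_RATES <- c(10, 25, 50, 100)
.STIM_LEVELS <- seq(45, 80, by = 5)

setValidity("StimulusTrain", function(object) {
  if (!object@ratePerS %in% .STIM_RATES)
    return(sprintf("stimulus rate must be one of %s /s",
                   paste(.STIM_RATES, collapse = ", ")))
  if (!object@levelDbNhl %in% .STIM_LEVELS)
    return("stimulus level must be 45-80 dB nHL in 5 dB steps")
  if (object@nStimuli < 1L) return("nStimuli must be >= 1")
  if (object@onsetJitterMs < 0) return("onset jitter must be >= 0")
  TRUE
})

#' Background noise model
#'
#' Spatially correlated background EEG (random in-layer dipoles with
#' 1/f^alpha time courses projected through the lead field) plus independent
#' white sensor noise.
#'
#' @slot nNoiseDipoles number of random cortical noise dipoles.
#' @slot spectrumExponent alpha of the 1/f^alpha source spectrum (a spectral
#'   floor below 0.1 Hz bounds the DC power).
#' @slot scalpRmsUv target broadband scalp RMS of the correlated background,
#'   averaged over channels (microvolts).
#' @slot sensorNoiseRmsUv white sensor noise RMS per channel (microvolts).
#' @slot seed RNG seed making the draw reproducible.
#' @export
setClass("NoiseModel",
  representation(nNoiseDipoles = "integer", spectrumExponent = "numeric",
                 scalpRmsUv = "numeric", sensorNoiseRmsUv = "numeric",
                 seed = "integer"))

setValidity("NoiseModel", function(object) {
  if (object@scalpRmsUv < 0 || object@sensorNoiseRmsUv < 0)
    return("noise RMS values must be >= 0")
  if (object@nNoiseDipoles < 1L) return("need at least one noise dipole")
  TRUE
})

#' Continuous multichannel recording
#'
#' Channels x samples matrix in microvolts with stimulus event markers and a
#' descriptor of how the data are referenced (`"infinity"`, a physical
#' electrode label such as `"REF"`, or `"AR"`, `"MM"`, `"REST"`).
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot fsHz sampling rate (Hz).
#' @slot events integer sample indices (1-based) of stimulus onsets.
#' @slot reference reference descriptor.
#' @slot channelNames channel labels aligned with rows of `data`.
#' @export
setClass("Recording",
  representation(data = "matrix", fsHz = "numeric", events = "integer",
                 reference = "character", channelNames = "character"))

setValidity("Recording", function(object) {
  if (nrow(object@data) != length(object@channelNames))
    return("data rows must match channelNames")
  if (length(object@events) &&
      (min(object@events) < 1L || max(object@events) > ncol(object@data)))
    return("all event indices must lie within the data length")
  if (object@fsHz <= 0) return("fsHz must be positive")
  TRUE
})

#' Stimulus-locked epochs
#'
#' @slot epochs numeric array, channels x samples x epochs.
#' @slot channelNames channel labels.
#' @slot fsHz sampling rate (Hz).
#' @slot reference reference descriptor inherited from the recording.
#' @export
setClass("EpochSet",
  representation(epochs = "array", channelNames = "character",
                 fsHz = "numeric", reference = "character"))

setValidity("EpochSet", function(object) {
  d <- dim(object@epochs)
  if (length(d) != 3) return("epochs must be channels x samples x epochs")
  if (d[1] != length(object@channelNames))
    return("epoch channels must match channelNames")
  TRUE
})

#' Averaged evoked waveform
#'
#' Channels x samples arithmetic mean of stimulus-locked epochs; the time
#' axis starts at the stimulus onset (t = 0).
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot channelNames channel labels.
#' @slot fsHz sampling rate (Hz).
#' @slot nAveraged number of epochs averaged.
#' @slot reference reference descriptor.
#' @export
setClass("AveragedWaveform",
  representation(data = "matrix", channelNames = "character",
                 fsHz = "numeric", nAveraged = "integer",
                 reference = "character"))

setValidity("AveragedWaveform", function(object) {
  if (nrow(object@data) != length(object@channelNames))
    return("data rows must match channelNames")
  if (object@nAveraged < 1L) return("nAveraged must be >= 1")
  TRUE
})

#' Linear re-referencing operator
#'
#' @slot method `"AR"`, `"MM"` or `"REST"`.
#' @slot matrix channels_out x channels_in linear operator.
#' @slot channels channel names the operator applies to (both axes).
#' @slot leadfieldKey montage identity of the lead field (REST only, else "").
#' @export
setClass("ReferenceTransform",
  representation(method = "character", matrix = "matrix",
                 channels = "character", leadfieldKey = "character"))

setValidity("ReferenceTransform", function(object) {
  if (!object@method %in% c("AR", "MM", "REST"))
    return("method must be AR, MM or REST")
  if (nrow(object@matrix) != ncol(object@matrix) ||
      nrow(object@matrix) != length(object@channels))
    return("matrix must be square and match the channel set")
  TRUE
})

#' Detected wave peaks
#'
#' Per-wave (I, III, V) latency and amplitude at one channel, with the
#' search windows actually used and a detectability flag.
#'
#' @slot peaks data.frame with columns `wave`, `latency_ms`, `amplitude_uv`,
#'   `found`.
#' @slot channel channel the waves were scored at.
#' @slot searchWindows data.frame with columns `wave`, `lo_ms`, `hi_ms`.
#' @export
setClass("WavePeaks",
  representation(peaks = "data.frame", channel = "character",
                 searchWindows = "data.frame"))

setValidity("WavePeaks", function(object) {
  p <- object@peaks
  if (!all(c("wave", "latency_ms", "amplitude_uv", "found") %in% names(p)))
    return("peaks is missing columns")
  lat <- p$latency_ms[p$found]
  if (any(diff(lat) <= 0)) return("found-wave latencies must strictly increase")
  if (any(p$amplitude_uv[p$found] < 0)) return("amplitudes must be >= 0")
  TRUE
})

#' Cross-subject summary of wave measurements
#'
#' Mean and sample SD (n - 1) of wave amplitudes and interwave latencies per
#' reference method, mirroring the usual clinical table layout.
#'
#' @slot amplitudes data.frame: method x wave mean/SD of amplitude, with the
#'   number of contributing ears per cell.
#' @slot interwave data.frame: method x pair (I-III, III-V) mean/SD latency
#'   difference.
#' @slot nEars number of contributing subjects.
#' @export
setClass("AbrSummary",
  representation(amplitudes = "data.frame", interwave = "data.frame",
                 nEars = "integer"))
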