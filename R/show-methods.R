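#' @include AllClasses.R
NULL

setMethod("show", "Montage", function(object) {
  tab <- table(factor(object@roles, levels = .ELECTRODE_ROLES))
  cat("Montage with", length(object@labels), "electrodes (",
      tab[["scalp"]], "scalp,", tab[["mastoid_left"]] + tab[["mastoid_right"]],
      "mastoid,", tab[["physical_reference"]], "reference )\n")
  cat("  labels:", paste(utils::head(object@labels, 8), collapse = " "),
      if (length(object@labels) > 8) "..." else "", "\n")
})

setMethod("show", "HeadModel", function(object) {
  cat("Three-shell HeadModel: radii", paste(object@radii, collapse = " / "),
      "x", object@scalpRadiusM, "m; conductivities",
      paste(object@conductivities, collapse = " / "), "\n")
})

setMethod("show", "SourceLayer", function(object) {
  cat("SourceLayer:", nrow(object@locations), "dipole locations at radius",
      signif(sqrt(sum(object@locations[1, ]^2)), 4),
      "m, 3 orientations each\n")
})

setMethod("show", "LeadField", function(object) {
  cat("LeadField:", nrow(object@matrix), "channels x", ncol(object@matrix),
      "source moments (", nrow(object@layer@locations),
      "dipoles ), series order", object@nTerms, "\n")
})

setMethod("show", "AbrTemplate", function(object) {
  cat("AbrTemplate (", nrow(object@components), "components at",
      object@refLevelDb, "dB nHL /", object@refRatePerS, "per s):\n")
  print(object@components, row.names = FALSE)
})

setMethod("show", "StimulusTrain", function(object) {
  cat("StimulusTrain:", object@nStimuli, "clicks at", object@ratePerS,
      "/s,", object@levelDbNhl, "dB nHL\n")
})

setMethod("show", "NoiseModel", function(object) {
  cat("NoiseModel:", object@nNoiseDipoles, "dipoles, 1/f^",
      object@spectrumExponent, ", scalp", object@scalpRmsUv,
      "uV RMS + sensor", object@sensorNoiseRmsUv, "uV (seed",
      object@seed, ")\n")
})

setMethod("show", "Recording", function(object) {
  cat("Recording:", nrow(object@data), "channels x", ncol(object@data),
      "samples at", object@fsHz, "Hz (",
      signif(ncol(object@data) / object@fsHz, 4), "s ),",
      length(object@events), "events, reference:", object@reference, "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat("EpochSet:", d[3], "epochs x", d[1], "channels x", d[2],
      "samples, reference:", object@reference, "\n")
})

setMethod("show", "AveragedWaveform", function(object) {
  cat("AveragedWaveform:", nrow(object@data), "channels x",
      ncol(object@data), "samples ( 0 -",
      signif((ncol(object@data) - 1) / object@fsHz * 1000, 4),
      "ms ), average of", object@nAveraged, "epochs, reference:",
      object@reference, "\n")
})

setMethod("show", "ReferenceTransform", function(object) {
  cat("ReferenceTransform:", object@method, "over",
      length(object@channels), "channels\n")
})

setMethod("show", "WavePeaks", function(object) {
  cat("WavePeaks at", object@channel, ":\n")
  print(object@peaks, row.names = FALSE)
})

setMethod("show", "AbrSummary", function(object) {
  cat("AbrSummary over", object@nEars, "ears\n amplitudes (uV):\n")
  print(object@amplitudes, row.names = FALSE)
  cat(" interwave latencies (ms):\n")
  print(object@interwave, row.names = FALSE)
})
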