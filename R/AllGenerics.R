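#' Channel labels of an object
#' @param x a Montage, LeadField, Recording, EpochSet or AveragedWaveform.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Sampling rate in Hz
#' @param x a Recording, EpochSet or AveragedWaveform.
#' @return numeric scalar (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Reference descriptor of an object
#' @param x a Recording, EpochSet or AveragedWaveform.
#' @return character scalar: `"infinity"`, an electrode label, `"AR"`,
#'   `"MM"` or `"REST"`.
#' @export
setGeneric("referenceType", function(x) standardGeneric("referenceType"))

#' Stimulus event sample indices
#' @param x a Recording.
#' @return integer vector of 1-based onset sample indices.
#' @export
setGeneric("stimulusEvents", function(x) standardGeneric("stimulusEvents"))

#' Time axis in milliseconds
#' @param x an AveragedWaveform or EpochSet.
#' @return numeric vector, one value per sample, starting at 0 ms.
#' @export
setGeneric("timeMs", function(x) standardGeneric("timeMs"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "Montage", function(x) x@labels)
#' @rdname channelNames
#' @export
setMethod("channelNames", "LeadField", function(x) x@channels)
#' @rdname channelNames
#' @export
setMethod("channelNames", "Recording", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "AveragedWaveform", function(x) x@channelNames)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "Recording", function(x) x@fsHz)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fsHz)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "AveragedWaveform", function(x) x@fsHz)

#' @rdname referenceType
#' @export
setMethod("referenceType", "Recording", function(x) x@reference)
#' @rdname referenceType
#' @export
setMethod("referenceType", "EpochSet", function(x) x@reference)
#' @rdname referenceType
#' @export
setMethod("referenceType", "AveragedWaveform", function(x) x@reference)

#' @rdname stimulusEvents
#' @export
setMethod("stimulusEvents", "Recording", function(x) x@events)

#' @rdname timeMs
#' @export
setMethod("timeMs", "AveragedWaveform",
          function(x) (seq_len(ncol(x@data)) - 1) / x@fsHz * 1000)
#' @rdname timeMs
#' @export
setMethod("timeMs", "EpochSet",
          function(x) (seq_len(dim(x@epochs)[2]) - 1) / x@fsHz * 1000)
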