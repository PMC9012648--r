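#' @include AllClasses.R leadfield.R
NULL

# apply a channels x channels matrix to Recording / AveragedWaveform /
# matrix, updating the reference descriptor
.applySpatial <- function(x, fun, reference) {
  if (is(x, "Recording")) {
    Recording(fun(x@data), fsHz = x@fsHz, events = x@events,
              reference = reference, channelNames = x@channelNames)
  } else if (is(x, "AveragedWaveform")) {
    new("AveragedWaveform", data = fun(x@data), channelNames = x@channelNames,
        fsHz = x@fsHz, nAveraged = x@nAveraged, reference = reference)
  } else if (is.matrix(x)) {
    fun(x)
  } else stop("unsupported input type")
}

.chanNames <- function(x) {
  if (is.matrix(x)) rownames(x) else x@channelNames
}

#' Average reference (AR)
#'
#' Subtracts the instantaneous mean over all channels from every channel,
#' so each output column sums to zero. By default every channel present
#' (scalp and mastoids) enters the average, matching a 32-channel cap;
#' `channels` restricts the set entering the mean (the output still covers
#' all channels).
#'
#' @param x a [Recording-class], [AveragedWaveform-class] or channels x
#'   samples matrix (with row names).
#' @param channels optional labels of the channels whose mean is
#'   subtracted.
#' @return the re-referenced object, descriptor `"AR"`.
#' @export
toAverageReference <- function(x, channels = NULL) {
  nm <- .chanNames(x)
  if (length(nm) < 2) stop("average reference needs at least 2 channels")
  rows <- if (is.null(channels)) seq_along(nm) else match(channels, nm)
  if (anyNA(rows)) stop("identity error: unknown channels in AR set")
  .applySpatial(x, function(d) sweep(d, 2, colMeans(d[rows, , drop = FALSE])),
                "AR")
}

#' Mean-mastoid reference (MM)
#'
#' Subtracts the average of the left and right mastoid channels from every
#' channel; the mean of the re-referenced mastoids is identically zero.
#'
#' @param x a [Recording-class], [AveragedWaveform-class] or matrix.
#' @param m1Label,m2Label mastoid channel labels.
#' @return the re-referenced object, descriptor `"MM"`.
#' @export
toMeanMastoid <- function(x, m1Label = "M1", m2Label = "M2") {
  nm <- .chanNames(x)
  i <- match(c(m1Label, m2Label), nm)
  if (anyNA(i))
    stop("identity error: mastoid channel(s) missing: ",
         paste(c(m1Label, m2Label)[is.na(i)], collapse = ", "))
  .applySpatial(x, function(d) sweep(d, 2, colMeans(d[i, , drop = FALSE])),
                "MM")
}

#' Build the REST transform from a lead field
#'
#' Reference electrode standardization: with G the infinity-referenced lead
#' field of the equivalent source layer and G_avg its average-referenced
#' version (channel-mean row removed), the transfer matrix is
#' `T = G %*% pinv(G_avg)`. Applied to average-referenced scalp data it
#' returns the minimum-norm-consistent potentials against a point at
#' infinity. The pseudo-inverse is a truncated SVD with relative cutoff
#' 1e-6 x the largest singular value (G_avg is rank-deficient by one
#' because of the centering).
#'
#' @param leadfield a [LeadField-class].
#' @param channels channel labels to include (default: all lead-field
#'   channels except any named `REF`/`GND`, i.e. scalp + mastoids).
#' @return a [ReferenceTransform-class] with `method = "REST"`.
#' @export
buildRestTransform <- function(leadfield, channels = NULL) {
  if (is.null(channels))
    channels <- setdiff(leadfield@channels, c("REF", "GND"))
  rows <- match(channels, leadfield@channels)
  if (anyNA(rows))
    stop("identity error: channels absent from the lead field: ",
         paste(channels[is.na(rows)], collapse = ", "))
  G <- leadfield@matrix[rows, , drop = FALSE]
  Gavg <- sweep(G, 2, colMeans(G))
  sv <- svd(Gavg)
  keep <- sv$d > 1e-6 * max(sv$d)
  if (sum(keep) < length(channels) - 1L)
    warning("conditioning: centred lead field has rank ", sum(keep),
            " < channels - 1")
  dinv <- ifelse(keep, 1 / sv$d, 0)
  Tm <- G %*% (sv$v %*% (dinv * t(sv$u)))
  dimnames(Tm) <- list(channels, channels)
  new("ReferenceTransform", method = "REST", matrix = Tm,
      channels = channels, leadfieldKey = leadfield@montageKey)
}

#' Re-reference data to infinity (REST)
#'
#' Centers the data across channels at every sample (removing whatever
#' common-mode reference the data carry) and applies the REST transfer
#' matrix, yielding approximately infinity-referenced potentials. The
#' operation is idempotent and invariant to any common waveform added to
#' all channels.
#'
#' @param x a [Recording-class], [AveragedWaveform-class] or matrix whose
#'   channels match the transform (order may differ).
#' @param transform a [ReferenceTransform-class] from
#'   [buildRestTransform()].
#' @return the re-referenced object, descriptor `"REST"`.
#' @export
toRest <- function(x, transform) {
  if (transform@method != "REST") stop("transform is not a REST transform")
  nm <- .chanNames(x)
  perm <- match(nm, transform@channels)
  if (anyNA(perm) || length(nm) != length(transform@channels))
    stop("identity error: data channels do not match the REST transform")
  # reorder the operator to the data's channel order
  Tm <- transform@matrix[perm, perm, drop = FALSE]
  .applySpatial(x, function(d) Tm %*% sweep(d, 2, colMeans(d)), "REST")
}

#' Apply a named re-referencing method
#'
#' Convenience dispatcher used by the pipeline: `"AR"`, `"MM"` or
#' `"REST"`.
#'
#' @param x data object accepted by the individual transforms.
#' @param method one of `"AR"`, `"MM"`, `"REST"`.
#' @param restTransform a [ReferenceTransform-class], required for REST.
#' @param ... passed through to the underlying transform.
#' @return the re-referenced object.
#' @export
applyReference <- function(x, method = c("AR", "MM", "REST"),
                           restTransform = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         AR = toAverageReference(x, ...),
         MM = toMeanMastoid(x, ...),
         REST = {
           if (is.null(restTransform))
             stop("REST requires a transform from buildRestTransform()")
           toRest(x, restTransform)
         })
}
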