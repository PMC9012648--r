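# shared fixtures, computed once per session and cached

.fixtures <- new.env(parent = emptyenv())

cachedLeadField <- function(nSources = 200) {
  key <- sprintf("lf%d", nSources)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- computeLeadField(standardMontage(), headModel(),
                                         sourceLayer(headModel(), nSources))
  .fixtures[[key]]
}

# small noiseless acquired recording (one subject, default template)
noiselessRecording <- function(nStimuli = 50, rate = 25, level = 75) {
  key <- sprintf("rec%d_%g_%g", nStimuli, rate, level)
  if (is.null(.fixtures[[key]])) {
    lf <- cachedLeadField()
    tpl <- defaultAbrTemplate()
    clean <- abrref:::.cleanRecording(tpl, stimulusTrain(rate, level, nStimuli),
                                      lf, 20000)
    .fixtures[[key]] <- acquireAgainstReference(clean, "REF")
  }
  .fixtures[[key]]
}

# quasi-uniform whole-coverage montage for REST fidelity benchmarks
uniformMontage <- function(n) denseMontage(n, zMin = -1)

restRecoveryErrors <- function(montage, nSources = 300) {
  lf <- computeLeadField(montage, headModel(),
                         sourceLayer(headModel(), nSources))
  rt <- buildRestTransform(lf, channels = lf@channels)
  G <- lf@matrix
  Gavg <- sweep(G, 2, colMeans(G))
  W <- rt@matrix %*% Gavg
  sqrt(colSums((W - G)^2) / colSums(G^2))
}
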