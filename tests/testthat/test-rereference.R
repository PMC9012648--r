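test_that("average reference removes the channel mean, idempotently", {
  d <- matrix(c(1, 2, 3), 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  ar <- toAverageReference(d)
  expect_equal(ar, matrix(c(-1, 0, 1), 3, 4,
                          dimnames = dimnames(d)))
  set.seed(4)
  r <- matrix(rnorm(40), 4, dimnames = list(letters[1:4], NULL))
  ar1 <- toAverageReference(r)
  expect_lt(max(abs(colMeans(ar1))), 1e-12)
  expect_equal(toAverageReference(ar1), ar1, tolerance = 1e-12)
  expect_error(toAverageReference(r[1, , drop = FALSE]), "at least 2")
})

test_that("mean-mastoid reference subtracts the mastoid mean", {
  d <- matrix(c(10, 2, 4), 3, 5,
              dimnames = list(c("Cz", "M1", "M2"), NULL))
  mm <- toMeanMastoid(d)
  expect_equal(mm["Cz", ], rep(7, 5))
  expect_lt(max(abs(colMeans(mm[c("M1", "M2"), ]))), 1e-12)
  expect_equal(toMeanMastoid(mm), mm, tolerance = 1e-12)  # idempotent
  expect_error(toMeanMastoid(d[1:2, ]), "identity error")
})

test_that("reference descriptors track the applied transform", {
  rec <- noiselessRecording()
  expect_equal(referenceType(toAverageReference(rec)), "AR")
  expect_equal(referenceType(toMeanMastoid(rec)), "MM")
  rt <- buildRestTransform(cachedLeadField())
  expect_equal(referenceType(toRest(rec, rt)), "REST")
})

test_that("the REST transform kills common mode and is idempotent", {
  lf <- cachedLeadField()
  rt <- buildRestTransform(lf)
  expect_equal(rt@method, "REST")
  # centering removes any common waveform before the transfer matrix
  ones <- rt@matrix %*% rep(1, length(rt@channels))
  expect_lt(sqrt(sum(ones^2)) / norm(rt@matrix, "F"), 1e-6)
  set.seed(8)
  d <- matrix(rnorm(length(rt@channels) * 50), length(rt@channels),
              dimnames = list(rt@channels, NULL))
  r1 <- toRest(d, rt)
  common <- matrix(sin(seq_len(50)), length(rt@channels), 50, byrow = TRUE)
  expect_lt(max(abs(toRest(d + common, rt) - r1)), 1e-9)
  expect_lt(max(abs(toRest(r1, rt) - r1)), 1e-9)
  # channel sets must match
  expect_error(toRest(d[1:10, ], rt), "identity error")
})

test_that("the REST transform is invariant to channel ordering", {
  m <- subsetMontage(standardMontage(),
                     c("Cz", "Fz", "Pz", "Oz", "C3", "C4", "M1", "M2"))
  hd <- headModel()
  lay <- sourceLayer(hd, 100)
  rt1 <- buildRestTransform(computeLeadField(m, hd, lay))
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  rt2 <- buildRestTransform(
    computeLeadField(subsetMontage(m, channelNames(m)[perm]), hd, lay))
  back <- match(rt1@channels, rt2@channels)
  expect_equal(rt2@matrix[back, back], rt1@matrix, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("REST recovery error shrinks as montage coverage grows", {
  # the physical 30+2 cap vs a 128-point synthetic cap of equal extent
  errCap <- restRecoveryErrors(
    subsetMontage(standardMontage(),
                  setdiff(channelNames(standardMontage()), "REF")))
  errDense <- restRecoveryErrors(denseMontage(128))
  expect_lt(mean(errDense), mean(errCap))
})

test_that("noiseless REST output approximates infinity-referenced truth at Cz", {
  lf <- cachedLeadField()
  tpl <- defaultAbrTemplate()
  train <- stimulusTrain(25, 75, 50)
  clean <- abrref:::.cleanRecording(tpl, train, lf, 20000)
  keep <- setdiff(channelNames(clean), "REF")
  gt <- Recording(clean@data[keep, ], 20000, clean@events, "infinity", keep)
  gtAvg <- averageEpochs(extractEpochs(bandpassFilter(gt)))
  acq <- acquireAgainstReference(clean, "REF")
  restAvg <- averageEpochs(extractEpochs(
    toRest(bandpassFilter(acq), buildRestTransform(lf))))
  cz <- gtAvg@data["Cz", ]
  err <- restAvg@data["Cz", ] - cz
  expect_lt(sqrt(mean(err^2) / mean(cz^2)), 0.05)
})

test_that("re-referencing leaves wave latencies untouched and orders amplitudes", {
  rec <- noiselessRecording()
  base <- abrref:::.filteredEpochAverage(rec)
  rt <- buildRestTransform(cachedLeadField())
  lats <- list(); amps <- list()
  for (m in c("AR", "REST", "MM")) {
    wp <- detectWaves(applyReference(base, m, restTransform = rt), "Cz",
                      25, 75)
    expect_true(all(wp@peaks$found))
    lats[[m]] <- wp@peaks$latency_ms
    amps[[m]] <- wp@peaks$amplitude_uv
  }
  # purely spatial maps cannot move peaks: agreement within one sample
  expect_lt(max(abs(lats$AR - lats$REST)), 0.05)
  expect_lt(max(abs(lats$AR - lats$MM)), 0.05)
  # deep midline source: mean-mastoid amplifies, average reference shrinks
  expect_true(all(amps$MM > amps$REST & amps$REST > amps$AR))
})
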