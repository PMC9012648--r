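test_that("default template carries the clinical interwave spacings", {
  tpl <- defaultAbrTemplate()
  lat <- trueWaveLatencies(tpl, 25, 80)
  expect_equal(unname(lat["III"] - lat["I"]), 2.05)
  expect_equal(unname(lat["V"] - lat["III"]), 1.95)
  # level law shifts all waves together; rate law shifts only wave V
  lat75 <- trueWaveLatencies(tpl, 25, 75)
  expect_equal(unname(lat75 - lat), rep(0.15, 3))
  lat50 <- trueWaveLatencies(tpl, 50, 80)
  expect_equal(unname(lat50 - lat), c(0, 0, 0.2))
})

test_that("ground-truth wave V latency is monotone in rate and inverse level", {
  tpl <- defaultAbrTemplate()
  vByRate <- sapply(c(10, 25, 50, 100),
                    function(r) trueWaveLatencies(tpl, r, 75)["V"])
  expect_true(all(diff(vByRate) > 0))
  vByLevel <- sapply(seq(80, 45, by = -5),
                     function(l) trueWaveLatencies(tpl, 25, l)["V"])
  expect_true(all(diff(vByLevel) > 0))
})

test_that("stimulus trains outside the study grids are rejected", {
  expect_error(stimulusTrain(30, 75), "rate")
  expect_error(stimulusTrain(25, 62), "level")
  expect_error(stimulusTrain(25, 75, 0), "nStimuli")
})

test_that("rendering superposes shifted kernels (brute-force oracle)", {
  tpl <- defaultAbrTemplate()
  fs <- 20000
  # a single stimulus gives the bare kernel
  one <- renderSourceTimecourse(tpl, stimulusTrain(100, 75, 1), fs, "mlr")
  ker <- abrref:::.templateKernel(tpl, 100, 75, fs, "mlr")
  expect_equal(one$wave[seq_along(ker)], ker)

  # at 100/s the rendered trace equals the brute-force shifted-kernel sum
  tr <- stimulusTrain(100, 75, 8)
  r <- renderSourceTimecourse(tpl, tr, fs, "mlr")
  oracle <- numeric(r$nSamples)
  for (e in r$events) {
    idx <- e:(e + length(ker) - 1L)
    oracle[idx] <- oracle[idx] + ker
  }
  expect_equal(r$wave, oracle, tolerance = 1e-12)
  # and consecutive responses genuinely overlap: the 10 ms epoch of
  # stimulus k+1 contains middle-latency activity from stimulus k
  epoch2 <- r$wave[r$events[2]:(r$events[2] + 199)]
  expect_gt(max(abs(epoch2 - ker[1:200])), 1e-3)

  # at 25/s the kernel support (< 40 ms) fits the ISI: every epoch-spanning
  # segment reproduces the single-stimulus kernel exactly
  r25 <- renderSourceTimecourse(tpl, stimulusTrain(25, 75, 6), fs, "abr")
  k25 <- abrref:::.templateKernel(tpl, 25, 75, fs, "abr")
  for (e in r25$events)
    expect_equal(r25$wave[e:(e + length(k25) - 1L)], k25, tolerance = 1e-12)
})

test_that("scalp projection is linear and sees the dipole geometry", {
  lf <- cachedLeadField()
  w <- sin(seq(0, 4 * pi, length.out = 400))
  rec <- projectToScalp(w, c(0, 0.02, 0.02), c(0, 0, 1), lf)
  expect_equal(referenceType(rec), "infinity")
  # zero waveform -> all-zero scalp data; scaling by 2 doubles everything
  rec0 <- projectToScalp(numeric(400), c(0, 0.02, 0.02), c(0, 0, 1), lf)
  expect_equal(max(abs(rec0@data)), 0)
  rec2 <- projectToScalp(2 * w, c(0, 0.02, 0.02), c(0, 0, 1), lf)
  expect_equal(rec2@data, 2 * rec@data)
  # deep superior midline source: vertex-positive, mastoid-negative
  gCz <- rec@data["Cz", which.max(w)]
  gM1 <- rec@data["M1", which.max(w)]
  expect_gt(abs(gCz), abs(gM1))
  expect_lt(gCz * gM1, 0)
  # a montage that does not match the lead field is refused
  expect_error(projectToScalp(w, c(0, 0.02, 0.02), c(0, 0, 1), lf,
                              montage = denseMontage(16)),
               "identity error")
  # sources outside the equivalent layer are refused
  expect_error(projectToScalp(w, c(0, 0, 0.08), c(0, 0, 1), lf),
               "source layer")
})

test_that("background noise is seeded, scaled and optional", {
  lf <- cachedLeadField()
  clean <- projectToScalp(numeric(20000), c(0, 0.02, 0.02), c(0, 0, 1), lf)
  # zero-noise model returns the input untouched
  silent <- noiseModel(scalpRmsUv = 0, sensorNoiseRmsUv = 0)
  expect_identical(addBackgroundNoise(clean, silent, lf)@data, clean@data)
  # determinism: same seed twice -> identical; new seed -> different
  nm <- noiseModel(nNoiseDipoles = 6, seed = 31)
  n1 <- addBackgroundNoise(clean, nm, lf)
  n2 <- addBackgroundNoise(clean, nm, lf)
  expect_identical(n1@data, n2@data)
  n3 <- addBackgroundNoise(clean, noiseModel(nNoiseDipoles = 6, seed = 32), lf)
  expect_gt(max(abs(n3@data - n1@data)), 0.1)
  # channel-averaged RMS lands on the requested scalp RMS (within 10%)
  corrOnly <- noiseModel(nNoiseDipoles = 6, sensorNoiseRmsUv = 0, seed = 7)
  n4 <- addBackgroundNoise(clean, corrOnly, lf)
  expect_equal(sqrt(mean(n4@data^2)), 8, tolerance = 0.1)
})

test_that("acquisition against a physical reference works entrywise", {
  d <- rbind(A = c(1, 2, 3), B = c(4, 5, 6), REF = c(1, 1, 2))
  rec <- Recording(d, fsHz = 1000, reference = "infinity")
  acq <- acquireAgainstReference(rec, "REF")
  expect_equal(channelNames(acq), c("A", "B"))
  expect_equal(acq@data, rbind(A = c(0, 1, 1), B = c(3, 4, 4)))
  expect_equal(referenceType(acq), "REF")
  # all-equal channels are pure common mode
  same <- Recording(rbind(A = 1:5, B = 1:5, REF = 1:5) + 0, fsHz = 1000)
  expect_equal(max(abs(acquireAgainstReference(same, "REF")@data)), 0)
  # a second application is a no-op on the remaining channels
  expect_identical(acquireAgainstReference(acq, "REF"), acq)
  expect_error(acquireAgainstReference(rec, "NOPE"), "identity error")
})

test_that("simulated sessions have the designed bookkeeping", {
  cfg <- sessionConfig(seed = 5, nSubjects = 1, nStimuli = 50, trials = 2,
                       noise = TRUE, nSources = 150, nNoiseDipoles = 4)
  ses <- simulateSession(cfg)
  rec1 <- ses$recordings[["r25_l75"]][[1]][[1]]
  rec2 <- ses$recordings[["r25_l75"]][[1]][[2]]
  # duration = nStimuli / rate exactly; every event marked
  expect_equal(ncol(rec1@data), 50 / 25 * 20000)
  expect_length(stimulusEvents(rec1), 50)
  # the two trials share ground truth but carry different noise draws
  expect_gt(max(abs(rec1@data - rec2@data)), 0.1)
  expect_equal(nrow(ses$groundTruth), 3)
  # determinism end to end: an identical config reproduces trial 1 exactly
  ses2 <- simulateSession(cfg)
  expect_identical(ses2$recordings[["r25_l75"]][[1]][[1]]@data, rec1@data)
})

test_that("per-subject jitter respects latencies and bounds amplitudes", {
  tpl <- defaultAbrTemplate()
  t1 <- abrref:::.subjectParams(tpl, 1, 99)
  t2 <- abrref:::.subjectParams(tpl, 2, 99)
  # latencies are never jittered (interwave truth is common to subjects)
  expect_equal(t1@components$latency_ms, tpl@components$latency_ms)
  expect_equal(t2@components$latency_ms, tpl@components$latency_ms)
  # amplitudes jitter within +/-15%, differently per subject
  r1 <- t1@components$amplitude / tpl@components$amplitude
  expect_true(all(r1 >= 0.85 & r1 <= 1.15))
  expect_false(isTRUE(all.equal(t1@components$amplitude,
                                t2@components$amplitude)))
  # orientations stay unit length
  expect_equal(sqrt(sum(t1@sources$abr$orientation^2)), 1, tolerance = 1e-12)
})
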