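mkAvg <- function(y, channel = "Cz", fs = 20000) {
  new("AveragedWaveform",
      data = matrix(y, 1, dimnames = list(channel, NULL)),
      channelNames = channel, fsHz = fs, nAveraged = 1L, reference = "MM")
}

# synthetic trace with known peak latencies (ms) and peak heights (uV)
mkTrace <- function(lat, amp, sigmaMs = 0.25, fs = 20000, durMs = 10) {
  t <- (seq_len(durMs * fs / 1000) - 1) / fs * 1000
  y <- numeric(length(t))
  for (i in seq_along(lat)) {
    u <- (t - (lat[i] + sigmaMs)) / sigmaMs
    y <- y - amp[i] * u * exp(0.5 - u^2 / 2)
  }
  y
}

test_that("wave detection scores clean traces at sub-sample accuracy", {
  y <- mkTrace(c(1.60, 3.65, 5.60), c(0.1, 0.12, 0.3))
  wp <- detectWaves(mkAvg(y), "Cz", 25, 80)
  expect_true(all(wp@peaks$found))
  expect_equal(wp@peaks$latency_ms, c(1.60, 3.65, 5.60), tolerance = 0.02)
  # peak-to-trough amplitude of the biphasic wavelet is twice the peak
  expect_equal(wp@peaks$amplitude_uv, 2 * c(0.1, 0.12, 0.3),
               tolerance = 0.05)
})

test_that("wave detection is offset-invariant and amplitude-linear", {
  y <- mkTrace(c(1.60, 3.65, 5.60), c(0.1, 0.12, 0.3))
  a <- detectWaves(mkAvg(y), "Cz", 25, 80)@peaks
  b <- detectWaves(mkAvg(y + 0.4), "Cz", 25, 80)@peaks
  expect_equal(b$latency_ms, a$latency_ms)
  expect_equal(b$amplitude_uv, a$amplitude_uv, tolerance = 1e-9)
  c3 <- detectWaves(mkAvg(3 * y), "Cz", 25, 80)@peaks
  expect_equal(c3$latency_ms, a$latency_ms)
  expect_equal(c3$amplitude_uv, 3 * a$amplitude_uv, tolerance = 1e-9)
})

test_that("undetectable waves are flagged, not invented", {
  wp0 <- detectWaves(mkAvg(numeric(200)), "Cz", 25, 75)
  expect_false(any(wp0@peaks$found))
  # peaks below twice the late-window RMS are rejected
  set.seed(9)
  noisy <- mkTrace(5.6, 0.005) + rnorm(200, sd = 0.05)
  wpN <- detectWaves(mkAvg(noisy), "Cz", 25, 80)
  expect_false(wpN@peaks$found[wpN@peaks$wave == "V"] &&
                 wpN@peaks$amplitude_uv[3] > 1)
  expect_error(detectWaves(mkAvg(numeric(200)), "Pz"), "identity error")
})

test_that("search windows track the stimulus condition", {
  # at 45 dB every window shifts late; at 100/s only wave V does
  w75 <- detectWaves(mkAvg(numeric(200)), "Cz", 25, 75)@searchWindows
  w45 <- detectWaves(mkAvg(numeric(200)), "Cz", 25, 45)@searchWindows
  expect_equal(w45$lo_ms - w75$lo_ms, rep(0.9, 3))
  w100 <- detectWaves(mkAvg(numeric(200)), "Cz", 100, 75)@searchWindows
  expect_equal(w100$lo_ms - w75$lo_ms, c(0, 0, 0.2 * log2(4)))
})

test_that("interwave latencies difference found waves and flag absences", {
  wp <- detectWaves(mkAvg(mkTrace(c(1.60, 3.65, 5.60), c(0.1, 0.1, 0.3))),
                    "Cz", 25, 80)
  iw <- interwaveLatencies(wp)
  expect_equal(unname(iw), c(2.05, 1.95), tolerance = 0.02)
  # a shift common to all waves cancels in the differences
  wp2 <- detectWaves(mkAvg(mkTrace(c(1.90, 3.95, 5.90), c(0.1, 0.1, 0.3))),
                     "Cz", 25, 70)
  expect_equal(unname(interwaveLatencies(wp2)), c(2.05, 1.95),
               tolerance = 0.02)
  # missing wave I -> I-III absent (NA), never zero
  wp3 <- detectWaves(mkAvg(mkTrace(c(3.65, 5.60), c(0.1, 0.3))), "Cz", 25, 80)
  iw3 <- interwaveLatencies(wp3)
  expect_true(is.na(iw3["I_III"]))
  expect_false(is.na(iw3["III_V"]))
})

test_that("repeatability is the Pearson correlation at the channel", {
  y <- mkTrace(c(1.6, 3.65, 5.6), c(0.1, 0.1, 0.3))
  expect_equal(repeatability(mkAvg(y), mkAvg(y)), 1)
  expect_equal(repeatability(mkAvg(y), mkAvg(-y)), -1)
  expect_error(repeatability(mkAvg(y), mkAvg(y[1:100])), "lengths differ")
  expect_error(repeatability(mkAvg(y), mkAvg(y), "Pz"), "identity error")
})

test_that("summaries report mean and n-1 SD per method and wave", {
  tab <- data.frame(
    subject = rep(1:2, each = 3), method = "AR",
    wave = rep(c("I", "III", "V"), 2),
    latency_ms = rep(c(1.6, 3.65, 5.6), 2),
    amplitude_uv = c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3),
    found = TRUE)
  s <- summarizePeaks(tab)
  expect_equal(s@nEars, 2L)
  a <- s@amplitudes
  expect_equal(a$mean_uv, rep(0.2, 3))
  expect_equal(a$sd_uv, rep(sd(c(0.1, 0.3)), 3), tolerance = 1e-12)
  iw <- s@interwave
  expect_equal(iw$mean_ms[iw$pair == "I_III"], 2.05)
  expect_equal(iw$sd_ms, rep(0, 2))            # identical subjects
  expect_error(summarizePeaks(tab[0, ]), "empty")
  expect_error(summarizePeaks(tab[tab$subject == 1, ]), "2 subjects")
})
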