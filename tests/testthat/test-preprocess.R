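mkRec <- function(x, fs = 20000, events = integer()) {
  Recording(matrix(x, nrow = 1, dimnames = list("Cz", NULL)), fsHz = fs,
            events = events)
}

test_that("band-pass filtering has the designed frequency response", {
  fs <- 20000
  n <- 10000
  trim <- 1001:9000
  # DC is fully rejected
  dc <- bandpassFilter(mkRec(rep(1, n)))
  expect_lt(max(abs(dc@data[1, trim])), 1e-6)
  # a 500 Hz sine passes with amplitude within 2% of unity
  t <- (seq_len(n) - 1) / fs
  s <- bandpassFilter(mkRec(sin(2 * pi * 500 * t)))
  expect_equal(sqrt(2 * mean(s@data[1, trim]^2)), 1, tolerance = 0.02)
  # zero phase: a symmetric pulse keeps its peak sample
  k <- 5000
  pulse <- exp(-((seq_len(n) - k) / 10)^2 / 2)
  p <- bandpassFilter(mkRec(pulse))
  expect_equal(which.max(p@data[1, ]), k)
  # cutoffs above Nyquist are a configuration error
  expect_error(bandpassFilter(mkRec(rnorm(n)), 100, 12000),
               "configuration error")
})

test_that("epoch extraction follows the half-open onset window", {
  fs <- 20000
  x <- rnorm(2000)
  rec <- mkRec(x, events = c(1L, 501L, 1001L, 1901L))
  expect_warning(ep <- extractEpochs(rec), "dropped")
  expect_equal(dim(ep@epochs), c(1, 200, 3))     # the 1901 window overruns
  expect_equal(ep@epochs[1, , 1], x[1:200])      # onset sample included
  expect_equal(ep@epochs[1, , 2], x[501:700])
  expect_error(extractEpochs(mkRec(x)), "empty-epochs")
})

test_that("epoch averaging is the arithmetic mean and shrinks noise as 1/sqrt(N)", {
  ep <- array(rep(1:200, 5), c(1, 200, 5))
  av <- averageEpochs(new("EpochSet", epochs = ep, channelNames = "Cz",
                          fsHz = 20000, reference = "AR"))
  expect_equal(av@data[1, ], as.numeric(1:200))
  expect_equal(av@nAveraged, 5L)
  # x and -x cancel exactly
  ep2 <- array(c(rnorm(200), 0), c(1, 200, 2)); ep2[1, , 2] <- -ep2[1, , 1]
  av2 <- averageEpochs(new("EpochSet", epochs = ep2, channelNames = "Cz",
                           fsHz = 20000, reference = "AR"))
  expect_equal(max(abs(av2@data)), 0)

  # 1/sqrt(N) law on white-noise epochs, slope -0.5 on log-log
  set.seed(202)
  noise <- array(rnorm(200 * 4000), c(1, 200, 4000))
  rmsAt <- function(N) {
    a <- averageEpochs(new("EpochSet",
                           epochs = noise[, , seq_len(N), drop = FALSE],
                           channelNames = "Cz", fsHz = 20000,
                           reference = "AR"))
    sqrt(mean(a@data^2))
  }
  r <- vapply(c(250, 1000, 4000), rmsAt, 1)
  expect_equal(r[3] / r[2], 0.5, tolerance = 0.1)
  slope <- coef(lm(log(r) ~ log(c(250, 1000, 4000))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})

test_that("filtering commutes with every spatial re-reference", {
  lf <- cachedLeadField()
  rt <- buildRestTransform(lf)
  set.seed(11)
  chans <- rt@channels
  d <- matrix(rnorm(length(chans) * 3000), length(chans),
              dimnames = list(chans, NULL))
  rec <- Recording(d, fsHz = 20000)
  for (m in c("AR", "MM", "REST")) {
    a <- applyReference(bandpassFilter(rec), m, restTransform = rt)@data
    b <- bandpassFilter(applyReference(rec, m, restTransform = rt))@data
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-9)
  }
})

test_that("zero-phase filtering leaves clean template peaks in place", {
  rec <- noiselessRecording()
  avgRaw <- averageEpochs(extractEpochs(rec))
  avgFilt <- averageEpochs(extractEpochs(bandpassFilter(rec)))
  pRaw <- detectWaves(toMeanMastoid(avgRaw), "Cz", 25, 75)
  pFilt <- detectWaves(toMeanMastoid(avgFilt), "Cz", 25, 75)
  expect_true(all(pRaw@peaks$found) && all(pFilt@peaks$found))
  # within one sample (0.05 ms at 20 kHz)
  expect_lt(max(abs(pRaw@peaks$latency_ms - pFilt@peaks$latency_ms)), 0.05)
})

test_that("the pipeline fast path reproduces filter-epoch-average exactly", {
  lf <- cachedLeadField()
  tpl <- defaultAbrTemplate()
  ev <- 3000L + (0:29) * 800L
  rs <- renderSourceTimecourse(tpl, stimulusTrain(25, 75, 30), 20000,
                               "abr", events = ev)
  rec <- projectToScalp(rs$wave, c(0, 0.02, 0.02), c(0, 0, 1), lf,
                        events = rs$events)
  rec <- addBackgroundNoise(rec, noiseModel(nNoiseDipoles = 4, seed = 3), lf)
  rec <- acquireAgainstReference(rec)
  fast <- abrref:::.filteredEpochAverage(rec)
  slow <- averageEpochs(extractEpochs(bandpassFilter(rec)))
  expect_equal(fast@nAveraged, slow@nAveraged)
  expect_lt(max(abs(fast@data - slow@data)) / max(abs(slow@data)), 1e-5)
})
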