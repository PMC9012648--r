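# independent oracle: direct high-order Legendre series for the
# homogeneous-sphere dipole potential (kept separate from the package's
# closed form and from the multi-shell solver)
seriesHomPotential <- function(elec, dipPos, moment, sigma, R, nTerms = 300) {
  e <- elec / sqrt(sum(elec^2))
  b <- sqrt(sum(dipPos^2))
  if (b == 0) return(3 * sum(e * moment) / (4 * pi * sigma * R^2))
  j <- dipPos / b
  x <- sum(e * j)
  beta <- b / R
  pr <- sum(j * moment)
  pt <- sum((e - x * j) * moment)
  P <- numeric(nTerms + 1); dP <- numeric(nTerms + 1)
  P[1] <- 1; P[2] <- x; dP[1] <- 0; dP[2] <- 1
  for (n in 2:nTerms) {
    P[n + 1] <- ((2 * n - 1) * x * P[n] - (n - 1) * P[n - 1]) / n
    dP[n + 1] <- dP[n - 1] + (2 * n - 1) * P[n]
  }
  v <- 0
  for (n in 1:nTerms) {
    v <- v + beta^(n - 1) * ((2 * n + 1) / n) *
      (n * pr * P[n + 1] + pt * dP[n + 1])
  }
  v / (4 * pi * sigma * R^2)
}

test_that("closed-form homogeneous potential matches an independent series", {
  R <- 0.09; sigma <- 0.33
  elecs <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0.7, 0.714), c(0, -0.6, -0.8))
  dip <- c(0.01, 0.02, 0.03)
  for (mom in list(c(0, 0, 1e-9), c(1e-9, 0, 0), c(3e-10, -4e-10, 5e-10))) {
    v <- homogeneousSpherePotential(elecs, dip, mom, sigma, R)
    o <- apply(elecs, 1, seriesHomPotential, dipPos = dip, moment = mom,
               sigma = sigma, R = R)
    expect_equal(v, o, tolerance = 1e-10)
  }
})

test_that("homogeneous potential obeys the basic physics", {
  # zero moment -> zero potential
  expect_equal(homogeneousSpherePotential(c(0, 0, 1), c(0, 0, 0.03),
                                          c(0, 0, 0)), 0)
  # linear in the moment
  v1 <- homogeneousSpherePotential(c(0, 1, 0), c(0, 0.02, 0.01),
                                   c(0, 1e-9, 1e-9))
  v3 <- homogeneousSpherePotential(c(0, 1, 0), c(0, 0.02, 0.01),
                                   3 * c(0, 1e-9, 1e-9))
  expect_equal(v3, 3 * v1)
  # no net monopole: surface mean over a dense uniform grid ~ 0
  grid <- abrref:::.fibSphere(4000)
  v <- homogeneousSpherePotential(grid, c(0, 0.01, 0.03), c(1e-9, 2e-9, 3e-9))
  expect_lt(abs(mean(v)) / max(abs(v)), 1e-3)
  # dipole outside the sphere is rejected
  expect_error(homogeneousSpherePotential(c(0, 0, 1), c(0, 0, 0.1),
                                          c(0, 0, 1e-9), R = 0.09),
               "invalid geometry")
})

test_that("three-shell lead field reduces to the homogeneous closed form", {
  m <- standardMontage()
  hdE <- headModel(conductivities = c(1, 1, 1))
  lay <- sourceLayer(hdE, 150)
  lf <- computeLeadField(m, hdE, lay, nTerms = 60L)
  O <- matrix(0, length(lf@channels), ncol(lf@matrix))
  for (s in seq_len(nrow(lay@locations))) {
    for (k in 1:3) {
      O[, 3 * (s - 1) + k] <- homogeneousSpherePotential(
        lf@positions, lay@locations[s, ], lay@orientations[s, , k],
        sigma = 1, R = hdE@scalpRadiusM)
    }
  }
  expect_lt(norm(lf@matrix - O, "F") / norm(O, "F"), 1e-6)
})

test_that("lead field scales and converges as the physics demands", {
  m <- subsetMontage(standardMontage(),
                     c("Cz", "Fz", "Pz", "T7", "T8", "M1", "M2", "Oz"))
  hd <- headModel()
  lay <- sourceLayer(hd, 100)
  lf <- computeLeadField(m, hd, lay, nTerms = 60L)

  # doubling all conductivities exactly halves every entry
  hd2 <- headModel(conductivities = 2 * hd@conductivities)
  lf2 <- computeLeadField(m, hd2, lay, nTerms = 60L)
  expect_equal(2 * lf2@matrix, lf@matrix, tolerance = 1e-12)

  # series truncation: 60 -> 120 changes nothing beyond 1e-6 (relative)
  lf120 <- computeLeadField(m, hd, lay, nTerms = 120L)
  expect_lt(norm(lf@matrix - lf120@matrix, "F") / norm(lf120@matrix, "F"),
            1e-6)

  # central radial dipole: potential proportional to cos(polar angle)
  g <- abrref:::.dipoleGains(m, hd, c(0, 0, 0), c(0, 0, 1))
  cosang <- electrodePositions(m)[, "z"]
  expect_equal(as.vector(g) / g[1], unname(cosang / cosang[1]),
               tolerance = 1e-9)

  # geometry validation
  expect_error(computeLeadField(m, hd, sourceLayer(hd, 10, relRadius = 1.2)),
               "inside the brain shell")
})

test_that("lead-field caching stores and reuses by identity", {
  dir <- withr::local_tempdir()
  m <- subsetMontage(standardMontage(), c("Cz", "Fz", "Pz", "M1", "M2"))
  hd <- headModel()
  lay <- sourceLayer(hd, 50)
  lf1 <- computeLeadField(m, hd, lay, cacheDir = dir)
  files <- list.files(dir)
  expect_length(files, 1)
  lf2 <- computeLeadField(m, hd, lay, cacheDir = dir)
  expect_equal(lf1@matrix, lf2@matrix)
  # a different head model must not reuse the stale cache
  hd2 <- headModel(conductivities = c(1, 0.05, 1))
  lf3 <- computeLeadField(m, hd2, lay, cacheDir = dir)
  expect_length(list.files(dir), 2)
  expect_gt(max(abs(lf3@matrix - lf1@matrix)) / max(abs(lf1@matrix)), 1e-3)
})
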