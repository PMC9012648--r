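#' @include AllClasses.R montage.R
NULL

#' Three-shell head model constructor
#'
#' Defaults follow the standard three-shell values used with equivalent
#' source-layer infinity re-referencing: shell radii 0.87 / 0.92 / 1.0 of
#' the scalp radius, conductivities 1 / 0.0125 / 1 (skull = 1/80 of brain
#' and scalp) and a 0.09 m scalp radius.
#'
#' @param radii numeric(3) fractions of the scalp radius (brain, outer
#'   skull, scalp), strictly increasing, last = 1.
#' @param conductivities numeric(3) relative conductivities.
#' @param scalpRadiusM scalp radius in metres.
#' @return a [HeadModel-class].
#' @export
headModel <- function(radii = c(0.87, 0.92, 1.0),
                      conductivities = c(1.0, 0.0125, 1.0),
                      scalpRadiusM = 0.09) {
  new("HeadModel", radii = radii, conductivities = conductivities,
      scalpRadiusM = scalpRadiusM)
}

# Fibonacci lattice on the unit sphere
.fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# orthonormal basis (radial, 2 tangentials) per unit location
.radialBasis <- function(u) {
  n <- nrow(u)
  ori <- array(0, c(n, 3, 3))
  ori[, , 1] <- u
  pole <- abs(u[, 3]) > 0.9
  a <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  a[pole, ] <- matrix(rep(c(1, 0, 0), each = sum(pole)), ncol = 3)
  t1 <- cbind(u[, 2] * a[, 3] - u[, 3] * a[, 2],
              u[, 3] * a[, 1] - u[, 1] * a[, 3],
              u[, 1] * a[, 2] - u[, 2] * a[, 1])
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(u[, 2] * t1[, 3] - u[, 3] * t1[, 2],
              u[, 3] * t1[, 1] - u[, 1] * t1[, 3],
              u[, 1] * t1[, 2] - u[, 2] * t1[, 1])
  ori[, , 2] <- t1
  ori[, , 3] <- t2
  ori
}

#' Equivalent dipole source layer
#'
#' `n` quasi-uniform locations (Fibonacci lattice) on a sphere of radius
#' `relRadius` x the brain-shell radius, each with a radial and two
#' tangential unit dipole orientations.
#'
#' @param head a [HeadModel-class].
#' @param n number of source locations (default 500).
#' @param relRadius layer radius as a fraction of the brain radius
#'   (default 0.86, strictly < 1).
#' @return a [SourceLayer-class].
#' @export
sourceLayer <- function(head = headModel(), n = 500, relRadius = 0.86) {
  if (relRadius >= 1)
    stop("source layer must lie strictly inside the brain shell")
  rSrc <- relRadius * head@radii[1] * head@scalpRadiusM
  u <- .fibSphere(n)
  new("SourceLayer", locations = u * rSrc, orientations = .radialBasis(u))
}

# Per-degree surface gain of the three-shell sphere.
#
# For each harmonic degree n the primary (infinite-medium) dipole potential
# inside the brain shell carries an exterior term q * u^-(n+1) (u = r/R).
# Matching potential and radial current density across both interfaces and
# imposing zero current through the scalp surface yields a 5x5 linear
# system in the secondary coefficients; the returned gain S_n is the
# surface potential per unit q. For equal conductivities S_n = (2n+1)/n.
.shellGains <- function(nMax, head) {
  u1 <- head@radii[1]; u2 <- head@radii[2]
  s1 <- head@conductivities[1]; s2 <- head@conductivities[2]
  s3 <- head@conductivities[3]
  S <- numeric(nMax)
  for (n in seq_len(nMax)) {
    M <- matrix(0, 5, 5); rhs <- numeric(5)
    M[1, ] <- c(u1^n, -u1^n, -u1^(-(n + 1)), 0, 0)
    rhs[1] <- -u1^(-(n + 1))
    M[2, ] <- c(s1 * n * u1^(n - 1), -s2 * n * u1^(n - 1),
                s2 * (n + 1) * u1^(-(n + 2)), 0, 0)
    rhs[2] <- s1 * (n + 1) * u1^(-(n + 2))
    M[3, ] <- c(0, u2^n, u2^(-(n + 1)), -u2^n, -u2^(-(n + 1)))
    M[4, ] <- c(0, s2 * n * u2^(n - 1), -s2 * (n + 1) * u2^(-(n + 2)),
                -s3 * n * u2^(n - 1), s3 * (n + 1) * u2^(-(n + 2)))
    M[5, ] <- c(0, 0, 0, n, -(n + 1))
    # row/column equilibration: entries span u^n .. u^-(n+2), which
    # overwhelms the double-precision solve at high degree otherwise
    rs <- 1 / apply(abs(M), 1, max)
    M <- M * rs
    cs <- 1 / apply(abs(M), 2, max)
    sol <- solve(sweep(M, 2, cs, "*"), rhs * rs) * cs
    S[n] <- sol[4] + sol[5]
  }
  S
}

# Legendre-series accumulation shared by the lead-field builders.
#
# Returns U, W (electrodes x sources) such that the potential of a unit
# dipole with orientation v at source j, seen by electrode e, is
#   U[e,j] * (jhat_j . v) + W[e,j] * (ehat_e . v)
# using g = sum_n c_n [ (n P_n - x P_n') jhat + P_n' ehat ],
# c_n = S_n beta^(n-1) / (4 pi sigma1 R^2). The derivative recurrence
# P'_{n+1} = P'_{n-1} + (2n+1) P_n avoids the (x^2 - 1) division.
.seriesUW <- function(elecU, srcU, beta, head, nTerms) {
  X <- elecU %*% t(srcU)                    # cos(gamma), E x S
  Sn <- .shellGains(nTerms, head)
  k <- 1 / (4 * pi * head@conductivities[1] * head@scalpRadiusM^2)
  E <- nrow(elecU); S <- nrow(srcU)
  U <- matrix(0, E, S); W <- matrix(0, E, S)
  Pprev <- matrix(1, E, S); Pcur <- X       # P0, P1
  dPprev <- matrix(0, E, S); dPcur <- matrix(1, E, S)
  betaPow <- rep(1, S)                      # beta^(n-1), per source
  for (n in seq_len(nTerms)) {
    cN <- k * Sn[n] * betaPow               # per-source coefficient
    U <- U + sweep(n * Pcur - X * dPcur, 2, cN, "*")
    W <- W + sweep(dPcur, 2, cN, "*")
    if (n < nTerms) {
      Pnext <- ((2 * n + 1) * X * Pcur - n * Pprev) / (n + 1)
      dPnext <- dPprev + (2 * n + 1) * Pcur
      Pprev <- Pcur; Pcur <- Pnext
      dPprev <- dPcur; dPcur <- dPnext
      betaPow <- betaPow * beta
    }
  }
  list(U = U, W = W)
}

# gains (E x nDipoles) for arbitrary dipoles inside the brain shell
.dipoleGains <- function(montage, head, locations, orientations, nTerms = 60L) {
  locations <- matrix(locations, ncol = 3)
  orientations <- matrix(orientations, ncol = 3)
  b <- sqrt(rowSums(locations^2))
  R <- head@scalpRadiusM
  if (any(b >= head@radii[1] * R))
    stop("invalid geometry: source on or outside the innermost shell")
  srcU <- locations / ifelse(b > 0, b, 1)
  srcU[b == 0, ] <- matrix(rep(c(0, 0, 1), sum(b == 0)),
                           ncol = 3, byrow = TRUE)
  uw <- .seriesUW(montage@positions, srcU, b / R, head, nTerms)
  jd <- rowSums(srcU * orientations)                 # per dipole
  ed <- montage@positions %*% t(orientations)        # E x nDipoles
  sweep(uw$U, 2, jd, "*") + uw$W * ed
}

#' Compute the infinity-referenced lead field
#'
#' Potentials at every montage electrode for every source-layer dipole in a
#' three-shell concentric sphere, by truncated Legendre-series expansion.
#' Potentials are referenced at infinity: no centering or re-referencing is
#' applied. Ground electrodes are excluded; all other electrodes (scalp,
#' mastoids and any physical reference) get a row, so the same field can
#' drive both synthesis and re-referencing.
#'
#' @param montage a [Montage-class].
#' @param head a [HeadModel-class].
#' @param layer a [SourceLayer-class]; every source must lie strictly inside
#'   the brain shell.
#' @param nTerms series truncation order (default 60; relative truncation
#'   error below 1e-6 at the default layer radius).
#' @param cacheDir optional directory: the computed field is stored there in
#'   a binary cache file keyed by the montage/head/layer identity and reused
#'   when the key matches; a stale cache is regenerated automatically.
#' @return a [LeadField-class] (volts per A.m).
#' @export
computeLeadField <- function(montage, head = headModel(),
                             layer = sourceLayer(head), nTerms = 60L,
                             cacheDir = NULL) {
  nTerms <- as.integer(nTerms)
  if (nTerms < 1L) stop("nTerms must be >= 1")
  rmax <- max(sqrt(rowSums(layer@locations^2)))
  if (rmax >= head@radii[1] * head@scalpRadiusM)
    stop("invalid geometry: source on or outside the innermost shell")
  keep <- montage@roles != "ground"
  sub <- subsetMontage(montage, montage@labels[keep])
  key <- .montageKey(sub, head, layer, nTerms)

  if (!is.null(cacheDir)) {
    cacheFile <- file.path(cacheDir, paste0("leadfield-", key, ".rds"))
    if (file.exists(cacheFile)) {
      lf <- tryCatch(readRDS(cacheFile), error = function(e) NULL)
      if (is(lf, "LeadField") && lf@montageKey == key) return(lf)
    }
  }

  S <- nrow(layer@locations)
  G <- matrix(0, nrow(sub@positions), 3L * S)
  for (k in 1:3) {
    G[, seq(k, 3L * S, by = 3L)] <-
      .dipoleGains(sub, head, layer@locations, layer@orientations[, , k],
                   nTerms)
  }
  rownames(G) <- sub@labels
  lf <- new("LeadField", matrix = G, channels = sub@labels,
            positions = sub@positions, montageKey = key, head = head,
            layer = layer, nTerms = nTerms)
  if (!is.null(cacheDir)) {
    dir.create(cacheDir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(lf, cacheFile)
  }
  lf
}

#' Closed-form dipole potential in a homogeneous conducting sphere
#'
#' Surface potential of a current dipole inside a homogeneous sphere,
#' obtained by summing the Legendre series in closed form (generating
#' functions). Serves as an independent oracle for the three-shell series
#' in the equal-conductivity limit.
#'
#' @param electrode electrode position(s): a length-3 vector or an n x 3
#'   matrix; interpreted as directions and evaluated on the surface.
#' @param dipolePos dipole location (length-3, metres), strictly inside the
#'   sphere.
#' @param dipoleMoment dipole moment vector (A.m).
#' @param sigma conductivity (S/m).
#' @param R sphere radius (metres).
#' @return potential(s) in volts, one per electrode.
#' @export
homogeneousSpherePotential <- function(electrode, dipolePos, dipoleMoment,
                                       sigma = 1, R = 0.09) {
  E <- matrix(electrode, ncol = 3)
  E <- E / sqrt(rowSums(E^2))
  b <- sqrt(sum(dipolePos^2))
  if (b >= R) stop("invalid geometry: dipole on or outside the sphere")
  k <- 1 / (4 * pi * sigma * R^2)
  if (b < 1e-12 * R) {                       # central dipole: only n = 1
    return(as.vector(3 * k * (E %*% dipoleMoment)))
  }
  jhat <- dipolePos / b
  beta <- b / R
  x <- as.vector(E %*% jhat)
  d <- sqrt(1 - 2 * beta * x + beta^2)
  Fr <- 2 * (x - beta) / d^3 + (1 / beta) * (1 / d - 1)
  Ft <- 2 / d^3 + (d + 1) / (d * (1 - beta * x + d))
  pr <- sum(jhat * dipoleMoment)
  ptan <- as.vector(E %*% dipoleMoment) - x * pr   # p . (ehat - x jhat)
  k * (pr * Fr + ptan * Ft)
}
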