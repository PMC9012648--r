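#' @include AllClasses.R
NULL

.deg2rad <- function(d) d * pi / 180

# unit vector from inclination theta (degrees from vertex) and azimuth alpha
# (degrees counterclockwise from +x = right; +y = anterior)
.sphPos <- function(theta, alpha) {
  t <- .deg2rad(theta); a <- .deg2rad(alpha)
  c(sin(t) * cos(a), sin(t) * sin(a), cos(t))
}

.gcMid <- function(u, v) {
  w <- u + v
  w / sqrt(sum(w^2))
}

#' Construct a Montage
#'
#' Positions are unit-normalised; labels must be unique.
#'
#' @param labels character vector of electrode names.
#' @param positions numeric matrix (electrodes x 3).
#' @param roles character vector of electrode roles; defaults to `"scalp"`.
#' @return a [Montage-class].
#' @export
Montage <- function(labels, positions, roles = rep("scalp", length(labels))) {
  positions <- as.matrix(positions)
  nrm <- sqrt(rowSums(positions^2))
  if (any(nrm == 0)) stop("electrode positions must be non-zero")
  positions <- positions / nrm
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  new("Montage", labels = as.character(labels), positions = positions,
      roles = roles)
}

.MIDLINE <- c("Fz", "FCz", "Cz", "CPz", "Pz", "Oz")

#' Standard 30-channel 10/20 montage with mastoids
#'
#' The 30 scalp electrodes of the extended international 10/20 system used
#' for multichannel ABR work, at idealised unit-sphere coordinates
#' (x = right, y = anterior, z = superior, Cz at the vertex), plus the left
#' and right mastoids (M1/M2, placed at 115 degrees of polar angle below the
#' T7/T8 meridian) and a physical reference electrode on the midline between
#' Cz and CPz.
#'
#' @return a [Montage-class] with 33 electrodes (30 scalp + M1 + M2 + REF).
#' @examples
#' m <- standardMontage()
#' electrodePositions(m)["Cz", ]   # the vertex, (0, 0, 1)
#' @export
standardMontage <- function() {
  pos <- list(
    # vertex and midline (azimuth +90 anterior, -90 posterior)
    Cz  = .sphPos(0, 0),
    FCz = .sphPos(18, 90),  Fz  = .sphPos(36, 90),
    CPz = .sphPos(18, -90), Pz  = .sphPos(36, -90), Oz = .sphPos(72, -90),
    # central coronal arc
    C3 = .sphPos(36, 180), C4 = .sphPos(36, 0),
    # outer 10% ring (polar angle 72), circumferential 10/20 spacing
    Fp1 = .sphPos(72, 108), Fp2 = .sphPos(72, 72),
    F7  = .sphPos(72, 144), F8  = .sphPos(72, 36),
    T7  = .sphPos(72, 180), T8  = .sphPos(72, 0),
    P7  = .sphPos(72, -144), P8 = .sphPos(72, -36),
    O1  = .sphPos(72, -108), O2 = .sphPos(72, -72),
    FT7 = .sphPos(72, 162), FT8 = .sphPos(72, 18),
    TP7 = .sphPos(72, -162), TP8 = .sphPos(72, -18)
  )
  # intermediate electrodes: great-circle midpoints of their 10/20 neighbours
  pos$F3  <- .gcMid(pos$Fz, pos$F7);   pos$F4  <- .gcMid(pos$Fz, pos$F8)
  pos$FC3 <- .gcMid(pos$FCz, pos$FT7); pos$FC4 <- .gcMid(pos$FCz, pos$FT8)
  pos$CP3 <- .gcMid(pos$CPz, pos$TP7); pos$CP4 <- .gcMid(pos$CPz, pos$TP8)
  pos$P3  <- .gcMid(pos$Pz, pos$P7);   pos$P4  <- .gcMid(pos$Pz, pos$P8)
  # mastoids below the ears and the physical reference near the vertex
  pos$M1  <- .sphPos(115, 180); pos$M2 <- .sphPos(115, 0)
  pos$REF <- .sphPos(9, -90)

  order <- c("FP1", "FP2", "F7", "F3", "Fz", "F4", "F8", "FT7", "FC3", "FCz",
             "FC4", "FT8", "T7", "C3", "Cz", "C4", "T8", "TP7", "CP3", "CPz",
             "CP4", "TP8", "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2",
             "M1", "M2", "REF")
  key <- order
  key[key == "FP1"] <- "Fp1"; key[key == "FP2"] <- "Fp2"
  P <- do.call(rbind, pos[key])
  roles <- c(rep("scalp", 30), "mastoid_left", "mastoid_right",
             "physical_reference")
  Montage(order, P, roles)
}

#' Midline channel labels
#'
#' The six electrodes arranged along the scalp midline (Fz, FCz, Cz, CPz,
#' Pz, Oz) used for waveform comparison.
#'
#' @param montage a [Montage-class]; defaults to [standardMontage()].
#' @return character vector of labels present in the montage.
#' @export
midlineChannels <- function(montage = standardMontage()) {
  intersect(.MIDLINE, montage@labels)
}

#' Electrode positions
#' @param montage a [Montage-class].
#' @return numeric matrix (electrodes x 3) of unit vectors, with labels as
#'   row names.
#' @export
electrodePositions <- function(montage) montage@positions

#' Electrode roles
#' @param montage a [Montage-class].
#' @return named character vector of roles.
#' @export
electrodeRoles <- function(montage) {
  stats::setNames(montage@roles, montage@labels)
}

#' Subset a montage by label
#' @param montage a [Montage-class].
#' @param labels labels to keep, in the requested order.
#' @return a [Montage-class].
#' @export
subsetMontage <- function(montage, labels) {
  i <- match(labels, montage@labels)
  if (anyNA(i))
    stop("labels not in montage: ", paste(labels[is.na(i)], collapse = ", "))
  Montage(montage@labels[i], montage@positions[i, , drop = FALSE],
          montage@roles[i])
}

#' Dense quasi-uniform test montage
#'
#' A synthetic cap of `n` electrodes quasi-uniformly covering the head down
#' to the mastoid level (Fibonacci lattice), used to study how
#' re-referencing fidelity varies with montage density. Not a physical cap
#' layout.
#'
#' @param n number of electrodes.
#' @param zMin lowest z covered (default: the mastoid level, cos 115 deg).
#' @return a [Montage-class] with labels `E001...`.
#' @export
denseMontage <- function(n = 128, zMin = cos(.deg2rad(115))) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - zMin) * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  P <- cbind(r * cos(phi), r * sin(phi), z)
  Montage(sprintf("E%03d", seq_len(n)), P)
}

#' Read / write electrode position files
#'
#' Whitespace-delimited text, one electrode per line: `label x y z`
#' (BESA .sfp style). Positions are validated and unit-normalised on read;
#' mastoid and reference roles are inferred from the labels M1/M2/REF
#' (case-insensitive, also A1/A2 for mastoids).
#'
#' @param path file path.
#' @return `readMontageFile` returns a [Montage-class].
#' @export
readMontageFile <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("label", "x", "y", "z"),
                           colClasses = c("character", rep("numeric", 3)))
  if (nrow(tab) == 0) stop("no electrodes in ", path)
  lab <- tab$label
  roles <- rep("scalp", nrow(tab))
  roles[toupper(lab) %in% c("M1", "A1")] <- "mastoid_left"
  roles[toupper(lab) %in% c("M2", "A2")] <- "mastoid_right"
  roles[toupper(lab) == "REF"] <- "physical_reference"
  roles[toupper(lab) == "GND"] <- "ground"
  Montage(lab, as.matrix(tab[, c("x", "y", "z")]), roles)
}

#' @rdname readMontageFile
#' @param montage a [Montage-class] to write.
#' @export
writeMontageFile <- function(montage, path) {
  p <- montage@positions
  lines <- sprintf("%s %.9f %.9f %.9f", montage@labels, p[, 1], p[, 2], p[, 3])
  writeLines(lines, path)
  invisible(path)
}

# identity string for cache keying / mismatch detection
.montageKey <- function(montage, head = NULL, layer = NULL, nTerms = NULL) {
  s <- paste(montage@labels,
             apply(round(montage@positions, 9), 1, paste, collapse = ","),
             collapse = ";")
  if (!is.null(head))
    s <- paste(s, paste(c(head@radii, head@conductivities, head@scalpRadiusM),
                        collapse = ","), sep = "|")
  if (!is.null(layer))
    s <- paste(s, nrow(layer@locations),
               round(sqrt(sum(layer@locations[1, ]^2)), 9), sep = "|")
  if (!is.null(nTerms)) s <- paste(s, nTerms, sep = "|")
  # compact rolling hash (the key only needs to detect mismatch)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%d-%d", nchar(s), h)
}
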