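# Synthetic Ramachandran reference distributions.
#
# The probability grids are generated in code as mixtures of wrapped 2-D
# Gaussians placed on the classical basins (alpha, beta, polyproline-II,
# left-handed alpha, ...), one mixture per residue case, then calibrated to
# percentile scores: P(phi, psi) is the percentage of the reference
# distribution's mass lying at or below the local density, so P ~ 100 at a
# basin mode and P ~ 0 in empty space. This mirrors how empirical
# (MolProbity-style) contours are scored, but the underlying distribution
# here is SYNTHETIC — a smooth stand-in, not mined from experimental
# structures — so absolute percentages on real models are approximate.

RAMA_CASES <- c("general", "glycine", "proline-cis", "proline-trans",
                "pre-proline", "ile-val")

# mixture components: phi, psi, sd_phi, sd_psi, weight
RAMA_MIXTURES <- list(
  general = rbind(
    c(-63, -43, 12, 13, 0.35),
    c(-90, -10, 20, 20, 0.12),
    c(-120, 130, 20, 20, 0.25),
    c(-65, 145, 13, 15, 0.20),
    c(57, 42, 10, 10, 0.05),
    c(-100, 170, 18, 18, 0.03)),
  glycine = rbind(
    c(-63, -41, 13, 13, 0.25),
    c(63, 41, 13, 13, 0.25),
    c(-90, 175, 22, 22, 0.20),
    c(90, -175, 22, 22, 0.20),
    c(-170, 175, 20, 20, 0.10)),
  `proline-cis` = rbind(
    c(-75, 155, 10, 12, 0.6),
    c(-75, -20, 10, 12, 0.4)),
  `proline-trans` = rbind(
    c(-61, -35, 10, 11, 0.5),
    c(-61, 150, 10, 14, 0.5)),
  `pre-proline` = rbind(
    c(-63, -43, 12, 13, 0.35),
    c(-120, 130, 20, 20, 0.30),
    c(-65, 145, 13, 15, 0.25),
    c(57, 42, 10, 10, 0.10)),
  `ile-val` = rbind(
    c(-63, -45, 10, 11, 0.40),
    c(-115, 125, 15, 16, 0.40),
    c(-65, 145, 12, 13, 0.20))
)

RAMA_BIN <- 2          # degrees per grid bin
RAMA_WRAP_SHIFTS <- c(-360, 0, 360)

ramaGridCache <- new.env(parent = emptyenv())

# Density of a wrapped-Gaussian mixture on vectors of angles.
ramaMixtureDensity <- function(mix, phi, psi) {
  dens <- numeric(length(phi))
  for (r in seq_len(nrow(mix))) {
    dphi <- 0
    for (s in RAMA_WRAP_SHIFTS) dphi <- dphi + exp(-((phi - mix[r, 1] + s)^2) / (2 * mix[r, 3]^2))
    dpsi <- 0
    for (s in RAMA_WRAP_SHIFTS) dpsi <- dpsi + exp(-((psi - mix[r, 2] + s)^2) / (2 * mix[r, 4]^2))
    dens <- dens + mix[r, 5] * dphi * dpsi / (2 * pi * mix[r, 3] * mix[r, 4])
  }
  dens
}

# Percentile-calibrated probability grid for one case: 181 x 181 nodes at
# 2-degree spacing spanning [-180, 180] (the last row/col duplicates the
# first for seamless wrap-around interpolation).
ramaGrid <- function(case) {
  if (!case %in% RAMA_CASES) stop("unknown Ramachandran case: ", case)
  if (!is.null(ramaGridCache[[case]])) return(ramaGridCache[[case]])
  centers <- seq(-180, 180 - RAMA_BIN, by = RAMA_BIN)  # 180 bins
  gg <- expand.grid(phi = centers, psi = centers)
  dens <- ramaMixtureDensity(RAMA_MIXTURES[[case]], gg$phi, gg$psi)
  mass <- dens / sum(dens)
  ord <- order(dens)
  cum <- numeric(length(dens))
  cum[ord] <- cumsum(mass[ord])
  P <- matrix(100 * cum, length(centers), length(centers))
  # close the torus: append wrapped first row/col so bilinear lookup is seamless
  P <- rbind(P, P[1, , drop = FALSE])
  P <- cbind(P, P[, 1, drop = FALSE])
  out <- list(nodes = c(centers, 180), P = P)
  ramaGridCache[[case]] <- out
  out
}

#' Ramachandran probability score
#'
#' Percentile score P (percent) of a (phi, psi) pair under the bundled
#' reference distribution for the given residue case, from bilinear
#' interpolation of the case's contour grid (2-degree bins, periodic in
#' both angles). Residues with P < 0.05 are outliers, 0.05 <= P < 2
#' marginal, P >= 2 favoured.
#'
#' @param case one of "general", "glycine", "proline-cis", "proline-trans",
#'   "pre-proline", "ile-val".
#' @param phi,psi backbone dihedrals, degrees (vectorized).
#' @return numeric vector of P values, percent.
#' @export
ramaProbability <- function(case, phi, psi) {
  g <- ramaGrid(case)
  phi <- wrapAngle(phi); psi <- wrapAngle(psi)
  # continuous bin coordinates over the grid cell centres
  u <- (phi - g$nodes[1]) / RAMA_BIN + 1
  v <- (psi - g$nodes[1]) / RAMA_BIN + 1
  nmax <- length(g$nodes)
  i0 <- pmin(pmax(floor(u), 1), nmax - 1)
  j0 <- pmin(pmax(floor(v), 1), nmax - 1)
  tu <- u - i0; tv <- v - j0
  idx <- cbind(i0, j0)
  P00 <- g$P[idx]
  P10 <- g$P[cbind(i0 + 1, j0)]
  P01 <- g$P[cbind(i0, j0 + 1)]
  P11 <- g$P[cbind(i0 + 1, j0 + 1)]
  (1 - tu) * (1 - tv) * P00 + tu * (1 - tv) * P10 +
    (1 - tu) * tv * P01 + tu * tv * P11
}

#' Classify a Ramachandran score
#' @param P percent score from \code{ramaProbability}
#' @return character vector: "outlier", "marginal" or "favoured"
#' @export
ramaClass <- function(P) {
  ifelse(P < 0.05, "outlier", ifelse(P < 2, "marginal", "favoured"))
}

RAMA_COL_MAROON <- c(128, 0, 32)
RAMA_COL_YELLOW <- c(255, 255, 0)
RAMA_COL_GREEN <- c(0, 128, 0)

#' Ramachandran status colour
#'
#' Maps P to an RGB colour varying as log(P): maroon at or below the
#' outlier threshold (0.05), through yellow at the geometric midpoint,
#' to pure green at the favoured threshold (2) and above.
#'
#' @param P percent score (vectorized)
#' @return character vector of hex colours
#' @export
ramaColour <- function(P) {
  lo <- log(0.05); hi <- log(2)
  t <- (log(pmax(P, 1e-6)) - lo) / (hi - lo)
  t <- pmin(pmax(t, 0), 1)
  mix <- function(a, b, w) a + (b - a) * w
  out <- character(length(P))
  firstHalf <- t <= 0.5
  w <- ifelse(firstHalf, t * 2, (t - 0.5) * 2)
  for (k in seq_along(P)) {
    a <- if (firstHalf[k]) RAMA_COL_MAROON else RAMA_COL_YELLOW
    b <- if (firstHalf[k]) RAMA_COL_YELLOW else RAMA_COL_GREEN
    cc <- round(mix(a, b, w[k]))
    out[k] <- sprintf("#%02X%02X%02X", cc[1], cc[2], cc[3])
  }
  out
}
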