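#' @importFrom methods new validObject is slot
#' @importFrom stats splinefun rnorm runif optimize setNames
#' @importFrom utils combn read.csv
NULL

DEG <- 180 / pi

#' Wrap angles into (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrapAngle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vdot <- function(a, b) rowSums(a * b)

vnorm <- function(a) sqrt(rowSums(a * a))

asMat3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

#' Measure a dihedral angle
#'
#' Returns the torsion angle defined by four points, with the IUPAC sign
#' convention (right-handed rotation looking from \code{p2} towards
#' \code{p3}); an ideal trans peptide measures 180 degrees.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees, in (-180, 180].
#' @export
measureDihedral <- function(p1, p2, p3, p4) {
  as.numeric(measureDihedralBatch(asMat3(p1), asMat3(p2), asMat3(p3), asMat3(p4)))
}

# Vectorised torsion over M quadruples (M x 3 matrices).
measureDihedralBatch <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1
  b2 <- P3 - P2
  b3 <- P4 - P3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  ln1 <- vnorm(n1)
  ln2 <- vnorm(n2)
  bad <- ln1 < 1e-10 | ln2 < 1e-10 | vnorm(b2) < 1e-10
  if (any(bad, na.rm = TRUE)) {
    stop("undefined dihedral: colinear or coincident points in quadruple(s) ",
         paste(which(bad), collapse = ", "))
  }
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- vdot(n1, n2)
  y <- -vdot(m1, n2)     # IUPAC sign: right-handed looking p2 -> p3
  wrapAngle(atan2(y, x) * DEG)
}

# Analytic gradient of the torsion (radians per Angstrom) for M quadruples.
# Returns list of four M x 3 matrices (Blondel & Karplus formulation).
dihedralGradBatch <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1
  b2 <- P3 - P2
  b3 <- P4 - P3
  m <- vcross(b1, b2)
  n <- vcross(b2, b3)
  lb2 <- vnorm(b2)
  m2 <- rowSums(m * m)
  n2 <- rowSums(n * n)
  g1 <- -m * (lb2 / m2)
  g4 <- n * (lb2 / n2)
  c12 <- vdot(b1, b2) / lb2^2
  c32 <- vdot(b3, b2) / lb2^2
  g2 <- -g1 * (1 + c12) + g4 * c32
  g3 <- -(g1 + g2 + g4)
  list(g1, g2, g3, g4)
}

# Place an atom at the given internal coordinates: bonded to c (length `bond`),
# angle a(b)c-d = `angle` deg at c with respect to b, torsion a-b-c-d = `torsion` deg.
placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle / DEG
  tor <- torsion / DEG
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  ln <- sqrt(sum(n^2))
  if (ln < 1e-10) stop("degenerate internal coordinates: a, b, c colinear")
  n <- n / ln
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotate points about the axis through `origin` with direction `axis` by `angle` deg.
rotateAboutAxis <- function(points, origin, axis, angle) {
  P <- asMat3(points)
  u <- axis / sqrt(sum(axis^2))
  th <- angle / DEG
  ct <- cos(th); st <- sin(th)
  R <- ct * diag(3) + st * rbind(c(0, -u[3], u[2]),
                                 c(u[3], 0, -u[1]),
                                 c(-u[2], u[1], 0)) +
    (1 - ct) * (u %o% u)
  sweep(sweep(P, 2, origin) %*% t(R), 2, origin, `+`)
}
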