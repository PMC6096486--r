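# Density maps as attractive potentials: MRC/CCP4 I/O, tricubic
# interpolation with analytic gradients, selection masking, and synthetic
# Gaussian-blob map generation.

#' Read an MRC/CCP4 density map
#'
#' Reads a mode-2 (float) MRC map. The grid is normalized to the internal
#' x-fastest convention whatever the file's MAPC/MAPR/MAPS axis order; the
#' origin honours both the MRC2000 ORIGIN record and NXSTART-style offsets
#' (their contributions are summed).
#'
#' @param path file path.
#' @return a \code{DensityMap}.
#' @export
readMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdrInt <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdrFlt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nc <- hdrInt[1]; nr <- hdrInt[2]; ns <- hdrInt[3]
  mode <- hdrInt[4]
  if (any(c(nc, nr, ns) <= 0) || mode != 2)
    stop("corrupt or unsupported MRC header (mode ", mode, ", dims ",
         nc, "x", nr, "x", ns, "); only mode-2 float maps are supported")
  nstart <- hdrInt[5:7]
  m <- hdrInt[8:10]
  cella <- hdrFlt[11:13]
  mapcrs <- hdrInt[17:19]
  if (!all(sort(mapcrs) == 1:3)) stop("corrupt MRC header: bad MAPC/MAPR/MAPS")
  if (any(m <= 0) || any(cella <= 0)) stop("corrupt MRC header: nonpositive cell/sampling")
  originXYZ <- hdrFlt[50:52]
  nsymbt <- hdrInt[24]
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", n = nc * nr * ns, size = 4, endian = "little")
  if (length(vals) < nc * nr * ns) stop("corrupt MRC file: truncated data block")
  arr <- array(vals, dim = c(nc, nr, ns))
  # permute (cols, rows, sections) -> (x, y, z)
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  voxel <- (cella / m)[1:3]  # cell is stated per axis already in x,y,z
  if (any(voxel <= 0)) stop("nonpositive voxel size")
  origin <- originXYZ
  # nstart counts are in (col, row, section) order; map them onto x,y,z
  startXYZ <- numeric(3)
  startXYZ[mapcrs] <- nstart
  origin <- origin + startXYZ * voxel
  newDensityMap(arr, origin, voxel)
}

#' Write an MRC/CCP4 density map
#'
#' Emits a mode-2 float map. \code{axisOrder} permutes the fast/medium/slow
#' file axes (MAPC/MAPR/MAPS); the default writes x-fastest. Whatever the
#' order, \code{readMap} recovers the identical grid.
#'
#' @param map a \code{DensityMap}.
#' @param path output path.
#' @param axisOrder integer permutation of 1:3 giving the axis stored on the
#'   (column, row, section) file axes.
#' @export
writeMap <- function(map, path, axisOrder = c(1L, 2L, 3L)) {
  stopifnot(all(sort(axisOrder) == 1:3))
  d <- dim(map@values)
  arr <- aperm(map@values, axisOrder)
  dp <- dim(arr)
  s <- map@stats
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wInt(dp)                      # NC NR NS
  wInt(2)                       # MODE
  wInt(c(0, 0, 0))              # NxSTART
  wInt(d)                       # MX MY MZ (x,y,z)
  wFlt(d * map@voxel)           # CELLA
  wFlt(c(90, 90, 90))           # CELLB
  wInt(axisOrder)               # MAPC MAPR MAPS
  wFlt(c(s$min, s$max, s$mean)) # DMIN DMAX DMEAN
  wInt(c(1, 0))                 # ISPG, NSYMBT
  wInt(rep(0, 25))              # EXTRA (words 26-49, incl. EXTTYP/NVERSION)
  wFlt(map@origin)              # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(s$sigma)                 # RMS
  wInt(0)                       # NLABL
  writeBin(raw(800), con)       # labels
  wFlt(as.vector(arr))
  invisible(path)
}

# Catmull-Rom cubic-convolution weights and their t-derivatives for t in [0,1).
cubicWeights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  list(w = cbind(-0.5 * t + t2 - 0.5 * t3,
                 1 - 2.5 * t2 + 1.5 * t3,
                 0.5 * t + 2 * t2 - 1.5 * t3,
                 -0.5 * t2 + 0.5 * t3),
       dw = cbind(-0.5 + 2 * t - 1.5 * t2,
                  -5 * t + 4.5 * t2,
                  0.5 + 4 * t - 4.5 * t2,
                  -t + 1.5 * t2))
}

#' Interpolate a density map
#'
#' Tricubic (Catmull-Rom) interpolation with the exact analytic gradient of
#' the interpolant; the interpolant is C1 and reproduces linear fields
#' exactly. Points outside the grid (or within the one-voxel interpolation
#' margin) return zero value and zero gradient and are flagged: atoms
#' outside the map feel no map force.
#'
#' @param map a \code{DensityMap}.
#' @param points numeric 3-vector or M x 3 matrix, Angstrom.
#' @return list(value = numeric(M), gradient = M x 3 (density/Angstrom),
#'   inside = logical(M)).
#' @export
interpolateMap <- function(map, points) {
  P <- asMat3(points)
  M <- nrow(P)
  d <- dim(map@values)
  g <- sweep(sweep(P, 2, map@origin), 2, map@voxel, `/`) + 1  # 1-based grid coords
  i0 <- floor(g)
  t <- g - i0
  inside <- i0[, 1] >= 2 & i0[, 1] + 2 <= d[1] &
    i0[, 2] >= 2 & i0[, 2] + 2 <= d[2] &
    i0[, 3] >= 2 & i0[, 3] + 2 <= d[3]
  value <- numeric(M)
  gradient <- matrix(0, M, 3)
  if (any(inside)) {
    ii <- which(inside)
    wx <- cubicWeights(t[ii, 1]); wy <- cubicWeights(t[ii, 2]); wz <- cubicWeights(t[ii, 3])
    v <- as.vector(map@values)
    nx <- d[1]; nxy <- d[1] * d[2]
    bx <- i0[ii, 1]; by <- i0[ii, 2]; bz <- i0[ii, 3]
    val <- numeric(length(ii)); gx <- val; gy <- val; gz <- val
    for (dz in 0:3) {
      lz <- (bz + dz - 2) * nxy
      for (dy in 0:3) {
        ly <- (by + dy - 2) * nx + lz
        wyz <- wy$w[, dy + 1] * wz$w[, dz + 1]
        dyz <- wy$dw[, dy + 1] * wz$w[, dz + 1]
        ydz <- wy$w[, dy + 1] * wz$dw[, dz + 1]
        for (dx in 0:3) {
          f <- v[bx + dx - 1 + ly]
          val <- val + f * wx$w[, dx + 1] * wyz
          gx <- gx + f * wx$dw[, dx + 1] * wyz
          gy <- gy + f * wx$w[, dx + 1] * dyz
          gz <- gz + f * wx$w[, dx + 1] * ydz
        }
      }
    }
    value[ii] <- val
    gradient[ii, ] <- cbind(gx / map@voxel[1], gy / map@voxel[2], gz / map@voxel[3])
  }
  list(value = value, gradient = gradient, inside = inside)
}

#' MDFF energy and forces of a map potential
#'
#' E = -w * sum over enabled heavy atoms of the sigma-normalized density
#' rho_hat = (rho - mean)/sigma interpolated at each atom position; the
#' force on each atom is +w * grad(rho_hat) — up the density gradient, so
#' atoms are attracted into local density maxima. Atoms outside the map
#' contribute nothing. Normalization makes the coupling w transferable
#' across maps: scaling the raw map by any positive constant leaves the
#' forces unchanged.
#'
#' @param potential a \code{DensityMapPotential}.
#' @param positions nAtoms x 3 coordinate matrix, Angstrom.
#' @param enabled logical mask of atoms feeling the map (typically the
#'   mobile heavy atoms); recycled from the potential's own mask if missing.
#' @return list(energy, forces = nAtoms x 3).
#' @export
mdffEnergy <- function(potential, positions, enabled = NULL) {
  n <- nrow(positions)
  if (is.null(enabled)) {
    enabled <- if (length(potential@enabled)) potential@enabled else rep(TRUE, n)
  }
  forces <- matrix(0, n, 3)
  idx <- which(enabled)
  if (!length(idx)) return(list(energy = 0, forces = forces))
  s <- potential@map@stats
  sigma <- if (s$sigma > 0) s$sigma else 1
  ip <- interpolateMap(potential@map, positions[idx, , drop = FALSE])
  rhoHat <- ifelse(ip$inside, (ip$value - s$mean) / sigma, 0)
  energy <- -potential@weight * sum(rhoHat)
  forces[idx, ] <- potential@weight * ip$gradient / sigma
  list(energy = energy, forces = forces)
}

#' Mask a map to the neighbourhood of a selection
#'
#' Returns a copy of the map with every voxel farther than \code{radius}
#' from all heavy atoms of the selected residues set to zero; the input map
#' is untouched. Masking is idempotent for a fixed selection and radius.
#'
#' @param map a \code{DensityMap}.
#' @param model a \code{StructureModel}.
#' @param selection residue keys (see \code{residues()}).
#' @param radius Angstrom.
#' @return a new \code{DensityMap}.
#' @export
maskMap <- function(map, model, selection, radius = 4.0) {
  if (!length(selection)) stop("empty selection")
  keep <- atomMaskFromKeys(model, selection) & !isHydrogen(model)
  if (!any(keep)) stop("selection contains no heavy atoms")
  pts <- coords(model)[keep, , drop = FALSE]
  d <- dim(map@values)
  keepVox <- array(FALSE, d)
  r2 <- radius^2
  for (a in seq_len(nrow(pts))) {
    gmin <- pmax(1, ceiling((pts[a, ] - radius - map@origin) / map@voxel) + 1)
    gmax <- pmin(d, floor((pts[a, ] + radius - map@origin) / map@voxel) + 1)
    if (any(gmin > gmax)) next
    xs <- map@origin[1] + (gmin[1]:gmax[1] - 1) * map@voxel[1]
    ys <- map@origin[2] + (gmin[2]:gmax[2] - 1) * map@voxel[2]
    zs <- map@origin[3] + (gmin[3]:gmax[3] - 1) * map@voxel[3]
    dx2 <- (xs - pts[a, 1])^2
    dy2 <- (ys - pts[a, 2])^2
    dz2 <- (zs - pts[a, 3])^2
    box <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
    keepVox[gmin[1]:gmax[1], gmin[2]:gmax[2], gmin[3]:gmax[3]] <-
      keepVox[gmin[1]:gmax[1], gmin[2]:gmax[2], gmin[3]:gmax[3]] | box
  }
  vals <- map@values
  vals[!keepVox] <- 0
  newDensityMap(vals, map@origin, map@voxel)
}

#' Synthetic density map from a model
#'
#' Sum of unit-amplitude isotropic Gaussians of width \code{resolutionSigma}
#' centred on every heavy atom, sampled on a regular grid padded around the
#' model's bounding box. Used as synthetic ground truth for
#' parameter-recovery tests.
#'
#' @param model a \code{StructureModel}.
#' @param resolutionSigma Gaussian sigma, Angstrom (> 0).
#' @param voxel grid spacing, Angstrom (> 0).
#' @param padding Angstrom of padding around the bounding box.
#' @return a \code{DensityMap}.
#' @export
mapFromModel <- function(model, resolutionSigma = 1.0, voxel = 0.5, padding = 5.0) {
  if (nAtoms(model) == 0) stop("empty model")
  if (resolutionSigma <= 0 || any(voxel <= 0)) stop("sigma and voxel must be positive")
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  pts <- coords(model)[!isHydrogen(model), , drop = FALSE]
  lo <- apply(pts, 2, min) - padding
  hi <- apply(pts, 2, max) + padding
  d <- pmax(4L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  vals <- array(0, d)
  reach <- 4 * resolutionSigma
  for (a in seq_len(nrow(pts))) {
    gmin <- pmax(1, floor((pts[a, ] - reach - lo) / voxel) + 1)
    gmax <- pmin(d, ceiling((pts[a, ] + reach - lo) / voxel) + 1)
    xs <- lo[1] + (gmin[1]:gmax[1] - 1) * voxel[1]
    ys <- lo[2] + (gmin[2]:gmax[2] - 1) * voxel[2]
    zs <- lo[3] + (gmin[3]:gmax[3] - 1) * voxel[3]
    gx <- exp(-(xs - pts[a, 1])^2 / (2 * resolutionSigma^2))
    gy <- exp(-(ys - pts[a, 2])^2 / (2 * resolutionSigma^2))
    gz <- exp(-(zs - pts[a, 3])^2 / (2 * resolutionSigma^2))
    vals[gmin[1]:gmax[1], gmin[2]:gmax[2], gmin[3]:gmax[3]] <-
      vals[gmin[1]:gmax[1], gmin[2]:gmax[2], gmin[3]:gmax[3]] +
      outer(outer(gx, gy), gz)
  }
  newDensityMap(vals, lo, voxel)
}
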