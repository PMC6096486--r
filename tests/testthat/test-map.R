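test_that("MRC maps round trip bit-faithfully within float precision", {
  m <- idealHelix(4)
  mp <- mapFromModel(m, 1.0, 0.6, 4)
  path <- tempfile(fileext = ".mrc")
  writeMap(mp, path)
  mp2 <- readMap(path)
  expect_lt(max(abs(mp@values - mp2@values)), 1e-6)
  expect_lt(max(abs(mp@origin - mp2@origin)), 1e-5)
  expect_lt(max(abs(mp@voxel - mp2@voxel)), 1e-6)
})

test_that("permuted axis order yields the same density at the same coordinate", {
  m <- idealHelix(4)
  mp <- mapFromModel(m, 1.0, 0.6, 4)
  for (ord in list(c(2L, 1L, 3L), c(3L, 1L, 2L), c(2L, 3L, 1L))) {
    path <- tempfile(fileext = ".mrc")
    writeMap(mp, path, axisOrder = ord)
    mp2 <- readMap(path)
    expect_equal(dim(mp2@values), dim(mp@values))
    expect_lt(max(abs(mp@values - mp2@values)), 1e-6)
    pt <- mp@origin + dim(mp@values) * mp@voxel / 2
    expect_equal(interpolateMap(mp2, pt)$value, interpolateMap(mp, pt)$value,
                 tolerance = 1e-6)
  }
})

test_that("corrupt headers are rejected", {
  path <- tempfile(fileext = ".mrc")
  writeBin(as.raw(rep(0, 2048)), path)
  expect_error(readMap(path), "header")
  expect_error(newDensityMap(array(0, c(3, 3, 3)), c(0, 0, 0), c(0, 1, 1)),
               "voxel")
})

test_that("interpolation reproduces constant and linear fields exactly", {
  cst <- newDensityMap(array(2.5, c(8, 8, 8)), c(0, 0, 0), c(1, 1, 1))
  set.seed(3)
  pts <- matrix(runif(60, 2, 5), ncol = 3)
  ip <- interpolateMap(cst, pts)
  expect_true(all(abs(ip$value - 2.5) < 1e-12))
  expect_lt(max(abs(ip$gradient)), 1e-12)
  # ramp rho = 0.7 x
  xs <- (0:11) * 0.5
  ramp <- newDensityMap(array(rep(0.7 * xs, times = 144), c(12, 12, 12)),
                        c(0, 0, 0), c(0.5, 0.5, 0.5))
  pts <- matrix(runif(90, 1.2, 4.2), ncol = 3)
  ip <- interpolateMap(ramp, pts)
  expect_lt(max(abs(ip$value - 0.7 * pts[, 1])), 1e-6)
  expect_lt(max(abs(ip$gradient[, 1] - 0.7)), 1e-6)
  expect_lt(max(abs(ip$gradient[, 2:3])), 1e-6)
})

test_that("interpolated gradients match finite differences of the value", {
  m <- idealHelix(3)
  mp <- mapFromModel(m, 0.8, 0.5, 4)
  set.seed(11)
  lo <- mp@origin + 2 * mp@voxel
  hi <- mp@origin + (dim(mp@values) - 3) * mp@voxel
  pts <- cbind(runif(1000, lo[1], hi[1]), runif(1000, lo[2], hi[2]),
               runif(1000, lo[3], hi[3]))
  ip <- interpolateMap(mp, pts)
  h <- 1e-5
  worst <- 0
  for (cc in 1:3) {
    pp <- pts; pp[, cc] <- pp[, cc] + h
    pm <- pts; pm[, cc] <- pm[, cc] - h
    fd <- (interpolateMap(mp, pp)$value - interpolateMap(mp, pm)$value) / (2 * h)
    big <- abs(fd) > 1e-3
    worst <- max(worst, max(abs(fd[big] - ip$gradient[big, cc]) / abs(fd[big])))
  }
  expect_lt(worst, 1e-5)
})

test_that("out-of-bounds points feel no map force and are flagged", {
  mp <- newDensityMap(array(1, c(6, 6, 6)), c(0, 0, 0), c(1, 1, 1))
  ip <- interpolateMap(mp, rbind(c(-5, 0, 0), c(2.5, 2.5, 2.5)))
  expect_false(ip$inside[1])
  expect_true(ip$inside[2])
  expect_equal(ip$value[1], 0)
  expect_equal(max(abs(ip$gradient[1, ])), 0)
})

test_that("the map potential attracts atoms into density maxima", {
  one <- buildIdealPeptide("G", "alpha")
  ctr <- coords(one)[2, ]   # CA
  blobModel <- newStructureModel(atoms(one)[2, , drop = FALSE])
  mp <- mapFromModel(blobModel, 1.0, 0.3, 6)
  pot <- densityMapPotential(mp, 10)
  atCtr <- mdffEnergy(pot, matrix(ctr, 1, 3))
  expect_lt(max(abs(atCtr$forces)), 0.3)     # near-zero at the maximum
  # line scan: energy at the centre is minimal
  ens <- vapply(seq(-2, 2, by = 0.25), function(dx)
    mdffEnergy(pot, matrix(ctr + c(dx, 0, 0), 1, 3))$energy, 0)
  expect_equal(which.min(ens), which(seq(-2, 2, by = 0.25) == 0))
  # displaced +x: force points back toward the maximum (negative x)
  disp <- mdffEnergy(pot, matrix(ctr + c(1, 0, 0), 1, 3))
  expect_lt(disp$forces[1, 1], 0)
  # linearity in the coupling weight
  pot2 <- densityMapPotential(mp, 20)
  disp2 <- mdffEnergy(pot2, matrix(ctr + c(1, 0, 0), 1, 3))
  expect_equal(disp2$energy, 2 * disp$energy, tolerance = 1e-12)
  expect_equal(disp2$forces, 2 * disp$forces, tolerance = 1e-12)
})

test_that("sigma normalization makes forces invariant to raw map scaling", {
  m <- idealHelix(3)
  mp <- mapFromModel(m, 1.0, 0.5, 4)
  scaled <- newDensityMap(mp@values * 37.5, mp@origin, mp@voxel)
  pos <- coords(m) + 0.2
  f1 <- mdffEnergy(densityMapPotential(mp, 10), pos)
  f2 <- mdffEnergy(densityMapPotential(scaled, 10), pos)
  expect_equal(f1$forces, f2$forces, tolerance = 1e-9)
})

test_that("masking zeroes exactly the voxels outside the radius", {
  one <- buildIdealPeptide("G", "alpha")
  atomRow <- 2
  blobModel <- newStructureModel(atoms(one)[atomRow, , drop = FALSE])
  # grid with the atom exactly on a grid point
  vox <- 0.5
  ctr <- coords(blobModel)[1, ]
  origin <- ctr - 10 * vox
  mp <- newDensityMap(array(1, c(21, 21, 21)), origin, rep(vox, 3))
  r <- 2.3 * vox   # not a lattice distance: no floating-point boundary ties
  masked <- maskMap(mp, blobModel, residues(blobModel)$key, radius = r)
  # brute-force sphere count oracle
  idx <- expand.grid(i = 0:20, j = 0:20, k = 0:20)
  d <- sqrt((idx$i - 10)^2 + (idx$j - 10)^2 + (idx$k - 10)^2) * vox
  expect_equal(sum(masked@values != 0), sum(d <= r))
  # huge radius: untouched; and idempotence
  all1 <- maskMap(mp, blobModel, residues(blobModel)$key, radius = 1e4)
  expect_equal(all1@values, mp@values)
  again <- maskMap(masked, blobModel, residues(blobModel)$key, radius = r)
  expect_equal(again@values, masked@values)
  expect_error(maskMap(mp, blobModel, character(0), 2), "empty")
})

test_that("synthetic maps integrate to the analytic Gaussian mass", {
  m <- buildIdealPeptide("AA", "extended")
  sigma <- 0.9; vox <- 0.35
  mp <- mapFromModel(m, sigma, vox, padding = 5)
  nHeavy <- sum(toupper(atoms(m)$elesy) != "H")
  expected <- nHeavy * (2 * pi)^1.5 * sigma^3 / vox^3
  expect_equal(sum(mp@values), expected, tolerance = 0.02)
  # single atom: global maximum at the nearest grid point
  one <- newStructureModel(atoms(m)[1, , drop = FALSE])
  mp1 <- mapFromModel(one, 1, 0.5, 4)
  peak <- which(mp1@values == max(mp1@values), arr.ind = TRUE)[1, ]
  peakPos <- mp1@origin + (peak - 1) * mp1@voxel
  expect_lt(sqrt(sum((peakPos - coords(one)[1, ])^2)), sqrt(3) * 0.5)
  expect_error(mapFromModel(m, -1, 0.5), "positive")
})

test_that("map energy decreases along its own force direction", {
  m <- idealHelix(4)
  mp <- mapFromModel(m, 1.0, 0.5, 4)
  pot <- densityMapPotential(mp, 10)
  set.seed(9)
  for (trial in 1:25) {
    pos <- coords(m) + matrix(rnorm(3 * nAtoms(m), 0, 0.3), ncol = 3)
    ef <- mdffEnergy(pot, pos)
    fnorm <- sqrt(sum(ef$forces^2))
    if (fnorm < 1e-6) next
    step <- 1e-4 / fnorm
    e2 <- mdffEnergy(pot, pos + step * ef$forces)$energy
    expect_lt(e2, ef$energy)
  }
})
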