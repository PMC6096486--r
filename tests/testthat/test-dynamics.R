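test_that("the simplified force field is near zero on an ideal fixture", {
  m <- buildIdealPeptide("ARNDCQEGHI", "alpha")
  topo <- buildTopology(m)
  ff <- forcefieldEnergy(topo, coords(m))
  # built at template geometry: bonded terms vanish (repulsion is nonbonded
  # and depends on the rotamer packing of the fixture)
  expect_true(all(ff$terms[c("bond", "angle", "planarity")] < 0.1))
  expect_true(is.finite(ff$terms["repulsion"]))
  expect_error(buildTopology(
    newStructureModel(data.frame(chain = "A", resno = 1, insert = "",
                                 resid = "XYZ", elety = "X1", elesy = "C",
                                 x = 0, y = 0, z = 0, o = 1, b = 0)),
    strict = TRUE), "unknown residue")
})

test_that("overlapping atoms are pushed apart with a capped force", {
  df <- data.frame(chain = "A", resno = 1:2, insert = "", resid = "HOH",
                   elety = "O", elesy = "O", x = c(0, 0.5), y = 0, z = 0,
                   o = 1, b = 0)
  m <- newStructureModel(df)
  topo <- buildTopology(m)
  ff <- forcefieldEnergy(topo, coords(m))
  expect_lt(ff$forces[1, 1], 0)            # pushed in -x
  expect_gt(ff$forces[2, 1], 0)
  expect_lte(max(abs(ff$forces)), topo$fcap)
})

test_that("force-field forces match finite differences away from caps", {
  set.seed(20)
  m <- buildIdealPeptide("ALSKGF", "alpha")
  topo <- buildTopology(m)
  h <- 1e-5
  worst <- 0; checks <- 0
  for (trial in 1:1000) {
    pos <- coords(m) + matrix(rnorm(3 * nAtoms(m), 0, 0.06), ncol = 3)
    ef <- forcefieldEnergy(topo, pos)
    if (max(abs(ef$forces)) > 0.5 * topo$fcap) next   # near the repulsion cap
    i <- sample(nAtoms(m), 1); cc <- sample(3, 1)
    pp <- pos; pp[i, cc] <- pp[i, cc] + h
    pm <- pos; pm[i, cc] <- pm[i, cc] - h
    fd <- -(forcefieldEnergy(topo, pp)$energy - forcefieldEnergy(topo, pm)$energy) / (2 * h)
    if (abs(fd) < 1e-1) next
    # skip configurations near the repulsion onset (non-smooth boundary)
    dm <- as.matrix(stats::dist(pos))
    if (any(abs(dm[dm > 0] - topo$sigma) < 0.01)) next
    checks <- checks + 1
    worst <- max(worst, abs(fd - ef$forces[i, cc]) / abs(fd))
  }
  expect_gt(checks, 100)
  expect_lt(worst, 1e-6)
})

test_that("total energy is the sum of the per-provider energies", {
  m <- idealHelix(6)
  mp <- mapFromModel(m, 1, 0.5, 4)
  set.seed(2)
  st <- newSimulation(m, maps = list(densityMapPotential(mp, 10)))
  pos <- coords(m) + matrix(rnorm(3 * nAtoms(m), 0, 0.1), ncol = 3)
  tot <- totalEnergyForces(st, pos)
  ff <- forcefieldEnergy(st@topology, pos)
  rs <- restraintEnergyForces(st@restraints, pos)
  mdf <- mdffEnergy(st@maps[[1]], pos, enabled = st@mobile)
  expect_equal(tot$energy, ff$energy + rs$energy + mdf$energy, tolerance = 1e-9)
})

test_that("minimization is monotone and converges where it should", {
  m <- idealHelix(8)
  st <- newSimulation(m, temperature = 0)
  # already minimal: returns essentially immediately, atoms barely move
  st2 <- minimize(st, maxSteps = 100)
  expect_lte(length(attr(st2, "trace")), 2)
  expect_lt(max(abs(st2@positions - st@positions)), 1e-4)
  # displaced atom under a position restraint returns to its spot
  target <- st@positions[12, ]
  stp <- st
  stp@restraints <- addPositionRestraint(stp@restraints, 12, target)
  stp@positions[12, ] <- target + c(0.5, 0, 0)
  stp <- minimize(stp, maxSteps = 300, forceTol = 1)
  expect_lt(sqrt(sum((stp@positions[12, ] - target)^2)), 0.05)
  expect_true(all(diff(attr(stp, "trace")) <= 1e-9))
})

test_that("zero-temperature dynamics never heats up and fixed atoms stay", {
  m <- idealHelix(10)
  r <- residues(m)
  sel <- expandSelection(m, r$key[5], nAlong = 2, radius = 4)
  set.seed(8)
  st <- newSimulation(m, mobileResidues = sel$mobile, temperature = 0)
  st@positions <- st@positions + matrix(rnorm(3 * nAtoms(m), 0, 0.05), ncol = 3) *
    st@mobile
  e0 <- totalEnergyForces(st)$energy + kineticEnergy(st)
  energies <- numeric(5)
  s <- st
  for (i in 1:5) {
    s <- langevinRun(s, 20)
    energies[i] <- totalEnergyForces(s)$energy + kineticEnergy(s)
  }
  # damped dynamics: total (potential + kinetic) energy decays between
  # coordinate updates, up to integrator discretization error
  expect_true(all(diff(c(e0, energies)) <= 1e-3 * max(abs(e0), 1)))
  expect_lt(energies[5], e0)
  fixedIdx <- which(!st@mobile)
  expect_equal(s@positions[fixedIdx, ], st@positions[fixedIdx, ])
})

test_that("Langevin dynamics is deterministic under a fixed seed", {
  m <- idealHelix(5)
  set.seed(77)
  s1 <- langevinRun(newSimulation(m, temperature = 100), 60)
  set.seed(77)
  s2 <- langevinRun(newSimulation(m, temperature = 100), 60)
  expect_identical(s1@positions, s2@positions)
})

test_that("a harmonically restrained atom equilibrates to kT/k variance", {
  df <- data.frame(chain = "A", resno = 1, insert = "", resid = "ZN",
                   elety = "ZN", elesy = "ZN", x = 0, y = 0, z = 0, o = 1, b = 0)
  m <- newStructureModel(df)
  k <- 500; temp <- 100
  set <- addPositionRestraint(restraintSet(), 1, c(0, 0, 0), k = k, fmax = 1e5)
  st <- newSimulation(m, temperature = temp, restraints = set)
  set.seed(123)
  st <- langevinRun(st, 2000)   # discard as burn-in
  xs <- matrix(0, 2000, 3)
  for (i in 1:2000) {
    st <- langevinRun(st, 10)
    xs[i, ] <- st@positions[1, ]
  }
  expected <- 0.0083145 * temp / k
  measured <- mean(apply(xs, 2, var))
  expect_lt(abs(measured - expected) / expected, 0.2)
})

test_that("checkpoints restore positions bit-identically and restraints exactly", {
  m <- idealHelix(6)
  set.seed(4)
  st <- newSimulation(m, temperature = 100)
  st <- langevinRun(st, 40)
  cp1 <- saveCheckpoint(st)
  st <- langevinRun(st, 40)
  cp2 <- saveCheckpoint(st)
  # perturb heavily, add restraints
  st@positions <- st@positions + 3
  st@restraints <- tugAtom(st@restraints, m, 3, c(0, 0, 0))
  back1 <- restoreCheckpoint(st, cp1)
  expect_identical(back1@positions, cp1@positions)
  expect_equal(back1@restraints, cp1@restraints)
  # both checkpoints stay valid in any order
  back2 <- restoreCheckpoint(back1, cp2)
  expect_identical(back2@positions, cp2@positions)
  other <- newSimulation(idealHelix(7))
  expect_error(restoreCheckpoint(other, cp1), "different model")
})

test_that("settling resolves deliberate clashes to physical separations", {
  m <- buildIdealPeptide("AAAA", "extended")
  xyz <- coords(m)
  xyz[10, ] <- xyz[15, ] + c(0.8, 0, 0)    # 0.8 A clash
  coords(m) <- xyz
  out <- settleModel(m, temperature = 0, mdSteps = 100, seed = 1)
  topo <- buildTopology(out$model)
  p <- coords(out$model)
  dm <- as.matrix(stats::dist(p)); diag(dm) <- Inf
  for (kk in topo$exclKeys) {
    ij <- as.integer(strsplit(kk, " ")[[1]])
    dm[ij[1], ij[2]] <- Inf; dm[ij[2], ij[1]] <- Inf
  }
  expect_gt(min(dm), 2.0)
  # and no map, no noise: the energy cannot rise
  e0 <- totalEnergyForces(newSimulation(m, temperature = 0))$energy
  e1 <- totalEnergyForces(out$state)$energy
  expect_lte(e1, e0)
})
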