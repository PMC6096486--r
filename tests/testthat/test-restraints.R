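test_that("flat-bottomed dihedral restraint honours its closed form", {
  # inside the flat bottom: exactly zero energy and force
  m <- idealHelix(3)
  bd <- backboneDihedrals(m)
  om <- bd[bd$kind == "omega", ][1, ]
  P <- coords(m)[c(om$i1, om$i2, om$i3, om$i4), ]
  atBoundary <- dihedralRestraintEnergy(P, target = om$angle - 30, cutoff = 30)
  expect_equal(atBoundary$energy, 0)
  expect_equal(max(abs(atBoundary$forces)), 0)
  inside <- dihedralRestraintEnergy(P, target = om$angle - 12, cutoff = 30)
  expect_equal(inside$energy, 0)
  # outside: E = k (cos cutoff - cos delta); spot value at delta = 60, k = 10
  outside <- dihedralRestraintEnergy(P, target = om$angle - 60, k = 10, cutoff = 30)
  expect_equal(outside$energy, 10 * (cos(30 * pi / 180) - cos(60 * pi / 180)),
               tolerance = 1e-9)
  expect_equal(outside$energy, 3.6603, tolerance = 1e-4)
})

test_that("the restraint gradient vanishes at the 180-degree metastable point", {
  # dE/dtheta = k sin(delta) -> 0 at delta = 180 while E is maximal
  m <- idealHelix(3)
  bd <- backboneDihedrals(m)
  om <- bd[bd$kind == "omega", ][1, ]
  P <- coords(m)[c(om$i1, om$i2, om$i3, om$i4), ]
  opp <- dihedralRestraintEnergy(P, target = wrapAngle(om$angle + 180), k = 10, cutoff = 30)
  expect_equal(abs(opp$delta), 180, tolerance = 1e-6)
  expect_lt(max(abs(opp$forces)), 1e-6)
  near <- dihedralRestraintEnergy(P, target = wrapAngle(om$angle + 120), k = 10, cutoff = 30)
  expect_gt(opp$energy, near$energy)  # maximum, not minimum
})

test_that("dihedral restraint energy is continuous and periodic in delta", {
  k <- 7; cutoff <- 25
  eOf <- function(delta) ifelse(abs(wrapAngle(delta)) <= cutoff, 0,
                                k * (cos(cutoff / 57.29578) - cos(wrapAngle(delta) / 57.29578)))
  deltas <- seq(-400, 400, by = 0.5)
  expect_equal(eOf(deltas), eOf(deltas + 360), tolerance = 1e-12)
  eps <- 1e-8
  expect_lt(abs(eOf(cutoff + eps) - eOf(cutoff - eps)), 1e-6)
})

test_that("restraint forces match central finite differences", {
  set.seed(42)
  m <- idealHelix(6)
  set <- defaultOmegaRestraints(m)
  r <- residues(m)
  ssb <- restrainSecondaryStructure(set, m, r$key[2:5], "helix")
  set <- ssb$set
  set <- tugAtom(set, m, 7, coords(m)[7, ] + c(0.5, -0.3, 0.2))
  h <- 1e-5
  worst <- 0
  checks <- 0
  for (trial in 1:1000) {
    pos <- coords(m) + matrix(rnorm(3 * nAtoms(m), 0, 0.08), ncol = 3)
    ef <- restraintEnergyForces(set, pos)
    i <- sample(nAtoms(m), 1); cc <- sample(3, 1)
    pp <- pos; pp[i, cc] <- pp[i, cc] + h
    pm <- pos; pm[i, cc] <- pm[i, cc] - h
    fd <- -(restraintEnergyForces(set, pp)$energy -
              restraintEnergyForces(set, pm)$energy) / (2 * h)
    if (abs(fd) < 1e-2) next   # skip flat-bottom interiors and distant atoms
    # skip non-smooth boundaries: recompute deltas and cap engagement
    d <- set@dihedrals
    th <- measureDihedralBatch(pos[d$i1, , drop = FALSE], pos[d$i2, , drop = FALSE],
                               pos[d$i3, , drop = FALSE], pos[d$i4, , drop = FALSE])
    if (any(abs(abs(wrapAngle(th - d$target)) - d$cutoff) < 0.5)) next
    checks <- checks + 1
    worst <- max(worst, abs(fd - ef$forces[i, cc]) / max(abs(fd), 1e-9))
  }
  expect_gt(checks, 100)
  expect_lt(worst, 1e-6)
})

test_that("capped linear force follows the harmonic-then-constant law", {
  expect_equal(linearCappedForce(3.0, 3.0, 500, 100), 0)
  expect_equal(linearCappedForce(3.05, 3.0, 500, 100), 25)
  expect_equal(linearCappedForce(4.0, 3.0, 500, 100), 100)
  expect_error(linearCappedForce(-1, 0, 500, 100), "negative")
  # the cap binds everywhere: exhaustive random sweep
  set.seed(7)
  r <- runif(5000, 0, 50); r0 <- runif(5000, 0, 10)
  k <- runif(5000, 1, 2000); fmax <- runif(5000, 1, 500)
  expect_true(all(linearCappedForce(r, r0, k, fmax) <= fmax + 1e-12))
  # energy is the consistent C1 integral: numeric derivative equals force
  rr <- seq(0.01, 10, by = 0.001)
  e <- linearCappedEnergy(rr, 3, 500, 100)
  fNum <- abs(diff(e) / diff(rr))
  fAna <- linearCappedForce((rr[-1] + rr[-length(rr)]) / 2, 3, 500, 100)
  expect_lt(max(abs(fNum - fAna)), 0.5)
})

test_that("omega restraints are the exact default set on load", {
  m <- buildIdealPeptide("ARNDCQEGHI", "alpha")
  set <- defaultOmegaRestraints(m)
  bd <- backboneDihedrals(m)
  expect_equal(nrow(set@dihedrals), sum(bd$kind == "omega"))
  expect_true(all(set@dihedrals$kind == "omega"))
  expect_true(all(set@dihedrals$cutoff == 30))
  expect_true(all(set@dihedrals$target == 180))  # trans fixture: nearer state
  expect_equal(nrow(set@linear), 0)
})

test_that("cis-trans flips toggle the omega target and are involutive", {
  m <- idealHelix(5)
  r <- residues(m)
  set <- defaultOmegaRestraints(m)
  key <- r$key[3]
  s2 <- flipCisTrans(set, m, key)
  expect_equal(s2@dihedrals$target[s2@dihedrals$resKey == key], 0)
  s3 <- flipCisTrans(s2, m, key)
  expect_equal(s3@dihedrals$target[s3@dihedrals$resKey == key], 180)
  expect_error(flipCisTrans(restraintSet(), m, key), "omega")
})

test_that("peptide-plane flips add temporary restraints 180 degrees away", {
  m <- idealHelix(6)
  r <- residues(m)
  set <- flipPeptidePlane(restraintSet(), m, r$key[3])
  expect_equal(nrow(set@dihedrals), 2)
  expect_true(all(set@dihedrals$temporary))
  phiTarget <- set@dihedrals$target[set@dihedrals$kind == "phi"]
  expect_equal(phiTarget, wrapAngle(-57 + 180), tolerance = 1)
  # satisfied targets auto-release; unsatisfied ones expire with a warning
  posFake <- coords(m)
  relNot <- autoReleaseTemporary(set, posFake, frame = 1)
  expect_equal(nrow(relNot@dihedrals), 2)   # still far from targets
  expect_warning(relExp <- autoReleaseTemporary(set, posFake, frame = 1000),
                 "not satisfied")
  expect_equal(nrow(relExp@dihedrals), 0)
})

test_that("secondary-structure bundles have the index-arithmetic counts", {
  m <- buildIdealPeptide(paste(rep("A", 16), collapse = ""), "extended")
  r <- residues(m)
  base <- restraintSet()
  ssb <- restrainSecondaryStructure(base, m, r$key[4:13], "helix")
  expect_equal(sum(ssb$set@dihedrals$kind == "phi"), 10)
  expect_equal(sum(ssb$set@dihedrals$kind == "psi"), 10)
  lin <- ssb$set@linear
  expect_equal(nrow(lin[abs(lin$r0 - 3.0) < 1e-9, ]), 6)     # O(n)-N(n+4)
  expect_equal(nrow(lin[abs(lin$r0 - 5.43) < 1e-9, ]), 8)    # CA(n)-CA(n+2)
  # 3-residue run: 1 CA-CA(+2), no O-N(+4)
  ssb3 <- restrainSecondaryStructure(restraintSet(), m, r$key[1:3], "helix")
  expect_equal(nrow(ssb3$set@linear), 1)
  # strand: no O-N restraints
  ssbS <- restrainSecondaryStructure(restraintSet(), m, r$key[4:13], "strand")
  expect_true(all(abs(ssbS$set@linear$r0 - 6.8) < 1e-9))
  # releasing restores the pre-call count exactly
  before <- nRestraints(base)
  expect_equal(nRestraints(releaseBundle(ssb$set, ssb$bundle)), before)
  expect_error(restrainSecondaryStructure(base, m, r$key[c(1, 3, 5)], "helix"),
               "contiguous")
})

test_that("rotamer targets become chi restraints with 15-degree cutoffs", {
  m <- buildIdealPeptide("ALS", "alpha")   # Ala-Leu-Ser
  r <- residues(m)
  set <- applyRotamerTarget(restraintSet(), m, r$key[2], c(-60, 180))
  expect_equal(nrow(set@dihedrals), 2)
  expect_true(all(set@dihedrals$cutoff == 15))
  set <- applyRotamerTarget(set, m, r$key[3], c(60))
  expect_equal(nrow(set@dihedrals), 3)
  # re-applying replaces, never duplicates
  set2 <- applyRotamerTarget(set, m, r$key[2], c(65, -170))
  expect_equal(nrow(set2@dihedrals), 3)
  expect_equal(sort(set2@dihedrals$target[set2@dihedrals$resKey == r$key[2]]),
               c(-170, 65))
  expect_error(applyRotamerTarget(restraintSet(), m, r$key[1]), "no chi")
  expect_error(applyRotamerTarget(restraintSet(), m, r$key[3], c(1, 2)), "too many")
})

test_that("tugging is a capped moving position restraint on heavy atoms only", {
  m <- idealHelix(4)
  pos <- coords(m)
  set <- tugAtom(restraintSet(), m, 5, pos[5, ])
  ef <- restraintEnergyForces(set, pos)
  expect_equal(max(abs(ef$forces)), 0)          # target at the atom: no force
  set <- tugAtom(set, m, 5, pos[5, ] + c(10, 0, 0))
  ef <- restraintEnergyForces(set, pos)
  expect_equal(sqrt(sum(ef$forces[5, ]^2)), 100, tolerance = 1e-9)  # cap engaged
  expect_equal(nrow(set@linear), 1)             # re-tug replaced the target
  mh <- m
  mh@atoms$elesy[2] <- "H"
  expect_error(tugAtom(restraintSet(), mh, 2, c(0, 0, 0)), "heavy")
})

test_that("restraint sets survive a JSON round trip by atom address", {
  m <- idealHelix(6)
  r <- residues(m)
  set <- defaultOmegaRestraints(m)
  set <- tugAtom(set, m, 8, c(1, 2, 3))
  ssb <- restrainSecondaryStructure(set, m, r$key[2:5], "helix")
  set <- ssb$set
  path <- tempfile(fileext = ".json")
  writeRestraints(set, m, path)
  set2 <- readRestraints(m, path)
  expect_equal(nrow(set2@dihedrals), nrow(set@dihedrals))
  expect_equal(nrow(set2@linear), nrow(set@linear))
  expect_equal(sort(set2@dihedrals$target), sort(set@dihedrals$target))
  pos <- coords(m) + 0.1
  expect_equal(restraintEnergyForces(set2, pos)$energy,
               restraintEnergyForces(set, pos)$energy, tolerance = 1e-9)
})
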