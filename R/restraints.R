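# Restraint forms and lifecycle: flat-bottomed cosine dihedral restraints,
# capped harmonic (distance / position / tug) restraints, the scripted flip
# operations built from them, secondary-structure and rotamer bundles.

DIHEDRAL_K_DEFAULT <- 250     # kJ/mol
LINEAR_K_DEFAULT <- 500       # kJ/mol/A^2
FMAX_DEFAULT <- 100           # kJ/mol/A
CUTOFF_BACKBONE <- 30         # deg, flat-bottom half-width for phi/psi/omega
CUTOFF_CHI <- 15              # deg, for side-chain chi dihedrals
FLIP_STEP_BUDGET <- 500       # coordinate updates before a temporary flip
                              # restraint is abandoned with a warning

#' Flat-bottomed dihedral restraint energy and forces
#'
#' Zero energy and force inside the flat bottom (|delta| <= cutoff); outside,
#' E = k * (cos(cutoff) - cos(delta)) with delta = wrap(theta - target).
#' The form is continuous at the boundary and has dE/dtheta = k sin(delta),
#' so the gradient vanishes at delta = 180 (a metastable point) instead of
#' the discontinuity a harmonic would give there.
#'
#' @param positions 4 x 3 matrix of the dihedral's atom positions (Angstrom).
#' @param target target angle, degrees.
#' @param k restraint constant, kJ/mol.
#' @param cutoff flat-bottom half width, degrees in [0, 180).
#' @return list(energy, forces = 4 x 3 matrix (kJ/mol/A), delta = degrees).
#' @export
dihedralRestraintEnergy <- function(positions, target, k = DIHEDRAL_K_DEFAULT,
                                    cutoff = CUTOFF_BACKBONE) {
  stopifnot(nrow(positions) == 4, k >= 0, cutoff >= 0, cutoff < 180)
  theta <- measureDihedral(positions[1, ], positions[2, ], positions[3, ], positions[4, ])
  delta <- wrapAngle(theta - target)
  forces <- matrix(0, 4, 3)
  energy <- 0
  if (abs(delta) > cutoff) {
    energy <- k * (cos(cutoff / DEG) - cos(delta / DEG))
    dEdtheta <- k * sin(delta / DEG)   # per radian
    g <- dihedralGradBatch(positions[1, , drop = FALSE], positions[2, , drop = FALSE],
                           positions[3, , drop = FALSE], positions[4, , drop = FALSE])
    for (a in 1:4) forces[a, ] <- -dEdtheta * g[[a]]
  }
  list(energy = energy, forces = forces, delta = delta)
}

#' Capped harmonic restraint force magnitude
#'
#' A simple harmonic spring close to the target, switching to a constant
#' force at larger deviations: F = min(k * |r - r0|, Fmax). The direction
#' (applied by the caller) always pulls towards the target separation or
#' point.
#'
#' @param r current distance, Angstrom (>= 0).
#' @param r0 target distance (0 for position/tug restraints).
#' @param k spring constant, kJ/mol/A^2.
#' @param fmax force cap, kJ/mol/A.
#' @return force magnitude, kJ/mol/A (vectorized over \code{r}).
#' @export
linearCappedForce <- function(r, r0 = 0, k = LINEAR_K_DEFAULT, fmax = FMAX_DEFAULT) {
  if (any(r < 0) || any(r0 < 0) || any(k < 0) || any(fmax <= 0))
    stop("linearCappedForce: negative input")
  pmin(k * abs(r - r0), fmax)
}

#' Capped harmonic restraint energy
#'
#' The consistent C1 integral of \code{linearCappedForce}: quadratic
#' 0.5*k*(r-r0)^2 below the crossover |r - r0| = Fmax/k, then linear.
#'
#' @inheritParams linearCappedForce
#' @return energy, kJ/mol (vectorized).
#' @export
linearCappedEnergy <- function(r, r0 = 0, k = LINEAR_K_DEFAULT, fmax = FMAX_DEFAULT) {
  if (any(r < 0) || any(r0 < 0) || any(k < 0) || any(fmax <= 0))
    stop("linearCappedEnergy: negative input")
  d <- abs(r - r0)
  rc <- fmax / k
  ifelse(d <= rc, 0.5 * k * d^2, 0.5 * k * rc^2 + fmax * (d - rc))
}

bumpBundle <- function(set) {
  b <- set@nextBundle
  set@nextBundle <- b + 1L
  list(set = set, bundle = b)
}

# Add (or replace) a dihedral restraint; at most one active restraint per
# (residue, kind).
addDihedralRestraint <- function(set, model, resKey, kind, target,
                                 k = DIHEDRAL_K_DEFAULT,
                                 cutoff = if (startsWith(kind, "chi")) CUTOFF_CHI else CUTOFF_BACKBONE,
                                 temporary = FALSE, bundle = NA_integer_,
                                 frame = 0L) {
  rec <- dihedralRecordFor(model, resKey, kind)
  d <- set@dihedrals
  drop <- d$resKey == resKey & d$kind == kind & d$enabled
  if (any(drop)) d <- d[!drop, , drop = FALSE]
  d <- rbind(d, data.frame(i1 = rec$i1, i2 = rec$i2, i3 = rec$i3, i4 = rec$i4,
                           kind = kind, resKey = resKey,
                           target = wrapAngle(target), cutoff = cutoff, k = k,
                           enabled = TRUE, temporary = temporary,
                           bundle = as.integer(bundle), createdFrame = as.integer(frame),
                           stringsAsFactors = FALSE))
  rownames(d) <- NULL
  set@dihedrals <- d
  validObject(set)
  set
}

# Locate the atom quadruple of a named dihedral on a residue.
dihedralRecordFor <- function(model, resKey, kind) {
  if (startsWith(kind, "chi")) {
    recs <- chiDihedrals(model, resKey)
  } else {
    recs <- backboneDihedrals(model)
  }
  hit <- recs[recs$key == resKey & recs$kind == kind, , drop = FALSE]
  if (!nrow(hit)) stop("residue ", resKey, " has no measurable ", kind, " dihedral")
  hit[1, ]
}

#' Default peptide-bond restraints on model load
#'
#' Restrains exactly the omega dihedrals (peptide-bond geometry), each to the
#' nearer planar state (0 for cis, 180 for trans), with the backbone
#' flat-bottom cutoff of 30 degrees.
#'
#' @param model a \code{StructureModel}
#' @param set an existing \code{RestraintSet} to extend (default empty)
#' @param k restraint constant, kJ/mol
#' @return a \code{RestraintSet}
#' @export
defaultOmegaRestraints <- function(model, set = restraintSet(), k = DIHEDRAL_K_DEFAULT) {
  bd <- backboneDihedrals(model)
  om <- bd[bd$kind == "omega", , drop = FALSE]
  if (!nrow(om)) return(set)
  target <- ifelse(abs(om$angle) <= 90, 0, 180)
  d <- data.frame(i1 = om$i1, i2 = om$i2, i3 = om$i3, i4 = om$i4,
                  kind = "omega", resKey = om$key, target = target,
                  cutoff = CUTOFF_BACKBONE, k = k, enabled = TRUE,
                  temporary = FALSE, bundle = NA_integer_, createdFrame = 0L,
                  stringsAsFactors = FALSE)
  set@dihedrals <- rbind(set@dihedrals, d)
  validObject(set)
  set
}

#' Flip a peptide bond between cis and trans
#'
#' Toggles the omega restraint target of the peptide bond N-terminal to the
#' given residue between 0 and 180 degrees, always choosing the planar state
#' farther from the current omega; the restraint constant is unchanged.
#'
#' @param set a \code{RestraintSet} holding an omega restraint for the residue
#' @param model a \code{StructureModel}
#' @param resKey residue key (see \code{residues()})
#' @return the updated \code{RestraintSet}
#' @export
flipCisTrans <- function(set, model, resKey) {
  d <- set@dihedrals
  idx <- which(d$resKey == resKey & d$kind == "omega" & d$enabled)
  if (!length(idx))
    stop("no omega restraint on residue ", resKey,
         " (is it chain-N-terminal, or was the default restraint removed?)")
  d$target[idx] <- ifelse(abs(d$target[idx]) < 90, 180, 0)
  set@dihedrals <- d
  set
}

#' Flip a peptide plane
#'
#' Adds two temporary dihedral restraints — on psi of the residue before and
#' phi of the given residue (the two torsions flanking the peptide bond
#' N-terminal to it) — with targets 180 degrees away from the starting
#' values. They are released automatically by \code{autoReleaseTemporary}
#' once both are satisfied within the flat-bottom cutoff, or abandoned with
#' a warning after the step budget.
#'
#' @inheritParams flipCisTrans
#' @param frame current coordinate-update counter (for the step budget)
#' @param k restraint constant, kJ/mol
#' @return the updated \code{RestraintSet}
#' @export
flipPeptidePlane <- function(set, model, resKey, frame = 0L, k = DIHEDRAL_K_DEFAULT) {
  bd <- backboneDihedrals(model)
  phiRec <- bd[bd$key == resKey & bd$kind == "phi", , drop = FALSE]
  if (!nrow(phiRec)) stop("residue ", resKey, " has no measurable phi")
  res <- proteinResidueTable(model)
  pos <- match(resKey, res$key)
  prevKey <- res$key[pos - 1L]
  psiRec <- bd[bd$key == prevKey & bd$kind == "psi", , drop = FALSE]
  if (!nrow(psiRec)) stop("no measurable psi on the preceding residue ", prevKey)
  bb <- bumpBundle(set)
  set <- bb$set
  set <- addDihedralRestraint(set, model, prevKey, "psi",
                              wrapAngle(psiRec$angle + 180), k = k,
                              temporary = TRUE, bundle = bb$bundle, frame = frame)
  addDihedralRestraint(set, model, resKey, "phi",
                       wrapAngle(phiRec$angle + 180), k = k,
                       temporary = TRUE, bundle = bb$bundle, frame = frame)
}

#' Release satisfied or expired temporary restraints
#'
#' Temporary restraint bundles (e.g. peptide-plane flips) are removed once
#' every member is within its flat-bottom cutoff of its target, or — with a
#' warning — once \code{budget} coordinate updates have elapsed since their
#' creation.
#'
#' @param set a \code{RestraintSet}
#' @param positions nAtoms x 3 coordinate matrix to measure against
#' @param frame current coordinate-update counter
#' @param budget step budget in coordinate updates
#' @return the updated \code{RestraintSet}
#' @export
autoReleaseTemporary <- function(set, positions, frame, budget = FLIP_STEP_BUDGET) {
  d <- set@dihedrals
  tmp <- which(d$temporary & d$enabled)
  if (!length(tmp)) return(set)
  theta <- measureDihedralBatch(positions[d$i1[tmp], , drop = FALSE],
                                positions[d$i2[tmp], , drop = FALSE],
                                positions[d$i3[tmp], , drop = FALSE],
                                positions[d$i4[tmp], , drop = FALSE])
  satisfied <- abs(wrapAngle(theta - d$target[tmp])) <= d$cutoff[tmp]
  dropRows <- integer(0)
  for (b in unique(d$bundle[tmp])) {
    members <- tmp[d$bundle[tmp] == b]
    if (all(satisfied[match(members, tmp)])) {
      dropRows <- c(dropRows, members)
    } else if (frame - min(d$createdFrame[members]) >= budget) {
      warning("temporary restraint bundle ", b, " not satisfied within ",
              budget, " coordinate updates; removing", call. = FALSE)
      dropRows <- c(dropRows, members)
    }
  }
  if (length(dropRows)) set@dihedrals <- d[-dropRows, , drop = FALSE]
  set
}

SS_TARGETS <- list(
  helix = list(phi = -57, psi = -47, on4 = 3.0, caca2 = 5.43),
  strand = list(phi = -119, psi = 113, on4 = NA_real_, caca2 = 6.8)
)

#' Restrain a run of residues to a secondary structure
#'
#' Adds phi/psi dihedral restraints at canonical targets for the kind
#' (helix: -57/-47; strand: -119/113) for every run residue where the
#' dihedral is measurable, plus distance restraints between O(n) and N(n+4)
#' (helix only, 3.0 A) and between CA(n) and CA(n+2) (helix 5.43 A, strand
#' 6.8 A) where both partners lie inside the run. The whole bundle is
#' removable as a unit with \code{releaseBundle}.
#'
#' @param set a \code{RestraintSet}
#' @param model a \code{StructureModel}
#' @param resKeys contiguous run of residue keys (length >= 3, one chain,
#'   consecutive and peptide-bonded)
#' @param kind "helix" or "strand"
#' @param k dihedral restraint constant, kJ/mol
#' @param kDist distance restraint constant, kJ/mol/A^2
#' @param fmax distance restraint force cap, kJ/mol/A
#' @return list(set = updated \code{RestraintSet}, bundle = bundle id)
#' @export
restrainSecondaryStructure <- function(set, model, resKeys,
                                       kind = c("helix", "strand"),
                                       k = DIHEDRAL_K_DEFAULT,
                                       kDist = LINEAR_K_DEFAULT,
                                       fmax = FMAX_DEFAULT) {
  kind <- match.arg(kind)
  res <- proteinResidueTable(model)
  pos <- match(resKeys, res$key)
  if (any(is.na(pos))) stop("selection contains non-protein or unknown residues")
  if (length(pos) < 3) stop("secondary-structure runs need at least 3 residues")
  if (any(diff(pos) != 1L))
    stop("selection is not contiguous in the model")
  bonded <- peptideBondVector(model, res)
  if (!all(bonded[pos[-length(pos)]]))
    stop("selection contains a chain break")
  tg <- SS_TARGETS[[kind]]
  bb <- bumpBundle(set)
  set <- bb$set
  bundle <- bb$bundle
  bd <- backboneDihedrals(model)
  for (key in resKeys) {
    if (nrow(bd[bd$key == key & bd$kind == "phi", ]))
      set <- addDihedralRestraint(set, model, key, "phi", tg$phi, k = k, bundle = bundle)
    if (nrow(bd[bd$key == key & bd$kind == "psi", ]))
      set <- addDihedralRestraint(set, model, key, "psi", tg$psi, k = k, bundle = bundle)
  }
  nrun <- length(pos)
  lin <- set@linear
  addDist <- function(i, j, r0) {
    lin <<- rbind(lin, data.frame(kind = "distance", i = i, j = j,
                                  tx = NA_real_, ty = NA_real_, tz = NA_real_,
                                  r0 = r0, k = kDist, fmax = fmax, enabled = TRUE,
                                  bundle = bundle, stringsAsFactors = FALSE))
  }
  if (!is.na(tg$on4) && nrun >= 5) {
    for (nIdx in 1:(nrun - 4)) {
      iO <- res$iO[pos[nIdx]]
      jN <- res$iN[pos[nIdx + 4]]
      if (!is.na(iO) && !is.na(jN)) addDist(iO, jN, tg$on4)
    }
  }
  if (nrun >= 3) {
    for (nIdx in 1:(nrun - 2)) {
      iA <- res$iCA[pos[nIdx]]
      jA <- res$iCA[pos[nIdx + 2]]
      if (!is.na(iA) && !is.na(jA)) addDist(iA, jA, tg$caca2)
    }
  }
  rownames(lin) <- NULL
  set@linear <- lin
  validObject(set)
  list(set = set, bundle = bundle)
}

#' Remove a restraint bundle
#'
#' Removes all and only the restraints created under the given bundle id.
#'
#' @param set a \code{RestraintSet}
#' @param bundle bundle id as returned by the bundle-creating operations
#' @return the updated \code{RestraintSet}
#' @export
releaseBundle <- function(set, bundle) {
  set@dihedrals <- set@dihedrals[is.na(set@dihedrals$bundle) |
                                   set@dihedrals$bundle != bundle, , drop = FALSE]
  set@linear <- set@linear[is.na(set@linear$bundle) |
                             set@linear$bundle != bundle, , drop = FALSE]
  set
}

#' Apply a rotamer target as chi dihedral restraints
#'
#' One flat-bottomed restraint per chi dihedral, cutoff 15 degrees.
#' Re-applying replaces any existing chi restraints on the residue.
#'
#' @param set a \code{RestraintSet}
#' @param model a \code{StructureModel}
#' @param resKey residue key
#' @param chiTargets numeric vector of chi targets (degrees); defaults to the
#'   bundled most-common-rotamer table
#' @param k restraint constant, kJ/mol
#' @return the updated \code{RestraintSet}
#' @export
applyRotamerTarget <- function(set, model, resKey, chiTargets = NULL,
                               k = DIHEDRAL_K_DEFAULT) {
  res <- residues(model)
  row <- res[res$key == resKey, , drop = FALSE]
  if (!nrow(row)) stop("residue not found: ", resKey)
  nc <- nChi(row$resid)
  if (nc == 0) stop(row$resid, " has no chi dihedrals")
  if (is.null(chiTargets)) chiTargets <- rotamerTargets(row$resid)
  if (length(chiTargets) > nc)
    stop("too many chi targets for ", row$resid, " (max ", nc, ")")
  for (ci in seq_along(chiTargets)) {
    set <- addDihedralRestraint(set, model, resKey, paste0("chi", ci),
                                chiTargets[ci], k = k, cutoff = CUTOFF_CHI)
  }
  set
}

#' Bundled most-common rotamer targets
#' @param resid 3-letter residue name
#' @return numeric chi target vector (degrees)
#' @export
rotamerTargets <- function(resid) {
  tab <- rotamerTable()
  hit <- tab[tab$resid == resid, , drop = FALSE]
  if (!nrow(hit)) stop("no rotamer targets for ", resid)
  as.numeric(hit[1, paste0("chi", seq_len(hit$nchi[1]))])
}

rotamerTableCache <- new.env(parent = emptyenv())
rotamerTable <- function() {
  if (is.null(rotamerTableCache$tab)) {
    path <- system.file("extdata", "rotamer_targets.csv", package = "flexfit")
    if (path == "") path <- file.path("inst", "extdata", "rotamer_targets.csv")
    rotamerTableCache$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  rotamerTableCache$tab
}

#' Tug an atom towards a point
#'
#' A moving position restraint (same capped-harmonic force law) on a single
#' heavy atom. At most one tug restraint exists per atom; re-tugging
#' replaces the target.
#'
#' @param set a \code{RestraintSet}
#' @param model a \code{StructureModel}
#' @param atom atom row index into \code{atoms(model)}
#' @param target numeric(3) target point, Angstrom
#' @param k spring constant, kJ/mol/A^2
#' @param fmax force cap, kJ/mol/A
#' @return the updated \code{RestraintSet}
#' @export
tugAtom <- function(set, model, atom, target, k = LINEAR_K_DEFAULT,
                    fmax = FMAX_DEFAULT) {
  if (isHydrogen(model)[atom]) stop("only heavy atoms may be tugged")
  l <- set@linear
  l <- l[!(l$kind == "tug" & l$i == atom), , drop = FALSE]
  l <- rbind(l, data.frame(kind = "tug", i = atom, j = NA_integer_,
                           tx = target[1], ty = target[2], tz = target[3],
                           r0 = 0, k = k, fmax = fmax, enabled = TRUE,
                           bundle = NA_integer_, stringsAsFactors = FALSE))
  rownames(l) <- NULL
  set@linear <- l
  set
}

# Plain position restraint on one atom (used by register shifts and fixtures).
addPositionRestraint <- function(set, atom, target, k = LINEAR_K_DEFAULT,
                                 fmax = FMAX_DEFAULT, bundle = NA_integer_) {
  l <- set@linear
  l <- rbind(l, data.frame(kind = "position", i = atom, j = NA_integer_,
                           tx = target[1], ty = target[2], tz = target[3],
                           r0 = 0, k = k, fmax = fmax, enabled = TRUE,
                           bundle = as.integer(bundle), stringsAsFactors = FALSE))
  rownames(l) <- NULL
  set@linear <- l
  set
}

# Remove every restraint touching any atom in `atomIdx` (used before a
# register shift takes over a selection).
removeRestraintsOnAtoms <- function(set, atomIdx) {
  d <- set@dihedrals
  if (nrow(d)) {
    touch <- d$i1 %in% atomIdx | d$i2 %in% atomIdx | d$i3 %in% atomIdx | d$i4 %in% atomIdx
    set@dihedrals <- d[!touch, , drop = FALSE]
  }
  l <- set@linear
  if (nrow(l)) {
    touch <- l$i %in% atomIdx | (!is.na(l$j) & l$j %in% atomIdx)
    set@linear <- l[!touch, , drop = FALSE]
  }
  set
}

#' Total restraint energy and forces
#'
#' Evaluates every enabled restraint in the set at the given coordinates.
#'
#' @param set a \code{RestraintSet}
#' @param positions nAtoms x 3 coordinate matrix, Angstrom
#' @return list(energy = kJ/mol, forces = nAtoms x 3 kJ/mol/A)
#' @export
restraintEnergyForces <- function(set, positions) {
  n <- nrow(positions)
  forces <- matrix(0, n, 3)
  energy <- 0
  d <- set@dihedrals[set@dihedrals$enabled, , drop = FALSE]
  if (nrow(d)) {
    P1 <- positions[d$i1, , drop = FALSE]; P2 <- positions[d$i2, , drop = FALSE]
    P3 <- positions[d$i3, , drop = FALSE]; P4 <- positions[d$i4, , drop = FALSE]
    theta <- measureDihedralBatch(P1, P2, P3, P4)
    delta <- wrapAngle(theta - d$target)
    out <- abs(delta) > d$cutoff
    if (any(out)) {
      energy <- energy + sum(d$k[out] * (cos(d$cutoff[out] / DEG) - cos(delta[out] / DEG)))
      dEdth <- d$k * sin(delta / DEG) * out   # zero inside the flat bottom
      g <- dihedralGradBatch(P1, P2, P3, P4)
      idx <- list(d$i1, d$i2, d$i3, d$i4)
      for (a in 1:4) {
        contrib <- -dEdth * g[[a]]
        for (cc in 1:3) {
          acc <- tapply(contrib[, cc], idx[[a]], sum)
          ii <- as.integer(names(acc))
          forces[ii, cc] <- forces[ii, cc] + as.numeric(acc)
        }
      }
    }
  }
  l <- set@linear[set@linear$enabled, , drop = FALSE]
  if (nrow(l)) {
    isDist <- l$kind == "distance"
    tgt <- matrix(0, nrow(l), 3)
    tgt[isDist, ] <- positions[l$j[isDist], , drop = FALSE]
    tgt[!isDist, ] <- cbind(l$tx, l$ty, l$tz)[!isDist, , drop = FALSE]
    dvec <- positions[l$i, , drop = FALSE] - tgt
    r <- sqrt(rowSums(dvec^2))
    energy <- energy + sum(linearCappedEnergy(r, l$r0, l$k, l$fmax))
    fmag <- linearCappedForce(r, l$r0, l$k, l$fmax)
    sgn <- sign(r - l$r0)       # pull towards r0
    safe <- pmax(r, 1e-12)
    fvec <- -dvec * (fmag * sgn / safe)
    for (cc in 1:3) {
      acc <- tapply(fvec[, cc], l$i, sum)
      ii <- as.integer(names(acc))
      forces[ii, cc] <- forces[ii, cc] + as.numeric(acc)
      accJ <- tapply(-fvec[, cc][isDist], l$j[isDist], sum)
      if (length(accJ)) {
        jj <- as.integer(names(accJ))
        forces[jj, cc] <- forces[jj, cc] + as.numeric(accJ)
      }
    }
  }
  list(energy = energy, forces = forces)
}
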