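# Simplified geometry-maintenance force field: harmonic bonds and angles at
# ideal values taken from the built residue templates, two-fold periodic
# planarity torsions on peptide planes, and a capped soft-sphere repulsion.
# This deliberately replaces a full biomolecular force field: its job is to
# keep stereochemistry intact while restraints and map forces do the
# steering, and the provider interface lets a full engine be plugged in.

FF_KBOND <- 3000      # kJ/mol/A^2
FF_KANGLE <- 400      # kJ/mol/rad^2
FF_KPLANAR <- 40      # kJ/mol (two-fold torsion)
FF_REP_SIGMA <- 2.7   # A, soft-sphere onset
FF_REP_EPS <- 4       # kJ/mol
FF_REP_FCAP <- 1e4    # kJ/mol/A, repulsion force cap for bad starting clashes

templateCache <- new.env(parent = emptyenv())

# Ideal coordinates of a residue type, by atom name (built once per type).
residueTemplate <- function(resid) {
  if (!is.null(templateCache[[resid]])) return(templateCache[[resid]])
  m <- buildIdealPeptide(AA_3TO1[[resid]], "extended")
  a <- m@atoms
  tpl <- coords(m)
  rownames(tpl) <- a$elety
  templateCache[[resid]] <- tpl
  tpl
}

INTER_ANGLE_THETA0 <- c("CA|C|N" = 116.2, "O|C|N" = 123.0,
                        "C|N|CA" = 121.7, "C|N|CD" = 125.0)

#' Build the simplified force-field topology of a model
#'
#' Enumerates harmonic bonds and angles (ideal values measured on built
#' ideal residue templates; inter-residue peptide values from standard
#' geometry), two-fold planarity torsions on each peptide plane, and the
#' nonbonded exclusion list (atoms within three bonds). Unknown (non
#' amino-acid) residues get no bonded terms and interact only through
#' repulsion; hydrogens are ignored entirely.
#'
#' @param model a \code{StructureModel}
#' @param strict error on unknown residue types instead of skipping them
#' @return topology list consumed by \code{forcefieldEnergy}
#' @export
buildTopology <- function(model, strict = FALSE) {
  a <- model@atoms
  n <- nrow(a)
  res <- residues(model)
  keys <- atomResidueKeys(model)
  unknown <- setdiff(unique(res$resid[!isProteinResidue(res$resid)]),
                     c("HOH", "WAT"))
  unknown <- setdiff(unknown, names(ATOMIC_MASS))
  if (strict && length(unknown))
    stop("unknown residue type(s): ", paste(unknown, collapse = ", "))

  bi <- integer(0); bj <- integer(0); br0 <- numeric(0)
  for (r in seq_len(nrow(res))) {
    if (!isProteinResidue(res$resid[r])) next
    rowIdx <- which(keys == res$key[r])
    names(rowIdx) <- a$elety[rowIdx]
    tpl <- residueTemplate(res$resid[r])
    for (bond in residueBonds(res$resid[r])) {
      i <- rowIdx[bond[1]]; j <- rowIdx[bond[2]]
      if (is.na(i) || is.na(j)) next
      bi <- c(bi, i); bj <- c(bj, j)
      br0 <- c(br0, sqrt(sum((tpl[bond[1], ] - tpl[bond[2], ])^2)))
    }
  }
  # peptide links; a tolerant cutoff so noisy (jittered) models keep their
  # connectivity — genuine chain breaks (>= one residue's worth of backbone)
  # stay unlinked
  prt <- proteinResidueTable(model)
  bonded <- peptideBondVector(model, prt, cutoff = 2.5)
  link <- which(bonded)
  if (length(link)) {
    bi <- c(bi, prt$iC[link]); bj <- c(bj, prt$iN[link + 1])
    br0 <- c(br0, rep(BB_GEOM$C_N, length(link)))
  }
  bonds <- cbind(i = bi, j = bj)
  # adjacency for angles and exclusions
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds[b, 1]]] <- c(adj[[bonds[b, 1]]], bonds[b, 2])
    adj[[bonds[b, 2]]] <- c(adj[[bonds[b, 2]]], bonds[b, 1])
  }
  ai <- integer(0); aj <- integer(0); ak <- integer(0); ath0 <- numeric(0)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    prs <- utils::combn(sort(nb), 2)
    for (p in seq_len(ncol(prs))) {
      i <- prs[1, p]; k <- prs[2, p]
      sameRes <- keys[i] == keys[j] & keys[j] == keys[k]
      if (sameRes) {
        tpl <- residueTemplate(a$resid[j])
        u <- tpl[a$elety[i], ] - tpl[a$elety[j], ]
        v <- tpl[a$elety[k], ] - tpl[a$elety[j], ]
        th0 <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * DEG
      } else {
        lookupKey <- paste(a$elety[i], a$elety[j], a$elety[k], sep = "|")
        lookupKeyRev <- paste(a$elety[k], a$elety[j], a$elety[i], sep = "|")
        th0 <- INTER_ANGLE_THETA0[lookupKey]
        if (is.na(th0)) th0 <- INTER_ANGLE_THETA0[lookupKeyRev]
        if (is.na(th0)) th0 <- 120
      }
      ai <- c(ai, i); aj <- c(aj, j); ak <- c(ak, k); ath0 <- c(ath0, th0)
    }
  }
  # peptide-plane two-fold torsions
  ti <- matrix(integer(0), 0, 4)
  if (length(link)) {
    iCA <- prt$iCA[link]; iC <- prt$iC[link]; iO <- prt$iO[link]
    jN <- prt$iN[link + 1]; jCA <- prt$iCA[link + 1]
    ok1 <- !is.na(iCA) & !is.na(jCA)
    ti <- rbind(ti, cbind(iCA, iC, jN, jCA)[ok1, , drop = FALSE])
    ok2 <- !is.na(iO) & !is.na(jCA)
    ti <- rbind(ti, cbind(iO, iC, jN, jCA)[ok2, , drop = FALSE])
  }
  # exclusions: graph distance <= 3
  excl <- new.env(hash = TRUE, parent = emptyenv())
  markExcl <- function(i, j) {
    if (i != j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  }
  for (s in seq_len(n)) {
    if (!length(adj[[s]])) next
    lvl1 <- adj[[s]]
    lvl2 <- unique(unlist(adj[lvl1]))
    lvl3 <- unique(unlist(adj[lvl2]))
    for (t in unique(c(lvl1, lvl2, lvl3))) markExcl(s, t)
  }
  heavy <- !isHydrogen(model)
  list(n = n, bonds = bonds, br0 = br0,
       angles = cbind(i = ai, j = aj, k = ak), ath0 = ath0,
       torsions = ti, exclKeys = ls(excl), heavy = heavy,
       kb = FF_KBOND, ka = FF_KANGLE, kt = FF_KPLANAR,
       sigma = FF_REP_SIGMA, eps = FF_REP_EPS, fcap = FF_REP_FCAP)
}

#' Simplified force-field energy and forces
#'
#' @param topo topology from \code{buildTopology}
#' @param positions nAtoms x 3 coordinate matrix, Angstrom
#' @return list(energy, forces, terms = named energy breakdown)
#' @export
forcefieldEnergy <- function(topo, positions) {
  n <- topo$n
  forces <- matrix(0, n, 3)
  terms <- c(bond = 0, angle = 0, planarity = 0, repulsion = 0)

  if (nrow(topo$bonds)) {
    d <- positions[topo$bonds[, 1], , drop = FALSE] - positions[topo$bonds[, 2], , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    dr <- r - topo$br0
    terms["bond"] <- 0.5 * topo$kb * sum(dr^2)
    fmag <- -topo$kb * dr / pmax(r, 1e-12)
    fv <- d * fmag
    for (cc in 1:3) {
      acc <- tapply(fv[, cc], topo$bonds[, 1], sum)
      forces[as.integer(names(acc)), cc] <- forces[as.integer(names(acc)), cc] + acc
      acc <- tapply(-fv[, cc], topo$bonds[, 2], sum)
      forces[as.integer(names(acc)), cc] <- forces[as.integer(names(acc)), cc] + acc
    }
  }

  if (nrow(topo$angles)) {
    u <- positions[topo$angles[, 1], , drop = FALSE] - positions[topo$angles[, 2], , drop = FALSE]
    v <- positions[topo$angles[, 3], , drop = FALSE] - positions[topo$angles[, 2], , drop = FALSE]
    lu <- vnorm(u); lv <- vnorm(v)
    ct <- pmin(pmax(vdot(u, v) / (lu * lv), -1 + 1e-12), 1 - 1e-12)
    th <- acos(ct)
    st <- sqrt(1 - ct^2)
    dth <- th - topo$ath0 / DEG
    terms["angle"] <- 0.5 * topo$ka * sum(dth^2)
    uh <- u / lu; vh <- v / lv
    gi <- (uh * ct - vh) / (lu * st)
    gk <- (vh * ct - uh) / (lv * st)
    coef <- -topo$ka * dth
    fvI <- gi * coef; fvK <- gk * coef
    fvJ <- -(fvI + fvK)
    idx <- list(topo$angles[, 1], topo$angles[, 3], topo$angles[, 2])
    fvs <- list(fvI, fvK, fvJ)
    for (s in 1:3) for (cc in 1:3) {
      acc <- tapply(fvs[[s]][, cc], idx[[s]], sum)
      forces[as.integer(names(acc)), cc] <- forces[as.integer(names(acc)), cc] + acc
    }
  }

  if (nrow(topo$torsions)) {
    P1 <- positions[topo$torsions[, 1], , drop = FALSE]
    P2 <- positions[topo$torsions[, 2], , drop = FALSE]
    P3 <- positions[topo$torsions[, 3], , drop = FALSE]
    P4 <- positions[topo$torsions[, 4], , drop = FALSE]
    th <- measureDihedralBatch(P1, P2, P3, P4) / DEG
    terms["planarity"] <- topo$kt * sum(1 - cos(2 * th))
    dEdth <- 2 * topo$kt * sin(2 * th)
    g <- dihedralGradBatch(P1, P2, P3, P4)
    for (s in 1:4) {
      contrib <- -dEdth * g[[s]]
      for (cc in 1:3) {
        acc <- tapply(contrib[, cc], topo$torsions[, s], sum)
        forces[as.integer(names(acc)), cc] <- forces[as.integer(names(acc)), cc] + acc
      }
    }
  }

  # soft-sphere repulsion over non-excluded heavy pairs within sigma
  hv <- which(topo$heavy)
  if (length(hv) >= 2) {
    ph <- positions[hv, , drop = FALSE]
    nh <- nrow(ph)
    # all pairs within sigma (system sizes here are desk-scale)
    dmat <- as.matrix(stats::dist(ph))
    cand <- which(dmat < topo$sigma & upper.tri(dmat), arr.ind = TRUE)
    if (nrow(cand)) {
      gi <- hv[cand[, 1]]; gj <- hv[cand[, 2]]
      kk <- paste(pmin(gi, gj), pmax(gi, gj))
      keep <- !(kk %in% topo$exclKeys)
      if (any(keep)) {
        gi <- gi[keep]; gj <- gj[keep]
        d <- positions[gi, , drop = FALSE] - positions[gj, , drop = FALSE]
        r <- pmax(sqrt(rowSums(d^2)), 0.1)
        sr <- (topo$sigma / r)^12
        terms["repulsion"] <- topo$eps * sum(sr - 1)
        fmag <- pmin(12 * topo$eps * sr / r, topo$fcap)
        fv <- d * (fmag / r)
        for (cc in 1:3) {
          acc <- tapply(fv[, cc], gi, sum)
          forces[as.integer(names(acc)), cc] <- forces[as.integer(names(acc)), cc] + acc
          acc <- tapply(-fv[, cc], gj, sum)
          forces[as.integer(names(acc)), cc] <- forces[as.integer(names(acc)), cc] + acc
        }
      }
    }
  }
  list(energy = sum(terms), forces = forces, terms = terms)
}
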