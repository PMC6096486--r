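# Geometry validation: cis/twisted peptide-bond census, Ramachandran
# classification, and model-versus-model change analysis.

OMEGA_CIS_MAX <- 30      # deg: |omega| <= 30 is cis
OMEGA_TRANS_MIN <- 150   # deg: |omega| >= 150 is trans; in between is twisted

DIHEDRAL_CHANGE_CUTOFF <- 45   # deg, per-residue "changed" threshold
RMSD_CHANGE_CUTOFF <- 2        # Angstrom, per-residue "moved" threshold

#' Classify a peptide omega dihedral
#'
#' cis for |omega| <= 30 degrees, trans for |omega| >= 150, twisted in
#' between; the three classes partition (-180, 180] exactly.
#'
#' @param omega degrees (vectorized, finite)
#' @param cisMax,transMin class thresholds, degrees
#' @return character vector: "cis", "twisted" or "trans"
#' @export
classifyOmega <- function(omega, cisMax = OMEGA_CIS_MAX, transMin = OMEGA_TRANS_MIN) {
  if (any(!is.finite(omega))) stop("non-finite omega")
  a <- abs(wrapAngle(omega))
  ifelse(a <= cisMax, "cis", ifelse(a >= transMin, "trans", "twisted"))
}

#' Cis and twisted peptide-bond report
#'
#' Lists every non-trans peptide bond in the model (one entry per omega
#' dihedral classified cis or twisted), with cis bonds split into proline
#' and nonproline, and summary counts.
#'
#' @param model a \code{StructureModel}
#' @return list(table = data.frame(key, chain, resno, insert, resid, omega,
#'   class, proline), counts = named numeric(cis_nonproline, cis_proline,
#'   twisted, trans, total))
#' @export
peptideBondReport <- function(model) {
  bd <- backboneDihedrals(model)
  om <- bd[bd$kind == "omega", , drop = FALSE]
  cls <- if (nrow(om)) classifyOmega(om$angle) else character(0)
  pro <- om$resid == "PRO"
  tab <- data.frame(key = om$key, chain = om$chain, resno = om$resno,
                    insert = om$insert, resid = om$resid, omega = om$angle,
                    class = cls, proline = pro, stringsAsFactors = FALSE)
  counts <- c(cis_nonproline = sum(cls == "cis" & !pro),
              cis_proline = sum(cls == "cis" & pro),
              twisted = sum(cls == "twisted"),
              trans = sum(cls == "trans"),
              total = nrow(om))
  list(table = tab[tab$class != "trans", , drop = FALSE], counts = counts)
}

# Residue-specific Ramachandran case assignment for residues with phi+psi.
ramaCaseOf <- function(resid, isPrePro, omegaClass) {
  ifelse(resid == "PRO", ifelse(omegaClass == "cis", "proline-cis", "proline-trans"),
         ifelse(resid == "GLY", "glycine",
                ifelse(isPrePro, "pre-proline",
                       ifelse(resid %in% c("ILE", "VAL"), "ile-val", "general"))))
}

#' Ramachandran report
#'
#' Classifies every protein residue with measurable phi and psi using the
#' bundled case-specific contour grids (general, Gly, cis-Pro, trans-Pro,
#' pre-Pro, Ile/Val) and returns per-residue scores, classes and status
#' colours plus summary fractions.
#'
#' @param model a \code{StructureModel}
#' @return list(table = per-residue data.frame, summary = named numeric
#'   percentages (favoured, marginal, outlier) over classified residues)
#' @export
ramaReport <- function(model) {
  bd <- backboneDihedrals(model)
  phi <- bd[bd$kind == "phi", c("key", "resid", "chain", "resno", "insert", "angle")]
  psi <- bd[bd$kind == "psi", c("key", "angle")]
  om <- bd[bd$kind == "omega", c("key", "angle")]
  tab <- merge(phi, psi, by = "key", suffixes = c(".phi", ".psi"))
  if (!nrow(tab)) {
    return(list(table = data.frame(), summary = c(favoured = NaN, marginal = NaN, outlier = NaN)))
  }
  names(tab)[names(tab) == "angle.phi"] <- "phi"
  names(tab)[names(tab) == "angle.psi"] <- "psi"
  omCls <- classifyOmega(om$angle)[match(tab$key, om$key)]
  omCls[is.na(omCls)] <- "trans"
  res <- proteinResidueTable(model)
  pos <- match(tab$key, res$key)
  bonded <- peptideBondVector(model, res)
  nextIsPro <- pos < nrow(res) & res$resid[pmin(pos + 1, nrow(res))] == "PRO" &
    c(bonded, FALSE)[pos]
  tab$case <- ramaCaseOf(tab$resid, nextIsPro, omCls)
  tab$P <- NA_real_
  for (cs in unique(tab$case)) {
    sel <- tab$case == cs
    tab$P[sel] <- ramaProbability(cs, tab$phi[sel], tab$psi[sel])
  }
  tab$class <- ramaClass(tab$P)
  tab$colour <- ramaColour(tab$P)
  n <- nrow(tab)
  summary <- c(favoured = 100 * sum(tab$class == "favoured") / n,
               marginal = 100 * sum(tab$class == "marginal") / n,
               outlier = 100 * sum(tab$class == "outlier") / n)
  tab <- tab[order(match(tab$key, res$key)), ]
  rownames(tab) <- NULL
  list(table = tab, summary = summary)
}

kabschRotation <- function(X, Y) {
  # rotation + translation mapping X onto Y (row-matched point sets)
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, cx = cx, cy = cy)
}

#' Compare two models residue by residue
#'
#' Matches residues by (chain, residue number, insertion code) and reports
#' wrapped changes in phi, psi and omega plus the per-residue heavy-atom
#' RMSD over atoms present in both models. A residue is flagged
#' \code{dihedralChanged} if any |delta| > 45 degrees, \code{moved} if
#' RMSD > 2 Angstrom, and \code{combined} if either. No superposition is
#' applied by default (models refined against the same map share a frame);
#' set \code{superpose = TRUE} to least-squares fit on shared CA atoms
#' first.
#'
#' @param a,b \code{StructureModel} objects
#' @param superpose logical, align b onto a by shared CA atoms first
#' @param dihedralCutoff,rmsdCutoff flag thresholds (degrees / Angstrom)
#' @return list(table = per-residue data.frame, summary = named numeric,
#'   unmatched = list(a = keys only in a, b = keys only in b))
#' @export
compareModels <- function(a, b, superpose = FALSE,
                          dihedralCutoff = DIHEDRAL_CHANGE_CUTOFF,
                          rmsdCutoff = RMSD_CHANGE_CUTOFF) {
  resA <- residues(a)
  resB <- residues(b)
  shared <- intersect(resA$key, resB$key)
  if (!length(shared)) stop("no residues in common between the two models")
  xyzB <- coords(b)
  if (superpose) {
    keysA <- atomResidueKeys(a); keysB <- atomResidueKeys(b)
    atA <- a@atoms; atB <- b@atoms
    idA <- paste(keysA, atA$elety); idB <- paste(keysB, atB$elety)
    caA <- which(atA$elety == "CA" & keysA %in% shared)
    m <- match(idA[caA], idB)
    ok <- !is.na(m)
    if (sum(ok) >= 3) {
      fit <- kabschRotation(xyzB[m[ok], , drop = FALSE], coords(a)[caA[ok], , drop = FALSE])
      xyzB <- sweep(sweep(xyzB, 2, fit$cx) %*% t(fit$R), 2, fit$cy, `+`)
    }
  }
  dihA <- backboneDihedrals(a)
  dihB <- backboneDihedrals(b)
  angleOf <- function(d, keys, kind) d$angle[d$kind == kind][match(keys, d$key[d$kind == kind])]
  dPhi <- abs(wrapAngle(angleOf(dihB, shared, "phi") - angleOf(dihA, shared, "phi")))
  dPsi <- abs(wrapAngle(angleOf(dihB, shared, "psi") - angleOf(dihA, shared, "psi")))
  dOmega <- abs(wrapAngle(angleOf(dihB, shared, "omega") - angleOf(dihA, shared, "omega")))

  keysA <- atomResidueKeys(a); keysB <- atomResidueKeys(b)
  heavyA <- !isHydrogen(a); heavyB <- !isHydrogen(b)
  idA <- paste(keysA, a@atoms$elety); idB <- paste(keysB, b@atoms$elety)
  mAB <- match(idA, idB)
  okAtom <- heavyA & !is.na(mAB) & keysA %in% shared
  d2 <- rowSums((coords(a)[okAtom, , drop = FALSE] - xyzB[mAB[okAtom], , drop = FALSE])^2)
  agg <- tapply(d2, keysA[okAtom], mean)
  rmsd <- sqrt(as.numeric(agg))[match(shared, names(agg))]

  rowA <- match(shared, resA$key)
  tab <- data.frame(key = shared, chain = resA$chain[rowA], resno = resA$resno[rowA],
                    insert = resA$insert[rowA], resid = resA$resid[rowA],
                    dPhi = dPhi, dPsi = dPsi, dOmega = dOmega, rmsd = rmsd,
                    stringsAsFactors = FALSE)
  tab$dihedralChanged <- pmax(ifelse(is.na(dPhi), 0, dPhi),
                              ifelse(is.na(dPsi), 0, dPsi),
                              ifelse(is.na(dOmega), 0, dOmega)) > dihedralCutoff
  tab$moved <- !is.na(tab$rmsd) & tab$rmsd > rmsdCutoff
  tab$combined <- tab$dihedralChanged | tab$moved
  nPhiPsi <- sum(!is.na(dPhi)) + sum(!is.na(dPsi))
  summary <- c(
    n_residues = length(shared),
    phi_psi_changed_pct = 100 * (sum(dPhi > dihedralCutoff, na.rm = TRUE) +
                                   sum(dPsi > dihedralCutoff, na.rm = TRUE)) / max(nPhiPsi, 1),
    omega_changed_pct = 100 * sum(dOmega > dihedralCutoff, na.rm = TRUE) /
      max(sum(!is.na(dOmega)), 1),
    moved_pct = 100 * sum(tab$moved) / length(shared),
    combined_pct = 100 * sum(tab$combined) / length(shared))
  list(table = tab, summary = summary,
       unmatched = list(a = setdiff(resA$key, shared), b = setdiff(resB$key, shared)))
}
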