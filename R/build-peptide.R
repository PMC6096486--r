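# Synthetic ideal-peptide fixture generator. Backbone built by chained
# internal-coordinate (NeRF) placement at canonical phi/psi for the requested
# conformation, all omega trans-planar; side chains built from the bundled
# internal-coordinate recipes at most-common rotamer chi targets.

CANONICAL_PHIPSI <- list(alpha = c(-57, -47), beta = c(-119, 113),
                         extended = c(180, 180))

#' Build an ideal polypeptide
#'
#' Constructs a single-chain model with ideal bond lengths and angles, the
#' backbone at canonical phi/psi for the chosen conformation (alpha: -57/-47,
#' beta: -119/113, extended: 180/180) and every peptide bond trans
#' (omega = 180). Side chains are placed at most-common rotamer targets.
#' Hydrogens are not built.
#'
#' @param sequence one-letter amino-acid sequence (standard residues only).
#' @param conformation "alpha", "beta" or "extended".
#' @param chain chain identifier.
#' @return a \code{StructureModel}.
#' @export
buildIdealPeptide <- function(sequence, conformation = c("alpha", "beta", "extended"),
                              chain = "A") {
  conformation <- match.arg(conformation)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) stop("empty sequence")
  bad <- setdiff(letters1, names(AA_1TO3))
  if (length(bad)) stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  res3 <- AA_1TO3[letters1]
  phipsi <- CANONICAL_PHIPSI[[conformation]]
  phi <- phipsi[1]; psi <- phipsi[2]
  g <- BB_GEOM
  n <- length(res3)

  rows <- list()
  addAtom <- function(resno, resid, name, pos) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = resid, elety = name,
      elesy = elementFromName(name), x = pos[1], y = pos[2], z = pos[3],
      o = 1, b = 0, stringsAsFactors = FALSE)
  }

  ang <- g$ang_N_CA_C / (180 / pi)
  prev <- NULL
  for (i in seq_len(n)) {
    rn <- res3[[i]]
    if (i == 1) {
      N <- c(0, 0, 0)
      CA <- c(g$N_CA, 0, 0)
      C <- CA + g$CA_C * c(cos(pi - ang), sin(pi - ang), 0)
    } else {
      N <- placeAtom(prev$N, prev$CA, prev$C, g$C_N, g$ang_CA_C_N, psi)
      CA <- placeAtom(prev$CA, prev$C, N, g$N_CA, g$ang_C_N_CA, 180)
      C <- placeAtom(prev$C, N, CA, g$CA_C, g$ang_N_CA_C, phi)
    }
    O <- placeAtom(N, CA, C, g$C_O, g$ang_CA_C_O, wrapAngle(psi + 180))
    addAtom(i, rn, "N", N); addAtom(i, rn, "CA", CA)
    addAtom(i, rn, "C", C); addAtom(i, rn, "O", O)
    pos <- list(N = N, CA = CA, C = C, O = O)
    if (rn != "GLY") {
      pos$CB <- placeAtom(C, N, CA, g$CA_CB, g$ang_N_CA_CB, g$tor_CB)
      addAtom(i, rn, "CB", pos$CB)
      chi <- DEFAULT_CHI[[rn]]
      for (z in SIDECHAIN_Z[[rn]]) {
        p <- placeAtom(pos[[z$torsionRef]], pos[[z$angleVia]], pos[[z$bondTo]],
                       z$r, z$theta, resolveTau(z$tau, chi))
        pos[[z$name]] <- p
        addAtom(i, rn, z$name, p)
      }
    }
    prev <- pos
  }
  atomsDf <- do.call(rbind, rows)
  atomsDf$ss <- switch(conformation, alpha = "helix", beta = "strand", extended = "coil")
  newStructureModel(atomsDf, title = sprintf("ideal %s %s-mer", conformation, n))
}
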