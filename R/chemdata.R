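# Chemical reference data: residue topology templates, side-chain internal
# coordinates, chi-dihedral definitions and atomic masses. Heavy atoms only;
# models with hydrogens are tolerated everywhere but hydrogens are never built.

AA_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA_3TO1 <- setNames(names(AA_1TO3), AA_1TO3)

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, SE = 78.971, ZN = 65.38, MG = 24.305,
                 FE = 55.845, CA = 40.078, MN = 54.938, `NA` = 22.990,
                 K = 39.098, CL = 35.45, F = 18.998, BR = 79.904, I = 126.904)

KNOWN_ELEMENTS <- names(ATOMIC_MASS)

# Backbone ideal geometry (Angstrom / degrees), standard Engh-Huber-like values.
BB_GEOM <- list(
  N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231, CA_CB = 1.532,
  ang_C_N_CA = 121.7, ang_N_CA_C = 111.2, ang_CA_C_N = 116.2,
  ang_CA_C_O = 120.8, ang_O_C_N = 123.0, ang_N_CA_CB = 110.5,
  # improper torsion C-N-CA-CB fixing L-chirality
  tor_CB = -122.7
)

# chi dihedral atom-name quadruples per residue type (chi1..chi4)
CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

# Side-chain internal-coordinate recipes beyond CB. Each row:
# name, bondTo, angleVia, torsionRef, bond length, angle, torsion.
# Torsions are either numeric (degrees) or strings "chiK" / "chiK+off".
zrow <- function(name, bondTo, angleVia, torsionRef, r, theta, tau) {
  list(name = name, bondTo = bondTo, angleVia = angleVia,
       torsionRef = torsionRef, r = r, theta = theta, tau = tau)
}

SIDECHAIN_Z <- list(
  ALA = list(),
  ARG = list(
    zrow("CG", "CB", "CA", "N", 1.52, 114.1, "chi1"),
    zrow("CD", "CG", "CB", "CA", 1.52, 111.3, "chi2"),
    zrow("NE", "CD", "CG", "CB", 1.46, 112.0, "chi3"),
    zrow("CZ", "NE", "CD", "CG", 1.33, 124.2, "chi4"),
    zrow("NH1", "CZ", "NE", "CD", 1.33, 120.0, 0),
    zrow("NH2", "CZ", "NE", "CD", 1.33, 120.0, 180)),
  ASN = list(
    zrow("CG", "CB", "CA", "N", 1.52, 112.6, "chi1"),
    zrow("OD1", "CG", "CB", "CA", 1.23, 120.8, "chi2"),
    zrow("ND2", "CG", "CB", "CA", 1.33, 116.4, "chi2+180")),
  ASP = list(
    zrow("CG", "CB", "CA", "N", 1.52, 112.6, "chi1"),
    zrow("OD1", "CG", "CB", "CA", 1.25, 118.4, "chi2"),
    zrow("OD2", "CG", "CB", "CA", 1.25, 118.4, "chi2+180")),
  CYS = list(
    zrow("SG", "CB", "CA", "N", 1.81, 114.4, "chi1")),
  GLN = list(
    zrow("CG", "CB", "CA", "N", 1.52, 114.1, "chi1"),
    zrow("CD", "CG", "CB", "CA", 1.52, 112.6, "chi2"),
    zrow("OE1", "CD", "CG", "CB", 1.23, 120.8, "chi3"),
    zrow("NE2", "CD", "CG", "CB", 1.33, 116.4, "chi3+180")),
  GLU = list(
    zrow("CG", "CB", "CA", "N", 1.52, 114.1, "chi1"),
    zrow("CD", "CG", "CB", "CA", 1.52, 112.6, "chi2"),
    zrow("OE1", "CD", "CG", "CB", 1.25, 118.4, "chi3"),
    zrow("OE2", "CD", "CG", "CB", 1.25, 118.4, "chi3+180")),
  GLY = list(),
  HIS = list(
    zrow("CG", "CB", "CA", "N", 1.49, 113.7, "chi1"),
    zrow("ND1", "CG", "CB", "CA", 1.38, 122.7, "chi2"),
    zrow("CD2", "CG", "CB", "CA", 1.36, 131.1, "chi2+180"),
    zrow("CE1", "ND1", "CG", "CB", 1.32, 109.3, 180),
    zrow("NE2", "CD2", "CG", "CB", 1.37, 107.2, 180)),
  ILE = list(
    zrow("CG1", "CB", "CA", "N", 1.53, 110.4, "chi1"),
    zrow("CG2", "CB", "CA", "N", 1.52, 110.5, "chi1-122.6"),
    zrow("CD1", "CG1", "CB", "CA", 1.51, 113.9, "chi2")),
  LEU = list(
    zrow("CG", "CB", "CA", "N", 1.53, 116.3, "chi1"),
    zrow("CD1", "CG", "CB", "CA", 1.52, 110.7, "chi2"),
    zrow("CD2", "CG", "CB", "CA", 1.52, 110.7, "chi2+122.6")),
  LYS = list(
    zrow("CG", "CB", "CA", "N", 1.52, 114.1, "chi1"),
    zrow("CD", "CG", "CB", "CA", 1.52, 111.3, "chi2"),
    zrow("CE", "CD", "CG", "CB", 1.52, 111.3, "chi3"),
    zrow("NZ", "CE", "CD", "CG", 1.49, 111.9, "chi4")),
  MET = list(
    zrow("CG", "CB", "CA", "N", 1.52, 114.1, "chi1"),
    zrow("SD", "CG", "CB", "CA", 1.80, 112.7, "chi2"),
    zrow("CE", "SD", "CG", "CB", 1.79, 100.8, "chi3")),
  PHE = list(
    zrow("CG", "CB", "CA", "N", 1.50, 113.8, "chi1"),
    zrow("CD1", "CG", "CB", "CA", 1.39, 120.0, "chi2"),
    zrow("CD2", "CG", "CB", "CA", 1.39, 120.0, "chi2+180"),
    zrow("CE1", "CD1", "CG", "CB", 1.39, 120.0, 180),
    zrow("CE2", "CD2", "CG", "CB", 1.39, 120.0, 180),
    zrow("CZ", "CE1", "CD1", "CG", 1.39, 120.0, 0)),
  PRO = list(
    zrow("CG", "CB", "CA", "N", 1.50, 104.5, "chi1"),
    zrow("CD", "CG", "CB", "CA", 1.51, 106.1, "chi2")),
  SER = list(
    zrow("OG", "CB", "CA", "N", 1.42, 111.1, "chi1")),
  THR = list(
    zrow("OG1", "CB", "CA", "N", 1.43, 109.6, "chi1"),
    zrow("CG2", "CB", "CA", "N", 1.52, 110.5, "chi1-120")),
  TRP = list(
    zrow("CG", "CB", "CA", "N", 1.50, 113.8, "chi1"),
    zrow("CD1", "CG", "CB", "CA", 1.37, 126.9, "chi2"),
    zrow("CD2", "CG", "CB", "CA", 1.43, 126.8, "chi2+180"),
    zrow("NE1", "CD1", "CG", "CB", 1.38, 110.1, 180),
    zrow("CE2", "CD2", "CG", "CB", 1.41, 107.2, 180),
    zrow("CE3", "CD2", "CG", "CB", 1.40, 133.9, 0),
    zrow("CZ2", "CE2", "CD2", "CG", 1.40, 122.4, 180),
    zrow("CZ3", "CE3", "CD2", "CG", 1.39, 118.6, 180),
    zrow("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, 0)),
  TYR = list(
    zrow("CG", "CB", "CA", "N", 1.51, 113.8, "chi1"),
    zrow("CD1", "CG", "CB", "CA", 1.39, 120.0, "chi2"),
    zrow("CD2", "CG", "CB", "CA", 1.39, 120.0, "chi2+180"),
    zrow("CE1", "CD1", "CG", "CB", 1.39, 120.0, 180),
    zrow("CE2", "CD2", "CG", "CB", 1.39, 120.0, 180),
    zrow("CZ", "CE1", "CD1", "CG", 1.39, 120.0, 0),
    zrow("OH", "CZ", "CE1", "CD1", 1.38, 120.0, 180)),
  VAL = list(
    zrow("CG1", "CB", "CA", "N", 1.52, 110.4, "chi1"),
    zrow("CG2", "CB", "CA", "N", 1.52, 110.4, "chi1+122.6"))
)

# Ring-closure bonds not expressed in the Z-matrix (maintained by the
# force field; built to ~0.1 A of ideal by the recipes above).
RING_CLOSURE <- list(
  PRO = list(c("CD", "N", 1.474)),
  PHE = list(c("CZ", "CE2", 1.39)),
  TYR = list(c("CZ", "CE2", 1.39)),
  HIS = list(c("CE1", "NE2", 1.33)),
  TRP = list(c("NE1", "CE2", 1.37), c("CH2", "CZ3", 1.37))
)

# Most-common rotamer chi targets used when building ideal side chains and as
# the bundled minimal rotamer target table (approximate canonical values).
DEFAULT_CHI <- list(
  ARG = c(-67, 180, 65, 85), ASN = c(-65, -60), ASP = c(-70, -15),
  CYS = c(-65), GLN = c(-67, 180, -25), GLU = c(-67, 180, -10),
  HIS = c(-65, -70), ILE = c(-65, 170), LEU = c(-65, 175),
  LYS = c(-67, 180, 180, 180), MET = c(-67, 180, 75), PHE = c(-65, 90),
  # PRO torsions solved so the CD-N ring closure lands at 1.474 A
  PRO = c(-2.092, -12.338), SER = c(64), THR = c(62), TRP = c(-65, 100),
  TYR = c(-65, 90), VAL = c(175)
)

elementFromName <- function(elety) {
  # Derive the element from a PDB atom name when the element column is absent.
  nm <- gsub("[0-9']", "", toupper(trimws(elety)))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("SE", "ZN", "MG", "FE", "MN", "CL", "BR", "NA"),
                two, substr(nm, 1, 1))
  out[out == ""] <- "C"
  out
}

atomMass <- function(element) {
  m <- ATOMIC_MASS[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

nChi <- function(resid) {
  n <- lengths(CHI_ATOMS)[resid]
  n[is.na(n)] <- 0L
  unname(n)
}

resolveTau <- function(tau, chi) {
  if (is.numeric(tau)) return(tau)
  m <- regmatches(tau, regexec("^chi([0-9])([+-][0-9.]+)?$", tau))[[1]]
  base <- chi[as.integer(m[2])]
  off <- if (m[3] == "") 0 else as.numeric(m[3])
  wrapAngle(base + off)
}

# Intra-residue heavy-atom bond list (name pairs) for a residue type,
# including backbone and ring closures.
residueBonds <- function(resid) {
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (resid != "GLY") bonds <- c(bonds, list(c("CA", "CB")))
  for (z in SIDECHAIN_Z[[resid]]) bonds <- c(bonds, list(c(z$bondTo, z$name)))
  for (cl in RING_CLOSURE[[resid]]) bonds <- c(bonds, list(cl[1:2]))
  bonds
}
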