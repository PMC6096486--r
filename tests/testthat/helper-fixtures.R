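# Shared fixtures and independent oracles used across the suite.

idealHelix <- function(n = 20, seq1 = "A") {
  buildIdealPeptide(paste(rep(seq1, n), collapse = ""), "alpha")
}

# Independent brute-force torsion oracle: the textbook two-argument
# formulation over explicit plane normals, coded separately from the
# package's vectorised implementation.
bruteForceDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  y <- sum(sqrt(sum(b2^2)) * b1 * n2)
  x <- sum(n1 * n2)
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

heavyRmsd <- function(a, b) {
  ha <- toupper(atoms(a)$elesy) != "H"
  sqrt(mean(rowSums((coords(a)[ha, , drop = FALSE] - coords(b)[ha, , drop = FALSE])^2)))
}

# A handcrafted two-residue (Gly-Ala) PDB text, 9 atoms.
glyAlaPdbText <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       3.988   2.831   0.051  1.00  0.00           C",
    "ATOM      7  C   ALA A   2       5.489   2.705   0.151  1.00  0.00           C",
    "ATOM      8  O   ALA A   2       6.030   1.600   0.251  1.00  0.00           O",
    "ATOM      9  CB  ALA A   2       3.671   3.683  -1.181  1.00  0.00           C",
    "END")
}

writeGlyAlaPdb <- function() {
  path <- tempfile(fileext = ".pdb")
  writeLines(glyAlaPdbText(), path)
  path
}
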