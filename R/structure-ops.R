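# Measurement and selection logic on StructureModel objects.

PEPTIDE_BOND_CUTOFF <- 1.8  # Angstrom; C(i)-N(i+1) closer than this = bonded

isProteinResidue <- function(resid) resid %in% names(AA_3TO1)

# Residue table restricted to amino acids, annotated with backbone atom row
# indices (NA where missing).
proteinResidueTable <- function(model) {
  res <- residues(model)
  res <- res[isProteinResidue(res$resid), , drop = FALSE]
  if (!nrow(res)) {
    res$iN <- res$iCA <- res$iC <- res$iO <- integer(0)
    return(res)
  }
  res$iN <- atomIndexIn(model, res, "N")
  res$iCA <- atomIndexIn(model, res, "CA")
  res$iC <- atomIndexIn(model, res, "C")
  res$iO <- atomIndexIn(model, res, "O")
  rownames(res) <- NULL
  res
}

# For consecutive protein residues within a chain, TRUE where a peptide bond
# exists (C-N distance below the detection cutoff). Length nrow(res) - 1;
# entry i refers to the bond res[i] -> res[i+1].
peptideBondVector <- function(model, res = proteinResidueTable(model),
                              cutoff = PEPTIDE_BOND_CUTOFF) {
  n <- nrow(res)
  if (n < 2) return(logical(0))
  xyz <- coords(model)
  sameChain <- res$chain[-n] == res$chain[-1]
  iC <- res$iC[-n]
  iN <- res$iN[-1]
  ok <- sameChain & !is.na(iC) & !is.na(iN)
  d <- rep(NA_real_, n - 1)
  d[ok] <- sqrt(rowSums((xyz[iC[ok], , drop = FALSE] - xyz[iN[ok], , drop = FALSE])^2))
  !is.na(d) & d < cutoff
}

#' Backbone dihedrals of a model
#'
#' One phi, psi and omega record per protein residue where the defining atoms
#' exist and the required peptide bond is present (C-N < 1.8 Angstrom);
#' chain termini and gaps simply yield absent records. omega of residue i is
#' the CA(i-1)-C(i-1)-N(i)-CA(i) torsion.
#'
#' @param model a \code{StructureModel}
#' @return data.frame with columns \code{key}, \code{chain}, \code{resno},
#'   \code{insert}, \code{resid}, \code{kind} (phi/psi/omega), \code{i1..i4}
#'   (atom row indices) and \code{angle} (degrees, (-180, 180]).
#' @export
backboneDihedrals <- function(model) {
  res <- proteinResidueTable(model)
  n <- nrow(res)
  out <- list()
  if (n >= 1) {
    bonded <- peptideBondVector(model, res)
    addRec <- function(ri, kind, i1, i2, i3, i4) {
      ok <- !is.na(i1) & !is.na(i2) & !is.na(i3) & !is.na(i4)
      if (!any(ok)) return(NULL)
      data.frame(key = res$key[ri][ok], chain = res$chain[ri][ok],
                 resno = res$resno[ri][ok], insert = res$insert[ri][ok],
                 resid = res$resid[ri][ok], kind = kind,
                 i1 = i1[ok], i2 = i2[ok], i3 = i3[ok], i4 = i4[ok],
                 stringsAsFactors = FALSE)
    }
    if (n >= 2) {
      prev <- which(bonded)        # bond res[prev] -> res[prev+1]
      cur <- prev + 1L
      out$phi <- addRec(cur, "phi", res$iC[prev], res$iN[cur], res$iCA[cur], res$iC[cur])
      out$psi <- addRec(prev, "psi", res$iN[prev], res$iCA[prev], res$iC[prev], res$iN[cur])
      out$omega <- addRec(cur, "omega", res$iCA[prev], res$iC[prev], res$iN[cur], res$iCA[cur])
    }
  }
  rec <- do.call(rbind, out)
  if (is.null(rec)) {
    rec <- data.frame(key = character(), chain = character(), resno = integer(),
                      insert = character(), resid = character(), kind = character(),
                      i1 = integer(), i2 = integer(), i3 = integer(), i4 = integer(),
                      angle = numeric(), stringsAsFactors = FALSE)
    return(rec)
  }
  xyz <- coords(model)
  rec$angle <- measureDihedralBatch(xyz[rec$i1, , drop = FALSE], xyz[rec$i2, , drop = FALSE],
                                    xyz[rec$i3, , drop = FALSE], xyz[rec$i4, , drop = FALSE])
  rec <- rec[order(match(rec$key, res$key), match(rec$kind, c("phi", "psi", "omega"))), ]
  rownames(rec) <- NULL
  rec
}

# chi dihedral records (kind chi1..chi4) for one residue; atoms looked up by
# the standard name quadruples. Returns zero rows for ALA/GLY.
chiDihedrals <- function(model, resKey) {
  res <- residues(model)
  row <- res[res$key == resKey, , drop = FALSE]
  if (!nrow(row)) stop("residue not found: ", resKey)
  defs <- CHI_ATOMS[[row$resid]]
  if (is.null(defs)) return(emptyDihedralRecords())
  xyz <- coords(model)
  recs <- list()
  for (ci in seq_along(defs)) {
    idx <- vapply(seq_len(4), function(j) atomIndexIn(model, row, defs[[ci]][j]), integer(1))
    if (any(is.na(idx))) next
    recs[[length(recs) + 1]] <- data.frame(
      key = row$key, chain = row$chain, resno = row$resno, insert = row$insert,
      resid = row$resid, kind = paste0("chi", ci),
      i1 = idx[1], i2 = idx[2], i3 = idx[3], i4 = idx[4],
      angle = measureDihedral(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ]),
      stringsAsFactors = FALSE)
  }
  if (!length(recs)) return(emptyDihedralRecords())
  do.call(rbind, recs)
}

emptyDihedralRecords <- function() {
  data.frame(key = character(), chain = character(), resno = integer(),
             insert = character(), resid = character(), kind = character(),
             i1 = integer(), i2 = integer(), i3 = integer(), i4 = integer(),
             angle = numeric(), stringsAsFactors = FALSE)
}

# Residue keys within `radius` of the heavy atoms listed in `fromAtomIdx`.
residuesWithinRadius <- function(model, fromAtomIdx, radius) {
  xyz <- coords(model)
  heavy <- !isHydrogen(model)
  cand <- which(heavy)
  from <- xyz[fromAtomIdx, , drop = FALSE]
  keys <- atomResidueKeys(model)
  hit <- logical(length(cand))
  # chunk over candidate atoms to bound memory
  step <- 20000L
  for (s in seq(1, length(cand), by = step)) {
    ii <- cand[s:min(s + step - 1L, length(cand))]
    sub <- xyz[ii, , drop = FALSE]
    d2min <- rep(Inf, length(ii))
    for (f in seq_len(nrow(from))) {
      d2 <- (sub[, 1] - from[f, 1])^2 + (sub[, 2] - from[f, 2])^2 + (sub[, 3] - from[f, 3])^2
      d2min <- pmin(d2min, d2)
    }
    hit[s:(s + length(ii) - 1L)] <- d2min <= radius^2
  }
  unique(keys[cand[hit]])
}

#' Expand a residue selection for simulation
#'
#' Grows a seed selection along the chain (by default three residues in each
#' direction), adds every residue with any heavy atom within \code{radius} of
#' the extended set (the mobile set), and returns the surrounding fixed shell:
#' residues outside the mobile set with any heavy atom within
#' \code{shellRadius} of a mobile heavy atom.
#'
#' @param model a \code{StructureModel}
#' @param seed character vector of residue keys (see \code{residues()}), or a
#'   data.frame with chain/resno/insert columns.
#' @param nAlong residues to extend along the chain in each direction.
#' @param radius Angstrom, inclusion radius around the chain-extended seed.
#' @param shellRadius Angstrom, thickness of the fixed shell (defaults to
#'   \code{radius}).
#' @return list(mobile = keys, fixedShell = keys); the two sets are disjoint.
#' @export
expandSelection <- function(model, seed, nAlong = 3L, radius = 5.0,
                            shellRadius = radius) {
  res <- residues(model)
  if (is.data.frame(seed)) {
    seed <- residueKeyOf(seed$chain, seed$resno,
                         if (is.null(seed$insert)) "" else seed$insert)
  }
  if (!length(seed)) stop("empty seed selection")
  if (!all(seed %in% res$key))
    stop("seed residues not in model: ", paste(setdiff(seed, res$key), collapse = ", "))
  # extend along each chain by index within the chain
  ext <- character(0)
  for (ch in unique(res$chain[res$key %in% seed])) {
    inChain <- res$key[res$chain == ch]
    pos <- which(inChain %in% seed)
    take <- unique(unlist(lapply(pos, function(p)
      seq(max(1, p - nAlong), min(length(inChain), p + nAlong)))))
    ext <- c(ext, inChain[take])
  }
  ext <- unique(ext)
  keys <- atomResidueKeys(model)
  heavy <- !isHydrogen(model)
  extAtoms <- which(keys %in% ext & heavy)
  mobile <- union(ext, residuesWithinRadius(model, extAtoms, radius))
  mobileAtoms <- which(keys %in% mobile & heavy)
  shell <- setdiff(residuesWithinRadius(model, mobileAtoms, shellRadius), mobile)
  list(mobile = res$key[res$key %in% mobile],
       fixedShell = res$key[res$key %in% shell])
}

# logical per-atom masks from residue key sets
atomMaskFromKeys <- function(model, resKeys) {
  atomResidueKeys(model) %in% resKeys
}
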