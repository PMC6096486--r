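#' @import methods
NULL

ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "elesy",
               "x", "y", "z", "o", "b")

#' Macromolecular model
#'
#' An atomic model: chains of residues of atoms, with author numbering,
#' occupancies, B-factors and (optionally) secondary-structure annotation
#' consumed from the source file (never computed here).
#'
#' @slot atoms data.frame with one row per atom: \code{chain}, \code{resno}
#'   (author numbering, integer), \code{insert} (insertion code, "" if none),
#'   \code{resid} (3-letter residue name), \code{elety} (atom name),
#'   \code{elesy} (element symbol), \code{x,y,z} (Angstrom), \code{o}
#'   (occupancy), \code{b} (B-factor, Angstrom^2), and \code{ss} (secondary
#'   structure: helix/strand/coil/unassigned).
#' @slot title character title.
#' @export
setClass("StructureModel",
         representation(atoms = "data.frame", title = "character"),
         prototype(atoms = data.frame(), title = ""))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  if (nrow(a) == 0) return(TRUE)
  miss <- setdiff(c(ATOM_COLS, "ss"), names(a))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (!all(toupper(a$elesy) %in% KNOWN_ELEMENTS))
    return(paste("unrecognized element(s):",
                 paste(unique(setdiff(toupper(a$elesy), KNOWN_ELEMENTS)), collapse = ", ")))
  TRUE
})

newStructureModel <- function(atoms, title = "") {
  if (nrow(atoms)) {
    if (is.null(atoms$ss)) atoms$ss <- "unassigned"
    if (is.null(atoms$insert)) atoms$insert <- ""
    atoms$insert[is.na(atoms$insert)] <- ""
    if (is.null(atoms$elesy)) atoms$elesy <- elementFromName(atoms$elety)
    if (is.null(atoms$o)) atoms$o <- 1
    if (is.null(atoms$b)) atoms$b <- 0
    atoms <- atoms[, c(ATOM_COLS, "ss")]
    rownames(atoms) <- NULL
  }
  new("StructureModel", atoms = atoms, title = title)
}

#' @describeIn StructureModel-class number of atoms
#' @param model a \code{StructureModel}
#' @export
nAtoms <- function(model) nrow(model@atoms)

#' Atom table of a model
#' @param model a \code{StructureModel}
#' @return data.frame of atoms (one row per atom)
#' @export
atoms <- function(model) model@atoms

#' Coordinates of a model
#' @param model a \code{StructureModel}
#' @return numeric matrix nAtoms x 3 (Angstrom)
#' @export
coords <- function(model) {
  as.matrix(model@atoms[, c("x", "y", "z")])
}

#' Replace coordinates of a model
#' @param model a \code{StructureModel}
#' @param value numeric matrix nAtoms x 3
#' @export
`coords<-` <- function(model, value) {
  stopifnot(nrow(value) == nAtoms(model), ncol(value) == 3)
  model@atoms$x <- value[, 1]
  model@atoms$y <- value[, 2]
  model@atoms$z <- value[, 3]
  model
}

residueKeyOf <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == "", ".", insert), sep = "|")
}

#' Per-atom residue keys
#'
#' The residue key (chain|resno|insertion) of every atom, aligned with the
#' rows of \code{atoms(model)}; keys match those in \code{residues(model)}.
#'
#' @param model a \code{StructureModel}
#' @return character vector, one key per atom
#' @export
atomResidueKeys <- function(model) {
  a <- model@atoms
  residueKeyOf(a$chain, a$resno, a$insert)
}

#' Residue table of a model
#'
#' @param model a \code{StructureModel}
#' @return data.frame with one row per residue in file order: \code{key},
#'   \code{chain}, \code{resno}, \code{insert}, \code{resid}, \code{ss},
#'   \code{firstAtom}, \code{lastAtom} (row indices into \code{atoms(model)}).
#' @export
residues <- function(model) {
  a <- model@atoms
  if (!nrow(a)) {
    return(data.frame(key = character(), chain = character(), resno = integer(),
                      insert = character(), resid = character(), ss = character(),
                      firstAtom = integer(), lastAtom = integer()))
  }
  key <- atomResidueKeys(model)
  first <- which(!duplicated(key))
  ord <- first
  idx <- match(key, key[ord])
  last <- vapply(seq_along(ord), function(i) max(which(idx == i)), integer(1))
  data.frame(key = key[ord], chain = a$chain[ord], resno = a$resno[ord],
             insert = a$insert[ord], resid = a$resid[ord], ss = a$ss[ord],
             firstAtom = ord, lastAtom = last, stringsAsFactors = FALSE)
}

#' @describeIn StructureModel-class number of residues
#' @export
nResidues <- function(model) nrow(residues(model))

isHydrogen <- function(model) toupper(model@atoms$elesy) == "H"

# Row indices of the atom with the given name in each listed residue
# (NA where absent). `res` is a residues() table subset.
atomIndexIn <- function(model, res, name) {
  a <- model@atoms
  key <- atomResidueKeys(model)
  hit <- which(a$elety == name)
  hit[match(res$key, key[hit])]
}

setMethod("show", "StructureModel", function(object) {
  r <- residues(object)
  cat("StructureModel:", if (nzchar(object@title)) object@title else "<untitled>", "\n")
  cat(sprintf("  %d atoms, %d residues, %d chain(s) [%s]\n",
              nAtoms(object), nrow(r), length(unique(r$chain)),
              paste(unique(r$chain), collapse = ",")))
})

#' Density map
#'
#' A real-space density grid with origin and voxel metadata. Values are
#' stored x-fastest; \code{origin} is the Angstrom position of the first
#' grid point.
#'
#' @slot values 3-D numeric array (x, y, z)
#' @slot origin numeric(3), Angstrom
#' @slot voxel numeric(3), Angstrom per grid step
#' @slot stats list(min, max, mean, sigma), recomputed on mutation
#' @export
setClass("DensityMap",
         representation(values = "array", origin = "numeric",
                        voxel = "numeric", stats = "list"))

setValidity("DensityMap", function(object) {
  if (length(dim(object@values)) != 3) return("values must be a 3-D array")
  if (length(object@voxel) != 3 || any(object@voxel <= 0))
    return("voxel sizes must be three positive numbers")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    return("origin must be a finite 3-vector")
  TRUE
})

mapStats <- function(values) {
  list(min = min(values), max = max(values),
       mean = mean(values), sigma = stats::sd(as.vector(values)))
}

newDensityMap <- function(values, origin, voxel) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  new("DensityMap", values = values, origin = as.numeric(origin),
      voxel = as.numeric(voxel), stats = mapStats(values))
}

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@values)
  s <- object@stats
  cat(sprintf("DensityMap: %d x %d x %d voxels (%.3g x %.3g x %.3g A)\n",
              d[1], d[2], d[3], object@voxel[1], object@voxel[2], object@voxel[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A; density %.4g..%.4g (mean %.4g, sigma %.4g)\n",
              object@origin[1], object@origin[2], object@origin[3],
              s$min, s$max, s$mean, s$sigma))
})

#' Density map as an MDFF potential
#'
#' Couples a sigma-normalized density map to a model as an attractive
#' potential: E = -w * sum over enabled heavy atoms of the normalized
#' density interpolated at each atom position.
#'
#' @slot map a \code{DensityMap}
#' @slot weight global coupling w, kJ/mol per normalized-density unit (>= 0)
#' @slot enabled logical per-atom enablement mask (or length 0 for all heavy atoms)
#' @export
setClass("DensityMapPotential",
         representation(map = "DensityMap", weight = "numeric", enabled = "logical"))

setValidity("DensityMapPotential", function(object) {
  if (length(object@weight) != 1 || object@weight < 0) return("weight must be a single value >= 0")
  TRUE
})

#' Construct a map potential
#' @param map a \code{DensityMap}
#' @param weight coupling constant w (kJ/mol per normalized-density unit)
#' @param enabled optional per-atom logical mask
#' @export
densityMapPotential <- function(map, weight, enabled = logical(0)) {
  new("DensityMapPotential", map = map, weight = weight, enabled = enabled)
}

#' Restraint set
#'
#' Holds all active dihedral and linear-capped (distance/position/tug)
#' restraints on a model, with bundle bookkeeping so that compound
#' operations (secondary-structure bundles, peptide-plane flips, register
#' shifts) can be released as a unit.
#'
#' @slot dihedrals data.frame: i1..i4 (atom row indices), kind (phi/psi/
#'   omega/chi1..chi4), resKey, target (deg), cutoff (deg), k (kJ/mol),
#'   enabled, temporary, bundle, createdFrame
#' @slot linear data.frame: kind (distance/position/tug), i, j (NA for
#'   position/tug), tx,ty,tz (target point for position/tug), r0 (A), k
#'   (kJ/mol/A^2), fmax (kJ/mol/A), enabled, bundle
#' @slot nextBundle integer counter
#' @export
setClass("RestraintSet",
         representation(dihedrals = "data.frame", linear = "data.frame",
                        nextBundle = "integer"))

emptyDihedralDf <- function() {
  data.frame(i1 = integer(), i2 = integer(), i3 = integer(), i4 = integer(),
             kind = character(), resKey = character(), target = numeric(),
             cutoff = numeric(), k = numeric(), enabled = logical(),
             temporary = logical(), bundle = integer(), createdFrame = integer(),
             stringsAsFactors = FALSE)
}

emptyLinearDf <- function() {
  data.frame(kind = character(), i = integer(), j = integer(),
             tx = numeric(), ty = numeric(), tz = numeric(), r0 = numeric(),
             k = numeric(), fmax = numeric(), enabled = logical(),
             bundle = integer(), stringsAsFactors = FALSE)
}

#' Create an empty restraint set
#' @return a \code{RestraintSet} with no restraints
#' @export
restraintSet <- function() {
  new("RestraintSet", dihedrals = emptyDihedralDf(), linear = emptyLinearDf(),
      nextBundle = 1L)
}

setValidity("RestraintSet", function(object) {
  d <- object@dihedrals
  if (nrow(d)) {
    if (any(d$cutoff < 0 | d$cutoff >= 180)) return("dihedral cutoffs must be in [0, 180)")
    if (any(d$k < 0)) return("dihedral k must be >= 0")
    act <- d[d$enabled, , drop = FALSE]
    if (anyDuplicated(act[, c("resKey", "kind")]))
      return("more than one active restraint per (dihedral, kind)")
  }
  l <- object@linear
  if (nrow(l) && any(l$k < 0 | l$fmax <= 0)) return("linear restraints need k >= 0, fmax > 0")
  TRUE
})

#' @describeIn RestraintSet-class total number of restraints (enabled or not)
#' @param set a \code{RestraintSet}
#' @export
nRestraints <- function(set) nrow(set@dihedrals) + nrow(set@linear)

setMethod("show", "RestraintSet", function(object) {
  cat(sprintf("RestraintSet: %d dihedral, %d distance/position/tug restraint(s)\n",
              nrow(object@dihedrals), nrow(object@linear)))
})
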