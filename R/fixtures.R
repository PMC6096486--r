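# Deliberate error injection with ground-truth bookkeeping: every corrupted
# model carries an answer key naming the defects a perfect rebuild (or the
# matching validation report) should find.

#' Build an error recipe
#'
#' @param cisFlip character vector of residue keys whose peptide bond
#'   (N-terminal to the residue) is rotated to cis
#' @param registerShift NULL or list(resKeys = contiguous run, n = signed
#'   integer shift)
#' @param rotamerScramble character vector of residue keys whose side chain
#'   is rotated 120 degrees about chi1
#' @param jitterSigma Gaussian noise sd applied to all heavy atoms, Angstrom
#'   (0 = none)
#' @param seed RNG seed making the corruption reproducible
#' @return an ErrorRecipe list
#' @export
errorRecipe <- function(cisFlip = character(0), registerShift = NULL,
                        rotamerScramble = character(0), jitterSigma = 0,
                        seed = 0) {
  list(cisFlip = cisFlip, registerShift = registerShift,
       rotamerScramble = rotamerScramble, jitterSigma = jitterSigma,
       seed = seed)
}

#' Inject deliberate errors into a model
#'
#' Applies the recipe's defects and returns the corrupted model together
#' with an answer key listing each defect and its locus. cis flips rotate
#' the backbone N about the CA(i-1)-CA(i) axis so only the peptide plane
#' moves; register shifts move the run's backbone along splines fitted to
#' its own path (the same machinery a corrective shift uses, in reverse);
#' rotamer scrambles rotate the side chain about chi1; jitter adds seeded
#' Gaussian noise to every heavy atom. Defect loci may not overlap.
#'
#' @param model a \code{StructureModel}
#' @param recipe from \code{errorRecipe}
#' @return list(model = corrupted \code{StructureModel}, key = data.frame
#'   answer key (defect, resKey))
#' @export
injectErrors <- function(model, recipe) {
  res <- residues(model)
  loci <- c(recipe$cisFlip, recipe$rotamerScramble,
            if (!is.null(recipe$registerShift)) recipe$registerShift$resKeys)
  if (anyDuplicated(loci)) stop("overlapping defect loci in recipe")
  if (length(setdiff(loci, res$key)))
    stop("recipe targets unknown residues: ",
         paste(setdiff(loci, res$key), collapse = ", "))
  set.seed(recipe$seed)
  xyz <- coords(model)
  key <- list()

  for (rk in recipe$cisFlip) {
    bd <- backboneDihedrals(model)
    om <- bd[bd$key == rk & bd$kind == "omega", , drop = FALSE]
    if (!nrow(om)) stop("residue ", rk, " has no omega dihedral to flip")
    # rotate CA(i) about the C(i-1)-N(i) peptide-bond axis: a torsion about
    # the bond changes omega by exactly the rotation angle, so the cis
    # state is always reachable; N-CA length is preserved (N lies on the
    # axis) and everything downstream of CA(i) is untouched
    axisFrom <- xyz[om$i2, ]               # C(i-1)
    axisDir <- xyz[om$i3, ] - axisFrom     # towards N(i)
    unit <- om$i4                          # CA(i)
    omegaAt <- function(ang) {
      p <- rotateAboutAxis(xyz[unit, , drop = FALSE], axisFrom, axisDir, ang)
      abs(measureDihedral(xyz[om$i1, ], xyz[om$i2, ], xyz[om$i3, ], p[1, ]))
    }
    best <- optimize(omegaAt, c(-180, 180), tol = 1e-8)
    xyz[unit, ] <- rotateAboutAxis(xyz[unit, , drop = FALSE], axisFrom,
                                   axisDir, best$minimum)
    key[[length(key) + 1]] <- data.frame(defect = "cis_flip", resKey = rk,
                                         stringsAsFactors = FALSE)
  }
  if (length(recipe$cisFlip)) coords(model) <- xyz

  if (!is.null(recipe$registerShift)) {
    rs <- recipe$registerShift
    bs <- fitBackboneSplines(model, rs$resKeys)
    nrun <- length(rs$resKeys)
    keys <- atomResidueKeys(model)
    for (r in seq_len(nrun)) {
      rowR <- res[res$key == rs$resKeys[r], , drop = FALSE]
      tshift <- min(max(r + rs$n, bs$tMin), bs$tMax)
      dispRef <- NULL
      for (atomName in c("N", "C", "CA", "CB")) {
        f <- bs$splines[[atomName]]
        i <- atomIndexIn(model, rowR, atomName)
        if (is.null(f) || is.na(i)) next
        newp <- f(tshift)
        if (atomName == "CA") dispRef <- as.numeric(newp) - xyz[i, ]
        xyz[i, ] <- newp
      }
      # drag remaining side-chain atoms rigidly with the CA displacement
      others <- which(keys == rs$resKeys[r] &
                        !model@atoms$elety %in% c("N", "C", "CA", "CB") &
                        !isHydrogen(model))
      if (length(others) && !is.null(dispRef))
        xyz[others, ] <- sweep(xyz[others, , drop = FALSE], 2, dispRef, `+`)
    }
    coords(model) <- xyz
    # answer key lists the residues that traverse a full register unit;
    # the |n| residues at the clamped end barely move and are not expected
    # to be individually detectable
    idxRun <- seq_len(nrun)
    detectable <- rs$resKeys[idxRun + rs$n >= 1 & idxRun + rs$n <= nrun]
    key[[length(key) + 1]] <- data.frame(defect = "register_shift",
                                         resKey = detectable,
                                         stringsAsFactors = FALSE)
  }

  for (rk in recipe$rotamerScramble) {
    rowR <- res[res$key == rk, , drop = FALSE]
    iCA <- atomIndexIn(model, rowR, "CA")
    iCB <- atomIndexIn(model, rowR, "CB")
    if (is.na(iCB)) stop("residue ", rk, " has no side chain to scramble")
    keys <- atomResidueKeys(model)
    side <- which(keys == rk &
                    !model@atoms$elety %in% c("N", "CA", "C", "O", "CB") &
                    !isHydrogen(model))
    if (!length(side)) stop("residue ", rk, " has no atoms beyond CB")
    xyz[side, ] <- rotateAboutAxis(xyz[side, , drop = FALSE], xyz[iCA, ],
                                   xyz[iCB, ] - xyz[iCA, ], 120)
    key[[length(key) + 1]] <- data.frame(defect = "rotamer_scramble", resKey = rk,
                                         stringsAsFactors = FALSE)
  }
  if (length(recipe$rotamerScramble)) coords(model) <- xyz

  if (recipe$jitterSigma > 0) {
    heavy <- which(!isHydrogen(model))
    xyz[heavy, ] <- xyz[heavy, ] +
      matrix(rnorm(3 * length(heavy), 0, recipe$jitterSigma), ncol = 3)
    coords(model) <- xyz
    key[[length(key) + 1]] <- data.frame(defect = "jitter", resKey = NA_character_,
                                         stringsAsFactors = FALSE)
  }
  keyDf <- if (length(key)) do.call(rbind, key) else
    data.frame(defect = character(0), resKey = character(0))
  list(model = model, key = keyDf)
}

#' Check validation recall against an answer key
#'
#' For each defect class in the key, runs the matching validation operation
#' on the corrupted model and reports whether every locus was recovered:
#' cis flips must appear in the nonproline cis list, register-shift and
#' rotamer-scramble residues must be flagged by \code{compareModels}
#' against the original (combined / moved), and jitter must show as nonzero
#' per-residue displacement.
#'
#' @param original the uncorrupted \code{StructureModel}
#' @param corrupted the model returned by \code{injectErrors}
#' @param key the answer key returned by \code{injectErrors}
#' @return data.frame(defect, resKey, detected)
#' @export
defectRecall <- function(original, corrupted, key) {
  cmp <- NULL
  need <- any(key$defect %in% c("register_shift", "rotamer_scramble", "jitter"))
  if (need) cmp <- compareModels(original, corrupted)
  out <- key
  out$detected <- FALSE
  for (r in seq_len(nrow(key))) {
    out$detected[r] <- switch(
      key$defect[r],
      cis_flip = {
        pr <- peptideBondReport(corrupted)
        key$resKey[r] %in% pr$table$key[pr$table$class == "cis"]
      },
      register_shift = {
        row <- cmp$table[cmp$table$key == key$resKey[r], , drop = FALSE]
        nrow(row) > 0 && row$combined
      },
      rotamer_scramble = {
        row <- cmp$table[cmp$table$key == key$resKey[r], , drop = FALSE]
        nrow(row) > 0 && row$moved
      },
      jitter = any(cmp$table$rmsd > 0, na.rm = TRUE),
      FALSE)
  }
  out
}

#' Serialize an error recipe to JSON
#' @param recipe from \code{errorRecipe}
#' @param path output file
#' @export
writeErrorRecipe <- function(recipe, path) {
  jsonlite::write_json(recipe, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read an error recipe from JSON
#' @param path JSON file
#' @export
readErrorRecipe <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  errorRecipe(cisFlip = as.character(r$cisFlip %||% character(0)),
              registerShift = r$registerShift,
              rotamerScramble = as.character(r$rotamerScramble %||% character(0)),
              jitterSigma = r$jitterSigma %||% 0,
              seed = r$seed %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
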