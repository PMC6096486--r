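# Register-shift machinery: parametric backbone splines and moving
# position-restraint schedules that walk a run of residues n register units
# along its own backbone path.

UPDATES_PER_REGISTER <- 10   # coordinate updates per register unit

#' Fit parametric backbone splines to a residue run
#'
#' Natural interpolating cubic splines through the (x, y, z) positions of
#' the N, C, CA and (where present) CB atoms, as functions of residue
#' position along the run (integer parameter t = 1..length(run)). Glycine
#' contributes no CB control point; the CB spline interpolates through the
#' remaining ones.
#'
#' @param model a \code{StructureModel}
#' @param resKeys contiguous run of residue keys, length >= 4
#' @return a BackboneSplines list: per atom type, function(t) -> M x 3
#'   matrix, plus the fitted range
#' @export
fitBackboneSplines <- function(model, resKeys) {
  res <- proteinResidueTable(model)
  pos <- match(resKeys, res$key)
  if (any(is.na(pos))) stop("unknown or non-protein residues in selection")
  if (length(pos) < 4) stop("spline fitting needs at least 4 residues")
  if (any(diff(pos) != 1L)) stop("selection is not contiguous")
  xyz <- coords(model)
  splines <- list()
  for (atomName in c("N", "C", "CA", "CB")) {
    idx <- atomIndexIn(model, res[pos, ], atomName)
    t <- which(!is.na(idx))
    if (atomName != "CB" && length(t) < length(pos)) {
      missing <- resKeys[is.na(idx)]
      stop("backbone atom ", atomName, " missing in residue(s): ",
           paste(missing, collapse = ", "))
    }
    if (length(t) < 2) {
      splines[[atomName]] <- NULL
      next
    }
    fx <- splinefun(t, xyz[idx[t], 1], method = "natural")
    fy <- splinefun(t, xyz[idx[t], 2], method = "natural")
    fz <- splinefun(t, xyz[idx[t], 3], method = "natural")
    splines[[atomName]] <- local({
      fx <- fx; fy <- fy; fz <- fz
      function(tt) cbind(fx(tt), fy(tt), fz(tt))
    })
  }
  list(splines = splines, tMin = 1, tMax = length(pos), resKeys = resKeys)
}

#' Plan a register shift
#'
#' @param model a \code{StructureModel}
#' @param resKeys contiguous residue run to shift
#' @param shift signed integer register shift (negative = towards the
#'   N-terminus), |shift| >= 1
#' @param updatesPerRegister coordinate updates spent traversing one
#'   register unit (default 10)
#' @param endHandling "clamp" (default) or "extrapolate" for target indices
#'   beyond the fitted range
#' @return a RegisterShiftPlan list
#' @export
planRegisterShift <- function(model, resKeys, shift,
                              updatesPerRegister = UPDATES_PER_REGISTER,
                              endHandling = c("clamp", "extrapolate")) {
  endHandling <- match.arg(endHandling)
  shift <- as.integer(shift)
  if (abs(shift) < 1) stop("shift must be a nonzero integer")
  bs <- fitBackboneSplines(model, resKeys)
  list(resKeys = resKeys, shift = shift, splines = bs,
       updatesPerRegister = updatesPerRegister,
       timestepsPerUpdate = COORD_UPDATE_INTERVAL,
       endHandling = endHandling, progress = 0, released = FALSE)
}

#' Moving-restraint targets of a register-shift plan
#'
#' Target position for residue i, atom type a, at a given progress
#' fraction: spline_a(i + progress * shift), clamped (or extrapolated) at
#' the run's ends. At progress 1 each interior residue targets the original
#' position of residue i + shift.
#'
#' @param plan a RegisterShiftPlan
#' @param progress fraction complete, in [0, 1]
#' @return data.frame: resKey, atom, x, y, z
#' @export
shiftTargets <- function(plan, progress) {
  if (progress < 0 || progress > 1) stop("progress must be in [0, 1]")
  bs <- plan$splines
  nrun <- length(plan$resKeys)
  out <- list()
  for (atomName in names(bs$splines)) {
    f <- bs$splines[[atomName]]
    if (is.null(f)) next
    tt <- seq_len(nrun) + progress * plan$shift
    if (plan$endHandling == "clamp") tt <- pmin(pmax(tt, bs$tMin), bs$tMax)
    xyz <- f(tt)
    out[[atomName]] <- data.frame(resKey = plan$resKeys, atom = atomName,
                                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                  stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# atom row indices for the plan's (residue, atom-type) targets; NA where the
# atom does not exist (e.g. CB of glycine)
planAtomIndices <- function(model, targets) {
  res <- residues(model)
  vapply(seq_len(nrow(targets)), function(r) {
    row <- res[res$key == targets$resKey[r], , drop = FALSE]
    atomIndexIn(model, row, targets$atom[r])
  }, integer(1))
}

#' Execute a register shift
#'
#' Removes every pre-existing restraint on the selected residues, attaches
#' moving position restraints to the N, C, CA and CB atoms (side chains are
#' never restrained), and advances their targets along the fitted splines —
#' one register unit per ten coordinate updates, targets refreshed at every
#' update — while running Langevin dynamics. On completion the restraints
#' stay at their final targets until \code{releaseRegisterShift} is called.
#'
#' @param state a \code{SimulationState} whose mobile set covers the plan
#' @param plan a RegisterShiftPlan
#' @param settleUpdates extra coordinate updates to run at full progress
#'   before returning
#' @param k,fmax moving position-restraint parameters
#' @return list(state = updated \code{SimulationState}, plan = plan with
#'   progress 1 and its bundle id)
#' @export
executeRegisterShift <- function(state, plan, settleUpdates = 10,
                                 k = LINEAR_K_DEFAULT, fmax = FMAX_DEFAULT) {
  model <- state@model
  selAtoms <- which(atomMaskFromKeys(model, plan$resKeys))
  heavySel <- selAtoms[!isHydrogen(model)[selAtoms]]
  if (!all(state@mobile[heavySel]))
    stop("register-shift selection extends outside the mobile set")
  set <- removeRestraintsOnAtoms(state@restraints, selAtoms)
  bb <- bumpBundle(set)
  set <- bb$set
  bundle <- bb$bundle
  tg0 <- shiftTargets(plan, 0)
  idx <- planAtomIndices(model, tg0)
  ok <- !is.na(idx)
  tg0 <- tg0[ok, , drop = FALSE]
  idx <- idx[ok]
  for (r in seq_along(idx)) {
    set <- addPositionRestraint(set, idx[r], c(tg0$x[r], tg0$y[r], tg0$z[r]),
                                k = k, fmax = fmax, bundle = bundle)
  }
  state@restraints <- set
  totalUpdates <- plan$updatesPerRegister * abs(plan$shift)
  updateTargets <- function(state, progress) {
    tg <- shiftTargets(plan, progress)[ok, , drop = FALSE]
    l <- state@restraints@linear
    rows <- which(!is.na(l$bundle) & l$bundle == bundle)
    stopifnot(length(rows) == length(idx))
    l$tx[rows] <- tg$x; l$ty[rows] <- tg$y; l$tz[rows] <- tg$z
    state@restraints@linear <- l
    state
  }
  startFrame <- state@frame
  onFrame <- function(s, frame) {
    prog <- min((frame - startFrame) / totalUpdates, 1)
    updateTargets(s, prog)
  }
  nSteps <- (totalUpdates + settleUpdates) * plan$timestepsPerUpdate
  state <- langevinRun(state, nSteps, onFrame = onFrame)
  plan$progress <- 1
  plan$bundle <- bundle
  list(state = state, plan = plan)
}

#' Release a completed register shift
#'
#' Dismisses the plan's moving position restraints (they otherwise persist
#' at their final targets).
#'
#' @param state a \code{SimulationState}
#' @param plan an executed RegisterShiftPlan (with a bundle id)
#' @return the updated \code{SimulationState}
#' @export
releaseRegisterShift <- function(state, plan) {
  if (is.null(plan$bundle)) stop("plan has not been executed")
  state@restraints <- releaseBundle(state@restraints, plan$bundle)
  state
}

#' Serialize a register-shift plan to JSON
#' @param plan a RegisterShiftPlan
#' @param path output file
#' @export
writeRegisterShiftPlan <- function(plan, path) {
  jsonlite::write_json(list(resKeys = plan$resKeys, shift = plan$shift,
                            updatesPerRegister = plan$updatesPerRegister,
                            timestepsPerUpdate = plan$timestepsPerUpdate,
                            endHandling = plan$endHandling),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a register-shift plan from JSON (refits splines against the model)
#' @param model a \code{StructureModel}
#' @param path JSON file written by \code{writeRegisterShiftPlan}
#' @export
readRegisterShiftPlan <- function(model, path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  planRegisterShift(model, spec$resKeys, spec$shift,
                    updatesPerRegister = spec$updatesPerRegister,
                    endHandling = spec$endHandling)
}
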