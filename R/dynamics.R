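# Minimal checkpointed simulation engine: additive force providers
# (simplified force field + restraints + map potentials), gradient-based
# minimization, BAOAB Langevin dynamics with a mobile/fixed partition, and
# the coordinate-update cadence on which moving restraints advance and
# temporary restraints are re-examined.

KB_KJMOL <- 0.0083145      # kJ/mol/K
ACC_SCALE <- 1e-4          # (kJ/mol/A)/amu -> A/fs^2
VEL2_TO_KJ <- 1e4          # amu*(A/fs)^2 -> kJ/mol
COORD_UPDATE_INTERVAL <- 20  # timesteps per coordinate update ("frame")
VALIDATION_INTERVAL <- 10    # frames between validation refreshes

#' Simulation state
#'
#' Working coordinates, velocities, the mobile/fixed atom partition, active
#' restraints, map potentials and integrator settings for one model.
#' Hydrogens and fixed-shell atoms never move.
#'
#' @slot model the source \code{StructureModel}
#' @slot positions,velocities nAtoms x 3 matrices (Angstrom, Angstrom/fs)
#' @slot mobile logical per-atom mask (heavy atoms of mobile residues)
#' @slot restraints a \code{RestraintSet}
#' @slot maps list of \code{DensityMapPotential}
#' @slot temperature kelvin
#' @slot timestep fs
#' @slot friction fs^-1
#' @slot frame coordinate-update counter
#' @slot topology force-field topology (from \code{buildTopology})
#' @export
setClass("SimulationState",
         representation(model = "StructureModel", positions = "matrix",
                        velocities = "matrix", mobile = "logical",
                        restraints = "RestraintSet", maps = "list",
                        temperature = "numeric", timestep = "numeric",
                        friction = "numeric", frame = "integer",
                        topology = "list"))

setValidity("SimulationState", function(object) {
  n <- nAtoms(object@model)
  if (nrow(object@positions) != n || nrow(object@velocities) != n)
    return("positions/velocities do not match the model's atom count")
  if (length(object@mobile) != n) return("mobile mask length mismatch")
  if (object@temperature < 0) return("temperature must be >= 0")
  TRUE
})

setMethod("show", "SimulationState", function(object) {
  cat(sprintf("SimulationState: %d atoms (%d mobile), T = %g K, dt = %g fs, frame %d\n",
              nAtoms(object@model), sum(object@mobile), object@temperature,
              object@timestep, object@frame))
})

#' Create a simulation state
#'
#' Selected residues (after \code{expandSelection}-style growth, if the
#' caller used it) become mobile; everything else — including the fixed
#' shell and all hydrogens — is pinned. On creation exactly the omega
#' dihedrals are restrained (peptide-bond geometry), each to its nearer
#' planar state.
#'
#' @param model a \code{StructureModel}
#' @param mobileResidues residue keys to mobilize (default: all)
#' @param maps list of \code{DensityMapPotential}
#' @param temperature kelvin (100 K default)
#' @param timestep fs
#' @param friction Langevin friction, fs^-1
#' @param restraints starting \code{RestraintSet}; default restrains omega
#' @return a \code{SimulationState}
#' @export
newSimulation <- function(model, mobileResidues = NULL, maps = list(),
                          temperature = 100, timestep = 1,
                          friction = 0.01, restraints = NULL) {
  n <- nAtoms(model)
  if (is.null(mobileResidues)) mobileResidues <- residues(model)$key
  mobile <- atomMaskFromKeys(model, mobileResidues) & !isHydrogen(model)
  if (is.null(restraints)) restraints <- defaultOmegaRestraints(model)
  new("SimulationState", model = model, positions = coords(model),
      velocities = matrix(0, n, 3), mobile = mobile, restraints = restraints,
      maps = maps, temperature = temperature, timestep = timestep,
      friction = friction, frame = 0L, topology = buildTopology(model))
}

#' Total energy and forces of all providers
#'
#' Sums the simplified force field, every enabled restraint, and every map
#' potential; forces on non-mobile atoms are zeroed.
#'
#' @param state a \code{SimulationState}
#' @param positions optional coordinates to evaluate (default: state's)
#' @return list(energy, forces, terms = per-provider energies)
#' @export
totalEnergyForces <- function(state, positions = state@positions) {
  ff <- forcefieldEnergy(state@topology, positions)
  rs <- restraintEnergyForces(state@restraints, positions)
  energy <- ff$energy + rs$energy
  forces <- ff$forces + rs$forces
  terms <- c(ff$terms, restraints = rs$energy)
  for (k in seq_along(state@maps)) {
    mp <- mdffEnergy(state@maps[[k]], positions,
                     enabled = state@mobile)
    energy <- energy + mp$energy
    forces <- forces + mp$forces
    terms[paste0("map", k)] <- mp$energy
  }
  if (!is.finite(energy)) {
    stop("non-finite energy; worst atom: ",
         which.max(apply(!is.finite(forces), 1, any)))
  }
  forces[!state@mobile, ] <- 0
  list(energy = energy, forces = forces, terms = terms)
}

#' Kinetic energy of a simulation state
#' @param state a \code{SimulationState}
#' @return kinetic energy, kJ/mol
#' @export
kineticEnergy <- function(state) {
  m <- atomMass(state@model@atoms$elesy)
  0.5 * sum(m * rowSums(state@velocities^2)) * VEL2_TO_KJ
}

#' Energy minimization
#'
#' Chunked quasi-Newton (L-BFGS-B) minimization over the mobile degrees of
#' freedom; the energy recorded after each chunk is non-increasing. Stops
#' when the maximum per-atom force drops below \code{forceTol} or after
#' \code{maxSteps} iterations.
#'
#' @param state a \code{SimulationState}
#' @param maxSteps iteration budget
#' @param forceTol kJ/mol/A convergence threshold on the max mobile force
#' @return the updated \code{SimulationState} (with attribute "trace": the
#'   energy after each accepted chunk)
#' @export
minimize <- function(state, maxSteps = 200, forceTol = 10) {
  mob <- which(state@mobile)
  if (!length(mob)) return(state)
  pos <- state@positions
  ef <- totalEnergyForces(state, pos)
  trace <- ef$energy
  maxF <- function(f) if (length(mob)) max(abs(f[mob, ])) else 0
  if (maxF(ef$forces) <= forceTol) {
    attr(state, "trace") <- trace
    return(state)
  }
  chunk <- 25L
  done <- 0L
  while (done < maxSteps) {
    par0 <- as.vector(pos[mob, ])
    fn <- function(p) {
      pp <- pos; pp[mob, ] <- matrix(p, ncol = 3)
      totalEnergyForces(state, pp)$energy
    }
    gr <- function(p) {
      pp <- pos; pp[mob, ] <- matrix(p, ncol = 3)
      -as.vector(totalEnergyForces(state, pp)$forces[mob, ])
    }
    opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = chunk))
    if (!is.finite(opt$value)) stop("minimization diverged to non-finite energy")
    if (opt$value <= trace[length(trace)]) {
      pos[mob, ] <- matrix(opt$par, ncol = 3)
      trace <- c(trace, opt$value)
    } else {
      break  # no further decrease found
    }
    done <- done + chunk
    ef <- totalEnergyForces(state, pos)
    if (maxF(ef$forces) <= forceTol) break
    if (opt$convergence == 0 && done > chunk) break
  }
  state@positions <- pos
  attr(state, "trace") <- trace
  state
}

#' Langevin dynamics
#'
#' BAOAB velocity-Langevin integration at the state's temperature; at T = 0
#' this reduces to damped descent. Fixed atoms are pinned. Every 20
#' timesteps (one coordinate update, a "frame") the \code{onFrame} hook runs
#' — moving restraints (tugs, register-shift targets) advance there — and
#' temporary restraints are released when satisfied or expired; every 10
#' frames the optional \code{onValidate} hook runs (real-time-style
#' validation refresh).
#'
#' @param state a \code{SimulationState}
#' @param nSteps number of timesteps
#' @param onFrame optional function(state, frame) -> state, called at each
#'   coordinate update
#' @param onValidate optional function(state, frame), called every 10 frames
#' @return the updated \code{SimulationState}
#' @export
langevinRun <- function(state, nSteps, onFrame = NULL, onValidate = NULL) {
  dt <- state@timestep
  mob <- state@mobile
  if (!any(mob)) return(state)
  mass <- atomMass(state@model@atoms$elesy)
  invm <- ifelse(mob, 1 / mass, 0)
  c1 <- exp(-state@friction * dt)
  sigv <- sqrt(pmax(0, (1 - c1^2) * KB_KJMOL * state@temperature / (mass * VEL2_TO_KJ)))
  sigv[!mob] <- 0
  pos <- state@positions
  vel <- state@velocities
  ef <- totalEnergyForces(state, pos)
  acc <- ef$forces * (invm * ACC_SCALE)
  nmob <- sum(mob)
  for (step in seq_len(nSteps)) {
    vel <- vel + 0.5 * dt * acc
    half <- 0.5 * dt * vel
    pos <- pos + half
    if (state@temperature > 0) {
      noise <- matrix(0, nrow(pos), 3)
      noise[mob, ] <- rnorm(3 * nmob)
      vel <- c1 * vel + sigv * noise
    } else {
      vel <- c1 * vel
    }
    pos <- pos + 0.5 * dt * vel
    if (max(abs(pos - state@positions)) > 50)
      stop("unstable integration: atoms moved > 50 A; reduce the timestep or minimize first")
    ef <- totalEnergyForces(state, pos)
    acc <- ef$forces * (invm * ACC_SCALE)
    vel <- vel + 0.5 * dt * acc
    if (max(abs(0.5 * dt * vel)) > 1)
      stop("unstable step: displacement > 1 A in one timestep")
    if (step %% COORD_UPDATE_INTERVAL == 0) {
      state@positions <- pos
      state@velocities <- vel
      state@frame <- state@frame + 1L
      state@restraints <- autoReleaseTemporary(state@restraints, pos, state@frame)
      if (!is.null(onFrame)) state <- onFrame(state, state@frame)
      if (!is.null(onValidate) && state@frame %% VALIDATION_INTERVAL == 0)
        onValidate(state, state@frame)
      pos <- state@positions
      vel <- state@velocities
      ef <- totalEnergyForces(state, pos)
      acc <- ef$forces * (invm * ACC_SCALE)
    }
  }
  state@positions <- pos
  state@velocities <- vel
  state
}

#' Checkpoint
#'
#' A restorable snapshot of atomic positions, velocities and the full
#' restraint set. Any number of checkpoints may coexist, and they serialize
#' with the R session (they are plain objects), so they outlive a single
#' simulation.
#'
#' @slot positions,velocities coordinate/velocity matrices
#' @slot restraints the \code{RestraintSet} at save time
#' @slot frame coordinate-update counter at save time
#' @slot signature model topology fingerprint used to refuse cross-model restores
#' @export
setClass("Checkpoint",
         representation(positions = "matrix", velocities = "matrix",
                        restraints = "RestraintSet", frame = "integer",
                        signature = "character"))

modelSignature <- function(model) {
  a <- model@atoms
  paste(nrow(a), digest_chars(paste(a$chain, a$resno, a$elety, collapse = ";")))
}

# tiny stable string hash (sum of char codes in blocks); enough to detect
# topology mismatch without external dependencies
digest_chars <- function(s) {
  v <- utf8ToInt(s)
  paste(sum(v * (seq_along(v) %% 97)) %% 1e9, length(v))
}

#' Save a checkpoint
#' @param state a \code{SimulationState}
#' @return a \code{Checkpoint}
#' @export
saveCheckpoint <- function(state) {
  new("Checkpoint", positions = state@positions, velocities = state@velocities,
      restraints = state@restraints, frame = state@frame,
      signature = modelSignature(state@model))
}

#' Restore a checkpoint
#'
#' Returns positions bit-identically and the restraint set exactly as
#' saved; restoring a checkpoint from a different model topology is an
#' error.
#'
#' @param state a \code{SimulationState}
#' @param cp a \code{Checkpoint}
#' @return the updated \code{SimulationState}
#' @export
restoreCheckpoint <- function(state, cp) {
  if (cp@signature != modelSignature(state@model))
    stop("checkpoint belongs to a different model topology")
  state@positions <- cp@positions
  state@velocities <- cp@velocities
  state@restraints <- cp@restraints
  state@frame <- cp@frame
  state
}

#' Correct non-trans peptide bonds by scripted flips
#'
#' Automates the standard workflow of walking the cis/twisted peptide list:
#' every nonproline cis (or twisted) peptide bond has its omega restraint
#' flipped to the trans state, followed by short Langevin settling and
#' minimization; rounds repeat while the census of non-trans bonds
#' improves. Pre-existing cis prolines are left alone.
#'
#' @param state a \code{SimulationState}
#' @param maxRounds flip/settle rounds
#' @param mdSteps Langevin timesteps per round
#' @return the updated \code{SimulationState}
#' @export
correctNonTransPeptides <- function(state, maxRounds = 3, mdSteps = 100) {
  for (round in seq_len(maxRounds)) {
    cur <- state@model
    coords(cur) <- state@positions
    rep <- peptideBondReport(cur)
    bad <- rep$table[!(rep$table$class == "cis" & rep$table$proline), , drop = FALSE]
    if (!nrow(bad)) break
    for (key in bad$key) {
      d <- state@restraints@dihedrals
      row <- which(d$resKey == key & d$kind == "omega" & d$enabled)
      if (!length(row)) {
        # no restraint exists (e.g. the bond was stretched past detection at
        # load time): restrain straight to trans
        state@restraints <- addDihedralRestraint(state@restraints, cur, key,
                                                 "omega", 180)
      } else if (abs(d$target[row[1]]) < 90) {
        # restrained to cis: flip to trans
        state@restraints <- flipCisTrans(state@restraints, cur, key)
      }
    }
    if (mdSteps > 0) state <- langevinRun(state, mdSteps)
    state <- minimize(state, maxSteps = 200)
    cur2 <- state@model
    coords(cur2) <- state@positions
    if (sum(peptideBondReport(cur2)$counts[c("cis_nonproline", "twisted")]) >=
        sum(rep$counts[c("cis_nonproline", "twisted")])) break
  }
  state
}

#' Settle a model (optionally against a map)
#'
#' The standard non-interactive pipeline: build a simulation over the
#' selection (default: the entire structure), minimize, run Langevin
#' dynamics at the requested temperature, minimize again at 0 K, and (by
#' default) run the scripted cis/twisted correction pass before the final
#' minimization. Geometry validation summaries are computed before and
#' after.
#'
#' @param model a \code{StructureModel}
#' @param map optional \code{DensityMap} used as an MDFF potential
#' @param weight map coupling w, kJ/mol per normalized-density unit
#' @param mobileResidues residue keys to mobilize (default: all)
#' @param temperature kelvin (default 100)
#' @param mdSteps Langevin timesteps
#' @param minSteps minimizer iteration budget per phase
#' @param fixPeptides run \code{correctNonTransPeptides} after settling
#' @param seed RNG seed (all stochastic output is reproducible)
#' @return list(model = updated \code{StructureModel}, before, after =
#'   validation summaries, state = final \code{SimulationState})
#' @export
settleModel <- function(model, map = NULL, weight = 20, mobileResidues = NULL,
                        temperature = 100, mdSteps = 400, minSteps = 400,
                        fixPeptides = TRUE, seed = 0) {
  set.seed(seed)
  maps <- list()
  if (!is.null(map)) maps <- list(densityMapPotential(map, weight))
  state <- newSimulation(model, mobileResidues = mobileResidues, maps = maps,
                         temperature = temperature)
  before <- list(peptide = peptideBondReport(model)$counts,
                 rama = ramaReport(model)$summary)
  state <- minimize(state, maxSteps = minSteps)
  if (mdSteps > 0 && temperature >= 0) state <- langevinRun(state, mdSteps)
  if (fixPeptides) state <- correctNonTransPeptides(state)
  state@temperature <- 0
  state@velocities[] <- 0
  state <- minimize(state, maxSteps = minSteps)
  out <- model
  coords(out) <- state@positions
  after <- list(peptide = peptideBondReport(out)$counts,
                rama = ramaReport(out)$summary)
  list(model = out, before = before, after = after, state = state)
}
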