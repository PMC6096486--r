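---
title: "Restraint-guided flexible fitting: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint-guided flexible fitting: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexfit)
```

# The problem

Atomic models built into low-resolution (3–4 Å) cryo-EM or crystallographic
maps accumulate errors that summary statistics hide: nonproline cis peptide
bonds, severely twisted peptide planes, side chains in the wrong rotamer,
and whole stretches of sequence modelled one or more positions out of
register with the density. flexfit provides the computational machinery for
diagnosing and repairing such errors headlessly: a model is coupled to its
density map as an attractive potential (the molecular dynamics flexible
fitting, MDFF, idea), manipulated through restraints rather than direct
coordinate edits, and monitored with fast backbone validation while it
settles.

All state lives in S4 objects — `StructureModel` (atoms/residues/chains),
`DensityMap` / `DensityMapPotential`, `RestraintSet`, `SimulationState`,
`Checkpoint` — and every operation is a pure function returning an updated
object, so checkpointing and scripted workflows compose naturally.

# Restraint forms

**Flat-bottomed dihedral restraints.** A dihedral restrained to target
$\theta_0$ with flat-bottom half-width $\Delta\theta_\mathrm{cutoff}$ feels

$$E = \begin{cases}
0 & |\Delta\theta| \le \Delta\theta_\mathrm{cutoff}\\
k\,(\cos\Delta\theta_\mathrm{cutoff} - \cos\Delta\theta) & \text{otherwise,}
\end{cases}$$

with $\Delta\theta = \mathrm{wrap}(\theta - \theta_0)$. The cosine form is
continuous at the boundary and, unlike a harmonic, has a smooth gradient
$k\sin\Delta\theta$ that vanishes at $\Delta\theta = 180^\circ$: a restraint
whose target is diametrically opposed (as after a cis↔trans flip) pushes
with steadily growing force instead of tearing the model at a gradient
discontinuity. The $180^\circ$ point is formally metastable but measure-zero
in practice. Defaults: cutoff $30^\circ$ for $\varphi,\psi,\omega$ and
$15^\circ$ for side-chain $\chi$ (ultra-high-resolution surveys show real
peptide bonds twisting $10$–$20^\circ$ from planar, so tighter windows would
fight genuine structure); $k = 250$ kJ/mol, chosen so one restraint
dominates 100 K thermal motion without ejecting atoms. All are arguments,
not constants.

**Capped harmonic distance/position restraints.** Near the target these are
simple springs; past the crossover $|r - r_0| = F_\mathrm{max}/k$ the force
plateaus at $F_\mathrm{max}$, so a badly violated restraint can never
destabilize the integrator:
$F = \min(k\,|r - r_0|,\; F_\mathrm{max})$, with the unique $C^1$ energy
(quadratic, then linear). Defaults $k = 500$ kJ/mol/Å², $F_\mathrm{max} =
100$ kJ/mol/Å. Tugging is a position restraint whose target moves every
coordinate update; at most one tug exists per atom and only heavy atoms may
be tugged.

**Lifecycle.** On model load exactly the $\omega$ dihedrals are restrained,
each to its nearer planar state — peptide-bond geometry is the one thing
restrained by default, because interactive-scale forces flip peptides
easily. Compound operations create *bundles* that release as a unit:
secondary-structure restraints ($\varphi/\psi$ at canonical targets plus
O$_n$–N$_{n+4}$ at 3.0 Å and C$\alpha_n$–C$\alpha_{n+2}$ at 5.43 Å for
helices, 6.8 Å and no O–N pairs for strands), rotamer targets (one
$15^\circ$ restraint per $\chi$, re-application replaces), and peptide-plane
flips (temporary $\varphi/\psi$ restraints at $+180^\circ$ from the starting
values, auto-released when both are inside their flat bottoms, abandoned
with a warning after 500 coordinate updates — the satisfaction tolerance and
budget are our choices; only their existence is prescribed by the workflow).

# The map as a potential

A real-space grid (MRC/CCP4, mode-2 float; axis order and NXSTART/ORIGIN
headers are normalized on read) is sigma-normalized,
$\hat\rho = (\rho - \bar\rho)/\sigma_\rho$, and coupled as

$$E_\mathrm{map} = -w \sum_{i \in \text{enabled heavy atoms}} \hat\rho(x_i),$$

so atoms feel a force $+w\,\nabla\hat\rho$ up the density gradient.
Normalization makes $w$ (kJ/mol per normalized-density unit) transferable
across maps: rescaling the raw values leaves the forces unchanged. No
functional form is canonical here; linear coupling is the simplest one
consistent with attraction into local maxima, and $w$ is deliberately
config-required in the CLI. Interpolation is tricubic (separable
Catmull–Rom), which is $C^1$ — forces stay continuous — reproduces linear
fields exactly, and has an analytic gradient; trilinear would give
discontinuous forces at voxel boundaries. Atoms outside the grid (or its
one-voxel margin) feel nothing and are flagged. Maps can be masked to an
arbitrary selection (default radius 4 Å); masking is idempotent and
non-destructive. Hydrogens never feel map forces: they are invisible at
these resolutions.

# Register shifts

A register error is corrected by moving a run of residues along its own
backbone path. Natural interpolating cubic splines are fitted through the
N, C, CA and (where present) CB positions as functions of integer residue
index; glycines simply contribute no CB knot. Moving position restraints on
exactly those four atom types (never side chains) then walk each residue
from index $i$ to $i + n$: targets are $\mathrm{spline}(i + p\,n)$ at
progress $p$, updated every coordinate update (20 timesteps), traversing
one register unit per ten updates. Indices past the fitted range clamp to
the ends (extrapolation is available but off by default — nothing principled
distinguishes the choices, so the conservative one is the default). After
execution the restraints persist at their final targets until explicitly
released; the recommended sequence is execute → minimize with the restraints
held → release → minimize, which on the 20-mer helix round-trip recovers the
interior backbone to well under 0.5 Å.

# Validation

**Peptide bonds.** $\omega$ (the C$\alpha$–C–N–C$\alpha$ torsion) classifies
as cis ($|\omega| \le 30^\circ$), trans ($\ge 150^\circ$) or twisted (in
between); the 30° boundary follows the convention of the standard validation
ecosystem and is configurable. The report lists every non-trans bond with
cis split into proline/nonproline — nonproline cis bonds occur at roughly 5
per 10,000 residues in reality, so an excess is a strong error signal.

**Ramachandran.** Six cases (general, Gly, cis-Pro, trans-Pro, pre-Pro with
Gly/Pro taking precedence, Ile/Val) are scored by bilinear interpolation of
2°-bin percentile grids, periodic in both angles: $P(\varphi,\psi)$ is the
percentage of the reference distribution's mass at or below the local
density, so outlier ($P < 0.05$), marginal ($0.05 \le P < 2$) and favoured
($P \ge 2$) thresholds mean the same thing they mean in MolProbity-style
reports. The reference distributions themselves are **synthetic** — smooth
mixtures of wrapped Gaussians on the classical basins, generated in code —
because the empirical Top8000-style grids are third-party data that cannot
be bundled. Consequences: classifications are reliable deep inside basins
and deep outside them (the fixtures and tests exercise exactly those
regimes), but percentages within a few tenths of a boundary on *real*
models should not be expected to match wwPDB reports to the decimal. The
C$\alpha$ status colour ramps maroon → yellow → green in $\log P$ between
the outlier and favoured thresholds.

**Model change analysis.** Two models are matched residue-by-residue on
(chain, author number, insertion code); wrapped $|\Delta\varphi|$,
$|\Delta\psi|$, $|\Delta\omega|$ and the per-residue heavy-atom RMSD over
shared atoms are reported with flags at $>45^\circ$ and $>2$ Å and a
combined flag. No superposition is applied by default — models refined
against the same map share a frame — but a shared-CA least-squares option
exists.

# The simulation engine

The engine exists to keep stereochemistry sane while restraints and map
forces do the steering; it deliberately replaces a full biomolecular force
field, and the additive provider contract (`forcefieldEnergy` +
`restraintEnergyForces` + `mdffEnergy` summed in `totalEnergyForces`) is
the seam where a production engine could be plugged in.

* **Bonded terms**: harmonic bonds ($k_b = 3000$ kJ/mol/Å²) and angles
  ($k_a = 400$ kJ/mol/rad²) at ideal values measured once from internally
  built template residues, so a freshly built fixture scores exactly zero;
  two-fold torsions ($k = 40$ kJ/mol) on both peptide-plane dihedrals keep
  planarity while permitting both cis and trans.
* **Nonbonded**: soft-sphere repulsion $\varepsilon(\sigma/r)^{12}$
  (truncated and shifted at $\sigma = 2.7$ Å, $\varepsilon = 4$ kJ/mol,
  pairs within three bonds excluded), with the force capped at $10^4$
  kJ/mol/Å so a catastrophic starting clash cannot launch atoms; $\sigma$
  sits below hydrogen-bonding heavy-atom distances (≈2.9 Å) and above clash
  distances, so packing is excluded without fighting secondary structure.
  No electrostatics, no solvent, no attractive dispersion.
* **Topology**: peptide links use a tolerant 2.5 Å C–N cutoff so noisy
  (jittered) models keep their connectivity, while the stricter 1.8 Å
  *detection* cutoff governs whether an $\omega$ record exists at all —
  genuine chain breaks produce neither.
* **Integration**: BAOAB Langevin, 1 fs timestep, friction 10 ps⁻¹,
  default 100 K; at 0 K it reduces to damped descent. Fixed atoms
  (everything outside the mobile selection, plus all hydrogens) are pinned
  exactly. Every 20 timesteps is a *coordinate update*: moving restraints
  advance, temporary restraints are re-examined, and every 10 updates an
  optional validation hook runs.
* **Minimization**: chunked L-BFGS-B over the mobile coordinates; the
  recorded per-chunk energies are non-increasing by construction.
* **Checkpoints** snapshot positions, velocities and the entire restraint
  set; restores are bit-identical, any number coexist, and they are plain
  serializable objects, so they survive beyond a single simulation.

`settleModel` chains the standard pipeline — minimize, Langevin at
temperature, minimize at 0 K — and by default finishes with a scripted
correction pass (`correctNonTransPeptides`): any nonproline cis or twisted
peptide in the census gets its $\omega$ restraint flipped to trans, followed
by short settling, repeated while the census improves. This automation of
the flip-the-list workflow matters in practice: coordinate noise of only
0.3 Å occasionally rotates a peptide past $90^\circ$, after which the
default nearer-state $\omega$ restraint locks it on the wrong side; the
census finds exactly these traps.

# Selections

A seed selection expands three residues along the chain in each direction,
then takes every residue with a heavy atom within 5 Å of that extension as
the mobile set; non-mobile residues within a further shell (default
thickness also 5 Å — the source workflow states only that a shell is fixed,
so the thickness is our configurable choice) are held fixed to preserve
context. Expansion is monotone in the seed.

# Synthetic data and what the tests show

`buildIdealPeptide` constructs polypeptides by internal-coordinate chaining
at canonical backbone targets (alpha $-57/-47$, beta $-119/113$, extended
$180/180$), all-trans peptides, most-common-rotamer side chains (bundled
table), and L-chirality (C–N–CA–CB $= -122.7^\circ$, matched to real
structures). Aromatic rings close exactly by construction; the five-membered
rings (Pro, His, Trp) close to within 0.1 Å with their closure bonds
maintained by the force field, and the proline ring torsions were solved
once so the CD–N closure lands at 1.474 Å. `mapFromModel` renders
unit-amplitude Gaussians (default $\sigma = 1$ Å, voxel 0.5 Å) at heavy-atom
centres. `injectErrors` corrupts with an exact answer key: cis flips rotate
CA$_i$ about the C$_{i-1}$–N$_i$ bond (the one single-atom move that changes
$\omega$ by exactly the rotation angle), register shifts move a run along
its own fitted splines, rotamer scrambles rotate $\chi_1$ by 120°, and
jitter adds seeded Gaussian noise.

These fixtures emulate geometry, not data quality: maps are noise-free
Gaussian renders with no solvent, no anisotropy, no missing wedge, and the
force field has no electrostatics. Recovery results (register-shift
round-trip < 0.5 Å; 0.3 Å-jittered helix settling to < 0.2 Å against its
own map; 100% defect recall on seeded fixtures) therefore demonstrate that
the machinery is self-consistent and convergent under its stated
conditions, not that real 3.8 Å maps yield these accuracies. Rotamer
scrambles are injected on long/aromatic side chains (Arg, Lys, Phe, Tyr,
Trp) because a $\chi_1$ rotation of a short side chain displaces the
residue by less than the 2 Å "moved" threshold — the defect generator
guarantees detectability at default thresholds by construction, and says
so here rather than lowering the threshold.

Problem sizes used throughout the suite and the acceptance script — 20-mer
helices (~100 heavy atoms), maps of ~$50^3$ voxels, hundreds of Langevin
steps — were chosen as the smallest systems on which every behaviour
(expansion, shifts, recovery, recall) is observable.

# Known limitations

* The simplified force field maintains geometry; it does not rank
  conformers energetically. Hydrogens are carried but never simulated.
* Ramachandran percentages on real models are approximate (synthetic
  reference distributions; see above).
* Ligand chemistry is absent: heteroatoms interact only through repulsion
  and position restraints (metals can be pinned, not coordinated).
* Real-space grids only; no structure factors, symmetry, FSC or
  sharpening.
* Register-shift end handling clamps by default; shifting a run across a
  chain break is rejected rather than bridged.
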