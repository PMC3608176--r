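---
title: "Refining seven-transmembrane helix bundles from multiple templates"
author: "TMRefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining seven-transmembrane helix bundles from multiple templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TMRefine)
```

## The problem

G-protein-coupled receptors share a conserved architecture: seven
transmembrane (TM) helices packed into a bundle, joined by three
intracellular and three extracellular loops.  Homology models of these
receptors inherit the template's helix placements, and when sequence
identity is modest the placements are off by several angstroms -- too far
for docking or full-chain refinement to succeed downstream.  TMRefine
implements a refinement engine for exactly this regime: given one or more
backbone template models of the target (all length-matched to the target
sequence) and the TM/loop topology, it treats each helix as a rigid body
and searches for a better-packed bundle, optionally exchanging helices
between refinement workers started from different templates.

Two ideas carry the method.  First, a *bundle-packing penalty*: project
the seven helix axes onto the membrane midplane, fan triangles from the
centroid O of the seven intersection points to adjacent pairs of points
(TM7 wraps to TM1), and demand that the summed triangle area S stay within
the band [S~min~, S~max~] observed in reference structures:

$$E' = \begin{cases}
\left(\frac{S - S_\min}{S_\min}\right)^2 & S < S_\min \\
0 & S_\min \le S \le S_\max \\
\left(\frac{S - S_\max}{S_\max}\right)^2 & S > S_\max
\end{cases}$$

A small E' means a tight, native-like bundle; a large E' means the bundle
has collapsed or blown open.  (The two outer branches point in opposite
directions; the upper branch is active above the band -- any other reading
would leave the piecewise function ill-defined.)

Second, a *parallelized multi-template protocol*: eight pipelines each own
an adjacent helix pair (the first and last own a single terminal helix
plus its terminus), refine only their region, and at the end of every
iteration offer their best-so-far helices to the other pipelines.  A graft
is kept only when it strictly lowers the total energy.  Improved
conformations enter a bounded, energy-sorted elite pool that seeds the
next iteration.  This lets locally correct regions of different templates
recombine without ever building a single merged "super template".

## The single-pipeline protocol

Each pipeline run repeats, `iterationsT` times, a fixed stage sequence on
its assigned helices, scoring every proposal with the whole-pose energy
and accepting greedily (strictly lower total energy; ties rejected):

1. **Translation stage** -- rigid translations with each component drawn
   uniformly from [-5, 5] angstroms.
2. **Spin stage** -- rotation about the helix's own fitted axis, uniform
   on [-180, 180] degrees.
3. **Tilt stage** -- the angle between the helix axis and the membrane
   normal is set to a target drawn from a Gaussian with mean 30 degrees
   and standard deviation 5 degrees (the observed tilt distribution of
   transmembrane helices; both parameters are configurable, and the
   standard deviation is deliberately the more conservative of the two
   plausible calibrations of this prior).
4. **Loop refinement** -- one randomly chosen assigned loop is re-closed
   (see below), again greedily accepted.

Helix axes are re-fitted on the fly as helices move (the axis is the
dominant principal component of the CA positions, sign-fixed N-to-C); the
membrane frame is fixed for the duration of a run.  When no frame is
supplied it is derived from the structure: normal = sign-aligned mean of
the seven axis directions, midplane through the TM CA centroid.

## The energy

`totalEnergy()` is the sum of the weighted packing penalty E' above and a
coarse-grained surrogate membrane score.  The surrogate stands in for a
full membrane energy function, which is outside the scope of this
package; it is deterministic, has a known zero point, and is built from
hinge penalties calibrated against the synthetic reference family (see
below).  Its terms, all with configurable weights:

* **Excluded volume.**  At backbone resolution a TM helix is effectively a
  rigid cylinder, so helix-helix clash is evaluated between fitted axis
  segments with a soft floor `dHelix` (default 9 angstroms; the reference
  family's closest adjacent-axis approach is 9.24).  Loop residues keep a
  floor distance `dLoopAxis` (default 7) from every non-flanking helix
  axis, and loop-loop residue pairs at least 4 apart in sequence have a
  CA-CA soft-sphere floor `dClash` (default 4).
* **Membrane embedding.**  The two endpoints of each fitted helix-axis
  segment must stay within `halfThickness` (default 16.5 angstroms) of
  the midplane.
* **Bundle shape.**  Adjacent helix axes must stay within `contactMax`
  (default 11 angstroms) of each other at three stations along the normal
  (lower leaflet, midplane, upper leaflet; the leaflet hinges are widened
  by the geometric flare of a twisted bundle), and each fan triangle's
  area is held within its proportional share of the packing band.

A design constraint runs through all of this: **every helix-level term is
exactly invariant under a spin of a helix about its own axis.**  A
backbone-level score contains no side chains and cannot meaningfully rank
helix register; the alpha-helical screw symmetry (spin by ~100 degrees
plus a 1.5 angstrom axial slide maps the backbone point cloud nearly onto
itself) means that any spurious spin sensitivity -- including plain
floating-point jitter -- lets greedy acceptance randomize helix register
without real energetic cause.  For the same reason the greedy rule
rejects proposals within a small absolute tolerance (1e-9) of the current
energy: numerical ties are ties.  Spin moves are therefore only ever
accepted when they change something the score genuinely measures; with
the default terms they are inert, and register errors are corrected by
helix crossing from a better template rather than by the score.

The default packing band is calibrated with `calibrateAreaBounds()` on
the synthetic family (ring radii within 5 percent of 12 angstroms, i.e.
S in [356.4, 435.3] square angstroms); the TM bundle cross-section is a
conserved feature, so a narrow band is the realistic choice.  Users
modelling real receptors should re-calibrate on known structures, which
is what the band's definition -- the extreme S values over reference
structures -- prescribes.

## Loop closure

Rigid helix moves break the chain at helix-loop junctions.  The gap is
measured by `connectivityGap()` as the deviation of the C(i)-N(i+1)
distance from the ideal peptide bond (1.33 angstroms).  `ccdClose()`
re-closes a loop by cyclic coordinate descent on its backbone phi/psi
dihedrals: the upstream junction is first re-attached rigidly, then each
pivot in turn takes the closed-form rotation angle that minimizes the
distance between a ghost backbone N built one residue beyond the loop
(ideal geometry, entry dihedral frozen) and the fixed downstream anchor
N.  Because every pivot step minimizes that single distance, the closure
distance is non-increasing sweep by sweep, and a converged closure
(tolerance 0.08 angstroms, conventional for this family of algorithms)
bounds the junction gap by the same amount.  Only loop coordinates move,
and only dihedrals change -- bond lengths and angles are preserved
exactly.  Terminal tails, which have a single junction, are re-attached
rigidly.  Ideal peptide geometry constants: C-N 1.33, CA-C-N 116.2
degrees, C-N-CA 121.7 degrees.  Alternative closure protocols (e.g.
analytic kinematic closure) can be slotted in via the `protocol` field of
`LoopRefineConfig`; only CCD ships.

## The synthetic reference family

`makeIdealBundle()` builds the test system every module is validated on:
seven ideal alpha-helices (phi -57, psi -47; 25 residues by default) on a
12-angstrom ring, axes alternating up/down and uniformly leaned 30
degrees tangentially -- a twisted bundle, which preserves the seven-fold
neighbor spacing at every height and places every helix at the tilt
prior's mean.  Six-residue loops are built from random dihedral restarts
and CCD-closed, screened so the finished bundle sits strictly inside
every hinge of the energy: the generated bundle scores exactly zero, so
the energy's global-minimum neighborhood is known by construction.

`perturbBundle()` applies independent per-helix rigid perturbations
(defaults: uniform within 3 angstroms per translation component, 30
degrees of spin, 10 degrees of tilt increment) and re-closes all
junctions deterministically; the drawn perturbations are returned and
replaying them reproduces the perturbed pose bit-for-bit.
`makeComplementaryTemplates()` splits the helices (default TM1-4 /
TM5-7) and perturbs each template heavily outside its subset (6
angstroms, 60 degrees spin, 20 degrees tilt) and lightly inside (0.3
angstroms, 5, 2).  The heavy noise is deliberately sized beyond the
single-template refiner's basin of attraction: each template is
individually wrong somewhere, the pair is jointly correct everywhere, and
only helix crossing can assemble the correct bundle -- which is precisely
the mechanism the multi-template test is meant to exercise.

What the family does *not* emulate: real sequences and side chains (so no
register/spin signal, see above), helix kinks and irregularity (helices
here are ideal rigid bodies), membrane curvature, and realistic loop
conformational preferences.  Passing the synthetic-recovery tests shows
that the machinery -- moves, energy plumbing, closure, crossing, pool --
behaves as designed around a known optimum; it does not certify accuracy
on real receptors, which depends on the quality of the membrane score
used there.

## Framework semantics and determinism

Pipelines execute under deterministic barrier semantics: within an
iteration every pipeline selects a start (uniformly from the templates in
iteration 1, from the elite pool afterwards), refines its region, and
only then does crossing read an immutable snapshot of all best-so-far
poses; pool updates happen once per iteration, admitting only candidates
that improved on their starting energy.  Donors are tried in pipeline
index order and the first strictly improving graft wins; duplicate donor
helices are skipped.  All randomness flows through `randomStream`
objects -- resumable RNG states that never touch the global RNG -- with
every per-(iteration, pipeline) stream seeded from the master seed, so a
whole framework run is bit-reproducible, including the emitted decoy PDB
files.  An asynchronous execution mode is intentionally not provided;
the barrier mode is the specification of behaviour, and a parallel
implementation would have to reproduce its iteration-boundary snapshots.

## Problem sizes used in the shipped tests

The default bundle has n = 223 residues (7 x 25 helix + 8 x 6
loop/terminus).  The test suite runs the single-pipeline recovery study
with 20 cycles per stage and 8 stage-sequence repetitions over 20
perturbation seeds, and the multi-template study with 8 pipelines, 4
iterations, 3 cycles per stage over 10 master seeds; these sizes were
chosen as the smallest at which the studied effects are stable across
seeds.  Full-scale runs would use stage cycles on the order of n, as
`defaultPipelineConfig()` does.

## Design notes on genuinely open points

* **RMSD atoms.**  TM, full-length and loop RMSDs are CA-only, computed
  after an optimal superposition restricted to the region's residues;
  CA-only is the conventional reading of backbone RMSD for helix-placement
  accuracy and is what `regionRMSD()` implements.
* **The fan center O.**  O is the centroid of the seven
  axis/midplane intersection points (not a fixed pore point), and
  adjacency follows sequence order with TM7 wrapping to TM1, giving
  exactly seven triangles in a closed fan.
* **Tilt semantics.**  The tilt stage *sets* the absolute angle between
  helix axis and membrane normal to the sampled target rather than
  incrementing by it; the Gaussian is a prior over tilt angles, not over
  tilt changes.
* **Translation frame.**  Stage-2 translations are axis-aligned in the
  laboratory frame by default (any translation decomposes into components
  along and perpendicular to the helix axis); an optional helix-aligned
  frame mode is available in `runStageTranslation()`.
* **Crossing donors.**  A donor offers any helix of its whole best pose,
  not only the helices it owns -- poses are whole structures, ownership
  governs refinement only.  Donors are tried in pipeline index order and
  the first strictly improving graft wins, which keeps the step
  deterministic.
* **Pool admission.**  Only pipeline results that improved on their
  selected start are offered to the elite pool (elitist admission).
* **Axis freshness.**  Helix axes are re-fitted whenever a move needs
  them, rather than computed once per run; axes drift as helices move,
  and stale axes would make the spin/tilt moves subtly non-rigid with
  respect to their own definitions.

## Known limitations

* The surrogate score is a geometric stand-in; it defines a sensible
  optimum for the synthetic family but is not a physical membrane energy.
* Helix register (spin) is invisible to the score by design; single-
  template refinement cannot repair spin errors, only crossing can.
* Templates must be length-matched to the target; sequence alignment and
  TM-boundary detection are upstream concerns, and the topology is a
  required input.
* Loops are closed geometrically, not conformationally sampled for
  accuracy; loop quality is secondary to TM placement throughout.
* Insertion codes in PDB inputs are rejected; of alternate locations the
  first is kept; only N, CA, C, O are modelled.
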