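---
title: "Coarse-grained chromatin reconstitution: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained chromatin reconstitution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromassemble)
```

## The model

`chromassemble` simulates the self-assembly of a 10-nm chromatin fibre
from its two constituents: naked DNA and histone-octamer cores. The
emphasis is on DNA topology — twist, writhe and linking number — because
wrapping ~147 bp of DNA in ~1.75 left-handed turns around each octamer
injects roughly two negative units of writhe per nucleosome into the
chain, and that topological debt must go somewhere before a regular
fibre can form.

### DNA

DNA is a bead-and-patch polymer. Each bead represents 7.35 bp (2.5 nm of
B-DNA at 0.34 nm/bp, so one bead is as wide as the double helix and a
canonical 147 bp wrap is exactly 20 beads). A bead is a rigid body: its
orientation quaternion carries a body frame whose x-axis follows the
backbone and whose y-axis — the *patch* — marks the minor-groove face.
The patch plays two roles: it is the moiety that octamer binding sites
recognise, and it is the ribbon used for all twist bookkeeping.

Bonded terms:

* harmonic stretch (`bond_k` = 10 kBT/nm², rest length 2.5 nm),
* Kratky–Porod bending on the position tangents,
* a patch–tangent alignment spring (`align_k` = 30 kBT) keeping the body
  frame attached to the backbone,
* torsion: `twist_k (1 − cos φ)` per joint, where φ is the dihedral of
  consecutive patches *referenced to the bond between them* — the same
  functional the topology module measures.

The bond-referenced dihedral matters. A frame-to-frame ("swing–twist")
torsion energy looks equivalent but is not topologically protected: with
it, a closed supercoiled ring silently unwinds even in noiseless
gradient descent, because total frame winding is not constrained by the
configuration. With the bond-referenced dihedral the total twist of a
closed chain can change only in exchange with writhe (the discrete
analogue of White's theorem), and in our tests a ring with ΔLk = +4
buckles into plectonemes conserving its Gauss linking number to machine
precision. This is what "the patch gives the polymer torsional rigidity,
i.e. it can support supercoiling" means operationally.

Stiffness calibration. The bending persistence length target is 50 nm
and the torsional rigidity is C = 3×10⁻¹⁹ erg·cm, i.e. a twist
persistence length C/kBT ≈ 72 nm, mapped to a per-joint stiffness
`twist_k = C/(kBT σ)` ≈ 29 kBT/rad². Because the alignment springs act
as two springs in series between consecutive bonds they contribute
`align_k/2` of effective Kratky–Porod stiffness; the explicit bend
constant supplies the remainder of the discrete-chain calibration
`1/(1 − exp(−σ/lp))` ≈ 20.5 kBT. The measured persistence length of the
simulated chain — not a formula — is the quantity we hold to 50 nm
(tests: equilibrium sampler within 5%, dynamics within 10%; twist
fluctuation variance within 15% of 1/`twist_k`).

### Cores

A histone octamer is a single hard sphere (diameter 6.75 nm, matching
the nanoparticle model for comparability) decorated with 20 binding
sites on a left-handed helical path: radius 4.2 nm, 1.75 turns, pitch
3.0 nm/turn, one site per wrapped bead. The crystal-structure pitch is
nearer 2.4 nm, but at bead resolution consecutive gyres 2.4 nm apart sit
inside the DNA–DNA excluded volume (cutoff 2.81 nm) and the second turn
of the wrap would be sterically forbidden; 3.0 nm/turn is the smallest
clean-clearance pitch and keeps the overall wrap geometry
nucleosome-like. The DNA–core repulsion is a WCA potential whose cutoff
is placed exactly at the path radius, so a docked bead feels no residual
push.

Each site stores a target patch direction. Site-patch attraction is a
short-range well (capture radius 1.5 nm, depth `eps_site` = 10 kBT ≈
1.4 kBT/bp) modulated by the cosine of the patch/site angle (cone cutoff
60°). The depth is chosen to exceed the per-bead cost of wrapping
(≈ 3.3 kBT bending + 2.5 kBT alignment + up to 0.8 kBT stored twist)
by a few kBT — strong enough that isolated cores wrap, weak enough that
the *topological* penalties of a trapped configuration can stall
completion, which is the regime the reconstitution problem lives in.

Stored twist. The twist-storing nucleosome model ("dLk100") rotates the
site patch registry progressively so that a fully wrapped nucleosome
carries ΔTw = +0.75 turns; together with the wrap writhe ≈ −1.75 this
gives the experimentally observed ΔLk ≈ −1 per nucleosome and resolves
the linking-number paradox. The naive model ("dLk175") stores no twist
(ΔLk ≈ −1.75). The registry construction is exact: the *measured*
dihedral sum across the wrap equals the stored twist to 1e−6 turns.

The isotropic nanoparticle has no sites: any DNA bead is attracted by a
flat-bottomed well of depth 4.3 kBT at surface contact decaying over
2.5 nm. The depth is fixed by the reference conditions; the width is
this package's calibration toward the stated benchmark that an isolated
sphere wraps about two turns of DNA. At 2.9 kBT/bead bending cost the
4.3 kBT depth is marginal, and our isolated spheres equilibrate at
~1.3–1.8 azimuthal turns with excursions to 2 — consistent with
two-turn wrapping being achievable but not deeply locked.

### Wrap-path writhe

The ideal wrap centreline with straight entry/exit legs is the reference
object for all ΔLk accounting. The legs leave tangentially with a small
tilt (0.08) toward ∓z so that the crossing of the entering and exiting
strands — the crossing that completes the canonical writhe — is clean
and numerically stable; the open Gauss integral of this curve converges
to ≈ −1.73 for 1.75 left-handed turns (−1.69 at 20-bead resolution).
Writhe is evaluated with the exact per-segment-pair solid-angle formula
(atan2 spherical-triangle form, robust where the asin form fails), so
polyline writhe is exact, not quadrature.

Open chains use the `extended-axis` convention: both termini extended
100 nm along their end tangents, then the open double integral. Closed
chains need no convention, and the Gauss linking number between the
centreline and the patch-offset curve provides an independent,
exactly conserved cross-check.

## Dynamics

First-order Euler–Maruyama overdamped Langevin dynamics, no hydrodynamic
interactions. Mobilities are Stokes–Einstein: the DNA bead defines the
Brownian time τ_B = σ²/D ≈ 3.6×10⁻⁸ s in water at 300 K (so 0.3 ms of
mapped time ≈ 8.4×10³ τ_B); cores scale as 1/d (translation) and 1/d³
(rotation). The default step is 0.002 τ_B, set by the stiffest mode (the
per-joint twist, relaxing at ≈ 90/τ_B) so its Euler discretization bias
stays under ~10%. Thermostat noise uses zero-mean unit-variance uniform
kicks (only the first two moments matter at O(dt); the stationary
distributions pass KS tests against Boltzmann). Integration uses a
Verlet-style neighbour list with a 2.5 nm skin.

Displacements above 0.5 σ abort with an unstable-step error when the
integrator is run bare; production protocols enable a per-step
displacement clamp at 0.45 σ (the usual soft-launch for overlapping
initial conditions), which only ever triggers on pathological contacts.

Protocol systems are softly confined to a sphere ~1.3× the equilibrium
coil size. This emulates the finite box (i.e. the reconstitution
concentration): without it, a core that detaches early diffuses away to
infinite dilution and can never rebind, which no finite experiment
exhibits.

Reproducibility: one master seed; each stage, replica and analysis draws
from deterministic streams derived from it; identical seed + config
gives byte-identical trajectories.

## Protocols

`make_protocol()` encodes the experiment matrix at full scale: 22.1 kbp
with 100 cores (high density; low density doubles the DNA), 0.3 ms
total, hierarchical switch-on (central H3·H4-tetramer sites only until
0.05 ms, then the full octamer — the in-silico analogue of salt-gradient
dialysis), regular or random pre-positioning (601-array-like vs
unpositioned), and optional interventions: topo-II (DNA–DNA repulsion
capped at 2 kBT during 0.1–0.2 ms so thermal motion passes strands;
verified to change a ring's Lk in steps of ±2 only) or topo-I (twist
stiffness scaled to 0.02 in the window, letting DNA over/under-wind at
little cost).

`scale` shrinks DNA length and core count together; `time_scale`
(default √scale) shrinks stage times less than linearly, because
per-nucleosome wrapping kinetics do not accelerate on shorter DNA.
Desk-scale runs in the tests use 1.1 kbp / 5 cores.

## Analysis battery

* **Wrapping**: a bead is associated with a core if its best site
  contact is below half of −`eps_site`, or it lies within the site
  capture radius, or it sits on the core's binding shell (±0.5 nm of the
  path radius; half-depth range for nanoparticles). The shell term is
  what makes nonspecific association — nanoparticles, right-handed
  wraps — count as "DNA associated with a core", as a wrapped-length
  histogram requires.
* **Handedness**: the axial circulation of the bound run multiplied by
  the sign of its advance along the core axis; the product is a true
  chirality, invariant to the DNA's traversal direction.
* **Defect classes** with explicit precedence: right_handed > loop
  (bound segments > 500 bp apart) > dimer_cluster (bound-range centres
  within 160 bp, both cores under-wrapped) > correct (≥ 130 bp,
  contiguous, left) > locked_partial (partial coverage plus a
  site-bound bead out of path registry) > partial (everything else).
  All thresholds are configurable and reported in the output metadata.
* **Digestion**: unprotected beads (not bound, not within 1 bead of a
  bound run) are cut with probability 1 − exp(−rate) on their upstream
  bond; fragment lengths in bp always sum to the DNA length; structure
  is held fixed during digestion. The gel render maps migration
  linearly in −log10(length) with intensity ∝ bp.
* **Flattening**: auxiliary dynamics in a slit narrowing to one core
  diameter, binding forces on, soft-core off; warns if the gap is not
  reached.
* **AFM-style statistics** on (flattened) configurations: triplet
  angles, 2D nearest-neighbour distances, linker contour lengths, the
  all-pairs separation distribution, and the zig-zag fraction (how often
  a nucleosome's spatial nearest neighbour is its next-but-one along
  the fibre).
* **Welch's t-test** wraps `stats::t.test` (unequal variances,
  Welch–Satterthwaite df).

## What the synthetic generator does and does not show

`make_fixture()` builds the ideal fibre and one archetype per defect
class by construction, with nuisance randomization (global pose, small
jitter) under a seed. These fixtures validate the *analysis* — the
classifier recalls 100% of archetypes across seeds — and calibrate
thresholds. They are geometrically ideal: passing those tests says the
observables are computed correctly, not that real chromatin looks like
the fixtures. The dynamical claims are tested separately on simulated
assemblies.

## Numerical choices and degenerate inputs

* Twist over an empty/single-bead range returns 0 with a warning;
  per-nucleosome ΔLk on a core wrapping < 130 bp raises an
  undefined-topology error.
* Writhe needs ≥ 4 vertices; degenerate (zero-length) pair geometry
  contributes zero.
* The bead/site angular well and the distance wells are C¹ at their
  cutoffs; all gradients are exact (finite-difference validated to
  < 1e−5 relative).
* The gel mobility model is purely presentational.

## Problem sizes used by the tests

Calibrations run 150–200-bead free chains for ~100–150 τ_B;
reconstitution checks run 1.1 kbp with 5 cores for 0.135 ms mapped;
topology property tests use 60–80-bead rings. These sizes are chosen so
the whole battery completes on a laptop-class single core while each
check still has the statistics its tolerance needs; the full-scale
experiment (22.1 kbp, 100 cores, 0.3 ms, 10 replicas) runs through
exactly the same code path via `make_protocol(scale = 1)` on cluster
time.

## Known limitations

* Desk-scale chains are ~15 persistence lengths, so the coil
  self-entanglement that makes topo-II rescue dramatic at full scale is
  largely absent; at these sizes the intervention improves the correct
  fraction consistently but with a small effect size, and free chain
  ends drain part of the torsional frustration.
* No explicit electrostatics (phenomenological force fields; Debye
  length ≈ 1 nm at ≥100 mM salt), no hydrodynamic interactions, no
  histone tails or H1, no sequence-dependent affinity: positioning
  sequences are emulated only by regular pre-placement.
* Digestion does not let the structure rearrange while being cut, so
  partial wraps are not rescued by the nuclease as they may be in real
  experiments.
* The discrete ribbon's Tw + Wr tracks the exact linking number to
  ~0.1 turn at 2.5 nm resolution; exact statements use the Gauss
  linking integral.
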