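---
title: "Methods: contacts, hydrogen bonds, flexibility and orientation landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contacts, hydrogen bonds, flexibility and orientation landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchortraj)
```

This vignette documents the models and estimators the package implements,
the assumptions they make, the numerical choices behind them, and what the
synthetic validation does and does not demonstrate about real data.

## Data model and units

Structures and trajectories enter as (multi-model) PDB. Internally all
lengths are nanometres — PDB Ångström values are divided by 10 on read —
because the contact cutoffs that define the headline analysis are naturally
quoted in nm; hydrogen-bond criteria remain in Å, the unit in which they
are universally quoted. Frames and atom indices are 0-based internally;
`residue_seq` keeps the source file's (typically 1-based) numbering so that
residues can be addressed the way structural biologists name them
(e.g. Y61). Only orthorhombic boxes are supported and minimum-image
distances wrap per axis; bilayer systems are conventionally built in such
boxes, and triclinic support would complicate the distance kernel for no
gain here. Readers for binary trajectory formats (DCD/XTC) are not
bundled; any converter that emits multi-model PDB, or code that fills the
`Trajectory` contract (a frames × atoms × 3 nm array plus optional box and
time stamps), plugs in above the same analyses.

## Dual-cutoff contact booking

A residue–lipid-molecule contact is defined on the *minimum* atom–atom
distance with hysteresis: entry requires dropping below the lower cutoff
(default 0.55 nm), exit requires reaching the upper cutoff (default
1.0 nm). A single threshold would fragment one physical binding event into
many as the distance flickers around the boundary; the two-cutoff rule
books it as one event. With the two cutoffs set equal the rule
degenerates to simple thresholding, which the tests exploit as an oracle.

Two residence-time estimators are provided:

* **mean event duration** (default) — unambiguous, assumption-free;
* **survival-exponential** — least-squares fit of the event survival curve
  S(t) = P(duration ≥ t) by a single exponential (residence = 1/k) or a
  two-component mixture (residence = A/k₁ + (1−A)/k₂). The biexponential
  is legitimately singular when the underlying process is memoryless; the
  fit then falls back to the single exponential.

Occupancy is the percentage of frames in which the residue touches at
least one molecule of the species (a union over molecules, so two lipids
swapping places do not double-count frames). Events still open at the end
of a trajectory are closed there and their truncated durations counted;
with event counts in the hundreds this censoring bias is far below the
sampling noise, and correcting it would require dwell-law assumptions the
default estimator deliberately avoids. Replicates are pooled with equal
frame weight: tables are concatenated and frame counts summed.

Hotspot flagging is a pure reporting convenience — residues with occupancy
and residence both above user thresholds. No default thresholds are
supplied because sensible values depend on the lipid: weakly bound species
(cholesterol) warrant lower bars than strongly bound ones.

## Hydrogen bonds

A bond is booked for every donor–hydrogen–acceptor triplet with
D–A ≤ 3.0 Å and D–H–A angle ≥ 150°, the documented defaults of the
standard geometric analysis; both are parameters since reasonable studies
use 3.0–3.5 Å and 120–150°. Donor/acceptor typing is by atom-name lookup
(backbone and polar side-chain N/O for protein; phosphate and ester
oxygens for phosphatidylcholine lipids), extensible per call — this avoids
any dependence on force-field topology files. Hydrogens are attached to
the nearest donor heavy atom within 1.2 Å in the first frame; donors with
no resolvable hydrogen (coarse-grained input) are skipped with a warning
rather than an error, so mixed-resolution systems still analyse.

Per-residue averages divide the residue's record count by the total frame
count. The default counts only bonds the residue *donates*; `count =
"both"` adds accepted bonds, since which convention a published
per-residue profile uses is often unstated and the two differ for
acceptor-rich residues.

## Tilt, linker angle and RMSF

The membrane normal is taken as the +z box axis — exact for a planar
bilayer built that way, and deliberately not replaced by a fitted membrane
plane, which would entangle protein motion with membrane undulation. A
tilt series is `acos(v·ẑ/|v|)` for the vector between two single-atom
selections, reported unsigned in [0°, 180°]; `tilt(v) + tilt(−v) = 180°`
is enforced as a property test. Distributions are exported both as raw
series and Gaussian-KDE curves per replicate.

RMSF per residue is `sqrt(mean |r − ⟨r⟩|²)` over frames of the Cα atoms.
With `superpose = TRUE` (default) rigid-body motion is removed first by
iterated mean-structure fitting: superpose all frames on the current mean
(Kabsch), recompute the mean, repeat until the mean moves < 1e-6 nm (≤ 10
rounds — convergence in practice takes 2–3). The same estimator applied to
a multi-model NMR deposition (`ensemble_spread()`) gives the per-residue
ensemble RMSD on an identical footing, so simulation and experiment
overlay without convention mismatches. Note one estimator-intrinsic bias:
the 6-DOF rigid fit absorbs a fraction ≈ 6/(3N) of isotropic noise
variance for N fitted atoms, deflating RMSF by ~1% at N = 100. The
synthetic recovery tests hold the plain estimator to 2% and the superposed
one to 5% accordingly.

## Orientation landscape

Each frame's alignment selection is superposed onto a reference by the
Kabsch algorithm (SVD of the weighted cross-covariance, reflection branch
corrected to det = +1; collinear point sets are rejected as
underdetermined). The *orientation* of the frame is the inverse of the
superposition rotation — the rotation carrying the reference into the
frame — and is decomposed under the Tait–Bryan Z–Y–X convention
R = Rz(φ)·Ry(θ)·Rx(ψ):

* θ = −asin(R₃₁) ∈ [−90°, 90°] (tilt about y),
* ψ = atan2(R₃₂/cos θ, R₃₃/cos θ) ∈ (−180°, 180°] (tilt about x),
* φ (rotation about the membrane normal) is discarded.

Z–Y–X is the unique order in which those two closed-form expressions hold,
and the discard of φ is exact in it: the tests verify that (θ, ψ) are
recovered to < 1e-9° from Rz(φ)Ry(θ)Rx(ψ) for arbitrary φ. At
|θ| → 90° (cos θ → 0) ψ and φ cease to be separable ("gimbal lock"); such
poses are flagged, given ψ = 0, kept in the pose table and excluded from
the density with a reported count, rather than silently assigned an
arbitrary ψ. The second analytic solution θ′ = 180° − θ is intentionally
not emitted; one consistent branch suffices for a landscape.

The pooled (θ, ψ) pairs are smoothed by a separable Gaussian KDE on a 1°
grid (181 × 361), bandwidth per axis by Scott's rule (σ·n^(−1/6), floored
at the grid step so zero-variance degenerate inputs still produce a
density). The ψ axis is periodic and the kernel wraps on its 360° circle;
θ does not wrap (±90° are genuinely extreme tilts, not neighbours). Modes
are 8-neighbour local maxima at ≥ 10% of the global maximum (ties broken
toward lower (θ, ψ)); each non-gimbal pose is assigned to its nearest mode
under the metric √(Δθ² + Δψ²_wrapped), which also drives
representative-frame retrieval. The default reference is frame 0 of the
first replicate; any structure sharing the alignment selection can be
supplied instead, and all poses are relative to that choice.

## Synthetic generators: what they emulate, and what they do not

Every analysis stage is tested against a generator whose ground truth is
analytic:

* **Orientation mixtures** — components at chosen (θ, ψ) means with
  independent clipped-Gaussian spread (default σ = 5°, a tight preferred
  pose) and uniform φ. A matrix-Fisher distribution would be the
  principled choice on SO(3), but its modes are not readable off the spec;
  independent Gaussians keep recovery tests exact.
* **Markov contact kinetics** — two-state chains started at stationarity;
  bound/unbound frames draw distances strictly below/above the cutoff
  band, so booked events equal dwell times exactly and occupancy/residence
  have closed forms. The study-scale fixture uses p_on = 0.05,
  p_off = 0.10 over 50 000 frames (stationary occupancy 1/3, mean dwell
  10 frames).
* **Hydrogen-bond triplets** — three atoms placed at an exact D–A distance
  and D–H–A angle (D–H = 1.0 Å, the hydrogen position solved by
  root-finding on the D-side opening angle; unrealisable geometries are
  rejected). Triplets are spaced 5 nm apart so criteria act on one triplet
  at a time.
* **Per-residue jitter** — isotropic Gaussian noise of known σ, RMSF
  √3·σ in closed form; σ = 0.05 nm over 10 000 frames for the recovery
  test.

These fixtures verify the *estimators*, not the physics: they contain no
correlated protein motion, no anchored-tether kinematics (the GPI linker
analysis is exercised on explicit two-point vectors instead, keeping its
truth analytic), no multi-exponential unbinding, and uniform rather than
Boltzmann-weighted distances within a state. Passing them shows the
pipeline measures what it claims to measure on data whose answer is known;
it does not certify force fields or sampling of any particular real
system.

## Problem sizes and reproducibility

The test-suite and acceptance-script problem sizes — 1000 random rotations
for the Euler oracle, 100 ten-atom bodies × 1000 probe rotations for
Kabsch optimality, 50 000-frame kinetics, 100 residues × 10 000 frames for
RMSF, 2000-frame two-component landscapes — are chosen so each statistic's
sampling error sits comfortably inside its tolerance while the whole
validation runs in well under a minute on one core. Generators are pure
functions of their spec (seed included); the CLI records tool version,
options and seed in a JSON sidecar next to every output, and the global
RNG state is saved and restored around every generator call so library use
never perturbs a user's session RNG.

## Known limitations

* Multi-model PDB is the only bundled trajectory reader; large binary
  trajectories must be converted or adapted.
* Triclinic boxes and curved membranes are unsupported; the membrane
  normal is fixed to +z.
* Contact analysis is residue ↔ lipid-molecule on minimum distance;
  binding-*site* clustering across residues, representative-pose scoring
  and bootstrapped koff estimation are out of scope.
* Hydrogen-bond detection is geometric only — no energies, no
  water-mediated bridges.
* The landscape treats (θ, ψ) with a product metric; for |θ| near 90° the
  underlying spherical geometry compresses ψ, so mode positions there are
  grid-accurate but inter-mode distances are not geodesic.
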