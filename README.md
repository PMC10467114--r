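# anchortraj

Trajectory analysis for GPI-anchored and other membrane-tethered proteins.

A protein held to a lipid bilayer by a glycosylphosphatidylinositol (GPI)
anchor — such as the complement-regulatory receptor CD59 — is not fixed in
one pose: its ectodomain tilts, wobbles and can even flop down onto the
membrane surface, and which poses it samples determines which binding
partners can reach it. Characterising that behaviour from molecular-dynamics
trajectories takes four standard analyses, which this package implements
over plain multi-model PDB input:

1. **Protein–lipid contacts** with the dual-cutoff (hysteresis) definition:
   a residue–lipid contact begins when their minimum atom–atom distance
   drops below a lower cutoff (default 0.55 nm) and persists until it
   exceeds an upper cutoff (default 1.0 nm). Per residue and lipid species
   the pipeline reports *occupancy* (% of frames in contact with ≥ 1
   molecule of the species) and *residence time* (mean contact-event
   duration; an exponential survival-curve fit is available as an
   alternative estimator), plus hotspot flagging at user thresholds.
2. **Hydrogen bonds** by the geometric criterion D–A ≤ 3.0 Å and
   D–H–A ≥ 150° (both configurable), with per-residue average bond counts
   over pooled replicates.
3. **Flexibility**: tilt-angle series of any two-atom axis (e.g. the
   N-to-C-terminal vector, or the GPI linker from inositol C6 to the
   protein-proximal mannose C4) against the membrane normal (+z), and
   per-residue Cα RMSF after iterated least-squares superposition, directly
   comparable to the per-residue RMSD of an NMR ensemble
   (`ensemble_spread()`).
4. **Orientation landscape**: every frame is superposed onto a reference
   with the Kabsch algorithm; the body's orientation matrix
   R = Rz(φ)·Ry(θ)·Rx(ψ) (Tait–Bryan Z–Y–X) is decomposed as

       θ = −asin(R₃₁)          (tilt about y, −90° … 90°)
       ψ = atan2(R₃₂/cos θ, R₃₃/cos θ)   (tilt about x, −180° … 180°)

   discarding φ, the rotation about the membrane normal, which is
   functionally irrelevant for a membrane-tethered body. The pooled (θ, ψ)
   pairs form a 2-D landscape via Gaussian KDE (Scott's-rule bandwidth,
   1° grid); local density maxima are reported as preferred poses, and
   `frames_near()` retrieves the frames closest to any queried orientation.
   Poses with |θ| ≈ 90° (gimbal lock, where ψ and φ are inseparable) are
   flagged and excluded from the density.

Every stage is validated against a synthetic generator with analytic ground
truth: orientation mixtures with known (θ, ψ) per frame, two-state Markov
contact kinetics (stationary occupancy p_on/(p_on+p_off), mean dwell
1/p_off), hydrogen-bond triplets constructed at exact distance/angle, and
per-residue Gaussian jitter whose RMSF is √3·σ in closed form.

## Worked example

Plant two preferred poses, rebuild the landscape, and retrieve
representative frames:

```r
library(anchortraj)

spec <- orientation_mixture_spec(
  data.frame(mean_theta = c(-30, 45), mean_psi = c(40, -120),
             stdev = c(5, 5), weight = c(0.5, 0.5)),
  n_frames = 1000, seed = 42)
sim <- make_orientation_trajectory(spec)

ls <- build_landscape(sim$trajectory, sim$topology,
                      reference = spec$reference_coords,
                      align_sel = "name CA")
ls
#> Orientation landscape: 1000 poses (0 gimbal-locked excluded from KDE)
#> KDE bandwidth (theta, psi): 11.9, 25.3 deg
#> Modes:
#>   theta_deg psi_deg      density n_members
#> 2        45    -120 0.0002511922       527
#> 1       -30      40 0.0002267091       473
```

Both planted poses are recovered exactly on the 1° grid, with the 1000
frames split 527/473 between them (the mixture draw for this seed).
Frames nearest the (−30°, 40°) pose:

```r
frames_near(ls, -30, 40, k = 3)
#>   replicate frame theta_deg  psi_deg      rmsd_nm gimbal_flag distance_deg
#> 1         1   742 -30.02822 39.81979 4.393288e-16       FALSE    0.1824081
#> 2         1   701 -29.81697 39.64131 3.849579e-16       FALSE    0.4026928
#> 3         1   328 -29.53116 40.09283 2.213044e-16       FALSE    0.4779417
```

Dual-cutoff booking on a hand-traceable distance series (nm): the contact
entered at 0.40 survives 0.60 and 0.90 (still under the 1.0 nm upper
cutoff), ends at 1.20, and a second contact starts at 0.30:

```r
book_events(c(0.40, 0.60, 0.90, 1.20, 0.30, 0.30))
#>   start_frame end_frame
#> 1           0         3
#> 2           4         6
```

A command-line interface wrapping the same functions ships at
`inst/cli/anchortraj.R` (subcommands `simulate`, `contacts`, `hbonds`,
`tilt`, `rmsf`, `orient`, `orient-frames`).

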