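# hingescope

Hinge-bending domain motion analysis for two-domain enzymes.

Angiotensin-converting enzyme (ACE) and its homologue ACE2 bury their
catalytic zinc at the bottom of a cleft between two subdomains. Substrate
access requires a hinge-bending "mouth" motion: the subdomains swing
apart (open), admit the peptide, and reclose. `hingescope` provides the
trajectory and structure analyses used to quantify this motion from MD
trajectories and crystal structures, for structural biologists and
simulators studying domain motions in ACE-family (or any two-domain)
enzymes:

- **Lip-center distance** — the distance between the centers of geometry
  of two Cα residue sets ("lips") flanking the cleft, one per subdomain:
  `d = |⟨x⟩_lipI − ⟨x⟩_lipII|`.
- **Conformational states** — closed (`d < 15 Å`), open (`d > 20 Å`),
  semi-open in between; occupancies and the number of closed↔open
  conversions along a trajectory.
- **Hinge-bending angle** — the magnitude of the rigid rotation of
  subdomain I relative to subdomain II, via a two-stage Kabsch
  superposition anchored on subdomain II:
  `θ = arccos((tr R − 1)/2)` of the second-stage rotation `R`.
- **Cα RMSD / RMSF** — per-frame deviation from the initial structure and
  per-residue fluctuation about the two-pass mean structure.
- **Hydrogen bonds** — geometric detection (donor–acceptor ≤ 3.3 Å,
  proton-donor-acceptor angle ≤ 30°) and per-frame counts reported as
  mean ± sd.
- **Synthetic ground truth** — a two-rigid-domain toy enzyme whose
  domain I rotates about a known hinge axis under a programmed angle
  schedule with Gaussian coordinate noise, so every estimator can be
  validated against exact expected values without running MD.

Region presets for the somatic ACE C-domain (PDB 4APH numbering) and
ACE2 (1R4L/1R42 numbering) ship with the package; see
`?region_preset` and the vignette for their definitions and provenance.

## A worked example

```r
library(hingescope)

params <- synthetic_hinge_params(
  angle_schedule = list(type = "sinusoid", amplitude = 25, period = 2),
  n_frames = 101, timestep = 0.1, noise_sd = 0.1, seed = 42)
sim <- generate_hinge_trajectory(params)

sim$toy$theta_open
#> [1] 19.09258

res <- analyze_trajectory(sim$trajectory, sim$toy$regions,
                          reference = sim$toy$frame)
res
#> <hinge_result> 101 frames | distance 11.96-22.41 A | occupancy closed 0.356 / semi 0.297 / open 0.347 | 10 conversions

head(res$table, 3)
#>   time_ns distance_A  state  angle_deg
#> 1     0.0   11.96281 closed 0.02699443
#> 2     0.1   12.27898 closed 0.52771277
#> 3     0.2   13.05987 closed 2.34589667
```

The toy opens past 20 Å whenever the programmed hinge angle exceeds
`theta_open` = 19.09°; the 25°-amplitude sinusoid does so five times in
10 ns, producing the 10 closed↔open conversions reported (each round
trip counts twice: once opening, once reclosing). The per-frame
`angle_deg` column recovers the programmed schedule to a fraction of a
degree despite 0.1 Å coordinate noise.

For crystal-structure pairs, `lip_distance()` and `hinge_angle()` operate
on `read_pdb()` output with a preset, e.g.
`lip_distance(read_pdb("4APH.pdb"), region_preset("sace_cdomain"))`.

A command-line front end over the same functions (subcommands `analyze`,
`compare`, `hbonds`, `simulate`) is installed at
`system.file("cli", "hingescope.R", package = "hingescope")`.

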