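---
title: "Quantifying hinge-bending domain motions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hinge-bending domain motions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hingescope)
```

## The scientific problem

Angiotensin-converting enzyme (ACE) and its homologue ACE2 are two-lobed
zinc peptidases whose active site lies buried at the bottom of a deep
cleft between two subdomains. Substrates can only reach the catalytic
zinc if the two subdomains swing apart about a hinge — a mouth
opening/closing motion. Crystal structures of ACE are almost exclusively
closed; the open conformation is known experimentally only from ACE2. MD
simulations of the ligand-free enzyme, by contrast, show spontaneous
opening and reclosing. This package implements the trajectory analyses
that quantify that motion:

1. **Lip-center distance.** Two residue sets ("lips") flanking the cleft
   are fixed, one on each subdomain. For a conformation, the distance
   between the centers of geometry of the lip Calpha atoms measures how
   far the mouth is open.
2. **Conformational states.** A frame is *closed* when the lip distance
   is `< 15` Å, *open* when `> 20` Å, and *semi-open* in between.
   Distances exactly at a threshold fall to semi-open, preserving the
   strict inequalities of the open/closed definitions.
3. **Hinge-bending angle.** The rigid rotation of subdomain I relative to
   subdomain II between a frame and a reference conformation.
4. **Calpha RMSD/RMSF.** Standard per-frame deviation from the initial
   structure and per-residue fluctuation about the time-averaged
   structure.
5. **Hydrogen-bond counts.** Geometric detection between a ligand and the
   enzyme, summarised as mean ± sd per frame.

Long explicit-solvent MD is far outside a test suite's budget, so the
package also ships a synthetic two-rigid-domain generator with exact
ground truth; every stage of the analysis is validated against it.

## The hinge-angle procedure

The literature reports mouth-open angles without fixing a procedure, so
the package defines one and applies it uniformly:

1. Superpose the frame onto the reference with the Kabsch algorithm using
   the Calpha atoms of **subdomain II** common to both structures. This
   anchors the subdomain that the field conventionally treats as fixed
   (the same anchoring used when rendering open/closed snapshots).
2. Kabsch-fit the aligned frame's **subdomain I** Calpha set onto the
   reference subdomain I.
3. Report the rotation angle of that second fit,
   `acos((trace(R) - 1) / 2)`, in degrees in `[0, 180]`.

Because step 1 removes the global motion and step 2 isolates the
interdomain rotation, the procedure returns exactly the programmed angle
on noise-free rigid-body data (verified to ~1e-12 degrees in the test
suite) and is symmetric in frame/reference to numerical precision. When
the two structures share only a subset of the region residues (crystal
gaps), the residue intersection is used for both fits.

Both referencing modes used in practice are supported: a trajectory's
first production frame (the default in `analyze_trajectory()`) or an
explicit crystal structure (`reference =`), the closed structure being
the conventional reference for structure pairs.

## Kabsch superposition

`kabsch()` is implemented from the singular-value decomposition of the
3×3 cross-covariance of the centred point sets, with the sign of the
smallest singular vector corrected so the returned rotation always has
determinant +1 — reflections are never returned, even for near-mirrored
inputs. Fits are unweighted throughout: every analysis here operates on
Calpha atoms only, so mass weighting would change nothing and is not
offered. Orthonormality of rotation matrices supplied by the caller is
validated to 1e-6 on entry; near-collinear point sets (smallest two
singular values degenerate) produce a warning rather than an error, since
the translation and fitted RMSD remain meaningful.

An independent implementation of rigid superposition (`bio3d::fit.xyz`)
is used in the test suite as a cross-check oracle on random instances; it
is never called by the package itself.

## RMSD and RMSF conventions

- `rmsd_series()` superposes each frame onto the first frame (or a
  supplied reference) on all Calpha atoms, then reports the unfitted
  paired RMSD over the same atoms. Whether published trajectory RMSD
  curves fit on all Calpha or on subdomain II alone is usually unstated;
  all-Calpha fitting is the conventional reading, and the fitting
  selection is exposed (`fit_selection`) for the other choice.
- `rmsf_profile()` uses the two-pass mean-structure convention: align all
  frames to frame 1, average, re-align all frames to the average, then
  `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|²)`. For pure isotropic
  N(0, σ²) coordinate noise the closed-form expectation is σ√3; the test
  suite confirms convergence within 5% at T = 2,000 frames.
- RMSD is conventionally computed on the full trajectory while RMSF,
  occupancies and hydrogen-bond summaries use only the production stage
  (frames with time strictly after the equilibration cutoff);
  `run_analysis()` follows exactly that split. Equilibration is specified
  in nanoseconds, not frames, and automatic detection of the
  equilibration point is deliberately out of scope — published cutoffs
  are determined by eye from RMSD/energy traces, so the cutoff is a
  required input.

## Conversion counting

"Conversions between the open and closed states" is made precise as:
each time the state sequence reaches *open* after most recently having
been *closed*, or vice versa, one conversion is counted. Semi-open frames
are transparent — they neither count nor reset the most recent endpoint.
Consequently a closed → semi-open → closed excursion counts zero, a
closed → semi-open → open passage counts one, and one full
closed → open → closed round trip counts two. This endpoint definition is
the only reading under which semi-open flicker (ubiquitous in noisy
trajectories, since the band is only 5 Å wide) does not inflate the
count, and it makes the statistic robust: coordinate noise can jitter the
crossing frame but cannot create or destroy a conversion unless it
carries the distance across the full 5 Å band.

## Hydrogen-bond detection

The geometric criteria are the standard `3.3` Å donor–acceptor distance
and `30`° proton–donor–acceptor angle, both inclusive. The angle is
measured at the donor, between the D→H and D→A vectors, so small values
mean near-linear D—H···A; this matches the convention of the common MD
post-processing tools. Donors are N/O atoms with a hydrogen within
1.25 Å (proximity, not connectivity records, because PDB inputs often
lack CONECT), acceptors are all N/O atoms, and each (donor, hydrogen,
acceptor) triple is reported at most once per frame — a donor with
several hydrogens can bond the same acceptor only via distinct
hydrogens.

Two deliberate safety choices:

- A structure with no hydrogens raises an explicit `no_hydrogens` error.
  Crystal structures carry no protons, and a silent zero would be a
  trap. A documented `heavy_atom_mode` applies the distance criterion
  only, reports each heavy-atom pair once (donor/acceptor roles being
  indistinguishable without protons), and labels its output.
- Per-frame counts are summarised as mean and **population** standard
  deviation (denominator T). With thousands of frames the T vs T−1
  distinction is far below reporting precision, but the choice is fixed
  and documented so summaries are exactly recomputable from the counts.

## The synthetic two-domain generator

`build_toy_enzyme()` places two compact Calpha lattices (3.8 Å spacing,
near-cubic) facing each other across a cleft: domain II below, domain I
above, inner faces 12 Å apart, with the mouth centre 25 Å from the hinge
point along +x and the hinge axis along −y. The lips are the mutually
closest `lip_fraction` (default 0.2) of each domain's residues — the
patch rimming the cleft. With the default 100+100 residues this yields a
closed-state lip distance of 12 Å and an opening angle
`theta_open ≈ 19.1°` at which the lip distance crosses 20 Å — deliberately
in the 16–18° range reported for real ACE/ACE2 hinge motions, so the toy
exercises the same numerical regime.

Because rotation commutes with taking the centre of geometry, the
noise-free lip distance has the closed form

d(θ)² = |w₀|² + |v⊥|² + 2 cos θ (w₀·v⊥) + 2 sin θ (w₀·(a×v)),

where `v` is the lip-I centre relative to the hinge point, `v⊥` its
component normal to the axis `a`, and `w₀` collects the fixed terms.
`theta_open` is the root of `d(θ) = 20` on (0°, 90°], found by uniroot at
1e-12 tolerance; geometries that cannot reach 20 Å within 90° are
rejected as infeasible. This closed form is also the generator's ground
truth for per-frame ideal distances, verified against the measured
distances to 1e-9 in the tests.

`generate_hinge_trajectory()` supports three angle schedules — constant,
sinusoid (0 → amplitude → 0 per period), and a reflecting-bounds random
walk whose dwell statistics resemble the multiple spontaneous
open/closed conversions seen in long Apo simulations. Gaussian coordinate
noise (default study conditions: 0–0.3 Å, bracketing the effective
positional noise of a thermalised Calpha trace) is applied **after** the
rotation and to **all** atoms including the anchor domain, so
alignment-based analyses are stressed realistically. All randomness flows
from one explicit integer seed; generation is bit-reproducible.

What the toy does *not* emulate: internal flexibility within a domain,
anharmonic side-chain chemistry, solvent damping, and the
autocorrelation of thermal noise. Passing tests therefore demonstrate the
*correctness of the estimators on rigid-body motion plus white noise*,
not force-field realism; conclusions about real trajectories still
require real trajectories.

`generate_hbond_fixture()` plants donor–hydrogen–acceptor triples on a
20 Å grid (so triples cannot interact): true bonds satisfy both criteria
with ≥ 0.05 Å / 2° margin, decoys violate exactly one criterion by at
least the same margin, alternating which. This gives exact expected
counts for the detector with no tolerance juggling.

## Region presets and their provenance

Two presets ship as YAML (`region_preset()`):

- `sace_cdomain` — the somatic ACE C-domain in 4APH author numbering:
  lip I 73–100, 297–304, 348–354, 370–379 on subdomain I (40–122,
  297–437, 551–583); lip II 128–150, 160–173, 284–293 on subdomain II
  (123–296, 438–550, 584–625).
- `ace2` — ACE2 in 1R4L/1R42 numbering: lip I 54–81, 289–296, 340–346,
  361–370; lip II 109–131, 143–156, 267–276.

Two caveats are worth recording. First, some published figure captions
list the *ACE2* lip-II residue numbers alongside the *sACE* subdomain
definition; the sACE preset here follows the sACE residue sets, and the
discrepancy is simply documented rather than resolved. Second, no
published ACE2 subdomain partition exists in ACE2 numbering, so the
`ace2` preset's subdomain boundaries are a package-defined
homology-based split chosen to contain the published lips with the same
topology as the ACE partition; they affect only the hinge-angle anchor,
not the lip distances.

Residue numbering is author (PDB) numbering including insertion codes,
ranges inclusive on both ends. Residues declared in a range but absent
from a structure are reported and skipped with a warning, never a hard
failure — crystal structures routinely lack loop residues. Alternate
locations resolve to the highest-occupancy copy (ties to the
lexicographically first altloc), and HETATM records are retained but can
never enter a Calpha selection (a calcium ion named `CA` is not a
Calpha).

## Numerical and degenerate-input choices

- Thresholds: boundaries (exactly 15 or 20 Å) classify as semi-open.
- Kabsch needs ≥ 3 paired points; fewer is an `underdetermined` error.
  Collinear sets warn.
- Rotation-matrix validation tolerance: 1e-6; the `acos` argument is
  clamped to [−1, 1].
- Empty selections, zero-ATOM structures, non-increasing frame times,
  overlapping H-bond selections, and negative distances all raise typed
  conditions (`hingescope_*` classes) rather than generic errors.
- Trajectory trimming keeps frames with time strictly greater than the
  cutoff and errors if fewer than 2 frames remain.

## Problem sizes used in validation

The test suite and the acceptance script validate at the following
scales, chosen to give each statistic comfortable resolving power:
1,000 random rigid motions for exact Kabsch recovery and for the noisy
optimality check; 100 random frames against the brute-force hydrogen-bond
oracle plus 50 planted-fixture seeds; hinge-angle recovery on the default
200-residue toy over 2,000-frame trajectories (one noise-free run, and
100 seeds at 0.3 Å noise, where the mean absolute error is ≈ 0.28–0.30°
against a 1.5° requirement); and RMSF convergence to the σ√3 closed form
at T = 2,000. The complete run takes a few minutes on one core.

## A worked example

```{r example}
params <- synthetic_hinge_params(
  angle_schedule = list(type = "sinusoid", amplitude = 25, period = 2),
  n_frames = 101, timestep = 0.1, noise_sd = 0.1, seed = 42)
sim <- generate_hinge_trajectory(params)
sim$toy$theta_open

res <- analyze_trajectory(sim$trajectory, sim$toy$regions,
                          reference = sim$toy$frame)
res
res$occupancy
res$n_conversions
```

The trajectory opens and recloses five times (amplitude 25° exceeds
`theta_open` ≈ 19.1°), giving ten closed↔open conversions; with 0.1 Å
coordinate noise the recovered per-frame angles track the programmed
schedule to a small fraction of a degree.

## Known limitations

- The hinge angle is a magnitude in [0°, 180°]; the axis and its
  placement (DynDom-style screw axes) are not localised.
- State occupancies are raw frequencies; no free-energy or kinetic
  modelling is attempted.
- PDB input only (single- or multi-MODEL, or topology + frames written
  as MODELs); mmCIF, DCD/XTC binary trajectories, bond perception and
  hydrogen placement are out of scope. Crystal-structure analyses that
  need protons should be run on pre-protonated models or in the labelled
  heavy-atom mode.
- Equilibration detection is manual by design (see above).
```
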