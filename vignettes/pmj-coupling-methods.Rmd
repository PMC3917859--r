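---
title: "Purkinje-myocyte junction coupling and reentry dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purkinje-myocyte junction coupling and reentry dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The Purkinje system is the heart's fast conduction network. It touches the
working myocardium only at discrete Purkinje-myocyte junctions (PMJs), whose
number and distribution are essentially unknown in vivo, and many of which
may be non-functional. During ventricular fibrillation the junctions conduct
in both directions — anterogradely (Purkinje to muscle) and retrogradely
(muscle to Purkinje) — and the density and electrical properties of the PMJ
population can plausibly change how reentrant arrhythmia organizes and
sustains itself.

`pmjsim` is a desk-scale computational laboratory for this question. It
grows fractal Purkinje trees with a controllable PMJ density on synthetic
endocardial surrogate surfaces, couples them to a two-dimensional monodomain
tissue sheet through an asymmetric resistive junction model, induces reentry
with an S1-S2 cross-field protocol, and quantifies the resulting dynamics
with mean firing rate (MFR), phase-singularity counts, wavebreak incidence
(WBI) and junctional conduction-success statistics. Everything runs from
code in minutes on one CPU; no imaging data or external meshes are needed.

It is deliberately *not* a whole-heart model: there is no bidomain solve, no
biophysically detailed ionic model, no 3D ventricular geometry, and no shock
electrophysiology. The design goal is that every mechanism that the
junction-level analyses depend on — thresholded activation timing,
source-sink asymmetry at the junction, refractoriness mismatch between the
two cell populations — is present and calibrated, while everything else is
reduced to the simplest standard form.

## Synthetic geometry

`make_hemiellipsoid_surface(semi_axes, target_edge, seed)` triangulates the
dome of an ellipsoid by latitude rings spaced at equal meridian arc length,
with per-ring azimuthal resolution tracking `target_edge` (mm). Every vertex
satisfies the ellipsoid equation exactly, winding is outward, and the
reported area (cm^2) is the exact sum of triangle areas. A hemi-ellipsoid is
used as the endocardial surrogate because the tree-growth and
density-placement logic is geometry-generic; a single smooth dome exercises
it fully. The dome is meshed without an equatorial cap so that the reported
area is the endocardial (lateral) area that PMJ densities are normalized by.

The tissue sheet (`tissue_sheet`) is a uniform grid, default 256 x 256 nodes
at dx = 0.25 mm (6.4 x 6.4 cm, 40.96 cm^2), 0-based row-major grid
coordinates, positions in mm, areas in cm^2.

Two analytic fixtures provide oracles with known answers: a rotating-spiral
voltage field whose core position is exact (for the phase-singularity
detector), and an action-potential pulse train with known AP onset times
(for the activation detector). Voltage conventions everywhere: rest at
-85 mV, peak at +30 mV, so the -60 / -40 / -20 mV analysis thresholds apply
without rescaling.

## Fractal tree growth and PMJ placement

Growth is a parallel rewriting process on the surface. Each iteration
replaces every open tip by `daughters_per_tip` (default 2) branches at
+/- `branch_half_angle` (default 40 deg) in the local tangent plane, with
Gaussian angular jitter (sd 8 deg) from a seeded RNG. A branch is five
straight segments of total length 2 mm; after each segment step the new
point is projected onto the closest triangle (exact closest-point search
with a conservative centroid-radius prefilter), so branches follow surface
curvature and every node lies on the surface to machine precision. Branches
whose tip folds back to within half a branch length of their grandparent
node are discarded — the rewriting rule in the literature this follows is
silent on collisions, and rejection is the simplest deterministic choice.
His pacing stimulates all cable nodes within 2 mm of the root seeds; a point
stimulus at a single branch node cannot overcome the diffusive drain of its
neighbours.

PMJ sites are chosen over all grown-branch nodes by a seeded farthest-point
(maximin) traversal: the first site is random, each next site is the
candidate farthest from all chosen sites, and selection stops when that
distance falls below `min_distance`. This guarantees two properties the
analyses rely on: all pairs are at least `min_distance` apart (straight-line
Euclidean distance; the along-branch alternative is not used), and the site
set for a smaller `min_distance` is a superset of the set for a larger one
under the same seed, so PMJ count is strictly monotone in `min_distance`.
Seven `min_distance` values give the package's default density ladder.
`insertion_depth_fraction` (default 0.2) is carried as metadata: wall-depth
insertion has no analog in a 2D sheet, where a PMJ couples to the
`k_coupled` nearest sheet nodes around the terminal's mapped position.

## Electrophysiology

Both cell populations use a two-variable phenomenological excitable model
(Mitchell-Schaeffer class) in normalized voltage u with gate h:

    du/dt = h u^2 (1 - u) / tau_in - u / tau_out + I
    dh/dt = (1 - h) / tau_open        (u < u_gate)
          = -h / tau_close            (u >= u_gate)

mapped to membrane voltage by V = -85 + 115 u (mV). Parameters (ms):

| population | tau_in | tau_out | tau_open | tau_close | u_gate | APD at 500 ms |
|------------|--------|---------|----------|-----------|--------|----------------|
| myocardium | 0.3    | 6       | 80       | 50        | 0.13   | ~85 ms         |
| Purkinje   | 0.3    | 5       | 100      | 90        | 0.13   | ~130 ms        |

The Purkinje action potential is intrinsically longer than the myocardial
one — the premise behind the junctional asymmetry analyses — and the
myocardial wavelength (CV x APD ~ 3 cm at D = 0.05 mm^2/ms) fits several
times into the default sheet so spiral-wave reentry can sustain. The
myocardial `di_facilitation = 0.5` knob shortens the effective recovery time
constant while the gate is far from rest, easing re-excitation at short
diastolic intervals; it replaces, at the same functional level, a
calcium-current recovery-kinetics modification used for the same purpose in
detailed ionic models.

Numerics: explicit operator splitting at dt = 0.05 ms; 5-point Laplacian
with no-flux boundaries on the sheet (stability dt <= dx^2/(4 D)); graph
Laplacian weighted by 1/len^2 on the cable network, sub-stepped twice per
sheet step because degree-3 branch nodes tighten the explicit bound to
1/(D max_i sum_e len_e^-2); both bounds are checked before every run and
violations are an error, as is any voltage outside +/-100 mV. Halving dt
changes activation times by under 1%. Cable diffusivity is 1.4 mm^2/ms,
giving a Purkinje conduction velocity several-fold the sheet's, and all
stimuli are conductance-like drives amp (1 - u), bounded by construction.

## The PMJ model

Each PMJ connects one terminal Purkinje node to its `k_coupled` (default 6)
nearest sheet nodes through a fixed resistance `R_PMJ`. With voltages in mV
and resistance in MOhm, the current into coupled myocyte j is

    I_j = (V_terminal - V_j) / R_PMJ        (nA)

and the load drawn from the terminal is `loading_factor * sum_j I_j`,
representing the electrotonic load of the tissue around the junction. Charge
bookkeeping is exact: the load divided by the loading factor equals the
summed myocyte currents identically.

Currents enter the normalized cell model through two constants exposed in
`pmj_coupling_params`: `current_conversion` (du/dt per nA for a myocyte,
0.025) and `terminal_capacitance_scale` (the terminal Purkinje cell's
effective capacitance relative to a myocyte, 24; Purkinje cells are large,
and the terminal integrates the scaled load current more slowly). These two
constants were calibrated once, on the single-PMJ rig, so that at
R_PMJ = 20 MOhm and loading factor 20 the anterograde delay lands mid-way in
the physiological 4-14 ms window and the retrograde delay inside 2-4 ms;
they are never varied afterwards. One constant alone cannot satisfy both
windows: scaled by the loading factor, a conversion large enough to charge
the myocytes anterogradely either blocks the terminal or makes retrograde
transmission near-instant.

The junction is asymmetric by construction: anterogradely one loaded
terminal must charge k myocytes through R_PMJ against their diffusive
neighbours, while retrogradely k excited myocytes drive one terminal with
gain `loading_factor`. Measured on the rig, delays increase with R_PMJ and
decrease with `k_coupled` in both directions, and the anterograde delay
exceeds the retrograde delay at matched parameters.

The delay rig (`build_delay_rig`) is a 20 mm straight cable whose distal end
couples to the centre of a 49 x 49 sheet. Anterograde pacing stimulates the
proximal cable end; retrograde pacing launches a plane wave across the
sheet. Delay is the difference between the terminal's first -20 mV upward
crossing and the mean first crossing of the coupled myocytes.

## Reentry induction and sustainedness

`run_s1s2` applies two His paces 500 ms apart (S1), then a premature
half-domain stimulus on the sheet (S2, cross-field surrogate) at coupling
interval CI after the second S1. The vulnerable window is not assumed: it is
found by scanning CI in 10 ms steps (`scan_vulnerable_window`); with the
default calibration the window sits near CI = 140-170 ms. A run is labeled
sustained iff any sheet activation occurs more than 3000 ms after S2.
Failure to induce is a labeled outcome, not an error, and non-sustained runs
terminate early once the whole domain is quiescent.

## Metrics

* **Activation**: first upward crossing of -20 mV, accepted only if at least
  50 ms after the previous accepted activation (blanking applies to accepted
  activations only) and only if the trace has been below -60 mV since the
  previous accepted one. The same rule runs online in the stepper and as the
  trace-based `detect_activations`.
* **MFR**: activation count divided by the 3 s counting interval, per node;
  population means over all sheet / all cable nodes.
* **Phase singularities**: the 2D dialect of the isosurface-intersection
  filament method — marching-squares isolines of V = -40 mV computed on two
  frames 8 ms apart are geometrically intersected; crossing points are where
  the temporal derivative of the iso level vanishes. Intersections are
  deduplicated within 2 grid cells.
* **WBI**: the per-frame PS counts are *time-averaged* and normalized by
  sheet area and by excitation cycles (MFR x duration). Whether to sum or
  average over frames was an open choice; the time average is robust to the
  frame rate and is recorded in the report metadata. The 2D sheet reports a
  single WBI (no endo/epi split exists here).
* **Junctional conduction**: each PMJ's terminal and myocyte activations are
  grouped into episodes separated by >50 ms of quiet. The side that fired
  first sets the direction. Anterograde success requires a strict majority
  (>50%) of coupled myocytes within 16 ms after the terminal; retrograde
  success requires the terminal within 8 ms after the time the myocyte
  majority was reached. Every episode maps to exactly one of the four
  direction x outcome cells; ratios with an empty denominator are reported
  missing, not zero.

## Experiment drivers and problem sizes

`run_density_sweep`, `run_resistance_sweep` and `run_size_sweep` orchestrate
the three experiments (density ladder at R = 20 MOhm / loading 20;
resistance 10-25 MOhm at loading 20; junction size at R = 20 MOhm). Each
condition is replicated over several geometry seeds (default 3) because 2D
reentry on a small sheet is more fragile than whole-ventricle fibrillation,
and trend statements are made on replicate means. Every output row carries
the config hash, seed and a derived run id, and identical configurations
reproduce bit-identical event logs.

The package's standard problem sizes — 256 x 256 sheet, trees of a few
thousand cable nodes, 3.2 s of simulated reentry per run — were chosen so a
full three-density, three-seed study completes in roughly a quarter of an
hour on a single core.

## What the synthetic conditions do and do not show

The generator emulates: a smooth endocardial-like surface, an excitable
sheet that supports sustained spiral reentry at ~8 Hz tissue MFR, fast
cable conduction with longer Purkinje refractoriness, and delay-calibrated
asymmetric junctions. It does not emulate: 3D wall propagation and
transmural filament dynamics, bath/shock physics, heterogeneous fiber
architecture, or biophysical restitution detail. Passing trends here show
that the junction-level mechanisms behave as in the full-scale setting
(delay sensitivities, conduction-success asymmetry, density trends); they do
not reproduce full-scale absolute quantities (epicardial breakthrough times,
specific PMJ counts, WBI magnitudes), which depend on the unavailable
ventricular geometry and detailed ionic models.

## Known limitations

* The sheet-mapped junction ignores wall depth; `insertion_depth_fraction`
  is metadata only.
* The cable-to-sheet footprint mapping is an affine scaling of the tree's
  (x, y) extent; geodesic relationships on the dome are not preserved.
* Episode grouping at very high firing rates can merge near-simultaneous
  bidirectional events; the 50 ms gap matches the blanking interval, so an
  episode holds at most one accepted activation per node.
* A single stable figure-of-eight pair, not multi-wavelet fibrillation, is
  the typical sustained state on the default sheet; PS counts are
  correspondingly small and WBI magnitudes are not comparable to 3D values.
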