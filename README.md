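# pmjsim

Desk-scale simulation of Purkinje–myocardial coupling during reentrant
arrhythmia.

The Purkinje system — the heart's fast conduction network — contacts working
myocardium only at discrete Purkinje–myocyte junctions (PMJs). How many
junctions there are, and how strongly they couple, is largely unknown, yet
both plausibly shape how ventricular fibrillation organizes: junctions let
reentrant wavefronts escape into the Purkinje network (retrograde
conduction) and re-emerge elsewhere (anterograde conduction). `pmjsim` is a
self-contained computational laboratory for that question, for
arrhythmia modellers who want junction-level mechanisms without a
whole-heart pipeline: it grows fractal Purkinje trees with controllable PMJ
density on synthetic endocardial surfaces, couples them to a 2D monodomain
sheet through an asymmetric resistive junction model, induces reentry with
an S1–S2 cross-field protocol, and quantifies the dynamics.

## The model at its core

Each PMJ couples a terminal Purkinje node to its *k* nearest myocardial
nodes through a fixed junctional resistance. With voltages in mV and
resistance in MΩ, the current into coupled myocyte *j* and the load on the
terminal Purkinje cell are

    I_j  = (V_terminal − V_j) / R_PMJ           [nA]
    load = λ · Σ_j I_j                          [nA]

where λ is a loading factor representing surrounding tissue. The junction is
asymmetric by construction — one loaded terminal must charge *k* myocytes
anterogradely, while *k* excited myocytes drive one terminal with gain λ
retrogradely — which reproduces the physiological transmission delays:
anterograde 4–14 ms and retrograde 2–4 ms at R_PMJ = 20 MΩ, λ = 20. Both
cell populations follow a two-variable excitable model (Mitchell–Schaeffer
class) with a longer Purkinje action potential; reentry metrics are mean
firing rate (MFR, −20 mV crossings with 50 ms blanking / 3 s), phase
singularities (intersection of −40 mV isolines 8 ms apart), wavebreak
incidence (WBI = PS per cm² per excitation cycle), and junctional
conduction-success tallies (strict myocyte majority within 16 ms
anterograde / terminal within 8 ms retrograde).

See `vignettes/pmj-coupling-methods.Rmd` for the full model description,
parameter tables and design rationale.

## Worked example

Measure junctional transmission delays on the single-PMJ rig, then run a
small PMJ-density study:

```r
library(pmjsim)

pmj_transmission_delay(r_pmj = 20, loading_factor = 20, k_coupled = 6,
                       direction = "anterograde")
#> [1] 10.35833
pmj_transmission_delay(r_pmj = 20, loading_factor = 20, k_coupled = 6,
                       direction = "retrograde")
#> [1] 3
```

Both land in the physiological windows (4–14 ms and 2–4 ms). A
three-density, three-seed reentry study on the default 256×256 sheet
(roughly a quarter hour on one core):

```r
spec <- sweep_spec("min_distance", values = c(6, 4, 2.5), seeds = 1:3)
res  <- run_density_sweep(spec)
aggregate(cbind(retro_ratio, mean_mfr_purkinje, mean_mfr_tissue, n_pmjs)
          ~ condition, res$table, mean)
#>   condition retro_ratio mean_mfr_purkinje mean_mfr_tissue   n_pmjs
#> 1       2.5   0.2126726          4.748312        8.075772 91.00000
#> 2       4.0   0.1402527          4.282327        8.112749 39.66667
#> 3       6.0   0.1076112          4.062394        8.141841 20.66667
```

Reading the table: smaller `min_distance` means more PMJs. As PMJ density
rises, the fraction of successful retrograde conductions roughly doubles and
the Purkinje-system firing rate rises with it (the network is driven by
retrograde entry), while the tissue firing rate stays pinned near 8 Hz —
the sheet, not the network, sets the reentry cycle length. Anterograde
conduction succeeds far more often than retrograde at every density
(≈0.55–0.65 vs ≈0.10–0.22 here) because the myocardium, with its shorter
action potential, is more likely to be recovered when activity arrives.

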