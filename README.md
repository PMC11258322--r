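# oceStrain

Phase-sensitive optical coherence elastography (OCE) of the cornea:
simulation and analysis of dynamic axial deformation — osmotic swelling and
deswelling in preservation media, and the anterior shrinkage that accompanies
UV-riboflavin cross-linking (CXL) — from time series of complex OCT volumes.

Post-mortem corneas swell or deswell depending on the tonicity of the medium
they sit in, and photochemical cross-linking actively deforms the anterior
stroma during treatment. Both effects are large enough to confound
biomechanical experiments, and both can be tracked without contact by
phase-sensitive OCE: the phase difference between two consecutive OCT scans
measures axial tissue displacement at nanometre sensitivity. This package is
for researchers who want to reproduce, test, or extend that analysis chain
without access to an OCT system: a speckle phantom with prescribed
deformation fields stands in for the instrument, so every stage of the
pipeline can be verified against known ground truth.

## The estimator

With `C1`, `C2` two consecutive complex C-scans, the amplitude-weighted
complex cross-correlation over a phase-processing window (half-widths
`w_z = w_x = 3` pixels)

    W(z,x,y) = sum_{j,k} C2(z+j, x+k, y) * conj(C1(z+j, x+k, y)) , normalised to |W| = 1

carries the local phase difference, giving the axial displacement

    U = lambda_mean * angle(W) / (4 pi n)         [m]

with `lambda_mean = 877.8 nm` and tissue refractive index `n = 1.375`.
A second cross-correlation of `W` with its own axial shift,

    R(z,x,y) = sum_{j,k} W(z+1+j, x+k, y) * conj(W(z+j, x+k, y))

yields the axial strain (the depth gradient of displacement)

    eps_zz = dU/dz = lambda_mean * angle(R) / (4 pi n delta)      [-]

with axial sampling unit `delta = 4.48 um`. The conjugation order is fixed so
that axial expansion (swelling) is positive. Phase wrapping bounds the
per-pair measurables at `lambda/(4n)` (displacement) and `lambda/(4n delta)`
(strain); larger increments alias.

Per-pair strains are averaged over surface-anchored regions (e.g. the
anterior 400 um of corneal thickness in a central lateral window) and
accumulated over time into percent cumulative strain curves; curves are
segmented (1–20, 21–50, 51–80 min by default) and per-sample regression
slopes are compared between treatment groups with paired or unpaired
(Welch) t-tests.

## Worked example

Simulate one eye swelling in a hypotonic (PBS-like) bath for 45 min at one
volume per minute, then recover its cumulative anterior strain curve:

```r
library(oceStrain)

cfg <- phantom_config(n_z = 260, n_x = 32, n_y = 3, delta = 4.48,
                      anterior_apex_depth = 100, corneal_thickness = 1000,
                      snr_db = 25, seed = 42)
params <- processing_params()          # 877.8 nm, n = 1.375, delta = 4.48 um
scenario <- scenario_preset("hypotonic_swelling", thickness = 1000)

sim   <- simulate_timeseries(cfg, scenario, params, keep_fields = FALSE)
surf  <- detect_surfaces(sim$frames[[1]])
curve <- strain_curve(sim$frames, surf,
                      region_spec(band = "anterior", lateral_halfwidth_y = 1000),
                      params, label = "PBS-like eye")
curve
#> Cumulative strain curve 'PBS-like eye': 45 pairs over 44.5 min, 0 invalid
#>   final cumulative strain: 3.83%

segment_slopes(curve, breaks = list(c(1, 20), c(21, 45)))
#> Segment slopes for 'PBS-like eye' (% strain / min):
#>   1-20 min     m = +0.1817, r2 = 1.0000, n = 19
#>   21-45 min    m = +0.0079, r2 = 1.0000, n = 24
```

The scenario prescribes uniform swelling at 1.85e-3 per minute for the first
20 minutes (3.7% cumulative) and a near-plateau afterwards; the recovered
curve ends at 3.83% with a first-segment slope of 0.182 %/min — the small
shortfall is the expected attenuation of the strain map within one
window-resolution length of the tissue boundaries. `plot(curve)` draws the
curve; `depth_time_map()` and `depth_profile()` give the depth-resolved
views, and `run_oce_pipeline(pipeline_config(seed = 1))` runs a full
two-group (control vs CXL-like) simulated study including slope statistics.

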