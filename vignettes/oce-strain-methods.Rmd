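---
title: "Phase-sensitive OCE strain mapping: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-sensitive OCE strain mapping: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceStrain)
```

## The measurement model

Optical coherence tomography records, per voxel, a complex reflectivity
whose phase is tied to the optical path length to the scatterers inside
that voxel. When tissue moves axially by $U$ between two scans, the phase of
its signal changes by $4\pi n U / \lambda_{mean}$ (the factor 2 from the
double pass, and $n$ because the path is in tissue). Phase-sensitive OCE
inverts this: the angle of an amplitude-weighted complex cross-correlation
$W$ between consecutive scans, summed over a small window, estimates the
local phase difference, and

$$U = \frac{\lambda_{mean}\,\angle W}{4\pi n}.$$

Axial strain is the depth gradient of $U$. Rather than differentiating a
noisy phase map, a second cross-correlation $R$ between $W$ and its own
one-pixel axial shift is summed over the same window, so that

$$\varepsilon_{zz} = \frac{dU}{dz}
  = \frac{\lambda_{mean}\,\angle R}{4\pi n \delta},$$

with $\delta$ the axial pixel pitch in tissue. Because only consecutive-scan
*increments* are measured, rigid body motion common to the window cancels,
and per-pair increments are summed ("accumulated") into cumulative strain.

Assumptions worth keeping in mind: the deformation within one
phase-processing window is locally uniform (the window average is then
unbiased); per-pair increments stay inside the wrap-free bounds
$\lambda/(4n)$ for displacement and $\lambda/(4n\delta)$ for strain; and the
speckle pattern stays correlated between consecutive scans (violated by
fluid-application artifacts, handled by masking, below).

## Conventions fixed by this package

Two sign choices are left open by the algebra and fixed here once:

* **Conjugation order of `W`.** `W` multiplies the *later* scan by the
  conjugate of the earlier one, so a phase factor applied to the later scan
  is read back with its own sign, and motion towards larger depth gives
  positive displacement.
* **Axial shift order of `R`.** `R` correlates `W(z+1)` against `W(z)`
  (conjugated), so strain is the forward depth-gradient of phase and axial
  *expansion* — swelling — is **positive**. Deswelling and the anterior
  shrinkage during cross-linking come out negative.

The z index runs from the shallowest depth downward; depth is geometric
(pixel index times $\delta$, with $\delta$ defined in tissue), and no
refraction correction is applied — the phantom uses the same convention, so
the two sides agree by construction.

No phase unwrapping is performed. Strains reported for corneal osmotics and
CXL sit well inside the unambiguous range at one-minute cadence; increments
beyond the bound alias to wrapped values, which is detected in simulation
(the generator records a metadata warning when a prescribed per-pair
increment exceeds the bound) and demonstrated explicitly in the aliasing
tests: $0.99\times$ the bound is recovered, $1.01\times$ returns a
sign-flipped $0.99\times$.

## Numerical choices

* **Window sums** are computed by cumulative-sum box filters and are
  *truncated* at array borders (out-of-bounds positions contribute zero);
  there is no wrap-around. Positions whose windowed sum has zero modulus
  (e.g. noise-free background) are flagged invalid and set to zero rather
  than divided by zero.
* **Edge attenuation.** Because `W` averages phase over $2w_z+1$ axial
  pixels and `R` differences it, the strain map has an effective axial
  resolution of roughly $2w_z+1$ pixels. Within that distance of the tissue
  boundary (or the array border) a linear phase ramp is compressed, so the
  strain map under-reads there. Regional means anchored at a surface
  therefore carry a small negative bias that shrinks as the band grows
  relative to the window: at $\delta = 4.48\,\mu m$ and a 400 $\mu m$ band
  the effect is of order 1–2%; at coarse test samplings (16 $\mu m$) it is
  larger. Tests that assert exact closed-form recovery evaluate the interior
  rows whose windows are fully in-bounds.
* **Amplitude weighting and the uniform phantom.** With fully developed
  speckle, the amplitude weights inside the windows make the recovered phase
  ramp fluctuate pixel-to-pixel (order $10^{-4}$ strain at typical
  settings) even with no detector noise: this is speckle-induced strain
  noise, not an implementation error. The phantom therefore exposes
  `speckle = FALSE` — unit amplitude with uniform random phase — for which
  the window algebra is exact; closed-form recovery tests use it, noise and
  robustness tests use real speckle.
* **Quality masking.** Pixels whose structural amplitude falls below
  `amp_threshold` (default 0.1) times the frame's upper-quartile amplitude
  in either frame are masked. A whole pair is dropped when the mean
  phase-correlation coefficient $|\sum C_2 C_1^\ast| / \sum |C_1||C_2|$ over
  the mask falls below `corr_floor`. That coefficient is summed over the
  *lateral* window only: a genuine axial strain ramp advances phase along z
  and would depress an axially-summed coefficient, while decorrelation
  destroys phase in all directions. Coherent pairs score above 0.9 even at
  20 dB SNR; phase-randomised (dropout) pairs score near 0.5 because
  amplitude weighting inflates the random-phasor expectation above
  $1/\sqrt{N}$ — the default floor of 0.75 separates the two regimes with
  wide margin.
* **Degenerate inputs.** All-zero frames mask everything and invalidate the
  pair; an all-zero volume is a segmentation error; a slope comparison of
  two constant, equal groups reports $t=0,\ p=1$ with a warning instead of
  dividing by zero; segments with fewer than 3 valid points are flagged
  unfit and excluded from comparisons.

## The phantom: what it emulates, and what it does not

The generator builds a curved (or flat) two-surface corneal band filled with
circular-Gaussian speckle: per-voxel scatterer sums (Poisson occupancy times
complex Gaussian amplitude) convolved with a separable Gaussian PSF whose
default widths follow a 3.26 um axial / 12 um lateral resolution at 4.48 um
/ 12 um pitches. Geometry defaults (anterior radius, ~1 mm thickness,
12 um lateral pitch, 100 B-scans) follow a porcine cornea under a
spectral-domain system; every size is configurable, and tests run at reduced
grids.

Deformation is prescribed as a strain-rate profile over normalized stromal
depth $d \in [0,1]$ and time. Cumulative strain is integrated per frame,
converted to a displacement field with the **posterior surface held fixed**
(swelling moves the anterior surface toward the probe), and imposed in
`phase_only` mode: each voxel is rotated by the phase the estimator should
read back, leaving amplitude — and hence speckle correlation — untouched. A
`resample` mode additionally shifts the speckle pattern by $U/\delta$ pixels
to probe decorrelation robustness; it is not used for accuracy claims.
Detector noise is complex Gaussian per frame at a configurable amplitude SNR
(dB, relative to unit rms tissue amplitude); optional per-frame phase jitter
models extra decorrelation; scheduled dropout frames have their phase fully
randomised, reproducing the periodic loss of strain data when fluid is
applied during an experiment (the real artifact is stripe-shaped within a
frame; modelling it frame-wide exercises the same masking path with less
bookkeeping).

Scenario presets encode the study conditions as descriptive defaults —
printed cumulative strains divided by their durations: hypotonic (PBS-like)
uniform swelling of 3.7% over the first 20 min with a near-plateau after;
hypertonic (7% dextran-like) deswelling with a rate linear in depth crossing
zero at 55% of thickness (anterior −5.6% at 20 min); a near-isotonic medium
(−1.8% over 45 min); irrigation-only controls swelling at 0.14 %/min then
0.09 %/min over an 80-min protocol with dropouts every 5 min; and a CXL-like
scenario identical to the control until UV onset at minute 20, then
shrinking inside the anterior 200 um. Group simulations can scale each eye's
rate profile by $1 + \mathcal{N}(0, \sigma)$ (`rate_scale_sd`, default 0.25
in the pipeline configuration) to emulate biological spread between eyes.

What the phantom does **not** model: light propagation (no attenuation with
depth, no refraction at the liquid interface, no shadowing), lateral
displacement or shear, epithelial/endothelial sublayers, and intra-frame
scan-time skew. Passing tests therefore validate the estimator, the
geometry/averaging chain, and the statistics on idealised speckle — they do
not certify performance on attenuated, motion-blurred clinical data.

## Statistics

Curves are segmented (defaults 1–20, 21–50, 51–80 min, the protocol phases
of an 80-min CXL experiment) and each segment is fitted by ordinary least
squares on the valid points; slopes are in % strain per minute. Slopes are
fitted **per sample** and then compared: unpaired comparisons between groups
use Welch's t-test by default (no equal-variance assumption; a pooled
Student variant is available for exact replication attempts), within-group
comparisons across segments of the same eyes are paired. Raw p-values are
reported with the customary 0.05 threshold; no multiple-testing correction
is applied, and this is deliberate — the analyses replicated here report raw
p-values. Invalid (dropout) increments contribute zero to the cumulative
sum and are excluded from fits rather than interpolated; this is
conservative and slightly biases cumulative magnitudes low in proportion to
the invalid fraction, identically across compared groups.

## Problem sizes

Simulation-based checks are sized to run comfortably on one CPU: oracle
comparisons use volumes up to $16\times16\times3$; noise-robustness uses a
$128\times256\times3$ phantom over 5 seeds; the two-group discrimination
study uses 6 + 6 eyes at a reduced $60\times24\times1$ grid with 16 um axial
sampling, 80 frames at one per minute, repeated 20 times; the null
calibration of the slope test draws 2000 replicates. The depth-profile
check uses a $256\times48\times1$ phantom at the native 4.48 um sampling.
These sizes are the package's chosen simulation conditions; the generator
scales to full instrument grids ($\sim900\times1000\times100$) if memory
allows.

## Known limitations

* The strain map's boundary attenuation (above) means surface-anchored
  band means are not exactly unbiased; quantitative comparisons should use
  matched bands and samplings, as the group statistics here do.
* Frame-wide dropout modelling is coarser than the real stripe artifacts;
  column-wise masking would preserve more data per affected pair.
* The accumulation is a plain sum of increments. For per-pair strains below
  a few per mille the compounding error is second-order and negligible, but
  the approximation degrades if increments are pushed toward the wrap
  bound.
* `resample` mode uses linear interpolation, which slightly low-passes the
  speckle; sub-pixel decorrelation statistics are approximate.
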