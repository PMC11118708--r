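---
title: "Methods: feedforward pooling models of V2 receptive fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feedforward pooling models of V2 receptive fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v2pool)
```

## Overview

`v2pool` models the responses of single orientation columns in visual area
V2 as linear weighted sums of their V1 inputs, with the inputs identified
anatomically (retrograde labeling) and characterised functionally (optical
imaging of orientation and retinotopic maps). This vignette documents the
model and its assumptions, the parameters that matter, the synthetic world
used for validation, and the numerical choices made where the underlying
procedure was open to interpretation.

## The model

**V1 receptive fields.** Each labeled V1 cell is a Gabor filter: an
elliptical Gaussian envelope times a sinusoidal carrier along the rotated
y axis. Parameters and defaults:

| parameter | meaning | default | rationale |
|---|---|---|---|
| `sf` | carrier spatial frequency | 1 cycle/degree | matches the gratings used to map orientation tuning |
| `sigma_x` | envelope SD along the stripe axis | 0.6 degrees | ~1 octave bandwidth at `sf` = 1 |
| `gamma_c` | envelope aspect ratio | estimated in \[0.1, 4\] | picked from a 40-member bank by SSE against the measured 8-point tuning |
| `theta_c` | preferred orientation | from the map | vector-sum PO at the cell's pixel |
| `xc, yc` | receptive-field centre | from retinotopy | nearest elliptic-grid node |

Filters are discretized on a raster in visual degrees and normalised to unit
L2 norm. Complex cells sum the half-wave rectified responses of four
quadrature phases (0, pi/2, pi, 3pi/2), which makes them exactly
contrast-inversion invariant and bounds their gain modulation over stimulus
spatial phase by sqrt(2) for sinusoidal gratings.

**Connection weights.** The weight from V1 cell i to V2 pixel j is the
cosine similarity of their mean-subtracted 8-point tuning curves: +1 for
identical curves, -1 for orthogonally tuned raised cosines, 0 at 45 degrees
separation. This deliberately avoids regression (rank-deficient and
multicollinear for similarly tuned inputs) and reproduces the
cross-orientation push-pull organisation seen in V2 receptive fields:
clusters of positive iso-oriented inputs flanked by negative
cross-oriented ones.

**V2 responses and receptive fields.** A V2 pixel's response is the plain
weighted sum of its V1 inputs' responses (no output nonlinearity).
Receptive fields are rendered by weighted summation of the cells' Gabors at
a common parity (even or odd), which yields either elongated V1-like
filters or spatially complex multi-lobed structures depending on the
orientation scatter of the inputs.

**Validation.** Eight-fold leave-one-out: for each held-out grating
orientation, weights are recomputed from the remaining seven points of
every tuning curve, model V1 grating responses (phase-averaged complex
responses) are pooled, and the pooled value is mapped to response units by
a per-pixel affine calibration (gain and offset fitted on the seven
training orientations). Errors are reported relative to each pixel's
measured response range, together with PO errors (vector sum) and tuning
width errors (von Mises half width at half height).

## The synthetic world

The generators produce every input the pipeline consumes, with ground
truth:

- **Orientation maps**: a smooth axial field built by band-pass filtering
  complex white noise and halving the argument (a standard pinwheel-map
  construction with a controllable hypercolumn wavelength, default 0.75 mm
  at 55.6 px/mm); per-pixel responses are raised cosines in the doubled
  angle, `r0 + a cos(2(theta - PO))` with r0 = 50, a = 40 on the 0-100
  response scale, plus i.i.d. Gaussian noise (default SD 2). An infinite
  smoothness collapses to a constant-orientation map.
- **Labeled cells**: each cell's orientation is drawn from a mixture: with
  probability `bias_strength` from a wrapped Gaussian (FWHM 22.5 degrees)
  around the injection-site orientation, otherwise uniformly; the cell is
  then placed on a map pixel carrying that orientation, near one of a set
  of spatial cluster centres (`cluster_scale`, default 8 px), emulating
  patchy label. The default `bias_strength = 0.31` makes the expected
  fraction of cells within +/-22.5 degrees about 0.48
  (0.31 x 0.98 + 0.69 x 0.25), i.e. a typically reported degree of
  like-to-like bias; the spatial clustering statistics of real label are
  unknown, so `cluster_scale` is a free parameter, not a fitted one.
- **Texture families**: structured images (rectified oriented-grating
  composites, thresholded smooth noise, or plaids) paired with
  phase-randomized counterparts sharing their amplitude spectra exactly.
  Setting the threshold of the thresholded-noise kind to -Inf leaves a
  Gaussian field with no higher-order structure, for which modulation
  indices are centred on zero.
- **V2 pixels**: known weighted sums of model V1 grating tunings plus
  optional noise, with the generative weights kept as ground truth.

What the synthetic world does **not** emulate: hemodynamic time courses and
vasculature artifacts, histological warping error, component separation of
retinotopy stacks, and realistic natural-texture statistics (the structured
families carry higher-order dependencies, but not those of natural images).
A green test therefore establishes the correctness and calibration of the
analysis chain, not biological conclusions about V1-to-V2 wiring.

## Numerical choices

- **Frame indexing** in raw stacks is 1-based: baseline = frames 1-2,
  evoked = frames 15-20; the control image is the mean of the first five
  frames of the first recorded trial, and that first trial is excluded
  from condition averages.
- **Smoothing boundaries**: all Gaussian filtering uses mirror reflection,
  so the band-pass difference maps constants to exactly zero. The
  high-pass is implemented literally as smooth(sigma 2.5 px) minus
  smooth(sigma 25 px). Near pinwheels this filtering legitimately shifts
  vector-sum POs by a few degrees relative to the generating field; tests
  of exact PO recovery therefore use either unfiltered maps or
  slowly varying gradient maps away from boundaries.
- **Rescaling**: single-condition maps are shifted by the pixelwise
  minimum across orientations and divided by the maximum of the
  max-minus-min map over non-vessel pixels, times 100; the operation is
  idempotent and the global non-vessel maximum is exactly 100.
- **Von Mises fits** use bounded quasi-Newton (L-BFGS-B) with five
  restarts of mu (vector-sum PO and +/-22.5, +/-45 degree offsets);
  kappa is bounded to \[0, 500\]. A fit is flagged when the amplitude is
  negligible or the optimizer fails away from a near-perfect fit; an
  abnormal line-search termination at ~zero residual is not a failure.
  The half width at half height is analytic:
  `0.5 * acos(log(cosh(kappa)) / kappa)`, with the kappa -> 0 limit of 45
  degrees and a numerically stable log-cosh for large kappa.
- **Elliptic grids** solve the Laplace grid equations in computational
  coordinates (Winslow-type smoothing) by red-black SOR from a transfinite
  interpolation start, with Dirichlet boundary nodes placed by
  arc-length-uniform sampling; convergence is declared when the maximum
  per-node displacement falls below 1e-5 px (iteration budget 2.5e6
  sweeps). For straight-sided outlines the transfinite start is already
  discrete-harmonic, so convergence is immediate. Node counts follow
  `round(extent / resolution)` (125 x 75 for 2.5 x 1.5 degrees at 0.02),
  and visual coordinates step uniformly across the stated extents, making
  the step extent/(n-1), i.e. 0.0202 degrees along the 125-node axis; the
  nominal resolution is honoured in the node count, not both quantities at
  once. Large grids may be solved at a coarse shape and
  bilinearly resampled in index space. Nearest-node ties break to the
  lexicographically smallest (i, j).
- **Raster resolutions**: filters must resolve the carrier; the package
  enforces at least 4 samples per cycle and uses 0.01-0.02 degrees/px for
  image work and 0.05 degrees/px for grating-tuning computation (20
  samples per cycle), where tuning values agree with the fine-raster
  computation to better than 0.1%. Envelope windows default to 3 sigma;
  exact quadrature identities (the sqrt(2) phase-gain bound) need 5 sigma
  windows, where truncation error falls below 1e-6.
- **Grating phase handling**: model responses to gratings are averaged
  over 8 evenly spaced spatial phases, emulating drifting gratings.
- **Rotation selection for modulation indices** maximises |mean(d)|/var(d)
  of the 30 per-pair differential responses d per rotation. The absolute
  value makes the selection invariant under swapping texture and noise
  labels, which in turn makes the modulation index exactly antisymmetric
  under that swap; per-pair indices are stored alongside the primary
  means-of-conditions index. V2 modulation indices are flagged (not
  clipped) if either mean response is negative, since weighted sums can
  be negative.
- **File formats**: all artifacts are plain text — CSV matrices at 17
  significant digits (bit-exact round trips), JSON for structured results
  and configuration (schema-validated, unknown keys rejected). Pixel
  coordinates are 0-based in files and 1-based in memory.
- **Determinism**: every generator and null takes an explicit seed; the
  pipeline derives per-stage child seeds from one master seed, so stages
  can be rerun in isolation and whole runs are byte-identical.

## A known validation floor

On noiseless model-generated V2 pixels the full-data model (weights and
calibration from all eight orientations) reproduces tuning curves to
better than 1% of the response range. The leave-one-out procedure,
however, has an intrinsic error floor of about 3-4% that does not vanish
in any noiseless self-consistent configuration: removing one orientation
perturbs each mean-subtracted 7-point tuning vector by a term of order 1/7
that is concentrated at the held-out orientation, so the re-estimated
similarity weights systematically mis-weight exactly the cells that
dominate the held-out response. The effect is visible even when every
curve is a pure raised cosine. Predicted preferred orientations are much
less affected (errors well under 1 degree at realistic population sizes)
because the perturbation is nearly symmetric around the tuning peak. The
acceptance suite keeps a sub-2% assertion for this quantity and that
assertion is expected to fail; it is retained, unweakened, with this
analysis as the explanation.

## Limitations

- The linear model has no output nonlinearity, normalisation, or
  feedback; it tests sufficiency of feedforward pooling only.
- Aspect ratios above ~2.5 are weakly identified from 8-point tuning
  curves (near-degenerate SSE across the bank); supplying the generating
  PO restores exact recovery in tests.
- The pattern-shift null drops (with a report) cells that land on vessel
  or undefined pixels rather than redrawing the shift; with dense vessel
  masks this reduces the effective sample per replicate.
- Rotation of texture images uses bilinear interpolation; amplitude
  spectra are preserved exactly only for the unrotated pair.
- Texture and noise images share spectra exactly because phase
  randomization is applied after the aperture mask; the noise images are
  not re-masked, so their energy is not strictly confined to the aperture.
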