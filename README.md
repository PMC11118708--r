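# v2pool

Feedforward pooling models of V2 receptive fields from anatomically
identified V1 inputs.

## The scientific problem

Neurons in the secondary visual area (V2) of the primate brain respond to
more complex image features than their inputs in primary visual cortex (V1):
they are tuned to elongated contours, angles, and the higher-order
statistics of naturalistic textures. A central question in visual
neuroscience is whether these properties can emerge from nothing more than a
*linear weighted sum* of feedforward V1 inputs, once the actual anatomical
connectivity is known.

`v2pool` implements the full analysis chain needed to ask that question with
optical-imaging and tracer-labeling data, and ships a synthetic-data
generator with known ground truth so every stage can be validated end to
end:

1. **Orientation maps** (`oimaps`): single-condition response maps from raw
   imaging stacks (baseline subtraction, clipping, control division,
   band-pass filtering, rescaling to \[0, 100\]), per-pixel preferred
   orientation (PO) by vector summation of the eight grating responses, and
   axial von Mises tuning fits with analytic half width at half height.
2. **Retinotopy** (`retinotopy`): cortex-to-visual-field mapping by elliptic
   grid generation (Laplace grid equations, transfinite-interpolation start,
   relaxation to a 1e-5 displacement tolerance) and nearest-node assignment
   of labeled cells; at 0.02 degree resolution a 2.5 x 1.5 degree region
   yields a 125 x 75 node grid.
3. **Connectivity statistics** (`connstats`): like-to-like bias of labeled
   inputs (fraction of POs within +/-22.5 degrees of the injected site),
   doubled-angle circular statistics (MRL, CSD = sqrt(-2 ln MRL)),
   chi-square goodness of fit (8 bins, 7 degrees of freedom),
   pixel-resampling (1000x) and pattern-shift (1500x) nulls with exceedance
   fractions, a perfect like-to-like mixture model (wrapped Gaussians, FWHM
   22.5 degrees), and Bonferroni-corrected KS comparisons.
4. **Feedforward model** (`ffmodel`): V1 cells as Gabor receptive fields

   G(x, y) = A exp(-(x'^2 + gamma^2 y'^2) / (2 sigma_x^2)) cos(2 pi sf y' + phi)

   with sf = 1 cycle/degree, sigma_x = 0.6 degrees, unit L2 norm, and the
   aspect ratio gamma estimated from measured tuning against a bank of 40
   candidates in \[0.1, 4\]. Complex cells sum four half-wave rectified
   quadrature phases. The connection weight between V1 cell i and V2 pixel j
   is the cosine similarity of mean-subtracted tuning vectors

   w_ij = (X_i - mean(X_i)) . (X_j - mean(X_j)) / (|X_i - mean(X_i)| |X_j - mean(X_j)|)

   so identical curves give +1 and orthogonally tuned pairs give -1. V2
   responses are linear weighted sums; receptive fields are rendered as
   weighted sums of even- or odd-parity Gabors; prediction quality is
   assessed by eight-fold leave-one-out validation (relative error against
   the measured response range, PO error, half-width error).
5. **Textures** (`textures`): spectrally matched noise by Fourier phase
   randomization (amplitude spectra preserved to machine precision),
   320 x 320 preparation with a circular aperture at 100 px/degree, 8
   rotations in 22.5-degree steps (30 image pairs -> 240 samples per
   condition), standardized dot-product responses, and the modulation index
   MI = (R_texture - R_noise) / (R_texture + R_noise) at the rotation with
   the most significant differential response, compared between V1 and V2
   populations by t-test.
6. **Pipeline** (`cli_io`): JSON-configured, seed-deterministic end-to-end
   run (`run_pipeline()`) writing plain-text artifacts and a provenance
   report with checksums.

## Worked example

```r
library(v2pool)

# simulate a pinwheel orientation map and labeled V1 inputs
sim <- simulate_orientation_map(map_sim_config(64, 64, noise_sd = 2, seed = 42))
cells <- simulate_labeled_cells(
  connectivity_sim_config(500, injection_center = c(32, 32), seed = 42),
  sim)
pomap <- vector_sum_po(sim$maps)

# orientation bias of the labeled inputs
cpo <- po_at_points(pomap, cells$x_px, cells$y_px)
inj <- attr(cells, "injection_po")
fraction_within(cpo, inj)
obs <- circ_stats(cpo)
ex <- exceedance(pixel_resample_null(pomap, NULL, m = length(cpo), seed = 42), obs)

# connection weights between raised-cosine tuning curves
th <- standard_orientations()
rc <- function(p) 1 + cos(2 * (th - p) * pi / 180)
compute_weights(rbind(rc(0), rc(45), rc(90)), rbind(rc(0)))

# complex-cell tuning and aspect-ratio estimation
tun <- complex_grating_tuning(theta_c = 60, gamma_c = 1.5)
tuning_po(tun)
estimate_aspect_ratio(tun)$gamma_c
```

Output:

```
injection-site PO: 12.0 deg
fraction of cells within +/-22.5 deg: 0.528
observed MRL 0.350; F(null MRL > obs) = 0.000
weights vs a 0-deg pixel (POs 0, 45, 90): 1 0 -1
model cell PO recovered: 60.03 deg
estimated aspect ratio: 1.5
```

Read: with the default bias strength, 52.8% of the simulated labeled cells
prefer orientations within +/-22.5 degrees of the injected column
(uniform sampling would give 25%), and no pixel-resampling null replicate
reaches the observed mean resultant length — the bias is far outside the
null. The similarity weights hit their exact extremes (+1 same PO, 0 at 45
degrees, -1 orthogonal), and the model recovers a complex cell's preferred
orientation and envelope aspect ratio from its 8-point grating tuning.

## Documentation

The methods vignette (`vignettes/v2pool-methods.Rmd`) describes the model,
the synthetic world and what it does and does not emulate, the numerical
choices, and known limitations.
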