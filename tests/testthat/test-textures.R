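# Texture analysis: phase randomization, preparation, rotation, responses,
# modulation indices, population comparison.

test_that("spectral noise preserves amplitudes, mean, and autocorrelation", {
  set.seed(1)
  img <- gaussian_blur(matrix(rnorm(64 * 64), 64, 64), 2)
  sn <- spectral_noise(img, seed = 2)
  a0 <- amplitude_spectrum(img); a1 <- amplitude_spectrum(sn)
  expect_lt(max(abs(a0 - a1)) / max(a0), 1e-6)
  expect_equal(mean(sn), mean(img), tolerance = 1e-12)
  ac <- function(m) Re(fft(Mod(fft(m))^2, inverse = TRUE)) / length(m)
  expect_equal(ac(sn), ac(img), tolerance = 1e-9)
  # idempotence in distribution: re-randomizing keeps second-order stats
  sn2 <- spectral_noise(sn, seed = 3)
  expect_lt(max(abs(amplitude_spectrum(sn2) - a0)) / max(a0), 1e-6)
  expect_error(spectral_noise(1:5), "2-D")
})

test_that("phase randomization destroys higher-order structure", {
  fam <- simulate_texture_family(1, "thresholded-noise", seed = 3, size = 64,
                                 threshold = 0.5)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_gt(abs(skew(as.vector(fam$textures[[1]]))), 0.5)
  expect_lt(abs(skew(as.vector(fam$noises[[1]]))), 0.2)
})

test_that("prepared images are square, masked, and scale-annotated", {
  set.seed(2)
  img <- matrix(rnorm(50 * 80), 50, 80)
  out <- prepare_image(img, size = 64)
  expect_equal(dim(out), c(64, 64))
  expect_equal(attr(out, "deg_per_px"), 1 / 100)
  # pixels beyond the aperture radius carry the fill value
  ctr <- (64 + 1) / 2
  g <- expand.grid(r = 1:64, c = 1:64)
  outside <- sqrt((g$r - ctr)^2 + (g$c - ctr)^2) > 32
  expect_equal(length(unique(out[cbind(g$r[outside], g$c[outside])])), 1L)
  # an already-square 320 input is only masked
  img320 <- matrix(rnorm(320 * 320), 320, 320)
  out320 <- prepare_image(img320)
  expect_equal(dim(out320), c(320, 320))
  inside <- attr(out320, "mask")
  expect_equal(out320[inside], img320[inside])
  expect_error(prepare_image(matrix(1, 1, 1)), "degenerate")
})

test_that("rotation produces 8 masked samples per image (240 for 30 pairs)", {
  fam <- simulate_texture_family(30, "plaid", seed = 5, size = 32)
  rot <- rotate_family(fam)
  expect_length(rot$textures, 30)
  expect_length(rot$textures[[1]], 8)
  n_tex_samples <- length(rot$textures) * length(rot$rotations)
  n_noise_samples <- length(rot$noises) * length(rot$rotations)
  expect_equal(n_tex_samples, 240)
  expect_equal(n_noise_samples, 240)
  expect_equal(rot$rotations, seq(0, 157.5, by = 22.5))
  # zero rotation is the identity (up to masking)
  masked <- apply_circular_mask(fam$textures[[1]])
  expect_equal(unclass(rot$textures[[1]][[1]]), unclass(masked),
               tolerance = 1e-6)
})

test_that("standardized responses ignore affine luminance changes", {
  fam <- simulate_texture_family(1, "oriented-composite", seed = 9, size = 64)
  img <- fam$textures[[1]]
  cell <- v1_cell(gabor_params(0, 0, 45, 1), "complex")
  r1 <- cell_response_to_image(cell, img)
  r2 <- cell_response_to_image(cell, structure(3 * unclass(img) + 10,
                                               mask = attr(img, "mask")))
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-10)
  const <- apply_circular_mask(matrix(5, 64, 64))
  r3 <- cell_response_to_image(cell, const)
  expect_equal(as.numeric(r3), 0)
  expect_true(attr(r3, "flagged"))
})

test_that("V2 responses equal the hand-computed weighted sum on a toy set", {
  fam <- simulate_texture_family(2, "plaid", seed = 13, size = 48)
  rot <- rotate_family(fam, n_rotations = 2)
  cells <- list(v1_cell(gabor_params(-0.05, 0, 0, 1), "complex"),
                v1_cell(gabor_params(0, 0, 60, 1.5), "complex"),
                v1_cell(gabor_params(0.05, 0, 120, 0.8), "complex"))
  w <- c(0.7, -0.2, 0.4)
  resp <- family_responses(cells, matrix(w, 3, 1), rot)
  # oracle: per-cell standardized complex responses, then the weighted sum
  for (s in 1:2) {
    for (r in 1:2) {
      manual <- sum(w * vapply(cells, function(cl) {
        as.numeric(cell_response_to_image(cl, rot$textures[[s]][[r]]))
      }, numeric(1)))
      expect_equal(resp$v2_tex[1, s, r], manual, tolerance = 1e-10)
    }
  }
})

test_that("modulation indices respect their boundary cases and antisymmetry", {
  set.seed(7)
  r <- matrix(abs(rnorm(30 * 8)) + 0.5, 30, 8)
  same <- modulation_index(r, r)
  expect_equal(same$mi, 0)
  ones <- matrix(1, 30, 8)
  zero <- matrix(0, 30, 8)
  expect_equal(modulation_index(ones, zero)$mi, 1)
  # antisymmetry is exact, including the selected rotation
  rt <- r + matrix(rnorm(240, sd = 0.2), 30, 8)
  a <- modulation_index(rt, r)
  b <- modulation_index(r, rt)
  expect_identical(a$rotation, b$rotation)
  expect_equal(a$mi, -b$mi)
  expect_equal(a$pair_mi, -b$pair_mi)
  # deterministic selection under a fixed seed
  expect_identical(modulation_index(rt, r)$rotation, a$rotation)
  expect_error(modulation_index(matrix(1, 3, 2), matrix(-1, 3, 2)),
               "undefined")
})

test_that("elongated pooled receptive fields beat single cells on structure", {
  fam <- simulate_texture_family(15, "oriented-composite", seed = 7,
                                 size = 96)
  rot <- rotate_family(fam)
  cells <- lapply(seq(-0.3, 0.3, length.out = 7), function(d) {
    v1_cell(gabor_params(d, 0, 0, 1), "complex")
  })
  resp <- family_responses(cells, matrix(1, 7, 1), rot)
  mi_v2 <- modulation_index(resp$v2_tex[1, , ], resp$v2_noise[1, , ])$mi
  mi_v1 <- modulation_index(resp$v1_tex[4, , ], resp$v1_noise[4, , ])$mi
  expect_gt(mi_v2, mi_v1)
})

test_that("population comparison reports both mean- and max-MI tests", {
  set.seed(8)
  v1 <- matrix(rnorm(20 * 5, mean = 0.16, sd = 0.02), 20, 5)
  v2 <- matrix(rnorm(15 * 5, mean = 0.19, sd = 0.05), 15, 5)
  res <- compare_populations(v1, v2)
  expect_named(res, c("mean_test", "max_test"))
  # oracle: equal-variance two-sample t on the per-cell means
  a <- rowMeans(v1); b <- rowMeans(v2)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  t_manual <- (mean(b) - mean(a)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  expect_equal(res$mean_test$t, t_manual, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- compare_populations(v1, v1)
  expect_equal(same$mean_test$t, 0)
  expect_equal(same$mean_test$p.value, 1)
  expect_error(compare_populations(v1[1, , drop = FALSE], v2), "two cells")
})
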