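# Feedforward model: Gabor filters, simple/complex responses, aspect-ratio
# estimation, similarity weights, receptive-field rendering, leave-one-out
# validation.

test_that("discretized Gabors are unit-norm with the stated symmetries", {
  r <- raster_grid(c(-2, 2), c(-2, 2), 0.02)
  ge <- gabor_filter(gabor_params(0, 0, 0, 1, phi = 0), r)
  go <- gabor_filter(gabor_params(0, 0, 0, 1, phi = pi / 2), r)
  expect_equal(sum(ge^2), 1, tolerance = 1e-10)
  expect_equal(sum(go^2), 1, tolerance = 1e-10)
  # theta = 0: carrier varies along y, so flipping rows is the parity axis
  flip <- function(m) m[nrow(m):1, ]
  expect_equal(unclass(ge), flip(unclass(ge)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(go), -flip(unclass(go)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(gabor_filter(gabor_params(sf = 1),
                            raster_grid(c(-1, 1), c(-1, 1), 0.4)),
               "too coarse")
  expect_error(gabor_params(gamma_c = 5), "0.1, 4")
})

test_that("rotating parameters equals rotating the evaluation grid", {
  th <- 35
  r <- raster_grid(c(-1.5, 1.5), c(-1.5, 1.5), 0.05)
  a <- gabor_filter(gabor_params(0, 0, th, 1.3, phi = 0.4), r)
  # evaluate the theta = 0 filter on the grid rotated by -th
  X <- matrix(r$x, length(r$y), length(r$x), byrow = TRUE)
  Y <- matrix(r$y, length(r$y), length(r$x))
  rad <- th * pi / 180
  Xr <- X * cos(rad) - Y * sin(rad)
  Yr <- X * sin(rad) + Y * cos(rad)
  p0 <- gabor_params(0, 0, 0, 1.3, phi = 0.4)
  f <- v2pool:::gabor_fields(p0, Xr, Yr)
  g0 <- exp(-(f$xp^2 + 1.3^2 * f$yp^2) / (2 * 0.6^2)) *
    cos(2 * pi * f$yp + 0.4)
  g0 <- g0 / sqrt(sum(g0^2))
  expect_equal(unclass(a), g0, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("simple responses are rectified unit self-projections", {
  r <- raster_grid(c(-3, 3), c(-3, 3), 0.02)   # 5-sigma window
  g <- gabor_filter(gabor_params(0, 0, 30, 1), r)
  expect_equal(simple_response(g, g), 1, tolerance = 1e-12)
  neg <- structure(-unclass(g), raster = attr(g, "raster"))
  expect_equal(simple_response(g, neg), 0)
  orth <- grating_image(r, 120, 1, 0.3)
  expect_lt(abs(sum(g * orth)), 1e-3)
  expect_error(simple_response(g, grating_image(raster_grid(c(-1, 1),
                                                           c(-1, 1), 0.02),
                                                0)), "mismatch")
})

test_that("complex responses are contrast-invariant with bounded phase gain", {
  r <- raster_grid(c(-3, 3), c(-3, 3), 0.02)   # 5-sigma window
  cell <- v1_cell(gabor_params(0, 0, 30, 1), "complex")
  img <- grating_image(r, 30, 1, 0.7)
  inv <- structure(-unclass(img), raster = attr(img, "raster"))
  expect_identical(complex_response(cell, img), complex_response(cell, inv))
  expect_equal(complex_response(cell, structure(img * 0,
                                                raster = attr(img, "raster"))),
               0)
  resp <- vapply(seq(0, 2 * pi, length.out = 65)[-65], function(ps) {
    complex_response(cell, grating_image(r, 30, 1, ps))
  }, numeric(1))
  expect_true(all(resp > 0))
  expect_lte(max(resp) / min(resp), sqrt(2) + 1e-6)
  expect_error(complex_response(v1_cell(gabor_params(), "simple_even"), img),
               "complex mode")
})

test_that("complex responses equal the rectified quadrature decomposition", {
  # |even| + |odd| shortcut used by the fast tuning path
  r <- raster_grid(c(-1.8, 1.8), c(-1.8, 1.8), 0.05)
  cell <- v1_cell(gabor_params(0, 0, 72, 1.2), "complex")
  img <- grating_image(r, 50, 1, 1.1)
  ge <- gabor_filter(gabor_params(0, 0, 72, 1.2, phi = 0), r)
  go <- gabor_filter(gabor_params(0, 0, 72, 1.2, phi = pi / 2), r)
  expect_equal(complex_response(cell, img),
               abs(sum(ge * img)) + abs(sum(go * img)), tolerance = 1e-12)
})

test_that("fast grating tuning matches the literal raster computation", {
  tun <- complex_grating_tuning(60, 1.5, res = 0.05, n_phases = 8)
  raster <- v2pool:::local_gabor_raster(1.5, 0.6, 1, 0.05)
  cell <- v1_cell(gabor_params(0, 0, 60, 1.5), "complex")
  direct <- vapply(ORI, function(o) {
    mean(vapply(2 * pi * (0:7) / 8, function(ps) {
      complex_response(cell, grating_image(raster, o, 1, ps))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(tun, direct, tolerance = 1e-10)
})

test_that("complex-cell PO is recovered across aspect ratios", {
  for (g in c(0.5, 1, 2, 4)) {
    for (th in c(13, 77, 141)) {
      tun <- complex_grating_tuning(th, g)
      expect_lt(axial_diff(tuning_po(tun), th), 1)
    }
  }
})

test_that("aspect-ratio estimation recovers bank members exactly", {
  bank <- fixture_bank()
  expect_length(bank$gammas, 40)
  expect_equal(range(bank$gammas), c(0.1, 4))
  for (g_true in c(0.5, 1.5)) {
    gi <- which.min(abs(bank$gammas - g_true))
    tc <- v2pool:::bank_tuning(bank, gi, 73)
    est <- estimate_aspect_ratio(tc, bank = bank)
    expect_equal(est$gamma_c, bank$gammas[gi])
  }
  # large aspect ratios are weakly identified from 8-point tuning (nearly
  # degenerate SSE); with the generating PO supplied, recovery is exact
  gi <- which.min(abs(bank$gammas - 3.2))
  tc <- v2pool:::bank_tuning(bank, gi, 73)
  est <- estimate_aspect_ratio(tc, bank = bank, po = 73)
  expect_equal(est$gamma_c, bank$gammas[gi])
  expect_warning(flat <- estimate_aspect_ratio(rep(3, 8), bank = bank),
                 "flat")
  expect_true(flat$flagged)
  expect_equal(flat$gamma_c, 1)
})

test_that("similarity weights hit their exact extremes", {
  expect_equal(as.numeric(compute_weights(rbind(cosine_tuning(45)),
                                          rbind(cosine_tuning(45)))), 1)
  expect_equal(as.numeric(compute_weights(rbind(cosine_tuning(0)),
                                          rbind(cosine_tuning(90)))), -1)
  expect_lt(abs(as.numeric(compute_weights(rbind(cosine_tuning(0)),
                                           rbind(cosine_tuning(45))))),
            1e-12)
})

test_that("weights are bounded and constant curves are excluded", {
  set.seed(12)
  v1 <- matrix(rnorm(40 * 8), 40)
  v2 <- matrix(rnorm(10 * 8), 10)
  w <- compute_weights(v1, v2)
  expect_true(all(w >= -1 & w <= 1))
  v1[3, ] <- 5
  w2 <- compute_weights(v1, v2)
  expect_true(all(is.na(w2[3, ])))
  expect_equal(attr(w2, "excluded")$v1, 3L)
  expect_error(compute_weights(v1, v2[, 1:7]), "lengths differ")
})

test_that("v2_response is a linear weighted sum", {
  r <- c(2, 3, 4)
  expect_equal(v2_response(c(1, 0, 0), r), 2)
  expect_equal(v2_response(c(0, 0, 0), r), 0)
  # additive and homogeneous in the weights
  w1 <- c(0.2, -0.5, 1); w2 <- c(1, 2, -1)
  expect_equal(v2_response(w1 + w2, r),
               v2_response(w1, r) + v2_response(w2, r))
  expect_equal(v2_response(3 * w1, r), 3 * v2_response(w1, r))
  expect_error(v2_response(c(1, 2), r), "lengths")
})

test_that("rendered receptive fields follow the weighted-sum contract", {
  cellA <- v1_cell(gabor_params(0, 0, 0, 1), "complex")
  r <- raster_grid(c(-2, 2), c(-2, 2), 0.02)
  rf <- render_v2_rf(list(cellA), 1, "even", raster = r)
  expect_equal(unclass(rf),
               unclass(gabor_filter(gabor_params(0, 0, 0, 1, phi = 0), r)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # sign flip negates exactly
  cells <- lapply(c(-0.5, 0, 0.5), function(x) {
    v1_cell(gabor_params(x, 0, 0, 1), "complex")
  })
  w <- c(0.5, 1, 0.5)
  rf1 <- render_v2_rf(cells, w, "odd", raster = r)
  rf2 <- render_v2_rf(cells, -w, "odd", raster = r)
  expect_equal(unclass(rf1), -unclass(rf2))
  # collinear same-orientation cells elongate the envelope (second moments)
  second_moment <- function(m, coord) {
    e <- m^2 / sum(m^2)
    x <- matrix(r$x, length(r$y), length(r$x), byrow = TRUE)
    y <- matrix(r$y, length(r$y), length(r$x))
    v <- if (coord == "x") x else y
    sum(e * v^2) - sum(e * v)^2
  }
  single <- render_v2_rf(cells[2], 1, "even", raster = r)
  multi <- render_v2_rf(cells, w, "even", raster = r)
  expect_gt(second_moment(multi, "x"), second_moment(single, "x"))
})

test_that("leave-one-out validation reconstructs model-generated pixels", {
  pop <- fixture_v1_population(60)
  targets <- seq(5, 175, length.out = 12)
  wgen <- t(vapply(targets, function(tg) {
    as.numeric(compute_weights(pop$measured,
                               rbind(cosine_tuning(tg))))
  }, numeric(60)))
  v2 <- t(vapply(seq_along(targets), function(j) {
    simulate_v2_pixel(pop$model, wgen[j, ])$tuning
  }, numeric(8)))
  cv <- loo_cross_validate(pop$measured, v2, pop$model, fit_widths = TRUE)
  expect_identical(dim(cv$predicted), dim(v2))      # 8 folds, one per column
  expect_false(anyNA(cv$predicted))
  expect_lt(mean(cv$mean_relative_error), 0.08)
  expect_lt(max(cv$po_abs_error), 5)   # 60-cell population; shrinks with n
  # the full-data (non-LOO) model is close to exact
  full_err <- abs(cv$predicted_full - v2) /
    apply(v2, 1, function(x) diff(range(x)))
  expect_lt(mean(full_err), 0.03)
  expect_error(loo_cross_validate(pop$measured, rbind(rep(1, 8)), pop$model),
               "degenerate")
})

test_that("noisy weight recovery stays strongly correlated with truth", {
  pop <- fixture_v1_population(100)
  set.seed(31)
  targets <- runif(20, 0, 180)
  noise <- 0.05 * mean(apply(pop$model, 1, function(x) diff(range(x))))
  cors <- vapply(seq_along(targets), function(j) {
    wgen <- as.numeric(compute_weights(pop$measured,
                                       rbind(cosine_tuning(targets[j]))))
    v2 <- simulate_v2_pixel(pop$model, wgen, noise_sd = noise, seed = j)
    wrec <- as.numeric(compute_weights(pop$model, rbind(v2$tuning)))
    cor(wrec, wgen)
  }, numeric(1))
  expect_true(all(cors > 0.8))
})
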