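# Connectivity-bias statistics: lookups, circular stats, chi-square, nulls,
# like-to-like model, KS comparisons.

make_po_map <- function(po, vessel = NULL) {
  r <- array(0, c(nrow(po), ncol(po), 8))
  for (k in 1:8) r[, , k] <- 1 + cos(2 * (ORI[k] - po) * pi / 180)
  m <- orientation_map_set(r, vessel_mask = vessel)
  vector_sum_po(m)
}

test_that("po_at_points looks up nearest pixels and reports vessel drops", {
  po <- matrix(45, 10, 10)
  po[1, 1] <- 90
  vessel <- matrix(FALSE, 10, 10)
  vessel[3, 4:10] <- TRUE
  pm <- make_po_map(po, vessel)
  expect_equal(as.numeric(po_at_points(pm, x = 5, y = 5)), 45)
  # 10 points, 3 on vessels -> 7 returned, 3 reported
  res <- po_at_points(pm, x = c(1:7, 4, 5, 6), y = c(rep(5, 7), 3, 3, 3))
  expect_length(as.numeric(res), 7)
  expect_length(attr(res, "dropped"), 3)
  # sub-pixel coordinates equal the rounding oracle
  res2 <- po_at_points(pm, x = 1.4, y = 1.2)
  expect_equal(as.numeric(res2), po[round(1.2), round(1.4)])
  expect_error(po_at_points(pm, x = 50, y = 1), "outside")
  expect_error(po_at_points(pm, x = 4, y = 3), "all points")
})

test_that("fraction_within implements the axial window", {
  expect_equal(fraction_within(rep(30, 5), 30), 1)
  expect_equal(fraction_within(120, 30), 0)       # orthogonal: distance 90
  expect_equal(fraction_within(c(30, 52.5, 7.5, 120), 30), 0.75)
  # exactly uniform axial orientations: window covers 45/180 of the circle
  po <- seq(0, 180, length.out = 721)[-721]
  expect_equal(fraction_within(po, 90), 0.25, tolerance = 0.01)
  expect_error(fraction_within(numeric(0), 0), "empty")
})

test_that("circular statistics follow the doubled-angle definitions", {
  cs <- circ_stats(rep(37, 10))
  expect_equal(cs$mrl, 1)
  expect_equal(cs$csd, 0)
  expect_equal(cs$mean_po, 37)
  # equal mass at theta and theta + 90: antipodal after doubling
  expect_lt(circ_stats(c(10, 100, 10, 100))$mrl, 1e-12)
  # 8-point uniform axial sample: roots of unity sum to zero
  expect_lt(circ_stats(ORI)$mrl, 1e-12)
  expect_error(circ_stats(numeric(0)), "empty")
})

test_that("the CSD-MRL identity holds on random samples", {
  set.seed(4)
  for (i in 1:20) {
    cs <- circ_stats(runif(sample(3:50, 1), 0, 180))
    expect_equal(cs$csd, sqrt(-2 * log(cs$mrl)), tolerance = 1e-12)
  }
})

test_that("chi-square GOF matches the textbook Pearson formula with dof 7", {
  obs <- c(12, 5, 9, 20, 8, 11, 15, 10)
  exp_ <- c(10, 10, 10, 10, 10, 10, 10, 20)
  res <- chisq_gof(obs, exp_)
  scaled <- exp_ / sum(exp_) * sum(obs)
  expect_equal(res$statistic, sum((obs - scaled)^2 / scaled))
  expect_identical(res$df, 7L)
  expect_equal(res$p.value,
               pchisq(res$statistic, 7, lower.tail = FALSE))
  # observed == expected
  same <- chisq_gof(obs, obs)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # zero-expected bins are merged with a report
  expect_warning(res0 <- chisq_gof(obs, c(0, exp_[-1])), "merged")
  expect_identical(res0$df, 6L)
})

test_that("orientation histograms conserve mass and wrap at 180", {
  po <- c(0, 11, 179, 90, 101.2, 12)
  h <- po_histogram(po)
  expect_equal(sum(h), length(po))
  expect_equal(unname(h[1]), 3L)   # 0, 179 (wraps) and 11 -> the 0-deg bin
  expect_equal(unname(h[5]), 2L)   # 90 and 101.2 (11.2 < 11.3 to 112.5)
})

test_that("pixel-resampling nulls are deterministic and flag biased data", {
  sim <- fixture_map(64, seed = 9)
  pm <- vector_sum_po(sim$maps)
  a <- pixel_resample_null(pm, NULL, m = 50, n_rep = 200, seed = 5)
  b <- pixel_resample_null(pm, NULL, m = 50, n_rep = 200, seed = 5)
  expect_identical(a$mrl, b$mrl)
  expect_identical(a$csd, b$csd)
  # strongly biased observation on an unbiased map: exceedance 0
  obs <- circ_stats(rnorm(50, mean = 40, sd = 2))
  ex <- exceedance(a, obs)
  expect_equal(ex$f_mrl_greater, 0)
  expect_equal(ex$f_csd_smaller, 0)
  expect_error(pixel_resample_null(pm, NULL, m = 1e6), "fewer eligible")
})

test_that("resampling respects the field contour", {
  po <- matrix(10, 20, 20)
  po[1:10, ] <- 150
  pm <- make_po_map(po)
  contour <- cbind(c(0.5, 20.5, 20.5, 0.5), c(10.5, 10.5, 20.5, 20.5))
  ens <- pixel_resample_null(pm, contour, m = 30, n_rep = 20, seed = 1)
  expect_true(all(ens$mrl > 0.999))  # all draws from the constant-PO half
})

test_that("pattern shifts preserve layout and enumerate admissible offsets", {
  po <- matrix(77, 20, 20)
  pm <- make_po_map(po)
  x <- c(3, 5, 9); y <- c(4, 4, 11)
  # constant map: every replicate has MRL 1
  ens <- pattern_shift_null(pm, x, y, n_shifts = 50, seed = 3)
  expect_true(all(ens$mrl == 1))
  # admissible set equals brute-force enumeration on the toy map
  sh <- admissible_shifts(pm, x, y)
  brute <- expand.grid(dx = -10:11, dy = -10:16)
  ok <- apply(brute, 1, function(s) {
    all(x + s[1] >= 1 & x + s[1] <= 20 & y + s[2] >= 1 & y + s[2] <= 20)
  })
  expect_setequal(paste(sh[, 1], sh[, 2]), paste(brute$dx[ok], brute$dy[ok]))
  # zero shift reproduces the observed statistic
  sim <- fixture_map(64, seed = 9)
  pm2 <- vector_sum_po(sim$maps)
  set.seed(8)
  xs <- round(runif(30, 10, 50)); ys <- round(runif(30, 10, 50))
  ens2 <- pattern_shift_null(pm2, xs, ys, n_shifts = 10, seed = 4,
                             include_zero = TRUE)
  obs <- circ_stats(pm2$po[cbind(ys, xs)])
  expect_equal(ens2$mrl[1], obs$mrl)
})

test_that("the like-to-like model reduces to its stated limits", {
  # single-column injection at 90: wrapped Gaussian with mode bin at 90
  inj <- c(0, 0, 0, 0, 100, 0, 0, 0)
  mod <- like_to_like_model(inj, fwhm = 22.5)
  expect_equal(unname(which.max(mod$bin_probs)), 5L)
  expect_equal(sum(mod$bin_probs), 1, tolerance = 1e-9)
  expect_equal(mod$sigma, 22.5 / (2 * sqrt(2 * log(2))))
  # fwhm -> 0: simulated histogram equals the injection histogram
  inj2 <- c(5, 60, 30, 3, 1, 0, 0, 2)
  mod0 <- like_to_like_model(inj2, fwhm = 0)
  expect_equal(unname(mod0$bin_probs), unname(inj2 / sum(inj2)),
               tolerance = 1e-12)
  expect_error(like_to_like_model(rep(0, 8)), "empty")
})

test_that("like-to-like chi-square accepts its own draws", {
  inj <- c(5, 60, 30, 3, 1, 0, 0, 2)
  mod <- like_to_like_model(inj)
  draws <- like_to_like_draw(mod, 5000, seed = 42)
  res <- like_to_like_sim(inj, po_histogram(draws))
  expect_identical(res$chisq$df, 7L)
  expect_gt(res$chisq$p.value, 0.05)
})

test_that("KS comparisons apply the Bonferroni threshold", {
  set.seed(6)
  a <- runif(500, 0, 180)
  same <- ks_bonferroni(a, list(a))
  expect_equal(same$p.value, 1)
  expect_false(same$reject)
  res <- ks_bonferroni(a, list(a, a, a))
  expect_equal(res$threshold, rep(0.05 / 3, 3))
  # power: a 45-degree shift at n = 1000 is rejected
  shift <- ks_bonferroni(runif(1000, 0, 90), list(runif(1000, 45, 135)))
  expect_true(shift$reject)
  expect_error(ks_bonferroni(a, list()), "at least one")
})
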