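# Linear feedforward model of V2 responses: Gabor V1 receptive fields
# (simple and energy-style complex variants), tuning-similarity connection
# weights, V2 responses as weighted sums, receptive-field rendering, and
# eight-fold leave-one-out validation.

#' Gabor receptive-field parameters
#'
#' Parameterisation of a V1 simple-cell receptive field: an oriented sinusoidal
#' carrier under an elliptical Gaussian envelope. The carrier varies along the
#' rotated y axis, so `theta_c` is the preferred (grating) orientation. The
#' discretized filter is always normalised to unit L2 norm.
#'
#' @param xc,yc receptive-field centre in degrees of visual angle.
#' @param theta_c preferred orientation in degrees.
#' @param gamma_c aspect ratio of the Gaussian envelope (dimensionless,
#'   clamped to \[0.1, 4\] by convention).
#' @param sigma_x envelope standard deviation along the rotated x axis
#'   (degrees); the default 0.6 corresponds to an optimal spatial frequency of
#'   1 cycle/degree at a bandwidth of about one octave.
#' @param sf carrier spatial frequency in cycles/degree.
#' @param phi carrier phase in radians (0 = even-symmetric, pi/2 = odd).
#' @return object of class `gabor_params`.
#' @export
gabor_params <- function(xc = 0, yc = 0, theta_c = 0, gamma_c = 1,
                         sigma_x = 0.6, sf = 1, phi = 0) {
  stopifnot_scalar(sigma_x, "sigma_x", positive = TRUE)
  stopifnot_scalar(sf, "sf", positive = TRUE)
  if (gamma_c < 0.1 || gamma_c > 4) {
    stop("'gamma_c' must lie in [0.1, 4]", call. = FALSE)
  }
  structure(
    list(xc = xc, yc = yc, theta_c = wrap_po(theta_c), gamma_c = gamma_c,
         sigma_x = sigma_x, sf = sf, phi = phi),
    class = "gabor_params"
  )
}

#' Construct an evaluation raster in visual-field degrees
#'
#' @param xlim,ylim extents in degrees, e.g. `c(-2, 2)`.
#' @param res pixel size in degrees (must resolve the carrier; see
#'   [gabor_filter()]).
#' @return list with coordinate vectors `x` (columns), `y` (rows) and `res`.
#' @export
raster_grid <- function(xlim, ylim, res) {
  stopifnot_scalar(res, "res", positive = TRUE)
  list(x = seq(xlim[1], xlim[2], by = res),
       y = seq(ylim[1], ylim[2], by = res),
       res = res)
}

check_nyquist <- function(res, sf) {
  # require at least 4 samples per carrier cycle
  if (res > 1 / (4 * sf)) {
    stop(sprintf(
      "raster resolution %.4g deg/px too coarse for sf = %.3g cyc/deg (need <= %.4g)",
      res, sf, 1 / (4 * sf)), call. = FALSE)
  }
  invisible(TRUE)
}

# rotated Gabor coordinates, given coordinate matrices
gabor_fields <- function(params, X, Y) {
  th <- params$theta_c * pi / 180
  dx <- X - params$xc
  dy <- Y - params$yc
  xp <- -dy * sin(th) + dx * cos(th)
  yp <- dy * cos(th) + dx * sin(th)
  list(xp = xp, yp = yp)
}

#' Discretized Gabor filter
#'
#' Evaluates the parameterised Gabor on a raster and normalises it to unit L2
#' norm. Errors if the raster undersamples the carrier.
#'
#' @param params a [gabor_params()] object.
#' @param raster a [raster_grid()].
#' @return matrix (rows = y, cols = x) with attribute `raster`.
#' @export
gabor_filter <- function(params, raster) {
  check_nyquist(raster$res, params$sf)
  X <- matrix(raster$x, nrow = length(raster$y), ncol = length(raster$x),
              byrow = TRUE)
  Y <- matrix(raster$y, nrow = length(raster$y), ncol = length(raster$x))
  f <- gabor_fields(params, X, Y)
  env <- exp(-(f$xp^2 + params$gamma_c^2 * f$yp^2) / (2 * params$sigma_x^2))
  g <- env * cos(2 * pi * params$sf * f$yp + params$phi)
  nrm <- sqrt(sum(g^2))
  if (nrm == 0) stop("degenerate Gabor (zero norm on raster)", call. = FALSE)
  structure(g / nrm, raster = raster)
}

#' Sinusoidal grating image on a raster
#'
#' @param raster a [raster_grid()].
#' @param orientation grating orientation in degrees (0 = horizontal).
#' @param sf spatial frequency in cycles/degree.
#' @param phase spatial phase in radians.
#' @param contrast peak amplitude.
#' @return matrix with attribute `raster`.
#' @export
grating_image <- function(raster, orientation, sf = 1, phase = 0,
                          contrast = 1) {
  th <- orientation * pi / 180
  X <- matrix(raster$x, nrow = length(raster$y), ncol = length(raster$x),
              byrow = TRUE)
  Y <- matrix(raster$y, nrow = length(raster$y), ncol = length(raster$x))
  u <- Y * cos(th) + X * sin(th)
  structure(contrast * cos(2 * pi * sf * u + phase), raster = raster)
}

same_raster <- function(a, b) {
  ra <- attr(a, "raster"); rb <- attr(b, "raster")
  !is.null(ra) && !is.null(rb) &&
    isTRUE(all.equal(ra$x, rb$x)) && isTRUE(all.equal(ra$y, rb$y))
}

#' Simple-cell response: half-wave rectified inner product
#'
#' @param filter a filter image from [gabor_filter()].
#' @param image a stimulus image on the same raster.
#' @return nonnegative scalar response.
#' @export
simple_response <- function(filter, image) {
  if (!all(dim(filter) == dim(image))) {
    stop("filter and image raster mismatch", call. = FALSE)
  }
  if (!is.null(attr(filter, "raster")) && !is.null(attr(image, "raster")) &&
      !same_raster(filter, image)) {
    stop("filter and image raster mismatch", call. = FALSE)
  }
  max(0, sum(filter * image))
}

#' Construct a model V1 cell
#'
#' @param params phase-free [gabor_params()] (the `phi` field is ignored).
#' @param mode one of `"complex"` (four quadrature filters at phases 0, pi/2,
#'   pi, 3pi/2), `"simple_even"` (phi = 0) or `"simple_odd"` (phi = pi/2).
#' @param tuning optional measured 8-point tuning curve.
#' @return object of class `v1_cell`.
#' @export
v1_cell <- function(params, mode = c("complex", "simple_even", "simple_odd"),
                    tuning = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "gabor_params"))
  structure(list(params = params, mode = mode, tuning = tuning),
            class = "v1_cell")
}

v1_cell_phases <- function(cell) {
  switch(cell$mode,
         complex = c(0, pi / 2, pi, 3 * pi / 2),
         simple_even = 0,
         simple_odd = pi / 2)
}

#' Energy-style complex-cell response
#'
#' Sum of half-wave rectified responses of four quadrature-phase Gabors
#' (phases 0, pi/2, pi, 3pi/2); contrast-inversion invariant by construction.
#'
#' @param cell a [v1_cell()] with `mode = "complex"`.
#' @param image stimulus image carrying a `raster` attribute.
#' @return nonnegative scalar response.
#' @export
complex_response <- function(cell, image) {
  stopifnot(inherits(cell, "v1_cell"))
  if (cell$mode != "complex") stop("cell is not in complex mode", call. = FALSE)
  raster <- attr(image, "raster")
  if (is.null(raster)) stop("image must carry a raster attribute", call. = FALSE)
  r <- 0
  for (phi in v1_cell_phases(cell)) {
    p <- cell$params; p$phi <- phi
    r <- r + simple_response(gabor_filter(p, raster), image)
  }
  r
}

# ---- fast phase-averaged grating tuning ------------------------------------

# Local raster centred on the envelope; the grid side is capped and the
# resolution relaxed (within the Nyquist bound) for very elongated envelopes.
local_gabor_raster <- function(gamma_c, sigma_x, sf, res, n_max = 321L) {
  half <- 3 * sigma_x * max(1, 1 / gamma_c)
  res_eff <- max(res, 2 * half / (n_max - 1))
  check_nyquist(res_eff, sf)
  raster_grid(c(-half, half), c(-half, half), res_eff)
}

#' Phase-averaged complex-cell tuning to gratings
#'
#' Responses of an energy-model complex cell to full-field gratings at the
#' given orientations, averaged over evenly spaced stimulus spatial phases.
#' Computed on a local raster centred on the receptive field; grating tuning
#' is independent of the receptive-field position.
#'
#' @param theta_c preferred orientation (degrees).
#' @param gamma_c envelope aspect ratio.
#' @param sigma_x envelope width in degrees.
#' @param sf spatial frequency (cycles/degree) of both carrier and gratings.
#' @param orientations stimulus orientations (degrees).
#' @param n_phases number of stimulus spatial phases averaged over.
#' @param res raster resolution in degrees/pixel.
#' @return numeric vector of responses, one per orientation.
#' @export
complex_grating_tuning <- function(theta_c, gamma_c = 1, sigma_x = 0.6,
                                   sf = 1,
                                   orientations = standard_orientations(),
                                   n_phases = 8, res = 0.05) {
  raster <- local_gabor_raster(gamma_c, sigma_x, sf, res)
  pe <- gabor_params(0, 0, theta_c, gamma_c, sigma_x, sf, phi = 0)
  po <- gabor_params(0, 0, theta_c, gamma_c, sigma_x, sf, phi = pi / 2)
  ge <- gabor_filter(pe, raster)
  go <- gabor_filter(po, raster)
  psis <- 2 * pi * (seq_len(n_phases) - 1) / n_phases
  out <- numeric(length(orientations))
  for (k in seq_along(orientations)) {
    gc_ <- grating_image(raster, orientations[k], sf, phase = 0)
    gs_ <- grating_image(raster, orientations[k], sf, phase = -pi / 2)
    ec <- sum(ge * gc_); es <- sum(ge * gs_)
    oc <- sum(go * gc_); os <- sum(go * gs_)
    # response to phase psi is <g, cos(2 pi sf u + psi)> = ec cos - es sin;
    # quadrature sum of four rectified phases collapses to |even| + |odd|
    e <- ec * cos(psis) - es * sin(psis)
    o <- oc * cos(psis) - os * sin(psis)
    out[k] <- mean(abs(e) + abs(o))
  }
  out
}

# ---- aspect-ratio estimation -----------------------------------------------

.bank_cache <- new.env(parent = emptyenv())

#' Precomputed tuning bank over envelope aspect ratios
#'
#' Phase-averaged complex-cell grating tuning as a function of the (axial)
#' offset between stimulus and preferred orientation, tabulated for a bank of
#' envelope aspect ratios (default 40 values from 0.1 to 4). Results are
#' cached per parameter combination.
#'
#' @inheritParams complex_grating_tuning
#' @param gammas candidate aspect ratios.
#' @param dtheta offsets (degrees, in \[0, 90\]) at which tuning is tabulated.
#' @return object of class `aspect_ratio_bank`.
#' @export
aspect_ratio_bank <- function(gammas = seq(0.1, 4, length.out = 40),
                              sigma_x = 0.6, sf = 1, n_phases = 8, res = 0.05,
                              dtheta = seq(0, 90, by = 0.5)) {
  key <- paste(c(gammas, sigma_x, sf, n_phases, res, dtheta),
               collapse = "|")
  if (!is.null(.bank_cache[[key]])) return(.bank_cache[[key]])
  tuning <- matrix(NA_real_, length(gammas), length(dtheta))
  for (g in seq_along(gammas)) {
    tuning[g, ] <- complex_grating_tuning(0, gammas[g], sigma_x, sf,
                                          orientations = dtheta,
                                          n_phases = n_phases, res = res)
  }
  bank <- structure(
    list(gammas = gammas, dtheta = dtheta, tuning = tuning,
         sigma_x = sigma_x, sf = sf, n_phases = n_phases, res = res),
    class = "aspect_ratio_bank"
  )
  .bank_cache[[key]] <- bank
  bank
}

# tuning of bank member g for a cell with preferred orientation po,
# sampled at the stimulus orientations (linear interpolation in |offset|)
bank_tuning <- function(bank, g, po, orientations = standard_orientations()) {
  d <- axial_diff(orientations, po)
  stats::approx(bank$dtheta, bank$tuning[g, ], xout = d, rule = 2)$y
}

#' Estimate the envelope aspect ratio from a measured tuning curve
#'
#' Simulates the 8-orientation complex-cell tuning for each aspect ratio in
#' the bank and picks the one minimising the sum of squared errors between
#' the unit-normalised simulated and measured curves.
#'
#' @param responses measured tuning curve.
#' @param orientations matching stimulus orientations (degrees).
#' @param bank an [aspect_ratio_bank()]; the default bank holds 40 candidate
#'   ratios from 0.1 to 4.
#' @param po preferred orientation; default is the vector-sum estimate.
#' @return list with `gamma_c`, `sse` (per candidate), `po`, and `flagged`
#'   (TRUE for flat/degenerate tuning, where gamma 1 is returned).
#' @export
estimate_aspect_ratio <- function(responses,
                                  orientations = standard_orientations(),
                                  bank = aspect_ratio_bank(), po = NULL) {
  if (is.null(po)) po <- tuning_po(responses, orientations)
  rng <- diff(range(responses))
  if (rng <= 0 || is.na(po)) {
    warning("flat or degenerate tuning; defaulting to aspect ratio 1")
    return(list(gamma_c = 1, sse = rep(NA_real_, length(bank$gammas)),
                po = po, flagged = TRUE))
  }
  meas <- responses / sqrt(sum(responses^2))
  sse <- vapply(seq_along(bank$gammas), function(g) {
    sim <- bank_tuning(bank, g, po, orientations)
    sim <- sim / sqrt(sum(sim^2))
    sum((sim - meas)^2)
  }, numeric(1))
  list(gamma_c = bank$gammas[which.min(sse)], sse = sse, po = po,
       flagged = FALSE)
}

# ---- connection weights and V2 responses -----------------------------------

#' Tuning-similarity connection weights
#'
#' The weight between V1 cell i and V2 pixel j is the inner product of their
#' mean-subtracted, unit-normalised tuning vectors (cosine similarity of the
#' centred curves), so identical curves give +1 and curves preferring
#' orthogonal orientations give -1. Constant curves have undefined weights:
#' the corresponding entries are NA and reported via the `excluded` attribute.
#'
#' @param v1_tunings matrix (cells x orientations) of V1 tuning curves.
#' @param v2_tunings matrix (pixels x orientations) of V2 tuning curves.
#' @return weight matrix (cells x pixels) in \[-1, 1\], with attribute
#'   `excluded` listing row/column indices with zero-variance curves.
#' @export
compute_weights <- function(v1_tunings, v2_tunings) {
  v1_tunings <- rbind(v1_tunings)
  v2_tunings <- rbind(v2_tunings)
  if (ncol(v1_tunings) != ncol(v2_tunings)) {
    stop("tuning vector lengths differ", call. = FALSE)
  }
  norm_rows <- function(m) {
    c_ <- m - rowMeans(m)
    n <- sqrt(rowSums(c_^2))
    list(mat = c_ / ifelse(n > 0, n, 1), bad = which(n == 0))
  }
  a <- norm_rows(v1_tunings)
  b <- norm_rows(v2_tunings)
  w <- tcrossprod(a$mat, b$mat)
  if (length(a$bad)) w[a$bad, ] <- NA_real_
  if (length(b$bad)) w[, b$bad] <- NA_real_
  w <- pmin(pmax(w, -1), 1)
  attr(w, "excluded") <- list(v1 = a$bad, v2 = b$bad)
  w
}

#' Linear V2 response: weighted sum of V1 responses
#'
#' @param weights weight vector, one entry per V1 cell (NA treated as
#'   excluded, i.e. zero contribution).
#' @param v1_responses matching V1 response vector.
#' @return scalar response (kept linear; no output rectification).
#' @export
v2_response <- function(weights, v1_responses) {
  if (length(weights) != length(v1_responses)) {
    stop("weights and responses have different lengths", call. = FALSE)
  }
  sum(ifelse(is.na(weights), 0, weights) * v1_responses)
}

#' Render a model V2 receptive field
#'
#' Weighted spatial sum of the V1 cells' Gabor filters at a common parity
#' (even: phase 0; odd: phase pi/2), on a shared raster covering all
#' receptive-field centres.
#'
#' @param cells list of [v1_cell()] objects (positions in degrees).
#' @param weights numeric weights, one per cell.
#' @param parity `"even"` or `"odd"`.
#' @param raster optional [raster_grid()]; default covers all centres plus a
#'   3-sigma margin at `res` degrees/pixel.
#' @param res default raster resolution (degrees/pixel).
#' @return receptive-field image (matrix) with attribute `raster`.
#' @export
render_v2_rf <- function(cells, weights, parity = c("even", "odd"),
                         raster = NULL, res = 0.02) {
  parity <- match.arg(parity)
  stopifnot(length(cells) == length(weights))
  phi <- if (parity == "even") 0 else pi / 2
  if (is.null(raster)) {
    xs <- vapply(cells, function(cl) cl$params$xc, numeric(1))
    ys <- vapply(cells, function(cl) cl$params$yc, numeric(1))
    margin <- max(vapply(cells, function(cl) {
      3 * cl$params$sigma_x * max(1, 1 / cl$params$gamma_c)
    }, numeric(1)))
    raster <- raster_grid(range(xs) + c(-margin, margin),
                          range(ys) + c(-margin, margin), res)
  }
  acc <- matrix(0, length(raster$y), length(raster$x))
  for (i in seq_along(cells)) {
    if (is.na(weights[i]) || weights[i] == 0) next
    p <- cells[[i]]$params; p$phi <- phi
    acc <- acc + weights[i] * gabor_filter(p, raster)
  }
  structure(acc, raster = raster)
}

# ---- leave-one-out cross validation ----------------------------------------

# gain + offset least squares: predict y from x, return fitted function
affine_calibration <- function(x, y) {
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) {
    b <- 0
  } else {
    b <- stats::cov(x, y) / vx
  }
  a <- mean(y) - b * mean(x)
  function(newx) a + b * newx
}

#' Eight-fold leave-one-out validation of the feedforward model
#'
#' For each held-out orientation, connection weights are recomputed from the
#' remaining seven points of every tuning curve, model V1 grating responses
#' (phase-averaged complex-cell responses from the Gabor filters) are pooled
#' with those weights, and the pooled response is affine-calibrated (gain and
#' offset fitted on the seven training orientations) before comparison with
#' the measured response. Relative error is the absolute prediction error
#' divided by the measured response range across all 8 orientations.
#' Predicted preferred orientation (vector sum) and tuning width (von Mises
#' half width at half height) are reported both from the leave-one-out
#' assembled curves and from a single full-data model.
#'
#' @param v1_tunings measured V1 tuning curves (cells x 8).
#' @param v2_tunings measured V2 tuning curves (pixels x 8).
#' @param v1_model_responses model V1 responses to the 8 gratings (cells x 8),
#'   e.g. from [complex_grating_tuning()]; defaults to `v1_tunings`.
#' @param orientations stimulus orientations (degrees).
#' @param fit_widths if TRUE (default), von Mises fits are run per pixel to
#'   report half-width errors; disable to save time.
#' @return object of class `cv_result`: matrices `predicted` and `measured`
#'   (pixels x 8), `relative_error` (pixels x 8), and per-pixel summaries
#'   `mean_relative_error`, `po_abs_error`, `hwhh_abs_error` (leave-one-out),
#'   plus `po_abs_error_full`/`hwhh_abs_error_full` (full-data model).
#' @export
loo_cross_validate <- function(v1_tunings, v2_tunings,
                               v1_model_responses = NULL,
                               orientations = standard_orientations(),
                               fit_widths = TRUE) {
  v1_tunings <- rbind(v1_tunings)
  v2_tunings <- rbind(v2_tunings)
  if (is.null(v1_model_responses)) v1_model_responses <- v1_tunings
  nfold <- length(orientations)
  stopifnot(ncol(v1_tunings) == nfold, ncol(v2_tunings) == nfold,
            all(dim(v1_model_responses) == dim(v1_tunings)))
  m <- nrow(v2_tunings)
  rng <- apply(v2_tunings, 1, function(r) diff(range(r)))
  if (any(rng <= 0)) {
    stop("degenerate measured V2 tuning (zero range)", call. = FALSE)
  }

  predicted <- matrix(NA_real_, m, nfold)
  for (k in seq_len(nfold)) {
    w <- compute_weights(v1_tunings[, -k, drop = FALSE],
                         v2_tunings[, -k, drop = FALSE])
    w[is.na(w)] <- 0
    raw <- crossprod(w, v1_model_responses)   # pixels x 8 raw pooled
    for (j in seq_len(m)) {
      cal <- affine_calibration(raw[j, -k], v2_tunings[j, -k])
      predicted[j, k] <- cal(raw[j, k])
    }
  }
  relative_error <- abs(predicted - v2_tunings) / rng

  # full-data model (weights and calibration from all 8 orientations)
  w_full <- compute_weights(v1_tunings, v2_tunings)
  w_full[is.na(w_full)] <- 0
  raw_full <- crossprod(w_full, v1_model_responses)
  predicted_full <- t(vapply(seq_len(m), function(j) {
    affine_calibration(raw_full[j, ], v2_tunings[j, ])(raw_full[j, ])
  }, numeric(nfold)))

  po_meas <- apply(v2_tunings, 1, tuning_po, orientations = orientations)
  po_err <- function(pred) {
    po_pred <- apply(pred, 1, tuning_po, orientations = orientations)
    axial_diff(po_pred, po_meas)
  }
  hwhh_err <- function(pred) {
    if (!fit_widths) return(rep(NA_real_, m))
    vapply(seq_len(m), function(j) {
      a <- fit_von_mises(pred[j, ], orientations)
      b <- fit_von_mises(v2_tunings[j, ], orientations)
      if (a$flagged || b$flagged) return(NA_real_)
      abs(a$hwhh - b$hwhh)
    }, numeric(1))
  }

  structure(
    list(predicted = predicted, measured = v2_tunings,
         relative_error = relative_error,
         mean_relative_error = rowMeans(relative_error),
         po_abs_error = po_err(predicted),
         hwhh_abs_error = hwhh_err(predicted),
         predicted_full = predicted_full,
         po_abs_error_full = po_err(predicted_full),
         hwhh_abs_error_full = hwhh_err(predicted_full),
         orientations = orientations),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d pixels; mean relative error %.4f; median |PO error| %.2f deg\n",
    nrow(x$measured), mean(x$mean_relative_error),
    stats::median(x$po_abs_error, na.rm = TRUE)))
  invisible(x)
}
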