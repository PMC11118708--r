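# Orientation map processing: single-condition maps from raw response stacks,
# pixelwise vector-sum preferred orientations, and von Mises tuning fits.

#' The eight standard grating orientations
#'
#' Stimulus orientations used throughout: 0, 22.5, ..., 157.5 degrees.
#' @return numeric vector of length 8.
#' @export
standard_orientations <- function() seq(0, 157.5, by = 22.5)

#' Construct a raw response stack
#'
#' Container for trial-resolved imaging data. Frames are 1-based: the baseline
#' window is frames 1-2 and the evoked window frames 15-20, so at least 20
#' frames per trial are required.
#'
#' @param data 4-d numeric array indexed (trial, frame, row, col).
#' @param orientation per-trial stimulus orientation in degrees (length =
#'   number of trials).
#' @param frame_rate acquisition rate in Hz (default 5).
#' @return an object of class `response_stack`.
#' @export
response_stack <- function(data, orientation, frame_rate = 5) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[2] < 20L) {
    stop("response stacks need >= 20 frames per trial", call. = FALSE)
  }
  if (length(orientation) != dim(data)[1]) {
    stop("'orientation' must have one entry per trial", call. = FALSE)
  }
  structure(
    list(data = data, orientation = wrap_po(orientation),
         frame_rate = frame_rate),
    class = "response_stack"
  )
}

#' Construct an orientation map set
#'
#' Eight single-condition response maps plus metadata. The third array
#' dimension indexes the stimulus orientations.
#'
#' @param responses numeric array (rows, cols, 8).
#' @param orientations stimulus orientations (degrees), default the standard 8.
#' @param vessel_mask logical matrix flagging blood-vessel pixels (TRUE =
#'   vessel), or NULL.
#' @param po_true optional ground-truth preferred-orientation matrix (degrees).
#' @return an object of class `orientation_map_set`.
#' @export
orientation_map_set <- function(responses,
                                orientations = standard_orientations(),
                                vessel_mask = NULL, po_true = NULL) {
  stopifnot(is.array(responses), length(dim(responses)) == 3L)
  if (dim(responses)[3] != length(orientations)) {
    stop("third dimension of 'responses' must match 'orientations'",
         call. = FALSE)
  }
  if (is.null(vessel_mask)) {
    vessel_mask <- matrix(FALSE, dim(responses)[1], dim(responses)[2])
  }
  structure(
    list(responses = responses, orientations = orientations,
         vessel_mask = vessel_mask, po_true = po_true),
    class = "orientation_map_set"
  )
}

#' @export
print.orientation_map_set <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<orientation_map_set> %d x %d px, %d orientations\n",
              d[1], d[2], d[3]))
  invisible(x)
}

# single application of the [0, 100] rescaling used for single-condition maps;
# idempotent by construction (after one pass the max difference equals 100)
rescale_scm <- function(responses, vessel_mask) {
  mn <- apply(responses, c(1, 2), min)
  mx <- apply(responses, c(1, 2), max)
  shifted <- sweep(responses, c(1, 2), mn, `-`)
  denom <- max((mx - mn)[!vessel_mask])
  if (denom <= 0) {
    attr(shifted, "degenerate") <- TRUE
    return(shifted)
  }
  shifted / denom * 100
}

#' Single-condition maps from a raw response stack
#'
#' Per trial, the evoked map (mean of frames 15-20) minus the baseline map
#' (mean of frames 1-2) is inverted, clipped to +/-100, divided by the control
#' image, and band-pass filtered (Gaussian sigma 2.5 px minus sigma 25 px).
#' Trials are then averaged per orientation (excluding the first recorded
#' trial, which supplies the control image), the pixelwise minimum-across-
#' orientations map is subtracted, and the set is rescaled so non-vessel
#' values span \[0, 100\].
#'
#' @param stack a [response_stack()].
#' @param vessel_mask logical matrix (TRUE = vessel) or NULL.
#' @param control_image reference image; default is the average of the first
#'   five frames of the first recorded trial. Must contain no zeros.
#' @param sigma_high,sigma_low standard deviations (pixels) of the light and
#'   heavy smoothing kernels of the high-pass step.
#' @param clip absolute clipping bound applied to raw difference maps.
#' @return an [orientation_map_set()] with one map per orientation present in
#'   the stack (all 8 required).
#' @export
single_condition_maps <- function(stack, vessel_mask = NULL,
                                  control_image = NULL,
                                  sigma_high = 2.5, sigma_low = 25,
                                  clip = 100) {
  stopifnot(inherits(stack, "response_stack"))
  d <- dim(stack$data)
  n_trial <- d[1]
  orientations <- standard_orientations()
  if (!setequal(unique(stack$orientation), orientations)) {
    stop("stack must contain trials for all 8 standard orientations",
         call. = FALSE)
  }
  tab <- table(factor(stack$orientation, levels = orientations))
  if (any(tab < 2)) {
    stop("need >= 2 trials per orientation", call. = FALSE)
  }
  if (is.null(vessel_mask)) vessel_mask <- matrix(FALSE, d[3], d[4])
  if (all(vessel_mask)) stop("vessel mask covers the whole image", call. = FALSE)
  if (is.null(control_image)) {
    control_image <- apply(stack$data[1, 1:5, , , drop = FALSE], c(3, 4), mean)
  }
  if (any(control_image == 0)) {
    stop("control image contains zeros", call. = FALSE)
  }

  trial_map <- function(t) {
    evoked <- apply(stack$data[t, 15:20, , , drop = FALSE], c(3, 4), mean)
    base <- apply(stack$data[t, 1:2, , , drop = FALSE], c(3, 4), mean)
    m <- -(evoked - base)
    m <- pmin(pmax(m, -clip), clip)
    m <- m / control_image
    gaussian_blur(m, sigma_high) - gaussian_blur(m, sigma_low)
  }

  # the globally first recorded trial is the control source and is excluded
  use <- setdiff(seq_len(n_trial), 1L)
  responses <- array(0, c(d[3], d[4], length(orientations)))
  for (k in seq_along(orientations)) {
    idx <- use[stack$orientation[use] == orientations[k]]
    acc <- matrix(0, d[3], d[4])
    for (t in idx) acc <- acc + trial_map(t)
    responses[, , k] <- acc / length(idx)
  }

  nonspec <- apply(responses, c(1, 2), min)
  responses <- sweep(responses, c(1, 2), nonspec, `-`)
  responses <- rescale_scm(responses, vessel_mask)
  orientation_map_set(responses, orientations, vessel_mask)
}

#' Pixelwise vector-sum preferred-orientation map
#'
#' For every pixel the responses to the eight orientations are summed as
#' vectors on the doubled-angle circle; the preferred orientation is half the
#' argument of the resultant and the magnitude is the resultant length
#' normalised by the summed response.
#'
#' @param maps an [orientation_map_set()] or a (rows, cols, 8) array.
#' @param orientations stimulus orientations if `maps` is a bare array.
#' @return an object of class `po_map` with elements `po` (degrees, NA where
#'   undefined), `magnitude`, `vessel_mask`, and `undefined` (logical matrix).
#' @export
vector_sum_po <- function(maps, orientations = standard_orientations()) {
  if (inherits(maps, "orientation_map_set")) {
    responses <- maps$responses
    orientations <- maps$orientations
    vessel_mask <- maps$vessel_mask
  } else {
    responses <- maps
    vessel_mask <- matrix(FALSE, dim(responses)[1], dim(responses)[2])
  }
  d <- dim(responses)
  phase <- exp(2i * orientations * pi / 180)
  z <- matrix(0i, d[1], d[2])
  tot <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) {
    z <- z + responses[, , k] * phase[k]
    tot <- tot + responses[, , k]
  }
  po <- wrap_po(Arg(z) * 90 / pi)
  magnitude <- ifelse(tot > 0, Mod(z) / tot, 0)
  undefined <- Mod(z) <= 1e-9 * pmax(tot, .Machine$double.eps)
  po[undefined] <- NA_real_
  structure(
    list(po = po, magnitude = magnitude, vessel_mask = vessel_mask,
         undefined = undefined),
    class = "po_map"
  )
}

#' @export
print.po_map <- function(x, ...) {
  cat(sprintf("<po_map> %d x %d px (%d undefined, %d vessel)\n",
              nrow(x$po), ncol(x$po), sum(x$undefined), sum(x$vessel_mask)))
  invisible(x)
}

#' Vector-sum preferred orientation of a single tuning curve
#'
#' @param responses response vector (one value per orientation).
#' @param orientations matching orientations in degrees.
#' @return preferred orientation in degrees, or NA if the resultant vanishes.
#' @export
tuning_po <- function(responses, orientations = standard_orientations()) {
  z <- sum(responses * exp(2i * orientations * pi / 180))
  if (Mod(z) <= 1e-9 * max(sum(abs(responses)), .Machine$double.eps)) {
    return(NA_real_)
  }
  wrap_po(Arg(z) * 90 / pi)
}

#' Axial von Mises tuning function
#'
#' `b + a * exp(kappa * cos(2 * (theta - mu) * pi / 180))`.
#'
#' @param theta orientations in degrees.
#' @param baseline,amplitude,kappa,mu model parameters (mu in degrees).
#' @return response values.
#' @export
von_mises <- function(theta, baseline, amplitude, kappa, mu) {
  baseline + amplitude * exp(kappa * cos(2 * (theta - mu) * pi / 180))
}

#' Half width at half height from the von Mises concentration
#'
#' Analytic half-width of the axial von Mises curve: the offset at which the
#' response falls halfway between its minimum and maximum.
#'
#' @param kappa concentration (>= 0).
#' @return half width at half height in degrees (45 in the flat limit, -> 0 as
#'   kappa -> Inf).
#' @export
hwhh_from_kappa <- function(kappa) {
  ifelse(kappa < 1e-8, 45,
         0.5 * acos(pmin(1, logcosh(kappa) / pmax(kappa, 1e-12))) * 180 / pi)
}

#' Fit an axial von Mises function to a tuning curve
#'
#' Least-squares fit of [von_mises()] by bounded quasi-Newton optimisation
#' with restarts of the preferred orientation at the vector-sum estimate and
#' +/-22.5, +/-45 degree offsets. Flat curves are returned flagged rather
#' than raising an error.
#'
#' @param responses tuning-curve responses.
#' @param orientations matching orientations in degrees.
#' @return object of class `von_mises_fit` with fields `baseline`,
#'   `amplitude`, `mu` (degrees in \[0,180)), `kappa`, `hwhh` (degrees),
#'   `rss`, and `flagged`.
#' @export
fit_von_mises <- function(responses, orientations = standard_orientations()) {
  stopifnot(length(responses) == length(orientations),
            all(is.finite(responses)))
  rng <- diff(range(responses))
  if (rng <= 0) {
    return(structure(
      list(baseline = responses[1], amplitude = 0, mu = NA_real_, kappa = 0,
           hwhh = NA_real_, rss = 0, flagged = TRUE),
      class = "von_mises_fit"
    ))
  }
  mu0 <- tuning_po(responses, orientations)
  if (is.na(mu0)) mu0 <- orientations[which.max(responses)]
  k0 <- 2
  sse <- function(p) {
    sum((responses - von_mises(orientations, p[1], p[2], p[3], p[4]))^2)
  }
  best <- NULL
  for (off in c(0, -22.5, 22.5, -45, 45)) {
    a0 <- rng / (exp(k0) - exp(-k0))
    p0 <- c(min(responses) - a0 * exp(-k0), a0, k0, mu0 + off)
    fit <- tryCatch(
      stats::optim(p0, sse, method = "L-BFGS-B",
                   lower = c(-Inf, 0, 0, -Inf),
                   upper = c(Inf, Inf, 500, Inf),
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    return(structure(
      list(baseline = NA_real_, amplitude = NA_real_, mu = NA_real_,
           kappa = NA_real_, hwhh = NA_real_, rss = NA_real_, flagged = TRUE),
      class = "von_mises_fit"
    ))
  }
  p <- best$par
  # an abnormal optimizer code at a near-perfect fit is not a failure
  ss_tot <- sum((responses - mean(responses))^2)
  poor <- best$convergence != 0 && best$value > 1e-6 * ss_tot
  flagged <- poor || p[2] * (exp(p[3]) - exp(-p[3])) < 1e-6 * rng
  structure(
    list(baseline = p[1], amplitude = p[2], mu = wrap_po(p[4]),
         kappa = p[3], hwhh = hwhh_from_kappa(p[3]), rss = best$value,
         flagged = flagged),
    class = "von_mises_fit"
  )
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf(
    "<von_mises_fit> mu = %.2f deg, kappa = %.3f, hwhh = %.2f deg, rss = %.4g%s\n",
    x$mu, x$kappa, x$hwhh, x$rss, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}
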