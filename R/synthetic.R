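# Synthetic-data generators: pinwheel-style orientation maps with cosine
# pixel tuning, spatially clustered labeled-cell sets with a tunable
# like-to-like orientation bias, texture families, and model-generated V2
# pixels with known generative weights. Every generator is deterministic
# under its seed and routes all randomness through that seed.

#' Configuration for synthetic orientation maps
#'
#' @param height,width map size in pixels.
#' @param pixels_per_mm cortical magnification of the raster; the default
#'   (55.6 px/mm) matches an imaging setup where 2.5 px is about 45 microns.
#' @param map_smoothness orientation-map correlation length (hypercolumn
#'   spacing) in mm; `Inf` produces a constant-orientation map.
#' @param noise_sd additive Gaussian noise on single-condition responses
#'   (response units on the 0-100 scale).
#' @param n_orientations must be 8.
#' @param seed integer RNG seed.
#' @return object of class `map_sim_config`.
#' @export
map_sim_config <- function(height, width, pixels_per_mm = 55.6,
                           map_smoothness = 0.75, noise_sd = 2,
                           n_orientations = 8, seed = 1) {
  if (n_orientations != 8) stop("'n_orientations' must be 8", call. = FALSE)
  if (height <= 0 || width <= 0) {
    stop("map dimensions must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(
    list(height = as.integer(height), width = as.integer(width),
         pixels_per_mm = pixels_per_mm, map_smoothness = map_smoothness,
         noise_sd = noise_sd, n_orientations = 8L, seed = as.integer(seed)),
    class = "map_sim_config"
  )
}

fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n) / n
}

# Smooth axial orientation field: band-pass filtered complex white noise;
# the preferred orientation is half the argument of the filtered field.
smooth_po_field <- function(h, w, lambda_px) {
  if (!is.finite(lambda_px)) {
    return(matrix(wrap_po(stats::runif(1, 0, 180)), h, w))
  }
  z <- matrix(complex(real = stats::rnorm(h * w),
                      imaginary = stats::rnorm(h * w)), h, w)
  fr <- sqrt(outer(fft_freqs(h)^2, fft_freqs(w)^2, `+`))
  fc <- 1 / lambda_px
  mask <- exp(-(fr - fc)^2 / (2 * (fc / 3)^2))
  zf <- stats::fft(stats::fft(z) * mask, inverse = TRUE)
  wrap_po(Arg(zf) * 90 / pi)
}

#' Simulate an orientation map set with known ground truth
#'
#' Generates a smooth pinwheel-style preferred-orientation field (doubled-
#' angle construction: half the argument of band-pass filtered complex white
#' noise) and eight single-condition response maps with raised-cosine pixel
#' tuning `r0 + a * cos(2 * (theta_s - PO))` plus i.i.d. Gaussian noise.
#'
#' @param config a [map_sim_config()].
#' @param r0,a baseline and modulation amplitude of the cosine tuning
#'   (response units; defaults place noiseless responses in \[10, 90\]).
#' @return list of class `sim_orientation_map` with elements `maps` (an
#'   [orientation_map_set()] whose `po_true` holds the ground truth) and
#'   `truth` (list with `true_po_map`).
#' @export
simulate_orientation_map <- function(config, r0 = 50, a = 40) {
  stopifnot(inherits(config, "map_sim_config"))
  with_seed(config$seed, {
    lambda_px <- config$map_smoothness * config$pixels_per_mm
    po <- smooth_po_field(config$height, config$width, lambda_px)
    orientations <- standard_orientations()
    responses <- array(0, c(config$height, config$width, 8L))
    for (k in 1:8) {
      responses[, , k] <- r0 + a * cos(2 * (orientations[k] - po) * pi / 180)
      if (config$noise_sd > 0) {
        responses[, , k] <- responses[, , k] +
          stats::rnorm(length(po), sd = config$noise_sd)
      }
    }
    maps <- orientation_map_set(responses, orientations, po_true = po)
    structure(list(maps = maps, truth = list(true_po_map = po),
                   config = config),
              class = "sim_orientation_map")
  })
}

#' Configuration for synthetic labeled-cell sets
#'
#' @param n_cells number of labeled cells to place.
#' @param like_to_like_fwhm full width at half maximum (degrees) of the
#'   wrapped-Gaussian orientation bias around the injection-site orientation.
#' @param bias_strength mixing weight in \[0, 1\] between biased and uniform
#'   orientation sampling; the default 0.31 reproduces a mean like-to-like
#'   fraction (within +/-22.5 deg) close to 48%.
#' @param cluster_scale spatial scale (pixels) of the cell clusters.
#' @param injection_center injection-site centre, `c(x_px, y_px)` (1-based).
#' @param injection_radius injection-site radius in pixels.
#' @param n_clusters number of spatial clusters; default `n_cells / 100`
#'   (at least 3).
#' @param seed integer RNG seed.
#' @return object of class `connectivity_sim_config`.
#' @export
connectivity_sim_config <- function(n_cells, like_to_like_fwhm = 22.5,
                                    bias_strength = 0.31, cluster_scale = 8,
                                    injection_center, injection_radius = 4,
                                    n_clusters = NULL, seed = 1) {
  if (n_cells <= 0) stop("'n_cells' must be positive", call. = FALSE)
  if (bias_strength < 0 || bias_strength > 1) {
    stop("'bias_strength' must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(n_clusters)) n_clusters <- max(3L, round(n_cells / 100))
  structure(
    list(n_cells = as.integer(n_cells), like_to_like_fwhm = like_to_like_fwhm,
         bias_strength = bias_strength, cluster_scale = cluster_scale,
         injection_center = injection_center,
         injection_radius = injection_radius,
         n_clusters = as.integer(n_clusters), seed = as.integer(seed)),
    class = "connectivity_sim_config"
  )
}

#' Simulate labeled V1 cells with a like-to-like orientation bias
#'
#' Each cell's orientation is drawn, with probability `bias_strength`, from a
#' wrapped Gaussian (FWHM `like_to_like_fwhm`) centred on the injection-site
#' orientation, and uniformly otherwise; the cell is then placed on a map
#' pixel carrying that orientation, preferring pixels near one of a set of
#' cluster centres (so the label is concentrated in patches). The reported
#' `po_deg` is always the map value at the chosen pixel.
#'
#' @param config a [connectivity_sim_config()].
#' @param maps an [orientation_map_set()] with ground-truth `po_true`, or a
#'   `sim_orientation_map`.
#' @return data.frame of class `cell_set` with columns `cell_id`, `x_px`,
#'   `y_px` (1-based pixel coordinates), `po_deg`, `injection_id`;
#'   attributes `injection_po` (degrees) and `biased` (logical per cell).
#' @export
simulate_labeled_cells <- function(config, maps) {
  stopifnot(inherits(config, "connectivity_sim_config"))
  if (inherits(maps, "sim_orientation_map")) maps <- maps$maps
  po_mat <- maps$po_true
  if (is.null(po_mat)) po_mat <- vector_sum_po(maps)$po
  h <- nrow(po_mat); w <- ncol(po_mat)
  cx <- config$injection_center[1]; cy <- config$injection_center[2]
  r <- config$injection_radius
  if (cx - r < 1 || cx + r > w || cy - r < 1 || cy + r > h) {
    stop("injection disc extends outside the map", call. = FALSE)
  }
  gx <- matrix(seq_len(w), h, w, byrow = TRUE)
  gy <- matrix(seq_len(h), h, w)
  disc <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  injection_po <- axial_mean(po_mat[disc])

  # index map pixels by integer-degree orientation bins for fast candidate
  # lookup when matching a sampled orientation to a map location
  pix_po <- as.vector(po_mat)
  bins <- pmin(180L, 1L + as.integer(floor(pix_po)))
  by_bin <- split(seq_along(pix_po), factor(bins, levels = 1:180))

  candidates_for <- function(target, tol) {
    ctr <- 1L + as.integer(floor(wrap_po(target)))
    span <- as.integer(ceiling(tol))
    b <- 1L + ((ctr - 1L + (-span):span) %% 180L)
    unlist(by_bin[b], use.names = FALSE)
  }

  with_seed(config$seed, {
    sigma_po <- config$like_to_like_fwhm / (2 * sqrt(2 * log(2)))
    n <- config$n_cells
    biased <- stats::runif(n) < config$bias_strength
    target <- ifelse(
      biased,
      wrap_po(injection_po + stats::rnorm(n, sd = sigma_po)),
      stats::runif(n, 0, 180)
    )
    centers <- cbind(x = stats::runif(config$n_clusters, 1, w),
                     y = stats::runif(config$n_clusters, 1, h))
    cl <- sample.int(config$n_clusters, n, replace = TRUE)
    idx <- integer(n)
    for (i in seq_len(n)) {
      tol <- 1.5
      cand <- candidates_for(target[i], tol)
      while (length(cand) == 0 && tol < 180) {
        tol <- tol * 2
        cand <- candidates_for(target[i], tol)
      }
      d2 <- (((cand - 1L) %% h) + 1L - centers[cl[i], "y"])^2 +
        (((cand - 1L) %/% h) + 1L - centers[cl[i], "x"])^2
      wgt <- exp(-d2 / (2 * config$cluster_scale^2)) + 1e-12
      idx[i] <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L, prob = wgt)]
    }
    cells <- data.frame(
      cell_id = seq_len(n),
      x_px = ((idx - 1L) %/% h) + 1L,
      y_px = ((idx - 1L) %% h) + 1L,
      po_deg = pix_po[idx],
      injection_id = 1L
    )
    class(cells) <- c("cell_set", "data.frame")
    attr(cells, "injection_po") <- injection_po
    attr(cells, "biased") <- biased
    cells
  })
}

#' Simulate a texture family with spectrally matched noise counterparts
#'
#' Generates `n_samples` structured grayscale images (per `kind`) and their
#' phase-randomized, amplitude-preserving noise counterparts via
#' [spectral_noise()]. Textures are prepared (square, resized, circularly
#' masked) before phase randomization, so each texture/noise pair shares its
#' amplitude spectrum exactly.
#'
#' @param n_samples number of texture/noise pairs (>= 1).
#' @param kind `"oriented-composite"` (rectified multi-orientation grating
#'   mixtures), `"thresholded-noise"` (binarized smooth noise), or `"plaid"`.
#' @param seed integer RNG seed.
#' @param size prepared image side in pixels (default 320).
#' @param threshold for `"thresholded-noise"`: binarization threshold in SD
#'   units; `-Inf` skips thresholding, leaving a Gaussian (structureless)
#'   field.
#' @return object of class `texture_family`: lists `textures` and `noises`
#'   (each `n_samples` matrices of side `size`), `kind`, `size`,
#'   `deg_per_px` (1/100).
#' @export
simulate_texture_family <- function(n_samples, kind = c("oriented-composite",
                                                        "thresholded-noise",
                                                        "plaid"),
                                    seed = 1, size = 320, threshold = 0.2) {
  kind <- match.arg(kind)
  if (n_samples < 1) stop("'n_samples' must be >= 1", call. = FALSE)
  with_seed(seed, {
    xy <- seq_len(size)
    X <- matrix(xy, size, size, byrow = TRUE)
    Y <- matrix(xy, size, size)
    # family-level structure parameters are drawn once
    if (kind == "oriented-composite") {
      n_comp <- sample(3:5, 1)
      th <- stats::runif(n_comp, 0, pi)
      f <- stats::runif(n_comp, 3 / size, 10 / size)  # cycles per px
    } else if (kind == "plaid") {
      th <- stats::runif(1, 0, pi) + c(0, stats::runif(1, pi / 4, pi / 2))
      f <- stats::runif(2, 3 / size, 10 / size)
    }
    make_one <- function() {
      if (kind == "thresholded-noise") {
        z <- matrix(stats::rnorm(size^2), size, size)
        z <- gaussian_blur(z, size / 40)
        z <- z / stats::sd(z)
        if (is.infinite(threshold) && threshold < 0) return(z)
        return(ifelse(z > threshold, 1, -1))
      }
      acc <- matrix(0, size, size)
      for (i in seq_along(th)) {
        ph <- stats::runif(1, 0, 2 * pi)
        g <- cos(2 * pi * f[i] * (X * cos(th[i]) + Y * sin(th[i])) + ph)
        acc <- acc + pmax(0, g)^2     # rectification: phase-aligned structure
      }
      acc
    }
    textures <- vector("list", n_samples)
    noises <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      tex <- prepare_image(make_one(), size = size)
      textures[[s]] <- tex
      noises[[s]] <- spectral_noise(tex, seed = child_seed(seed, s))
    }
    structure(
      list(textures = textures, noises = noises, kind = kind, size = size,
           deg_per_px = 1 / 100, seed = seed),
      class = "texture_family"
    )
  })
}

#' Simulate a V2 pixel as a known weighted sum of model V1 cells
#'
#' The 8-orientation tuning curve of the synthetic V2 pixel equals the
#' weighted sum of the cells' phase-averaged complex-model grating responses
#' plus optional Gaussian noise; the generative weights are returned as
#' ground truth.
#'
#' @param v1_tunings matrix (cells x orientations) of model V1 tuning curves,
#'   e.g. rows of [complex_grating_tuning()] outputs.
#' @param weights generative weight vector (length = number of cells).
#' @param noise_sd additive Gaussian noise SD (response units).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return list of class `sim_v2_pixel` with `tuning` (length 8) and
#'   `weights_true`.
#' @export
simulate_v2_pixel <- function(v1_tunings, weights, noise_sd = 0, seed = 1) {
  v1_tunings <- rbind(v1_tunings)
  if (length(weights) != nrow(v1_tunings)) {
    stop("'weights' length must match the number of V1 cells", call. = FALSE)
  }
  tuning <- as.numeric(crossprod(weights, v1_tunings))
  if (noise_sd > 0) {
    tuning <- with_seed(seed, tuning + stats::rnorm(length(tuning),
                                                    sd = noise_sd))
  }
  structure(list(tuning = tuning, weights_true = weights),
            class = "sim_v2_pixel")
}
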