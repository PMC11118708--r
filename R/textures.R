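# Naturalistic-texture analysis: spectrally matched noise via Fourier phase
# randomization, image preparation and rotation, standardized model-cell
# responses, modulation indices with rotation selection, and population
# comparisons.

#' Spectrally matched noise by Fourier phase randomization
#'
#' Replaces the phases of the 2-D Fourier transform with random phases
#' carrying Hermitian symmetry (taken from the transform of white noise) and
#' inverts, preserving the amplitude spectrum exactly. The self-conjugate
#' bins (DC and Nyquist) keep their original values, so mean luminance is
#' untouched and the output is real.
#'
#' @param image grayscale matrix.
#' @param seed RNG seed for the random phases.
#' @return matrix of the same shape with identical amplitude spectrum.
#' @export
spectral_noise <- function(image, seed = 1) {
  if (!is.matrix(image)) stop("'image' must be a 2-D matrix", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  f <- stats::fft(image)
  ph <- with_seed(seed, {
    Arg(stats::fft(matrix(stats::rnorm(h * w), h, w)))
  })
  g <- Mod(f) * exp(1i * ph)
  # self-conjugate bins must stay real; keep the originals there
  sc_r <- unique(c(1L, if (h %% 2 == 0) h / 2 + 1L))
  sc_c <- unique(c(1L, if (w %% 2 == 0) w / 2 + 1L))
  g[sc_r, sc_c] <- f[sc_r, sc_c]
  Re(stats::fft(g, inverse = TRUE)) / (h * w)
}

#' Amplitude spectrum of an image
#'
#' @param image grayscale matrix.
#' @return matrix of Fourier amplitudes.
#' @export
amplitude_spectrum <- function(image) Mod(stats::fft(image))

circular_mask <- function(size) {
  c0 <- (size + 1) / 2
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  matrix(sqrt((g$r - c0)^2 + (g$c - c0)^2) <= size / 2, size, size)
}

#' Apply the standard circular aperture
#'
#' Pixels outside the inscribed circle (diameter = image side) are set to
#' the mean of the pixels inside it.
#'
#' @param image square matrix.
#' @param fill fill value; default the mean luminance inside the aperture.
#' @return masked matrix with attribute `mask` (logical, TRUE inside).
#' @export
apply_circular_mask <- function(image, fill = NULL) {
  stopifnot(nrow(image) == ncol(image))
  m <- circular_mask(nrow(image))
  if (is.null(fill)) fill <- mean(image[m])
  image[!m] <- fill
  structure(image, mask = m)
}

resize_bilinear <- function(image, size) {
  if (nrow(image) == size && ncol(image) == size) return(image)
  rows <- seq(1, nrow(image), length.out = size)
  cols <- seq(1, ncol(image), length.out = size)
  r <- matrix(rows, size, size)
  c_ <- matrix(cols, size, size, byrow = TRUE)
  matrix(bilinear_lookup(image, as.vector(r), as.vector(c_)), size, size)
}

#' Prepare a texture image for presentation
#'
#' Center-crops to a square, resizes to `size` x `size` (bilinear), and
#' applies the circular aperture (diameter = `size`). At the standard scale,
#' 100 pixels correspond to 1 degree of visual angle.
#'
#' @param image grayscale matrix.
#' @param size output side in pixels (default 320).
#' @return prepared matrix with attributes `mask` and `deg_per_px`.
#' @export
prepare_image <- function(image, size = 320) {
  if (!is.matrix(image) || min(dim(image)) < 2) {
    stop("degenerate image", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  side <- min(h, w)
  r0 <- floor((h - side) / 2); c0 <- floor((w - side) / 2)
  sq <- image[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), drop = FALSE]
  out <- apply_circular_mask(resize_bilinear(sq, size))
  attr(out, "deg_per_px") <- 1 / 100
  out
}

#' Rotate a texture family
#'
#' Rotates every prepared texture and noise image about the aperture centre
#' in 22.5-degree steps (default 8 rotations; the first is the identity),
#' re-applying the circular mask, so 30 image pairs yield 240 texture and
#' 240 noise samples.
#'
#' @param family a `texture_family` from [simulate_texture_family()] (or any
#'   list with `textures` and `noises` lists of equal-size square matrices).
#' @param n_rotations number of rotations (default 8).
#' @return object of class `rotated_family`: `textures` and `noises` are
#'   lists indexed `[[sample]][[rotation]]`, plus `rotations` (degrees).
#' @export
rotate_family <- function(family, n_rotations = 8) {
  angles <- (seq_len(n_rotations) - 1) * 22.5
  rot_all <- function(imgs) {
    lapply(imgs, function(img) {
      lapply(angles, function(a) {
        if (a == 0) return(apply_circular_mask(img))
        apply_circular_mask(rotate_image(img, a, fill = mean(img)))
      })
    })
  }
  structure(
    list(textures = rot_all(family$textures), noises = rot_all(family$noises),
         rotations = angles, size = nrow(family$textures[[1]])),
    class = "rotated_family"
  )
}

# standardize values inside the mask to zero mean / unit SD; flagged NULL on
# zero variance
standardize_masked <- function(image, mask) {
  v <- image[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(NULL)
  out <- (image - mean(v)) / s
  out[!mask] <- 0
  out
}

#' Standardized response of a model cell to a prepared image
#'
#' Both the receptive field(s) and the image are standardized to zero mean
#' and unit standard deviation over the circular aperture before the dot
#' product. For a complex cell the four quadrature filters are rectified and
#' summed; a constant (zero-variance) image is flagged and yields response 0.
#'
#' @param cell a [v1_cell()] (complex mode) whose Gabor is evaluated on the
#'   image raster, or a precomputed list of filter matrices.
#' @param image prepared image (square matrix); its raster is derived from
#'   `deg_per_px` (default 1/100) centred on the image.
#' @param deg_per_px degrees per pixel of the image raster.
#' @return scalar response with attribute `flagged` (TRUE for constant
#'   images).
#' @export
cell_response_to_image <- function(cell, image, deg_per_px = 1 / 100) {
  mask <- attr(image, "mask")
  if (is.null(mask)) mask <- circular_mask(nrow(image))
  img_s <- standardize_masked(image, mask)
  if (is.null(img_s)) {
    return(structure(0, flagged = TRUE))
  }
  filters <- if (inherits(cell, "v1_cell")) {
    raster <- image_raster(nrow(image), deg_per_px)
    lapply(v1_cell_phases(cell), function(phi) {
      p <- cell$params; p$phi <- phi
      unclass(gabor_filter(p, raster))
    })
  } else {
    cell
  }
  r <- 0
  for (flt in filters) {
    f_s <- standardize_masked(flt, mask)
    if (is.null(f_s)) next
    r <- r + max(0, sum(f_s * img_s) / sum(mask))
  }
  structure(r, flagged = FALSE)
}

# centred raster for a size x size image at the given scale
image_raster <- function(size, deg_per_px) {
  half <- (size - 1) / 2 * deg_per_px
  raster_grid(c(-half, half), c(-half, half), deg_per_px)
}

#' Responses of V1 cells and V2 pixels to a rotated texture family
#'
#' Computes standardized complex-cell responses of every V1 cell to every
#' texture and noise sample at every rotation, and V2 responses as weighted
#' sums of the V1 responses.
#'
#' @param cells list of [v1_cell()] objects (positions in degrees, relative
#'   to the image centre).
#' @param weights matrix (cells x pixels) of connection weights, or NULL to
#'   skip V2.
#' @param rotated a `rotated_family` from [rotate_family()].
#' @param deg_per_px image scale (default 1/100).
#' @return list with arrays `v1_tex`, `v1_noise` (cell x sample x rotation)
#'   and, when weights are given, `v2_tex`, `v2_noise` (pixel x sample x
#'   rotation).
#' @export
family_responses <- function(cells, weights, rotated, deg_per_px = 1 / 100) {
  size <- rotated$size
  raster <- image_raster(size, deg_per_px)
  mask <- circular_mask(size)
  nm <- sum(mask)
  fmat <- do.call(cbind, lapply(cells, function(cl) {
    vapply(v1_cell_phases(cl), function(phi) {
      p <- cl$params; p$phi <- phi
      f <- standardize_masked(unclass(gabor_filter(p, raster)), mask)
      as.vector(f[mask])
    }, numeric(nm))
  }))
  n_cells <- length(cells)
  n_phase <- 4L   # complex cells
  resp_set <- function(imgs) {
    ns <- length(imgs); nr <- length(rotated$rotations)
    out <- array(NA_real_, c(n_cells, ns, nr))
    for (s in seq_len(ns)) {
      im <- vapply(imgs[[s]], function(img) {
        z <- standardize_masked(img, mask)
        if (is.null(z)) rep(0, nm) else as.vector(z[mask])
      }, numeric(nm))
      dots <- crossprod(fmat, im) / nm     # (cells*phases) x rotations
      rect <- pmax(dots, 0)
      idx <- rep(seq_len(n_cells), each = n_phase)
      out[, s, ] <- rowsum(rect, idx)
    }
    out
  }
  v1_tex <- resp_set(rotated$textures)
  v1_noise <- resp_set(rotated$noises)
  out <- list(v1_tex = v1_tex, v1_noise = v1_noise)
  if (!is.null(weights)) {
    w <- as.matrix(weights)
    w[is.na(w)] <- 0
    mix <- function(a) {
      d <- dim(a)
      array(crossprod(w, matrix(a, d[1], d[2] * d[3])), c(ncol(w), d[2], d[3]))
    }
    out$v2_tex <- mix(v1_tex)
    out$v2_noise <- mix(v1_noise)
  }
  out
}

#' Texture modulation index with rotation selection
#'
#' For one cell, given paired texture and noise responses per rotation,
#' selects the rotation with the most significant differential response
#' (largest `|mean(d)| / var(d)` of the per-pair differences d) and reports
#' the modulation index there: the mean texture response minus the mean
#' noise response, divided by their sum. MI is antisymmetric under swapping
#' the texture and noise labels.
#'
#' @param r_tex,r_noise matrices (samples x rotations) of responses.
#' @return list of class `mi_result`: `mi`, `rotation` (selected index),
#'   `score` per rotation, `pair_mi` (per-pair MIs at the selected rotation),
#'   `mean_tex`, `mean_noise`, `flagged` (TRUE when either mean response is
#'   negative, where the \[-1, 1\] bound no longer holds).
#' @export
modulation_index <- function(r_tex, r_noise) {
  r_tex <- as.matrix(r_tex); r_noise <- as.matrix(r_noise)
  stopifnot(all(dim(r_tex) == dim(r_noise)))
  d <- r_tex - r_noise
  mu <- colMeans(d)
  v <- apply(d, 2, stats::var)
  score <- ifelse(v > 0, abs(mu) / v, ifelse(abs(mu) > 0, Inf, 0))
  if (anyNA(score)) score[is.na(score)] <- 0
  k <- which.max(score)
  mt <- mean(r_tex[, k]); mn <- mean(r_noise[, k])
  if (mt + mn == 0) {
    if (mt == 0 && mn == 0) {
      # all-zero responses: defined as no modulation
      mi <- 0
    } else {
      stop("modulation index undefined: mean responses sum to zero",
           call. = FALSE)
    }
  } else {
    mi <- (mt - mn) / (mt + mn)
  }
  pair_sum <- r_tex[, k] + r_noise[, k]
  pair_mi <- ifelse(pair_sum != 0, d[, k] / pair_sum, 0)
  structure(
    list(mi = mi, rotation = k, score = score, pair_mi = pair_mi,
         mean_tex = mt, mean_noise = mn,
         flagged = (mt < 0 || mn < 0)),
    class = "mi_result"
  )
}

#' Modulation indices for every cell over a family response set
#'
#' @param resp output of [family_responses()].
#' @param which_pop `"v1"` or `"v2"`.
#' @return data.frame with one row per cell: `mi`, `rotation`, `flagged`.
#' @export
population_mi <- function(resp, which_pop = c("v1", "v2")) {
  which_pop <- match.arg(which_pop)
  tex <- resp[[paste0(which_pop, "_tex")]]
  noi <- resp[[paste0(which_pop, "_noise")]]
  rows <- lapply(seq_len(dim(tex)[1]), function(i) {
    r <- modulation_index(tex[i, , ], noi[i, , ])
    data.frame(cell = i, mi = r$mi, rotation = r$rotation,
               flagged = r$flagged)
  })
  do.call(rbind, rows)
}

#' Compare texture sensitivity between V1 and V2 populations
#'
#' Two-sample t-tests (equal variances) on per-cell modulation indices,
#' run on both the per-cell mean MI across families and the per-cell maximum
#' MI across families.
#'
#' @param v1_mi,v2_mi numeric matrices (cells x families) of MIs, or plain
#'   vectors (treated as a single family).
#' @return list with `mean_test` and `max_test` (each: `t`, `df`, `p.value`,
#'   group means and SDs).
#' @export
compare_populations <- function(v1_mi, v2_mi) {
  v1_mi <- as.matrix(v1_mi); v2_mi <- as.matrix(v2_mi)
  if (nrow(v1_mi) < 2 || nrow(v2_mi) < 2) {
    stop("need at least two cells per population", call. = FALSE)
  }
  run <- function(f) {
    a <- apply(v1_mi, 1, f); b <- apply(v2_mi, 1, f)
    if (stats::sd(c(a, b)) == 0) {
      return(list(t = 0, df = length(a) + length(b) - 2, p.value = 1,
                  mean_v1 = mean(a), mean_v2 = mean(b),
                  sd_v1 = stats::sd(a), sd_v2 = stats::sd(b)))
    }
    tt <- stats::t.test(b, a, var.equal = TRUE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, mean_v1 = mean(a), mean_v2 = mean(b),
         sd_v1 = stats::sd(a), sd_v2 = stats::sd(b))
  }
  list(mean_test = run(mean), max_test = run(max))
}
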