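# Internal helpers: axial angle arithmetic, scoped RNG, image primitives.
# Orientations are axial quantities on [0, 180); circular statistics on them
# are always computed after doubling the angle.

wrap_po <- function(x) ((x %% 180) + 180) %% 180

#' Axial distance between orientations
#'
#' Smallest absolute difference between two axial angles (period 180 degrees),
#' so the result lies in \[0, 90\].
#'
#' @param a,b orientations in degrees (vectors recycle).
#' @return distances in degrees.
#' @export
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# circular mean of axial data via angle doubling; optional nonnegative weights
axial_mean <- function(po, w = NULL) {
  z <- exp(2i * po * pi / 180)
  if (!is.null(w)) z <- z * w
  wrap_po(Arg(sum(z)) * 90 / pi)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Deterministic child seed derivation (kept below 2^31 - 1 for set.seed()).
child_seed <- function(seed, k) {
  as.integer(((as.double(seed) %% 2147483647) * 1103 + 9176 * k) %% 2147483629)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# ---- separable Gaussian smoothing with mirror (reflective) boundaries ------

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# mirror indices about the edges (no edge duplication): 0 -> 2, n+1 -> n-1
mirror_idx <- function(n, r) {
  c(seq.int(r + 1L, 2L), seq_len(n), seq.int(n - 1L, n - r))
}

conv_cols_reflect <- function(img, k) {
  n <- nrow(img)
  r <- (length(k) - 1L) %/% 2L
  if (r > n - 1L) stop("Gaussian kernel radius exceeds image size", call. = FALSE)
  pad <- img[mirror_idx(n, r), , drop = FALSE]
  out <- matrix(0, n, ncol(img))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
  }
  out
}

#' Gaussian smoothing of an image
#'
#' Separable isotropic Gaussian filter with mirror-reflective boundary
#' handling, so a constant image is mapped to itself exactly.
#'
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels.
#' @return smoothed matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  if (!is.matrix(img)) stop("'img' must be a matrix", call. = FALSE)
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  t(conv_cols_reflect(t(conv_cols_reflect(img, k)), k))
}

# ---- interpolation / rotation ----------------------------------------------

# Bilinear lookup at fractional (row, col) positions, clamped to the image.
bilinear_lookup <- function(img, row, col) {
  n <- nrow(img); m <- ncol(img)
  row <- pmin(pmax(row, 1), n)
  col <- pmin(pmax(col, 1), m)
  r0 <- pmin(floor(row), n - 1L); c0 <- pmin(floor(col), m - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

# Rotate an image counter-clockwise about its centre by `angle` degrees,
# bilinear interpolation; pixels mapping outside the source get `fill`.
rotate_image <- function(img, angle, fill = 0) {
  if (angle %% 360 == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  a <- angle * pi / 180
  g <- expand.grid(row = seq_len(n), col = seq_len(m))
  dy <- g$row - cy; dx <- g$col - cx
  # inverse mapping (rotate sample points by -angle)
  sr <- cy + dy * cos(a) - dx * sin(a)
  sc <- cx + dy * sin(a) + dx * cos(a)
  out <- bilinear_lookup(img, sr, sc)
  bad <- sr < 1 | sr > n | sc < 1 | sc > m
  out[bad] <- fill
  matrix(out, n, m)
}

# ---- geometry ---------------------------------------------------------------

# Even-odd rule point-in-polygon test; poly is a two-column (x, y) matrix.
point_in_polygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  np <- length(px)
  inside <- logical(length(x))
  j <- np
  for (i in seq_len(np)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# numerically stable log(cosh(k)) for the analytic half-width formula
logcosh <- function(k) {
  ifelse(k > 20, k - log(2), log(cosh(k)))
}
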