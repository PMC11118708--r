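# Cortex-to-visual-field mapping: elliptic grid generation over an outlined
# retinotopic region and nearest-node assignment of labeled cells.

#' Construct a retinotopic outline
#'
#' Four boundary polylines enclosing the labeled region, in pixel
#' coordinates. Side `a` is the V1/V2 border (the vertical-meridian
#' representation); grid index i runs along it. Side `c` is the opposite
#' boundary, oriented the same way; sides `b` and `d` connect the start and
#' end points respectively. Corners must meet.
#'
#' @param side_a,side_b,side_c,side_d two-column (x, y) matrices; single
#'   segments may be given as 2 x 2 matrices.
#' @param extent_par_deg visual-field extent (degrees) along side a.
#' @param extent_orth_deg extent (degrees) along the orthogonal axis.
#' @return object of class `retinotopic_outline`.
#' @export
retinotopic_outline <- function(side_a, side_b, side_c, side_d,
                                extent_par_deg, extent_orth_deg) {
  sides <- lapply(list(a = side_a, b = side_b, c = side_c, d = side_d),
                  function(s) {
                    s <- as.matrix(s)
                    stopifnot(ncol(s) == 2, nrow(s) >= 2)
                    s
                  })
  stopifnot_scalar(extent_par_deg, "extent_par_deg", positive = TRUE)
  stopifnot_scalar(extent_orth_deg, "extent_orth_deg", positive = TRUE)
  near <- function(p, q) sqrt(sum((p - q)^2)) < 1e-6
  first <- function(s) s[1, ]; last <- function(s) s[nrow(s), ]
  if (!near(first(sides$a), first(sides$b)) ||
      !near(first(sides$c), last(sides$b)) ||
      !near(last(sides$a), first(sides$d)) ||
      !near(last(sides$c), last(sides$d))) {
    stop("outline sides do not meet at corners (a/c run i, b/d run j)",
         call. = FALSE)
  }
  structure(
    list(sides = sides, extent_par_deg = extent_par_deg,
         extent_orth_deg = extent_orth_deg),
    class = "retinotopic_outline"
  )
}

#' Rectangular outline helper
#'
#' Axis-aligned rectangle with side a (the border) along y at `x0`.
#'
#' @param x0,y0 top-left corner in pixels.
#' @param width_px,height_px rectangle size in pixels; side a runs along the
#'   height.
#' @param extent_par_deg,extent_orth_deg visual-field extents in degrees.
#' @return a [retinotopic_outline()].
#' @export
outline_rect <- function(x0, y0, width_px, height_px,
                         extent_par_deg, extent_orth_deg) {
  a <- rbind(c(x0, y0), c(x0, y0 + height_px))
  c_ <- rbind(c(x0 + width_px, y0), c(x0 + width_px, y0 + height_px))
  b <- rbind(a[1, ], c_[1, ])
  d <- rbind(a[2, ], c_[2, ])
  retinotopic_outline(a, b, c_, d, extent_par_deg, extent_orth_deg)
}

# boundary polygon (closed, counter-clockwise-ish) for point-in-region tests
outline_polygon <- function(outline) {
  s <- outline$sides
  rbind(s$a, s$d[-1, , drop = FALSE],
        s$c[rev(seq_len(nrow(s$c) - 1)), , drop = FALSE],
        s$b[rev(seq_len(nrow(s$b) - 1)), , drop = FALSE])
}

# arc-length-uniform resampling of a polyline to n points
sample_polyline <- function(p, n) {
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= 0) stop("degenerate outline side", call. = FALSE)
  target <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, p[, 1], xout = target)$y,
        stats::approx(s, p[, 2], xout = target)$y)
}

# transfinite interpolation of the four sampled boundaries
tfi_init <- function(Bx, By) {
  ni <- nrow(Bx); nj <- ncol(Bx)
  u <- (seq_len(ni) - 1) / (ni - 1)
  v <- (seq_len(nj) - 1) / (nj - 1)
  tf <- function(B) {
    outer(1 - u, rep(1, nj)) * matrix(B[1, ], ni, nj, byrow = TRUE) +
      outer(u, rep(1, nj)) * matrix(B[ni, ], ni, nj, byrow = TRUE) +
      outer(rep(1, ni), 1 - v) * matrix(B[, 1], ni, nj) +
      outer(rep(1, ni), v) * matrix(B[, nj], ni, nj) -
      outer(1 - u, 1 - v) * B[1, 1] - outer(u, 1 - v) * B[ni, 1] -
      outer(1 - u, v) * B[1, nj] - outer(u, v) * B[ni, nj]
  }
  tf2 <- tf(Bx); tf2y <- tf(By)
  Bx[2:(ni - 1), 2:(nj - 1)] <- tf2[2:(ni - 1), 2:(nj - 1)]
  By[2:(ni - 1), 2:(nj - 1)] <- tf2y[2:(ni - 1), 2:(nj - 1)]
  list(x = Bx, y = By)
}

# red-black successive over-relaxation of the Laplace grid equations;
# returns on max per-node displacement < tol
relax_grid <- function(X, Y, tol = 1e-5, max_iter = 2.5e6) {
  ni <- nrow(X); nj <- ncol(X)
  if (ni < 3 || nj < 3) {
    return(list(x = X, y = Y, err = 0, iter = 0L, converged = TRUE))
  }
  ii <- 2:(ni - 1); jj <- 2:(nj - 1)
  red <- outer(ii, jj, `+`) %% 2 == 0
  omega <- 2 / (1 + sin(pi / max(ni, nj)))
  err <- Inf; iter <- 0L
  while (err >= tol && iter < max_iter) {
    err <- 0
    for (color in list(red, !red)) {
      nx <- (X[ii - 1, jj] + X[ii + 1, jj] + X[ii, jj - 1] + X[ii, jj + 1]) / 4
      ny <- (Y[ii - 1, jj] + Y[ii + 1, jj] + Y[ii, jj - 1] + Y[ii, jj + 1]) / 4
      dx <- omega * (nx - X[ii, jj]) * color
      dy <- omega * (ny - Y[ii, jj]) * color
      X[ii, jj] <- X[ii, jj] + dx
      Y[ii, jj] <- Y[ii, jj] + dy
      err <- max(err, max(abs(dx)), max(abs(dy)))
    }
    iter <- iter + 1L
  }
  list(x = X, y = Y, err = err, iter = iter, converged = err < tol)
}

# bilinear resampling of node coordinate matrices in index space
resample_nodes <- function(M, ni, nj) {
  u <- seq(1, nrow(M), length.out = ni)
  v <- seq(1, ncol(M), length.out = nj)
  row <- matrix(u, ni, nj)
  col <- matrix(v, ni, nj, byrow = TRUE)
  matrix(bilinear_lookup(M, as.vector(row), as.vector(col)), ni, nj)
}

#' Elliptic grid generation over a retinotopic outline
#'
#' Lays an evenly distributed curvilinear grid over the outlined region by
#' solving the Laplace grid equations (Winslow-type smoothing in
#' computational coordinates) with Dirichlet boundary nodes placed by
#' arc-length-uniform sampling of each side, starting from transfinite
#' interpolation, iterated until the maximum per-node displacement falls
#' below `tol`. Visual-field coordinates are assigned linearly along the
#' grid indices using the outline's degree extents.
#'
#' @param outline a [retinotopic_outline()].
#' @param n_i,n_j grid shape; alternatively give `resolution` (degrees per
#'   step), from which `n_i = round(extent_par / resolution)` and
#'   `n_j = round(extent_orth / resolution)`.
#' @param resolution target resolution in degrees per step.
#' @param tol convergence threshold on the maximum node displacement
#'   (pixels).
#' @param max_iter iteration budget (default 2.5e6 sweeps).
#' @param coarse optional `c(ci, cj)`: solve at this coarse shape first, then
#'   bilinear-resample node coordinates to the requested shape.
#' @return object of class `elliptic_grid`: node matrices `x`, `y`
#'   (n_i x n_j, pixels), visual coordinates `deg_i`, `deg_j`, shape, the
#'   final `convergence_error`, `iterations_used`, and `converged` flag.
#' @export
generate_elliptic_grid <- function(outline, n_i = NULL, n_j = NULL,
                                   resolution = NULL, tol = 1e-5,
                                   max_iter = 2.5e6, coarse = NULL) {
  stopifnot(inherits(outline, "retinotopic_outline"))
  if (!is.null(resolution)) {
    n_i <- round(outline$extent_par_deg / resolution)
    n_j <- round(outline$extent_orth_deg / resolution)
  }
  if (is.null(n_i) || is.null(n_j) || n_i < 2 || n_j < 2) {
    stop("grid shape must be at least 2 x 2", call. = FALSE)
  }
  solve_shape <- if (is.null(coarse)) c(n_i, n_j) else coarse
  a <- sample_polyline(outline$sides$a, solve_shape[1])
  c_ <- sample_polyline(outline$sides$c, solve_shape[1])
  b <- sample_polyline(outline$sides$b, solve_shape[2])
  d <- sample_polyline(outline$sides$d, solve_shape[2])
  X <- matrix(NA_real_, solve_shape[1], solve_shape[2])
  Y <- X
  X[, 1] <- a[, 1]; Y[, 1] <- a[, 2]
  X[, solve_shape[2]] <- c_[, 1]; Y[, solve_shape[2]] <- c_[, 2]
  X[1, ] <- b[, 1]; Y[1, ] <- b[, 2]
  X[solve_shape[1], ] <- d[, 1]; Y[solve_shape[1], ] <- d[, 2]
  init <- tfi_init(X, Y)
  sol <- relax_grid(init$x, init$y, tol = tol, max_iter = max_iter)
  if (!sol$converged) {
    warning(sprintf("elliptic grid did not converge (error %.3g)", sol$err))
  }
  X <- sol$x; Y <- sol$y
  if (!is.null(coarse)) {
    X <- resample_nodes(X, n_i, n_j)
    Y <- resample_nodes(Y, n_i, n_j)
  }
  structure(
    list(x = X, y = Y,
         deg_i = seq(0, outline$extent_par_deg, length.out = n_i),
         deg_j = seq(0, outline$extent_orth_deg, length.out = n_j),
         n_i = n_i, n_j = n_j,
         resolution = c(outline$extent_par_deg / (n_i - 1),
                        outline$extent_orth_deg / (n_j - 1)),
         convergence_error = sol$err, iterations_used = sol$iter,
         converged = sol$converged, outline = outline),
    class = "elliptic_grid"
  )
}

#' @export
print.elliptic_grid <- function(x, ...) {
  cat(sprintf(
    "<elliptic_grid> %d x %d nodes; %s after %d sweeps (error %.3g)\n",
    x$n_i, x$n_j, if (x$converged) "converged" else "NOT converged",
    x$iterations_used, x$convergence_error))
  invisible(x)
}

#' Signed areas of all grid quadrilaterals
#'
#' Shoelace areas of the (n_i-1) x (n_j-1) cells; all positive (or all
#' negative, depending on outline handedness) for a fold-free grid.
#'
#' @param grid an [elliptic_grid()].
#' @return numeric matrix of signed areas.
#' @export
grid_cell_areas <- function(grid) {
  ni <- grid$n_i; nj <- grid$n_j
  i <- seq_len(ni - 1); j <- seq_len(nj - 1)
  x1 <- grid$x[i, j]; y1 <- grid$y[i, j]
  x2 <- grid$x[i + 1, j]; y2 <- grid$y[i + 1, j]
  x3 <- grid$x[i + 1, j + 1]; y3 <- grid$y[i + 1, j + 1]
  x4 <- grid$x[i, j + 1]; y4 <- grid$y[i, j + 1]
  0.5 * ((x1 * y2 - x2 * y1) + (x2 * y3 - x3 * y2) +
           (x3 * y4 - x4 * y3) + (x4 * y1 - x1 * y4))
}

#' Assign labeled cells to visual-field positions
#'
#' Each cell inside the outline is assigned the Euclidean-nearest grid node
#' (cortex pixel coordinates); ties break to the smallest (i, j) in
#' lexicographic order. Cells outside the outline are excluded and reported.
#'
#' @param cells a `cell_set` data.frame (columns `x_px`, `y_px`) or any
#'   data.frame with those columns.
#' @param grid a converged [elliptic_grid()].
#' @return data.frame with columns `cell_id`, `i`, `j`, `x_deg`, `y_deg`,
#'   `dist_px`; attribute `dropped` holds the row indices of cells outside
#'   the outline.
#' @export
assign_cells <- function(cells, grid) {
  stopifnot(inherits(grid, "elliptic_grid"))
  if (!grid$converged) {
    warning("assigning cells on a non-converged grid")
  }
  if (grid$n_i * grid$n_j == 0) stop("empty grid", call. = FALSE)
  poly <- outline_polygon(grid$outline)
  inside <- point_in_polygon(cells$x_px, cells$y_px, poly)
  dropped <- which(!inside)
  keep <- which(inside)
  # lexicographic (i, j) node order so which.min resolves ties correctly
  ij <- expand.grid(j = seq_len(grid$n_j), i = seq_len(grid$n_i))[, c("i", "j")]
  nx <- grid$x[cbind(ij$i, ij$j)]
  ny <- grid$y[cbind(ij$i, ij$j)]
  n <- length(keep)
  best <- integer(n); dist <- numeric(n)
  for (start in seq(1, n, by = 512)) {
    rows <- start:min(start + 511, n)
    dx <- outer(cells$x_px[keep[rows]], nx, `-`)
    dy <- outer(cells$y_px[keep[rows]], ny, `-`)
    d2 <- dx * dx + dy * dy
    b <- apply(d2, 1, which.min)
    best[rows] <- b
    dist[rows] <- sqrt(d2[cbind(seq_along(rows), b)])
  }
  out <- data.frame(
    cell_id = if ("cell_id" %in% names(cells)) cells$cell_id[keep] else keep,
    i = ij$i[best], j = ij$j[best],
    x_deg = grid$deg_i[ij$i[best]],
    y_deg = grid$deg_j[ij$j[best]],
    dist_px = dist
  )
  attr(out, "dropped") <- dropped
  out
}

#' Visual-field extent from retinotopic stripe crossings
#'
#' The extent of the outlined region along an axis, in degrees, computed
#' from the number of retinotopic stripe periods it spans: the outline span
#' divided by the mean stripe period in pixels, times the period in degrees.
#' Fractional periods interpolate linearly.
#'
#' @param outline a [retinotopic_outline()].
#' @param stripe_traces positions (pixels, along the chosen axis) of
#'   successive stripe centres, one period apart; at least two are required.
#' @param period_deg stripe period in degrees of visual angle.
#' @param axis `"parallel"` (along side a) or `"orthogonal"`.
#' @return extent in degrees.
#' @export
degrees_from_stripes <- function(outline, stripe_traces, period_deg,
                                 axis = c("parallel", "orthogonal")) {
  axis <- match.arg(axis)
  stopifnot(inherits(outline, "retinotopic_outline"))
  if (length(stripe_traces) < 2) {
    stop("need at least two stripe traces to measure the period",
         call. = FALSE)
  }
  side <- if (axis == "parallel") outline$sides$a else outline$sides$b
  dirv <- side[nrow(side), ] - side[1, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  proj <- outline_polygon(outline) %*% dirv
  span_px <- diff(range(proj))
  period_px <- mean(diff(sort(stripe_traces)))
  if (period_px <= 0) stop("stripe traces must be distinct", call. = FALSE)
  span_px / period_px * period_deg
}
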