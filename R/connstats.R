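# Orientation-bias statistics for labeled V1 inputs: axial histograms,
# circular summary statistics (doubled-angle), chi-square and KS tests, and
# the pixel-resampling, pattern-shift and perfect-like-to-like nulls.

#' Orientations at labeled points on a preferred-orientation map
#'
#' Nearest-pixel lookup of the map orientation at each point; points landing
#' on vessel (or undefined) pixels are dropped and reported.
#'
#' @param po_map a `po_map` from [vector_sum_po()].
#' @param x,y point coordinates in pixels (1-based; fractional values round
#'   to the nearest pixel).
#' @return numeric vector of orientations (degrees); attribute `dropped`
#'   holds indices of points that fell on vessels or undefined pixels.
#' @export
po_at_points <- function(po_map, x, y) {
  stopifnot(inherits(po_map, "po_map"), length(x) == length(y))
  h <- nrow(po_map$po); w <- ncol(po_map$po)
  ri <- as.integer(round(y)); ci <- as.integer(round(x))
  if (any(ri < 1 | ri > h | ci < 1 | ci > w)) {
    stop("points outside the map", call. = FALSE)
  }
  idx <- cbind(ri, ci)
  bad <- po_map$vessel_mask[idx] | po_map$undefined[idx]
  if (all(bad)) stop("all points fall on vessel/undefined pixels",
                     call. = FALSE)
  out <- po_map$po[idx][!bad]
  attr(out, "dropped") <- which(bad)
  out
}

#' Fraction of cells within an orientation tolerance of the injection site
#'
#' @param cells_po cell orientations in degrees.
#' @param injection_po injection-site orientation (degrees; typically the
#'   doubled-angle circular mean over the injection pixels).
#' @param tol half-width of the acceptance window in degrees (axial distance;
#'   default 22.5).
#' @return fraction in \[0, 1\].
#' @export
fraction_within <- function(cells_po, injection_po, tol = 22.5) {
  if (length(cells_po) == 0) stop("empty orientation list", call. = FALSE)
  mean(axial_diff(cells_po, injection_po) <= tol)
}

#' Axial orientation histogram over the eight stimulus bins
#'
#' Bins are centred at the stimulus orientations (width 22.5 degrees) and
#' wrap at 180, so e.g. 175 degrees falls in the 0-degree bin. Values on a
#' bin edge go to the bin with the lower centre.
#'
#' @param po orientations in degrees.
#' @param orientations bin centres (default the standard 8).
#' @return integer vector of counts (class `po_distribution`, with the bin
#'   centres as names).
#' @export
po_histogram <- function(po, orientations = standard_orientations()) {
  d <- vapply(orientations, function(ctr) axial_diff(po, ctr),
              numeric(length(po)))
  d <- rbind(d)
  bin <- apply(d, 1, which.min)
  counts <- tabulate(bin, nbins = length(orientations))
  names(counts) <- orientations
  structure(counts, class = "po_distribution")
}

#' Circular statistics for axial orientation data
#'
#' Angles are doubled before computing the mean resultant length (MRL); the
#' circular standard deviation is `sqrt(-2 * log(MRL))` and the mean
#' orientation is half the resultant angle.
#'
#' @param po orientations in degrees.
#' @return list of class `circular_stats`: `mrl` in \[0, 1\], `csd`
#'   (radians, `Inf` when MRL = 0) and `mean_po` (degrees).
#' @export
circ_stats <- function(po) {
  if (length(po) == 0) stop("empty orientation list", call. = FALSE)
  z <- mean(exp(2i * po * pi / 180))
  mrl <- Mod(z)
  structure(
    list(mrl = mrl,
         csd = if (mrl > 0) sqrt(-2 * log(mrl)) else Inf,
         mean_po = wrap_po(Arg(z) * 90 / pi)),
    class = "circular_stats"
  )
}

# vectorised MRL/CSD over columns of a doubled-angle phase matrix
circ_stats_cols <- function(po_matrix) {
  z <- colMeans(exp(2i * po_matrix * pi / 180))
  mrl <- Mod(z)
  list(mrl = mrl, csd = ifelse(mrl > 0, sqrt(-2 * log(mrl)), Inf))
}

#' Chi-square goodness-of-fit test on orientation histograms
#'
#' Pearson chi-square comparing observed to expected counts; expected counts
#' are rescaled to the observed total. Zero-expected bins are merged into the
#' cyclically following bin and reported. Eight intact bins give 7 degrees of
#' freedom.
#'
#' @param observed observed counts.
#' @param expected expected counts (any positive scale).
#' @return list with `statistic`, `df`, `p.value`, and `merged` (indices of
#'   bins merged away, possibly empty).
#' @export
chisq_gof <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  expected <- expected / sum(expected) * sum(observed)
  merged <- integer(0)
  while (any(expected == 0) && length(expected) > 1) {
    k <- which(expected == 0)[1]
    nxt <- if (k == length(expected)) 1L else k + 1L
    expected[nxt] <- expected[nxt] + expected[k]
    observed[nxt] <- observed[nxt] + observed[k]
    expected <- expected[-k]; observed <- observed[-k]
    merged <- c(merged, k)
  }
  if (length(merged)) {
    warning(sprintf("%d zero-expected bin(s) merged", length(merged)))
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       merged = merged)
}

#' Pixel-resampling null for the orientation bias of labeled cells
#'
#' Draws `m` pixels uniformly without replacement from the non-vessel pixels
#' inside the labeled-field contour, `n_rep` times, and records the circular
#' statistics of each draw.
#'
#' @param po_map a `po_map`.
#' @param field_contour two-column (x, y) polygon in pixel coordinates, or
#'   NULL for the whole map.
#' @param m number of pixels per draw (the number of labeled cells).
#' @param n_rep number of replicates (default 1000).
#' @param seed RNG seed.
#' @return object of class `null_ensemble` with vectors `mrl` and `csd`,
#'   `kind = "pixel_resample"`, and the draw parameters.
#' @export
pixel_resample_null <- function(po_map, field_contour = NULL, m,
                                n_rep = 1000, seed = 1) {
  stopifnot(inherits(po_map, "po_map"))
  ok <- !po_map$vessel_mask & !po_map$undefined
  if (!is.null(field_contour)) {
    h <- nrow(po_map$po); w <- ncol(po_map$po)
    gx <- matrix(seq_len(w), h, w, byrow = TRUE)
    gy <- matrix(seq_len(h), h, w)
    ok <- ok & matrix(point_in_polygon(as.vector(gx), as.vector(gy),
                                       as.matrix(field_contour)), h, w)
  }
  pool <- po_map$po[ok]
  if (length(pool) < m) {
    stop("contour contains fewer eligible pixels than cells", call. = FALSE)
  }
  with_seed(seed, {
    draws <- matrix(NA_real_, m, n_rep)
    for (r in seq_len(n_rep)) {
      draws[, r] <- pool[sample.int(length(pool), m)]
    }
    st <- circ_stats_cols(draws)
    structure(
      list(mrl = st$mrl, csd = st$csd, kind = "pixel_resample",
           n_rep = n_rep, m = m, seed = seed),
      class = "null_ensemble"
    )
  })
}

#' Admissible rigid shifts for a cell pattern on a map
#'
#' All integer (dx, dy) translations that keep every cell inside the map.
#'
#' @param po_map a `po_map` (or anything with `$po` a matrix).
#' @param x,y cell coordinates in pixels.
#' @return two-column integer matrix of shifts (dx, dy).
#' @export
admissible_shifts <- function(po_map, x, y) {
  h <- nrow(po_map$po); w <- ncol(po_map$po)
  x <- round(x); y <- round(y)
  dxs <- seq.int(1L - min(x), w - max(x))
  dys <- seq.int(1L - min(y), h - max(y))
  if (length(dxs) == 0 || length(dys) == 0) {
    stop("no admissible shift keeps the pattern in bounds", call. = FALSE)
  }
  as.matrix(expand.grid(dx = dxs, dy = dys))
}

#' Pattern-shift null for the orientation bias of labeled cells
#'
#' Rigidly translates the observed cell pattern (integer pixels, no rotation
#' or reflection) to positions sampled uniformly from the set of shifts that
#' keep every cell inside the map, and records the circular statistics of the
#' map orientations under the shifted pattern. Cells landing on vessel or
#' undefined pixels are dropped per replicate.
#'
#' @param po_map a `po_map`.
#' @param x,y observed cell coordinates in pixels.
#' @param n_shifts number of replicates (default 1500).
#' @param seed RNG seed.
#' @param include_zero if TRUE the unshifted pattern is included as the first
#'   replicate.
#' @return `null_ensemble` with `kind = "pattern_shift"` and per-replicate
#'   `n_dropped`.
#' @export
pattern_shift_null <- function(po_map, x, y, n_shifts = 1500, seed = 1,
                               include_zero = FALSE) {
  stopifnot(inherits(po_map, "po_map"))
  x <- round(x); y <- round(y)
  shifts <- admissible_shifts(po_map, x, y)
  ok <- !po_map$vessel_mask & !po_map$undefined
  with_seed(seed, {
    pick <- shifts[sample.int(nrow(shifts), n_shifts, replace = TRUE), ,
                   drop = FALSE]
    if (include_zero) pick[1, ] <- c(0L, 0L)
    mrl <- numeric(n_shifts); csd <- numeric(n_shifts)
    n_dropped <- integer(n_shifts)
    for (r in seq_len(n_shifts)) {
      xi <- x + pick[r, 1]; yi <- y + pick[r, 2]
      idx <- cbind(yi, xi)
      good <- ok[idx]
      n_dropped[r] <- sum(!good)
      if (!any(good)) {
        mrl[r] <- NA_real_; csd[r] <- NA_real_
        next
      }
      st <- circ_stats(po_map$po[idx][good])
      mrl[r] <- st$mrl; csd[r] <- st$csd
    }
    structure(
      list(mrl = mrl, csd = csd, kind = "pattern_shift", n_rep = n_shifts,
           m = length(x), seed = seed, n_dropped = n_dropped,
           shifts = pick),
      class = "null_ensemble"
    )
  })
}

#' Exceedance fractions of observed circular statistics under a null
#'
#' The fraction of null replicates with MRL strictly greater than the
#' observed MRL, and with CSD strictly smaller than the observed CSD.
#'
#' @param ensemble a `null_ensemble`.
#' @param observed a `circular_stats` object for the observed cells.
#' @return list with `f_mrl_greater` and `f_csd_smaller`.
#' @export
exceedance <- function(ensemble, observed) {
  stopifnot(inherits(ensemble, "null_ensemble"),
            inherits(observed, "circular_stats"))
  list(f_mrl_greater = mean(ensemble$mrl > observed$mrl, na.rm = TRUE),
       f_csd_smaller = mean(ensemble$csd < observed$csd, na.rm = TRUE))
}

# ---- perfect like-to-like model --------------------------------------------

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# probability mass of a wrapped (period-180) Gaussian at `center` within the
# bin [lo, hi]; sigma = 0 collapses to a point mass
wrapped_bin_prob <- function(center, lo, hi, sigma) {
  if (sigma <= 0) {
    d <- wrap_po(center - lo)
    width <- wrap_po(hi - lo)
    return(as.numeric(d < width | d - 180 >= -1e-9))
  }
  ks <- -4:4
  sum(stats::pnorm(hi + 180 * ks, mean = center, sd = sigma) -
        stats::pnorm(lo + 180 * ks, mean = center, sd = sigma))
}

#' Perfect like-to-like connectivity model
#'
#' Models the orientation distribution expected under exact like-to-like
#' connectivity from a multi-column injection site: a mixture of wrapped
#' Gaussians centred at the orientations represented at the injection site,
#' with mixture weights equal to the injection-site pixel fractions and a
#' fixed full width at half maximum (default 22.5 degrees, the stimulus
#' sampling resolution).
#'
#' @param injection_counts 8-bin orientation histogram of the injection-site
#'   pixels (e.g. from [po_histogram()]).
#' @param fwhm component FWHM in degrees.
#' @param orientations bin centres.
#' @return list of class `like_to_like_model`: `centers`, `alpha` (weights
#'   summing to 1), `sigma` (degrees), `bin_probs` over the 8 bins.
#' @export
like_to_like_model <- function(injection_counts, fwhm = 22.5,
                               orientations = standard_orientations()) {
  if (sum(injection_counts) <= 0) {
    stop("empty injection histogram", call. = FALSE)
  }
  alpha <- injection_counts / sum(injection_counts)
  keep <- alpha > 0
  centers <- orientations[keep]
  alpha <- alpha[keep]
  sigma <- fwhm_to_sd(fwhm)
  half <- 22.5 / 2
  bin_probs <- vapply(orientations, function(ctr) {
    sum(vapply(seq_along(centers), function(i) {
      alpha[i] * wrapped_bin_prob(centers[i], ctr - half, ctr + half, sigma)
    }, numeric(1)))
  }, numeric(1))
  names(bin_probs) <- orientations
  structure(
    list(centers = centers, alpha = as.numeric(alpha), sigma = sigma,
         fwhm = fwhm, orientations = orientations, bin_probs = bin_probs),
    class = "like_to_like_model"
  )
}

#' Draw orientations from a like-to-like model
#'
#' @param model a [like_to_like_model()].
#' @param n number of draws.
#' @param seed RNG seed.
#' @return orientations in degrees, wrapped to \[0, 180).
#' @export
like_to_like_draw <- function(model, n, seed = 1) {
  with_seed(seed, {
    comp <- sample.int(length(model$centers), n, replace = TRUE,
                       prob = model$alpha)
    wrap_po(model$centers[comp] + stats::rnorm(n, sd = model$sigma))
  })
}

#' Test observed cell orientations against perfect like-to-like connectivity
#'
#' Builds the like-to-like mixture from the injection-site histogram, bins
#' its density into the 8 stimulus bins, and compares the observed cell
#' histogram to the expected counts with a chi-square goodness-of-fit test.
#' A non-significant result is consistent with perfect like-to-like
#' connectivity.
#'
#' @param injection_counts injection-site 8-bin histogram.
#' @param observed_counts labeled-cell 8-bin histogram.
#' @param fwhm component FWHM in degrees (default 22.5).
#' @param orientations bin centres.
#' @return list with the fitted `model`, `expected` counts, and `chisq`
#'   (from [chisq_gof()]).
#' @export
like_to_like_sim <- function(injection_counts, observed_counts, fwhm = 22.5,
                             orientations = standard_orientations()) {
  model <- like_to_like_model(injection_counts, fwhm, orientations)
  expected <- model$bin_probs * sum(observed_counts)
  list(model = model, expected = expected,
       chisq = chisq_gof(observed_counts, expected))
}

#' Bonferroni-corrected Kolmogorov-Smirnov comparisons
#'
#' Two-sample KS tests of the observed orientation sample against each of a
#' set of comparison samples, rejecting at a Bonferroni-corrected family-wise
#' level.
#'
#' @param observed observed orientations (degrees).
#' @param samples list of comparison samples (each a numeric vector).
#' @param family_alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per comparison: `statistic`, `p.value`,
#'   `threshold`, `reject`, `degenerate` (constant sample flag).
#' @export
ks_bonferroni <- function(observed, samples, family_alpha = 0.05) {
  if (length(samples) < 1) stop("need at least one comparison", call. = FALSE)
  thr <- family_alpha / length(samples)
  rows <- lapply(seq_along(samples), function(k) {
    s <- samples[[k]]
    degenerate <- length(unique(observed)) < 2 || length(unique(s)) < 2
    kt <- suppressWarnings(stats::ks.test(observed, s))
    data.frame(comparison = k, statistic = unname(kt$statistic),
               p.value = kt$p.value, threshold = thr,
               reject = kt$p.value < thr, degenerate = degenerate)
  })
  do.call(rbind, rows)
}
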