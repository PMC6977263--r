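# Root-shape dimension reduction: mean-boundary radial profiles,
# convex-hull contours, and their Fourier expansions (real series for
# radial profiles, elliptical Fourier descriptors for closed contours)
# with truncated reconstruction for display.

#' Mean boundary distance profile
#'
#' For each of `samples` equally spaced directions from the foreground
#' centroid, a ray is marched across the mask and the distances of all
#' foreground-to-background crossings are recorded; the profile value is
#' their mean (the "mean boundary"). Directions with no foreground are
#' interpolated circularly.
#'
#' @param mask A [root_mask()] or logical matrix.
#' @param samples Number of directions (default 360).
#' @param step Ray marching step in px.
#' @return Object of class `"radial_profile"`: list with `profile`
#'   (length `samples`, px), `centroid` (row, col) and `samples`.
#' @export
mean_boundary_profile <- function(mask, samples = 360, step = 0.25) {
  m <- mask_pixels(mask)
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) < 3) stop("mask too small for a boundary profile")
  ctr <- colMeans(fg)
  H <- nrow(m); W <- ncol(m)
  rmax <- sqrt(H^2 + W^2)
  prof <- rep(NA_real_, samples)
  ts <- seq(step, rmax, by = step)
  for (j in seq_len(samples)) {
    phi <- 2 * pi * (j - 1) / samples
    # direction in (row, col): phi = 0 points along +col, increasing
    # counter-clockwise in standard orientation (row axis points down)
    rr <- round(ctr[1] - ts * sin(phi))
    cc <- round(ctr[2] + ts * cos(phi))
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    if (!any(ok)) next
    inside <- rep(FALSE, length(ts))
    inside[ok] <- m[cbind(rr[ok], cc[ok])]
    if (!any(inside)) next
    # crossings: last inside sample of each maximal inside run
    runs_end <- which(inside & !c(inside[-1], FALSE))
    prof[j] <- mean(ts[runs_end])
  }
  if (anyNA(prof)) {
    if (all(is.na(prof))) stop("degenerate mask: no ray hits foreground")
    idx <- seq_len(samples)
    good <- which(!is.na(prof))
    # circular linear interpolation over missing directions
    ext_x <- c(good - samples, good, good + samples)
    ext_y <- rep(prof[good], 3)
    prof[is.na(prof)] <- stats::approx(ext_x, ext_y, xout = idx[is.na(prof)])$y
  }
  structure(list(profile = prof, centroid = ctr, samples = samples),
            class = "radial_profile")
}

#' Convex-hull contour of a mask
#'
#' Counter-clockwise (in standard x/y orientation, x = column,
#' y = negated row) polygon of the convex hull of the foreground pixel
#' centres, starting at the vertex with the lowest row index (ties to the
#' lowest column).
#'
#' @param mask A [root_mask()] or logical matrix with at least 3
#'   non-collinear foreground pixels.
#' @return Two-column matrix (`col`, `row`) of hull vertices, closed
#'   implicitly (first vertex not repeated).
#' @export
hull_contour <- function(mask) {
  m <- mask_pixels(mask)
  hull <- hull_of_mask(m)
  if (is.null(hull)) stop("mask is degenerate (fewer than 3 non-collinear pixels)")
  if (poly_area(hull) <= 0) stop("mask is degenerate (collinear pixels)")
  x <- hull[, 1]; y <- hull[, 2]
  n <- length(x)
  # orient counter-clockwise in (x, -y): signed area in (x, y) negative
  jn <- c(n, seq_len(n - 1))
  signed <- sum(x[jn] * y - x * y[jn]) / 2
  if (signed > 0) { x <- rev(x); y <- rev(y) }
  start <- order(y, x)[1]
  idx <- c(start:length(x), seq_len(start - 1))
  cbind(col = x[idx], row = y[idx])
}

#' Fourier expansion of a shape
#'
#' Radial profiles expand in a real Fourier series (cosine/sine pairs per
#' harmonic); closed contours expand in elliptical Fourier descriptors
#' (one `a, b, c, d` quadruple per harmonic, arc-length parameterised,
#' closed form for polygonal contours). With `normalize = TRUE`,
#' elliptical descriptors are scaled so the first-harmonic semi-major
#' axis is 1 (size invariance); radial profiles are scaled by their mean.
#'
#' @param x A `"radial_profile"` or a 2-column matrix of closed-contour
#'   vertices.
#' @param N Number of harmonics (1..100; must not exceed half the number
#'   of samples).
#' @param normalize Scale-normalise the spectrum.
#' @return Object of class `"shape_spectrum"`: `source`, `N`,
#'   `coefficients` data frame, `offset` (mean/centroid term),
#'   `normalize`, `scale` and, for contours, the vertex count.
#' @export
fourier_expand <- function(x, N = 20, normalize = FALSE) {
  stopifnot(N >= 1, N <= 100)
  if (inherits(x, "radial_profile")) {
    p <- x$profile
    M <- length(p)
    if (N > M / 2) stop("N exceeds samples/2 (aliasing)")
    scale <- if (normalize) mean(p) else 1
    p <- p / scale
    j <- 0:(M - 1)
    co <- t(vapply(seq_len(N), function(n) {
      c(a = 2 / M * sum(p * cos(2 * pi * n * j / M)),
        b = 2 / M * sum(p * sin(2 * pi * n * j / M)))
    }, c(a = 0, b = 0)))
    structure(list(source = "mean_boundary", N = N,
                   coefficients = data.frame(n = seq_len(N), co),
                   offset = mean(p), normalize = normalize, scale = scale,
                   samples = M),
              class = "shape_spectrum")
  } else {
    stopifnot(is.matrix(x), ncol(x) == 2)
    eft <- elliptical_fourier(x, N)
    scale <- 1
    if (normalize) {
      # semi-major axis of harmonic 1
      a1 <- eft$coefficients[1, c("a", "b", "c", "d")]
      M1 <- matrix(as.numeric(a1), 2, 2, byrow = TRUE)
      sv <- svd(M1)$d
      scale <- sv[1]
      eft$coefficients[, c("a", "b", "c", "d")] <-
        eft$coefficients[, c("a", "b", "c", "d")] / scale
    }
    structure(list(source = "convex_hull", N = N,
                   coefficients = eft$coefficients,
                   offset = eft$offset, normalize = normalize, scale = scale,
                   perimeter = eft$perimeter),
              class = "shape_spectrum")
  }
}

# Elliptical Fourier descriptors of a closed polygon (closed-form
# integrals over the linear segments; standard arc-length convention).
elliptical_fourier <- function(poly, N) {
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  K <- nrow(poly)
  stopifnot(K >= 3)
  dx <- diff(c(poly[, 1], poly[1, 1]))
  dy <- diff(c(poly[, 2], poly[1, 2]))
  dt <- sqrt(dx^2 + dy^2)
  if (any(dt == 0)) {
    keep <- dt > 0
    poly <- poly[keep, , drop = FALSE]
    dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
    K <- nrow(poly)
  }
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-K])
  T <- t1[K]
  co <- t(vapply(seq_len(N), function(n) {
    w <- 2 * pi * n / T
    cs <- cos(w * t1) - cos(w * t0)
    sn <- sin(w * t1) - sin(w * t0)
    f <- T / (2 * n^2 * pi^2)
    c(a = f * sum(dx / dt * cs), b = f * sum(dx / dt * sn),
      c = f * sum(dy / dt * cs), d = f * sum(dy / dt * sn))
  }, c(a = 0, b = 0, c = 0, d = 0)))
  # offset (A0, C0): mean position over arc length, exact for
  # piecewise-linear contours
  xs <- c(poly[, 1]); ys <- c(poly[, 2])
  x_end <- xs + dx; y_end <- ys + dy
  A0 <- sum((xs + x_end) / 2 * dt) / T
  C0 <- sum((ys + y_end) / 2 * dt) / T
  list(coefficients = data.frame(n = seq_len(N), co),
       offset = c(A0 = A0, C0 = C0), perimeter = T)
}

#' Reconstruct an outline from a shape spectrum
#'
#' Inverse Fourier series truncated at `N_use` harmonics.
#'
#' @param spectrum A `"shape_spectrum"`.
#' @param N_use Harmonics to use (`<= spectrum$N`).
#' @param samples Output sampling density.
#' @return For radial spectra, a list with `theta` and `radius`; for
#'   contour spectra, a 2-column matrix of outline points.
#' @export
fourier_reconstruct <- function(spectrum, N_use = spectrum$N, samples = 400) {
  stopifnot(inherits(spectrum, "shape_spectrum"))
  if (N_use > spectrum$N) stop("N_use exceeds the stored harmonic count")
  co <- spectrum$coefficients[seq_len(N_use), , drop = FALSE]
  if (spectrum$source == "mean_boundary") {
    th <- seq(0, 2 * pi, length.out = samples + 1)[-(samples + 1)]
    r <- rep(spectrum$offset, samples)
    for (k in seq_len(N_use))
      r <- r + co$a[k] * cos(co$n[k] * th) + co$b[k] * sin(co$n[k] * th)
    list(theta = th, radius = r * spectrum$scale)
  } else {
    t <- seq(0, 1, length.out = samples + 1)[-(samples + 1)]
    x <- rep(spectrum$offset["A0"] / spectrum$scale, samples)
    y <- rep(spectrum$offset["C0"] / spectrum$scale, samples)
    for (k in seq_len(N_use)) {
      w <- 2 * pi * co$n[k] * t
      x <- x + co$a[k] * cos(w) + co$b[k] * sin(w)
      y <- y + co$c[k] * cos(w) + co$d[k] * sin(w)
    }
    cbind(col = x * spectrum$scale, row = y * spectrum$scale)
  }
}
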