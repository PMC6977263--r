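# Shared fixtures (memoised per session) and independent brute-force
# oracles used across the test files.

.fx_cache <- new.env(parent = emptyenv())

# One rendered scene per seed, cached.
fx_scene <- function(seed, ...) {
  key <- paste0("scene_", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- render_blueprint(sample_blueprint(seed = seed, ...))
  .fx_cache[[key]]
}

# Labelled skeleton of a scene's truth mask, cached.
fx_skeleton <- function(seed, ...) {
  key <- paste0("skel_", seed)
  if (is.null(.fx_cache[[key]])) {
    sc <- fx_scene(seed, ...)
    g <- skeletonize(sc$truth$mask)
    g <- detect_primary_root(g)
    g <- prune_spurs(g, 10)
    .fx_cache[[key]] <- label_laterals(g)
  }
  .fx_cache[[key]]
}

# Digitised straight line through a window, angle from vertical (deg).
mk_line_patch <- function(angle_deg, H = 100, W = 100, half = 45, ctr = c(50, 50)) {
  th <- angle_deg * pi / 180
  u <- seq(-half, half, by = 0.5)
  r <- round(ctr[1] + u * cos(th)); c <- round(ctr[2] + u * sin(th))
  ok <- r >= 1 & r <= H & c >= 1 & c <= W
  m <- matrix(FALSE, H, W)
  m[cbind(r[ok], c[ok])] <- TRUE
  m
}

# --- independent oracles ----------------------------------------------------

# Perimeter by direct enumeration: foreground pixels with a 4-neighbour
# outside the mask (border counts as background).
oracle_perimeter <- function(m) {
  H <- nrow(m); W <- ncol(m)
  cnt <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!m[r, c]) next
    nb <- c(
      if (r > 1) m[r - 1, c] else FALSE,
      if (r < H) m[r + 1, c] else FALSE,
      if (c > 1) m[r, c - 1] else FALSE,
      if (c < W) m[r, c + 1] else FALSE)
    if (!all(nb)) cnt <- cnt + 1
  }
  cnt
}

# O(n^3) convex hull: a point is a hull vertex iff it is not strictly
# inside any triangle of other points, implemented via the half-plane
# test (vertex iff some line through it has all points on one side).
oracle_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      # edge i -> j: is every other point on the left (or on the line)?
      v <- pts[j, ] - pts[i, ]
      cr <- (pts[, 1] - pts[i, 1]) * v[2] - (pts[, 2] - pts[i, 2]) * v[1]
      if (all(cr <= 1e-9) || all(cr >= -1e-9)) {
        on_hull[i] <- TRUE
        break
      }
    }
  }
  pts[on_hull, , drop = FALSE]
}

# Row profile by direct row scan.
oracle_row_profile <- function(skel_matrix) {
  out <- NULL
  for (r in seq_len(nrow(skel_matrix))) {
    cols <- which(skel_matrix[r, ])
    if (!length(cols)) next
    runs <- sum(diff(cols) > 1) + 1
    out <- rbind(out, data.frame(row = r, run_count = runs,
                                 pixel_sum = length(cols)))
  }
  out
}

# Elliptical Fourier coefficients by dense midpoint quadrature of the
# defining integrals a_n = -1/(n pi) int x\'(t) sin(2 pi n t/T) dt (and
# analogues), evaluated on a fine uniform resampling of the polygon.
oracle_efd <- function(poly, N, samples = 2^16) {
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  K <- nrow(poly)
  nxt <- c(2:K, 1)
  seg <- sqrt(rowSums((poly[nxt, ] - poly)^2))
  Tt <- sum(seg)
  cum <- c(0, cumsum(seg))
  tt <- seq(0, Tt, length.out = samples + 1)
  pos <- function(t) {
    t <- pmin(t, Tt - 1e-12)
    i <- findInterval(t, cum, rightmost.closed = TRUE)
    i[i > K] <- K
    frac <- (t - cum[i]) / seg[i]
    poly[i, , drop = FALSE] + frac * (poly[nxt, , drop = FALSE][i, , drop = FALSE] - poly[i, , drop = FALSE])
  }
  P <- pos(tt)
  dt <- diff(tt)
  dxdt <- diff(P[, 1]) / dt
  dydt <- diff(P[, 2]) / dt
  tm <- (tt[-1] + tt[-length(tt)]) / 2
  co <- t(vapply(seq_len(N), function(n) {
    w <- 2 * pi * n / Tt
    c(a = -1 / (n * pi) * sum(dxdt * sin(w * tm) * dt),
      b =  1 / (n * pi) * sum(dxdt * cos(w * tm) * dt),
      c = -1 / (n * pi) * sum(dydt * sin(w * tm) * dt),
      d =  1 / (n * pi) * sum(dydt * cos(w * tm) * dt))
  }, c(a = 0, b = 0, c = 0, d = 0)))
  data.frame(n = seq_len(N), co)
}

# Two-sample KS statistic by direct empirical-CDF evaluation.
oracle_ks_D <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}
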