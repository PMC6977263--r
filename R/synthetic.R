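# Synthetic root-image generator with analytic ground truth.
#
# Renders a parametric soybean-like root system (one sinuous taproot plus
# first-order laterals) on a blue, mildly noisy background, and returns the
# exact foreground mask together with analytic lengths, angles and counts.
# Every downstream module is tested against these generated scenes.

disc_offsets_cache <- new.env(parent = emptyenv())

disc_offsets <- function(radius) {
  key <- sprintf("r%.2f", radius)
  if (!is.null(disc_offsets_cache[[key]])) return(disc_offsets_cache[[key]])
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
  out <- as.matrix(g)
  disc_offsets_cache[[key]] <- out
  out
}

paint_polyline <- function(mask, pts, widths) {
  # subpixel-accurate stamping: a pixel is foreground iff its centre lies
  # within the stroke radius of the (unrounded) sample point
  H <- nrow(mask); W <- ncol(mask)
  radii <- pmax(widths / 2, 0.6)
  box <- ceiling(max(radii)) + 1L
  off <- as.matrix(expand.grid(dr = -box:box, dc = -box:box))
  for (i in seq_len(nrow(pts))) {
    r <- floor(pts[i, 1]) + off[, 1]
    c <- floor(pts[i, 2]) + off[, 2]
    d2 <- (r - pts[i, 1])^2 + (c - pts[i, 2])^2
    ok <- d2 <= radii[i]^2 & r >= 1 & r <= H & c >= 1 & c <= W
    mask[cbind(r[ok], c[ok])] <- TRUE
  }
  mask
}

# Sample a constant-curvature lateral: start point, initial angle from
# vertical (deg), side (+1 right / -1 left), curvature (rad/px), length (px).
lateral_points <- function(p0, angle_deg, side, length_px, curvature = 0,
                           step = 0.4) {
  u <- seq(0, length_px, by = step)
  phi0 <- angle_deg * pi / 180
  if (abs(curvature) < 1e-12) {
    dr <- cos(phi0); dc <- side * sin(phi0)
    cbind(p0[1] + u * dr, p0[2] + u * dc)
  } else {
    # tangent angle from vertical grows linearly with arc length
    phi <- phi0 + curvature * u
    r <- p0[1] + (sin(phi) - sin(phi0)) / curvature
    c <- p0[2] + side * (cos(phi0) - cos(phi)) / curvature
    cbind(r, c)
  }
}

#' Draw a random root-system blueprint
#'
#' A blueprint fully determines one synthetic root scene: a taproot
#' rendered as a natural cubic spline through jittered control points with
#' a linearly tapering stroke width, plus straight (or constant-curvature)
#' first-order laterals. With `guarantee = TRUE` (the default) laterals
#' are well separated in depth, share a similar angle per side and stay
#' clear of each other, so skeletonization provably recovers the topology.
#'
#' @param seed Integer seed; the same seed reproduces the blueprint.
#' @param canvas `c(H, W)` canvas size in pixels.
#' @param depth_px Range (length-2) of taproot depth extents in px.
#' @param wiggle_px Horizontal control-point jitter sd of the taproot (px).
#' @param width_top_px,width_tip_px Ranges for the taproot stroke width at
#'   the top and at the tip (linear taper in arc length).
#' @param n_lat Range for the number of laterals per side.
#' @param lat_angle_deg Range of lateral branching angles from vertical.
#' @param lat_length_px Range of lateral lengths.
#' @param lat_width_px Range of lateral stroke widths.
#' @param lat_curvature Range of lateral curvatures (rad/px); 0 = straight.
#' @param guarantee Enforce the well-separated topology-recovery class.
#' @param noise_sd Gaussian pixel noise sd of the rendered image.
#' @param n_blotch Number of specular over-saturation blotches (0 = none).
#' @return An object of class `"root_blueprint"`.
#' @export
sample_blueprint <- function(seed = 1, canvas = c(400, 300),
                             depth_px = c(260, 330),
                             wiggle_px = 2,
                             width_top_px = c(5, 7),
                             width_tip_px = c(2.5, 3.5),
                             n_lat = c(2, 4),
                             lat_angle_deg = c(30, 65),
                             lat_length_px = c(60, 130),
                             lat_width_px = c(2, 3.5),
                             lat_curvature = c(0, 0),
                             guarantee = TRUE,
                             noise_sd = 0.02,
                             n_blotch = 0) {
  stopifnot(length(canvas) == 2, canvas[1] >= 60, canvas[2] >= 40)
  set.seed(seed)
  H <- canvas[1]; W <- canvas[2]
  depth <- runif(1, depth_px[1], depth_px[2])
  if (depth > H - 20) stop("taproot depth range exceeds the canvas")
  r0 <- 8
  c0 <- W / 2
  n_ctrl <- 6
  ctrl_r <- seq(r0, r0 + depth, length.out = n_ctrl)
  ctrl_c <- c0 + c(0, cumsum(rnorm(n_ctrl - 1, 0, wiggle_px)))
  ctrl_c <- pmin(pmax(ctrl_c, 15), W - 15)
  w_top <- runif(1, width_top_px[1], width_top_px[2])
  w_tip <- runif(1, width_tip_px[1], width_tip_px[2])

  laterals <- NULL
  k_per_side <- if (n_lat[2] < 1) 0
                else if (n_lat[1] == n_lat[2]) n_lat[1]
                else sample(seq(n_lat[1], n_lat[2]), 1)
  if (!guarantee && k_per_side >= 1) {
    for (side in c(-1, 1)) {
      k <- k_per_side
      s <- runif(k, 0.12, 0.85)
      ang <- runif(k, lat_angle_deg[1], lat_angle_deg[2])
      laterals <- rbind(laterals, data.frame(
        s_frac = s, side = side, angle_deg = ang,
        length_px = runif(k, lat_length_px[1], lat_length_px[2]),
        width_px = runif(k, lat_width_px[1], lat_width_px[2]),
        curvature = runif(k, lat_curvature[1], lat_curvature[2])))
    }
  } else if (k_per_side >= 1) {
    # guarantee class: the same number of laterals on each side, attached
    # on a global alternating slot grid in the upper-middle taproot.
    # Same-side attachments are two slots apart and the sides are
    # staggered by one slot, so every junction node is distinct. Per-side
    # angles are near-identical (laterals stay parallel, never touching)
    # and capped when a side holds several laterals so the band-overlap
    # length extension (below) cannot leave the canvas.
    k <- k_per_side
    s_lo <- 0.25; s_hi <- 0.58
    slot <- (s_hi - s_lo) / (2 * k)
    for (side in c(-1, 1)) {
      slots <- if (side < 0) seq(0, by = 2, length.out = k)
               else seq(1, by = 2, length.out = k)
      s <- s_lo + slots * slot + runif(k, 0.05, 0.30) * slot
      a_hi <- if (k > 1) min(lat_angle_deg[2], 55) else lat_angle_deg[2]
      a_lo <- min(lat_angle_deg[1], a_hi)
      base_angle <- runif(1, a_lo, a_hi)
      ang <- pmin(pmax(base_angle + runif(k, -1.5, 1.5), a_lo), a_hi)
      laterals <- rbind(laterals, data.frame(
        s_frac = s, side = side, angle_deg = ang,
        length_px = runif(k, lat_length_px[1], lat_length_px[2]),
        width_px = runif(k, lat_width_px[1], lat_width_px[2]),
        curvature = runif(k, lat_curvature[1], lat_curvature[2])))
    }
  }
  if (!is.null(laterals)) {
    sp <- stats::splinefun(ctrl_r, ctrl_c, method = "natural")
    if (guarantee && nrow(laterals) > 1) {
      # band-overlap guarantee: every lateral of a side must still be
      # descending at the side's deepest attachment row, so one sliding
      # band crosses all of them simultaneously
      att_row <- vapply(seq_len(nrow(laterals)), function(i)
        attach_point(ctrl_r, sp, laterals$s_frac[i])[1], numeric(1))
      for (side in unique(laterals$side)) {
        idx <- which(laterals$side == side)
        r_last <- max(att_row[idx])
        need <- (r_last - att_row[idx] + 12) /
          cos(laterals$angle_deg[idx] * pi / 180)
        laterals$length_px[idx] <- pmax(laterals$length_px[idx], need)
      }
    }
    laterals <- clamp_laterals(laterals, ctrl_r, sp, canvas,
                               guarantee = guarantee)
  }
  structure(list(canvas = canvas, ctrl_r = ctrl_r, ctrl_c = ctrl_c,
                 depth_px = depth, width_top = w_top, width_tip = w_tip,
                 laterals = laterals, noise_sd = noise_sd,
                 n_blotch = n_blotch, guarantee = guarantee, seed = seed),
            class = "root_blueprint")
}


# Shrink lateral lengths so strokes stay inside the canvas (6 px margin)
# and, for the guarantee class, above the taproot tip. With
# on_infeasible = "error" a lateral squeezed below 20 px aborts;
# "truncate" keeps it at whatever room remains (used when a fixed
# template is injected into varying taproot depths).
clamp_laterals <- function(laterals, ctrl_r, sp, canvas, guarantee = TRUE,
                           on_infeasible = "error") {
  H <- canvas[1]; W <- canvas[2]
  for (i in seq_len(nrow(laterals))) {
    a <- attach_point(ctrl_r, sp, laterals$s_frac[i])
    th <- laterals$angle_deg[i] * pi / 180
    max_len_c <- if (laterals$side[i] > 0)
      (W - 6 - a[2]) / max(sin(th), 1e-6) else (a[2] - 6) / max(sin(th), 1e-6)
    max_len_r <- (H - 6 - a[1]) / max(cos(th), 1e-6)
    laterals$length_px[i] <- min(laterals$length_px[i], max_len_c, max_len_r)
    if (guarantee) {
      # keep the taproot tip the deepest point so the deepest skeleton
      # endpoint is unambiguously the primary-root tip
      tip_row <- max(ctrl_r)
      max_len_d <- (tip_row - 15 - a[1]) / max(cos(th), 1e-6)
      laterals$length_px[i] <- min(laterals$length_px[i], max_len_d)
    }
    if (laterals$length_px[i] < 20) {
      if (on_infeasible == "error")
        stop("infeasible lateral: too little canvas room at attachment")
      laterals$length_px[i] <- max(laterals$length_px[i], 6)
    }
  }
  laterals
}

# Arc length of the taproot spline between rows a and b (Gauss quadrature
# on the spline derivative, piecewise between control rows).
taproot_arclen <- function(ctrl_r, sp, a = min(ctrl_r), b = max(ctrl_r)) {
  f <- function(r) sqrt(1 + sp(r, deriv = 1)^2)
  gl_integrate(f, a, b, nodes = 16, pieces = 24)
}

# Point on the taproot at arc-length fraction s (0 = top, 1 = tip).
attach_point <- function(ctrl_r, sp, s_frac) {
  rr <- seq(min(ctrl_r), max(ctrl_r), by = 0.25)
  cc <- sp(rr)
  cum <- c(0, cumsum(sqrt(diff(rr)^2 + diff(cc)^2)))
  target <- s_frac * cum[length(cum)]
  i <- which.min(abs(cum - target))
  c(rr[i], cc[i])
}

#' Render a blueprint into an image plus ground truth
#'
#' Strokes the taproot spline and each lateral at their stated widths into
#' a binary truth mask, then composes the colour scene: yellow-white root
#' over blue paper with Gaussian pixel noise, a thin blended edge ring,
#' and optional specular blotches.
#'
#' @param blueprint A [sample_blueprint()] result.
#' @param cal A [calibration()] object.
#' @param plant_id,day Metadata stamped on the returned image.
#' @return List with `image` (a [root_image()]) and `truth` (class
#'   `"root_truth"`: the exact mask, polylines, analytic `PRL_cm`,
#'   `LRL_cm`, `TRL_cm`, mask-derived `DEP_cm`/`WID_cm`, per-side lateral
#'   counts and per-lateral angles).
#' @export
render_blueprint <- function(blueprint, cal = calibration(),
                             plant_id = "synthetic", day = 9L) {
  bp <- blueprint
  stopifnot(inherits(bp, "root_blueprint"))
  H <- bp$canvas[1]; W <- bp$canvas[2]
  sp <- stats::splinefun(bp$ctrl_r, bp$ctrl_c, method = "natural")

  rr <- seq(min(bp$ctrl_r), max(bp$ctrl_r), by = 0.4)
  cc <- sp(rr)
  if (any(cc < 1 | cc > W)) stop("taproot curve exits the canvas")
  tap_pts <- cbind(rr, cc)
  seg <- sqrt(diff(rr)^2 + diff(cc)^2)
  cum <- c(0, cumsum(seg))
  s_frac_pts <- cum / cum[length(cum)]
  tap_w <- bp$width_top + (bp$width_tip - bp$width_top) * s_frac_pts

  mask <- matrix(FALSE, H, W)
  mask <- paint_polyline(mask, tap_pts, tap_w)

  lat_polys <- list()
  PRL_px <- taproot_arclen(bp$ctrl_r, sp)
  LRL_px <- 0
  if (!is.null(bp$laterals) && nrow(bp$laterals)) {
    for (i in seq_len(nrow(bp$laterals))) {
      L <- bp$laterals[i, ]
      a <- attach_point(bp$ctrl_r, sp, L$s_frac)
      pts <- lateral_points(a, L$angle_deg, L$side, L$length_px, L$curvature)
      if (any(pts[, 1] < 1 | pts[, 1] > H | pts[, 2] < 1 | pts[, 2] > W))
        stop("lateral curve exits the canvas")
      mask <- paint_polyline(mask, pts, rep(L$width_px, nrow(pts)))
      lat_polys[[i]] <- pts
      LRL_px <- LRL_px + L$length_px
    }
  }

  # colour scene
  set.seed(bp$seed + 7919L)
  bg_rgb <- as.vector(grDevices::col2rgb(grDevices::hsv(220 / 360, 0.65, 0.72))) / 255
  rt_rgb <- as.vector(grDevices::col2rgb(grDevices::hsv(54 / 360, 0.30, 0.96))) / 255
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(bg_rgb[ch], H, W)
    plane[mask] <- rt_rgb[ch]
    img[, , ch] <- plane
  }
  # thin blended edge ring (sub-pixel coverage stand-in); truth stays the core
  ring <- (EBImage::dilate(mask * 1, EBImage::makeBrush(3, "box")) > 0.5) & !mask
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ring] <- 0.72 * bg_rgb[ch] + 0.28 * rt_rgb[ch]
    img[, , ch] <- plane
  }
  if (bp$n_blotch > 0) {
    for (b in seq_len(bp$n_blotch)) {
      ctr <- c(runif(1, 20, H - 20), runif(1, 20, W - 20))
      off <- disc_offsets(runif(1, 8, 18))
      r <- round(ctr[1]) + off[, 1]; c <- round(ctr[2]) + off[, 2]
      ok <- r >= 1 & r <= H & c >= 1 & c <= W & !mask[cbind(pmax(pmin(r, H), 1), pmax(pmin(c, W), 1))]
      bl <- grDevices::col2rgb(grDevices::hsv(220 / 360, 0.12, 0.98)) / 255
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[cbind(r[ok], c[ok])] <- bl[ch]
        img[, , ch] <- plane
      }
    }
  }
  img <- img + array(rnorm(H * W * 3, 0, bp$noise_sd), c(H, W, 3))
  img <- pmin(pmax(img, 0), 1)

  fg <- which(mask, arr.ind = TRUE)
  truth <- structure(list(
    mask = root_mask(mask, cal),
    taproot = tap_pts,
    laterals = lat_polys,
    lateral_meta = bp$laterals,
    PRL_cm = px_to_cm(PRL_px, cal),
    LRL_cm = px_to_cm(LRL_px, cal),
    TRL_cm = px_to_cm(PRL_px + LRL_px, cal),
    DEP_cm = px_to_cm(diff(range(fg[, 1])), cal),
    WID_cm = px_to_cm(diff(range(fg[, 2])), cal),
    n_lat = if (is.null(bp$laterals)) 0L else nrow(bp$laterals),
    n_left = if (is.null(bp$laterals)) 0L else sum(bp$laterals$side < 0),
    n_right = if (is.null(bp$laterals)) 0L else sum(bp$laterals$side > 0),
    angles_deg = if (is.null(bp$laterals)) numeric(0) else bp$laterals$angle_deg,
    width_top = bp$width_top, width_tip = bp$width_tip
  ), class = "root_truth")

  list(image = root_image(img, cal, plant_id = plant_id, day = day),
       truth = truth)
}

#' Generate a genotype panel of synthetic images on disk
#'
#' Emulates a replicated growth-chamber experiment: each genotype receives
#' a systematic taproot-depth shift (the genetic effect, sd `sigma_g_px`),
#' each block an additive environmental shift (`sigma_b_px`), and each
#' replicate independent noise (`sigma_e_px`), giving the two-way
#' random-effects structure with known variance components for end-to-end
#' testing of the statistics stage. Lateral configuration is held fixed
#' across the panel so the designed genetic variance of total root length
#' is exactly the depth-shift variance (up to a common linear scale, which
#' cancels in heritability).
#'
#' @param n_genotypes,reps,blocks Panel dimensions.
#' @param sigma_g_px,sigma_b_px,sigma_e_px Standard deviations (px) of the
#'   genotype, block and residual depth shifts.
#' @param base_depth_px Mean taproot depth extent (px).
#' @param canvas Canvas size `c(H, W)`.
#' @param seed Integer seed.
#' @param dir Output directory; images, truth masks and three CSVs
#'   (`manifest.csv`, `design.csv`, `truth.csv`) are written there.
#' @param day Imaging day stamped on every image.
#' @param cal A [calibration()] object.
#' @return Invisibly, a list with `manifest`, `design`, `truth` data
#'   frames and the design heritability `h2_design` of the depth shift at
#'   `n = reps`.
#' @export
make_panel <- function(n_genotypes = 10, reps = 14, blocks = 1,
                       sigma_g_px = 30, sigma_b_px = 8, sigma_e_px = 15,
                       base_depth_px = 260, canvas = c(400, 300),
                       seed = 1, dir = tempfile("panel"), day = 9L,
                       cal = calibration()) {
  stopifnot(n_genotypes >= 2, reps >= 1, blocks >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  set.seed(seed)
  g_eff <- rnorm(n_genotypes, 0, sigma_g_px)
  b_eff <- rnorm(blocks, 0, sigma_b_px)
  # one lateral template for the whole panel, with lengths proportional
  # to the taproot depth: total root length is then exactly linear in the
  # depth shift, so the designed variance components carry over to TRL
  bp0 <- sample_blueprint(seed = seed * 999L + 1L, canvas = canvas,
                          depth_px = c(base_depth_px, base_depth_px),
                          n_lat = c(3, 3))
  lat0 <- bp0$laterals
  len_frac <- lat0$length_px / base_depth_px
  manifest <- NULL; design <- NULL; truth_tab <- NULL
  rep_per_block <- split(seq_len(reps),
                         rep(seq_len(blocks), length.out = reps))
  img_seed <- seed * 1000L
  for (g in seq_len(n_genotypes)) {
    for (bk in seq_len(blocks)) {
      for (r in rep_per_block[[bk]]) {
        img_seed <- img_seed + 1L
        e <- rnorm(1, 0, sigma_e_px)
        depth <- base_depth_px + g_eff[g] + b_eff[bk] + e
        depth <- min(max(depth, 60), canvas[1] - 25)
        bp <- sample_blueprint(seed = img_seed, canvas = canvas,
                               depth_px = c(depth, depth),
                               n_lat = c(0, 0))
        lat <- lat0
        lat$length_px <- len_frac * depth
        sp_i <- stats::splinefun(bp$ctrl_r, bp$ctrl_c, method = "natural")
        bp$laterals <- clamp_laterals(lat, bp$ctrl_r, sp_i, canvas,
                                      guarantee = TRUE,
                                      on_infeasible = "truncate")
        id <- sprintf("G%03d-B%d-R%02d", g, bk, r)
        sc <- render_blueprint(bp, cal, plant_id = id, day = day)
        img_path <- file.path(dir, "images", sprintf("%s_%d.png", id, day))
        png::writePNG(sc$image$pixels, img_path)
        write_mask(sc$truth$mask, file.path(dir, "masks",
                                            sprintf("%s_%d_mask.png", id, day)))
        manifest <- rbind(manifest, data.frame(
          plant_id = id, day = day, path = img_path,
          pixels_per_cm = cal$pixels_per_cm, block = bk,
          stringsAsFactors = FALSE))
        design <- rbind(design, data.frame(
          plant_id = id, genotype = sprintf("G%03d", g), block = bk, rep = r,
          stringsAsFactors = FALSE))
        truth_tab <- rbind(truth_tab, data.frame(
          plant_id = id, day = day, TRL = sc$truth$TRL_cm,
          PRL = sc$truth$PRL_cm, LRL = sc$truth$LRL_cm,
          DEP = sc$truth$DEP_cm, WID = sc$truth$WID_cm,
          n_lat = sc$truth$n_lat, stringsAsFactors = FALSE))
      }
    }
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  write.csv(truth_tab, file.path(dir, "truth.csv"), row.names = FALSE)
  n_per_g <- reps
  h2 <- sigma_g_px^2 / (sigma_g_px^2 + sigma_e_px^2 / n_per_g)
  invisible(list(manifest = manifest, design = design, truth = truth_tab,
                 h2_design = h2, dir = dir))
}
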