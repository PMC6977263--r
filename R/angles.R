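# Root-angle estimation: per-window dominant orientation via 2D
# frequency-domain low-pass filtering followed by a straight-line Hough
# transform, aggregated into 2-degree histograms over [0, 90] with 0
# degrees pointing along gravity (down the image).
#
# Three window-placement rules:
#   LBA - one window at each lateral's attachment node (first segment,
#         primary path masked out),
#   LRA - non-overlapping windows tiled along each lateral's full path,
#   RTA - one window at each lateral tip (distal segment only).

#' Dominant orientation of a skeleton window
#'
#' The binary patch is low-pass filtered in the frequency domain (the
#' lowest `keep_frac` of the radial frequency range is retained, then the
#' image is re-binarised at half its maximum) to merge 1-px stair
#' stepping, and the dominant straight line is read off a Hough
#' accumulator at 1-degree orientation resolution. The returned angle is
#' measured from the gravity direction (0 = vertical, 90 = horizontal).
#'
#' @param patch Logical matrix (window contents), at most ~100 x 100.
#' @param keep_frac Fraction of the radial frequency range kept.
#' @param min_px Windows with fewer skeleton pixels return `NA`.
#' @return Angle in degrees in `[0, 90]`, or `NA` for an underfilled
#'   window.
#' @export
window_angle <- function(patch, keep_frac = 0.25, min_px = 5) {
  stopifnot(is.matrix(patch))
  storage.mode(patch) <- "logical"
  if (sum(patch) < min_px) return(NA_real_)
  H <- nrow(patch); W <- ncol(patch)
  if (H > 1 && W > 1) {
    F <- stats::fft(patch * 1)
    fr <- pmin(0:(H - 1), H - (0:(H - 1))) / (H / 2)
    fc <- pmin(0:(W - 1), W - (0:(W - 1))) / (W / 2)
    rad <- sqrt(outer(fr^2, fc^2, `+`))
    F[rad > keep_frac] <- 0
    sm <- Re(stats::fft(F, inverse = TRUE)) / (H * W)
    patch <- sm >= max(sm) / 2
    if (sum(patch) < min_px) return(NA_real_)
  }
  px <- which(patch, arr.ind = TRUE)
  theta <- (0:179) * pi / 180
  # rho = col*cos(theta) + row*sin(theta); 1-px rho bins
  rho <- outer(px[, 2], cos(theta)) + outer(px[, 1], sin(theta))
  diag_len <- ceiling(sqrt(H^2 + W^2))
  nr <- 2L * diag_len + 2L
  rho_bin <- round(rho) + diag_len + 1L
  comb <- (rep(0:179, each = nrow(px))) * nr + as.vector(rho_bin)
  acc <- tabulate(comb, nbins = 180L * nr)
  best <- which.max(acc)            # first max: ties go to the lower angle
  th_deg <- (best - 1L) %/% nr
  # line direction = normal + 90; fold into angle from vertical
  ang <- th_deg %% 180
  min(ang, 180 - ang)
}

#' Angle histogram container
#'
#' @param method `"LBA"`, `"LRA"` or `"RTA"`.
#' @param samples Numeric vector of per-window angles in degrees.
#' @param bin_deg Bin width (must divide 90).
#' @return Object of class `"angle_histogram"` with `bins` (counts over
#'   `[0, 90]`), `total_segments`, `modal_angle` (midpoint of the fullest
#'   bin, ties to the smaller angle) and the raw `samples`.
#' @export
angle_histogram <- function(method, samples, bin_deg = 2) {
  stopifnot(90 %% bin_deg == 0)
  samples <- samples[is.finite(samples)]
  nb <- 90 / bin_deg
  bin_of <- pmin(floor(samples / bin_deg) + 1L, nb)
  counts <- tabulate(bin_of, nbins = nb)
  names(counts) <- sprintf("[%g,%g)", (0:(nb - 1)) * bin_deg, (1:nb) * bin_deg)
  modal <- if (length(samples)) (which.max(counts) - 0.5) * bin_deg else NA_real_
  structure(list(method = method, bins = counts,
                 total_segments = length(samples),
                 modal_angle = modal, bin_deg = bin_deg, samples = samples),
            class = "angle_histogram")
}

#' @export
print.angle_histogram <- function(x, ...) {
  cat(sprintf("%s angle histogram: %d segments, modal angle %.1f deg\n",
              x$method, x$total_segments, x$modal_angle))
  invisible(x)
}

# Render a set of skeleton pixels into a square window centred at `centre`
# (clipped to the raster), containing only those pixels.
render_window <- function(pixels, centre, window_px, dim) {
  half <- floor(window_px / 2)
  r0 <- max(1, round(centre[1]) - half); r1 <- min(dim[1], r0 + window_px - 1)
  c0 <- max(1, round(centre[2]) - half); c1 <- min(dim[2], c0 + window_px - 1)
  keep <- pixels[, 1] >= r0 & pixels[, 1] <= r1 &
    pixels[, 2] >= c0 & pixels[, 2] <= c1
  patch <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
  if (any(keep))
    patch[cbind(pixels[keep, 1] - r0 + 1, pixels[keep, 2] - c0 + 1)] <- TRUE
  patch
}

#' Measure lateral root angles
#'
#' Applies [window_angle()] under the placement rule of the chosen
#' method; each window's dominant angle enters the histogram.
#'
#' @param graph Labelled `"skeleton_graph"`.
#' @param method `"LBA"`, `"LRA"` or `"RTA"`.
#' @param window_px Window side in px (default 100).
#' @param bin_deg Histogram bin width in degrees (default 2).
#' @return An [angle_histogram()]; empty (total 0) when there are no
#'   laterals.
#' @export
measure_angles <- function(graph, method = c("LBA", "LRA", "RTA"),
                           window_px = 100, bin_deg = 2) {
  stopifnot(inherits(graph, "skeleton_graph"))
  method <- match.arg(method)
  lats <- graph$laterals %||% list()
  angles <- numeric(0)
  for (L in lats) {
    path_px <- graph$pixels[L$path, , drop = FALSE]
    n <- nrow(path_px)
    if (method == "LBA") {
      seg <- path_px[seq_len(min(n, window_px)), , drop = FALSE]
      a <- window_angle(render_window(seg, seg[1, ], window_px, graph$dim))
      angles <- c(angles, a)
    } else if (method == "RTA") {
      for (tp in L$tip_paths) {
        tpx <- graph$pixels[tp, , drop = FALSE]
        k <- nrow(tpx)
        seg <- tpx[seq(max(1, k - window_px + 1), k), , drop = FALSE]
        a <- window_angle(render_window(seg, seg[nrow(seg), ], window_px,
                                        graph$dim))
        angles <- c(angles, a)
      }
    } else {
      # LRA: consecutive non-overlapping chunks along the full path; a
      # trailing remainder shorter than half a window merges into the
      # previous chunk (slivers give unreliable Hough estimates)
      starts <- seq(1, n, by = window_px)
      ends <- pmin(starts + window_px - 1, n)
      if (length(starts) > 1 && (n - starts[length(starts)] + 1) < window_px / 2) {
        starts <- starts[-length(starts)]
        ends <- ends[-length(ends)]
        ends[length(ends)] <- n
      }
      for (j in seq_along(starts)) {
        s0 <- starts[j]
        seg <- path_px[s0:ends[j], , drop = FALSE]
        ctr <- seg[ceiling(nrow(seg) / 2), ]
        a <- window_angle(render_window(seg, ctr, window_px, graph$dim))
        angles <- c(angles, a)
      }
    }
  }
  angle_histogram(method, angles, bin_deg)
}

#' Compare two angle distributions (directionality test)
#'
#' Two-sample Kolmogorov-Smirnov test on the raw per-window angle
#' samples (the binned histogram is for display only; the KS test assumes
#' continuous data).
#'
#' @param a,b [angle_histogram()] objects with nonzero totals.
#' @return List with the KS statistic `D` and asymptotic `p.value`.
#' @export
compare_angle_distributions <- function(a, b) {
  stopifnot(inherits(a, "angle_histogram"), inherits(b, "angle_histogram"))
  if (!length(a$samples) || !length(b$samples))
    stop("both angle histograms must contain at least one sample")
  kt <- suppressWarnings(stats::ks.test(a$samples, b$samples))
  list(D = unname(kt$statistic), p.value = kt$p.value)
}
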