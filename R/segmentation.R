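# Classical segmentation of root foreground from the blue germination
# paper: heuristic HSV thresholding, k-means colour clustering, threshold
# tuning against a reference mask, and shared morphological cleanup.

#' HSV threshold set for heuristic segmentation
#'
#' Foreground pixels must fall inside all three channel ranges. The hue
#' range may wrap through 0 degrees: with `hue_lo > hue_hi` the accepted
#' hues are `[hue_lo, 360) U [0, hue_hi]`. The defaults select everything
#' that is *not* blue blotter paper (background hue band 190-250 degrees)
#' and bright enough to be root tissue: hue outside the blue band and
#' value >= 0.35.
#'
#' @param hue_lo,hue_hi Hue bounds in degrees `[0, 360)`.
#' @param sat_lo,sat_hi Saturation bounds in `[0, 1]`.
#' @param val_lo,val_hi Value bounds in `[0, 1]`.
#' @return An object of class `"hsv_thresholds"`.
#' @export
hsv_thresholds <- function(hue_lo = 250, hue_hi = 190,
                           sat_lo = 0, sat_hi = 1,
                           val_lo = 0.35, val_hi = 1) {
  stopifnot(hue_lo >= 0, hue_lo < 360, hue_hi >= 0, hue_hi < 360,
            sat_lo >= 0, sat_hi <= 1, sat_lo <= sat_hi,
            val_lo >= 0, val_hi <= 1, val_lo <= val_hi)
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, sat_lo = sat_lo,
                 sat_hi = sat_hi, val_lo = val_lo, val_hi = val_hi),
            class = "hsv_thresholds")
}

image_hsv <- function(image) {
  px <- image$pixels
  d <- dim(px)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                                  as.vector(px[, , 3])), maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

hue_in_range <- function(h, lo, hi) {
  if (lo <= hi) h >= lo & h <= hi else h >= lo | h <= hi
}

# Shared cleanup: remove connected components below min_object_px, then a
# 3x3 morphological closing to bridge 1-px gaps.
clean_mask <- function(m, min_object_px = 100, close = TRUE) {
  if (any(m) && min_object_px > 1) {
    lab <- EBImage::bwlabel(m * 1)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (any(m) && close) {
    kern <- EBImage::makeBrush(3, shape = "box")
    m <- EBImage::closing(m * 1, kern) > 0.5
    m <- matrix(as.logical(m), nrow(m), ncol(m))
  }
  m
}

#' Heuristic HSV segmentation
#'
#' Thresholds the image in HSV space, removes small connected components,
#' and closes 1-px gaps. If nothing survives, the mask is returned empty
#' with a `"no_root"` flag rather than raising an error, so batch runs
#' continue.
#'
#' @param image A [root_image()].
#' @param thresholds An [hsv_thresholds()] object.
#' @param min_object_px Minimum connected-component size kept (px).
#' @return A [root_mask()]; inspect `$flag` and `$fraction_foreground`.
#' @export
segment_hsv <- function(image, thresholds = hsv_thresholds(),
                        min_object_px = 100) {
  stopifnot(inherits(image, "root_image"), inherits(thresholds, "hsv_thresholds"))
  ch <- image_hsv(image)
  m <- hue_in_range(ch$h, thresholds$hue_lo, thresholds$hue_hi) &
    ch$s >= thresholds$sat_lo & ch$s <= thresholds$sat_hi &
    ch$v >= thresholds$val_lo & ch$v <= thresholds$val_hi
  m <- clean_mask(m, min_object_px)
  root_mask(m, image$calibration,
            flag = if (!any(m)) "no_root" else character(0))
}

#' K-means colour segmentation
#'
#' Clusters the pixel colour cloud in HSV space (hue encoded circularly as
#' saturation-weighted cos/sin, plus value) with `stats::kmeans`; the
#' cluster whose centroid hue is farthest (circularly) from the blue
#' background anchor is taken as foreground. Deterministic under a fixed
#' seed. For speed on large rasters the centroids are fitted on a pixel
#' subsample and all pixels are then assigned to the nearest centroid.
#'
#' @param image A [root_image()].
#' @param k Number of colour clusters (>= 2).
#' @param seed Integer seed controlling initialisation.
#' @param background_hue Anchor hue (degrees) of the blue paper; default 220.
#' @param min_object_px Minimum connected-component size kept (px).
#' @param sample_px Pixel subsample size for centroid fitting.
#' @return A [root_mask()].
#' @export
segment_kmeans <- function(image, k = 2, seed = 1, background_hue = 220,
                           min_object_px = 100, sample_px = 20000) {
  stopifnot(inherits(image, "root_image"), k >= 2)
  ch <- image_hsv(image)
  hr <- ch$h * pi / 180
  X <- cbind(as.vector(ch$s * cos(hr)), as.vector(ch$s * sin(hr)), as.vector(ch$v))
  n <- nrow(X)
  if (stats::sd(X[, 1]) + stats::sd(X[, 2]) + stats::sd(X[, 3]) < 1e-6) {
    return(root_mask(matrix(FALSE, nrow(ch$h), ncol(ch$h)),
                     image$calibration, flag = "no_root"))
  }
  set.seed(seed)
  fitX <- if (n > sample_px) X[sample.int(n, sample_px), , drop = FALSE] else X
  km <- tryCatch(stats::kmeans(fitX, centers = k, nstart = 3, iter.max = 100),
                 error = function(e) NULL)
  if (is.null(km)) {
    return(root_mask(matrix(FALSE, nrow(ch$h), ncol(ch$h)),
                     image$calibration, flag = "no_root"))
  }
  # assign every pixel to the nearest fitted centroid
  cent <- km$centers
  d2 <- vapply(seq_len(k), function(j) {
    rowSums((X - matrix(cent[j, ], n, 3, byrow = TRUE))^2)
  }, numeric(n))
  assign <- max.col(-d2, ties.method = "first")
  # label the foreground cluster: centroid hue farthest from the background
  cent_hue <- (atan2(cent[, 2], cent[, 1]) * 180 / pi) %% 360
  dd <- abs(cent_hue - background_hue) %% 360
  circ_dist <- pmin(dd, 360 - dd)
  # nearly grey centroids (tiny chroma) carry no hue information: treat as background
  chroma <- sqrt(cent[, 1]^2 + cent[, 2]^2)
  circ_dist[chroma < 0.05] <- 0
  fg <- which.max(circ_dist)
  m <- matrix(assign == fg, nrow(ch$h), ncol(ch$h))
  m <- clean_mask(m, min_object_px)
  root_mask(m, image$calibration,
            flag = if (!any(m)) "no_root" else character(0))
}

#' Tune HSV thresholds against a reference mask
#'
#' Coarse grid search over the background hue band edges and the value
#' floor, followed by a local refinement, maximising IoU against the
#' reference. The returned thresholds always achieve an IoU at least as
#' high as the defaults on the tuning image.
#'
#' @param image A [root_image()].
#' @param ground_truth A [root_mask()] aligned with `image`.
#' @param min_object_px Cleanup parameter used during scoring.
#' @return List with `thresholds` (an [hsv_thresholds()]) and `iou`.
#' @export
tune_thresholds <- function(image, ground_truth, min_object_px = 100) {
  truth <- mask_pixels(ground_truth)
  if (!any(truth)) stop("ground-truth mask has no foreground pixels")
  ch <- image_hsv(image)
  score <- function(th) {
    m <- hue_in_range(ch$h, th$hue_lo, th$hue_hi) &
      ch$s >= th$sat_lo & ch$s <= th$sat_hi &
      ch$v >= th$val_lo & ch$v <= th$val_hi
    m <- clean_mask(m, min_object_px)
    mask_iou(m, truth)
  }
  best <- hsv_thresholds()
  best_iou <- score(best)
  for (bg_lo in seq(170, 210, by = 10)) {
    for (bg_hi in seq(230, 270, by = 10)) {
      for (v_lo in seq(0.15, 0.6, by = 0.05)) {
        th <- hsv_thresholds(hue_lo = bg_hi %% 360, hue_hi = bg_lo,
                             val_lo = v_lo)
        s <- score(th)
        if (s > best_iou) { best_iou <- s; best <- th }
      }
    }
  }
  list(thresholds = best, iou = best_iou)
}

#' Pixel-overlap metrics between a predicted and a reference mask
#'
#' @param pred,truth [root_mask()] objects or logical matrices of equal
#'   shape.
#' @return Named list with `F1` (2TP/(2TP+FP+FN)) and `IoU`
#'   (TP/(TP+FP+FN)). Two empty masks compare as `(1, 1)` with a warning.
#' @export
f1_iou <- function(pred, truth) {
  p <- mask_pixels(pred); t <- mask_pixels(truth)
  stopifnot(identical(dim(p), dim(t)))
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0) {
    warning("both masks are empty; F1 and IoU defined as 1")
    return(list(F1 = 1, IoU = 1))
  }
  list(F1 = 2 * tp / (2 * tp + fp + fn), IoU = tp / (tp + fp + fn))
}
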