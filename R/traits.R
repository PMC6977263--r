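# Geometric trait extraction from mask + labelled skeleton: lengths,
# extents, areas, primary-root solid measures, centre measures and ratios.

# Row of the upper/lower split: top of the root plus one third of its
# depth extent. Used by TRLUpper/TRLLower, TRAUpper/TRALower and LED.
upper_split_row <- function(mask_px) {
  fg <- which(rowSums(mask_px) > 0)
  top <- min(fg); bot <- max(fg)
  top + (bot - top) / 3
}

#' Length, extent and distribution traits
#'
#' `TRL` is the summed skeleton length (primary plus all lateral
#' components), `PRL` the chain-code length of the primary path,
#' `LRL = TRL - PRL`, `MSL` the mean lateral component length. `DEP` and
#' `WID` are the mask's depth/width extents; `WDR = WID/DEP`. The
#' upper/lower split sits at one third of the root's own depth extent:
#' `TRLUpper` is the skeleton length above it, `TRLLower` below, and
#' `LED = TRLUpper/TRLLower`. `LSLP` is the lateral branch count per cm of
#' primary root (computed when `lrb` is supplied).
#'
#' @param graph Labelled `"skeleton_graph"` (primary + laterals set).
#' @param mask The [root_mask()] the skeleton came from.
#' @param cal A [calibration()] object.
#' @param lrb Optional lateral-branch count used for `LSLP`.
#' @param diagonal_correction Passed to the chain-code metric.
#' @return Named list of trait values (cm or ratios); undefined ratios are
#'   `NA`.
#' @export
length_traits <- function(graph, mask, cal = calibration(), lrb = NULL,
                          diagonal_correction = TRUE) {
  stopifnot(inherits(graph, "skeleton_graph"))
  m <- mask_pixels(mask)
  edges <- length_edge_table(graph, diagonal_correction)
  prl_px <- sum(edges$len[edges$kind == "primary"])
  lrl_px <- sum(edges$len[edges$kind == "lateral"])
  trl_px <- prl_px + lrl_px
  n_lat <- length(graph$laterals %||% list())
  fg <- which(m, arr.ind = TRUE)
  dep_px <- diff(range(fg[, 1]))
  wid_px <- diff(range(fg[, 2]))
  split_row <- upper_split_row(m)
  mid_r <- (edges$r1 + edges$r2) / 2
  upper_px <- sum(edges$len[mid_r < split_row])
  lower_px <- trl_px - upper_px
  list(
    TRL = px_to_cm(trl_px, cal),
    PRL = px_to_cm(prl_px, cal),
    LRL = px_to_cm(lrl_px, cal),
    MSL = if (n_lat > 0) px_to_cm(lrl_px / n_lat, cal) else NA_real_,
    TRLUpper = px_to_cm(upper_px, cal),
    TRLLower = px_to_cm(lower_px, cal),
    LED = if (lower_px > 0) upper_px / lower_px else NA_real_,
    DEP = px_to_cm(dep_px, cal),
    WID = px_to_cm(wid_px, cal),
    WDR = if (dep_px > 0) wid_px / dep_px else NA_real_,
    LSLP = if (!is.null(lrb) && prl_px > 0) lrb / px_to_cm(prl_px, cal) else NA_real_
  )
}

# Perimeter pixel count: foreground pixels 4-adjacent to background (the
# raster border counts as background).
perimeter_px <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  i <- 2:(H + 1); j <- 2:(W + 1)
  sum(m & !(p[i - 1, j] & p[i + 1, j] & p[i, j - 1] & p[i, j + 1]))
}

# Convex hull of foreground pixel centres; NULL when degenerate.
hull_of_mask <- function(m) {
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) < 3) return(NULL)
  h <- grDevices::chull(fg[, 2], fg[, 1])   # (x = col, y = row)
  if (length(h) < 3) return(NULL)
  fg[h, c(2, 1), drop = FALSE]              # columns: x = col, y = row
}

#' Area traits
#'
#' `TRArea` is the projected root area (foreground pixel count), split at
#' the depth third into `TRAUpper`/`TRALower`; `PER` the perimeter pixel
#' count (foreground pixels touching background 4-adjacently), reported in
#' cm; `NWA` the skeleton pixel count; `CVA` the convex-hull area of the
#' foreground pixel centres; `SOL = TRArea/CVA` (clipped to 1; or skeleton
#' pixels over hull area with `solidity_mode = "skeleton"`); `RHZO` the
#' area of the skeleton dilated by a 2 mm disc.
#'
#' @param mask A [root_mask()].
#' @param graph The skeleton graph of `mask`.
#' @param cal A [calibration()] object.
#' @param rhizo_mm Rhizosphere radius in millimetres.
#' @param solidity_mode `"area"` or `"skeleton"`.
#' @return Named list of trait values; `CVA`/`SOL` are `NA` for collinear
#'   masks.
#' @export
area_traits <- function(mask, graph, cal = calibration(), rhizo_mm = 2,
                        solidity_mode = "area") {
  m <- mask_pixels(mask)
  area_px <- sum(m)
  split_row <- upper_split_row(m)
  rows <- which(m, arr.ind = TRUE)[, 1]
  upper_px <- sum(rows < split_row)
  per_px <- perimeter_px(m)
  nwa <- nrow(graph$pixels)
  hull <- hull_of_mask(m)
  cva_px <- if (is.null(hull)) NA_real_ else poly_area(hull)
  sol <- if (is.na(cva_px) || cva_px <= 0) NA_real_
  else if (solidity_mode == "skeleton") nwa / cva_px
  else min(1, area_px / cva_px)
  skel <- matrix(FALSE, graph$dim[1], graph$dim[2])
  skel[graph$pixels] <- TRUE
  r_px <- rhizo_mm / 10 * cal$pixels_per_cm
  brush <- EBImage::makeBrush(2 * floor(r_px) + 1, shape = "disc")
  rhzo_px <- sum(EBImage::dilate(skel * 1, brush) > 0.5)
  list(
    TRArea = px_to_cm(area_px, cal, 2),
    TRAUpper = px_to_cm(upper_px, cal, 2),
    TRALower = px_to_cm(area_px - upper_px, cal, 2),
    PER = px_to_cm(per_px, cal),
    NWA = as.numeric(nwa),
    CVA = px_to_cm(cva_px, cal, 2),
    SOL = sol,
    RHZO = px_to_cm(rhzo_px, cal, 2)
  )
}

#' Primary-root diameter, surface area and volume
#'
#' The local half-width along the primary path is read from the Euclidean
#' distance transform of the mask; the primary root is then modelled as
#' stacked frusta: `DIA = 2 * mean(r)`, `PRA = sum(2 pi r ds)`,
#' `VOL = sum(pi r^2 ds)` with `ds` the local chain step length.
#'
#' @param mask A [root_mask()].
#' @param graph Skeleton graph with `$primary_path` set.
#' @param cal A [calibration()] object.
#' @return Named list with `DIA` (cm), `PRA` (cm^2), `VOL` (cm^3) and the
#'   per-pixel `radius_px` profile; all `NA` (with empty profile) when the
#'   primary path is shorter than 3 px.
#' @export
primary_solid_traits <- function(mask, graph, cal = calibration()) {
  stopifnot(inherits(graph, "skeleton_graph"))
  if (is.null(graph$primary_path) || length(graph$primary_path) < 3)
    return(list(DIA = NA_real_, PRA = NA_real_, VOL = NA_real_,
                radius_px = numeric(0)))
  m <- mask_pixels(mask)
  dt <- EBImage::distmap(m * 1, metric = "euclidean")
  pp <- graph$pixels[graph$primary_path, , drop = FALSE]
  r <- pmax(dt[pp], 0.5)
  step <- sqrt(rowSums(diff(pp)^2))
  ds <- (c(step, 0) + c(0, step)) / 2     # trapezoid weights along the path
  list(
    DIA = px_to_cm(2 * mean(r), cal),
    PRA = px_to_cm(sum(2 * pi * r * ds), cal, 2),
    VOL = px_to_cm(sum(pi * r^2 * ds), cal, 3),
    radius_px = as.numeric(r)
  )
}

#' Centre-of-mass and centre-of-point traits
#'
#' Depth origin at the topmost foreground row, normalised by the depth
#' extent: `COM` is the mean foreground-pixel depth, `COP` the median
#' occupied row. The thirds variants (`CMT`/`CMM`/`CMB`, `CPT`/`CPM`/
#' `CPB`) apply the same measures within the top/middle/bottom thirds of
#' the occupied depth range, still normalised by the full extent.
#'
#' @param mask A [root_mask()].
#' @return Named list of 8 dimensionless traits; all `NA` when the depth
#'   extent is zero.
#' @export
center_traits <- function(mask) {
  m <- mask_pixels(mask)
  fg <- which(m, arr.ind = TRUE)
  rows <- fg[, 1]
  top <- min(rows); bot <- max(rows)
  dep <- bot - top
  if (dep == 0)
    return(as.list(setNames(rep(NA_real_, 8),
                            c("COM", "COP", "CMT", "CMM", "CMB",
                              "CPT", "CPM", "CPB"))))
  occ <- sort(unique(rows))
  b1 <- top + dep / 3; b2 <- top + 2 * dep / 3
  com_of <- function(r) if (length(r)) (mean(r) - top) / dep else NA_real_
  cop_of <- function(r) {
    u <- sort(unique(r))
    if (length(u)) (median(u) - top) / dep else NA_real_
  }
  list(
    COM = com_of(rows),
    COP = cop_of(rows),
    CMT = com_of(rows[rows < b1]),
    CMM = com_of(rows[rows >= b1 & rows < b2]),
    CMB = com_of(rows[rows >= b2]),
    CPT = cop_of(rows[rows < b1]),
    CPM = cop_of(rows[rows >= b1 & rows < b2]),
    CPB = cop_of(rows[rows >= b2])
  )
}
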