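# Core domain types: calibration, configuration, image/mask containers,
# and the trait-record registry shared by every downstream module.

#' Spatial calibration of a root image
#'
#' @param pixels_per_cm Positive number of pixels per centimetre. The
#'   default of 100 px/cm corresponds to a camera fixed at a height that
#'   resolves the imaging stage at high quality.
#' @return An object of class `"calibration"`.
#' @export
#' @examples
#' cal <- calibration(100)
#' px_to_cm(300, cal)        # 3 cm
calibration <- function(pixels_per_cm = 100) {
  stopifnot(is_scalar_num(pixels_per_cm), pixels_per_cm > 0)
  structure(list(pixels_per_cm = pixels_per_cm), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("calibration:", x$pixels_per_cm, "px/cm\n")
  invisible(x)
}

#' Convert a pixel measure to centimetre units
#'
#' Lengths use `power = 1`, areas `power = 2`, volumes `power = 3`.
#'
#' @param pixels Numeric vector of pixel measures (px, px^2, or px^3).
#' @param cal A [calibration()] object.
#' @param power Integer in 1:3, the dimensional power of the measure.
#' @return `pixels / pixels_per_cm^power`.
#' @export
px_to_cm <- function(pixels, cal, power = 1) {
  stopifnot(inherits(cal, "calibration"), power %in% 1:3)
  pixels / cal$pixels_per_cm^power
}

#' Pipeline configuration
#'
#' Bundles every tunable numeric of the extraction pipeline. Defaults
#' follow the standard operating point: 100 px/cm calibration, a
#' 100 x 100 px angle-measurement window with 2-degree histogram bins,
#' a 10 px spur-removal radius, a 2 mm rhizosphere radius, a 5 px
#' sliding-band height for lateral branch counting, and 5 display
#' harmonics for shape spectra.
#'
#' @param calibration A [calibration()] object.
#' @param thresholds An [hsv_thresholds()] object for heuristic segmentation.
#' @param min_object_px Connected components smaller than this many pixels
#'   are removed from segmentation masks.
#' @param angle_window_px Side of the square window used for angle
#'   estimation (px).
#' @param angle_bin_deg Histogram bin width in degrees; must divide 90.
#' @param spur_px Skeleton branches shorter than this (px) are pruned as
#'   thinning artifacts.
#' @param rhizo_mm Radius in millimetres of the rhizosphere band dilated
#'   around the skeleton.
#' @param band_px Height (px) of the sliding band used by the lateral
#'   branch counter.
#' @param harmonics Number of Fourier harmonics stored for shape spectra
#'   (1..100).
#' @param solidity_mode `"area"` (root area / convex area, the default) or
#'   `"skeleton"` (skeleton pixels / convex area).
#' @param diagonal_correction If `TRUE` (default) diagonal skeleton steps
#'   count sqrt(2) px; if `FALSE` every step counts 1 px.
#' @param turn_penalty Curvature penalty (px per radian) used when routing
#'   the primary-root path through the skeleton graph.
#' @param seed Integer seed for any stochastic step (k-means, CAE).
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(calibration = rootarch::calibration(),
                            thresholds = hsv_thresholds(),
                            min_object_px = 100,
                            angle_window_px = 100,
                            angle_bin_deg = 2,
                            spur_px = 10,
                            rhizo_mm = 2,
                            band_px = 5,
                            harmonics = 5,
                            solidity_mode = c("area", "skeleton"),
                            diagonal_correction = TRUE,
                            turn_penalty = 2,
                            seed = 1L) {
  stopifnot(
    inherits(calibration, "calibration"),
    min_object_px >= 0, angle_window_px > 0, angle_bin_deg > 0,
    90 %% angle_bin_deg == 0,
    spur_px > 0, rhizo_mm > 0, band_px > 0,
    harmonics >= 1, harmonics <= 100
  )
  structure(list(
    calibration = calibration, thresholds = thresholds,
    min_object_px = as.integer(min_object_px),
    angle_window_px = as.integer(angle_window_px),
    angle_bin_deg = angle_bin_deg,
    spur_px = as.integer(spur_px), rhizo_mm = rhizo_mm,
    band_px = as.integer(band_px), harmonics = as.integer(harmonics),
    solidity_mode = match.arg(solidity_mode),
    diagonal_correction = isTRUE(diagonal_correction),
    turn_penalty = turn_penalty,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  flat <- unlist(config[order(names(config))])
  str_hash(paste(names(flat), format(flat, digits = 12), sep = "=", collapse = ";"))
}

#' Construct a root image object
#'
#' @param pixels `H x W x 3` numeric array in `[0, 1]`, R/G/B order.
#' @param calibration A [calibration()] object.
#' @param plant_id Plant identifier.
#' @param day Integer imaging day (days after germination).
#' @return An object of class `"root_image"`.
#' @export
root_image <- function(pixels, calibration = rootarch::calibration(),
                       plant_id = NA_character_, day = NA_integer_) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 1, dim(pixels)[2] >= 1)
  structure(list(pixels = pixels, calibration = calibration,
                 plant_id = as.character(plant_id), day = as.integer(day)),
            class = "root_image")
}

#' @export
print.root_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("root_image %s (day %s): %d x %d px at %g px/cm\n",
              x$plant_id, x$day, d[1], d[2], x$calibration$pixels_per_cm))
  invisible(x)
}

#' Construct a binary root mask
#'
#' @param pixels `H x W` logical matrix, `TRUE` = root foreground.
#' @param calibration A [calibration()] object.
#' @param flag Character vector of quality flags (e.g. `"no_root"`).
#' @return An object of class `"root_mask"`.
#' @export
root_mask <- function(pixels, calibration = rootarch::calibration(),
                      flag = character(0)) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "logical"
  structure(list(pixels = pixels, calibration = calibration, flag = flag,
                 fraction_foreground = mean(pixels)),
            class = "root_mask")
}

# Accept either a root_mask or a bare logical matrix.
mask_pixels <- function(m) {
  if (inherits(m, "root_mask")) m$pixels else {
    stopifnot(is.matrix(m)); m1 <- m; storage.mode(m1) <- "logical"; m1
  }
}

mask_cal <- function(m, default = calibration()) {
  if (inherits(m, "root_mask")) m$calibration else default
}

#' @export
print.root_mask <- function(x, ...) {
  cat(sprintf("root_mask %d x %d px, %.2f%% foreground%s\n",
              nrow(x$pixels), ncol(x$pixels), 100 * x$fraction_foreground,
              if (length(x$flag)) paste0(" [", paste(x$flag, collapse = ","), "]") else ""))
  invisible(x)
}

#' @export
plot.root_mask <- function(x, ...) {
  img <- t(x$pixels[nrow(x$pixels):1, , drop = FALSE])
  graphics::image(img, col = c("grey15", "white"), axes = FALSE, asp = ncol(x$pixels) / nrow(x$pixels), ...)
  invisible(x)
}

# ---- trait registry --------------------------------------------------------

# One row per trait symbol in the catalogue, with its unit.
# "RTA" appears twice in the source catalogue (a tip count and a tip angle);
# they are split here into RTA_count and RTA_angle.
trait_registry <- function() {
  data.frame(
    symbol = c("TRL", "PRL", "LRL", "MSL", "TRLUpper", "TRLLower", "PER",
               "DEP", "WID", "DIA", "LRB", "NLR", "IRB", "RTA_count",
               "MED", "RMAX", "MNR", "NWA", "CVA", "RHZO", "TRArea",
               "PRA", "TRAUpper", "TRALower", "VOL", "LBA", "LRA",
               "RTA_angle", "WDR", "SOL", "BSH", "LED", "LSLP",
               "COM", "COP", "CMT", "CMM", "CMB", "CPT", "CPM", "CPB"),
    unit = c("cm", "cm", "cm", "cm", "cm", "cm", "cm",
             "cm", "cm", "cm", "count", "count", "count", "count",
             "count", "count", "count", "count", "cm2", "cm2", "cm2",
             "cm2", "cm2", "cm2", "cm3", "deg", "deg",
             "deg", "ratio", "ratio", "ratio", "ratio", "ratio",
             "ratio", "ratio", "ratio", "ratio", "ratio", "ratio", "ratio", "ratio"),
    stringsAsFactors = FALSE
  )
}

#' Trait symbols and units
#'
#' The full catalogue of root-system-architecture trait symbols emitted by
#' [extract_traits()], in stable column order, with the unit of each.
#'
#' @return A data frame with columns `symbol` and `unit`.
#' @export
trait_catalogue <- function() trait_registry()

#' Assemble a trait record
#'
#' @param plant_id,day Identity of the plant/time point.
#' @param values Named list or vector of trait values; names must be
#'   symbols from [trait_catalogue()]. Missing traits become `NA`.
#' @param qc_flag Logical quality flag for the record.
#' @return One-row data frame with columns `plant_id`, `day`, `qc_flag`,
#'   then every trait symbol in catalogue order.
#' @export
trait_record <- function(plant_id, day, values = list(), qc_flag = FALSE) {
  reg <- trait_registry()
  out <- as.list(rep(NA_real_, nrow(reg)))
  names(out) <- reg$symbol
  vals <- as.list(values)
  bad <- setdiff(names(vals), reg$symbol)
  if (length(bad)) stop("unknown trait symbols: ", paste(bad, collapse = ", "))
  for (nm in names(vals)) {
    v <- vals[[nm]]
    out[[nm]] <- if (is.null(v) || length(v) != 1 || !is.finite(v)) NA_real_ else as.numeric(v)
  }
  cbind(data.frame(plant_id = as.character(plant_id), day = as.integer(day),
                   qc_flag = isTRUE(qc_flag), stringsAsFactors = FALSE),
        as.data.frame(out))
}
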