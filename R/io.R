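# Raster and table I/O: reading root images (PNG/JPEG/TIFF), writing
# binary masks, and the trait-table CSV writer/reader.

decode_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    tif  = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  px
}

#' Read a root image from disk
#'
#' Decodes an 8-bit PNG/JPEG/TIFF raster and attaches plant identity.
#' Metadata come from `manifest_entry` when given; otherwise the filename
#' must follow the pattern `<plantid>_<day>.<ext>` (e.g. `A001_6.png`).
#'
#' @param path Path to the image file.
#' @param calibration A [calibration()] object (overridden by a
#'   `pixels_per_cm` column in the manifest entry).
#' @param manifest_entry Optional one-row data frame / named list with
#'   fields `plant_id`, `day` and optionally `pixels_per_cm`.
#' @return A [root_image()].
#' @export
read_root_image <- function(path, calibration = rootarch::calibration(),
                            manifest_entry = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  px <- tryCatch(decode_raster(path),
                 error = function(e) stop("failed to decode '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  plant_id <- NULL; day <- NULL
  if (!is.null(manifest_entry)) {
    me <- as.list(manifest_entry)
    plant_id <- me$plant_id
    day <- me$day
    if (!is.null(me$pixels_per_cm) && is.finite(as.numeric(me$pixels_per_cm)))
      calibration <- rootarch::calibration(as.numeric(me$pixels_per_cm))
  }
  if (is.null(plant_id) || is.null(day)) {
    base <- tools::file_path_sans_ext(basename(path))
    m <- regmatches(base, regexec("^(.*)_([0-9]+)$", base))[[1]]
    if (length(m) != 3)
      stop("cannot parse plant metadata from filename '", basename(path),
           "'; expected <plantid>_<day>.<ext> or a manifest entry")
    if (is.null(plant_id)) plant_id <- m[2]
    if (is.null(day)) day <- as.integer(m[3])
  }
  root_image(px, calibration, plant_id = plant_id, day = as.integer(day))
}

#' Read a batch manifest
#'
#' @param path CSV with columns `plant_id`, `day`, `path` and optional
#'   `pixels_per_cm`, `block`.
#' @return Data frame, one row per image.
#' @export
read_manifest <- function(path) {
  mf <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "day", "path")
  miss <- setdiff(need, names(mf))
  if (length(miss)) stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  mf
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask A [root_mask()] or logical matrix.
#' @param path Output path (`.png`).
#' @export
write_mask <- function(mask, path) {
  m <- mask_pixels(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#'
#' @param path PNG path; any pixel above 0.5 is foreground.
#' @param calibration A [calibration()] object.
#' @return A [root_mask()].
#' @export
read_mask <- function(path, calibration = rootarch::calibration()) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  root_mask(px > 0.5, calibration)
}

#' Write a trait table to CSV
#'
#' One header row with the trait symbols, one row per record. Missing
#' values are written as empty cells. A sidecar text file
#' `<path>.units.txt` documents the unit of every column.
#'
#' @param records Data frame of trait records ([trait_record()] rows).
#' @param path Output CSV path.
#' @export
write_trait_table <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  reg <- trait_registry()
  need <- c("plant_id", "day", "qc_flag", reg$symbol)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records are missing columns: ", paste(miss, collapse = ", "))
  write.csv(records[, need], path, row.names = FALSE, na = "")
  units <- c("plant_id: identifier", "day: days after germination",
             "qc_flag: TRUE if any quality flag was raised",
             paste0(reg$symbol, ": ", reg$unit))
  writeLines(units, paste0(path, ".units.txt"))
  invisible(path)
}

#' Read a trait table written by [write_trait_table()]
#'
#' @param path CSV path.
#' @return Data frame with empty cells restored as `NA`.
#' @export
read_trait_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$plant_id <- as.character(df$plant_id)
  df
}
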