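# Batch orchestration: per-image segment -> skeletonize -> extract ->
# aggregate, driven by a CSV manifest, with per-image quality flags,
# failure isolation and resumability; plus the statistics stage runner.

#' Extract the full trait record from a mask
#'
#' Runs the skeleton pipeline (thinning, primary-root detection, spur
#' pruning, lateral labelling) and every trait family, returning one
#' trait-record row.
#'
#' @param mask A [root_mask()].
#' @param config A [pipeline_config()].
#' @param plant_id,day Identity stamped on the record.
#' @return One-row data frame (see [trait_record()]); `qc_flag` is set
#'   when any stage raised a flag.
#' @export
extract_traits <- function(mask, config = pipeline_config(),
                           plant_id = NA_character_, day = NA_integer_) {
  stopifnot(inherits(config, "pipeline_config"))
  cal <- mask_cal(mask, config$calibration)
  g <- skeletonize(mask)
  g <- detect_primary_root(g, turn_penalty = config$turn_penalty)
  g <- prune_spurs(g, radius_px = config$spur_px)
  g <- label_laterals(g)

  lrb <- count_lrb(g, band_px = config$band_px)
  lens <- length_traits(g, mask, cal, lrb = lrb,
                        diagonal_correction = config$diagonal_correction)
  areas <- area_traits(mask, g, cal, rhizo_mm = config$rhizo_mm,
                       solidity_mode = config$solidity_mode)
  solids <- primary_solid_traits(mask, g, cal)
  centers <- center_traits(mask)
  rowp <- row_profile_traits(g)
  angs <- lapply(c(LBA = "LBA", LRA = "LRA", RTA = "RTA"), function(m)
    measure_angles(g, m, window_px = config$angle_window_px,
                   bin_deg = config$angle_bin_deg))

  vals <- c(
    lens[c("TRL", "PRL", "LRL", "MSL", "TRLUpper", "TRLLower", "LED",
           "DEP", "WID", "WDR", "LSLP")],
    areas[c("TRArea", "TRAUpper", "TRALower", "PER", "NWA", "CVA", "SOL",
            "RHZO")],
    solids[c("DIA", "PRA", "VOL")],
    centers,
    rowp[c("MED", "RMAX", "MNR", "BSH")],
    list(LRB = lrb, NLR = count_nlr(g), IRB = count_irb(g),
         RTA_count = count_tips(g),
         LBA = angs$LBA$modal_angle, LRA = angs$LRA$modal_angle,
         RTA_angle = angs$RTA$modal_angle)
  )
  rec <- trait_record(plant_id, day, vals,
                      qc_flag = length(g$flag) > 0 ||
                        length(mask$flag %||% character(0)) > 0)
  attr(rec, "skeleton") <- g
  attr(rec, "angle_histograms") <- angs
  rec
}

#' Segment an image by the configured method
#'
#' @param image A [root_image()].
#' @param method `"hsv"`, `"kmeans"` or `"cae"`.
#' @param config A [pipeline_config()].
#' @param cae_model A trained `"cae_model"` (required for
#'   `method = "cae"`).
#' @return A [root_mask()].
#' @export
segment_image <- function(image, method = c("hsv", "kmeans", "cae"),
                          config = pipeline_config(), cae_model = NULL) {
  method <- match.arg(method)
  switch(method,
    hsv = segment_hsv(image, config$thresholds, config$min_object_px),
    kmeans = segment_kmeans(image, k = 3, seed = config$seed,
                            min_object_px = config$min_object_px),
    cae = {
      if (is.null(cae_model)) stop("method 'cae' needs a trained cae_model")
      segment_cae(cae_model, image, min_object_px = config$min_object_px)
    })
}

#' Run a manifest-driven batch
#'
#' Processes every manifest row independently: read image, segment,
#' extract traits. A failing row is flagged and the batch continues.
#' Per-image results are cached as CSV rows under `out_dir/records/`, so
#' an interrupted batch resumes where it stopped; finished rows are not
#' recomputed unless `force = TRUE`. The configuration fingerprint is
#' stored in the output directory, and a re-run under a different
#' configuration refuses to mix results unless forced.
#'
#' @param manifest Path to a manifest CSV (see [read_manifest()]) or a
#'   manifest data frame.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param method Segmentation method (see [segment_image()]).
#' @param cae_model Optional trained CAE for `method = "cae"`.
#' @param force Recompute rows whose outputs already exist.
#' @return Invisibly, a list with `traits` (data frame, also written to
#'   `out_dir/traits.csv`) and `report` (per-image status data frame,
#'   written to `out_dir/report.csv`).
#' @export
run_batch <- function(manifest, config = pipeline_config(),
                      out_dir = "batch_out", method = "hsv",
                      cae_model = NULL, force = FALSE) {
  mf <- if (is.character(manifest)) read_manifest(manifest) else manifest
  dir.create(file.path(out_dir, "records"), recursive = TRUE,
             showWarnings = FALSE)
  hash <- config_hash(config)
  hash_file <- file.path(out_dir, "config.hash")
  if (file.exists(hash_file) && !force) {
    old <- readLines(hash_file, warn = FALSE)[1]
    if (!identical(old, hash))
      stop("output directory was produced under a different configuration (",
           old, " vs ", hash, "); use force = TRUE to overwrite")
  }
  writeLines(hash, hash_file)
  status <- character(nrow(mf))
  rows <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    rec_file <- file.path(out_dir, "records",
                          paste0(mf$plant_id[i], "_", mf$day[i], ".csv"))
    if (file.exists(rec_file) && !force) {
      rows[[i]] <- read_trait_table(rec_file)
      status[i] <- "cached"
      next
    }
    res <- tryCatch({
      cal <- if (!is.null(mf$pixels_per_cm) && is.finite(mf$pixels_per_cm[i]))
        calibration(mf$pixels_per_cm[i]) else config$calibration
      img <- read_root_image(mf$path[i], cal, manifest_entry = mf[i, ])
      msk <- segment_image(img, method, config, cae_model)
      if (!any(msk$pixels)) {
        list(rec = trait_record(mf$plant_id[i], mf$day[i], qc_flag = TRUE),
             status = "no_root")
      } else {
        rec <- extract_traits(msk, config, mf$plant_id[i], mf$day[i])
        attr(rec, "skeleton") <- NULL
        attr(rec, "angle_histograms") <- NULL
        list(rec = rec, status = if (rec$qc_flag) "trait_flag" else "ok")
      }
    }, error = function(e) {
      list(rec = trait_record(mf$plant_id[i], mf$day[i], qc_flag = TRUE),
           status = paste0("error: ", conditionMessage(e)))
    })
    rows[[i]] <- res$rec
    status[i] <- res$status
    if (!startsWith(res$status, "error"))
      write_trait_table(res$rec, rec_file)
  }
  traits <- do.call(rbind, rows)
  report <- data.frame(plant_id = mf$plant_id, day = mf$day,
                       status = status, config_hash = hash,
                       stringsAsFactors = FALSE)
  write_trait_table(traits, file.path(out_dir, "traits.csv"))
  write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  invisible(list(traits = traits, report = report))
}

#' Run the statistics stage on a trait table
#'
#' Joins the trait table with the experimental design, applies the IQR
#' outlier filter per genotype and trait, fits the random-effects model,
#' and derives heritability, CV_G, BLUPs, Tukey HSD groupings and the
#' BLUP trait-correlation matrix.
#'
#' @param traits Trait table (data frame or CSV path from [run_batch()]).
#' @param design Design table (data frame or CSV path) with columns
#'   `plant_id`, `genotype` and optionally `block`, `rep`.
#' @param trait_names Traits to analyse (default: a core set).
#' @param k IQR fence multiplier.
#' @param alpha Tukey HSD significance level.
#' @return List with `variance_components`, `heritability`, `blups`
#'   (genotype x trait matrix), `hsd` (per trait; `NULL` where it could
#'   not be computed), `correlations`, and `n_reps`.
#' @export
run_stats <- function(traits, design,
                      trait_names = c("TRL", "PRL", "LRL", "DEP", "WID",
                                      "TRArea", "LRB"),
                      k = 1.5, alpha = 0.05) {
  tt <- if (is.character(traits)) read_trait_table(traits) else traits
  dd <- if (is.character(design)) read.csv(design, stringsAsFactors = FALSE) else design
  if (!all(c("plant_id", "genotype") %in% names(dd)))
    stop("design table needs plant_id and genotype columns")
  dup <- dd$plant_id[duplicated(dd$plant_id)]
  if (length(dup)) stop("duplicate plant_id in design: ",
                        paste(unique(dup), collapse = ", "))
  merged <- merge(tt, dd, by = "plant_id")
  if (!nrow(merged)) stop("no plant_id overlap between traits and design")
  trait_names <- intersect(trait_names, names(merged))
  n_reps <- stats::median(table(merged$genotype))
  vc_tab <- NULL; h2 <- c(); cvg <- c(); blup_mat <- NULL; hsd_list <- list()
  for (tr in trait_names) {
    obs <- data.frame(genotype = merged$genotype, value = merged[[tr]],
                      trait = tr)
    if ("block" %in% names(merged)) obs$block <- merged$block
    obs <- obs[is.finite(obs$value), , drop = FALSE]
    if (nrow(obs) < 4 || length(unique(obs$genotype)) < 2) next
    filt <- iqr_filter(obs, k = k)
    mdl <- fit_random_model(filt$kept)
    vc_tab <- rbind(vc_tab, data.frame(
      trait = tr, sigma2_g = mdl$sigma2_g, sigma2_b = mdl$sigma2_b,
      sigma2_e = mdl$sigma2_e, mean = mdl$grand_mean,
      n_removed = nrow(filt$removed)))
    h2[tr] <- heritability(mdl, n_reps)
    cvg[tr] <- cv_g(mdl, mdl$grand_mean)
    b <- coef(mdl)
    if (is.null(blup_mat)) {
      blup_mat <- matrix(NA_real_, length(unique(dd$genotype)),
                         length(trait_names),
                         dimnames = list(sort(unique(dd$genotype)),
                                         trait_names))
    }
    blup_mat[names(b), tr] <- b
    hsd_list[[tr]] <- tryCatch(tukey_hsd(filt$kept, alpha = alpha),
                               error = function(e) NULL)
  }
  if (is.null(vc_tab)) stop("no analysable trait columns found")
  keep_cols <- colSums(!is.na(blup_mat)) > 0
  corr <- if (sum(keep_cols) >= 2 && nrow(blup_mat) >= 3)
    trait_correlations(blup_mat[, keep_cols, drop = FALSE]) else NULL
  list(variance_components = vc_tab,
       heritability = h2, cv_g = cvg, blups = blup_mat,
       hsd = hsd_list, correlations = corr, n_reps = n_reps)
}
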