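#' Pipeline configuration
#'
#' Collects every geometry, detection and statistics parameter of the
#' analysis pipeline. The defaults reproduce the analysis constants: a
#' 3-pixel plasma-membrane band, five 1-um intracellular layers, and a 1-um
#' small/large split on spot equivalent diameter.
#'
#' @param pixel_size_um pixel size, micrometres per pixel.
#' @param pm_thickness_px plasma-membrane band thickness in pixels.
#' @param layer_width_um intracellular layer width in micrometres.
#' @param n_layers number of intracellular layers.
#' @param size_threshold_um small/large split on equivalent diameter.
#' @param min_spot_area_px minimum spot area in pixels.
#' @param pcc_region `"fibre"` or `"pm"`; region for colocalization.
#' @param measure_from layer origin, `"pm_inner_edge"` or `"midline"`.
#' @param snake list of [segment_membrane()] parameters to override.
#' @param mhc1_fallback_cut fallback MHC1 positivity cut.
#' @param min_fibre_area_px minimum enclosed area for a valid fibre.
#' @param seed integer seed recorded with every run.
#' @return a validated `glut4_config` list.
#' @export
pipeline_config <- function(pixel_size_um = 0.2, pm_thickness_px = 3,
                            layer_width_um = 1, n_layers = 5L,
                            size_threshold_um = 1, min_spot_area_px = 2,
                            pcc_region = c("fibre", "pm"),
                            measure_from = c("pm_inner_edge", "midline"),
                            snake = list(), mhc1_fallback_cut = 400,
                            min_fibre_area_px = 400, seed = 1L) {
  for (nm in c("pixel_size_um", "pm_thickness_px", "layer_width_um",
               "size_threshold_um", "min_spot_area_px", "min_fibre_area_px"))
    assert_scalar_pos(get(nm), nm)
  structure(
    list(pixel_size_um = pixel_size_um, pm_thickness_px = pm_thickness_px,
         layer_width_um = layer_width_um, n_layers = as.integer(n_layers),
         size_threshold_um = size_threshold_um,
         min_spot_area_px = min_spot_area_px,
         pcc_region = match.arg(pcc_region),
         measure_from = match.arg(measure_from),
         snake = snake, mhc1_fallback_cut = mhc1_fallback_cut,
         min_fibre_area_px = min_fibre_area_px, seed = as.integer(seed)),
    class = "glut4_config"
  )
}

#' Run the full image-analysis pipeline on a set of fibre images
#'
#' For every image referenced by the design table: segments the membrane
#' midline from the dystrophin channel, builds the distance map and layer
#' masks, then (after pooling each participant's in-fibre GLUT4 pixels for
#' the participant-level Otsu threshold) detects and classifies spots,
#' measures per-layer intensities, computes GLUT4-dystrophin colocalization
#' and classifies the fibre type from the cohort's MHC1 levels.
#' Segmentation failures are excluded from the measurement table and
#' tallied per image in the status table; the run continues past them.
#'
#' @param images named list of `fibre_image` objects (names = image ids),
#'   e.g. from [simulate_study()] or [read_study_images()].
#' @param design design tibble with `image_id`, `subject_id`, `group`,
#'   `infusion`, `timepoint_h`.
#' @param config a [pipeline_config()].
#' @return A `glut4_run`: list with `measurements` (one row per analysed
#'   fibre), `spots`, `thresholds` (per participant), `status` (per image:
#'   ok / segmentation-failed with the message), and the `config`.
#' @export
run_pipeline <- function(images, design, config = pipeline_config()) {
  stopifnot(inherits(config, "glut4_config"))
  if (length(images) == 0L)
    rlang::abort("no images supplied", class = "glut4_pipeline_error")
  missing_imgs <- setdiff(design$image_id, names(images))
  if (length(missing_imgs) > 0L)
    rlang::abort(sprintf("design references missing images: %s",
                         paste(head(missing_imgs, 5), collapse = ", ")),
                 class = "glut4_pipeline_error")
  design <- dplyr::filter(design, .data$image_id %in% names(images))

  snake_args <- utils::modifyList(
    list(min_area_px = config$min_fibre_area_px), config$snake)

  # pass 1: segment every image, build masks, collect pooled fibre pixels
  seg <- vector("list", nrow(design))
  status <- character(nrow(design))
  message_log <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    id <- design$image_id[i]
    img <- images[[id]]
    res <- tryCatch({
      for (ch in c("dystrophin", "glut4", "mhc1"))
        if (is.null(img[[ch]]))
          rlang::abort(sprintf("image %s lacks channel `%s`", id, ch),
                       class = "glut4_pipeline_error")
      contour <- do.call(segment_membrane, c(
        list(dystrophin = img$dystrophin, image_id = id), snake_args))
      dmap <- signed_distance_map(contour, dim(img$dystrophin))
      layers <- build_layer_masks(
        dmap, config$pixel_size_um, config$pm_thickness_px,
        config$layer_width_um, config$n_layers, config$measure_from)
      list(contour = contour, dmap = dmap, layers = layers)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- if (inherits(res, "glut4_segmentation_failure"))
        "segmentation-failed" else "error"
      message_log[i] <- conditionMessage(res)
      seg[i] <- list(NULL)
    } else {
      status[i] <- "ok"
      message_log[i] <- ""
      seg[[i]] <- res
    }
  }
  ok <- status == "ok"
  status_tab <- tibble::tibble(image_id = design$image_id, status = status,
                               message = message_log)
  if (!any(ok))
    rlang::abort("no image segmented successfully",
                 class = "glut4_pipeline_error")

  # participant-pooled Otsu thresholds
  thresholds <- design[ok, ] |>
    dplyr::distinct(.data$subject_id) |>
    dplyr::mutate(threshold = vapply(.data$subject_id, function(sid) {
      idx <- which(ok & design$subject_id == sid)
      participant_threshold(
        purrr::map(idx, function(i) images[[design$image_id[i]]]$glut4),
        purrr::map(idx, function(i) seg[[i]]$layers$band_union))
    }, numeric(1)))

  # pass 2: measure every successfully segmented fibre
  meas <- vector("list", sum(ok))
  spot_tabs <- vector("list", sum(ok))
  mhc1_means <- numeric(sum(ok))
  j <- 0L
  for (i in which(ok)) {
    j <- j + 1L
    id <- design$image_id[i]
    img <- images[[id]]
    thr <- thresholds$threshold[thresholds$subject_id == design$subject_id[i]]
    m <- measure_fibre(img, seg[[i]]$layers, seg[[i]]$dmap, thr,
                       pcc_region = config$pcc_region,
                       min_area_px = config$min_spot_area_px,
                       size_threshold_um = config$size_threshold_um,
                       image_id = id)
    mhc1_means[j] <- mean(img$mhc1[seg[[i]]$layers$fibre])
    meas[[j]] <- m$measurement
    spot_tabs[[j]] <- m$spots
  }
  types <- classify_fibre_types(mhc1_means,
                                fallback_cut = config$mhc1_fallback_cut)
  measurements <- dplyr::bind_rows(meas) |>
    dplyr::mutate(mhc1_mean = mhc1_means, fibre_type = types$fibre_type) |>
    dplyr::left_join(design, by = "image_id") |>
    dplyr::relocate("image_id", "subject_id", "group", "infusion",
                    "timepoint_h", "fibre_type")
  structure(
    list(measurements = measurements, spots = dplyr::bind_rows(spot_tabs),
         thresholds = thresholds, status = status_tab, config = config),
    class = "glut4_run"
  )
}

#' @export
print.glut4_run <- function(x, ...) {
  tab <- table(x$status$status)
  cat(sprintf("<glut4_run> %d fibres measured (%s)\n",
              nrow(x$measurements),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Fit the standard analysis models to a pipeline run
#'
#' Convenience wrapper running the repeated-measures models the report is
#' built from: colocalization versus timepoint, and per-layer small and
#' large spot counts versus timepoint (PM and each layer), each with
#' post-hoc pairwise biopsy contrasts, plus the descriptive summary tables.
#'
#' @param measurements measurement tibble (from [run_pipeline()] or
#'   [simulate_measurements()]).
#' @param fixed fixed factors for the models (default timepoint only).
#' @return list with `fits` (named `glut4_fit` list), `contrasts` (named
#'   list of [posthoc_pairwise()] tables) and `summary` (from
#'   [summarize_study()]).
#' @export
analyze_study <- function(measurements, fixed = "timepoint") {
  responses <- c("pcc", "small_count", "large_count")
  fits <- purrr::map(setNames(responses, responses), function(r)
    fit_mixed_model(measurements, response = r, fixed = fixed))
  contrasts <- purrr::map(fits, posthoc_pairwise, factor = "timepoint")
  list(fits = fits, contrasts = contrasts,
       summary = summarize_study(measurements))
}

# ---- disk I/O -------------------------------------------------------------

#' Write a rendered study to disk
#'
#' Writes each image as a 3-page (dystrophin, GLUT4, MHC1) 16-bit TIFF, the
#' design table as CSV, and the ground truth (when present) as JSON.
#'
#' @param study a `glut4_study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "glut4_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxval <- 2^study$spec$bit_depth - 1
  for (id in names(study$images)) {
    img <- study$images[[id]]
    pages <- lapply(list(img$dystrophin, img$glut4, img$mhc1),
                    function(m) m / maxval)
    tiff::writeTIFF(pages, file.path(dir, paste0(id, ".tif")),
                    bits.per.sample = 16L)
  }
  utils::write.csv(study$design, file.path(dir, "design.csv"),
                   row.names = FALSE)
  truth <- purrr::map(study$truth, function(t) list(
    contour_px = t$contour_px, spots = t$spots,
    fibre_type = t$fibre_type, condition = t$condition))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study written by [write_study()] back from disk
#'
#' @param dir directory containing `design.csv` and one multi-page TIFF per
#'   image.
#' @param pixel_size_um pixel size to attach to the images.
#' @param bit_depth bit depth the TIFFs were written at.
#' @return list with `images` (named `fibre_image` list) and `design`.
#' @export
read_study_images <- function(dir, pixel_size_um = 0.2, bit_depth = 16L) {
  design_path <- file.path(dir, "design.csv")
  if (!file.exists(design_path))
    rlang::abort(sprintf("no design.csv in %s", dir),
                 class = "glut4_pipeline_error")
  design <- tibble::as_tibble(utils::read.csv(design_path))
  maxval <- 2^bit_depth - 1
  images <- purrr::map(setNames(design$image_id, design$image_id),
                       function(id) {
    path <- file.path(dir, paste0(id, ".tif"))
    if (!file.exists(path))
      rlang::abort(sprintf("image file missing: %s", path),
                   class = "glut4_pipeline_error")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) < 3L)
      rlang::abort(sprintf("image %s has %d channels, need 3", id,
                           length(pages)),
                   class = "glut4_pipeline_error")
    structure(list(dystrophin = round(pages[[1]] * maxval),
                   glut4 = round(pages[[2]] * maxval),
                   mhc1 = round(pages[[3]] * maxval),
                   pixel_size_um = pixel_size_um, image_id = id),
              class = "fibre_image")
  })
  list(images = images, design = design)
}

#' Write the outputs of a pipeline run
#'
#' Measurements, spot table, per-participant thresholds and per-image
#' status as CSV, plus a JSON snapshot of the configuration (including the
#' seed) from which the run can be regenerated.
#'
#' @param run a `glut4_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "glut4_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(run$spots, file.path(dir, "spots.csv"), row.names = FALSE)
  utils::write.csv(run$thresholds, file.path(dir, "thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(run$status, file.path(dir, "status.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(run$config),
                       file.path(dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
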