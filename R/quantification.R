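#' Otsu threshold of pooled pixel intensities
#'
#' Computes the intensity threshold maximising the between-class variance of
#' the pooled histogram, the criterion of Otsu's method. For integer-valued
#' data every integer level between the minimum and maximum is a candidate
#' threshold (16-bit histogram semantics); for continuous data the observed
#' unique values are the candidates, which makes the induced partition
#' equivariant under positive rescaling. Foreground is `value > threshold`.
#'
#' @param values numeric vector of pooled pixel intensities.
#' @return the threshold (numeric scalar).
#' @details Errors with class `glut4_threshold_error` when the pooled
#'   histogram is degenerate (a single intensity value).
#' @export
pooled_otsu <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    rlang::abort("no finite pixel values to threshold",
                 class = "glut4_threshold_error")
  if (is_integerish_values(values)) {
    v <- round(values)
    lo <- min(v)
    counts <- tabulate(v - lo + 1L, nbins = max(v) - lo + 1L)
    levels <- seq.int(lo, max(v))
  } else {
    tab <- table(values)
    levels <- as.numeric(names(tab))
    counts <- as.numeric(tab)
  }
  if (length(levels) < 2L)
    rlang::abort("degenerate histogram: all pixels share one value",
                 class = "glut4_threshold_error")
  n <- sum(counts)
  w0 <- cumsum(counts)
  mu0 <- cumsum(counts * levels)
  mu_t <- mu0[length(mu0)]
  # drop the last candidate (empty foreground class)
  k <- seq_len(length(levels) - 1L)
  w0k <- w0[k]; w1k <- n - w0k
  m0 <- mu0[k] / w0k
  m1 <- (mu_t - mu0[k]) / w1k
  sb <- (w0k / n) * (w1k / n) * (m0 - m1)^2
  sb[w0k == 0 | w1k == 0] <- -Inf
  levels[which.max(sb)]
}

#' Participant-pooled spot-detection threshold
#'
#' Pools the in-fibre GLUT4 pixels of all images belonging to one
#' participant and computes a single Otsu threshold, applied identically to
#' each of that participant's images, so that spot detection is comparable
#' across a participant's biopsies.
#'
#' @param glut4_images list of numeric matrices (GLUT4 channel), one per
#'   image of the participant.
#' @param fibre_masks list of logical matrices restricting the pooled
#'   histogram to fibre pixels (typically the `band_union` of the image's
#'   [build_layer_masks()] result). `NULL` entries use the whole raster.
#' @return the participant's threshold (numeric scalar).
#' @export
participant_threshold <- function(glut4_images, fibre_masks = NULL) {
  if (!is.list(glut4_images) || length(glut4_images) == 0L)
    rlang::abort("`glut4_images` must be a non-empty list of matrices")
  if (is.null(fibre_masks)) fibre_masks <- vector("list", length(glut4_images))
  if (length(fibre_masks) != length(glut4_images))
    rlang::abort("`fibre_masks` must match `glut4_images` in length")
  pooled <- unlist(purrr::map2(glut4_images, fibre_masks, function(img, m) {
    assert_matrix(img, "glut4_images[[i]]")
    if (is.null(m)) as.vector(img) else img[m]
  }), use.names = FALSE)
  pooled_otsu(pooled)
}

#' Detect GLUT4 spots and classify them by size
#'
#' Thresholds the GLUT4 channel at the participant threshold, labels
#' 8-connected supra-threshold components, keeps the components whose
#' centroid lies inside the membrane band or interior (so a spot's
#' footprint is never truncated by the reporting band), discards components
#' below the minimum-area floor, and records for each surviving component
#' its area, area-equivalent diameter `2 sqrt(area / pi)`, size class
#' (large strictly above the size cut, small otherwise), centroid, and the
#' layer containing the centroid.
#'
#' @param glut4 numeric matrix, GLUT4 channel.
#' @param threshold intensity threshold from [participant_threshold()].
#' @param layers a `layer_mask_set` for this image.
#' @param dmap the image's signed distance map (pixels); used to assign each
#'   centroid its layer under the same band rules as the masks.
#' @param min_area_px minimum component area in pixels.
#' @param size_threshold_um small/large split on equivalent diameter
#'   (micrometres); exactly at the cut counts as small.
#' @param image_id optional identifier carried into the table.
#' @return tibble with one row per spot: `image_id`, `label`, `area_px`,
#'   `area_um2`, `equivalent_diameter_um`, `size_class`, `centroid_row`,
#'   `centroid_col`, `layer`.
#' @export
detect_spots <- function(glut4, threshold, layers, dmap,
                         min_area_px = 2, size_threshold_um = 1,
                         image_id = NA_character_) {
  assert_matrix(glut4, "glut4")
  stopifnot(inherits(layers, "layer_mask_set"))
  px <- layers$pixel_size_um
  mask <- glut4 > threshold
  empty <- tibble::tibble(
    image_id = character(), label = integer(), area_px = integer(),
    area_um2 = numeric(), equivalent_diameter_um = numeric(),
    size_class = factor(character(), levels = c("small", "large")),
    centroid_row = numeric(), centroid_col = numeric(),
    layer = factor(character(), levels = LAYER_LEVELS)
  )
  if (!any(mask)) return(empty)
  lab <- label_components_cpp(mask)
  keep <- which(lab > 0)
  df <- tibble::tibble(
    label = lab[keep],
    row = ((keep - 1L) %% nrow(lab)) + 1L,
    col = ((keep - 1L) %/% nrow(lab)) + 1L
  )
  spots <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      area_px = dplyr::n(),
      centroid_row = mean(.data$row),
      centroid_col = mean(.data$col),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$area_px >= min_area_px)
  if (nrow(spots) == 0L) return(empty)
  d_at <- interp_bilinear(dmap, spots$centroid_row, spots$centroid_col)
  eqd_um <- 2 * sqrt(spots$area_px / pi) * px
  spots |>
    dplyr::mutate(
      image_id = image_id,
      area_um2 = .data$area_px * px^2,
      equivalent_diameter_um = eqd_um,
      size_class = factor(
        ifelse(eqd_um > size_threshold_um, "large", "small"),
        levels = c("small", "large")),
      layer = layer_of_distance(
        d_at, px, layers$pm_thickness_px, layers$layer_width_um,
        layers$n_layers, layers$measure_from)
    ) |>
    dplyr::filter(!is.na(.data$layer)) |>
    dplyr::mutate(label = dplyr::row_number()) |>
    dplyr::select(dplyr::all_of(names(empty)))
}

#' Per-layer and whole-fibre mean GLUT4 intensity
#'
#' Arithmetic mean of the raw GLUT4 intensity over the PM band, each
#' intracellular layer, and the whole fibre. Empty masks yield `NA`, never
#' zero.
#'
#' @param glut4 numeric matrix, GLUT4 channel.
#' @param layers a `layer_mask_set`.
#' @return tibble with columns `layer` (PM, L1.., interior, fibre),
#'   `mean_intensity`, `n_pixels`.
#' @export
layer_intensities <- function(glut4, layers) {
  assert_matrix(glut4, "glut4")
  stopifnot(inherits(layers, "layer_mask_set"))
  masks <- c(list(PM = layers$pm),
             setNames(layers$inner, paste0("L", seq_len(layers$n_layers))),
             list(interior = layers$interior, fibre = layers$fibre))
  purrr::imap_dfr(masks, function(m, nm) {
    n <- sum(m)
    tibble::tibble(
      layer = nm,
      mean_intensity = if (n == 0L) NA_real_ else mean(glut4[m]),
      n_pixels = n
    )
  })
}

#' Pearson colocalization of GLUT4 with dystrophin
#'
#' Pixel-wise Pearson product-moment correlation between the two channels
#' over a region mask, the standard colocalization coefficient for paired
#' fluorescence channels.
#'
#' @param glut4,dystrophin numeric matrices of identical dimension.
#' @param mask logical matrix selecting the region (e.g. the whole fibre
#'   including the membrane band, or the PM band alone).
#' @return correlation coefficient in `[-1, 1]`.
#' @details Errors with class `glut4_pcc_error` when the region has fewer
#'   than two pixels or either channel has zero variance there.
#' @export
colocalization_pcc <- function(glut4, dystrophin, mask) {
  assert_matrix(glut4, "glut4"); assert_matrix(dystrophin, "dystrophin")
  stopifnot(identical(dim(glut4), dim(dystrophin)),
            identical(dim(glut4), dim(mask)))
  x <- glut4[mask]; y <- dystrophin[mask]
  if (length(x) < 2L)
    rlang::abort("PCC region has fewer than 2 pixels",
                 class = "glut4_pcc_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    rlang::abort("PCC undefined: zero variance in a channel",
                 class = "glut4_pcc_error")
  stats::cor(x, y)
}

#' Classify fibres as type I or type II from MHC1 positivity
#'
#' Fibres staining positively for slow myosin heavy chain (MHC1) are type I;
#' unstained fibres are type II. The positivity cut is data-driven across
#' the cohort: a two-class 1-d split (k-means with extreme-value
#' initialisation, deterministic) of the per-fibre mean MHC1 intensities,
#' with the cut at the midpoint of the two class centres. Positive staining
#' is several-fold brighter than the unstained background, so the split
#' only counts as bimodal when the upper class centre exceeds the lower by
#' at least `min_fold`; otherwise (or with a single fibre) a fixed fallback
#' cut is used with a warning.
#'
#' @param mhc1_means numeric vector of per-fibre mean MHC1 intensities.
#' @param fallback_cut fixed intensity cut used when the cohort distribution
#'   is unimodal or too small.
#' @param min_fold minimum ratio of the two class centres for the cohort to
#'   count as bimodal.
#' @return tibble with `mhc1_mean`, `fibre_type` (factor I/II) and the `cut`
#'   used.
#' @export
classify_fibre_types <- function(mhc1_means, fallback_cut = 400,
                                 min_fold = 2) {
  stopifnot(is.numeric(mhc1_means), all(is.finite(mhc1_means)))
  n <- length(mhc1_means)
  use_fallback <- FALSE
  cut <- fallback_cut
  if (n >= 2L && stats::var(mhc1_means) > 0) {
    centers <- matrix(range(mhc1_means), ncol = 1)
    km <- stats::kmeans(matrix(mhc1_means, ncol = 1), centers = centers)
    c_lo <- min(km$centers); c_hi <- max(km$centers)
    if (c_lo > 0 && c_hi / c_lo >= min_fold) {
      cut <- mean(km$centers)
    } else {
      use_fallback <- TRUE
    }
  } else {
    use_fallback <- TRUE
  }
  if (use_fallback)
    rlang::warn(paste(
      "MHC1 cohort distribution not clearly bimodal;",
      "using fixed fallback positivity cut"))
  tibble::tibble(
    mhc1_mean = mhc1_means,
    fibre_type = factor(ifelse(mhc1_means > cut, "I", "II"),
                        levels = c("I", "II")),
    cut = cut
  )
}

#' Measure one fibre image
#'
#' Runs spot detection, per-layer intensity measurement and colocalization
#' on one segmented fibre and returns the per-fibre analysis row.
#'
#' @param image a `fibre_image` (see [render_fibre_image()]) or a named list
#'   with matrices `glut4` and `dystrophin`.
#' @param layers `layer_mask_set` for the image.
#' @param dmap signed distance map for the image.
#' @param threshold participant spot threshold.
#' @param pcc_region `"fibre"` (whole fibre including the PM band, default)
#'   or `"pm"` (PM band only).
#' @param min_area_px,size_threshold_um as in [detect_spots()].
#' @param image_id identifier for the row.
#' @return list with `measurement` (one-row tibble in wide layout: total and
#'   per-layer intensities, per-layer small/large counts, `pcc`) and
#'   `spots` (the [detect_spots()] table).
#' @export
measure_fibre <- function(image, layers, dmap, threshold,
                          pcc_region = c("fibre", "pm"),
                          min_area_px = 2, size_threshold_um = 1,
                          image_id = NA_character_) {
  pcc_region <- match.arg(pcc_region)
  spots <- detect_spots(image$glut4, threshold, layers, dmap,
                        min_area_px = min_area_px,
                        size_threshold_um = size_threshold_um,
                        image_id = image_id)
  ints <- layer_intensities(image$glut4, layers)
  region <- if (pcc_region == "fibre") layers$band_union else layers$pm
  pcc <- colocalization_pcc(image$glut4, image$dystrophin, region)

  layer_names <- c("PM", paste0("L", seq_len(layers$n_layers)))
  counts <- spots |>
    dplyr::filter(.data$layer %in% layer_names) |>
    dplyr::count(.data$layer, .data$size_class, .drop = FALSE) |>
    dplyr::filter(.data$layer %in% layer_names)
  count_wide <- tidyr::pivot_wider(
    counts,
    names_from = c("size_class", "layer"), values_from = "n",
    names_glue = "{size_class}_{layer}"
  )
  int_wide <- ints |>
    dplyr::filter(.data$layer %in% layer_names) |>
    dplyr::select("layer", "mean_intensity") |>
    tidyr::pivot_wider(names_from = "layer", values_from = "mean_intensity",
                       names_glue = "intensity_{layer}")
  measurement <- dplyr::bind_cols(
    tibble::tibble(
      image_id = image_id,
      total_intensity = ints$mean_intensity[ints$layer == "fibre"],
      pcc = pcc
    ),
    int_wide, count_wide
  )
  list(measurement = measurement, spots = spots)
}
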