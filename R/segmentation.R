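#' Segment the plasma-membrane midline with an active contour
#'
#' Finds the closed ridge of the dystrophin ring in a single-fibre image
#' using the classic snake formulation: an energy-minimising closed curve
#' with internal elasticity/rigidity terms, attracted up the gradient of the
#' Gaussian-smoothed intensity so that it settles on the local intensity
#' maximum across the ring (the membrane midline). The snake is initialised
#' from the outer boundary of the largest connected component of the
#' Otsu-thresholded dystrophin channel.
#'
#' @param dystrophin numeric matrix, the dystrophin channel of one fibre.
#' @param n_vertices number of snake vertices.
#' @param alpha,beta internal elasticity and rigidity weights.
#' @param gamma implicit time-step (viscosity) parameter.
#' @param kappa image-force weight.
#' @param sigma Gaussian smoothing sd (pixels) applied before taking the
#'   image gradient.
#' @param tol convergence tolerance: mean vertex displacement per iteration
#'   (pixels) below which the snake is declared converged.
#' @param max_iter iteration cap.
#' @param min_area_px minimum enclosed area (pixels) for a valid fibre.
#' @param image_id optional identifier carried into the result.
#'
#' @return A `membrane_contour` object: list with `vertices` (n x 2 matrix of
#'   (row, col) pixel coordinates, 1-based, implicitly closed), `converged`,
#'   `iterations`, `area_px` and `image_id`.
#'
#' @details Fails with class `glut4_segmentation_failure` when no closed
#'   bright ring is found (blank image, enclosed area below `min_area_px`,
#'   component touching the image border, or non-convergence).
#' @export
segment_membrane <- function(dystrophin, n_vertices = 200L,
                             alpha = 0.4, beta = 0.4, gamma = 3,
                             kappa = 4, sigma = 2, tol = 0.02,
                             max_iter = 500L, min_area_px = 400,
                             image_id = NA_character_) {
  assert_matrix(dystrophin, "dystrophin")
  rng <- range(dystrophin)
  if (diff(rng) <= 0)
    segmentation_failure("blank image: dystrophin channel is constant")
  img <- (dystrophin - rng[1]) / diff(rng)

  init <- snake_init_contour(img, min_area_px)
  v <- resample_closed(init, n_vertices)

  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
  gr <- gradient_images(sm)

  n <- n_vertices
  P <- internal_matrix(n, alpha, beta)
  M <- solve(P + diag(gamma, n))

  iterations <- 0L
  converged <- FALSE
  nr <- nrow(img); nc <- ncol(img)
  for (it in seq_len(max_iter)) {
    fr <- interp_bilinear(gr$dr, v[, 1], v[, 2])
    fc <- interp_bilinear(gr$dc, v[, 1], v[, 2])
    v_new <- cbind(
      M %*% (gamma * v[, 1] + kappa * fr),
      M %*% (gamma * v[, 2] + kappa * fc)
    )
    v_new[, 1] <- pmin(pmax(v_new[, 1], 1), nr)
    v_new[, 2] <- pmin(pmax(v_new[, 2], 1), nc)
    disp <- mean(sqrt(rowSums((v_new - v)^2)))
    v <- v_new
    iterations <- it
    if (disp < tol) { converged <- TRUE; break }
  }
  if (!converged)
    segmentation_failure(sprintf(
      "snake failed to converge within %d iterations", max_iter))
  area <- polygon_area(v)
  if (area < min_area_px)
    segmentation_failure(sprintf(
      "enclosed area %.0f px below minimum %.0f px", area, min_area_px))
  new_membrane_contour(v, converged, iterations, area, image_id)
}

new_membrane_contour <- function(vertices, converged, iterations, area_px,
                                 image_id = NA_character_) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 16)
  structure(
    list(vertices = unname(vertices), converged = converged,
         iterations = iterations, area_px = area_px, image_id = image_id),
    class = "membrane_contour"
  )
}

#' @export
print.membrane_contour <- function(x, ...) {
  cat(sprintf(
    "<membrane_contour> %d vertices, area %.0f px, %s in %d iterations\n",
    nrow(x$vertices), x$area_px,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

segmentation_failure <- function(msg) {
  rlang::abort(msg, class = "glut4_segmentation_failure")
}

# initial contour: Otsu-threshold the (normalised) dystrophin image, take the
# largest 8-connected component, fill it, and trace its outer boundary
snake_init_contour <- function(img, min_area_px) {
  t <- tryCatch(pooled_otsu(as.vector(img)),
                error = function(e) segmentation_failure(
                  "blank image: cannot threshold dystrophin channel"))
  mask <- img > t
  if (!any(mask))
    segmentation_failure("no foreground after thresholding")
  lab <- label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  comp <- lab == big
  # one-fibre-per-image capture: a ring touching the border cannot be closed
  if (any(comp[1, ]) || any(comp[nrow(comp), ]) ||
      any(comp[, 1]) || any(comp[, ncol(comp)]))
    segmentation_failure("fibre touches the image border")
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(comp * 1)))
  if (sum(filled) < min_area_px)
    segmentation_failure("largest component encloses too little area")
  oc <- EBImage::ocontour(EBImage::Image(filled))[[1]]
  # ocontour returns 0-based (x, y) = (row-index-1, col-index-1) of the
  # matrix as EBImage stores it; convert to 1-based (row, col)
  cbind(oc[, 1] + 1, oc[, 2] + 1)
}

# cyclic pentadiagonal internal-energy matrix of the snake
internal_matrix <- function(n, alpha, beta) {
  a <- 2 * alpha + 6 * beta
  b <- -alpha - 4 * beta
  c_ <- beta
  P <- matrix(0, n, n)
  idx <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    P[i, idx(i - 2)] <- P[i, idx(i - 2)] + c_
    P[i, idx(i - 1)] <- P[i, idx(i - 1)] + b
    P[i, i] <- P[i, i] + a
    P[i, idx(i + 1)] <- P[i, idx(i + 1)] + b
    P[i, idx(i + 2)] <- P[i, idx(i + 2)] + c_
  }
  P
}

# central-difference gradient images (d/drow, d/dcol)
gradient_images <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- matrix(0, nr, nc)
  dc <- matrix(0, nr, nc)
  dr[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  dc[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  list(dr = dr, dc = dc)
}

#' Signed Euclidean distance map to a membrane contour
#'
#' Exact per-pixel Euclidean distance from each pixel centre to the closed
#' contour polyline (point-to-segment, no rasterisation of the curve):
#' positive inside the fibre, negative outside, zero on the contour.
#'
#' @param contour a `membrane_contour`, or an n x 2 matrix of (row, col)
#'   vertices (1-based pixel coordinates).
#' @param dim integer length-2, raster dimensions (rows, cols).
#' @return numeric matrix of signed distances in pixels.
#' @export
signed_distance_map <- function(contour, dim) {
  v <- if (inherits(contour, "membrane_contour")) contour$vertices
       else as.matrix(contour)
  stopifnot(is.matrix(v), ncol(v) == 2, nrow(v) >= 3,
            length(dim) == 2, all(dim >= 1))
  signed_distance_cpp(v - 1, as.integer(dim[1]), as.integer(dim[2]))
}

#' Build the plasma-membrane band and concentric intracellular layer masks
#'
#' Applies the layer rules to a signed distance map: the plasma-membrane
#' (PM) band is the set of pixels within half the PM thickness of the
#' membrane midline (3 px thick by default); the k-th intracellular layer
#' collects pixels whose inward distance from the PM inner edge lies in
#' `((k-1) w, k w]` with `w` one layer width (1 um by default) in pixels;
#' everything deeper is the interior.
#'
#' @param dmap signed distance map from [signed_distance_map()] (pixels,
#'   positive inside).
#' @param pixel_size_um pixel size, micrometres per pixel.
#' @param pm_thickness_px thickness of the PM band in pixels.
#' @param layer_width_um width of each intracellular layer, micrometres.
#' @param n_layers number of intracellular layers.
#' @param measure_from `"pm_inner_edge"` (default) starts layer 1 at the
#'   inner edge of the PM band; `"midline"` starts it at the membrane
#'   midline (the PM band is subtracted to keep masks disjoint).
#' @return A `layer_mask_set`: logical matrices `pm`, `inner` (list of
#'   `n_layers`), `interior`, `fibre` (the full enclosed region), and
#'   `band_union` (PM plus everything inside), with the geometry parameters
#'   attached.
#' @export
build_layer_masks <- function(dmap, pixel_size_um, pm_thickness_px = 3,
                              layer_width_um = 1, n_layers = 5L,
                              measure_from = c("pm_inner_edge", "midline")) {
  assert_matrix(dmap, "dmap")
  assert_scalar_pos(pixel_size_um, "pixel_size_um")
  assert_scalar_pos(pm_thickness_px, "pm_thickness_px")
  measure_from <- match.arg(measure_from)
  w <- layer_width_um / pixel_size_um
  if (w < 2)
    rlang::warn(sprintf(
      "layer width is %.2f px (< 2 px); layer areas will be coarse", w))
  half <- pm_thickness_px / 2
  start <- if (measure_from == "pm_inner_edge") half else 0

  pm <- abs(dmap) <= half
  inner <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    lk <- dmap > (start + (k - 1) * w) & dmap <= (start + k * w)
    if (measure_from == "midline") lk <- lk & !pm
    inner[[k]] <- lk
  }
  interior <- dmap > (start + n_layers * w)
  if (measure_from == "midline") interior <- interior & !pm
  fibre <- dmap >= 0
  band_union <- dmap >= -half

  # a usable fibre must be at least one layer deep; emptiness of deeper
  # layers (or the interior) only warrants a warning
  if (max(dmap) <= start + w)
    rlang::abort("fibre too small to contain the requested layers")
  empty <- vapply(inner, function(m) !any(m), logical(1))
  if (any(empty))
    rlang::warn(sprintf("empty layer mask(s): %s",
                        paste(paste0("L", which(empty)), collapse = ", ")))

  structure(
    list(pm = pm, inner = inner, interior = interior, fibre = fibre,
         band_union = band_union, pixel_size_um = pixel_size_um,
         pm_thickness_px = pm_thickness_px, layer_width_um = layer_width_um,
         n_layers = as.integer(n_layers), measure_from = measure_from),
    class = "layer_mask_set"
  )
}

#' @export
print.layer_mask_set <- function(x, ...) {
  areas <- vapply(c(list(x$pm), x$inner, list(x$interior)), sum, numeric(1))
  cat("<layer_mask_set>", paste(
    c("PM", paste0("L", seq_len(x$n_layers)), "interior"), areas,
    sep = "=", collapse = " "), "px\n")
  invisible(x)
}

#' Assign layer labels from signed distances
#'
#' Maps signed distances (pixels, positive inside) to the layer labels used
#' by [build_layer_masks()], with the same band boundaries.
#'
#' @param d numeric vector of signed distances in pixels.
#' @param pixel_size_um,pm_thickness_px,layer_width_um,n_layers,measure_from
#'   as in [build_layer_masks()].
#' @return factor with levels [LAYER_LEVELS] (NA outside the membrane band).
#' @export
layer_of_distance <- function(d, pixel_size_um, pm_thickness_px = 3,
                              layer_width_um = 1, n_layers = 5L,
                              measure_from = c("pm_inner_edge", "midline")) {
  measure_from <- match.arg(measure_from)
  w <- layer_width_um / pixel_size_um
  half <- pm_thickness_px / 2
  start <- if (measure_from == "pm_inner_edge") half else 0
  out <- rep(NA_character_, length(d))
  out[abs(d) <= half] <- "PM"
  for (k in seq_len(n_layers)) {
    sel <- is.na(out) & d > (start + (k - 1) * w) & d <= (start + k * w)
    out[sel] <- paste0("L", k)
  }
  out[is.na(out) & d > (start + n_layers * w)] <- "interior"
  factor(out, levels = LAYER_LEVELS)
}
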