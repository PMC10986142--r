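#' Generate a synthetic fibre phantom
#'
#' Draws one fibre cross-section with known ground truth for a given design
#' cell: a smoothed, randomised convex-ish boundary (a low-order Fourier
#' perturbation of a circle) with at least a 2 um margin to the field edge,
#' a fibre type, an MHC1 level, and a set of planted GLUT4 spots. Spot
#' counts per layer are Poisson with the spec's per-layer rates (times the
#' condition's time factor and any subject multiplier), the small/large mix
#' follows the condition's small-spot fractions, and each spot centre is
#' placed uniformly over the pixels of its true layer band, so the true
#' layer label is consistent by construction with the layer rules applied
#' to the true contour.
#'
#' @param spec an [effect_spec()].
#' @param condition named list or one-row data frame with `group`
#'   (trained/sedentary), `infusion` (lipid/glycerol), `timepoint_h`
#'   (0/2/6) and optionally `fibre_type` ("I"/"II"; sampled if absent).
#' @param rate_multiplier subject-level multiplier on spot rates.
#' @param intensity_multiplier subject-level multiplier on intensities.
#' @return A `fibre_phantom`: boundary (n x 2 matrix, um coordinates with
#'   the origin at the centre of pixel (1,1)), membrane thickness,
#'   `planted_spots` tibble (centre, diameter, peak, size class, true
#'   layer), fibre type, MHC1 level, and the condition.
#' @export
generate_fibre_phantom <- function(spec, condition,
                                   rate_multiplier = 1,
                                   intensity_multiplier = 1) {
  stopifnot(inherits(spec, "glut4_effect_spec"))
  condition <- as.list(condition)
  group <- match.arg(condition$group, c("trained", "sedentary"))
  tp <- condition$timepoint_h %||% 0
  fibre_type <- condition$fibre_type %||%
    sample(c("I", "II"), 1L, prob = c(spec$p_type1, 1 - spec$p_type1))
  if (max(spec$large_diameter_um) >= 0.5 * spec$field_um)
    rlang::abort("spot diameters must be well below the fibre diameter")

  px <- spec$pixel_size_um
  n_px <- round(spec$field_um / px)
  boundary_um <- random_fibre_boundary(spec$field_um, margin_um = 2)
  boundary_px <- boundary_um / px + 1

  dmap <- signed_distance_map(boundary_px, c(n_px, n_px))
  # spot centres are sampled 0.5 px clear of the band edges so the true
  # layer label is stable under sub-pixel centroid error; the label itself
  # still follows the plain band rules
  layer_lab <- guarded_layer_bands(as.vector(dmap), px, guard_px = 0.5)
  layer_names <- c("PM", paste0("L", 1:5))

  spots <- purrr::map_dfr(layer_names, function(ly) {
    lam <- spec$spot_rates[[ly]] * rate_multiplier *
      small_rate_time_factor_total(spec, ly, tp, group)
    n <- rpois(1L, lam)
    if (n == 0L) return(NULL)
    f_small <- if (ly == "PM") pm_small_fraction(spec, group)
               else spec$inner_small_fraction
    # the 2->6 h decline acts on small spots only: recompute the mix
    n_small <- rbinom(1L, n, small_mix_at_time(spec, ly, tp, group, f_small))
    sizes <- c(rep("small", n_small), rep("large", n - n_small))
    cells <- which(layer_lab == ly)
    if (length(cells) == 0L) return(NULL)
    dia <- ifelse(sizes == "small",
                  runif(n, spec$small_diameter_um[1], spec$small_diameter_um[2]),
                  runif(n, spec$large_diameter_um[1], spec$large_diameter_um[2]))
    tibble::tibble(
      cells_key = ly,
      diameter_um = dia,
      peak = pmax(rnorm(n, spec$spot_peak_mean, spec$spot_peak_sd),
                  spec$spot_peak_mean / 3),
      size_class = factor(sizes, levels = c("small", "large")),
      layer = factor(ly, levels = LAYER_LEVELS)
    )
  })
  spots <- place_spots(spots, layer_lab, n_px, px)
  if (is.null(spots) || nrow(spots) == 0L)
    spots <- empty_spot_table()

  structure(
    list(
      boundary_um = boundary_um,
      boundary_px = boundary_px,
      membrane_thickness_um = spec$membrane_thickness_um,
      planted_spots = spots,
      fibre_type = fibre_type,
      mhc1_level = (if (fibre_type == "I") spec$mhc1_positive
                    else spec$mhc1_negative),
      intensity_multiplier = intensity_multiplier *
        (if (fibre_type == "II")
           1 + spec$type2_intensity_excess[[group]] else 1),
      condition = list(group = group,
                       infusion = condition$infusion %||% "lipid",
                       timepoint_h = tp, fibre_type = fibre_type),
      field_px = n_px,
      dmap = dmap
    ),
    class = "fibre_phantom"
  )
}

# layer bands shrunk by a guard margin on each side (placement pool only)
guarded_layer_bands <- function(d, px, guard_px = 0.5, pm_half = 1.5,
                                w_um = 1, n_layers = 5L) {
  w <- w_um / px
  out <- rep(NA_character_, length(d))
  out[abs(d) <= pm_half - guard_px] <- "PM"
  for (k in seq_len(n_layers)) {
    sel <- is.na(out) & d > (pm_half + (k - 1) * w + guard_px) &
      d <= (pm_half + k * w - guard_px)
    out[sel] <- paste0("L", k)
  }
  out
}

empty_spot_table <- function() {
  tibble::tibble(
    x_um = numeric(), y_um = numeric(), row_px = integer(),
    col_px = integer(), diameter_um = numeric(), peak = numeric(),
    size_class = factor(character(), levels = c("small", "large")),
    layer = factor(character(), levels = LAYER_LEVELS))
}

# Place spots on pixels of their true layer band, enforcing mutual
# resolvability: planted puncta are distinct objects, so centre separations
# keep neighbouring spots from fusing into one connected component at
# detection. Positions are re-drawn (counts are never changed) until the
# separation holds; after `max_tries` draws the least-crowded candidate is
# kept, so counts stay exactly Poisson.
place_spots <- function(spots, layer_lab, n_px, px, max_tries = 200L) {
  if (is.null(spots) || nrow(spots) == 0L) return(empty_spot_table())
  n <- nrow(spots)
  rowi <- integer(n); coli <- integer(n)
  placed_r <- numeric(0); placed_c <- numeric(0); placed_d <- numeric(0)
  for (i in seq_len(n)) {
    cells <- which(layer_lab == as.character(spots$layer[i]))
    # minimum centre separation: thresholded footprints must not touch
    need <- 0.75 * (spots$diameter_um[i] + placed_d) / px + 1.5
    best <- NULL; best_pen <- Inf
    for (try in seq_len(max_tries)) {
      pick <- cells[sample.int(length(cells), 1L)]
      r <- ((pick - 1L) %% n_px) + 1L
      c <- ((pick - 1L) %/% n_px) + 1L
      pen <- if (length(placed_r) == 0L) 0 else
        max(pmax(need - sqrt((placed_r - r)^2 + (placed_c - c)^2), 0))
      if (pen < best_pen) { best <- c(r, c); best_pen <- pen }
      if (pen == 0) break
    }
    rowi[i] <- best[1]; coli[i] <- best[2]
    placed_r <- c(placed_r, best[1]); placed_c <- c(placed_c, best[2])
    placed_d <- c(placed_d, spots$diameter_um[i])
  }
  spots$row_px <- rowi
  spots$col_px <- coli
  spots$x_um <- (coli - 1) * px
  spots$y_um <- (rowi - 1) * px
  spots$cells_key <- NULL
  spots[, c("x_um", "y_um", "row_px", "col_px", "diameter_um", "peak",
            "size_class", "layer")]
}

# time factor on the TOTAL spot rate of a layer: the 2->6 h decline removes
# a `small_spot_decline_2_to_6h` share of the small spots in PM and L1
small_rate_time_factor_total <- function(spec, layer, timepoint_h, group) {
  if (timepoint_h < 6 || !(layer %in% c("PM", "L1"))) return(1)
  f_small <- if (layer == "PM") pm_small_fraction(spec, group)
             else spec$inner_small_fraction
  1 - spec$small_spot_decline_2_to_6h * f_small
}

# small-spot share of the remaining spots after the 2->6 h decline
small_mix_at_time <- function(spec, layer, timepoint_h, group, f_small) {
  if (timepoint_h < 6 || !(layer %in% c("PM", "L1"))) return(f_small)
  kept <- f_small * (1 - spec$small_spot_decline_2_to_6h)
  kept / (kept + (1 - f_small))
}

# randomised convex-ish fibre outline: circle radius perturbed by a few
# low-order harmonics, guaranteed simple (radius stays positive) and inside
# the field with the requested margin
random_fibre_boundary <- function(field_um, margin_um = 2, n_vertices = 256L,
                                  n_harmonics = 4L, roughness = 0.06) {
  centre <- field_um / 2
  r_max <- field_um / 2 - margin_um
  r0 <- runif(1, 0.62, 0.80) * r_max
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[seq_len(n_vertices)]
  pert <- rep(0, n_vertices)
  for (h in seq_len(n_harmonics) + 1L) {
    amp <- roughness * r0 / h
    pert <- pert + runif(1, 0, amp) * cos(h * th + runif(1, 0, 2 * pi))
  }
  r <- pmin(r0 + pert, r_max)
  cbind(centre + r * sin(th), centre + r * cos(th)) # (row, col) um
}

#' Render a fibre phantom to a three-channel image
#'
#' Forward optics model: the dystrophin channel is a Gaussian-profile ridge
#' along the boundary whose full width at half maximum equals the membrane
#' thickness; the GLUT4 channel is the sum of 2-d Gaussian spots (FWHM equal
#' to the planted diameter) over a uniform background; the MHC1 channel is
#' uniform at the fibre's MHC1 level inside the fibre. Poisson photon noise
#' and Gaussian read noise are applied last and intensities are clipped to
#' the declared bit depth and rounded to integers.
#'
#' @param phantom a `fibre_phantom`.
#' @param spec the [effect_spec()] used to generate it.
#' @param noise apply the spec's noise model (set `FALSE` for noiseless
#'   renders).
#' @return A `fibre_image`: list with integer-valued matrices `dystrophin`,
#'   `glut4`, `mhc1`, plus `pixel_size_um` and `image_id`.
#' @export
render_fibre_image <- function(phantom, spec, noise = TRUE) {
  stopifnot(inherits(phantom, "fibre_phantom"),
            inherits(spec, "glut4_effect_spec"))
  px <- spec$pixel_size_um
  n_px <- phantom$field_px
  if (n_px < 64) rlang::abort("field must render to at least 64 x 64 px")
  dmap <- phantom$dmap %||%
    signed_distance_map(phantom$boundary_px, c(n_px, n_px))

  sig_m <- (phantom$membrane_thickness_um / px) / (2 * sqrt(2 * log(2)))
  dyst <- spec$background_mean +
    spec$membrane_peak * exp(-dmap^2 / (2 * sig_m^2))

  imult <- phantom$intensity_multiplier
  glut4 <- matrix(spec$background_mean, n_px, n_px)
  # diffuse cytoplasmic GLUT4 carrying the fibre-type intensity contrast;
  # it fills the fibre up to the outer edge of the membrane band so the
  # intensity step sits outside the PM spots, not across them
  half_m <- 0.5 * phantom$membrane_thickness_um / px
  glut4 <- glut4 + (dmap > -half_m) * 0.2 * spec$base_intensity * imult
  sp <- phantom$planted_spots
  if (nrow(sp) > 0) {
    for (i in seq_len(nrow(sp))) {
      fwhm_px <- sp$diameter_um[i] / px
      s <- fwhm_px / (2 * sqrt(2 * log(2)))
      half <- max(3L, ceiling(4 * s))
      r0 <- max(1L, sp$row_px[i] - half); r1 <- min(n_px, sp$row_px[i] + half)
      c0 <- max(1L, sp$col_px[i] - half); c1 <- min(n_px, sp$col_px[i] + half)
      rr <- r0:r1; cc <- c0:c1
      g <- outer(exp(-(rr - sp$row_px[i])^2 / (2 * s^2)),
                 exp(-(cc - sp$col_px[i])^2 / (2 * s^2)))
      glut4[rr, cc] <- glut4[rr, cc] + sp$peak[i] * imult * g
    }
  }
  mhc1 <- matrix(spec$background_mean, n_px, n_px) +
    (dmap > 0) * phantom$mhc1_level

  maxval <- 2^spec$bit_depth - 1
  finish <- function(m) {
    if (noise) {
      if (spec$photon_scale > 0)
        m <- spec$photon_scale * rpois(length(m), m / spec$photon_scale)
      m <- m + rnorm(length(m), 0, spec$read_sd)
      m <- matrix(m, n_px, n_px)
    }
    matrix(pmin(pmax(round(m), 0), maxval), n_px, n_px)
  }
  structure(
    list(dystrophin = finish(dyst), glut4 = finish(glut4),
         mhc1 = finish(mhc1), pixel_size_um = px,
         image_id = NA_character_),
    class = "fibre_image"
  )
}

#' @export
print.fibre_image <- function(x, ...) {
  cat(sprintf("<fibre_image> %d x %d px, %.3g um/px\n",
              nrow(x$glut4), ncol(x$glut4), x$pixel_size_um))
  invisible(x)
}
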