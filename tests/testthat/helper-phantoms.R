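# shared fixtures and independent oracles, built in code at test time

circle_contour <- function(r, centre = c(0, 0), n = 200L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  cbind(centre[1] + r * sin(th), centre[2] + r * cos(th))
}

# minimal hand-built phantom: circular fibre with caller-specified spots
make_circle_phantom <- function(spots, field_px = 160L, r_px = 60,
                                spec = effect_spec(),
                                fibre_type = "I") {
  centre <- (field_px + 1) / 2
  boundary_px <- circle_contour(r_px, c(centre, centre), 256L)
  px <- spec$pixel_size_um
  structure(
    list(
      boundary_um = (boundary_px - 1) * px,
      boundary_px = boundary_px,
      membrane_thickness_um = spec$membrane_thickness_um,
      planted_spots = spots,
      fibre_type = fibre_type,
      mhc1_level = if (fibre_type == "I") spec$mhc1_positive
                   else spec$mhc1_negative,
      intensity_multiplier = 1,
      condition = list(group = "trained", infusion = "lipid",
                       timepoint_h = 0, fibre_type = fibre_type),
      field_px = as.integer(field_px)
    ),
    class = "fibre_phantom"
  )
}

spot_row <- function(row_px, col_px, diameter_um, size_class, layer,
                     peak = 600, pixel_size_um = 0.2) {
  tibble::tibble(
    x_um = (col_px - 1) * pixel_size_um, y_um = (row_px - 1) * pixel_size_um,
    row_px = as.integer(row_px), col_px = as.integer(col_px),
    diameter_um = diameter_um, peak = peak,
    size_class = factor(size_class, levels = c("small", "large")),
    layer = factor(layer, levels = LAYER_LEVELS)
  )
}

# greedy nearest-centroid matching of detected spots to planted spots
match_spots <- function(detected, truth, max_dist_px = 2) {
  used <- rep(FALSE, nrow(detected))
  out <- data.frame(detected = logical(nrow(truth)),
                    size_ok = logical(nrow(truth)),
                    layer_ok = logical(nrow(truth)))
  for (i in seq_len(nrow(truth))) {
    if (nrow(detected) == 0L) break
    dd <- sqrt((detected$centroid_row - truth$row_px[i])^2 +
               (detected$centroid_col - truth$col_px[i])^2)
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) && is.finite(dd[j]) && dd[j] <= max_dist_px) {
      used[j] <- TRUE
      out$detected[i] <- TRUE
      out$size_ok[i] <- detected$size_class[j] == truth$size_class[i]
      out$layer_ok[i] <- detected$layer[j] == truth$layer[i]
    }
  }
  out
}

# independent Otsu oracle: direct two-class variance computation per level
brute_force_otsu <- function(values) {
  v <- round(values)
  levels <- seq.int(min(v), max(v))
  sb <- vapply(levels, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) return(-Inf)
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  levels[which.max(sb)]
}

# thresholds inside an empty histogram gap induce the same partition and an
# identical between-class variance, so the maximizer is unique only up to
# that plateau; the comparison checks that implementation and oracle select
# the same foreground set and reach the same maximum
expect_same_otsu <- function(values) {
  t_impl <- pooled_otsu(values)
  t_oracle <- brute_force_otsu(values)
  expect_identical(values > t_impl, values > t_oracle)
  sb <- function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    (length(lo) / length(values)) * (length(hi) / length(values)) *
      (mean(lo) - mean(hi))^2
  }
  expect_equal(sb(t_impl), sb(t_oracle), tolerance = 1e-12)
}

# independent signed-distance oracle: explicit min over point-segment
# distances plus an even-odd point-in-polygon test, all in R
brute_force_signed_distance <- function(vertices, dims) {
  n <- nrow(vertices)
  nxt <- c(2:n, 1L)
  out <- matrix(NA_real_, dims[1], dims[2])
  for (r in seq_len(dims[1])) {
    for (c in seq_len(dims[2])) {
      p <- c(r, c)
      dmin <- Inf
      inside <- FALSE
      for (i in seq_len(n)) {
        a <- vertices[i, ]; b <- vertices[nxt[i], ]
        ab <- b - a
        len2 <- sum(ab^2)
        t <- if (len2 > 0) max(0, min(1, sum((p - a) * ab) / len2)) else 0
        dmin <- min(dmin, sqrt(sum((a + t * ab - p)^2)))
        if ((a[1] > p[1]) != (b[1] > p[1])) {
          xc <- a[2] + (p[1] - a[1]) / (b[1] - a[1]) * (b[2] - a[2])
          if (p[2] < xc) inside <- !inside
        }
      }
      out[r, c] <- if (inside) dmin else -dmin
    }
  }
  out
}

# segment + masks + participant threshold for a single rendered image
analyse_one_fibre <- function(img, spec = effect_spec()) {
  ct <- segment_membrane(img$dystrophin)
  dmap <- signed_distance_map(ct, dim(img$dystrophin))
  layers <- build_layer_masks(dmap, spec$pixel_size_um)
  thr <- participant_threshold(list(img$glut4), list(layers$band_union))
  list(contour = ct, dmap = dmap, layers = layers, threshold = thr)
}
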