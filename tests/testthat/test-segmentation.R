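test_that("snake recovers a noiseless circular ring to sub-pixel accuracy", {
  n <- 160
  centre <- (n + 1) / 2
  rr <- sqrt((row(matrix(0, n, n)) - centre)^2 +
             (col(matrix(0, n, n)) - centre)^2)
  ring <- 100 + 900 * exp(-(rr - 50)^2 / (2 * 1.3^2))
  ct <- segment_membrane(ring)
  expect_true(ct$converged)
  radii <- sqrt((ct$vertices[, 1] - centre)^2 + (ct$vertices[, 2] - centre)^2)
  expect_lt(sqrt(mean((radii - 50)^2)), 0.5)
})

test_that("snake tracks noisy phantom membranes within 1 px RMS", {
  spec <- effect_spec()
  set.seed(17)
  rms <- numeric(5)
  for (i in 1:5) {
    ph <- generate_fibre_phantom(
      spec, list(group = "trained", infusion = "lipid", timepoint_h = 0))
    img <- render_fibre_image(ph, spec)
    ct <- segment_membrane(img$dystrophin)
    # radial error = true signed distance evaluated at the fitted vertices
    err <- glut4layers:::interp_bilinear(ph$dmap, ct$vertices[, 1],
                                         ct$vertices[, 2])
    rms[i] <- sqrt(mean(err^2))
  }
  expect_lt(mean(rms), 1)
})

test_that("degenerate dystrophin inputs raise segmentation failures", {
  blank <- matrix(100, 96, 96)
  expect_error(segment_membrane(blank), class = "glut4_segmentation_failure")
  # ring truncated by the image border cannot be closed
  n <- 96
  rr <- sqrt((row(matrix(0, n, n)) - 10)^2 + (col(matrix(0, n, n)) - 48)^2)
  open_ring <- 100 + 900 * exp(-(rr - 40)^2 / (2 * 1.3^2))
  expect_error(segment_membrane(open_ring),
               class = "glut4_segmentation_failure")
})

test_that("signed distance matches the closed form for a circle", {
  v <- circle_contour(20, c(32.5, 32.5), 256)
  d <- signed_distance_map(v, c(64, 64))
  rr <- sqrt((row(d) - 32.5)^2 + (col(d) - 32.5)^2)
  expect_lt(max(abs(d - (20 - rr))), 0.5)
})

test_that("signed distance is 1-Lipschitz across neighbouring pixels", {
  set.seed(8)
  v <- circle_contour(15, c(30, 30), 64) + matrix(rnorm(128, 0, 1), 64, 2)
  d <- signed_distance_map(v, c(60, 60))
  expect_lte(max(abs(diff(d))), 1 + 1e-9)        # vertical neighbours
  expect_lte(max(abs(diff(t(d)))), 1 + 1e-9)     # horizontal neighbours
})

test_that("signed distance equals the brute-force point-to-segment oracle", {
  set.seed(12)
  th <- sort(runif(9, 0, 2 * pi))
  v <- cbind(32 + runif(9, 10, 24) * sin(th), 32 + runif(9, 10, 24) * cos(th))
  d <- signed_distance_map(v, c(64, 64))
  oracle <- brute_force_signed_distance(v, c(64, 64))
  expect_lt(max(abs(d - oracle)), 1e-8)
})

test_that("layer rules reproduce the analytic annuli of a circle", {
  px <- 0.2 # um/px -> 1 um layer = 5 px
  v <- circle_contour(50, c(61, 61), 512)
  d <- signed_distance_map(v, c(121, 121))
  layers <- build_layer_masks(d, px)

  # PM band is the |d| <= 1.5 px band, i.e. 3 px thick along the normal
  expect_identical(layers$pm, abs(d) <= 1.5)
  expect_lt(abs(sum(layers$pm) / (2 * pi * 50) - 3), 0.05)

  # layer-1 pixels lie at distances in (1.5, 6.5] px
  d1 <- d[layers$inner[[1]]]
  expect_true(all(d1 > 1.5 & d1 <= 6.5))

  # areas match the analytic annuli within 2%
  for (k in 1:5) {
    r_out <- 50 - 1.5 - (k - 1) * 5
    r_in <- 50 - 1.5 - k * 5
    analytic <- pi * (r_out^2 - r_in^2)
    expect_lt(abs(sum(layers$inner[[k]]) - analytic) / analytic, 0.02)
  }

  # masks are pairwise disjoint and cover the band plus interior
  all_masks <- c(list(layers$pm), layers$inner, list(layers$interior))
  for (i in seq_along(all_masks))
    for (j in seq_along(all_masks))
      if (i < j) expect_false(any(all_masks[[i]] & all_masks[[j]]))
  union <- Reduce(`|`, all_masks)
  expect_identical(union, layers$band_union)
})

test_that("degenerate fibres trigger layer warnings and errors", {
  # fibre too small to hold any layer
  v <- circle_contour(2, c(16, 16), 64)
  d <- signed_distance_map(v, c(32, 32))
  expect_error(build_layer_masks(d, 0.2), "too small")
  # fibre with empty outer layers but a non-empty last layer cannot occur
  # on a disc; a thin fibre yields empty-layer warnings instead
  v <- circle_contour(17, c(24, 24), 128)
  d <- signed_distance_map(v, c(48, 48))
  expect_warning(build_layer_masks(d, 0.2), "empty layer")
})

test_that("layer_of_distance agrees with mask membership", {
  v <- circle_contour(40, c(51, 51), 256)
  d <- signed_distance_map(v, c(101, 101))
  layers <- build_layer_masks(d, 0.2)
  lab <- layer_of_distance(as.vector(d), 0.2)
  expect_identical(which(lab == "PM"), which(layers$pm))
  expect_identical(which(lab == "L3"), which(layers$inner[[3]]))
  expect_identical(which(lab == "interior"), which(layers$interior))
})
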