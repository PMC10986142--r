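test_that("pooled Otsu equals the brute-force between-class maximizer", {
  # two well-separated Gaussian modes
  set.seed(4)
  v <- round(c(rnorm(8000, 50, 10), rnorm(2000, 200, 10)))
  v <- pmin(pmax(v, 0), 65535)
  expect_same_otsu(v)

  # randomized histograms: mixtures with random means, sds, weights
  for (i in 1:20) {
    set.seed(100 + i)
    n1 <- sample(200:2000, 1); n2 <- sample(200:2000, 1)
    v <- round(c(rnorm(n1, runif(1, 20, 120), runif(1, 3, 25)),
                 rnorm(n2, runif(1, 150, 400), runif(1, 3, 40))))
    v <- pmax(v, 0)
    expect_same_otsu(v)
  }
})

test_that("participant pooling is idempotent and rejects degenerate input", {
  img <- matrix(round(c(rnorm(200, 50, 5), rnorm(56, 200, 5))), 16, 16)
  t1 <- participant_threshold(list(img))
  t2 <- participant_threshold(list(img, img))
  expect_identical(t1, t2)
  expect_error(pooled_otsu(rep(7, 100)), class = "glut4_threshold_error")
  expect_error(participant_threshold(list(matrix(3, 8, 8))),
               class = "glut4_threshold_error")
})

test_that("noiseless spots are detected with the stated size and layer", {
  spec <- effect_spec()
  centre <- 81
  # spot on the membrane (1.5 um -> large, PM) and one in layer 3 (0.5 um)
  # layer 3 at 0.2 um/px: d in (11.5, 16.5] px from midline; r = 60 px
  sp <- rbind(
    spot_row(centre, centre + 60, 1.5, "large", "PM"),
    spot_row(centre, centre - 60 + 14, 0.5, "small", "L3"))
  ph <- make_circle_phantom(sp, 160, 60, spec)
  img <- render_fibre_image(ph, spec, noise = FALSE)
  a <- analyse_one_fibre(img, spec)
  spots <- detect_spots(img$glut4, a$threshold, a$layers, a$dmap)
  expect_identical(nrow(spots), 2L)
  pm_spot <- spots[spots$layer == "PM", ]
  l3_spot <- spots[spots$layer == "L3", ]
  expect_identical(nrow(pm_spot), 1L)
  expect_identical(as.character(pm_spot$size_class), "large")
  expect_identical(nrow(l3_spot), 1L)
  expect_identical(as.character(l3_spot$size_class), "small")
})

test_that("spot counts are conserved across layers and size classes", {
  spec <- effect_spec()
  set.seed(23)
  ph <- generate_fibre_phantom(
    spec, list(group = "sedentary", infusion = "lipid", timepoint_h = 0))
  img <- render_fibre_image(ph, spec)
  a <- analyse_one_fibre(img, spec)
  m <- measure_fibre(img, a$layers, a$dmap, a$threshold, image_id = "f1")
  counts <- m$measurement[, grepl("^(small|large)_", names(m$measurement))]
  in_layers <- sum(m$spots$layer %in% c("PM", paste0("L", 1:5)))
  expect_identical(sum(unlist(counts)), in_layers)
})

test_that("positive rescaling leaves detection invariant, scales intensity", {
  spec <- effect_spec()
  set.seed(29)
  ph <- generate_fibre_phantom(
    spec, list(group = "trained", infusion = "glycerol", timepoint_h = 0))
  img <- render_fibre_image(ph, spec)
  a <- analyse_one_fibre(img, spec)
  spots <- detect_spots(img$glut4, a$threshold, a$layers, a$dmap)
  ints <- layer_intensities(img$glut4, a$layers)
  for (s in c(3, 2.5)) {
    scaled <- img$glut4 * s
    thr_s <- participant_threshold(list(scaled), list(a$layers$band_union))
    spots_s <- detect_spots(scaled, thr_s, a$layers, a$dmap)
    expect_identical(nrow(spots_s), nrow(spots))
    expect_identical(spots_s$size_class, spots$size_class)
    expect_identical(spots_s$layer, spots$layer)
    ints_s <- layer_intensities(scaled, a$layers)
    expect_equal(ints_s$mean_intensity, s * ints$mean_intensity,
                 tolerance = 1e-12)
  }
})

test_that("layer intensities are masked arithmetic means", {
  v <- circle_contour(12, c(16, 16), 128)
  d <- signed_distance_map(v, c(32, 32))
  suppressWarnings(layers <- build_layer_masks(d, 0.5))
  uni <- matrix(7.5, 32, 32)
  ints <- layer_intensities(uni, layers)
  expect_true(all(ints$mean_intensity[ints$n_pixels > 0] == 7.5))
  # empty masks are missing, not zero
  expect_true(all(is.na(ints$mean_intensity[ints$n_pixels == 0])))

  # hand-computed toy means
  toy <- matrix(seq_len(32 * 32), 32, 32)
  ints2 <- layer_intensities(toy, layers)
  expect_equal(ints2$mean_intensity[ints2$layer == "PM"],
               mean(toy[layers$pm]))
  expect_equal(ints2$mean_intensity[ints2$layer == "fibre"],
               mean(toy[layers$fibre]))
})

test_that("PCC reproduces exact and sampled correlations", {
  m <- matrix(runif(400, 10, 50), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(colocalization_pcc(m, m, mask), 1.0)
  expect_equal(colocalization_pcc(m, 3.2 * m + 11, mask), 1.0)

  set.seed(41)
  n <- 1e4
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- colocalization_pcc(matrix(x, 100, 100), matrix(y, 100, 100),
                            matrix(TRUE, 100, 100))
    se <- (1 - rho^2) / sqrt(n)
    expect_lt(abs(r - rho), 3 * se + 1e-6)
  }

  flat <- matrix(1, 20, 20)
  expect_error(colocalization_pcc(m, flat, mask), class = "glut4_pcc_error")
  one_px <- matrix(FALSE, 20, 20); one_px[1, 1] <- TRUE
  expect_error(colocalization_pcc(m, m, one_px), class = "glut4_pcc_error")
})

test_that("fibre typing splits a separated cohort and falls back otherwise", {
  res <- classify_fibre_types(c(10, 11, 12, 200, 210))
  expect_identical(as.character(res$fibre_type), c("II", "II", "II", "I", "I"))

  expect_warning(res1 <- classify_fibre_types(500), "bimodal")
  expect_identical(as.character(res1$fibre_type), "I") # above fallback cut
  expect_warning(res2 <- classify_fibre_types(c(100, 101, 102, 103)),
                 "bimodal")
  expect_true(all(res2$fibre_type == "II"))
})
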