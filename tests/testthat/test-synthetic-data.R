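test_that("effect spec validates proportions and rates", {
  expect_s3_class(effect_spec(), "glut4_effect_spec")
  expect_error(effect_spec(trained_small_fraction_pm = 1.2), "proportions")
  expect_error(effect_spec(spot_rates = c(PM = -1, L1 = 1, L2 = 1, L3 = 1,
                                          L4 = 1, L5 = 1)), "nonnegative")
  expect_error(effect_spec(pixel_size_um = 0), "pixel_size_um")
})

test_that("phantom geometry respects margins and ground-truth layer labels", {
  spec <- effect_spec(field_um = 32)
  set.seed(5)
  for (rep in 1:5) {
    ph <- generate_fibre_phantom(
      spec, list(group = "sedentary", infusion = "glycerol", timepoint_h = 2))
    # boundary entirely inside the field with >= 2 um margin
    expect_true(all(ph$boundary_um >= 2 - 1e-9))
    expect_true(all(ph$boundary_um <= spec$field_um - 2 + 1e-9))
    sp <- ph$planted_spots
    if (nrow(sp) == 0) next
    # every spot centre inside the membrane band (PM spots may sit in the
    # outer half of the band, i.e. just outside the midline), and its true
    # layer label equal to the label the segmentation-layer rules give its
    # signed distance
    d <- ph$dmap[cbind(sp$row_px, sp$col_px)]
    expect_true(all(d >= -1.5))
    relab <- layer_of_distance(d, spec$pixel_size_um)
    expect_equal(as.character(relab), as.character(sp$layer))
  }
})

test_that("zero spot rates give an empty planted-spot table", {
  spec <- effect_spec(spot_rates = c(PM = 0, L1 = 0, L2 = 0, L3 = 0,
                                     L4 = 0, L5 = 0), field_um = 32)
  set.seed(1)
  ph <- generate_fibre_phantom(
    spec, list(group = "trained", infusion = "lipid", timepoint_h = 0))
  expect_identical(nrow(ph$planted_spots), 0L)
})

test_that("oversized spot diameters are rejected", {
  spec <- effect_spec(large_diameter_um = c(20, 40), field_um = 32)
  set.seed(1)
  expect_error(generate_fibre_phantom(
    spec, list(group = "trained", infusion = "lipid", timepoint_h = 0)),
    "diameters")
})

test_that("per-layer spot counts and size mix match the sampler's moments", {
  # counts are Poisson(rate); small counts binomial given the total;
  # compare empirical layer means against exact moments at 3 SE
  spec <- effect_spec(field_um = 28)
  n_rep <- 400
  set.seed(99)
  counts <- matrix(0, n_rep, 6,
                   dimnames = list(NULL, c("PM", paste0("L", 1:5))))
  n_small_pm <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ph <- generate_fibre_phantom(
      spec, list(group = "trained", infusion = "lipid", timepoint_h = 0))
    tab <- table(ph$planted_spots$layer)
    counts[r, ] <- tab[colnames(counts)]
    sp <- ph$planted_spots
    n_small_pm[r] <- sum(sp$layer == "PM" & sp$size_class == "small")
  }
  for (ly in colnames(counts)) {
    lam <- spec$spot_rates[[ly]]
    se <- sqrt(lam / n_rep)
    expect_lt(abs(mean(counts[, ly]) - lam), 3 * se)
  }
  # small-spot share at the PM: binomial mean 0.99 in trained
  expect_lt(abs(sum(n_small_pm) / sum(counts[, "PM"]) - 0.99),
            3 * sqrt(0.99 * 0.01 / sum(counts[, "PM"])))
})

test_that("rendering is deterministic and reproduces planted spot size", {
  spec <- effect_spec()
  # noiseless single planted spot: thresholded equivalent diameter within
  # 1 px of the planted full width at half maximum
  for (d_um in c(1.0, 1.5, 2.0)) {
    ph <- make_circle_phantom(
      spot_row(81, 81, d_um, "large", "interior"), 160, 60, spec)
    img <- render_fibre_image(ph, spec, noise = FALSE)
    # threshold exactly at half the peak height above the local level
    local_bg <- img$glut4[5, 5] + 0.2 * spec$base_intensity
    thr <- local_bg + (max(img$glut4) - local_bg) / 2
    area <- sum(img$glut4 > thr)
    eqd_px <- 2 * sqrt(area / pi)
    expect_lt(abs(eqd_px - d_um / spec$pixel_size_um), 1)
  }

  set.seed(3)
  ph <- generate_fibre_phantom(
    effect_spec(field_um = 32),
    list(group = "trained", infusion = "lipid", timepoint_h = 0))
  set.seed(11); img1 <- render_fibre_image(ph, effect_spec(field_um = 32))
  set.seed(11); img2 <- render_fibre_image(ph, effect_spec(field_um = 32))
  expect_identical(img1$glut4, img2$glut4)
  expect_identical(img1$dystrophin, img2$dystrophin)
  expect_identical(img1$mhc1, img2$mhc1)
})

test_that("study generator is seed-reproducible and tracks its design", {
  spec <- effect_spec(field_um = 28)
  s1 <- simulate_study(spec, n_subjects_per_cell = 1,
                       images_per_timepoint = 1, seed = 21)
  s2 <- simulate_study(spec, n_subjects_per_cell = 1,
                       images_per_timepoint = 1, seed = 21)
  expect_identical(s1$images[[1]]$glut4, s2$images[[1]]$glut4)
  expect_identical(s1$truth, s2$truth)
  expect_identical(nrow(s1$design), 2L * 2L * 1L * 3L)
  expect_setequal(names(s1$images), s1$design$image_id)
  # one ground-truth entry per image, matching the phantom's spots
  expect_identical(names(s1$truth), s1$design$image_id)
})

test_that("measurement-level generator realizes the encoded PCC uplift", {
  # +9% encoded for sedentary-lipid at 2 h: realized mean uplift within
  # Monte-Carlo error of the encoded value
  spec <- effect_spec()
  m <- simulate_measurements(spec, n_subjects_per_cell = 12,
                             fibres_per_timepoint = 40, seed = 31)
  cell <- m[m$group == "sedentary" & m$infusion == "lipid", ]
  m0 <- mean(cell$pcc[cell$timepoint_h == 0])
  m2 <- mean(cell$pcc[cell$timepoint_h == 2])
  uplift <- (m2 - m0) / m0
  n0 <- sum(cell$timepoint_h == 0)
  # subject intercepts dominate the error of a cell mean
  se <- sqrt(2) * sqrt(spec$subject_sd$pcc^2 / 12 +
                       spec$pcc_resid_sd^2 / n0) / m0
  expect_lt(abs(uplift - 0.09), 3 * se)
})

test_that("single-subject designs are refused", {
  expect_error(study_design(n_subjects_per_cell = 0), "n_subjects_per_cell")
})
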