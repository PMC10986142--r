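test_that("model preconditions are enforced", {
  m <- simulate_measurements(effect_spec(), 2, 5, seed = 1)
  one_subj <- m[m$subject_id == m$subject_id[1], ]
  expect_error(fit_mixed_model(one_subj, "pcc"), "2 subjects")
  zero_tp <- m[m$timepoint_h == 0, ]
  expect_error(fit_mixed_model(zero_tp, "pcc", fixed = "timepoint"),
               "single observed level")
  fit <- fit_mixed_model(m, "pcc", fixed = "timepoint")
  expect_error(posthoc_pairwise(fit, "layer"), "not in the model")
  expect_error(test_fixed_effect(fit, "group"), "not in the model")
})

test_that("three timepoints yield exactly the three biopsy contrasts", {
  m <- simulate_measurements(effect_spec(), 3, 8, seed = 2)
  fit <- fit_mixed_model(m, "pcc", fixed = "timepoint")
  ph <- posthoc_pairwise(fit, "timepoint")
  expect_identical(nrow(ph), 3L)
  expect_setequal(ph$comparison,
                  c("timepoint0 - timepoint2", "timepoint0 - timepoint6",
                    "timepoint2 - timepoint6"))
  # multiplicity adjustment never lowers a p value; p in [0, 1]
  expect_true(all(ph$adj.p.value >= ph$p.value - 1e-12))
  expect_true(all(ph$p.value >= 0 & ph$adj.p.value <= 1))
})

test_that("tidy and glance expose estimates and variance components", {
  m <- simulate_measurements(effect_spec(), 3, 10, seed = 3)
  fit <- fit_mixed_model(m, "pcc", fixed = c("timepoint", "group"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in%
                  names(td)))
  expect_true(any(grepl("timepoint", td$term)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_gt(gl$sd_residual, 0)
  # refit on identical data is deterministic
  fit2 <- fit_mixed_model(m, "pcc", fixed = c("timepoint", "group"))
  expect_equal(tidy(fit2)$estimate, td$estimate, tolerance = 1e-12)
})

test_that("zero between-subject variance is estimated near zero", {
  spec <- effect_spec(subject_sd = list(pcc = 0, lograte = 0,
                                        logintensity = 0))
  m <- simulate_measurements(spec, 5, 20, seed = 4)
  fit <- fit_mixed_model(m, "pcc", fixed = "timepoint")
  # REML leaves a small sampling floor (~resid_sd / sqrt(fibres per
  # subject) = 0.005 here); "near zero" means well under the default
  # generator's 0.02 between-subject SD
  expect_lt(glance(fit)$sd_subject, 0.015)
})

test_that("planted fixed effects are recovered with nominal CI coverage", {
  # true 0->2 h PCC shift of 0.05 held at 6 h; subject SD 0.02;
  # 20 subjects x 30 fibres; the timepoint-2 coefficient estimates 0.05
  spec <- effect_spec(
    pcc_baseline = c(trained = 0.5, sedentary = 0.5),
    pcc_delta_0_to_2h = c(trained_lipid = 0.1, trained_glycerol = 0.1,
                          sedentary_lipid = 0.1, sedentary_glycerol = 0.1),
    subject_sd = list(pcc = 0.02, lograte = 0.15, logintensity = 0.10))
  n_rep <- 100
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    m <- simulate_measurements(spec, 5, 30, seed = 1000 + r)
    td <- tidy(fit_mixed_model(m, "pcc", fixed = "timepoint"))
    row <- td[td$term == "timepoint2", ]
    half <- stats::qt(0.975, row$df) * row$std.error
    covered[r] <- abs(row$estimate - 0.05) <= half
  }
  expect_gte(sum(covered), 93)
})

test_that("summary tables reproduce hand arithmetic and guard empty cells", {
  toy <- tibble::tibble(
    image_id = paste0("i", 1:6), subject_id = rep(c("a", "b"), 3),
    group = rep("trained", 6), infusion = rep("lipid", 6),
    timepoint_h = rep(c(0, 2, 6), 2),
    fibre_type = factor(rep(c("I", "II"), 3), levels = c("I", "II")),
    total_intensity = c(10, 20, 30, 40, 50, 60),
    pcc = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  for (ly in c("PM", paste0("L", 1:5))) {
    toy[[paste0("small_", ly)]] <- 0L
    toy[[paste0("large_", ly)]] <- 0L
    toy[[paste0("intensity_", ly)]] <- 1
  }
  toy$small_PM <- c(9L, 9L, 9L, 9L, 9L, 9L)
  toy$large_PM <- c(1L, 1L, 1L, 1L, 1L, 1L)
  s <- summarize_study(toy)
  expect_equal(s$pcc$mean_pcc[s$pcc$timepoint_h == 0], mean(c(0.1, 0.4)))
  expect_equal(
    s$intensity_by_type$mean_intensity[s$intensity_by_type$fibre_type == "I"],
    mean(c(10, 30, 50)))
  pm <- s$small_fraction[s$small_fraction$layer == "PM", ]
  expect_equal(pm$small_fraction, 54 / 60)
  # layers with no spots report a missing fraction, not 0/0
  l2 <- s$small_fraction[s$small_fraction$layer == "L2", ]
  expect_true(is.na(l2$small_fraction))
  expect_error(summarize_study(toy[0, ]), "empty")
})

test_that("trained fibres generated near 97% small report that fraction", {
  m <- simulate_measurements(effect_spec(), 5, 30, seed = 6)
  s <- summarize_study(m)
  tr <- s$overall_small_fraction[s$overall_small_fraction$group == "trained", ]
  expect_lt(abs(tr$small_fraction - 0.97), 0.01)
})
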