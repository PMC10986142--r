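#' Build the factorial study design table
#'
#' Crosses training group (trained/sedentary) with infusion (lipid/glycerol)
#' between subjects, with repeated biopsies at the given timepoints within
#' subject. Defaults mirror the emulated study: sequential biopsies at 0, 2
#' and 6 h and at least 30 images per participant per timepoint.
#'
#' @param n_subjects_per_cell subjects in each group x infusion cell.
#' @param images_per_timepoint fibre images per subject per timepoint.
#' @param timepoints_h biopsy timepoints in hours.
#' @return tibble with one row per image: `image_id`, `subject_id`, `group`,
#'   `infusion`, `timepoint_h`.
#' @export
study_design <- function(n_subjects_per_cell = 5L,
                         images_per_timepoint = 30L,
                         timepoints_h = c(0, 2, 6)) {
  stopifnot(n_subjects_per_cell >= 1, images_per_timepoint >= 1)
  cells <- tidyr::expand_grid(
    group = c("trained", "sedentary"),
    infusion = c("lipid", "glycerol"),
    subject_rep = seq_len(n_subjects_per_cell)
  )
  cells$subject_id <- sprintf("S%02d", seq_len(nrow(cells)))
  design <- tidyr::expand_grid(
    cells, timepoint_h = timepoints_h,
    image_rep = seq_len(images_per_timepoint)
  )
  design$image_id <- sprintf("img%05d", seq_len(nrow(design)))
  if (length(unique(design$subject_id)) < 2L)
    rlang::abort("design must contain at least 2 subjects overall")
  design[, c("image_id", "subject_id", "group", "infusion", "timepoint_h")]
}

#' Generate a rendered synthetic study with ground truth
#'
#' Draws subject-level random intercepts (log-normal multipliers on spot
#' rates and intensities), generates one fibre phantom per design row under
#' its condition, renders each phantom to a three-channel image, and returns
#' the images, the design table, and the full ground truth (true contour,
#' planted spots, true fibre type per image).
#'
#' @param spec an [effect_spec()].
#' @param n_subjects_per_cell,images_per_timepoint,timepoints_h passed to
#'   [study_design()]; the defaults are the emulated study design. Rendered
#'   studies at the full default size are large; tests and examples use
#'   smaller designs.
#' @param noise render with the spec's noise model.
#' @param seed optional integer seed; identical seed and spec give a
#'   bit-identical study.
#' @return A `glut4_study`: list with `images` (named list of
#'   `fibre_image`), `design` (tibble) and `truth` (named list per image:
#'   `contour_px`, `spots`, `fibre_type`, `condition`).
#' @export
simulate_study <- function(spec = effect_spec(),
                           n_subjects_per_cell = 5L,
                           images_per_timepoint = 30L,
                           timepoints_h = c(0, 2, 6),
                           noise = TRUE, seed = NULL) {
  stopifnot(inherits(spec, "glut4_effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  design <- study_design(n_subjects_per_cell, images_per_timepoint,
                         timepoints_h)
  subjects <- unique(design$subject_id)
  u_rate <- setNames(rnorm(length(subjects), 0, spec$subject_sd$lograte),
                     subjects)
  u_int <- setNames(rnorm(length(subjects), 0, spec$subject_sd$logintensity),
                    subjects)
  images <- vector("list", nrow(design))
  truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    ph <- generate_fibre_phantom(
      spec,
      condition = list(group = row$group, infusion = row$infusion,
                       timepoint_h = row$timepoint_h),
      rate_multiplier = exp(u_rate[[row$subject_id]]),
      intensity_multiplier = exp(u_int[[row$subject_id]])
    )
    img <- render_fibre_image(ph, spec, noise = noise)
    img$image_id <- row$image_id
    images[[i]] <- img
    truth[[i]] <- list(
      contour_px = ph$boundary_px,
      spots = ph$planted_spots,
      fibre_type = ph$fibre_type,
      condition = ph$condition
    )
  }
  names(images) <- design$image_id
  names(truth) <- design$image_id
  structure(list(images = images, design = design, truth = truth,
                 spec = spec),
            class = "glut4_study")
}

#' @export
print.glut4_study <- function(x, ...) {
  cat(sprintf("<glut4_study> %d images, %d subjects, timepoints %s h\n",
              nrow(x$design), length(unique(x$design$subject_id)),
              paste(sort(unique(x$design$timepoint_h)), collapse = "/")))
  invisible(x)
}

#' Simulate a per-fibre measurement table directly
#'
#' Draws the per-fibre measurement table from the same generative model as
#' the rendered study — identical condition-level PCC means, per-layer spot
#' rates, small-spot mixes, intensity contrasts and subject random
#' intercepts — without rendering or re-measuring images. This is the
#' measurement-level view of the generator used for statistical parameter
#' recovery and calibration at realistic study sizes.
#'
#' @param spec an [effect_spec()].
#' @param n_subjects_per_cell,fibres_per_timepoint,timepoints_h study size;
#'   defaults are the emulated design.
#' @param seed optional integer seed.
#' @return tibble with one row per fibre in the same wide layout the imaging
#'   pipeline produces (`image_id`, `subject_id`, `group`, `infusion`,
#'   `timepoint_h`, `fibre_type`, `total_intensity`, `intensity_*`,
#'   `small_*`, `large_*`, `pcc`), with the condition-level true values
#'   attached as attribute `"truth"`.
#' @export
simulate_measurements <- function(spec = effect_spec(),
                                  n_subjects_per_cell = 5L,
                                  fibres_per_timepoint = 30L,
                                  timepoints_h = c(0, 2, 6),
                                  seed = NULL) {
  stopifnot(inherits(spec, "glut4_effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  design <- study_design(n_subjects_per_cell, fibres_per_timepoint,
                         timepoints_h)
  subjects <- unique(design$subject_id)
  u_pcc <- setNames(rnorm(length(subjects), 0, spec$subject_sd$pcc), subjects)
  u_rate <- setNames(rnorm(length(subjects), 0, spec$subject_sd$lograte),
                     subjects)
  u_int <- setNames(rnorm(length(subjects), 0, spec$subject_sd$logintensity),
                    subjects)
  layer_names <- c("PM", paste0("L", 1:5))
  # per-layer intensity profile: membrane-concentrated GLUT4
  profile <- c(PM = 1.0, L1 = 0.45, L2 = 0.35, L3 = 0.30, L4 = 0.27, L5 = 0.25)

  n <- nrow(design)
  fibre_type <- sample(c("I", "II"), n, replace = TRUE,
                       prob = c(spec$p_type1, 1 - spec$p_type1))
  out <- design
  out$fibre_type <- factor(fibre_type, levels = c("I", "II"))

  mu_pcc <- mapply(condition_pcc,
                   group = design$group, infusion = design$infusion,
                   timepoint_h = design$timepoint_h,
                   MoreArgs = list(spec = spec))
  out$pcc <- pmin(pmax(
    mu_pcc + u_pcc[design$subject_id] + rnorm(n, 0, spec$pcc_resid_sd),
    -1), 1)

  imult <- exp(u_int[design$subject_id] + rnorm(n, 0, 0.10)) *
    ifelse(fibre_type == "II",
           1 + spec$type2_intensity_excess[design$group], 1)
  out$total_intensity <- spec$base_intensity * imult

  for (ly in layer_names) {
    f_small <- vapply(design$group, function(g) {
      if (ly == "PM") pm_small_fraction(spec, g) else spec$inner_small_fraction
    }, numeric(1))
    f_mix <- mapply(function(tp, g, fs)
      small_mix_at_time(spec, ly, tp, g, fs),
      design$timepoint_h, design$group, f_small)
    lam_tot <- spec$spot_rates[[ly]] * exp(u_rate[design$subject_id]) *
      mapply(function(tp, g) small_rate_time_factor_total(spec, ly, tp, g),
             design$timepoint_h, design$group)
    n_tot <- rpois(n, lam_tot)
    n_small <- rbinom(n, n_tot, f_mix)
    out[[paste0("small_", ly)]] <- n_small
    out[[paste0("large_", ly)]] <- n_tot - n_small
    out[[paste0("intensity_", ly)]] <- spec$base_intensity *
      profile[[ly]] * imult * exp(rnorm(n, 0, 0.05))
  }
  out <- tibble::as_tibble(out)
  attr(out, "truth") <- list(
    pcc_by_condition = unique(tibble::tibble(
      group = design$group, infusion = design$infusion,
      timepoint_h = design$timepoint_h, true_pcc = mu_pcc)),
    spot_rates = spec$spot_rates,
    small_spot_decline_2_to_6h = spec$small_spot_decline_2_to_6h
  )
  out
}
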