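#' Effect specification for the synthetic study generator
#'
#' Collects every tunable rate, effect size, and noise parameter of the
#' synthetic fibre-image generator into one validated object. The defaults
#' encode the study conditions the generator emulates: a small insulin-driven
#' rise in GLUT4-membrane colocalization from 0 to 2 h that is maintained at
#' 6 h (+2% in trained under both infusions, +9% in sedentary under lipid,
#' +4% in sedentary under glycerol), a decline in small-spot numbers at the
#' plasma membrane and layer 1 from 2 to 6 h, a small-spot share of plasma
#' membrane spots of ~99% in trained versus ~95% in sedentary fibres, and a
#' GLUT4 intensity excess of type II over type I fibres (~7% trained, ~12%
#' sedentary).
#'
#' @param pcc_baseline named numeric, baseline Pearson colocalization by
#'   training group (`trained`, `sedentary`).
#' @param pcc_delta_0_to_2h named numeric, proportional PCC increase from 0 to
#'   2 h for each `group_infusion` cell; the uplift is maintained at 6 h.
#' @param small_spot_decline_2_to_6h proportional decrease, between 2 h and
#'   6 h, of the small-spot rate in the plasma membrane and layer 1.
#' @param trained_small_fraction_pm,sedentary_small_fraction_pm proportion of
#'   plasma-membrane spots that are small, by training group.
#' @param inner_small_fraction small-spot proportion in layers 1-5; the
#'   default, together with the PM fractions and per-layer rates, puts the
#'   overall small-spot share in trained fibres near 97%.
#' @param spot_rates named numeric, mean number of spots per fibre in each of
#'   PM, L1..L5. Absolute per-fibre counts are free parameters of the
#'   generator, not literature claims.
#' @param type2_intensity_excess named numeric, proportional GLUT4 intensity
#'   excess of type II over type I fibres by training group.
#' @param p_type1 probability that a sampled fibre is type I.
#' @param base_intensity mean GLUT4 fibre intensity (arbitrary units) of a
#'   type I fibre at baseline.
#' @param small_diameter_um,large_diameter_um length-2 ranges (micrometres)
#'   from which small / large planted spot diameters are drawn uniformly.
#' @param spot_peak_mean,spot_peak_sd mean and sd of planted spot peak
#'   amplitude above background (16-bit counts).
#' @param membrane_peak dystrophin ring peak amplitude above background.
#' @param mhc1_positive,mhc1_negative mean MHC1 channel level inside type I /
#'   type II fibres.
#' @param background_mean,read_sd additive background level and Gaussian read
#'   noise sd (counts).
#' @param photon_scale gain of the Poisson photon-noise model; rendered
#'   intensity I is drawn as `photon_scale * rpois(I / photon_scale)`. Zero
#'   disables photon noise.
#' @param subject_sd named list of between-subject random-intercept standard
#'   deviations: `pcc` (additive), `lograte` and `logintensity`
#'   (log-normal multipliers on spot rates and intensities).
#' @param pcc_resid_sd residual sd of per-fibre PCC around its condition mean
#'   (used by the measurement-level simulator).
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @param field_um field of view (square) in micrometres.
#' @param membrane_thickness_um full width at half maximum of the rendered
#'   dystrophin ring.
#' @param bit_depth bit depth of rendered rasters.
#'
#' @return An object of class `glut4_effect_spec` (a validated list).
#' @examples
#' spec <- effect_spec()
#' spec$trained_small_fraction_pm
#' @export
effect_spec <- function(
    pcc_baseline = c(trained = 0.48, sedentary = 0.44),
    pcc_delta_0_to_2h = c(
      trained_lipid = 0.02, trained_glycerol = 0.02,
      sedentary_lipid = 0.09, sedentary_glycerol = 0.04
    ),
    small_spot_decline_2_to_6h = 0.25,
    trained_small_fraction_pm = 0.99,
    sedentary_small_fraction_pm = 0.95,
    inner_small_fraction = 0.94,
    spot_rates = c(PM = 30, L1 = 8, L2 = 6, L3 = 5, L4 = 4, L5 = 3),
    type2_intensity_excess = c(trained = 0.07, sedentary = 0.12),
    p_type1 = 0.5,
    base_intensity = 300,
    small_diameter_um = c(0.4, 0.6),
    large_diameter_um = c(1.3, 2.2),
    spot_peak_mean = 600,
    spot_peak_sd = 60,
    membrane_peak = 900,
    mhc1_positive = 800,
    mhc1_negative = 120,
    background_mean = 100,
    read_sd = 5,
    photon_scale = 0.5,
    subject_sd = list(pcc = 0.02, lograte = 0.15, logintensity = 0.10),
    pcc_resid_sd = 0.05,
    pixel_size_um = 0.2,
    field_um = 64,
    membrane_thickness_um = 0.6,
    bit_depth = 16L) {
  spec <- list(
    pcc_baseline = pcc_baseline,
    pcc_delta_0_to_2h = pcc_delta_0_to_2h,
    small_spot_decline_2_to_6h = small_spot_decline_2_to_6h,
    trained_small_fraction_pm = trained_small_fraction_pm,
    sedentary_small_fraction_pm = sedentary_small_fraction_pm,
    inner_small_fraction = inner_small_fraction,
    spot_rates = spot_rates,
    type2_intensity_excess = type2_intensity_excess,
    p_type1 = p_type1,
    base_intensity = base_intensity,
    small_diameter_um = small_diameter_um,
    large_diameter_um = large_diameter_um,
    spot_peak_mean = spot_peak_mean,
    spot_peak_sd = spot_peak_sd,
    membrane_peak = membrane_peak,
    mhc1_positive = mhc1_positive,
    mhc1_negative = mhc1_negative,
    background_mean = background_mean,
    read_sd = read_sd,
    photon_scale = photon_scale,
    subject_sd = subject_sd,
    pcc_resid_sd = pcc_resid_sd,
    pixel_size_um = pixel_size_um,
    field_um = field_um,
    membrane_thickness_um = membrane_thickness_um,
    bit_depth = as.integer(bit_depth)
  )
  validate_effect_spec(spec)
  structure(spec, class = "glut4_effect_spec")
}

validate_effect_spec <- function(spec) {
  props <- c(
    spec$small_spot_decline_2_to_6h, spec$trained_small_fraction_pm,
    spec$sedentary_small_fraction_pm, spec$inner_small_fraction,
    spec$p_type1
  )
  if (any(props < 0 | props > 1))
    rlang::abort("all proportions in the effect spec must lie in [0, 1]")
  nonneg <- c(
    spec$spot_rates, spec$base_intensity, spec$spot_peak_mean,
    spec$spot_peak_sd, spec$membrane_peak, spec$background_mean,
    spec$read_sd, spec$photon_scale, spec$pcc_resid_sd,
    unlist(spec$subject_sd), spec$type2_intensity_excess
  )
  if (any(nonneg < 0))
    rlang::abort("rates, intensities and noise scales must be nonnegative")
  for (nm in c("pixel_size_um", "field_um", "membrane_thickness_um"))
    assert_scalar_pos(spec[[nm]], nm)
  if (!setequal(names(spec$spot_rates), c("PM", paste0("L", 1:5))))
    rlang::abort("`spot_rates` must be named PM, L1..L5")
  stopifnot(
    all(c("trained", "sedentary") %in% names(spec$pcc_baseline)),
    all(c("trained_lipid", "trained_glycerol", "sedentary_lipid",
          "sedentary_glycerol") %in% names(spec$pcc_delta_0_to_2h)),
    all(c("trained", "sedentary") %in% names(spec$type2_intensity_excess))
  )
  invisible(spec)
}

#' @export
print.glut4_effect_spec <- function(x, ...) {
  cat("<glut4_effect_spec>\n")
  cat("  pixel size:", x$pixel_size_um, "um/px; field:", x$field_um, "um\n")
  cat("  spot rates:", paste(names(x$spot_rates), x$spot_rates,
                             sep = "=", collapse = " "), "\n")
  cat("  PM small fraction: trained", x$trained_small_fraction_pm,
      "/ sedentary", x$sedentary_small_fraction_pm, "\n")
  cat("  PCC uplift 0->2h:", paste(names(x$pcc_delta_0_to_2h),
                                   x$pcc_delta_0_to_2h,
                                   sep = "=", collapse = " "), "\n")
  invisible(x)
}

# multiplier applied to the small-spot rate of a layer at a timepoint
small_rate_time_factor <- function(spec, layer, timepoint_h) {
  if (timepoint_h >= 6 && layer %in% c("PM", "L1"))
    1 - spec$small_spot_decline_2_to_6h
  else 1
}

# condition-level mean PCC (before subject effects and residual noise)
condition_pcc <- function(spec, group, infusion, timepoint_h) {
  base <- spec$pcc_baseline[[group]]
  cell <- paste(group, infusion, sep = "_")
  uplift <- if (timepoint_h >= 2) spec$pcc_delta_0_to_2h[[cell]] else 0
  base * (1 + uplift)
}

# small-spot fraction at the plasma membrane for a training group
pm_small_fraction <- function(spec, group) {
  if (group == "trained") spec$trained_small_fraction_pm
  else spec$sedentary_small_fraction_pm
}
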