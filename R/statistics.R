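#' Fit a repeated-measures linear mixed model to fibre measurements
#'
#' Fits the analysis model of the pipeline: a linear mixed-effects model
#' with the chosen fixed factors (and optional interactions) and a random
#' intercept per subject to account for repeated fibres and biopsies within
#' participants. Fibres are the rows; the repeated-measures structure is
#' handled solely by the subject intercept. Count responses are modelled on
#' the `log1p` scale inside the Gaussian model by default (a Poisson GLMM is
#' available via `family = "poisson"`). Restricted maximum likelihood is
#' used for Gaussian fits, with Satterthwaite degrees of freedom.
#'
#' @param data measurement tibble (from [simulate_measurements()] or
#'   [run_pipeline()]), wide layout.
#' @param response one of `"pcc"`, `"total_intensity"`, `"layer_intensity"`,
#'   `"small_count"`, `"large_count"`, `"total_count"`. Layer-resolved
#'   responses pivot the wide table to long and add a `layer` factor.
#' @param fixed character vector of fixed factors, any of `"group"`,
#'   `"infusion"`, `"timepoint"`, `"fibre_type"`, `"layer"`.
#' @param interactions character vector of interaction terms, each written
#'   `"a:b"` with both factors in `fixed`.
#' @param family `"gaussian"` (default; counts log1p-transformed) or
#'   `"poisson"` (counts only, fitted with [lme4::glmer()]).
#' @param layers which layers to keep for layer-resolved responses.
#' @return A `glut4_fit`: the [lmerTest::lmer()] (or [lme4::glmer()]) fit
#'   plus the model specification, convergence and singularity flags. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
fit_mixed_model <- function(data, response, fixed = "timepoint",
                            interactions = character(),
                            family = c("gaussian", "poisson"),
                            layers = c("PM", paste0("L", 1:5))) {
  family <- match.arg(family)
  response <- match.arg(response, c(
    "pcc", "total_intensity", "layer_intensity",
    "small_count", "large_count", "total_count"))
  fixed <- match.arg(fixed, c("group", "infusion", "timepoint",
                              "fibre_type", "layer"), several.ok = TRUE)
  if (length(unique(data$subject_id)) < 2L)
    rlang::abort("mixed model needs at least 2 subjects (random intercept)")

  prep <- prepare_model_frame(data, response, layers)
  df <- prep$df
  term_map <- c(group = "group", infusion = "infusion",
                timepoint = "timepoint", fibre_type = "fibre_type",
                layer = "layer")
  terms <- unname(term_map[fixed])
  for (tm in terms)
    if (length(unique(df[[tm]])) < 2L)
      rlang::abort(sprintf("fixed factor `%s` has a single observed level", tm))
  rhs <- paste(c(terms, interactions, "(1 | subject_id)"), collapse = " + ")
  fml <- stats::as.formula(paste(prep$response_var, "~", rhs))

  if (family == "gaussian") {
    fit <- lmerTest::lmer(fml, data = df, REML = TRUE)
  } else {
    if (!prep$is_count)
      rlang::abort("poisson family is only available for count responses")
    fit <- lme4::glmer(fml, data = df, family = stats::poisson())
  }
  msgs <- fit@optinfo$conv$lme4$messages
  structure(
    list(fit = fit, response = response, fixed = fixed,
         interactions = interactions, family = family,
         singular = lme4::isSingular(fit),
         converged = is.null(msgs), convergence_messages = msgs,
         n_obs = nrow(df), n_subjects = length(unique(df$subject_id))),
    class = "glut4_fit"
  )
}

# pivot the wide measurement table into the model frame for a response
prepare_model_frame <- function(data, response, layers) {
  data <- dplyr::mutate(
    data,
    timepoint = factor(.data$timepoint_h),
    group = factor(.data$group),
    infusion = factor(.data$infusion),
    subject_id = factor(.data$subject_id)
  )
  if ("fibre_type" %in% names(data))
    data$fibre_type <- factor(data$fibre_type)
  is_count <- grepl("count$", response)
  if (response %in% c("pcc", "total_intensity")) {
    return(list(df = data, response_var = response, is_count = FALSE))
  }
  prefixes <- switch(response,
    layer_intensity = "intensity_",
    small_count = "small_",
    large_count = "large_",
    total_count = c("small_", "large_"))
  long <- data |>
    tidyr::pivot_longer(
      dplyr::matches("^(intensity|small|large)_(PM|L[0-9]+)$"),
      names_to = c("kind", "layer"), names_sep = "_",
      values_to = "value") |>
    dplyr::filter(.data$layer %in% layers)
  long$layer <- factor(long$layer, levels = c("PM", paste0("L", 1:5)))
  if (response == "total_count") {
    long <- long |>
      dplyr::filter(.data$kind %in% c("small", "large")) |>
      dplyr::group_by(dplyr::across(-dplyr::all_of(c("kind", "value")))) |>
      dplyr::summarise(value = sum(.data$value), .groups = "drop")
  } else {
    long <- dplyr::filter(long, paste0(.data$kind, "_") == prefixes[1])
  }
  if (is_count) long$log1p_value <- log1p(long$value)
  list(df = long,
       response_var = if (is_count) "log1p_value" else "value",
       is_count = is_count)
}

#' @export
print.glut4_fit <- function(x, ...) {
  cat(sprintf(
    "<glut4_fit> %s ~ %s + (1 | subject_id), %s family\n  %d fibres, %d subjects%s%s\n",
    x$response, paste(c(x$fixed, x$interactions), collapse = " + "),
    x$family, x$n_obs, x$n_subjects,
    if (x$singular) " [singular fit]" else "",
    if (!x$converged) " [convergence warning]" else ""))
  invisible(x)
}

#' Tidy the fixed effects of a fitted mixed model
#'
#' @param x a `glut4_fit`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `df`, `statistic`,
#'   `p.value` (Satterthwaite df for Gaussian fits).
#' @export
tidy.glut4_fit <- function(x, ...) {
  cf <- stats::coef(summary(x$fit))
  out <- tibble::tibble(term = rownames(cf))
  out$estimate <- cf[, "Estimate"]
  out$std.error <- cf[, "Std. Error"]
  out$df <- if ("df" %in% colnames(cf)) cf[, "df"] else NA_real_
  stat_col <- intersect(c("t value", "z value"), colnames(cf))[1]
  out$statistic <- cf[, stat_col]
  p_col <- intersect(c("Pr(>|t|)", "Pr(>|z|)"), colnames(cf))[1]
  out$p.value <- if (!is.na(p_col)) cf[, p_col] else NA_real_
  out
}

#' One-line summary of a fitted mixed model
#'
#' @param x a `glut4_fit`.
#' @param ... unused.
#' @return one-row tibble with variance components (`sd_subject`,
#'   `sd_residual`), log-likelihood, AIC, sample sizes and fit flags.
#' @export
glance.glut4_fit <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  sd_subj <- vc$sdcor[vc$grp == "subject_id"][1]
  sd_resid <- if (any(vc$grp == "Residual"))
    vc$sdcor[vc$grp == "Residual"][1] else NA_real_
  tibble::tibble(
    sd_subject = sd_subj, sd_residual = sd_resid,
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit),
    nobs = x$n_obs, n_subjects = x$n_subjects,
    singular = x$singular, converged = x$converged
  )
}

#' F-test of a fixed factor in a fitted mixed model
#'
#' Type-III test of one fixed factor (Satterthwaite degrees of freedom for
#' Gaussian fits; Wald chi-square for Poisson fits).
#'
#' @param fit a `glut4_fit`.
#' @param factor name of a fixed factor in the fit (e.g. `"timepoint"`).
#' @return one-row tibble with `factor`, `statistic`, `df1`, `df2`,
#'   `p.value`.
#' @export
test_fixed_effect <- function(fit, factor = "timepoint") {
  stopifnot(inherits(fit, "glut4_fit"))
  if (!(factor %in% fit$fixed))
    rlang::abort(sprintf("factor `%s` is not in the model", factor))
  if (fit$family == "gaussian") {
    an <- stats::anova(fit$fit, type = 3)
    row <- an[factor, ]
    tibble::tibble(factor = factor,
                   statistic = row[["F value"]],
                   df1 = row[["NumDF"]], df2 = row[["DenDF"]],
                   p.value = row[["Pr(>F)"]])
  } else {
    an <- car::Anova(fit$fit, type = 3)
    row <- an[factor, ]
    tibble::tibble(factor = factor, statistic = row[["Chisq"]],
                   df1 = row[["Df"]], df2 = NA_real_,
                   p.value = row[["Pr(>Chisq)"]])
  }
}

#' Post-hoc pairwise contrasts of a fixed factor
#'
#' All pairwise contrasts between the levels of one fixed factor of a
#' fitted mixed model (estimated marginal means), with Bonferroni
#' multiplicity adjustment by default. Significance is read at adjusted
#' p < 0.05.
#'
#' @param fit a `glut4_fit`.
#' @param factor factor to contrast (e.g. `"timepoint"` for the three
#'   biopsies, or `"layer"`).
#' @param adjust multiplicity adjustment passed to emmeans (default
#'   `"bonferroni"`).
#' @return tibble with `comparison`, `estimate`, `std.error`, `df`,
#'   `statistic`, `p.value` (unadjusted), `adj.p.value`, `significant`.
#' @export
posthoc_pairwise <- function(fit, factor = "timepoint",
                             adjust = "bonferroni") {
  stopifnot(inherits(fit, "glut4_fit"))
  if (!(factor %in% fit$fixed))
    rlang::abort(sprintf("factor `%s` is not in the model", factor))
  df_method <- if (fit$n_obs <= 3000) "satterthwaite" else "asymptotic"
  emm <- emmeans::emmeans(fit$fit, specs = factor, lmer.df = df_method)
  raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  adj <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = adjust))
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(raw))[1]
  tibble::tibble(
    comparison = as.character(raw$contrast),
    estimate = raw$estimate,
    std.error = raw$SE,
    df = if ("df" %in% names(raw)) raw$df else NA_real_,
    statistic = raw[[stat_col]],
    p.value = raw$p.value,
    adj.p.value = pmin(adj$p.value, 1),
    significant = adj$p.value < 0.05
  )
}

#' Results-style summary tables for a measurement table
#'
#' Assembles the descriptive report the pipeline's results are read from:
#' colocalization by group, infusion and timepoint; total intensity by
#' fibre type and group; per-layer small/large spot counts by condition;
#' and per-layer small-spot fractions (small / (small + large), reported as
#' missing when a cell has no spots).
#'
#' @param data measurement tibble (wide layout).
#' @return named list of tibbles: `pcc`, `intensity_by_type`,
#'   `spot_counts`, `small_fraction`, `overall_small_fraction`.
#' @export
summarize_study <- function(data) {
  if (nrow(data) == 0L) rlang::abort("empty measurement table")
  pcc_tab <- data |>
    dplyr::group_by(.data$group, .data$infusion, .data$timepoint_h) |>
    dplyr::summarise(mean_pcc = mean(.data$pcc, na.rm = TRUE),
                     se_pcc = se_mean(.data$pcc),
                     n = dplyr::n(), .groups = "drop")
  int_tab <- data |>
    dplyr::group_by(.data$group, .data$fibre_type) |>
    dplyr::summarise(mean_intensity = mean(.data$total_intensity, na.rm = TRUE),
                     se_intensity = se_mean(.data$total_intensity),
                     n = dplyr::n(), .groups = "drop")
  long <- data |>
    tidyr::pivot_longer(dplyr::matches("^(small|large)_(PM|L[0-9]+)$"),
                        names_to = c("size_class", "layer"), names_sep = "_",
                        values_to = "count") |>
    dplyr::mutate(layer = factor(.data$layer,
                                 levels = c("PM", paste0("L", 1:5))))
  counts_tab <- long |>
    dplyr::group_by(.data$group, .data$infusion, .data$timepoint_h,
                    .data$layer, .data$size_class) |>
    dplyr::summarise(mean_count = mean(.data$count),
                     se_count = se_mean(.data$count),
                     .groups = "drop")
  frac_tab <- long |>
    tidyr::pivot_wider(names_from = "size_class", values_from = "count") |>
    dplyr::group_by(.data$group, .data$layer) |>
    dplyr::summarise(
      small = sum(.data$small), large = sum(.data$large), .groups = "drop") |>
    dplyr::mutate(small_fraction = ifelse(
      .data$small + .data$large > 0,
      .data$small / (.data$small + .data$large), NA_real_))
  overall <- frac_tab |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(small = sum(.data$small), large = sum(.data$large),
                     .groups = "drop") |>
    dplyr::mutate(small_fraction = ifelse(
      .data$small + .data$large > 0,
      .data$small / (.data$small + .data$large), NA_real_))
  list(pcc = pcc_tab, intensity_by_type = int_tab, spot_counts = counts_tab,
       small_fraction = frac_tab, overall_small_fraction = overall)
}
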