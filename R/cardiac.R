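# Derived echocardiographic indices. All functions are vectorised over
# animals; units follow the echo table: dimensions mm, volumes ul, heart
# rate bpm, mass mg, body weight g.

#' Stroke volume from left-ventricular volumes
#'
#' @param lv_vol_d,lv_vol_s Diastolic and systolic LV volume (ul), both
#'   positive with `lv_vol_d >= lv_vol_s`.
#' @return Stroke volume in ul: `lv_vol_d - lv_vol_s`.
#' @export
#' @examples
#' stroke_volume(61.44, 24.14)  # 37.3
stroke_volume <- function(lv_vol_d, lv_vol_s) {
  if (any(lv_vol_d <= 0) || any(lv_vol_s < 0)) {
    abort_domain("LV volumes must be positive")
  }
  if (any(lv_vol_s > lv_vol_d)) {
    abort_domain("systolic LV volume exceeds diastolic LV volume")
  }
  lv_vol_d - lv_vol_s
}

#' Ejection fraction from left-ventricular volumes
#'
#' @inheritParams stroke_volume
#' @return Ejection fraction in percent:
#'   `100 * (lv_vol_d - lv_vol_s) / lv_vol_d`.
#' @export
ejection_fraction <- function(lv_vol_d, lv_vol_s) {
  if (any(lv_vol_d <= 0)) abort_domain("diastolic LV volume must be > 0")
  if (any(lv_vol_s < 0) || any(lv_vol_s > lv_vol_d)) {
    abort_domain("systolic LV volume must lie in [0, lv_vol_d]")
  }
  100 * (lv_vol_d - lv_vol_s) / lv_vol_d
}

#' Fractional shortening from left-ventricular internal diameters
#'
#' @param lvid_d,lvid_s Diastolic and systolic LV internal diameter (mm).
#' @return Fractional shortening in percent:
#'   `100 * (lvid_d - lvid_s) / lvid_d`.
#' @export
fractional_shortening <- function(lvid_d, lvid_s) {
  if (any(lvid_d <= 0) || any(lvid_s <= 0)) {
    abort_domain("LV internal diameters must be > 0")
  }
  if (any(lvid_s > lvid_d)) {
    abort_domain("systolic LVID exceeds diastolic LVID")
  }
  100 * (lvid_d - lvid_s) / lvid_d
}

#' Cardiac output from stroke volume and heart rate
#'
#' @param sv Stroke volume (ul), non-negative.
#' @param hr Heart rate (bpm), positive.
#' @return Cardiac output in ml/min: `sv * hr / 1000`.
#' @export
cardiac_output <- function(sv, hr) {
  if (any(sv < 0)) abort_domain("stroke volume must be >= 0")
  if (any(hr <= 0)) abort_domain("heart rate must be > 0")
  sv * hr / 1000
}

#' Left-ventricular mass by the corrected cube convention
#'
#' `mass = 1.053 * ((lvid_d + lvpw_d + lvaw_d)^3 - lvid_d^3)` with the
#' standard 0.8 correction factor applied for the corrected mass, so
#' `corrected / mass = 0.8` for all inputs.
#'
#' @param lvid_d LV internal diameter at diastole (mm).
#' @param lvpw_d LV posterior wall thickness at diastole (mm).
#' @param lvaw_d LV anterior wall thickness at diastole (mm).
#' @return A tibble with columns `lv_mass` and `lv_mass_corrected` (mg).
#' @export
lv_mass <- function(lvid_d, lvpw_d, lvaw_d) {
  if (any(lvid_d <= 0) || any(lvpw_d <= 0) || any(lvaw_d <= 0)) {
    abort_domain("LV dimensions must be > 0")
  }
  mass <- 1.053 * ((lvid_d + lvpw_d + lvaw_d)^3 - lvid_d^3)
  tibble::tibble(lv_mass = mass, lv_mass_corrected = 0.8 * mass)
}

#' Heart-weight to body-weight ratio, an index of hypertrophy
#'
#' @param heart_weight Heart weight (mg), positive.
#' @param body_weight Body weight (g), positive.
#' @return Ratio in mg/g.
#' @export
hypertrophy_index <- function(heart_weight, body_weight) {
  if (any(heart_weight <= 0)) abort_domain("heart weight must be > 0")
  if (any(body_weight <= 0)) abort_domain("body weight must be > 0")
  heart_weight / body_weight
}

#' Derive all cardiac indices for a per-animal echo table
#'
#' Adds, per animal: stroke volume, ejection fraction, fractional
#' shortening, cardiac output, LV mass and corrected LV mass, heart-weight
#' to body-weight ratio (when necropsy columns are present) and the mitral
#' valve E/A ratio (when Doppler columns are present). Group summaries
#' should be computed from these per-animal values and then averaged
#' ([summarize_cardiac()]): for ratio-based indices (EF, FS, CO) this is
#' *not* the same as applying the formula to group-mean inputs.
#'
#' @param echo A per-animal table with the [simulate_echo_table()] schema.
#' @return `echo` with the derived columns appended, as a tibble.
#' @export
#' @examples
#' echo_sim_config(seed = 7) |>
#'   simulate_echo_table() |>
#'   derive_cardiac()
derive_cardiac <- function(echo) {
  assert_columns(echo, c("animal_id", "genotype", "heart_rate",
                         "lvid_s", "lvid_d", "lvpw_d", "lvaw_d",
                         "lv_vol_s", "lv_vol_d"), "echo")
  out <- tibble::as_tibble(echo)
  out$sv <- stroke_volume(out$lv_vol_d, out$lv_vol_s)
  out$ef <- ejection_fraction(out$lv_vol_d, out$lv_vol_s)
  out$fs <- fractional_shortening(out$lvid_d, out$lvid_s)
  out$co <- cardiac_output(out$sv, out$heart_rate)
  mass <- lv_mass(out$lvid_d, out$lvpw_d, out$lvaw_d)
  out$lv_mass <- mass$lv_mass
  out$lv_mass_corrected <- mass$lv_mass_corrected
  if (all(c("heart_weight", "body_weight") %in% names(out))) {
    out$hw_bw_ratio <- hypertrophy_index(out$heart_weight, out$body_weight)
  }
  if (all(c("mv_e", "mv_a") %in% names(out))) {
    out$mv_ea_ratio <- out$mv_e / out$mv_a
  }
  out
}

#' Summarise derived cardiac parameters per genotype
#'
#' Mean and SD of every numeric parameter per genotype, computed from the
#' per-animal values (per-animal derivation then averaging, the convention
#' of the source study's summary table).
#'
#' @param derived Output of [derive_cardiac()].
#' @param genotypes Optional genotype ordering for the output.
#' @return A tibble with columns `parameter`, `genotype`, `n`, `mean`, `sd`.
#' @export
summarize_cardiac <- function(derived, genotypes = NULL) {
  assert_columns(derived, "genotype", "derived")
  num_cols <- names(derived)[vapply(derived, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "replicate")
  long <- tidyr::pivot_longer(derived[, c("genotype", num_cols)],
                              -"genotype", names_to = "parameter")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$parameter, .data$genotype),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    .groups = "drop")
  if (!is.null(genotypes)) {
    out$genotype <- factor(out$genotype, levels = genotypes)
    out <- dplyr::arrange(out, .data$parameter, .data$genotype)
    out$genotype <- as.character(out$genotype)
  }
  out
}

#' Compare genotype groups by one-way ANOVA with Tukey HSD
#'
#' Conventional group comparison for derived cardiac (and other per-animal)
#' parameters: a one-way ANOVA F test followed by Tukey's multiple
#' comparison test for all pairwise genotype contrasts. Groups with fewer
#' than two values are excluded with a warning.
#'
#' @param data A data frame.
#' @param value Column of values to compare (tidy-eval).
#' @param group Grouping column (default `genotype`).
#' @param conf_level Confidence level for the Tukey intervals.
#' @return An object of class `group_comparison` with `tidy()` (pairwise
#'   contrasts with adjusted p-values) and `glance()` (ANOVA F and p)
#'   methods, plus an [ggplot2::autoplot()] method.
#' @export
#' @examples
#' cmp <- echo_sim_config(seed = 7) |>
#'   simulate_echo_table() |>
#'   derive_cardiac() |>
#'   compare_groups(sv)
#' tidy(cmp)
#' glance(cmp)
compare_groups <- function(data, value, group = genotype,
                           conf_level = 0.95) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  v <- rlang::eval_tidy(value, data)
  label <- rlang::as_label(value)
  # also accept a column name given as a string
  if (is.character(v) && length(v) == 1 && v %in% names(data)) {
    label <- v
    v <- data[[v]]
  }
  df <- tibble::tibble(
    value = v,
    group = as.character(rlang::eval_tidy(group, data))
  )
  df <- df[stats::complete.cases(df), ]
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    rlang::warn(sprintf("excluding group(s) with < 2 values: %s",
                        paste(small, collapse = ", ")))
    df <- df[!df$group %in% small, ]
  }
  if (length(unique(df$group)) < 2) {
    abort_domain("at least two groups with >= 2 values are required")
  }
  df$group <- factor(df$group)
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  structure(
    list(
      anova = tibble::tibble(
        df_between = an$Df[1], df_within = an$Df[2],
        statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1]),
      tukey = tibble::tibble(
        contrast = rownames(tk),
        estimate = unname(tk[, "diff"]),
        conf.low = unname(tk[, "lwr"]),
        conf.high = unname(tk[, "upr"]),
        adj.p.value = unname(tk[, "p adj"])),
      data = df,
      value_label = label
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s: F(%d, %d) = %.3f, p = %.4g\n",
              x$value_label, x$anova$df_between, x$anova$df_within,
              x$anova$statistic, x$anova$p_value))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$tukey)
  invisible(x)
}

#' Tidy and glance methods for group comparisons
#'
#' `tidy()` returns the Tukey HSD pairwise contrasts; `glance()` the ANOVA
#' F test.
#'
#' @param x A [compare_groups()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$tukey

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$anova
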