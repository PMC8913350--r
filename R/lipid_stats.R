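#' Per-species pairwise fold-changes between two genotypes
#'
#' For every species whose mean concentration is present in both genotypes
#' and whose denominator mean is positive, computes the fold-change
#' `mean(numerator) / mean(denominator)` and its logarithm. Species missing
#' either genotype (e.g. dropped entirely by the triplicate rule) are
#' excluded and counted in a message; a zero denominator mean excludes the
#' species with a warning.
#'
#' Fold-changes are built from genotype mean concentrations — replicate
#' averaging precedes the comparison — because animals are not paired across
#' genotypes; the pairing unit of the downstream signed-rank test is the
#' lipid species.
#'
#' @param profiles A species-profile table from [average_replicates()] (or
#'   [peaks_to_profiles()]).
#' @param numerator Genotype in the numerator (e.g. `"KO"`).
#' @param denominator Reference genotype (default `"WT"`).
#' @param log_base Base for `log_fold_change` (default 2).
#' @return A tibble with columns `class`, `species_id`, `comparison`,
#'   `mean_numerator`, `mean_denominator`, `fold_change`, `log_fold_change`.
#' @export
#' @examples
#' profiles <- lipid_sim_config(seed = 1) |>
#'   simulate_peak_table() |>
#'   peaks_to_profiles()
#' compute_fold_changes(profiles, "KO")
compute_fold_changes <- function(profiles, numerator, denominator = "WT",
                                 log_base = 2) {
  assert_columns(profiles, c("species_id", "class", "genotype",
                             "mean_concentration"), "profiles")
  if (numerator == denominator) {
    abort_config("`numerator` and `denominator` genotypes must differ")
  }
  num <- profiles[profiles$genotype == numerator,
                  c("species_id", "class", "mean_concentration")]
  den <- profiles[profiles$genotype == denominator,
                  c("species_id", "class", "mean_concentration")]
  names(num)[3] <- "mean_numerator"
  names(den)[3] <- "mean_denominator"
  both <- dplyr::inner_join(num, den, by = c("species_id", "class"))
  n_species_all <- length(unique(profiles$species_id))
  n_dropped <- n_species_all - nrow(both)
  if (n_dropped > 0) {
    rlang::inform(sprintf(
      "%d species without a mean in both %s and %s excluded from %s_vs_%s",
      n_dropped, numerator, denominator, numerator, denominator))
  }
  zero_den <- both$mean_denominator == 0
  if (any(zero_den)) {
    rlang::warn(sprintf(
      "%d species with zero %s mean excluded (fold-change undefined)",
      sum(zero_den), denominator))
    both <- both[!zero_den, ]
  }
  both$comparison <- paste0(numerator, "_vs_", denominator)
  both$fold_change <- both$mean_numerator / both$mean_denominator
  both$log_fold_change <- log(both$fold_change, base = log_base)
  tibble::as_tibble(both[, c("class", "species_id", "comparison",
                             "mean_numerator", "mean_denominator",
                             "fold_change", "log_fold_change")])
}

#' Class-level fold-change summaries
#'
#' Per class and comparison: the median of the per-species fold-changes
#' (midpoint convention for even counts) and the total-mass fold-change,
#' the ratio of summed genotype mean concentrations over the species
#' entering the comparison.
#'
#' @param fold_changes Output of [compute_fold_changes()].
#' @return A tibble with columns `class`, `comparison`, `n_species`,
#'   `median_fold_change`, `total_mass_fold_change`.
#' @export
summarize_class <- function(fold_changes) {
  assert_columns(fold_changes,
                 c("class", "comparison", "fold_change",
                   "mean_numerator", "mean_denominator"),
                 "fold_changes")
  dplyr::summarise(
    dplyr::group_by(fold_changes, .data$class, .data$comparison),
    n_species = dplyr::n(),
    median_fold_change = stats::median(.data$fold_change),
    total_mass_fold_change =
      sum(.data$mean_numerator) / sum(.data$mean_denominator),
    .groups = "drop")
}

#' Test lipid classes for aggregate fold-change away from 1
#'
#' The package's core statistic: for each lipid class and genotype
#' comparison, the per-species log fold-changes are tested against zero with
#' the exact Wilcoxon signed-rank test ([exact_signed_rank()]); class
#' summaries (median and total-mass fold-change) are attached, and the
#' family of tests is controlled with a Bonferroni correction reported at
#' both the unadjusted ("pre") and adjusted ("post") significance levels
#' ([apply_family_control()]).
#'
#' @param profiles A species-profile table from [peaks_to_profiles()].
#' @param comparisons Tibble with columns `numerator`, `denominator`; the
#'   default tests HET and KO against WT.
#' @param alpha Family significance level (default 0.05).
#' @param m Bonferroni family size; defaults to the number of testable
#'   class-comparison pairs (13 classes x 2 comparisons = 26 under the
#'   default class list).
#' @param exact_n_max,p_convention Passed to [exact_signed_rank()].
#' @param log_base Base of the log fold-changes (the p-values do not depend
#'   on it).
#' @return A `lipid_class_tests` tibble with one row per class and
#'   comparison: summaries, rank sums, `p_value`, `method`,
#'   `significant_pre`, `significant_post`, `marker`. The per-species
#'   fold-change table is attached as attribute `"fold_changes"`.
#' @export
#' @examples
#' res <- lipid_sim_config(seed = 1) |>
#'   simulate_peak_table() |>
#'   peaks_to_profiles() |>
#'   test_lipid_classes()
#' res
#' glance(res)
test_lipid_classes <- function(profiles,
                               comparisons = tibble::tibble(
                                 numerator = c("HET", "KO"),
                                 denominator = "WT"),
                               alpha = 0.05, m = NULL,
                               exact_n_max = 25,
                               p_convention = "doubling",
                               log_base = 2) {
  assert_columns(comparisons, c("numerator", "denominator"), "comparisons")
  fcs <- purrr::map_dfr(seq_len(nrow(comparisons)), function(i) {
    compute_fold_changes(profiles, comparisons$numerator[i],
                         comparisons$denominator[i], log_base = log_base)
  })
  summaries <- summarize_class(fcs)
  tests <- dplyr::group_by(fcs, .data$class, .data$comparison)
  tests <- dplyr::summarise(
    tests,
    test = list(exact_signed_rank(.data$log_fold_change,
                                  exact_n_max = exact_n_max,
                                  p_convention = p_convention)),
    .groups = "drop")
  tests <- dplyr::mutate(
    tests,
    n_used = purrr::map_int(.data$test, "n_used"),
    w_plus = purrr::map_dbl(.data$test, "w_plus"),
    w_minus = purrr::map_dbl(.data$test, "w_minus"),
    p_value = purrr::map_dbl(.data$test, "p_value"),
    method = purrr::map_chr(.data$test, "method"))
  tests$test <- NULL
  out <- dplyr::left_join(summaries, tests, by = c("class", "comparison"))
  out <- apply_family_control(out, alpha = alpha, m = m)
  attr(out, "fold_changes") <- fcs
  out
}

#' Bonferroni family-wise control with dual pre/post reporting
#'
#' Marks each test as significant at the unadjusted level
#' (`p < alpha`, marker `"∗"`) and at the Bonferroni-adjusted level
#' (`p < alpha / m`, marker `"∗∗∗"`); post-correction significance
#' implies pre-correction significance.
#'
#' @param results A tibble with a `p_value` column (one row per test).
#' @param alpha Family significance level (default 0.05).
#' @param m Family size. Defaults to the number of non-missing p-values
#'   supplied; a user-supplied `m` smaller than that triggers a warning.
#' @return `results` with added columns `significant_pre`,
#'   `significant_post` and `marker`, classed `lipid_class_tests`; the level
#'   and family size are stored as attributes `alpha` and `m`.
#' @export
#' @examples
#' # reconstruct markers from a vector of reported p-values
#' apply_family_control(tibble::tibble(p_value = c(0.0027, 0.0007, 0.2)),
#'                      alpha = 0.05, m = 26)$marker
apply_family_control <- function(results, alpha = 0.05, m = NULL) {
  assert_columns(results, "p_value", "results")
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  n_tests <- sum(!is.na(results$p_value))
  if (is.null(m)) m <- max(n_tests, 1L)
  assert_count(m, "m", lower = 1)
  if (m < n_tests) {
    rlang::warn(sprintf(
      "family size m = %d is smaller than the %d tests supplied", m, n_tests))
  }
  results$significant_pre <- results$p_value < alpha
  results$significant_post <- results$p_value < alpha / m
  results$marker <- dplyr::case_when(
    is.na(results$p_value) ~ NA_character_,
    results$significant_post ~ "∗∗∗",
    results$significant_pre ~ "∗",
    TRUE ~ ""
  )
  out <- tibble::as_tibble(results)
  class(out) <- c("lipid_class_tests", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  out
}

#' Build a wide class-level fold-change report
#'
#' One row per lipid class, with fold-change, p-value (rounded to four
#' decimal places, the convention of the published report) and significance
#' marker for each comparison. Untestable entries appear as `NA`.
#'
#' @param results A `lipid_class_tests` tibble (see [test_lipid_classes()]).
#' @param classes Class ordering for the report rows; defaults to the
#'   classes present, in the published order where applicable.
#' @param fc_column Which fold-change to print as the headline column:
#'   `"median"` (default) or `"total_mass"`.
#' @return A wide tibble with columns `class` then, per comparison,
#'   `fc_<comparison>`, `p_<comparison>`, `marker_<comparison>`.
#' @export
build_class_report <- function(results, classes = NULL,
                               fc_column = c("median", "total_mass")) {
  fc_column <- match.arg(fc_column)
  assert_columns(results, c("class", "comparison", "p_value", "marker"),
                 "results")
  fc_col <- if (fc_column == "median") "median_fold_change" else
    "total_mass_fold_change"
  assert_columns(results, fc_col, "results")
  narrow <- tibble::tibble(
    class = results$class,
    comparison = results$comparison,
    fc = results[[fc_col]],
    p = round(results$p_value, 4),
    marker = results$marker
  )
  wide <- tidyr::pivot_wider(narrow, names_from = "comparison",
                             values_from = c("fc", "p", "marker"),
                             names_glue = "{.value}_{comparison}")
  # per-comparison column blocks: fc, p, marker for each comparison in turn
  comps <- unique(narrow$comparison)
  wide <- wide[, c("class", as.vector(vapply(
    comps, function(cm) paste0(c("fc_", "p_", "marker_"), cm),
    character(3))))]
  if (is.null(classes)) {
    published <- chkb_lipid_classes()
    classes <- if (all(wide$class %in% published)) published else
      c(intersect(published, wide$class), setdiff(wide$class, published))
  }
  wide <- wide[match(classes, wide$class), , drop = FALSE]
  wide$class <- classes
  tibble::as_tibble(wide)
}

#' @export
print.lipid_class_tests <- function(x, ...) {
  cat(sprintf(
    "Lipid class fold-change tests (exact signed-rank, alpha = %g, m = %d)\n",
    attr(x, "alpha") %||% 0.05, attr(x, "m") %||% sum(!is.na(x$p_value))))
  NextMethod()
  invisible(x)
}

#' Tidy and glance methods for lipid class tests
#'
#' `tidy()` returns the per-test rows as a plain tibble; `glance()` returns
#' a one-row summary of the family.
#'
#' @param x A `lipid_class_tests` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lipid_class_tests
#' @export
tidy.lipid_class_tests <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lipid_class_tests")
  attr(out, "fold_changes") <- NULL
  attr(out, "alpha") <- NULL
  attr(out, "m") <- NULL
  out
}

#' @rdname tidy.lipid_class_tests
#' @method glance lipid_class_tests
#' @export
glance.lipid_class_tests <- function(x, ...) {
  tibble::tibble(
    n_tests = sum(!is.na(x$p_value)),
    alpha = attr(x, "alpha") %||% 0.05,
    m = attr(x, "m") %||% sum(!is.na(x$p_value)),
    n_significant_pre = sum(x$significant_pre, na.rm = TRUE),
    n_significant_post = sum(x$significant_post, na.rm = TRUE)
  )
}
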