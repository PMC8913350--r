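peak_table_columns <- function() {
  c("species_id", "class", "adduct", "sample_id", "genotype", "replicate",
    "concentration", "snr", "pq")
}

#' Filter lipid peaks on signal-to-noise and peak-quality scores
#'
#' Removes peak concentration estimates whose signal-to-noise ratio (SNR) is
#' *less than* `snr_min` or whose peak-quality score (PQ) is *less than*
#' `pq_min`. Thresholds are strict: a peak exactly at a threshold is
#' retained. Row order is preserved.
#'
#' @param peaks A peak table with at least `snr` and `pq` columns (see
#'   [simulate_peak_table()] for the full schema).
#' @param snr_min SNR threshold (default 2.0).
#' @param pq_min PQ threshold (default 0.8).
#' @return The retained rows, as a tibble.
#' @export
#' @examples
#' peaks <- simulate_peak_table(lipid_sim_config(seed = 1))
#' nrow(filter_peaks(peaks)) / nrow(peaks)
filter_peaks <- function(peaks, snr_min = 2.0, pq_min = 0.8) {
  assert_columns(peaks, c("snr", "pq"), "peaks")
  assert_numeric_columns(peaks, c("snr", "pq"), "peaks")
  tibble::as_tibble(peaks[peaks$snr >= snr_min & peaks$pq >= pq_min, ])
}

#' Apply the triplicate-exclusion rule
#'
#' Within each biological replicate group — the peaks of one species and
#' adduct measured across the replicates of one genotype — a lone surviving
#' observation is considered unreliable: if the QC filter removed all but at
#' most one observation of a group of `group_size` expected replicates (for
#' the study's triplicates: two of three removed), the remaining observation
#' is also excluded.
#'
#' @param peaks_before The peak table before QC filtering.
#' @param peaks_after The output of [filter_peaks()] on `peaks_before`.
#' @param group_size Expected replicates per genotype (default 3). For
#'   general group sizes the rule reads: drop the whole group when fewer
#'   than two observations survive.
#' @return The surviving rows of `peaks_after`, as a tibble.
#' @export
apply_triplicate_rule <- function(peaks_before, peaks_after, group_size = 3) {
  key <- c("species_id", "adduct", "sample_id")
  assert_columns(peaks_before, c(key, "genotype"), "peaks_before")
  assert_columns(peaks_after, c(key, "genotype"), "peaks_after")
  assert_count(group_size, "group_size", lower = 1)
  orphan <- dplyr::anti_join(peaks_after, peaks_before, by = key)
  if (nrow(orphan) > 0) {
    abort_schema(
      "`peaks_after` contains rows absent from `peaks_before`; it must be a subset")
  }
  if (group_size < 2) return(tibble::as_tibble(peaks_after))
  survivors <- dplyr::count(peaks_after, .data$species_id, .data$adduct,
                            .data$genotype, name = "n_surviving")
  keep <- survivors[survivors$n_surviving >= 2,
                    c("species_id", "adduct", "genotype")]
  dplyr::inner_join(peaks_after, keep,
                    by = c("species_id", "adduct", "genotype"))
}

#' Run the full peak-level cleanup
#'
#' Convenience wrapper chaining [filter_peaks()] and
#' [apply_triplicate_rule()]. The returned table carries a `qc_report`
#' attribute summarising rows in and rows removed at each stage.
#'
#' @inheritParams filter_peaks
#' @inheritParams apply_triplicate_rule
#' @return The cleaned peak table; `attr(, "qc_report")` is a tibble with
#'   columns `stage`, `rows_in`, `rows_removed`.
#' @export
#' @examples
#' peaks <- simulate_peak_table(lipid_sim_config(seed = 1))
#' clean <- clean_peaks(peaks)
#' attr(clean, "qc_report")
clean_peaks <- function(peaks, snr_min = 2.0, pq_min = 0.8, group_size = 3) {
  filtered <- filter_peaks(peaks, snr_min = snr_min, pq_min = pq_min)
  kept <- apply_triplicate_rule(peaks, filtered, group_size = group_size)
  report <- tibble::tibble(
    stage = c("qc_filter", "triplicate_rule"),
    rows_in = c(nrow(peaks), nrow(filtered)),
    rows_removed = c(nrow(peaks) - nrow(filtered),
                     nrow(filtered) - nrow(kept))
  )
  attr(kept, "qc_report") <- report
  kept
}

#' Sum adduct concentrations per species and sample
#'
#' Multiple mass-spectrometry adducts originating from the same molecular
#' species are summed to a single concentration per species and sample.
#' Samples are never mixed; the class label is carried through.
#'
#' @param peaks A QC-filtered peak table.
#' @return A tibble with one row per species and sample: `species_id`,
#'   `class`, `sample_id`, `genotype`, `replicate`, `concentration`.
#' @export
aggregate_adducts <- function(peaks) {
  assert_columns(peaks, c("species_id", "class", "adduct", "sample_id",
                          "genotype", "replicate", "concentration"), "peaks")
  dup <- duplicated(peaks[, c("species_id", "adduct", "sample_id")])
  if (any(dup)) {
    abort_schema(sprintf(
      "duplicate peak(s): same species, adduct and sample appear twice (e.g. %s / %s / %s)",
      peaks$species_id[dup][1], peaks$adduct[dup][1], peaks$sample_id[dup][1]))
  }
  out <- dplyr::summarise(
    dplyr::group_by(peaks, .data$species_id, .data$class, .data$sample_id,
                    .data$genotype, .data$replicate),
    concentration = sum(.data$concentration), .groups = "drop")
  out
}

#' Average biological replicates into per-genotype species profiles
#'
#' Arithmetic mean of a species' concentration over the surviving replicates
#' of each genotype. Replicates dropped during QC reduce the denominator; a
#' species with no surviving replicate in a genotype has no row for that
#' genotype.
#'
#' @param species_sample A per species-and-sample table from
#'   [aggregate_adducts()].
#' @return A species-profile tibble: `species_id`, `class`, `genotype`,
#'   `mean_concentration`, `n_replicates`.
#' @export
average_replicates <- function(species_sample) {
  assert_columns(species_sample,
                 c("species_id", "class", "genotype", "concentration"),
                 "species_sample")
  dplyr::summarise(
    dplyr::group_by(species_sample, .data$species_id, .data$class,
                    .data$genotype),
    mean_concentration = mean(.data$concentration),
    n_replicates = dplyr::n(),
    .groups = "drop")
}

#' Partition species profiles by lipid class
#'
#' @param profiles A species-profile table from [average_replicates()].
#' @param classes Optional vector of known class labels; profiles with other
#'   labels are routed to an `"unassigned"` bucket with a warning.
#' @return A named list of tibbles, one per class present.
#' @export
group_by_class <- function(profiles, classes = NULL) {
  assert_columns(profiles, c("species_id", "class"), "profiles")
  if (nrow(profiles) == 0) return(stats::setNames(list(), character(0)))
  label <- profiles$class
  if (!is.null(classes)) {
    unknown <- !label %in% classes
    if (any(unknown)) {
      rlang::warn(sprintf(
        "%d profile(s) with unknown class label(s) (%s) routed to 'unassigned'",
        sum(unknown),
        paste(unique(label[unknown]), collapse = ", ")))
      label[unknown] <- "unassigned"
    }
  }
  split(profiles, label)
}

#' Full cleanup from raw peaks to species profiles
#'
#' Chains [clean_peaks()], [aggregate_adducts()] and [average_replicates()].
#'
#' @inheritParams clean_peaks
#' @return A species-profile tibble (see [average_replicates()]); the
#'   `qc_report` attribute of [clean_peaks()] is carried over.
#' @export
#' @examples
#' lipid_sim_config(seed = 1) |>
#'   simulate_peak_table() |>
#'   peaks_to_profiles()
peaks_to_profiles <- function(peaks, snr_min = 2.0, pq_min = 0.8,
                              group_size = 3) {
  cleaned <- clean_peaks(peaks, snr_min = snr_min, pq_min = pq_min,
                         group_size = group_size)
  profiles <- average_replicates(aggregate_adducts(cleaned))
  attr(profiles, "qc_report") <- attr(cleaned, "qc_report")
  profiles
}
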