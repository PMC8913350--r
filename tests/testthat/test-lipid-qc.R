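test_that("QC filtering uses strict less-than thresholds", {
  peaks <- make_peaks(
    species_id = "AcCa(30:3)",
    sample_id = c("WT_1", "WT_2", "WT_3", "WT_1"),
    genotype = "WT", replicate = c(1, 2, 3, 1),
    adduct = c("+H", "+H", "+H", "+Na"),
    snr = c(1.9, 2.0, 5.0, 3.0),
    pq = c(0.95, 0.8, 0.79, 0.9)
  )
  kept <- filter_peaks(peaks)
  # snr 1.9 removed; pq 0.79 removed; exact boundary (2.0, 0.8) retained
  expect_equal(kept$snr, c(2.0, 3.0))
  expect_equal(kept$pq, c(0.8, 0.9))
  # empty in, empty out
  expect_equal(nrow(filter_peaks(peaks[0, ])), 0)
  # missing column is a schema error
  expect_error(filter_peaks(peaks[, setdiff(names(peaks), "pq")]),
               class = "lipidheart_schema_error")
  expect_error(filter_peaks(dplyr::mutate(peaks, snr = as.character(snr))),
               class = "lipidheart_schema_error")
})

test_that("triplicate rule removes lone survivors and only those", {
  lone <- make_triplicate(snrs = c(1.0, 1.5, 8.0))     # 2 failures
  pair <- make_triplicate(snrs = c(1.0, 7.0, 8.0),     # 1 failure
                          species_id = "AcCa(31:6)")
  full <- make_triplicate(snrs = c(5, 6, 7), species_id = "AcCa(32:2)")
  peaks <- dplyr::bind_rows(lone, pair, full)
  filtered <- filter_peaks(peaks)
  kept <- apply_triplicate_rule(peaks, filtered)
  expect_false("AcCa(30:3)" %in% kept$species_id)      # survivor removed too
  expect_equal(sum(kept$species_id == "AcCa(31:6)"), 2)
  expect_equal(sum(kept$species_id == "AcCa(32:2)"), 3)
  # rows not present upstream are a consistency error
  alien <- make_peaks("PC(40:1)", sample_id = "WT_9", genotype = "WT")
  expect_error(apply_triplicate_rule(peaks, dplyr::bind_rows(filtered, alien)),
               class = "lipidheart_schema_error")
})

test_that("adduct aggregation sums within, never across, samples", {
  peaks <- make_peaks(
    species_id = "PC(40:1)", class = "PC",
    adduct = c("+H", "+Na", "+H"),
    sample_id = c("WT_1", "WT_1", "WT_2"),
    genotype = "WT", replicate = c(1, 1, 2),
    concentration = c(5, 3, 7)
  )
  agg <- aggregate_adducts(peaks)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$concentration[agg$sample_id == "WT_1"], 8)
  expect_equal(agg$concentration[agg$sample_id == "WT_2"], 7)
  # duplicated (species, adduct, sample) is an error
  dup <- dplyr::bind_rows(peaks, peaks[1, ])
  expect_error(aggregate_adducts(dup), "duplicate")
})

test_that("replicate averaging adapts the denominator to survivors", {
  tbl <- tibble::tibble(
    species_id = "PC(40:1)", class = "PC",
    sample_id = c("WT_1", "WT_2", "WT_3", "KO_1", "KO_2"),
    genotype = c("WT", "WT", "WT", "KO", "KO"),
    replicate = c(1L, 2L, 3L, 1L, 2L),
    concentration = c(2, 4, 6, 2, 4)
  )
  prof <- average_replicates(tbl)
  expect_equal(prof$mean_concentration[prof$genotype == "WT"], 4)
  expect_equal(prof$n_replicates[prof$genotype == "WT"], 3L)
  expect_equal(prof$mean_concentration[prof$genotype == "KO"], 3)
  expect_equal(prof$n_replicates[prof$genotype == "KO"], 2L)
  # a genotype with no surviving replicate has no row at all
  expect_false("HET" %in% prof$genotype)
})

test_that("class grouping partitions species and flags unknown labels", {
  profiles <- suppressMessages(peaks_to_profiles(
    simulate_peak_table(lipid_sim_config(seed = 6))))
  groups <- group_by_class(profiles)
  expect_setequal(names(groups), unique(profiles$class))
  expect_equal(sum(vapply(groups, nrow, integer(1))), nrow(profiles))
  # unknown labels go to an 'unassigned' bucket with a warning
  odd <- make_profiles("XX(1:0)", "XX", "WT", 1)
  expect_warning(
    g2 <- group_by_class(dplyr::bind_rows(profiles, odd),
                         classes = chkb_lipid_classes()),
    "unassigned")
  expect_true("unassigned" %in% names(g2))
  expect_length(group_by_class(profiles[0, ]), 0)
})

test_that("cleanup obeys monotonicity, subset and conservation properties", {
  peaks <- simulate_peak_table(lipid_sim_config(seed = 17, qc_fail_rate = 0.2))
  f1 <- filter_peaks(peaks)
  # idempotent
  expect_identical(filter_peaks(f1), f1)
  # monotone: raising either threshold only removes rows
  for (th in list(c(3, 0.8), c(2, 0.9), c(4, 0.95))) {
    f2 <- filter_peaks(peaks, snr_min = th[1], pq_min = th[2])
    expect_lte(nrow(f2), nrow(f1))
    expect_equal(nrow(dplyr::anti_join(
      f2, f1, by = c("species_id", "adduct", "sample_id"))), 0)
  }
  # triplicate-rule output is a subset of the filter output, and every
  # removed group had at most one survivor
  kept <- apply_triplicate_rule(peaks, f1)
  expect_equal(nrow(dplyr::anti_join(
    kept, f1, by = c("species_id", "adduct", "sample_id"))), 0)
  lost <- dplyr::anti_join(f1, kept,
                           by = c("species_id", "adduct", "sample_id"))
  if (nrow(lost) > 0) {
    sizes <- dplyr::count(lost, species_id, adduct, genotype)
    expect_true(all(sizes$n <= 1))
  }
  # adduct aggregation conserves retained concentration per sample
  agg <- aggregate_adducts(kept)
  before <- tapply(kept$concentration, kept$sample_id, sum)
  after <- tapply(agg$concentration, agg$sample_id, sum)
  expect_equal(as.numeric(after[names(before)]), as.numeric(before),
               tolerance = 1e-9)
})

test_that("the pipeline is equivariant under global concentration rescaling", {
  peaks <- simulate_peak_table(lipid_sim_config(seed = 23))
  p1 <- suppressMessages(peaks_to_profiles(peaks))
  scaled <- dplyr::mutate(peaks, concentration = concentration * 1e3)
  p2 <- suppressMessages(peaks_to_profiles(scaled))
  expect_equal(p2$mean_concentration, p1$mean_concentration * 1e3,
               tolerance = 1e-12)
})
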