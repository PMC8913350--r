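test_that("fold-changes are ratios of genotype means with exclusions logged", {
  profiles <- make_profiles(
    species_id = c("AcCa(30:3)", "AcCa(30:3)", "AcCa(31:6)", "AcCa(31:6)",
                   "AcCa(32:2)"),
    class = "AcCa",
    genotype = c("WT", "KO", "WT", "KO", "WT"),
    mean_concentration = c(2, 6, 5, 5, 4)
  )
  fcs <- suppressMessages(compute_fold_changes(profiles, "KO"))
  expect_equal(nrow(fcs), 2)   # species present only in WT is excluded
  fc1 <- fcs[fcs$species_id == "AcCa(30:3)", ]
  expect_equal(fc1$fold_change, 3)
  expect_equal(fc1$log_fold_change, log2(3), tolerance = 1e-12)
  fc2 <- fcs[fcs$species_id == "AcCa(31:6)", ]
  expect_equal(fc2$fold_change, 1)
  expect_equal(fc2$log_fold_change, 0)
  # zero denominator excludes the species with a warning, not an error
  zprof <- make_profiles(c("PC(40:1)", "PC(40:1)"), "PC", c("WT", "KO"),
                         c(0, 3))
  expect_warning(z <- compute_fold_changes(zprof, "KO"), "zero")
  expect_equal(nrow(z), 0)
})

test_that("class summaries use median and total-mass conventions", {
  profiles <- make_profiles(
    species_id = rep(c("TG(40:2)", "TG(41:5)", "TG(42:1)"), each = 2),
    class = "TG",
    genotype = rep(c("WT", "KO"), 3),
    mean_concentration = c(1, 2, 1, 3, 1, 4)
  )
  fcs <- suppressMessages(compute_fold_changes(profiles, "KO"))
  s <- summarize_class(fcs)
  expect_equal(s$n_species, 3)
  expect_equal(s$median_fold_change, 3)          # FCs {2, 3, 4}
  expect_equal(s$total_mass_fold_change, 9 / 3)
  # one species: median = that FC = total-mass FC
  one <- summarize_class(fcs[1, ])
  expect_equal(one$median_fold_change, one$total_mass_fold_change)
  # unit FCs with unequal masses: both summaries are exactly 1
  eq <- make_profiles(
    species_id = rep(c("PS(36:1)", "PS(38:4)"), each = 2), class = "PS",
    genotype = rep(c("WT", "KO"), 2), mean_concentration = c(10, 10, 2, 2))
  s_eq <- summarize_class(suppressMessages(compute_fold_changes(eq, "KO")))
  expect_equal(s_eq$median_fold_change, 1)
  expect_equal(s_eq$total_mass_fold_change, 1)
})

test_that("family control marks pre and post significance consistently", {
  res <- apply_family_control(
    tibble::tibble(p_value = c(0.0027, 0.0007, 0.2, NA)),
    alpha = 0.05, m = 26)
  expect_equal(res$marker[1], "∗")            # pre only
  expect_equal(res$marker[2], "∗∗∗") # survives Bonferroni
  expect_equal(res$marker[3], "")
  expect_true(is.na(res$marker[4]))
  # post-correction significance implies pre-correction significance
  expect_true(all(!res$significant_post | res$significant_pre, na.rm = TRUE))
  expect_warning(apply_family_control(tibble::tibble(p_value = rep(0.01, 5)),
                                      m = 3),
                 "smaller")
})

test_that("published p-values reproduce all 26 published markers", {
  presets <- chkb_fold_change_presets()
  res <- apply_family_control(presets[, c("class", "comparison", "p_value")],
                              alpha = 0.05, m = 26)
  expect_equal(res$marker, presets$marker)
  expect_equal(sum(res$marker == "∗∗∗"), 9)
  expect_equal(sum(res$marker == "∗"), 8)
})

test_that("the wide class report has the published shape and round-trips", {
  profiles <- suppressMessages(peaks_to_profiles(
    simulate_peak_table(lipid_sim_config(seed = 31))))
  res <- suppressMessages(test_lipid_classes(profiles))
  report <- build_class_report(res)
  expect_equal(nrow(report), 13)
  expect_equal(report$class, chkb_lipid_classes())
  expect_named(report, c("class",
                         "fc_HET_vs_WT", "p_HET_vs_WT", "marker_HET_vs_WT",
                         "fc_KO_vs_WT", "p_KO_vs_WT", "marker_KO_vs_WT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_class_report(report, path)
  back <- read_class_report(path)
  expect_equal(back$p_KO_vs_WT, report$p_KO_vs_WT, tolerance = 1e-12)
  expect_equal(back$fc_KO_vs_WT, report$fc_KO_vs_WT, tolerance = 1e-9)
  expect_equal(back$marker_KO_vs_WT, report$marker_KO_vs_WT)
  # an untestable class yields an NA row, not a dropped one
  sub <- res[res$class != "PS", ]
  attr(sub, "fold_changes") <- NULL
  rep2 <- build_class_report(sub)
  expect_equal(nrow(rep2), 13)
  expect_true(all(is.na(rep2[rep2$class == "PS",
                             c("p_HET_vs_WT", "p_KO_vs_WT")])))
})

test_that("group swap inverts fold-changes and preserves p-values", {
  profiles <- suppressMessages(peaks_to_profiles(
    simulate_peak_table(lipid_sim_config(seed = 37))))
  fwd <- suppressMessages(compute_fold_changes(profiles, "KO", "WT"))
  rev <- suppressMessages(compute_fold_changes(profiles, "WT", "KO"))
  key <- order(fwd$species_id)
  key2 <- order(rev$species_id)
  expect_equal(rev$fold_change[key2], 1 / fwd$fold_change[key],
               tolerance = 1e-12)
  for (cl in c("AcCa", "LPC", "PS")) {
    p_fwd <- exact_signed_rank(fwd$log_fold_change[fwd$class == cl])$p_value
    p_rev <- exact_signed_rank(rev$log_fold_change[rev$class == cl])$p_value
    expect_equal(p_fwd, p_rev, tolerance = 1e-12)
  }
})

test_that("p-values are invariant to global rescaling and log base", {
  profiles <- suppressMessages(peaks_to_profiles(
    simulate_peak_table(lipid_sim_config(seed = 41))))
  res1 <- suppressMessages(test_lipid_classes(profiles))
  # rescaling every concentration (a units change) alters nothing
  res3 <- suppressMessages(test_lipid_classes(
    dplyr::mutate(profiles, mean_concentration = mean_concentration * 1e3)))
  expect_equal(res3$p_value, res1$p_value, tolerance = 1e-12)
  expect_equal(res3$median_fold_change, res1$median_fold_change,
               tolerance = 1e-12)
  # the log base of the fold-changes never changes a p-value
  res_e <- suppressMessages(test_lipid_classes(profiles, log_base = exp(1)))
  expect_equal(res_e$p_value, res1$p_value, tolerance = 1e-12)
})
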