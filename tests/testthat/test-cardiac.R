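test_that("stroke volume reproduces the published group-mean values", {
  expect_equal(stroke_volume(61.44, 24.14), 37.30, tolerance = 1e-9)
  expect_equal(stroke_volume(65.28, 24.14), 41.14, tolerance = 1e-9)
  expect_equal(stroke_volume(37.61, 11.73), 25.88, tolerance = 1e-9)
  expect_error(stroke_volume(20, 25), class = "lipidheart_domain_error")
  expect_error(stroke_volume(-5, 2), class = "lipidheart_domain_error")
})

test_that("ejection fraction and fractional shortening behave as ratios", {
  expect_equal(ejection_fraction(50, 25), 50)
  expect_equal(ejection_fraction(40, 0), 100)     # degenerate bound
  expect_error(ejection_fraction(0, 0), class = "lipidheart_domain_error")
  expect_equal(fractional_shortening(4, 3), 25)
  expect_equal(fractional_shortening(2.5, 2.5), 0)
  expect_error(fractional_shortening(3, 4), class = "lipidheart_domain_error")
  # formula applied to printed group means approximates the printed FS%
  expect_equal(fractional_shortening(3.78, 2.56), 32.28, tolerance = 0.01)
})

test_that("cardiac output converts ul x bpm to ml/min", {
  expect_equal(cardiac_output(50, 500), 25)
  expect_equal(cardiac_output(0, 400), 0)
  expect_error(cardiac_output(10, 0), class = "lipidheart_domain_error")
  # group-mean inputs land near (not on) the published per-animal average
  expect_equal(cardiac_output(37.3, 504.88), 18.83, tolerance = 0.01)
})

test_that("LV mass correction is a fixed 0.8 factor matching the table", {
  m <- lv_mass(c(3.78, 3.08), c(0.87, 0.87), c(0.82, 0.71))
  expect_equal(m$lv_mass_corrected / m$lv_mass, c(0.8, 0.8),
               tolerance = 1e-12)
  # the published corrected values are 0.8 x the uncorrected ones
  expect_lt(abs(0.8 * 115.58 - 92.47), 0.01)
  expect_lt(abs(0.8 * 113.66 - 90.93), 0.01)
  expect_lt(abs(0.8 * 75.07 - 60.06), 0.01)
  expect_error(lv_mass(0, 1, 1), class = "lipidheart_domain_error")
})

test_that("hypertrophy index scales as a pure ratio", {
  expect_equal(hypertrophy_index(150, 30), 5)
  expect_equal(hypertrophy_index(300, 60), 5)   # doubling both: unchanged
  expect_error(hypertrophy_index(150, 0), class = "lipidheart_domain_error")
  # 40% lower body weight at equal heart weight elevates the index 1/0.6-fold
  expect_equal(hypertrophy_index(150, 30 * 0.6) / hypertrophy_index(150, 30),
               1 / 0.6, tolerance = 1e-12)
})

test_that("group summaries are linear for SV but not for EF", {
  echo <- simulate_echo_table(echo_sim_config(seed = 19))
  d <- derive_cardiac(echo)
  wt <- d[d$genotype == "WT", ]
  # SV is linear: mean SV == mean(vol_d) - mean(vol_s) exactly
  expect_equal(mean(wt$sv), mean(wt$lv_vol_d) - mean(wt$lv_vol_s),
               tolerance = 1e-12)
  # EF is not: per-animal average differs from EF of averaged volumes
  ef_of_means <- ejection_fraction(mean(wt$lv_vol_d), mean(wt$lv_vol_s))
  expect_gt(abs(mean(wt$ef) - ef_of_means), 1e-6)
  # derived indices are invariant under reordering of animals
  perm <- d[rev(seq_len(nrow(d))), ]
  expect_equal(sort(perm$co), sort(d$co))
  s <- summarize_cardiac(d, genotypes = c("WT", "HET", "KO"))
  expect_true(all(c("sv", "ef", "fs", "co", "lv_mass_corrected") %in%
                    s$parameter))
  expect_equal(s$n[s$parameter == "sv"], c(5, 9, 3))
})

test_that("group comparison matches a first-principles Tukey computation", {
  set.seed(101)
  for (i in 1:20) {
    k <- sample(3:4, 1)
    ns <- sample(3:8, k, replace = TRUE)
    g <- rep(paste0("g", seq_len(k)), ns)
    v <- stats::rnorm(sum(ns), mean = rep(stats::runif(k, 0, 3), ns))
    df <- tibble::tibble(value = v, group = g)
    cmp <- compare_groups(df, value, group)
    manual <- manual_tukey_p(v, g)
    got <- tidy(cmp)
    expect_equal(got$adj.p.value[match(names(manual), got$contrast)],
                 unname(manual), tolerance = 1e-8)
  }
})

test_that("group comparison handles degenerate and extreme separations", {
  # identical groups: no between-group variance, F ~ 0, adjusted p ~ 1
  same <- tibble::tibble(value = rep(c(1, 2, 3), 3),
                         group = rep(c("a", "b", "c"), each = 3))
  cmp <- compare_groups(same, value, group)
  expect_lt(glance(cmp)$statistic, 1e-20)
  expect_true(all(tidy(cmp)$adj.p.value > 0.999))
  # two groups separated by 10 SDs
  set.seed(5)
  far <- tibble::tibble(value = c(stats::rnorm(10), stats::rnorm(10, 10)),
                        group = rep(c("a", "b"), each = 10))
  expect_true(all(tidy(compare_groups(far, value, group))$adj.p.value
                  < 0.001))
  # undersized groups are dropped with a warning
  tiny <- tibble::tibble(value = c(1, 2, 3, 4, 5),
                         group = c("a", "a", "b", "b", "c"))
  expect_warning(cmp2 <- compare_groups(tiny, value, group), "c")
  expect_equal(nrow(tidy(cmp2)), 1)
})
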