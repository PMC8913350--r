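#' Lipid classes quantified in the Chkb-deficient heart study
#'
#' The 13 lipid classes quantified in cardiac muscle of wildtype,
#' `Chkb`-heterozygous and `Chkb`-knockout mice: acylcarnitine (AcCa),
#' ceramide (Cer), cardiolipin (CL), diacylglycerol (DG),
#' lysophosphatidylcholine (LPC), lysophosphatidylethanolamine (LPE),
#' phosphatidylcholine (PC), phosphatidylethanolamine (PE),
#' phosphatidylglycerol (PG), phosphatidylinositol (PI),
#' phosphatidylserine (PS), sphingomyelin (SM) and triacylglycerol (TG).
#'
#' @return Character vector of 13 class labels.
#' @export
#' @examples
#' chkb_lipid_classes()
chkb_lipid_classes <- function() {
  c("AcCa", "Cer", "CL", "DG", "LPC", "LPE", "PC",
    "PE", "PG", "PI", "PS", "SM", "TG")
}

#' Published class-level fold-change results for Chkb-deficient hearts
#'
#' The class-level median pairwise fold-changes, exact signed-rank p-values
#' and pre-/post-Bonferroni significance markers reported for cardiac lipid
#' classes in `Chkb`-heterozygous (HET) and `Chkb`-knockout (KO) mice versus
#' wildtype (WT). These printed values serve two roles in this package: as
#' true-effect presets for the synthetic peak-table generator
#' ([lipid_sim_config()]) and as a fixed reference against which the
#' family-wise control stage ([apply_family_control()]) can be checked.
#'
#' Markers follow the dual-reporting convention: `"∗"` marks
#' significance at the unadjusted 5% level, `"∗∗∗"` marks
#' significance after Bonferroni correction for the 26-test family.
#'
#' @return A tibble with one row per lipid class and columns
#'   `class`, `fold_change`, `p_value`, `marker` for each comparison
#'   (`comparison` is `"HET_vs_WT"` or `"KO_vs_WT"`), in long format.
#' @export
#' @examples
#' chkb_fold_change_presets()
chkb_fold_change_presets <- function() {
  s1 <- "∗"
  s3 <- "∗∗∗"
  het <- tibble::tribble(
    ~class, ~fold_change, ~p_value, ~marker,
    "AcCa", 1.68, 0.0053, s1,
    "Cer",  0.60, 0.0000, s3,
    "CL",   1.67, 0.0000, s3,
    "DG",   1.37, 0.0000, s3,
    "LPC",  0.62, 0.0001, s3,
    "LPE",  0.54, 0.0039, s1,
    "PC",   1.18, 0.0000, s3,
    "PE",   1.24, 0.0071, s1,
    "PG",   0.64, 0.8125, "",
    "PI",   0.87, 0.7819, "",
    "PS",   1.74, 0.0625, "",
    "SM",   0.82, 0.0027, s1,
    "TG",   1.19, 0.0418, s1
  )
  ko <- tibble::tribble(
    ~class, ~fold_change, ~p_value, ~marker,
    "AcCa", 3.07, 0.0002, s3,
    "Cer",  0.65, 0.0000, s3,
    "CL",   1.40, 0.0074, s1,
    "DG",   1.05, 0.5291, "",
    "LPC",  0.52, 0.0007, s3,
    "LPE",  0.79, 0.2500, "",
    "PC",   1.35, 0.0000, s3,
    "PE",   1.04, 0.7155, "",
    "PG",   1.21, 1.0000, "",
    "PI",   1.24, 0.0174, s1,
    "PS",   0.88, 0.6250, "",
    "SM",   1.06, 0.3777, "",
    "TG",   0.55, 0.0155, s1
  )
  dplyr::bind_rows(
    dplyr::mutate(het, comparison = "HET_vs_WT"),
    dplyr::mutate(ko, comparison = "KO_vs_WT")
  )[, c("class", "comparison", "fold_change", "p_value", "marker")]
}

#' Published per-genotype echocardiography summary statistics
#'
#' Group means and standard deviations of the raw echocardiographic and
#' necropsy measurements for 5-month-old wildtype (WT, n = 5),
#' `Chkb`-heterozygous (HET, n = 9) and `Chkb`-knockout (KO, n = 3) mice,
#' used as presets for the synthetic echo-table generator
#' ([echo_sim_config()]).
#'
#' Units: dimensions mm, volumes ul, heart rate bpm, mitral-valve velocities
#' mm/s, body weight g, heart weight mg. Body and heart weights were not
#' tabulated in the source study and are synthetic presets consistent with
#' its qualitative findings (knockouts weigh about 40% less with similar
#' heart weight).
#'
#' @return A tibble with columns `genotype`, `parameter`, `mean`, `sd`.
#' @export
#' @examples
#' chkb_echo_presets()
chkb_echo_presets <- function() {
  tb <- tibble::tribble(
    ~parameter,     ~wt_mean, ~wt_sd, ~het_mean, ~het_sd, ~ko_mean, ~ko_sd,
    "heart_rate",     504.88,  44.90,    515.10,   60.00,   551.38,  47.80,
    "lvid_s",           2.56,   0.30,      2.52,    0.48,     1.92,   0.27,
    "lvid_d",           3.78,   0.22,      3.85,    0.47,     3.08,   0.20,
    "lvpw_s",           1.14,   0.15,      1.20,    0.26,     1.11,   0.05,
    "lvpw_d",           0.87,   0.10,      0.88,    0.16,     0.87,   0.09,
    "lv_vol_s",        24.14,   6.84,     24.14,   10.89,    11.73,   4.35,
    "lv_vol_d",        61.44,   8.82,     65.28,   18.48,    37.61,   5.85,
    "lvaw_s",           1.29,   0.18,      1.27,    0.12,     1.09,   0.04,
    "lvaw_d",           0.82,   0.14,      0.76,    0.10,     0.71,   0.02,
    "mv_e",           546.05,  72.17,    607.41,   77.31,   543.06,  63.45,
    "mv_a",           454.86,  75.05,    495.07,   86.35,   413.80,  38.67,
    # synthetic necropsy presets: KO body weight ~40% below WT/HET,
    # heart weight similar across genotypes
    "body_weight",     30.00,   2.50,     30.00,    2.50,    18.00,   1.50,
    "heart_weight",   150.00,  15.00,    150.00,   15.00,   140.00,  12.00
  )
  dplyr::bind_rows(
    tibble::tibble(genotype = "WT",  parameter = tb$parameter,
                   mean = tb$wt_mean,  sd = tb$wt_sd),
    tibble::tibble(genotype = "HET", parameter = tb$parameter,
                   mean = tb$het_mean, sd = tb$het_sd),
    tibble::tibble(genotype = "KO",  parameter = tb$parameter,
                   mean = tb$ko_mean,  sd = tb$ko_sd)
  )
}

# Default per-class species richness for the synthetic peak-table generator.
# Abundant classes (PC, TG, PE) carry many molecular species; lyso classes,
# PG and PS are sparse. The LPE/PG/PS counts (9, 6, 5) are consistent with
# the small exact-test sample sizes implied by the dyadic p-values of the
# published class report.
default_species_per_class <- function() {
  c(AcCa = 20, Cer = 18, CL = 24, DG = 28, LPC = 12, LPE = 9, PC = 56,
    PE = 42, PG = 6, PI = 11, PS = 5, SM = 16, TG = 48)
}
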