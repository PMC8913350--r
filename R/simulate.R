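#' Configuration for the synthetic lipidomics peak-table generator
#'
#' Describes a simulated LipidSearch-style experiment: lipid classes and their
#' species richness, genotype groups with biological replicates, true
#' class-level fold-changes, log-normal baseline and noise models, adduct
#' splitting and a contamination fraction of QC-failing peaks.
#'
#' The defaults emulate the study conditions the pipeline was designed for:
#' 13 lipid classes ([chkb_lipid_classes()]), three biological replicates per
#' genotype (WT, HET, KO), and the published class-level fold-changes
#' ([chkb_fold_change_presets()]) as true effects.
#'
#' @param classes Character vector of lipid-class labels.
#' @param species_per_class Positive integer count of molecular species per
#'   class; either a single value recycled over `classes` or a named vector.
#' @param replicates_per_genotype Biological replicates per genotype
#'   (default 3, as in the study).
#' @param genotypes Ordered genotype labels; the first is the reference
#'   (denominator) group for fold-changes.
#' @param class_fc Tibble with columns `class`, `comparison`, `fold_change`
#'   giving the true median fold-change per class for each non-reference
#'   genotype (`comparison` is `"<genotype>_vs_<reference>"`). Classes or
#'   comparisons not listed default to fold-change 1.
#' @param species_fc_sd Standard deviation of per-species log fold-changes
#'   about the class value (natural-log scale). Species effects are drawn
#'   log-normally so the class *median* equals the configured fold-change.
#' @param baseline_log_mean,baseline_log_sd Mean and SD of log baseline
#'   species concentration (arbitrary units, natural-log scale).
#' @param noise_sd SD of multiplicative log-normal measurement noise applied
#'   per species and sample (natural-log scale).
#' @param adduct_weights Positive fractions summing to 1; each species'
#'   concentration is split across this many mass-spectrometry adducts.
#' @param qc_fail_rate Probability that a generated peak carries a failing
#'   quality score (SNR below 2 or PQ below 0.8, chosen with equal
#'   probability).
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `lipid_sim_config`.
#' @seealso [simulate_peak_table()]
#' @export
#' @examples
#' cfg <- lipid_sim_config(classes = c("AcCa", "PC"),
#'                         species_per_class = c(AcCa = 5, PC = 8))
#' peaks <- simulate_peak_table(cfg)
lipid_sim_config <- function(classes = chkb_lipid_classes(),
                             species_per_class = NULL,
                             replicates_per_genotype = 3,
                             genotypes = c("WT", "HET", "KO"),
                             class_fc = NULL,
                             species_fc_sd = 0.1,
                             baseline_log_mean = log(50),
                             baseline_log_sd = 1,
                             noise_sd = 0.2,
                             adduct_weights = c(0.7, 0.3),
                             qc_fail_rate = 0.1,
                             seed = 1L) {
  if (length(classes) < 1 || anyDuplicated(classes)) {
    abort_config("`classes` must be a non-empty vector of unique labels")
  }
  if (is.null(species_per_class)) {
    defaults <- default_species_per_class()
    species_per_class <- ifelse(classes %in% names(defaults),
                                defaults[classes], 15)
    names(species_per_class) <- classes
  }
  if (length(species_per_class) == 1L) {
    species_per_class <- stats::setNames(rep(species_per_class,
                                             length(classes)), classes)
  }
  assert_count(species_per_class, "species_per_class", lower = 1)
  if (!all(classes %in% names(species_per_class))) {
    abort_config("`species_per_class` must be named for every class")
  }
  assert_count(replicates_per_genotype, "replicates_per_genotype", lower = 1)
  if (length(genotypes) < 2 || anyDuplicated(genotypes)) {
    abort_config("`genotypes` must contain at least two unique labels")
  }
  if (is.null(class_fc)) {
    class_fc <- chkb_fold_change_presets()[, c("class", "comparison",
                                               "fold_change")]
  }
  assert_columns(class_fc, c("class", "comparison", "fold_change"),
                 "class_fc")
  if (any(!is.finite(class_fc$fold_change)) ||
      any(class_fc$fold_change <= 0)) {
    abort_config("`class_fc` fold-changes must be finite and > 0")
  }
  assert_number(species_fc_sd, "species_fc_sd", lower = 0)
  assert_number(baseline_log_mean, "baseline_log_mean")
  assert_number(baseline_log_sd, "baseline_log_sd", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  assert_number(adduct_weights, "adduct_weights")
  if (any(adduct_weights <= 0) ||
      abs(sum(adduct_weights) - 1) > 1e-9) {
    abort_config("`adduct_weights` must be positive and sum to 1 (within 1e-9)")
  }
  assert_number(qc_fail_rate, "qc_fail_rate", lower = 0, upper = 1)
  assert_count(seed, "seed", lower = -2^31)

  structure(
    list(
      classes = as.character(classes),
      species_per_class = species_per_class[classes],
      replicates_per_genotype = as.integer(replicates_per_genotype),
      genotypes = as.character(genotypes),
      class_fc = tibble::as_tibble(class_fc),
      species_fc_sd = species_fc_sd,
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      noise_sd = noise_sd,
      adduct_weights = adduct_weights,
      qc_fail_rate = qc_fail_rate,
      seed = as.integer(seed)
    ),
    class = "lipid_sim_config"
  )
}

# Adduct labels for up to six adducts per species.
adduct_labels <- function(n) {
  labs <- c("+H", "+Na", "+NH4", "-H", "+K", "+HCOO")
  if (n > length(labs)) labs <- c(labs, paste0("+X", seq_len(n)))
  labs[seq_len(n)]
}

#' Simulate a LipidSearch-style lipidomics peak table
#'
#' Generates one detected peak per species, adduct and sample. Each species
#' draws a log-normal baseline concentration shared across genotypes; each
#' non-reference genotype multiplies it by a species-level fold-change drawn
#' log-normally around the configured class fold-change (so the class median
#' effect equals the configured value); each sample adds multiplicative
#' log-normal noise. The resulting concentration is split across adducts by
#' `adduct_weights`. A `qc_fail_rate` fraction of peaks receives a failing
#' quality score (SNR < 2 or PQ < 0.8, with equal probability); all other
#' peaks pass both thresholds.
#'
#' @param config A [lipid_sim_config()].
#' @return A tibble with one row per peak and columns `species_id`, `class`,
#'   `adduct`, `sample_id`, `genotype`, `replicate`, `concentration`, `snr`,
#'   `pq`. Byte-identical across calls with the same configuration.
#' @export
#' @examples
#' peaks <- simulate_peak_table(lipid_sim_config(seed = 42))
#' dplyr::count(peaks, class)
simulate_peak_table <- function(config) {
  if (!inherits(config, "lipid_sim_config")) {
    abort_config("`config` must be created by lipid_sim_config()")
  }
  set.seed(config$seed)
  ref <- config$genotypes[1]

  # species frame with lipid-like identifiers (unique carbon numbers)
  species <- purrr::map_dfr(config$classes, function(cl) {
    n <- config$species_per_class[[cl]]
    tibble::tibble(
      class = cl,
      species_id = sprintf("%s(%d:%d)", cl, 29 + seq_len(n),
                           (seq_len(n) * 3L) %% 7L)
    )
  })
  n_species <- nrow(species)
  species$baseline <- exp(stats::rnorm(n_species, config$baseline_log_mean,
                                       config$baseline_log_sd))

  # per-species, per-genotype multiplicative effects (reference = 1)
  effects <- tidyr::expand_grid(species, genotype = config$genotypes)
  cmp <- paste0(effects$genotype, "_vs_", ref)
  key <- paste(config$class_fc$class, config$class_fc$comparison)
  class_mu <- log(config$class_fc$fold_change)[
    match(paste(effects$class, cmp), key)]
  class_mu[is.na(class_mu)] <- 0
  effects$effect <- ifelse(
    effects$genotype == ref, 1,
    exp(stats::rnorm(nrow(effects), class_mu, config$species_fc_sd))
  )

  samples <- tidyr::expand_grid(
    genotype = config$genotypes,
    replicate = seq_len(config$replicates_per_genotype)
  )
  samples$sample_id <- paste0(samples$genotype, "_", samples$replicate)

  obs <- dplyr::inner_join(effects, samples, by = "genotype",
                           relationship = "many-to-many")
  obs$concentration_total <- obs$baseline * obs$effect *
    exp(stats::rnorm(nrow(obs), 0, config$noise_sd))

  # split across adducts
  w <- config$adduct_weights
  adducts <- tibble::tibble(adduct = adduct_labels(length(w)), weight = w)
  peaks <- tidyr::expand_grid(obs, adducts)
  peaks$concentration <- peaks$concentration_total * peaks$weight

  # quality scores: failing peaks fall strictly below one threshold
  n <- nrow(peaks)
  fails <- stats::runif(n) < config$qc_fail_rate
  snr_mode <- stats::runif(n) < 0.5
  snr <- stats::runif(n, 2, 10)
  pq <- stats::runif(n, 0.8, 1)
  snr[fails & snr_mode] <- stats::runif(sum(fails & snr_mode), 0, 2)
  pq[fails & !snr_mode] <- stats::runif(sum(fails & !snr_mode), 0, 0.8)
  peaks$snr <- snr
  peaks$pq <- pq

  tibble::as_tibble(peaks[, c("species_id", "class", "adduct", "sample_id",
                              "genotype", "replicate", "concentration",
                              "snr", "pq")])
}

#' Configuration for the synthetic echocardiography-table generator
#'
#' Per-genotype means and standard deviations of each raw echo/necropsy
#' measurement, with the published per-genotype group summaries
#' ([chkb_echo_presets()]) and cohort sizes (WT 5, HET 9, KO 3) as defaults.
#'
#' @param presets Tibble with columns `genotype`, `parameter`, `mean`, `sd`.
#' @param n_per_genotype Named integer vector of animals per genotype.
#' @param seed Integer seed.
#' @return An object of class `echo_sim_config`.
#' @seealso [simulate_echo_table()]
#' @export
echo_sim_config <- function(presets = chkb_echo_presets(),
                            n_per_genotype = c(WT = 5, HET = 9, KO = 3),
                            seed = 1L) {
  assert_columns(presets, c("genotype", "parameter", "mean", "sd"), "presets")
  if (any(presets$sd < 0)) abort_config("`presets` SDs must be >= 0")
  assert_count(n_per_genotype, "n_per_genotype", lower = 1)
  genotypes <- names(n_per_genotype)
  if (is.null(genotypes) || !all(genotypes %in% presets$genotype)) {
    abort_config("`n_per_genotype` must be named with genotypes in `presets`")
  }
  wide <- tidyr::pivot_wider(presets, names_from = "parameter",
                             values_from = c("mean", "sd"))
  if (all(c("mean_lv_vol_d", "mean_lv_vol_s") %in% names(wide)) &&
      any(wide$mean_lv_vol_d <= wide$mean_lv_vol_s)) {
    abort_config(
      "`presets`: mean lv_vol_d must exceed mean lv_vol_s in every genotype")
  }
  assert_count(seed, "seed", lower = -2^31)
  structure(
    list(presets = tibble::as_tibble(presets),
         n_per_genotype = n_per_genotype,
         seed = as.integer(seed)),
    class = "echo_sim_config"
  )
}

# Normal truncated at zero by redraw; sd 0 returns the mean exactly.
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  }
  x
}

#' Simulate a per-animal echocardiography/necropsy table
#'
#' One row per animal; every measurement is drawn independently from a
#' zero-truncated normal with its genotype's preset mean and SD. Animals
#' whose drawn systolic LV volume (or diameter) exceeds the diastolic value
#' are redrawn, so the physiological ordering holds in every row.
#'
#' @param config An [echo_sim_config()].
#' @return A tibble with columns `animal_id`, `genotype` and one column per
#'   preset parameter. Deterministic given the configuration seed.
#' @export
#' @examples
#' echo <- simulate_echo_table(echo_sim_config(seed = 7))
#' derive_cardiac(echo)
simulate_echo_table <- function(config) {
  if (!inherits(config, "echo_sim_config")) {
    abort_config("`config` must be created by echo_sim_config()")
  }
  set.seed(config$seed)
  rows <- purrr::map_dfr(names(config$n_per_genotype), function(g) {
    n <- config$n_per_genotype[[g]]
    pg <- config$presets[config$presets$genotype == g, ]
    vals <- lapply(seq_len(nrow(pg)), function(i) {
      rnorm_pos(n, pg$mean[i], pg$sd[i])
    })
    names(vals) <- pg$parameter
    out <- tibble::as_tibble(vals)
    out <- tibble::add_column(out,
                              animal_id = paste0(g, "_", seq_len(n)),
                              genotype = g, .before = 1)
    # enforce diastole > systole orderings by redrawing offending animals
    for (pair in list(c("lv_vol_d", "lv_vol_s"), c("lvid_d", "lvid_s"))) {
      d <- pair[1]; s <- pair[2]
      if (!all(pair %in% names(out))) next
      md <- pg$mean[pg$parameter == d]; sdd <- pg$sd[pg$parameter == d]
      ms <- pg$mean[pg$parameter == s]; sds <- pg$sd[pg$parameter == s]
      bad <- out[[d]] <= out[[s]]
      while (any(bad)) {
        out[[d]][bad] <- rnorm_pos(sum(bad), md, sdd)
        out[[s]][bad] <- rnorm_pos(sum(bad), ms, sds)
        bad <- out[[d]] <= out[[s]]
      }
    }
    out
  })
  rows
}

#' Simulate stereological grid counts
#'
#' Emulates point counting on transmission electron micrographs: each field
#' carries `grid_points` test points of which a Binomial(`grid_points`,
#' `density`) number land on mitochondria.
#'
#' @param n_fields Number of image fields.
#' @param density True mitochondrial volume density, in `[0, 1]`.
#' @param grid_points Test points per field (default 400).
#' @param grid_spacing Grid spacing metadata in nm (default 165).
#' @param seed Integer seed.
#' @return A tibble with columns `field_id`, `points_mito`, `points_total`,
#'   `grid_spacing`.
#' @seealso [volume_density()]
#' @export
#' @examples
#' counts <- simulate_grid_counts(12, density = 0.3, seed = 3)
#' volume_density(counts)
simulate_grid_counts <- function(n_fields, density, grid_points = 400,
                                 grid_spacing = 165, seed = 1L) {
  assert_count(n_fields, "n_fields", lower = 1)
  assert_number(density, "density", lower = 0, upper = 1)
  assert_count(grid_points, "grid_points", lower = 1)
  assert_count(seed, "seed", lower = -2^31)
  set.seed(seed)
  tibble::tibble(
    field_id = sprintf("field_%03d", seq_len(n_fields)),
    points_mito = stats::rbinom(n_fields, grid_points, density),
    points_total = as.integer(grid_points),
    grid_spacing = grid_spacing
  )
}

#' Simulate per-field mitochondria counts
#'
#' Emulates blinded mitochondria-per-field counting: counts are Poisson with
#' the given mean rate per field.
#'
#' @param n_fields Number of image fields.
#' @param rate Mean mitochondria per field (> 0).
#' @param seed Integer seed.
#' @return Integer vector of length `n_fields`.
#' @seealso [mito_per_field()]
#' @export
simulate_field_counts <- function(n_fields, rate, seed = 1L) {
  assert_count(n_fields, "n_fields", lower = 1)
  assert_number(rate, "rate", lower = 0)
  assert_count(seed, "seed", lower = -2^31)
  set.seed(seed)
  stats::rpois(n_fields, rate)
}

#' Simulate a qPCR threshold-cycle (Ct) table
#'
#' Emulates TaqMan-style Ct measurements of a target gene and a reference
#' gene (e.g. `Gapdh`) in several genotype groups. The true relative
#' expression of each genotype versus the control enters as a shift of
#' `-log2(fold_change)` cycles in the target Ct.
#'
#' @param n_per_genotype Named integer vector of samples per genotype.
#' @param fold_change Named vector of true expression fold-changes versus the
#'   control genotype (control must be 1).
#' @param control_genotype Label of the control group.
#' @param base_delta_ct True target-minus-reference Ct difference in the
#'   control group (cycles).
#' @param ct_reference_mean Mean reference-gene Ct (cycles).
#' @param sd_ct Measurement SD of each Ct (cycles).
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `genotype`, `ct_target`,
#'   `ct_reference`.
#' @seealso [ddct_relative_expression()]
#' @export
simulate_ct_table <- function(n_per_genotype = c(WT = 3, HET = 3, KO = 3),
                              fold_change = c(WT = 1, HET = 1.9, KO = 1),
                              control_genotype = "WT",
                              base_delta_ct = 6,
                              ct_reference_mean = 18,
                              sd_ct = 0.15,
                              seed = 1L) {
  assert_count(n_per_genotype, "n_per_genotype", lower = 1)
  assert_number(fold_change, "fold_change", lower = 1e-12)
  if (!control_genotype %in% names(n_per_genotype)) {
    abort_config("`control_genotype` must appear in `n_per_genotype`")
  }
  assert_number(sd_ct, "sd_ct", lower = 0)
  assert_count(seed, "seed", lower = -2^31)
  set.seed(seed)
  purrr::map_dfr(names(n_per_genotype), function(g) {
    n <- n_per_genotype[[g]]
    fc <- if (g %in% names(fold_change)) fold_change[[g]] else 1
    ct_ref <- stats::rnorm(n, ct_reference_mean, sd_ct)
    dct <- base_delta_ct - log2(fc) + stats::rnorm(n, 0, sd_ct)
    tibble::tibble(
      sample_id = paste0(g, "_", seq_len(n)),
      genotype = g,
      ct_target = ct_ref + dct,
      ct_reference = ct_ref
    )
  })
}
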