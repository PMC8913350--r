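# Independent oracles and small fixture builders used across the suite.

# Brute-force exact signed-rank p-value by literal enumeration of all 2^n
# sign assignments of the realized rank vector (doubling rule). Kept
# deliberately independent of the package's convolution implementation.
brute_force_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Minimal peak-table fixture: one row per combination given, passing QC by
# default.
make_peaks <- function(species_id, adduct = "+H", sample_id, genotype,
                       replicate = 1L, concentration = 1,
                       snr = 5, pq = 0.95, class = "AcCa") {
  tibble::tibble(
    species_id = species_id, class = class, adduct = adduct,
    sample_id = sample_id, genotype = genotype,
    replicate = as.integer(replicate),
    concentration = concentration, snr = snr, pq = pq
  )
}

# A triplicate of one species/adduct in one genotype with given QC scores.
make_triplicate <- function(snrs, pqs = rep(0.95, length(snrs)),
                            species_id = "AcCa(30:3)", genotype = "WT") {
  make_peaks(
    species_id = species_id,
    sample_id = paste0(genotype, "_", seq_along(snrs)),
    genotype = genotype, replicate = seq_along(snrs),
    concentration = seq_along(snrs), snr = snrs, pq = pqs
  )
}

# Species profiles built directly (bypassing the peak pipeline).
make_profiles <- function(species_id, class, genotype, mean_concentration,
                          n_replicates = 3L) {
  tibble::tibble(
    species_id = species_id, class = class, genotype = genotype,
    mean_concentration = mean_concentration,
    n_replicates = as.integer(n_replicates)
  )
}

# Hand-computed Tukey HSD adjusted p-values from first principles
# (studentized range distribution), independent of stats::TukeyHSD.
manual_tukey_p <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum((values - ms[groups])^2) / df
  pairs <- utils::combn(levels(groups), 2)
  p <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(ms[pr[2]] - ms[pr[1]]) / se
    stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  })
  names(p) <- paste(pairs[2, ], pairs[1, ], sep = "-")
  p
}
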