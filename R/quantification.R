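# Stereological point-count estimators and ddCt relative expression.

#' Mitochondrial volume density from stereological grid counts
#'
#' Pooled (ratio-of-sums) estimator: total points assigned to mitochondria
#' divided by the total points counted inside the muscle, over all fields.
#' This is the standard stereology estimator when field point totals vary;
#' it equals the count-weighted mean of the per-field densities.
#'
#' @param counts A grid-count table with columns `points_mito` and
#'   `points_total` (see [simulate_grid_counts()]).
#' @param per_field If `TRUE`, also return per-field densities.
#' @return The pooled density, a fraction in `[0, 1]`; with
#'   `per_field = TRUE`, a list with elements `pooled` and `per_field`
#'   (a tibble of per-field densities).
#' @export
#' @examples
#' counts <- simulate_grid_counts(10, density = 0.3, seed = 2)
#' volume_density(counts)
volume_density <- function(counts, per_field = FALSE) {
  assert_columns(counts, c("points_mito", "points_total"), "counts")
  assert_numeric_columns(counts, c("points_mito", "points_total"), "counts")
  if (nrow(counts) == 0) abort_domain("`counts` must be non-empty")
  if (any(counts$points_mito < 0) ||
      any(counts$points_mito > counts$points_total)) {
    abort_domain("`points_mito` must lie in [0, points_total] per field")
  }
  total <- sum(counts$points_total)
  if (total <= 0) abort_domain("total points counted must be > 0")
  pooled <- sum(counts$points_mito) / total
  if (!per_field) return(pooled)
  fields <- tibble::tibble(
    field_id = counts[["field_id"]] %||% seq_len(nrow(counts)),
    density = ifelse(counts$points_total > 0,
                     counts$points_mito / counts$points_total, NA_real_)
  )
  list(pooled = pooled, per_field = fields)
}

#' Mean mitochondria count per image field
#'
#' @param counts Numeric vector of mitochondria counts, one per field.
#' @return Arithmetic mean count per field.
#' @export
#' @examples
#' mito_per_field(c(10, 20, 30))  # 20
mito_per_field <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0) {
    abort_domain("`counts` must be a non-empty numeric vector")
  }
  if (any(counts < 0)) abort_domain("counts must be >= 0")
  mean(counts)
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' For each sample: `delta_ct = ct_target - ct_reference` (normalisation to
#' the reference gene, e.g. `Gapdh`); `delta_delta_ct` subtracts the
#' arithmetic mean `delta_ct` of the control genotype; the relative
#' quantity is `2^(-delta_delta_ct)`. Centering on the control-group mean
#' `delta_ct` makes the control group's *geometric* mean relative quantity
#' exactly 1.
#'
#' @param records A Ct table with columns `sample_id`, `genotype`,
#'   `ct_target`, `ct_reference` (see [simulate_ct_table()]).
#' @param control_genotype Label of the control group (default `"WT"`).
#' @return A tibble with columns `sample_id`, `genotype`, `delta_ct`,
#'   `delta_delta_ct`, `relative_quantity`.
#' @export
#' @examples
#' ct <- simulate_ct_table(seed = 5)
#' ddct_relative_expression(ct)
ddct_relative_expression <- function(records, control_genotype = "WT") {
  assert_columns(records, c("sample_id", "genotype", "ct_target",
                            "ct_reference"), "records")
  assert_numeric_columns(records, c("ct_target", "ct_reference"), "records")
  if (any(!is.finite(records$ct_target)) ||
      any(!is.finite(records$ct_reference)) ||
      any(records$ct_target <= 0) || any(records$ct_reference <= 0)) {
    abort_domain("Ct values must be positive and finite")
  }
  control <- records$genotype == control_genotype
  if (!any(control)) {
    abort_domain(sprintf("no samples with control genotype '%s'",
                         control_genotype))
  }
  delta_ct <- records$ct_target - records$ct_reference
  ddct <- delta_ct - mean(delta_ct[control])
  tibble::tibble(
    sample_id = records$sample_id,
    genotype = records$genotype,
    delta_ct = delta_ct,
    delta_delta_ct = ddct,
    relative_quantity = 2^(-ddct)
  )
}
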