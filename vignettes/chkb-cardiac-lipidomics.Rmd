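---
title: "Methods: class-level lipidomics statistics and cardiac phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: class-level lipidomics statistics and cardiac phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidheart)
```

## The analysis problem

A mouse model of choline kinase β deficiency is phenotyped on three fronts:
shotgun lipidomics of cardiac muscle (wildtype, heterozygous and knockout
littermates, three biological replicates each), echocardiography with
necropsy, and small quantification assays (stereological point counting of
mitochondria, ΔΔCt relative expression). The package implements the full
computational path from raw tables to the reported summaries. Because the
primary data for this kind of study are typically not deposited, a
first-class synthetic-data module generates every input table with the
statistical structure the analysis assumes; all tests and the acceptance
script run on those generators.

## Peak-table cleanup

A LipidSearch-style peak table has one row per detected peak: lipid species
(class plus fatty-acyl composition), adduct, sample, concentration
(arbitrary units), a signal-to-noise ratio (SNR) and a peak-quality score
(PQ). Cleanup proceeds in four fixed steps:

1. **QC filter** (`filter_peaks()`): rows with SNR < 2.0 *or* PQ < 0.8 are
   removed. The thresholds are strict "less than", so a peak exactly at a
   threshold passes — a deliberate boundary convention.
2. **Triplicate rule** (`apply_triplicate_rule()`): within the replicates
   of one genotype for one species and adduct, a lone survivor is judged
   unreliable — if the filter removed all but at most one of the expected
   `group_size` (default 3) observations, the survivor is removed too. The
   rule is applied per adduct, before adduct summing, following the order
   of the cleanup steps; for general group sizes it generalises to "drop
   the group when fewer than two survive", preserving the intent that a
   single observation cannot be averaged meaningfully.
3. **Adduct aggregation** (`aggregate_adducts()`): concentrations of
   multiple adducts of the same molecular species are summed per sample,
   never across samples. Duplicate (species, adduct, sample) rows are an
   error rather than silently double-counted.
4. **Replicate averaging** (`average_replicates()`): arithmetic mean per
   species and genotype, with the denominator adapting to surviving
   replicates. A genotype with no survivors yields no mean at all; such
   species later drop out of fold-change construction for comparisons
   involving that genotype, because a fold-change against a missing mean is
   undefined.

These steps satisfy checkable invariants, each asserted in the test suite:
filtering is idempotent and monotone in both thresholds, the triplicate
rule removes exactly the groups with at most one survivor, aggregation
conserves retained concentration per sample to numerical precision, and
the whole pipeline is equivariant under a global rescaling of
concentrations (a change of units).

## The class-level fold-change statistic

The tested unit is the lipid class, not the species. For a class with
species $i = 1..n$ and a comparison of genotype $g$ against wildtype, the
per-species fold-change is the ratio of genotype mean concentrations,
$\mathrm{FC}_i = \bar{x}_{i,g} / \bar{x}_{i,\mathrm{WT}}$. Animals are not
paired across genotypes, so replicate averaging precedes the ratio; the
*species* are the paired observations. The log fold-changes (base 2 by
default; no p-value depends on the base) are tested against zero with an
exact Wilcoxon signed-rank test:

- zeros are removed (the classical convention), tied absolute values get
  average ranks;
- for $n \le$ `exact_n_max` (default 25) the null distribution of
  $W^+$ is the distribution over all $2^n$ equally likely sign assignments
  of the *realized* rank vector, so exactness holds under ties. The
  distribution is accumulated by convolution on the doubled-rank integer
  grid, which is algebraically identical to enumerating the $2^n$
  assignments at a fraction of the cost; the test suite checks it against
  a literal brute-force enumerator;
- the two-sided p-value uses the doubling rule
  $p = \min(1,\, 2\min(P(W^+ \le w), P(W^+ \ge w)))$. This is what
  produces the dyadic values ($0.0625$ for five one-signed differences,
  $0.25$ for three, $2/512 = 0.0039$ for nine) characteristic of small
  exact tests. A minimum-likelihood alternative is available behind
  `p_convention = "min-likelihood"` but is not the default;
- for larger $n$ a normal approximation with tie-corrected variance and
  continuity correction is used and flagged as `"approximate"`;
- no usable differences yield an explicitly not-testable result with a
  missing p-value — never a silent 1.0.

Two class summaries are reported: the **median** per-species fold-change
(midpoint convention for even counts) and the **total-mass** fold-change,
the ratio of summed genotype means. Which one a published table prints is
not always decidable; the report builder exposes both
(`build_class_report(fc_column = )`), defaulting to the median.

**Family-wise control.** The 13 classes × 2 comparisons form a 26-test
family controlled by Bonferroni at overall level $\alpha = 0.05$, with dual
reporting: `∗` for $p < \alpha$ (pre-correction) and
`∗∗∗` for $p < \alpha/m$ (post-correction). The family size
$m = 26$ is the unique simple Bonferroni family consistent with every
published marker: $p = 0.0027$ carries `∗` while $p = 0.0007$ carries
`∗∗∗`, bracketing the threshold inside $(0.0007, 0.0027]$, and
$0.05/26 \approx 0.00192$ sits there. `m` is configurable, and feeding the
26 published p-values through `apply_family_control()` reproduces all 26
published markers exactly (asserted in the tests and recomputed by the
acceptance script).

## Derived cardiac indices

From per-animal echo records: SV $=$ Vol(d) $-$ Vol(s) (µl), EF $= 100\,
\mathrm{SV}/\mathrm{Vol(d)}$ (%), FS $= 100\,(\mathrm{LVIDd} -
\mathrm{LVIDs})/\mathrm{LVIDd}$ (%), CO $= \mathrm{SV}\times\mathrm{HR}/1000$
(ml/min), and the corrected-cube LV mass $1.053\,((\mathrm{LVIDd} +
\mathrm{LVPWd} + \mathrm{LVAWd})^3 - \mathrm{LVIDd}^3)$ with the standard
0.8 correction factor — the exact 0.8 ratio between the published corrected
and uncorrected masses in all three genotypes identifies this convention.
The heart-weight/body-weight ratio (mg/g) indexes hypertrophy. LV volumes
are treated as inputs and never re-derived from diameters, since the
vendor's volume formula is not identifiable from published summaries.

Group summaries are computed **per animal and then averaged**. For SV,
which is linear in the volumes, this equals the formula applied to group
means; for EF, FS and CO (ratios and products) it does not, and both facts
are asserted in the tests. This convention is what reconciles a published
summary table whose SV matches the subtraction of its printed volume means
exactly while its EF and CO deviate slightly. Genotype comparison uses
one-way ANOVA followed by Tukey's HSD (`stats::aov` + `stats::TukeyHSD`);
the tests cross-check the adjusted p-values against a first-principles
studentized-range computation.

The published mitral-valve velocity rows are headed "m/s" but print values
near 550; they are carried as mm/s, the physiologically coherent unit.

## Quantification utilities

**Stereology.** The volume density estimator is the pooled ratio
$\sum_f \mathrm{mito}_f / \sum_f \mathrm{total}_f$ over fields — the
standard stereological choice when per-field totals vary, equal to the
count-weighted mean of per-field densities (asserted as an identity).
Per-field densities are also available. Grid spacing (165 nm default) is
carried as metadata only.

**ΔΔCt.** $\Delta C_T = C_T^{target} - C_T^{ref}$;
$\Delta\Delta C_T$ subtracts the *arithmetic mean* $\Delta C_T$ of the
control genotype (the conventional reading when the source does not
specify), so the control group's geometric mean relative quantity
$2^{-\Delta\Delta C_T}$ is exactly 1. Shifting every reference Ct by a
constant changes nothing — the normalisation property.

## The synthetic-data generators

`simulate_peak_table()` draws, per species, a log-normal baseline
(meanlog $\log 50$, sdlog 1 — broad, right-skewed abundances typical of a
lipidome); multiplies, in each non-reference genotype, by a species-level
effect drawn log-normally around the class's true fold-change (so the class
*median* effect is the configured value — matching a report that prints
one value per class above a species-level scatter); adds multiplicative
log-normal replicate noise (sdlog 0.20 default, ~20% CV); splits each
concentration over two adducts with weights 0.7/0.3; and makes a
configurable fraction (default 0.10) of peaks carry a failing score, SNR
or PQ with equal probability, failing draws strictly below the threshold.
The default true fold-changes are the 26 published class-level values, and
the default species richness per class (AcCa 20, …, PC 56, TG 48; 295
species in all) reflects typical cardiac lipidome coverage, with the
sparse classes (LPE 9, PG 6, PS 5) sized consistently with the small
exact-test sample sizes the published dyadic p-values imply.

`simulate_echo_table()` draws each measurement from a zero-truncated
normal with the published per-genotype group mean and SD (cohorts 5/9/3),
redrawing any animal whose systolic volume or diameter exceeds its
diastolic value. Body and heart weights are *synthetic* presets (WT/HET
30 g, KO 18 g; hearts ~150/150/140 mg) consistent with the qualitative
findings — knockouts weigh about 40% less with similar heart weight.
`simulate_grid_counts()` is binomial point counting;
`simulate_ct_table()` shifts the target Ct by $-\log_2 FC$.

What the generators do **not** emulate: retention times, m/z values and
identification scoring; correlated noise across species sharing acyl
chains; per-sample normalisation error from protein-content adjustment;
non-normal echo measurement error. Passing tests therefore demonstrate
correctness of the computational procedure under the stated stochastic
model, not robustness to every artefact of real instrument data.

## Numerical and design choices

- Exact-test cutoff `exact_n_max = 25`: the convolution is exact and fast
  there; beyond it the flagged normal approximation is already accurate.
- Degenerate inputs are explicit errors (zero diastolic volume, zero total
  grid points, empty control group) or explicit non-results (not-testable
  signed-rank), never silent defaults.
- The even-count median uses the conventional midpoint; published
  fold-changes cannot disambiguate the convention, and the choice is
  documented rather than hidden.
- Simulation sizes used by the test suite and acceptance script — 500
  brute-force oracle cases at $n \le 8$, 500 null classes of 10 species,
  200 recovery seeds for the acylcarnitine preset (20 species,
  species-level log-FC SD 0.1, noise SD 0.05, clean peaks) — were chosen
  to give the binomial bands quoted in the tests adequate resolution.
  Under the null configuration the exact test's attainable size at
  $\alpha = 0.05$ with $n = 10$ is $50/1024 \approx 0.0488$, and the
  observed rejection rates sit inside the 99% band around 0.05.
- The recovery runs use clean peaks (no QC contamination): with
  contamination, asymmetric adduct dropout (one genotype loses an adduct
  group the other keeps) biases individual species fold-changes by up to
  the adduct weight ratio — a property of any sum-over-adducts pipeline,
  exercised separately by the QC tests.

## Known limitations

- Fold-changes require a positive denominator mean; species observed in
  only one genotype are excluded from that comparison (and counted in a
  message) rather than imputed.
- The class list, family size and QC thresholds are configurable, but no
  attempt is made to infer them from data.
- ANOVA/Tukey assumes approximate normality within genotype groups; with
  cohorts of 3–9 animals this is an assumption, not a verified property.
- The exact signed-rank p-values are conditional on the realized tie
  pattern; with heavy rounding of concentrations the attainable
  significance levels coarsen accordingly.
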