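# lipidheart

Choline kinase β (CHKB) catalyses the first step of phosphatidylcholine
synthesis; its loss in mouse (`Chkb`⁻/⁻) produces cardiac hypertrophy,
reduced stroke volume and a striking accumulation of the arrhythmogenic
lipid acylcarnitine. **lipidheart** re-implements the computational analysis
behind such a study as a tested, reusable, tidyverse-native pipeline for:

- **Lipidomics peak-table cleanup** — LipidSearch-style peak tables are
  filtered on signal-to-noise (SNR < 2.0 removed) and peak quality
  (PQ < 0.8 removed); a biological-triplicate rule removes lone surviving
  observations; adduct concentrations of one molecular species are summed;
  biological replicates are averaged into per-genotype species profiles.
- **Class-level paired fold-change statistics** — the package's core
  statistic. For each lipid class *c* and comparison *g* vs WT, a
  fold-change FCᵢ = x̄ᵢ,g / x̄ᵢ,WT is computed per species *i*, and the
  log fold-changes are tested against 0 with an **exact Wilcoxon
  signed-rank test**: the null distribution of W⁺ is built over all 2ⁿ
  sign assignments of the realized (possibly tied) rank vector, and
  p = min(1, 2·min(P(W⁺ ≤ w), P(W⁺ ≥ w))). The 26-test family
  (13 classes × 2 comparisons) is Bonferroni-controlled with dual
  reporting: `∗` marks p < α, `∗∗∗` marks p < α/m.
- **Echocardiography-derived indices** — SV = Vol(d) − Vol(s),
  EF = 100·SV/Vol(d), FS = 100·(LVIDd − LVIDs)/LVIDd, CO = SV·HR/1000,
  corrected-cube LV mass (×0.8 correction), heart-weight/body-weight
  hypertrophy index; genotype groups compared by one-way ANOVA + Tukey HSD.
- **Quantification utilities** — stereological mitochondrial volume density
  (pooled point-count ratio), mitochondria per field, and ΔΔCt relative
  expression (RQ = 2^(−ΔΔCt), normalised to *Gapdh* and a control group).
- **A synthetic-data module** — no raw data were deposited for the study
  this pipeline emulates, so generators reproduce every input table's
  statistical structure (log-normal abundances, genotype fold-change
  presets, adduct splitting, QC contamination, per-genotype echo
  presets), making the whole analysis testable end to end.

## Worked example

```r
library(lipidheart)

res <- lipid_sim_config(seed = 42) |>   # 13 classes, WT/HET/KO presets
  simulate_peak_table() |>
  peaks_to_profiles() |>                # QC filter, triplicate rule,
  test_lipid_classes()                  #   adducts, replicate means
build_class_report(res)
#> # A tibble: 13 × 7
#>    class fc_HET_vs_WT p_HET_vs_WT marker_HET_vs_WT fc_KO_vs_WT p_KO_vs_WT
#>  1 AcCa         1.58       0      "∗∗∗"                  3.01      0
#>  2 Cer          0.634      0.0013 "∗∗∗"                  0.694     0.0267
#>  3 CL           1.67       0.0003 "∗∗∗"                  1.18      0.0001
#>  ...
#> 11 PS           1.72       0.0625 ""                     0.847     0.312
```

The simulated knockout recovers its true acylcarnitine effect (preset
fold-change 3.07; recovered median 3.01 with p below the Bonferroni
threshold), while a class like PS with five testable species can never
beat p = 0.0625 — exactly the granularity the exact test imposes at that
sample size.

```r
glance(res)
#>   n_tests alpha     m n_significant_pre n_significant_post
#> 1      26  0.05    26                18                 13

echo <- simulate_echo_table(echo_sim_config(seed = 7))
echo |> derive_cardiac() |> compare_groups(sv)
#> One-way ANOVA on sv: F(2, 14) = 1.985, p = 0.1742
#> Tukey HSD pairwise comparisons:
#>   contrast estimate conf.low conf.high adj.p.value
#> 1 KO-HET     -21.0     -49.3      7.35       0.165
#> 2 WT-HET      -9.25    -32.9     14.4        0.576
#> 3 WT-KO      11.7      -19.3     42.7        0.595
```

`autoplot(res)` draws the per-species fold-change scatter with total-mass
bars and significance markers; `run_chkb_pipeline(out_dir, seed = 7)` runs
every stage and writes all reports plus a reproducibility manifest.

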