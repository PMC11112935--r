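# tilspot

Spatial Hot/Cold-Spot profiling of tumor-infiltrating lymphocytes from
double-immunohistochemistry cell tables, with the GzmB/CCR8 prognostic
ratio and its statistical and survival layers.

## The problem

CCR8⁺Foxp3⁺ regulatory T cells (CCR8⁺ Tregs) suppress anti-tumor
immunity locally: where they accumulate, neighboring CD8⁺ cytotoxic T
cells express less granzyme B (GzmB), the effector protease that marks
active killing. Whole-slide averages blur this spatial effect, because
lymphocyte infiltration in tumors is strongly clustered. `tilspot`
implements the two quantification protocols used to resolve it on
double-IHC cell-object tables (e.g. HALO-style CSV exports) of a
CCR8/Foxp3 panel and a CD8/GzmB panel from serial sections:

* **WTA protocol** — whole-tumor-area densities over the
  pathologist-annotated tumor mask:
  `[CCR8⁺ Treg] = CCR8⁺Foxp3⁺ cells/mm²`,
  `[Total CD8⁺ T] = CD8⁺ cells/mm²`,
  `[GzmB⁺ CD8⁺ T] = GzmB⁺CD8⁺ cells/mm²`, and
  `[%GzmB⁺ in CD8⁺ T] = 100 · GzmB⁺CD8⁺ / CD8⁺`.
* **ROI protocol** — a box-count density map of CCR8⁺ Tregs on a stride
  grid of 360 × 270 µm fields; the five highest-count, non-overlapping
  fields are the **Hot Spots**, and the five lowest among fields that
  still contain lymphocytes (≥ 10 CD8⁺ **or** ≥ 10 Foxp3⁺ cells) are the
  **Cold Spots**. Matched fields are then measured on both panels, and
  the per-patient representative values are the means over the five
  Hot Spots.
* **GzmB/CCR8 ratio** — the composite prognostic score
  `[%GzmB⁺ in CD8⁺ T] / [CCR8⁺ Treg (cells/field)]` from Hot-Spot means
  (low ratio = strong local Treg accumulation with suppressed CD8
  cytotoxicity), plus the alternative CD8/Foxp3, GzmB/Foxp3 and
  CD8/CCR8 ratios.
* **Statistics** — median-split groupings, OLS correlation,
  Mann–Whitney U, Fisher's exact 2×2 tests for clinicopathological
  association tables, and Kaplan–Meier / log-rank / Cox
  proportional-hazards analysis of progression-free survival (PFS),
  univariate and multivariate.

Because the cell-level data of the motivating cohort are not public, the
package ships a first-class synthetic cohort generator: a Thomas-type
cluster process for lymphocyte positions (shared cluster parents across
the two panels, mimicking serial sections), a logistic local-suppression
link `P(GzmB⁺) = logistic(β₀ − β₁·d)` with `d` the CCR8⁺ Treg count
within 150 µm rescaled to cells/field, and exponential
proportional-hazards PFS driven by the standardized log GzmB/CCR8 ratio.
Every analysis stage is validated against brute-force oracles on this
generator.

## Worked example

```r
library(tilspot)

cfg <- run_config(simulate = sim_config(n_patients = 81), seed = 7)
bundle <- run_pipeline(cfg)
bundle$survival$by_metric[, c("metric", "n_high", "n_low",
                              "pfs3y_high_pct", "pfs3y_low_pct",
                              "logrank_p", "hr_low_vs_high")]
```

```
              metric n_high n_low pfs3y_high_pct pfs3y_low_pct logrank_p hr_low_vs_high
1    gzmb_ccr8_ratio     40    41           62.2          37.8   0.00642          2.322
2 hot_mean_ccr8_treg     40    41           32.6          67.2   0.00218          0.387
3  hot_mean_pct_gzmb     40    41           62.3          37.7   0.00689          2.305
```

Each row dichotomizes the 81 simulated patients at the cohort median of
one ROI metric (40 high / 41 low) and compares PFS: patients with a low
GzmB/CCR8 ratio have a 3-year PFS of 37.8% versus 62.2% in the high
group (log-rank p = 0.0064), and their hazard of progression is 2.3-fold
higher — the ratio behaves as the composite prognostic marker it was
designed to be, while its two components in isolation carry the same
information with opposite orientations (high Treg density is adverse,
high %GzmB⁺ protective). The multivariate Cox model (screened clinical
covariates plus the ratio grouping) retains the ratio:

```r
as.data.frame(bundle$survival$multivariate)
#        term hazard_ratio ci95_low ci95_high p_value
# 1 ratio_low         2.32     1.25      4.33 0.00799
```

Per-patient summaries, per-field metrics, association tables, KM step
curves and a run manifest are returned in the bundle and written as
CSV/JSON when `output_dir` is set. A thin CLI does the same from a
shell:

```sh
Rscript inst/scripts/tilspot simulate --seed 7 --patients 81 --out results/
Rscript inst/scripts/tilspot analyze --input cohort_dir/ --out results/
```

The published 2×2 clinicopathological cross-tabulations of the
motivating 81-patient lung squamous cell carcinoma cohort ship as input
data and can be replayed through the exact-test layer:

```r
subset(replay_crosstabs(), printed_p < 0.05,
       c(variable, grouping, p_value, printed_p, matches_printed))
```

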