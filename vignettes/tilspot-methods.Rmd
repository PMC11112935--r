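---
title: "Methods: spatial Hot/Cold-Spot profiling and the GzmB/CCR8 ratio"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tilspot` quantifies the local interplay between CCR8⁺Foxp3⁺ regulatory
T cells (Tregs) and GzmB⁺CD8⁺ cytotoxic T cells in tumor tissue from
double-IHC cell-object tables, and ties the resulting spatial scores to
progression-free survival (PFS). This vignette is the package's account
of its methods: the measurement model, every tunable parameter, what the
synthetic cohort generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## Measurement model

The input per patient is two point patterns in one µm coordinate frame
(image convention, y down): panel A cells carry boolean CCR8 and Foxp3
marks, panel B cells carry CD8 and GzmB marks. The panels come from
serially sectioned tissue, so regional densities correspond across
panels but individual cells do not; all cross-panel quantities in the
package are therefore field- or area-level, never cell-matched. A tumor
mask (GeoJSON polygons, µm) restricts all counting; a centroid on the
mask boundary counts as inside (closed polygons — a deterministic,
documented tie rule).

**WTA protocol.** Marker counts over the whole mask divided by mask area
(mm²): CCR8⁺Foxp3⁺ (the strict double-positive definition of a CCR8⁺
Treg — CCR8⁺Foxp3⁻ cells count toward no Treg metric, Foxp3⁺CCR8⁻ cells
only toward the total-Foxp3 density), total Foxp3⁺, total CD8⁺, and
GzmB⁺CD8⁺, plus `%GzmB⁺ in CD8⁺ T` = 100 × GzmB⁺CD8⁺/CD8⁺. The
percentage is undefined exactly when the region has no CD8⁺ cell; a
GzmB⁺ record without CD8 positivity is tolerated on input and ignored by
every CD8-denominated metric.

**ROI protocol.** Candidate fields of 360 × 270 µm (one high-power
microscope field; area 0.0972 mm²) are enumerated on a stride grid over
the mask bounding box, with half-open extents `[x0, x0+w) × [y0, y0+h)`
so no cell is double-counted on shared edges. The CCR8⁺ Treg box-count
map (no kernel smoothing) drives selection:

* **Hot Spots** — greedy maximal selection: repeatedly take the
  highest-count candidate that does not overlap an already selected
  field, until five fields are chosen. Ties break by (count descending,
  y0 ascending, x0 ascending), so selection is a pure function of the
  map, invariant to enumeration order.
* **Cold Spots** — the mirror-image greedy minimal selection, restricted
  to fields with at least 10 CD8⁺ *or* at least 10 Foxp3⁺ cells (the
  lymphocyte floor excludes "areas with no lymphocytes"; one stain
  clearing the floor suffices), and additionally barred from overlapping
  any selected Hot Spot.

Per-patient representative values are unweighted means over the five Hot
Spots (fields with undefined %GzmB are excluded from the percentage mean
and logged). The composite score is
`gzmb_ccr8_ratio = hot-mean %GzmB⁺ / hot-mean CCR8⁺ Treg count`;
CD8/Foxp3, GzmB/Foxp3 and CD8/CCR8 ratios are built analogously. A ratio
is undefined exactly when its denominator mean is zero; such patients
are excluded from groupings on that ratio but never from the cohort.

**Statistics.** Median-split grouping labels a patient *high* iff the
value strictly exceeds the cohort median (ties go low; with 81 distinct
values this yields the 40/41 split). Correlation is ordinary least
squares with the two-sided slope test; two-group comparisons use the
Mann–Whitney U test (exact enumeration when the combined sample is ≤ 20
and tie-free, otherwise the normal approximation with tie and continuity
corrections); 2×2 associations use Fisher's exact test with the
probability-ordering two-sided p-value (the convention of
`stats::fisher.test` and of common statistical desktops; mid-p and
doubling variants differ and are not used). Survival uses the
product-limit estimator (3-year PFS = S(36 months), right-continuous
steps), the two-group log-rank test, and Cox proportional-hazards models
with **Efron** tie handling pinned for reproducibility. The multivariate
model takes the clinical covariates whose univariate Cox p < 0.05 plus
the primary ratio grouping — a configurable screening rule, not a claim
about the optimal model. No multiple-testing correction is applied
anywhere, mirroring the reporting style of the analyses this package
operationalizes.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
patient data. It emulates, per patient:

1. **Clustered infiltration** — a Thomas-type cluster process: a Poisson
   number of cluster parents uniform in the mask, Poisson offspring per
   parent with isotropic Gaussian spread, plus uniform background.
   Offspring falling outside the mask are discarded. The two panels
   share one set of cluster parents and draw offspring and background
   independently: fully independent parent draws would make Hot Spots
   (selected on panel A) CD8-poor relative to Cold Spots, inverting the
   regional correspondence that serial sections of one tissue actually
   show; sharing parents reproduces it.
2. **Phenotypes** — each cell is CD8⁺, Foxp3⁺ or marker-negative by
   fixed fractions; the CCR8⁺ fraction among Foxp3⁺ cells is drawn
   logit-normal per patient, creating the between-patient high/low Treg
   contrast the protocols are designed to resolve.
3. **Local suppression** — each CD8⁺ cell is GzmB⁺ with probability
   `plogis(beta0 − beta1·d)`, where `d` is the CCR8⁺ Treg count within
   `suppression_radius_um`, rescaled from the circular neighborhood to
   cells/field units (× field area / circle area) so `beta1` stays
   comparable across radii and to field-level counts.
4. **Outcomes** — PFS times are exponential proportional hazards with
   linear predictor `log_hr_per_unit ×` (cohort-standardized log
   GzmB/CCR8 ratio, computed by actually running the ROI protocol on the
   simulated slide); censoring combines an independent exponential
   process calibrated to `censor_rate` with administrative censoring at
   `follow_up_months`. Binary clinicopathological covariates are drawn
   independently of everything (so association tables are null by
   construction).

Defaults (`sim_config()`): 81 patients; 4000 × 3000 µm slides;
Pois(30) clusters × Pois(60) cells, spread 80 µm, background 40
cells/mm²; CD8 fraction 0.45, Foxp3 0.25; CCR8|Foxp3 ~ logit-normal
(location 0.35, logit-SD 0.8); `beta0 = 0.5`, `beta1 = 0.08` per
cells/field, radius 150 µm (comparable to the 360 × 270 µm analysis
scale); baseline hazard 0.015/month (3-year PFS ≈ 0.58 at the cohort
mean, inside the 57–75% range typical of resected lung squamous cell
carcinoma), `log_hr_per_unit = −0.6` per SD of log ratio (a dichotomized
low-vs-high hazard ratio a little above 2), censor rate 0.30, follow-up
60 months; covariate prevalences follow a typical surgical LSCC cohort
(90% male, 96% smokers, 23% node-positive, 43% stage II/III, 12–14%
invasion rates). The suppression and survival effect magnitudes are
**illustrative** — no quantitative magnitude for local suppression is
available to estimate them from — and are chosen once, on the power
reasoning above, not fitted to any output.

What the generator does **not** emulate: staining artifacts,
segmentation error, cell morphology, stromal/intra-tumoral
compartments, non-rectangular tumor masks (analyses accept arbitrary
simple polygons; the generator uses rectangles), spatial correlation of
clinical covariates, or cell-level correspondence between panels.
Passing tests therefore demonstrate correctness of the measurement and
inference pipeline under clustered, suppressed, prognostic data — not
robustness to upstream image-analysis failure modes.

## Numerical choices and degenerate inputs

* Field counting is exact integer box-counting; the stride grid origin
  is the mask bounding-box corner. A field larger than the bounding box
  is a configuration error.
* Fewer than five selectable Spots (candidates exhausted, or no
  lymphocyte-bearing field for Cold Spots) yields the fields that exist
  plus a warning; the patient is retained. Zero Hot Spots is a
  patient-level error.
* Empty CD8 lists give empty GzmB flag vectors, not errors; `beta1 = Inf`
  with zero local density falls back to `plogis(beta0)`.
* Point-in-polygon is even-odd ray casting with an explicit boundary
  pass (tolerance 1e-9 µm); mask polygons must be simple
  (self-intersection is rejected by an O(n²) segment check) and hole-free.
* Cox models refuse to fit with fewer events than covariates + 1;
  |log HR| > 10 triggers a separation warning.
* All simulation is deterministic given `seed`: identical configuration
  and seed give byte-identical tables and report bundles.

## Calibration properties worth knowing

The package's null-calibration check (suppression and survival link off)
measures the realized type-I error of the four test families at
nominal 5%. Two families are intrinsically conservative and sit near the
lower end of their band:

* **Fisher's exact test** is a conditional exact test; its realized
  level at n = 81 with 40/41 margins and realistic covariate prevalences
  is ≈ 3–4%, lower still for rare covariates. This is a well-known
  property of exact conditional inference, not an implementation
  artifact.
* **The OLS slope test on field percentages** is mildly conservative
  because the precision of a field's %GzmB rises with its CD8 count,
  which co-varies with the Treg-count regressor; the homoskedastic
  variance estimate then overstates the slope variance. The package
  keeps plain OLS deliberately, since that is the correlation analysis
  the protocols prescribe.

The Mann–Whitney and log-rank families are nominal. The Cold-Spot
rule of avoiding Hot-Spot overlap matters here: without it, slides with
uniformly zero Treg counts select identical field sets as both Hot and
Cold Spots through the deterministic tie-break, and the Hot-vs-Cold
comparison degenerates.

## Problem sizes used by the test suite

Replicate-heavy checks run the full cohort structure (81 patients,
40/41 splits, the complete ROI protocol) on scaled-down slides
(1600 × 1200 µm, ≈ 330 cells per panel): 200 replicate null cohorts for
calibration, 100 random slides for the selection-oracle equivalence, and
one full-size default cohort for direction recovery. Cox coverage uses
200 replicates of n = 300 with ~30% censoring plus one n = 1000 point
recovery. These sizes are the package's choices for tight, deterministic
tests; all of them scale up by changing `sim_config()` fields.

## Known limitations

* Stromal versus intra-tumoral compartments are not separated — the
  protocols measure everything inside the mask.
* Serial-section co-registration is assumed done upstream: the two
  panels must arrive in one coordinate frame (the `frame` tag is
  checked, registration is out of scope).
* The candidate-grid stride (default 90 µm = ¼ field width) and the
  non-overlap constraint approximate a proprietary "top fields" picker;
  both are configurable (`roi_params()`), and the greedy non-overlapping
  selection is proven equal to its exhaustive-search specification by
  property tests rather than to any external tool.
* The exponential PFS model has constant baseline hazard; it is a
  generator for validating inference, not a disease model.
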