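---
title: "Methods: placental permeability modeling with QSAR, ARKA and q-RASAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: placental permeability modeling with QSAR, ARKA and q-RASAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placperm)
```

## The endpoint and its classification

The modeled endpoint is **log FM**: the base-10 logarithm of the
fetal-to-maternal blood concentration ratio of a compound at
equilibrium. FM is dimensionless; values near 1 mean free equilibration
across the placenta, values well below 1 mean the compound largely
stays in the maternal circulation. All models in this package are
linear on the log FM scale — the working assumption is that passive
diffusion dominates placental transfer for small, mostly neutral
molecules, so log-scale partitioning behaves additively in descriptors
of size (`M_w`, Da), polarity (`TPSA`, Å²) and lipophilicity (`iLOGP`
and other logP estimates).

Qualitative permeability uses the FM cutoff 0.3: a compound crosses
(class C, binary score PL1) iff `10^log_fm >= 0.3`. Two numerical
choices are deliberate:

* **The boundary is inclusive** (FM exactly at the cutoff → C). The
  cutoff's open/closed status is not standardized; an inclusive rule is
  deterministic and documented.
* The comparison is carried out on the **log scale with a 1e-12 slack**,
  so that `log_fm = log10(0.3)` classifies as C despite
  `10^log10(0.3)` rounding a hair below 0.3 in floating point.

The alternative clearance-index criterion (ex vivo clearance relative
to antipyrine, cutoff 0.8) is documented but not modeled; when both
measures exist for a compound, the FM-based call prevails.

## The model bank

`get_model("eq1")` … `get_model("eq9")` return nine
fixed-coefficient models exactly as published (central estimates; the
± intervals are not propagated). They fall into three families:

* **MLR QSAR** (eq1–eq5) on conventional descriptors;
* **ARKA MLR** (eq6–eq7) on the two supervised aggregate descriptors;
* **q-RASAR PLS** (eq8–eq9) on descriptors fused with Read-Across
  features.

The bank only applies models. `ARKA1`/`ARKA2` and
`RA_function`/`MaxPos`/`gm` must be supplied as columns or produced by
the `arka_pipeline()` / `compute_rasar_descriptors()` machinery —
keeping the published coefficients separate from any re-derivation of
their inputs.

One metadata conflict is preserved rather than resolved: for eq8 the
printed equation block and the printed comparison table disagree on
adjusted R² (0.838 vs 0.789). The analytic identity
`r2_adj = 1 − (1 − r2)(n − 1)/(n − p − 1)` with R² = 0.800, n = 40 and
p = LV = 2 gives 0.789, so the equation-line value is almost certainly
a transcription slip; both values are kept in the model's metadata
(`notes` field) and neither is silently corrected.

## Validation statistics

`training_stats()` implements `R² = 1 − RSS/TSS`, the adjusted form
above, and `F = [R²/(1 − R²)]·[(n − p − 1)/p]`. For PLS models the
parameter count p is the **number of latent variables**, not the number
of original descriptors — this convention reproduces the published F
values (74.0 and 83.71 at LV = 2) and is applied consistently in
`validation_report()`.

Internal validation uses leave-one-out cross-validation
(`q2_loo = 1 − PRESS/TSS`, TSS about the full training mean) and
8-fold leave-many-out RMSECV. Fold construction is not standardized
anywhere, so `rmsecv_lmo()` makes it part of the contract: a seeded
uniform shuffle (default seed 1) into near-equal folds; the same seed
always yields the same folds. External validation reports
`Q²_F1` (error scaled by deviations about the *training* mean),
`Q²_F2` (about the *test* mean), RMSEP, and `R²_ext`. `R²_ext` is
defined here as the squared Pearson correlation between observed and
predicted test values — the name "determination coefficient of
external prediction" admits several formulas; the correlation form is
standard and bounded by 1.

## Regression machinery

* `fit_ols()` solves least squares by QR; rank deficiency is an error
  naming the collinear columns (no silent dropping).
* `forward_stepwise()` adds, at each step, the candidate with the
  smallest partial-F p-value below `p_enter` (default 0.05). Ties break
  to the lowest column index; if nothing qualifies at step one an
  intercept-only model is returned with a warning, not an error.
* `pls_fit()` is NIPALS PLS1 with auto-scaling (unit-variance columns,
  centred response). The equivalent regression vector is back-mapped to
  the original descriptor scale, so prediction is a plain affine map
  and is bitwise-reproducible.
* `vip_scores()` uses the standard weight/explained-variance VIP with
  the normalization `mean(VIP²) = 1`; `vip_reduce()` repeats
  fit-score-drop until every score reaches the floor (default 1.0),
  with an iteration cap of 50 purely to guarantee termination.
* `best_subset()` enumerates all subsets up to `max_size`, ranks by
  leave-one-out Q² computed via the hat-matrix PRESS shortcut
  (`residual/(1 − h_ii)`), and breaks ties lexicographically on the
  joined descriptor names. The test suite checks the shortcut against
  explicit per-row refits. A configurable guard limit (default 1e5
  combinations) forces pool reduction instead of runaway enumeration.
* Upstream of PLS/stepwise, `prefilter_descriptors()` removes
  zero-variance columns (variance ≤ 1e-12) and reduces near-collinear
  groups (pairwise |r| > 0.99) to the first-listed member. The source
  procedure discards such variables "automatically" without stating
  thresholds; these two are this package's explicit choices.

## ARKA

ARKA reduces a modeling descriptor set to K = 2 aggregates. The
procedure, in this package's formulation:

1. Min-max scale each descriptor to [0, 1] on the training set
   (`scale_minmax()`); test/screen compounds are transformed with the
   training parameters and may fall outside [0, 1] — no clipping.
2. Split training compounds at the **median response** (`y > median` is
   the higher half; ties at the median go to the lower half — a
   deterministic choice where the source is silent). A descriptor joins
   group 1 if its mean scaled value is higher in the higher-response
   half, group 2 otherwise (equality → group 2).
3. `ARKA1`/`ARKA2` are each compound's mean scaled value over group-1 /
   group-2 descriptors. An empty group yields 0 with a warning.

Min-max scaling is adopted because it is the convention of the ARKA
framework this module emulates; an alternative grouping by the FM = 0.3
class boundary instead of the response median is plausible but is left
as a non-default option with no claim of fidelity.

Confidence quadrants: points with both ARKA values of the same sign
(first or third quadrant of the ARKA2-vs-ARKA1 plane) are
`less_confident`; axis points are `confident`. Raw min-max ARKA values
are non-negative, so the plane is informative only after centering —
`arka_pipeline(center = TRUE)` (the default) centres by the training
means for the quadrant analysis while leaving the regression inputs
uncentred. Both paths are tested.

## Read-Across and q-RASAR

Similarity is computed on auto-scaled descriptors (training mean/sd)
from the Euclidean distance d:

* euclidean kernel: `1/(1 + d)`;
* gaussian: `exp(−d²/(2σ²))`;
* laplacian: `exp(−d/γ)`.

The kernels' names and hyperparameters follow the reference tools; the
formulas themselves are the conventional forms, chosen here because the
source names no formulas. `ra_predict()` takes the `n_close` most
similar source compounds (ties → lexicographically lower compound id)
and returns the similarity-weighted mean of their responses — a convex
combination, hence bounded by the close-set response range. Internally
the weights are computed in log space: for very tight kernels the raw
similarities underflow to zero although their *ratios* are well
defined, and the log-space form preserves the exact σ→0⁺ (nearest
neighbour) and σ→∞ (unweighted mean) limits. The applicability error
("all similarities numerically zero") therefore fires only when
distances are genuinely non-finite.

`optimize_hyperparameters()` splits the training set 75/25 into
sub-training and validation with a seeded shuffle (the split ratio is
unstated in the source; 0.75 is this package's default) and minimizes
validation RMSE over a bounded default lattice: σ, γ ∈ {0.25, 0.5, 1,
2, 4}, `n_close` ∈ 2…8. Ties take the first grid point in order.

RASAR descriptors per query, over the close set: `RA_function` (the
Read-Across prediction), `AvgSim`/`SDSim` (mean/sd of close
similarities; sd defined as 0 for a single close compound), `MaxPos` /
`MaxNeg` (maximum similarity to a higher-/lower-response source, 0 if
that half is absent from the close set; higher/lower by training-median
split), and `gm = 1 iff MaxPos ≥ MaxNeg`. The reference tools do not
publish a formula for `gm`; this binary concordance definition is an
operational approximation, flagged as such, and the package makes no
claim of bit-compatibility with those tools.

`build_qrasar()` computes training-compound features **leave-self-out**
(a compound's own row never serves as its source — otherwise
`RA_function` would leak the response into Q²_LOO), fuses QSAR
descriptors with RASAR features, selects by `best_subset()` and fits a
final PLS with `n_latent = 2` by default, matching the published LV
count. The auto-scaling used for distances is fitted once on the full
training set; only the source *rows* are left out.

## Drug-likeness filters

Eight filters with printed thresholds (see `?evaluate_filters`). Two
interpretation choices are explicit modeling decisions, since the exact
Mordred-vs-SwissADME implementation differences are not published:

* "Lipinski (Mordred)" uses MLOGP ≤ 4.15 for the lipophilicity
  sub-rule and is always strict (zero violations) — this is the variant
  most closely linked to placental permeability; "Lipinski (SwissADME)"
  uses cLogP ≤ 5 and honours the `tolerance` argument
  (`allow_one` accepts a single violation).
* The two Ghose variants share the printed bounds and differ only in
  tolerance handling.

Egan's WLOGP bound is exclusive (< 5.88) exactly as printed; every
other bound is inclusive. A filter with a missing input column is
reported not-evaluable (`NA`), never failed — missing data is an error
in modeling but merely a gap in screening.

`cluster_filter_profiles()` clusters the binary filter columns together
with the PL1/PL0 column (Jaccard distance by default, simple-matching
as fallback when a column pair has an empty union, where Jaccard is
undefined) and reports the filter joining PL at the smallest cophenetic
height. On synthetic compounds whose PL is derived from the strict
Lipinski rule itself, that filter is PL's nearest neighbour under every
linkage × distance combination — the level at which the robustness
claim is testable without the original compound tables.

## The synthetic-data generator

`generate_dataset()` draws descriptors from stated marginals. The
defaults encode the property envelope of the reference compounds:
`M_w` uniform 100–700 Da, `TPSA` uniform 0–271 Å², `iLOGP` uniform
−1–6; `MLOGP` (normal, mean 2.5, sd 1.5) and integer `HA` (0–12) /
`HD` (0–6) counts are added so that the binary `Lipinski` descriptor
can be derived from the drawn properties through the same strict
rule-of-five code path as the filter module (the two are asserted
identical in the tests). The response is
`intercept + Σ coef·descriptor + N(0, noise_sd)`. Pairwise correlation,
when requested, is induced through a Gaussian copula on the underlying
normals. `generate_reference_like()` fixes the shape of the reference
set: 54 compounds, 40 train / 14 test, a truth with the negative-`M_w`
/ positive-`TPSA` sign structure, noise sd 0.2.

What the generator does **not** emulate: real descriptor distributions
are heavy-tailed and strongly inter-correlated (size, polarizability
and lipophilicity co-vary); descriptors here are independent unless a
correlation is requested, and integer counts are uniform rather than
size-linked. A green parameter-recovery test therefore establishes that
the estimation machinery is correct under the stated world, not that
the published models would be recovered from real measurements.

## Determinism and degenerate inputs

Every stochastic step (fold shuffles, sub-training splits, the
generator) takes an explicit seed and restores the caller's RNG state.
Tie-breaks are fixed throughout (column order for stepwise, compound-id
order for similarity, grid order for hyperparameters, lexicographic
subset names for best-subset). Degenerate inputs fail loudly and early:
constant columns, duplicate identifiers, missing responses for
train/test compounds, rank-deficient designs and non-finite values are
all errors naming the offending compound or column; missing values are
never imputed anywhere.

## Known limitations

* The nine bank models are transcriptions; their original training
  data is not shipped, so the package can verify their printed summary
  statistics analytically but cannot refit them.
* `gm`, `MaxPos` and the RASAR roster approximate tools whose exact
  definitions are unpublished; no bit-compatibility is claimed.
* The ARKA grouping rule (response median) is one of at least two
  plausible readings; the class-boundary alternative is available but
  carries no fidelity claim.
* Only regression-endpoint modeling is implemented; classification-mode
  ARKA/RASAR, applicability-domain metrics and Y-randomization are out
  of scope.
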