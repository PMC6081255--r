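---
title: "Methods: radiomic discrimination of symptomatic basilar-artery plaque"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic discrimination of symptomatic basilar-artery plaque}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and limitations of
the `plaquerad` workflow: a re-implementable pipeline that discriminates
acute/sub-acute symptomatic from asymptomatic basilar-artery plaque on
high-resolution vessel-wall MRI using conventional plaque measurements, a
2D radiomic feature engine, and a shallow random-forest classifier, all
exercised on a synthetic image cohort.

## The analysis in one paragraph

Each patient contributes one analysed cross-sectional slice (the slice of
maximum plaque area) in three contrasts — pre-contrast T1, T2 and
contrast-enhanced T1 — with manual segmentations of the lumen, the outer
wall, the plaque (wall minus lumen), a reference muscle region and a
grey-matter reference of about 15 mm². Conventional measurements and 98
radiomic features per sequence are computed from these regions. Univariate
screening feeds a stepwise logistic model (the *traditional* tier);
radiomic features passing a significance + AUC gate feed a ten-tree,
depth-3 random forest (the *radiomic* tier); a *combined* tier gives the
forest the conventional markers as well. Performance is summarised by ROC
AUC, the Youden-optimal operating point with likelihood ratios, and DeLong
tests between tiers; inter-reader reproducibility is summarised by
ICC(2,1), Bland–Altman limits and Cohen's κ.

## Conventional measurements

* **Plaque burden** `(1 − lumen/outer) × 100 %`. Areas are pixel counts
  times pixel area; no sub-pixel polygon fitting, matching manual raster
  segmentation.
* **MLA** — the minimum lumen area across available slices; with a single
  analysed slice (the maximum-plaque-area slice) its lumen area plays that
  role.
* **Stenosis** — diameter-based: areas are converted to equivalent-circle
  diameters, `(1 − d_sten/d_ref) × 100 %`. The reference site is supplied by
  the caller (the generator provides a latent healthy lumen area); the
  original measurement protocol lives in an external clinical reference, so
  only the arithmetic is fixed here.
* **IPH** — the published rule is a signal threshold ("more than 150 % of
  muscle signal on pre-contrast T1") without an aggregation rule. We require
  an 8-connected component of at least `min_component_px = 3` hyperintense
  plaque pixels (every pixel above 1.5 × muscle mean), which is robust to
  single-pixel noise; the component size and the threshold are parameters.
* **Enhancement ratio** — the grey-matter-normalised formula
  `((post_plaque/post_gm)/(pre_plaque/pre_gm) − 1) × 100 %`. The
  normalisation makes the ratio invariant to independent global rescaling of
  the pre- and post-contrast scans, which is exactly why it is used: MR
  intensities are arbitrary per-scan units.

## The radiomic engine

Discretisation uses equal-width bins over the in-mask intensity range with
`n_bins = 32` (the source protocol states discretisation but no bin count;
32 is a common radiomics default and is exposed in the API). The maximum
intensity is assigned to the top bin; a constant ROI maps to bin 1.

The catalogue is fixed and ordered (98 names): 14 first-order moments plus
18 histogram/percentile auxiliaries, 10 shape descriptors, 24 GLCM, 16
GLRLM and 16 GLSZM features. The published feature count (94) is not
enumerated anywhere; this catalogue is a documented superset of every named
feature, with stable order, shipped as `feature_catalogue()`.

Conventions, fixed across all texture families:

* grey-level indices *i*, *j* are 1-based bin labels; logs are base 2 with
  `0·log 0 ≡ 0`;
* GLCM/GLRLM use distance 1 and the four in-plane directions (0°, 45°, 90°,
  135°); features are computed per direction and averaged; pixel pairs and
  runs crossing the mask boundary are discarded; directions without a valid
  pair are dropped from the average, and an ROI with no valid pair in any
  direction raises an error rather than returning silent NaNs;
* GLCMs are symmetrised and normalised per direction;
* GLSZM zones are 8-connected components of equal grey level. Under
  8-connectivity a checkerboard's levels connect diagonally into one zone
  per level — the 4-connected intuition ("all zones size 1") does not hold,
  and the tests pin the 8-connected behaviour;
* shape features treat the slice as a slab one slice-thickness deep:
  `Volume = area × thickness`, `SurfaceArea = 2·area + perimeter ×
  thickness`, maximum diameters from pairwise pixel-centre distances (the
  3D and column/row variants add the thickness offset);
* first-order spread statistics use the population convention
  (denominator n).

The whole engine is validated against independent brute-force enumerators
(explicit loops over pixel pairs, run walks and flood fills) on hundreds of
random small images to 1e-10, and against hand-enumerated fixtures.

## Statistical machinery

* **t-test**: Student pooled-variance by default (`var_equal = TRUE`),
  Welch switchable — the pooled variant matches the era's SPSS default.
  Zero-variance degenerate inputs return p = 1 (equal means) or 0.
* **χ²**: Pearson without continuity correction by default, correction by
  flag. The printed univariate p-values of the source cohort cannot be
  matched to a unique χ² variant from the printed counts, so both variants
  are exposed and none is privileged.
* **Stepwise logistic**: forward selection by likelihood-ratio p-value with
  entry 0.10, backward pruning at removal 0.05, in the SPSS forward-LR
  style. Selection states are tracked and the procedure stops if a state
  repeats — a variable whose removal p lies in (0.05, 0.10) would otherwise
  enter and leave forever. Complete separation (possible: the asymptomatic
  IPH prevalence is 1/35, so simulated cohorts regularly contain zero
  asymptomatic IPH) is flagged on the fit rather than silently reported.
* **Feature gate**: t-test p < 0.05 *and* univariate AUC > 0.65, the AUC
  taken symmetrically as max(AUC, 1 − AUC). No multiple-testing correction
  is applied across the 98 features, mirroring the source analysis; a
  Benjamini–Hochberg option exists in the univariate tools but is off.
* **Operating point**: "optimised sensitivity/specificity" is read as the
  Youden-J maximum; ties are broken toward higher specificity; accuracy,
  LR+ = sens/(1−spec) and 1/LR− = spec/(1−sens) are reported at the same
  threshold.
* **DeLong**: placement-value implementation with the structural
  S₁₀/S₀₁ covariance components; degenerate variance returns z = 0, p = 1.
  Cross-checked in the tests against `pROC` and against a bootstrap
  variance.
* **ICC**: single-measure, two-way random, absolute agreement — ICC(2,1)
  from the two-way ANOVA mean squares. Absolute agreement (not consistency)
  because a systematic offset between readers is a real disagreement for
  these measurements. The "average ICC" over a feature set is the
  arithmetic mean of per-feature ICCs.

## The classifier

"Ten classification trees with three layers" is implemented as a bootstrap
forest of `n_trees = 10` binary trees with `max_depth = 3` (root plus two
internal levels, at most 8 leaves), Gini impurity, `⌈√d⌉` features per
split, minimum leaf size 2, and leaf-probability averaging (hard majority
votes are available by flag since the source text does not distinguish the
two). Ties in the best split break toward the lowest feature index and then
the lowest threshold, and all randomness flows from one seed, so fits are
bit-reproducible. The forest is implemented natively (not delegated to an
external library) so the tree structure is inspectable, serialisable to
JSON, and portable across platforms.

**Evaluation protocol.** The source analysis reports what is almost
certainly resubstitution performance (no held-out set is mentioned at
n = 96). The pipeline therefore scores resubstitution by default — that is
what its diagnostic table emulates — and `run_radiomic_model(cv_folds = 5)`
additionally reports a stratified 5-fold cross-validated AUC, with
selection redone inside each training fold, as an explicit measure of the
optimism (the worked example in the README shows the gap: about 0.99
resubstitution vs about 0.83–0.88 cross-validated).

**The combined tier.** The combination mechanism is not specified in the
source. Plainly concatenating the three conventional markers to ~70
selected radiomic features dilutes them: with `mtry ≈ 9` they are rarely in
a split's candidate set, and the combined forest became the radiomic forest
plus noise. The stated design here is therefore: the forest receives the
selected radiomic features plus IPH, MLA, the enhancement ratio *and the
traditional model's linear predictor*, and these four columns are included
in every split's candidate subset (`always_try`). That keeps the
conventional signal available at every node without changing the forest
family.

## The synthetic cohort generator

No images from the source cohort are available, so the generator is the
study-conditions module: it fixes the cohort structure the analysis
assumes, and everything downstream is tested against it.

Geometry (per patient): a 64×64 grid at 0.3 mm in-plane spacing and 2 mm
slice thickness — the published acquisition's resolution class — with one
analysed slice. The lumen is an ellipse of area MLA drawn from a truncated
normal per group (3.78 ± 2.80 vs 2.39 ± 1.46 mm²; bounds 0.6–14 mm²; the
location is mean-adjusted so the post-truncation mean stays on target). The
wall/plaque cross-sectional area is drawn from the group wall-volume
statistics divided by slice thickness (20.08 ± 12.00 vs 13.70 ± 7.32 mm²),
and the outer wall is an ellipse of area MLA + plaque area. Plaque burden
is then *emergent* — about 83–85 % in both groups, matching the published
burden means — rather than drawn; drawing burden directly would cancel the
wall-area difference between groups that the published shape statistics
report. Reference regions: a muscle disc and a ~15 mm² grey-matter disc,
disjoint from the vessel.

Intensities: constant wall base plus a spatially correlated noise field —
white noise smoothed with a Gaussian kernel whose width is the *inverse* of
the group's texture-heterogeneity parameter (defaults 0.75 symptomatic,
0.50 asymptomatic; T2 uses 0.65 for both groups with a wide per-patient
spread, since T2 texture carried no group signal in the source). The kernel
width is the texture knob: heterogeneity 0 gives a constant annulus (zero
texture entropy downstream), and increasing heterogeneity strictly
increases mean GLCM entropy (a property test pins this on 50-study
batches). Discretisation makes texture features invariant to the noise
amplitude, so only the correlation structure and the ROI geometry carry
texture information — with ~150–250-pixel ROIs the co-occurrence matrix is
sparsely sampled, which caps entropy sensitivity; the generator therefore
reproduces the *direction and approximate size of the group gaps* in the
published feature table, not their absolute values. A substantial part of
the entropy and run-length gaps is carried by the plaque-size difference,
which is also true of those features mathematically.

IPH: with probability 19/61 (symptomatic) vs 1/35 (asymptomatic), a
3–8-pixel 8-connected blob at 1.6–2.2 × muscle signal is grown by
breadth-first search inside the plaque (BFS guarantees the blob is one
connected component, so the 150 % rule recovers it). CE-T1: the plaque is
rescaled so the enhancement-ratio formula recovers a value drawn from the
group distribution (24.20 ± 29.46 vs 3.38 ± 21.91 %) exactly. Each
sequence image is finally multiplied by its own lognormal(0, 0.35) global
factor — MR intensities are arbitrary per-scan units — which leaves every
within-scan-normalised quantity untouched and makes non-normalised
absolute-intensity statistics uninformative, as they are in practice.

Clinical covariates follow the published group frequencies; sex and smoking
are drawn with a logit shift shared with the imaging markers rather than
independently, because risk factors act through plaque biology — fully
independent draws would stack the printed marginal gaps into extra
independent signal and push the traditional model above its plausible
performance band.

The second reader is emulated by `perturb_segmentation`: boundary pixels of
the lumen and outer wall are randomly flipped (dilation/erosion candidates,
`jitter_scale` expected displacement in pixels), invariants re-established,
images untouched.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: MR physics (coil profiles, partial volume, flow
artefacts), 3D vessel tortuosity and multi-slice context, real plaque
component architecture (the IPH blob is a flat hyperintense disc, so T1
histograms compress around it and the T1 entropy gap is attenuated relative
to the published one), reader behaviour beyond boundary jitter, and any
correlation structure among covariates beyond the single shared-marker
shift. Radiomic-feature ICCs under boundary jitter are lower for
small-dynamic-range CE-T1 first-order/texture features than the published
reader study found, because jitter of a ~200-pixel ROI perturbs those
features more than human re-segmentation apparently did.

## Numerical choices and degenerate inputs

* Ties: Youden ties → higher specificity; split ties → lowest feature
  index, lowest threshold; AUC ties → 1/2 per tied pair.
* A split whose floating-point midpoint fails to separate the node (two
  adjacent near-equal values) becomes a leaf.
* Degenerate inputs are explicit: zero-variance t-tests (p ∈ {0, 1}), zero
  χ² marginals (error), one-class AUC/forest inputs (error), empty feature
  selection (degenerate model, AUC 0.5, flagged), zero between-subject
  variance ICC and both-raters-constant κ (NaN with warning), identical
  scores in DeLong (z = 0, p = 1).
* All simulation randomness is seed-isolated (`.Random.seed` is saved and
  restored), so library calls never perturb a caller's RNG stream.

## Problem sizes

The test-suite and acceptance runs use: the full 96-patient cohort for
pipeline checks (50 repeated seeds for the tier-ordering stability), 200
patients per group for distribution-recovery checks, 500 random ≤8×8 images
for the brute-force texture equivalence, 1000 null features for the
selection-gate calibration, a 2000-replicate bootstrap at n = 100 for the
DeLong variance check, and a 40-patient subset for the reader-agreement
emulation. These sizes give stable statistics for every check while keeping
a full run in the minutes range on one core.
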