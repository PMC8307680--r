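---
title: "Methods: preprocessing, differential abundance and signature discovery for sEV lipidomics panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing, differential abundance and signature discovery for sEV lipidomics panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the data
model the pipeline assumes, what each stage computes and why, the numerical
and design decisions that were genuinely open, what the synthetic-panel
generator does and does not emulate, and the known limitations. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## The data model

A panel is a samples × metabolites matrix of concentrations (μmol) from a
targeted lipidomics assay, with two qualitatively different kinds of missing
cell:

* **below-LOQ ("zero") values** — the measurement fell under the limit of
  quantitation of that compound on that 96-well preparation plate. These are
  left-censored: the value exists but is known only to lie in (0, LOQ).
* **IS failures** — the internal standard failed, so the measurement is
  missing for technical reasons unrelated to the underlying concentration.

Samples carry a group label from an ordered set (default HC, LN, LC for
healthy controls, benign nodules, lung cancer in a screening cohort) and a
plate identifier; each plate is treated as one batch. Metabolites carry a
lipid class (AC, LPC, PC, PC-O, SM, Cer, DG, TG, CE, HEX) and one LOQ per
plate.

## Preprocessing chain

The order is fixed: policy → below-LOQ imputation → kNN imputation → log2 →
batch correction; permille normalization applies to the *unlogged* imputed
concentrations. Re-running with the same seed is bit-identical.

**Missingness policy.** Per compound and group, the fractions of below-LOQ
and IS-failure cells are computed over that group's samples. Tier 1 retains
a compound iff every group has ≤ 50% below-LOQ *and* ≤ 10% IS failures
(`zero_missing_ceiling`, `is_missing_ceiling`). The quantitative tier is
strict (< 50% below-LOQ in every group). The boundary case — exactly 50% —
is therefore retained but not quantitative; with odd group sizes the two
tiers coincide in practice. Compounds outside the quantitative tier are
analysed only as present/absent (χ² independence test per compound, no
Yates correction, flagged when fewer than 80% of expected counts reach 5).

**Below-LOQ imputation.** Each censored cell is replaced by a draw from a
normal distribution truncated to (0, LOQ). The untruncated parameterization
is mean LOQ/2 and SD LOQ/4: this centres the mass mid-interval and puts the
truncation bounds at ±2 SD, so boundary pile-up is negligible while the
draws still spread over the censored interval. Both fractions are exposed
(`mean_frac`, `sd_frac`). Sampling is inverse-CDF (`qnorm` of a uniform
restricted to the CDF interval), which is exact and vectorizes; the
truncated mean equals LOQ/2 by symmetry, which the tests verify by Monte
Carlo against the closed form.

**kNN imputation of IS failures.** For a missing cell (sample *s*,
metabolite *m*), candidates are samples with *m* observed in *s*'s group
*and* plate; the distance is 1 − Pearson correlation of log2 profiles over
the metabolites observed in both, requiring at least 10 shared metabolites
(correlation on fewer points is too unstable to rank neighbours). The
imputed value is the arithmetic mean of the *k* = 3 nearest candidates'
concentrations. When fewer than *k* candidates exist the ladder widens:
same group/any plate, then same plate/any group, then the metabolite's
global mean; the tier used is logged per cell. Log2 is used for the
distance (concentrations are multiplicative; correlation on the raw scale
would be dominated by the most abundant compounds) while the imputed value
itself is the plain mean of concentrations.

**Batch correction.** After log2 transform, per-plate location/scale
effects are estimated per metabolite and shrunk across metabolites by the
parametric empirical-Bayes method (ComBat, via the sva package), treating
each plate as one batch. The group label is included as a covariate in the
location model by default (`protect_group = TRUE`): on group-balanced
plates this is nearly a no-op, but on imbalanced plates it prevents real
group differences from being absorbed into the batch estimates. The
alternative behaviour is available behind the flag. Single-plate panels are
returned unchanged — there is no batch to remove — and a plate with fewer
than two samples is an error.

Two properties of empirical-Bayes correction are worth knowing when reading
the diagnostics. First, shrinkage pulls each metabolite's batch estimate
toward the across-metabolite mean, so the *per-metabolite* residual plate
difference after correction retains part of the per-metabolite sampling
noise (the systematic shift is what gets removed). The batch-recovery check
in the test suite therefore plants a +1.0 log2 shift on panels generated
with small residual noise (SD 0.1 log2, 120 samples per plate), where that
sampling-noise floor sits well under the 0.05 log2 bound being asserted;
with study-level noise the floor alone would exceed the bound regardless
of correction quality. Second, correction never changes sample or
metabolite counts, and provenance flags pass through untouched.

**Permille normalization.** Vesicle counts per sample are unavailable, so
absolute concentrations confound vesicle load with composition. Each
quantitative compound is expressed as 1000 · conc / (sample total over
quantitative compounds); rows sum to 1000 to numerical precision, and a
non-positive sample total is an error. Note the closure constraint this
introduces: a genuine increase in one compound mechanically depresses the
permille of all others. With markers that carry a small share of total mass
the effect is negligible, which is why the generator pins its plantable
marker species at mid-abundance (below).

## Differential abundance

All tests are rank-based and therefore invariant under strictly monotone
transforms of the values; they operate on the permille scale.

* **Omnibus:** tie-corrected Kruskal–Wallis H (via `stats::kruskal.test`)
  with χ²-approximation p-values; a compound constant across all samples
  gets H = 0, p = 1 and a flag instead of an error. The effect size is the
  standard Kruskal–Wallis eta-squared η² = (H − k + 1)/(n − k), clipped at
  0 (the formula is the field's convention; the clip handles H < k − 1).
* **Post hoc:** Conover–Iman t statistics on the omnibus ranks, with the
  pooled tie-corrected rank variance S², the (n − 1 − H)/(n − k)
  multiplier, and two-sided p-values from the t distribution on n − k
  degrees of freedom. The standardized effect is r = |t|/√(nᵢ + nⱼ) — the
  denominator is the total size of the two compared groups; "the sample's
  size" admits other readings, so the computation is explicit in the code
  and trivially adaptable. If the rank variance correction degenerates
  (H → n − 1 under complete separation), the statistic is reported as
  signed infinity with p = 0 rather than NaN.
* **Multiplicity:** Benjamini–Hochberg within each family separately — the
  omnibus family, each group-pair family, and the presence family. The
  significance gate for reporting "differential" compounds uses raw p <
  0.05 at both the omnibus and pairwise level (q-values are reported
  alongside); pairwise rows are only flagged differential behind the
  omnibus protection.
* **Fold-changes** are ratios of group medians on the permille scale; a
  zero denominator median yields NA with a flag.
* **Compartment comparison** takes the top-n compounds per fold-change
  direction by pairwise p in one compartment (e.g. vesicles) and reports
  their p, p-rank and fold-change in another (e.g. whole serum), marking
  compounds missing there as not detected/quantitated.

## Signature discovery

The classifier is a multinomial logistic regression (MLR) with intercept,
fitted by Newton/Fisher scoring from a zero start with step-halving — a
deterministic function of its input, cross-checked in the tests against
`glm` (binary) and `nnet::multinom` (three-class) to 1e-6 in
log-likelihood. A tiny ridge on the slopes (default 1e-6, excluded from the
BIC parameter count) keeps coefficients finite on perfectly separable
teaching subsets; such fits are flagged rather than failing, so forward
selection never crashes mid-search. BIC is −2ℓ + p·log n with
p = (features + 1)(K − 1).

The discovery procedure nests three loops:

1. **Forward-ΔBIC selection.** From the intercept-only model, each step
   adds the candidate with the lowest BIC iff it improves the current BIC
   by more than `delta_bic_stop` = 2; ties break by feature order; a
   candidate whose fit fails (collinearity) is skipped and recorded.
2. **MRCV.** The training samples are split 70/30 (stratified by class)
   `mrcv_repeats` = 100 times; forward selection runs on each teaching
   part and MAP accuracy is recorded on both parts. Features are then
   ranked by selection frequency (descending), mean addition order
   (ascending), then id; the ranked frequency list is cut at its largest
   consecutive drop (first such drop on ties) — the elbow — and the final
   set is everything above the cut.
3. **Outer 8-fold CV.** Eight samples per group per fold are drawn without
   replacement, non-overlapping across folds (with 81 per group, 64 are
   ever tested; the remaining 17 stay in every training set — the wording
   of the procedure supports extraction of test sets, not a full
   partition). Each fold runs MRCV on its training remainder, refits the
   elbow set on the whole remainder, and evaluates training and test
   accuracy, AUC, and per-class sensitivity/specificity. Fold metrics are
   aggregated as means with t-distribution confidence intervals on
   folds − 1 degrees of freedom (the procedure reports a mean with 95% CI;
   the t interval is the natural small-sample choice for 8 folds). A
   summary ranking over all folds' MRCV models gives the final model,
   fitted on all samples; per-feature counts of fold-level selection are
   reported so a "selected in at least x of 8 folds" rule can be applied
   alongside the elbow.

Classification is maximum a posteriori with ties (within 1e-9) resolved to
the earlier class in the declared order. For binary models a decision
threshold maximizing Youden's J over the training ROC is attached, with
tied maximizers resolved to the midpoint of the tied interval. AUC is the
rank (trapezoidal) area for two classes; for three or more it is the
macro-averaged one-vs-rest AUC — the definition is a package choice among
several reasonable ones (Hand–Till being the main alternative) and is
isolated in one internal function. Features enter the classifier on the
permille scale, matching the interpretation of signatures as relative
compound contributions; any matrix can be supplied instead (e.g. the
batch-corrected log2 matrix).

`max_candidates` (default Inf) caps the candidate pool per outer fold via a
Kruskal–Wallis p-value prescreen computed on training samples only — a
standard filter-then-wrapper arrangement that keeps desk-scale runs
tractable without touching test data.

## The synthetic-panel generator

The generator exists so that every stage above is testable without patient
data. Its defaults are the study conditions of the screening design it
emulates, chosen once:

* 3 groups × 81 samples, interleaved into 3 plates of 81, so plates are
  group-balanced (the plate layout of the original design is not public;
  balanced enrolment order is the neutral choice).
* 352 compounds over 10 lipid classes with class counts mirroring a
  Biocrates-style panel; per-class log2 abundance means chosen so
  cholesteryl esters carry about two-thirds of the total lipid mass and
  choline phospholipids about a quarter — the composition of an
  LDL-depleted serum sEV fraction.
* The generating model is log-normal per compound:
  log2 x = class mean + compound offset (SD 0.8) + plate shift (SD 0.15) +
  sample heterogeneity (SD 0.35, shared across all compounds of a sample) +
  residual (SD 0.25 ≈ 19% CV), with an optional shared per-sample,
  per-class factor inducing within-class correlation (`within_class_cor`).
  The heterogeneity term is what makes groups inseparable in unsupervised
  2-D views while specific compounds still differ.
* Per-plate LOQs sit at the 2.5% quantile of each compound's per-plate
  generating distribution, so zero-type missingness arises mechanistically
  by truncation as well as via the explicit rate.
* The explicit below-LOQ rate is detectability-driven: with the default
  range c(0, 0.80), per-compound rates follow the abundance rank (the
  least abundant compound at the top of the range). This concentrates
  censoring in the low-abundance tail — as LOQ censoring does — and lands
  the quantitative tier at roughly 200 of 352 compounds while keeping the
  mass-dominant compounds quantifiable, so the permille denominator is
  stable. A scalar rate applies uniformly (and is what the
  rate-convergence test uses). IS failures are technical, so their rates
  are drawn independently of abundance (default range c(0, 0.05)).
* Ten curated marker species (Cer(42:1), CE(19:2), TG(54:2), PC(38:6), …)
  are seeded into the name space and pinned at mid-range global abundance
  (log2 mean 0, SD 0.5). Markers must be quantifiable in most samples yet
  carry little total mass: an early design draft let a marker drawn at
  high abundance carry a quarter of the permille denominator, and its
  planted fold-change then propagated through the closure to every other
  compound. Real marker species of this kind (odd-chain CE, very-long-chain
  PC) are minor species, and the pinning encodes that.
* Default planted effects are the ten reported fold-changes of the top
  differential sEV lipids (1.326 for the Cer(42:1) analogue, 0.783–1.673
  overall), applied multiplicatively to the LC group *before* missingness
  injection, so the complete pre-missingness matrix (kept in the `truth`
  slot) is a clean oracle for recovery checks.

What the generator does **not** emulate: realistic inter-compound
correlation beyond the optional class factor (no literature value is
asserted), lipid-class-specific missingness chemistry, plate-position or
drift effects within a plate, covariate structure (age, smoking), or the
serum compartment jointly with the vesicle compartment (compartment
comparisons are tested by generating two independent panels). Passing tests
on synthetic panels therefore demonstrate correctness of the computations
and calibration under the stated model, not performance on real cohorts.

## Problem sizes used by the test suite

The suite runs the full study geometry where the property demands it and
smaller panels where it does not: chance calibration runs the complete
nested pipeline on ten null panels of 3 × 81 samples with 25 MRCV repeats
and a candidate cap of 50; effect recovery runs 50 study-sized repeats with
a 30-compound panel (the per-compound test is unaffected by panel width);
selection sanity runs ten repeats of 5 planted features among 200 at
n = 243 with 25 MRCV repeats; the masking and batch diagnostics use panels
of 20–60 compounds. These sizes are the package's choices for a
routinely-runnable suite; the full-size procedure (100 MRCV repeats, no
candidate cap) is the documented default of `analysis_config()`.

## Known limitations

* **Weak redundant predictors under forward-BIC.** A feature whose marginal
  association is clear can still have a *negative* conditional BIC gain
  once stronger features are in the model: sharp class posteriors shrink
  the information a weak predictor adds, even when predictors are
  statistically independent. In the selection-sanity experiment the
  weakest planted feature (1.2× in one group, CV ≈ 25%) is never selected
  in roughly one realization in five — at any number of MRCV repeats — and
  so cannot be ranked above unselected noise. The elbow set still recovers
  three or more of the five planted features reliably. This is a property
  of the selection procedure itself, worth keeping in mind when
  interpreting feature rankings near the detection limit.
* **kNN imputation needs correlated profiles.** Correlation-distance
  neighbours are only meaningful when sample profiles genuinely
  correlate; the correlation is also shift-invariant on the log scale, so
  a pure per-sample scale factor is invisible to it. On panels with
  uncorrelated residuals no neighbour scheme can beat the per-metabolite
  mean; the masking benchmark therefore runs on panels with strong
  within-class correlation, and masking error is scored as log2 RMSE (the
  conventional metric for multiplicative abundances).
* **Embedding.** The 2-D view uses non-metric multidimensional scaling on
  Euclidean distances of the batch-corrected log2 matrix, with the mean
  silhouette of the group labels as the separation score. The embedding is
  descriptive only — nothing downstream consumes its coordinates — and
  NMDS stress around 0.25 on study-sized panels means fine geometry should
  not be over-read; the silhouette-based conclusions (separation vs none)
  are robust to the choice of ordination.
* **Inference after selection.** Training metrics exceed test metrics by
  construction (selection optimism); only the outer-fold test metrics are
  honest estimates of generalization, and with 8 folds their confidence
  intervals are wide.
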