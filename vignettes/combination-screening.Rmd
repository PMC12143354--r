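---
title: "Sex-specific drug combination screening for VIC myofibroblast activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific drug combination screening for VIC myofibroblast activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicombo)
```

## The problem and the modelling strategy

Valvular interstitial cells (VICs) are the resident fibroblasts of the
aortic valve. On stiff substrates they activate into myofibroblasts,
marked by alpha-smooth muscle actin (aSMA) stress fibers — the cellular
phenotype behind fibrotic aortic valve disease, which progresses
differently in males and females. The screening strategy implemented
here asks: out of eight pathway inhibitors, each used at clinically
bounded low doses, which *combinations* best suppress aSMA — and do the
answers differ by cell sex?

Testing all combinations of 8 drugs at 3 dose levels means 3^8 = 6561
conditions per sex: infeasible in hydrogel culture. The pipeline
instead measures a small, carefully structured subset of combinations,
fits a second-order quadratic response surface, and ranks the whole
space from the fitted model. Every stage is implemented and verified in
silico against a synthetic-data generator whose statistical structure
matches what the analysis assumes.

The universal response unit is the percent aSMA reduction,

$$\%\text{reduction} = 100 \times \frac{\text{control} - \text{drug}}{\text{control}},$$

so the vehicle control maps to zero by construction and one-sample
comparisons are made against a theoretical mean of zero.

## Dose levels: the min(EC, CC, Cmax) rule

Each drug enters the screen at three levels: L0 (absent), L1 and L2.
Monotherapy efficacy and cytotoxicity curves are fit with a constrained
four-parameter logistic,

$$y(x) = \frac{\text{top}}{1 + (\text{EC}_{50}/x)^{h}},$$

with the bottom fixed at 0, the top capped at 100 (the maximum possible
effect) and the Hill slope $h$ capped at 5 (a smoothness constraint);
the dose-0 limit is handled exactly rather than on a log axis.
`absolute_ec()` inverts the fitted curve in closed form to the
concentration giving an *absolute* response of $f$ percent. Dose levels
are then bounded both pharmacologically and clinically:

* L1 = min(EC$_1$, CC$_1$, 5% of Cmax),
* L2 = min(EC$_2$, CC$_2$, 10% of Cmax),

where Cmax is the clinical maximum serum concentration. The binding
constraint is recorded per level (`select_levels()`), so it is always
known whether efficacy, toxicity or clinical exposure limited a dose.

The fit uses multi-start bounded optimization from a fixed coarse grid
over (EC50, Hill); there is no randomness in the optimizer, so fits are
reproducible and robust to the local minima that plague single-start
4PL fitting. When all responses are indistinguishable from zero the fit
returns a flat-curve sentinel instead of a spurious EC.

Replication is sized by an exact noncentral-t power analysis
(`power_n()`): detecting a 35-unit mean difference at SD 10 with
alpha = 0.05 and power 0.8 requires n = 3 per group, which is the
default replicate count throughout.

## The 59-run orthogonal array composite design

The screen measures 59 combinations: a 32-run two-level fractional
factorial plus a 27-run three-level orthogonal array
(`build_oacd(8)`).

* The two-level block is the minimum-aberration $2^{8-3}$ fraction with
  generators F = ABC, G = ABD, H = BCDE. Its shortest defining word has
  length 4, so it is resolution IV: no main effect is aliased with any
  two-factor interaction. Levels are coded 0/2 — absence versus L2 —
  following the convention of embedding the factorial at the extreme
  levels.
* The three-level block takes 8 pairwise linearly independent GF(3)
  columns of the 27-run strength-2 orthogonal array: for every pair of
  columns, each of the 9 ordered level pairs occurs exactly 3 times.

The published screen used a design with these same properties; the
exact run list is not reproducible from text, so the package constructs
a design from documented generators and *verifies* the properties that
drive the statistics — balance, strength-2 orthogonality, resolution-IV
aliasing — by brute force (`verify_design()`). The 16 L1/L2 monotherapy
runs are appended before fitting; together the 75 runs identify all 45
terms of the full quadratic basis (the expanded model matrix has rank
45, asserted numerically in the tests).

## Response-surface fitting

Responses are modelled as a second-order quadratic series in *coded*
levels: intercept, per-drug linear and quadratic terms, and all
pairwise bilinear terms. Codes {L0, L1, L2} map to {0, 0.5, 1}: the
L1-to-L2 concentration spacing differs per drug and sex, so an ordinal
coding keeps coefficients comparable across drugs; a
concentration-valued coding would make them incommensurable.

Term selection is classical bidirectional stepwise regression on
partial sum-of-squares F tests: add the excluded term with the smallest
p-value below `p_enter` (default 0.05), then remove any included term
whose p-value exceeds `p_remove` (default 0.10), until stable. The
thresholds are exposed because the original platform's values are not
published; 0.05/0.10 are the classical defaults. No effect hierarchy is
enforced — an interaction may enter without its main effects, matching
unconstrained stepwise behaviour. Degenerate SSE bookkeeping (treating
sub-epsilon SSE changes as no improvement) guarantees termination and
makes the noiseless case exact: on noiseless sparse data the selected
support and coefficients equal the least-squares oracle on the true
support to 1e-6.

Before selection, a Box-Cox scan over the exponent grid
{-1, -0.5, 0, 0.5, 1, 2} picks the response transform maximizing the
profile log-likelihood of the full-basis fit; responses are shifted by
$1 - \min(y)$ first when any response is nonpositive, and the shift is
recorded in the model. The identity wins ties. The square transform
(lambda = 2) is the empirically relevant non-identity case for this
assay. After fitting, externally studentized residuals above 3 in
absolute value flag outlying runs (`outlier_scan()`).

## Ranking, candidates and sex bias

`predict_all()` evaluates the fitted model over the full 6561-run
enumeration, back-transforms predictions, and ranks them descending.
Under an even power transform a negative transformed prediction has no
real preimage (its root is imaginary); such combinations are assigned
zero efficacy before ranking, and all back-transformed predictions are
clamped at zero. Ties are broken lexicographically by level vector so
the ranking is a deterministic permutation.

From the ranking, `top_k_by_drug_count()` shortlists the top
two-, three- and four-drug candidates and `bottom_controls()` picks
predicted-ineffective multi-drug negative controls.
`validate_predictions()` correlates model predictions with validation
measurements (Pearson r with a t-distribution p-value).

Sex bias is computed by aligning the male and female rankings over the
identical space and subtracting female from male predictions
(`sex_bias_table()`). The sign rule — positive difference means
male-biased — is supplemented with a +/-5-unit neutral deadband: under
well noise of SD 10 a literal sign rule would classify noise, so small
differences are reported as neutral. The deadband is configurable.

## Bliss checkerboard synergy

Promising pairs are examined on a 6x6 checkerboard: each drug at
{0, L2/4, L2/2, L2, 2 L2, 4 L2} (`checkerboard_ladder()`), giving 25
nonzero dose pairs. Effects are mapped to [0, 1] by dividing by 100 and
clamping — Bliss independence is defined on probabilities, and a
negative reduction counts as no effect. Each cell is scored

$$S = 100\,(f_{AB} - (f_A + f_B - f_A f_B)),$$

with monotherapy effects $f_A, f_B$ taken from the checkerboard's own
zero row and column, keeping the map self-contained rather than
re-using refit monotherapy curves. Scores above +10 are synergistic,
below -10 antagonistic, in between additive. Per-cell significance is a
one-sample t test of the per-replicate scores against zero, without
multiplicity correction (matching how significance is conventionally
reported for these maps). `sex_synergy_contrast()` puts male and female
maps side by side and contrasts the score groups with a Welch test.

## The synthetic-data generator

The generator replaces the unavailable wet-lab measurements with data
having the statistical structure the analysis assumes:

* per-sex 4PL monotherapy curves (`simulate_monotherapy()`);
* a per-sex ground-truth quadratic surface with weak monotherapy
  effects and sparse bilinear interactions (`true_surface()`,
  `make_sex_pair()`), optionally warped by a monotone power law;
* additive Gaussian well noise with SD defaulting to 10
  %aSMA-reduction units — the variability the power analysis assumes —
  and 3 replicates (`noise_model()`);
* responses clipped below at -50: percent reduction can be negative
  (drug-worsened activation) but is physically bounded;
* checkerboards built as Bliss expectation plus a planted excess
  (`simulate_checkerboard()`), so scoring the noiseless table returns
  the planted value exactly.

`make_sex_pair()` plants one strong male-specific interaction
(losartan x SD-208, +30 units at both-L2) and one female-specific
interaction (LY294002 x H1152, +30), a weak shared interaction, and
per-seed jitter of the weak monotherapy coefficients; every single-drug
L2 run evaluates to at most 15 units, reflecting broadly ineffective
monotherapies. All randomness flows through explicit seeds; the global
RNG state is saved and restored, and identical seeds reproduce output
tables byte for byte.

What the generator does *not* emulate: per-cell image statistics,
plate/batch effects, heteroscedastic or non-Gaussian biological
variability, and any mechanistic link between cytotoxicity and
efficacy. Passing tests therefore demonstrate that the analysis
recovers what it assumes — additive Gaussian noise on a quadratic
surface — not that real VIC data satisfy those assumptions. The
additive-Gaussian, SD-10 choice is adopted from the power-analysis
assumption rather than from reported residuals.

## Numerical and design choices

* Dead/alive thresholding for cytotoxicity uses the midpoint of the
  positive and negative control means — the simplest symmetric rule,
  isolated in `percent_cytotoxicity()` so it can be swapped.
* The 4PL optimizer grid is fixed (7 log-spaced EC50 starts x 4 Hill
  starts); bounds top in (0, 100], hill in (0, 5].
* Stepwise ties and ranking ties break lexicographically;
  deterministic results do not depend on row order of the design.
* Sub-epsilon SSE differences (relative to SST) are treated as zero so
  that perfect fits terminate cleanly with p-values 0/1 rather than
  0/0.
* `power_n()` defaults to the two-sample formulation (experimental
  group vs control); the one-sample variant is available since the
  normalization thresholds controls to zero.

Problem sizes used by the test suite follow the screen's own structure:
the 59 + 16-run design with 3 replicates and SD-10 noise for recovery
experiments (100 seeded runs for interaction selection, 50 for ranking
recovery, 200 for EC20 recovery and for the stepwise null), and the
full 6561-run enumeration for ranking checks.

## Known limitations

* The stepwise thresholds, Box-Cox grid and residual-based outlier
  battery of the original analysis platform are unpublished; the
  package exposes classical defaults in their place.
* The exact 59-run matrix of the published screen is not reproducible
  from text; the constructed design shares its defining properties but
  not necessarily its run list, so run-by-run comparisons with the
  published tables are out of scope.
* Selection of validation candidates is strictly rank-ordered;
  drug-diversity curation of a shortlist is left to the analyst.
* No alternative synergy nulls (Loewe, ZIP, HSA) and no smoothing of
  the dose-response matrix before Bliss scoring.

## A worked run

```{r, eval = FALSE}
cfg <- list(
  drugs = lapply(c("H1152", "irosustat", "losartan", "LY294002",
                   "SB203580", "SD208", "TM5441", "Y27632"),
                 function(n) list(name = n, cmax = 10)),
  seed = 11, out_dir = "vic_run")
manifest <- run_pipeline(cfg)
```

This writes per-stage CSVs (curves, levels, design, responses,
coefficients, rankings, candidates, sex bias, checkerboards, synergy
maps) and a manifest with content hashes; rerunning with the same
configuration reproduces every file byte for byte.
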