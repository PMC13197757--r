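---
title: "Determining and predicting metabolizable energy of a feed ingredient from total-collection trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining and predicting metabolizable energy of a feed ingredient from total-collection trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastME)
```

## The problem

The energy a broiler chicken can extract from a feed ingredient — its
apparent metabolizable energy (AME) — is measured in total-excreta-collection
trials: birds are fed a marked diet, all excreta over a collection window
are collected and assayed, and the diet's AME is the gross energy ingested
minus the gross energy excreted, per kilogram of dry-matter intake. Because
a by-product such as dehydrated sugarcane yeast cannot be fed alone, its
ingredient-level energy is obtained by the *substitution method*: a test
diet replaces 30% of a reference diet with the ingredient, and the
ingredient's value is extracted from the difference between the two diets.
Running such trials for every ingredient lot is slow and expensive, so the
second half of the pipeline fits *prediction equations* — linear models of
AME on bird age and the ingredient's physicochemical composition — selects
among them by AIC, and validates them against the in vivo values.

`yeastME` implements this pipeline end to end, ships the published
four-sample sugarcane-yeast tables as fixtures, and includes a synthetic
trial generator with known ground truth so every stage is testable without
animal data.

## Energy bookkeeping

For one experimental unit over the collection window, with intake and
excreta masses in grams and concentrations on the dry-matter basis:

* dry-matter intake `DMI = intake * DM%/100`;
* gross energy ingested `GE_in = DMI_kg * diet GE` (kcal);
* gross energy excreted `GE_out = excreta_DM_kg * excreta GE`;
* nitrogen balance `NB = N ingested − N excreted` (g);
* `AME = (GE_in − GE_out) / DMI_kg`;
* `AMEn = (GE_in − (GE_out + 8.22 · NB)) / DMI_kg`.

The nitrogen correction removes 8.22 kcal per gram of retained nitrogen —
the energy equivalent of tissue-deposited protein — so that `AMEn ≤ AME`
exactly when the balance is positive, as it is in growing birds. Two
metabolizability coefficients summarize the same records:
`AMC_DM = 100 · (DMI − excreta DM)/DMI` and `AMC_GE = 100 · AMEn/GE`, the
latter recomputed from the *ingredient's* gross energy at the ingredient
level. The identity `AME − AMEn = 8.22 · NB / DMI_kg` is enforced to
numerical precision by a property test.

A negative AME is possible under assay noise at 30% inclusion and is
deliberately a warning, not an error.

## Substitution and its pairing rule

With inclusion `f`, a test diet's value is `(1−f)·reference + f·ingredient`
for any additive, DM-basis quantity, so the ingredient value is
`(test − (1−f)·reference)/f` — the exact inverse of mixing, which a
1000-case property test checks to machine precision. Fractions are
interpreted on the DM basis because every energy here is expressed per kg
DM.

The source tables report ingredient-level SEM/CV, which cannot arise from
diet means alone, so the default pairing computes one substitution estimate
*per test-diet replicate* against the reference-diet phase mean
(`mode = "per_replicate"`), preserving replicate variance for ANOVA and
regression; `mode = "by_means"` is available and agrees exactly at zero
noise. A consequence worth knowing: the reference-mean error is shared by
every estimate in a phase, which makes replicate estimates within a phase
positively correlated — see the limitations below.

The published diet-level and ingredient-level tables are *not* mutually
consistent under this (or any linear) substitution rule — e.g. the
pre-initial cells give `(2927 − 0.7·3186)/0.3 = 2322.7` against a printed
ingredient value of 2223 — so the packaged tables are treated as data, and
the demonstration bundle (`paper_like_dataset()`) constructs test-diet
energies by mixing so that the pipeline reproduces the published
ingredient table exactly at zero noise.

## The age covariate

Records carry the age at the midpoint of the collection days (6.5, 16.5,
26.5, 36.5 d for the four standard phases — each phase is 4 adaptation + 4
collection days). For phase-pooled predictions a single default age of
21.5 d (the mean of the midpoints) is used; it is a configurable scalar,
because the published validation tables imply an undisclosed common age
(back-solving their intercept equation suggests roughly 20.7 d).

## Prediction equations

Equations are linear in up to eight predictors, in the fixed canonical
order *age, DM, CP, MM, EE, NDF, MGD, GE*. Fits use a QR factorization;
a normal-equations oracle cross-checks coefficients to 1e-8 in tests.
Conventions, each recorded in the fitted object:

* **R²** is centered with an intercept and uncentered
  (`1 − SSE/Σy²`) without one. Only the uncentered convention reproduces
  the published pattern of through-origin registry equations scoring ~0.96
  against ~0.58–0.68 with an intercept; the response mean is far from zero,
  so the uncentered total sum of squares is much larger.
* **AIC** is `n·ln(SSE/n) + 2(k+1)`, Gaussian likelihood with the error
  variance counted as a parameter. The published AIC magnitudes
  (~1070–1086) depend on the unpublished 96-unit raw data and are carried
  as registry metadata only, never recomputed or tested against.
* **Backward elimination** starts from the full candidate set and greedily
  drops the predictor whose removal most lowers AIC, stopping when no drop
  improves it or a floor is reached; the selected model is the best-AIC
  visited model with 3–4 predictors (the size range the source recommends).
  Exact ties — which necessarily occur while aliased predictors are being
  shed — are broken by the canonical order, dropping the tied predictor
  *latest* in that order so that earlier-listed predictors are retained.
  During rank-deficient steps `k` counts all requested coefficients, so
  each aliased predictor costs 2 AIC points and is shed first. An
  exhaustive all-subsets search is available as the slow counterpart for
  up to 8 candidates.

Validation scores each equation by the sum of squared deviations (SSD)
from the in vivo values, `Σ(observed − predicted)²`, plus the mean SSD per
ingredient. The published SSD figures are orders of magnitude larger than
anything recomputable from the published observed/predicted columns (their
basis — per replicate? per phase? — is not disclosed), so the validation
report always prints the recomputed and published figures side by side and
never reconciles them.

## Trial statistics

Per-variable, per-phase comparisons use the standard one-way decomposition:
`SEM = sqrt(MSE/r)` for balanced designs (harmonic-mean `r`, flagged, when
unbalanced), `CV = 100·sqrt(MSE)/grand mean`, and Tukey(-Kramer) HSD
pairwise p-values from the studentized range distribution. The compact
letter display is the set of maximal cliques of the non-significance graph,
lettered from the highest mean downward, so sharing a letter is exactly
equivalent to a non-significant pair — a property checked against an
`aov`/`TukeyHSD` oracle on random instances. A zero within-group mean
square is degenerate and flagged (F = 0, p = 1 when the means coincide).
α defaults to 0.05.

## The synthetic generator

`generate_trial()` emulates the four-phase design: 4 ingredients, one
reference diet plus one 70/30 test diet each, 6 replicates. Compositions
are drawn uniformly within ranges spanning the packaged composition table;
the true ingredient AME is a through-origin linear model (default
`−32·age + 49·CP + 2736·EE` kcal/kg); diets mix linearly; and per-unit
records are constructed by *inverting* the bookkeeping above, so zero-noise
generation is reproduced exactly by the pipeline — an invariant, not a
tolerance. All randomness derives from one seed.

Noise placement: intake is measured essentially exactly in total-collection
trials, so noise enters through the assays — Gaussian on the excreta GE
concentration and on excreta N (truncated at zero). The magnitude
`noise_sd_kcal` (default 100) is expressed on the *ingredient-energy*
scale, the scale of the substitution estimates the trial exists to measure
and the scale on which the recovery targets are stated; the induced
diet-level perturbation is `inclusion × noise_sd_kcal` (~30 kcal/kg, about
1% of a diet AME — typical bomb-calorimetry precision). The resulting
ingredient-level CVs (~5–10%) sit at the lower end of the published
ingredient-table CVs (10–29%).

Nitrogen balance is drawn positive (growing birds) and calibrated so every
diet's AME − AMEn gap equals `amen_gap` (default 156.5 kcal/kg, the source's
average); a uniform diet-level gap propagates through substitution to the
same ingredient-level gap. The published diet-level gaps reach 392 kcal/kg,
which implies nitrogen retention near 4.8% of DM intake; the demonstration
bundle therefore sets diet N per phase to the minimum feasible value plus a
margin so excreta N stays non-negative — a property of the published
numbers, preserved rather than smoothed.

What the generator does *not* emulate: growth and intake responses to
diet, heat-stress effects on intake, assay-error correlations between GE
and N, and between-bird variance components (none are published; the noise
default is calibrated only to the printed CV magnitudes). Passing tests on
generated data therefore demonstrate the *arithmetic and inferential*
correctness of the pipeline, not the biological realism of any particular
variance structure.

## Problem sizes and numerical choices

The test suite and the acceptance script use the design sizes of the study
itself: 4 ingredients × 4 phases × 6 replicates (96 regression rows, 120
records), 100 seeded trials for the selection and coverage rates, 100
random instances for the OLS oracle, 1000 cases for the substitution
inverse. Ties in elimination use an absolute AIC tolerance of 1e-7; a
perfect fit (SSE = 0) makes AIC degenerate (−Inf with a warning);
rank-deficient strict fits are errors naming the aliased columns.

## Known limitations

* **Support identifiability.** With four ingredients the seven composition
  descriptors span at most a rank-4 space, so the true predictor support is
  only partially identifiable: entire families of 3–4-variable models fit
  equally well — visible in the published registry itself, where seven
  through-origin models share R² = 0.968 to three decimals. At the default
  noise, backward elimination recovers the exact generating support
  {age, CP, EE} in roughly four of five seeded trials (the acceptance
  script reports the rate it measures); the remainder select an
  equally-fitting collinear substitute. This is a property of the 4-point
  composition design, not of the selection algorithm.
* **Mean-pairing correlation.** Pairing each test replicate against the
  reference phase mean shares the reference error across a phase; OLS
  standard errors ignore that correlation, so the age coefficient (a
  phase-level contrast) is slightly over-confident and its nominal 3-SE
  coverage falls a few points short of nominal in the acceptance
  measurements. A mixed model with a phase random effect would repair this
  but is outside the scope the pipeline reproduces.
* The published tables contain internal slips that are preserved, not
  repaired: a pre-initial `AMC_DM` Average cell that repeats a treatment
  cell, one `AMEn > AME` cell (781 vs 779), and validation-table headers
  that disagree with the equation registry on two coefficients (the
  registry is taken as authoritative).
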