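# yeastME

Determination and prediction of metabolizable energy values of a feed
ingredient — dehydrated sugarcane yeast — for broiler chickens, from
total-excreta-collection metabolism trials.

Direct measurement of an ingredient's energy requires a metabolism trial:
birds fed a test diet (70% reference diet + 30% ingredient, DM basis) and a
reference diet, with all excreta over a marked 4-day window collected and
assayed. Per experimental unit,

    AME  = (GE_in − GE_out) / DMI                      (kcal/kg DM intake)
    AMEn = (GE_in − (GE_out + 8.22 · NB)) / DMI        (N-corrected)
    AMC_DM = 100 · (DMI − DM_out) / DMI                (%)
    AMC_GE = 100 · AMEn / GE                           (%)

where NB is the nitrogen balance (g) and 8.22 kcal/g is the energy
equivalent of retained nitrogen. The ingredient-level value follows by the
substitution method, `(test − 0.7·reference) / 0.3`, computed per test
replicate against the reference phase mean. On top of the determination
pipeline, the package fits composition-based prediction equations
(`AME ~ age + DM + CP + MM + EE + NDF + MGD + GE`, through-origin by
convention), selects among them by stepwise backward elimination on
`AIC = n·ln(SSE/n) + 2(k+1)`, and validates printed or fitted equations
against in vivo values by the sum of squared deviations. Trial tables are
summarized with one-way ANOVA, SEM, CV and Tukey compact-letter displays.

The published four-sample study tables (composition, diet-level and
ingredient-level trial summaries, the 20-equation prediction registry, and
the observed-vs-predicted validation tables) ship as plain-text fixtures,
and a synthetic trial generator with known ground truth makes every stage
testable end to end.

## Worked example

Rebuild the published ingredient-level energy table from unit records: the
demonstration bundle carries the published compositions and reference-diet
energies, and at zero assay noise the substitution pipeline reproduces the
published ingredient energies exactly.

```r
library(yeastME)

bundle <- paper_like_dataset()          # 4 phases x 5 diets x 6 replicates
res <- energy_result(bundle$records)    # per-unit AME, AMEn, AMC_DM, AMC_GE
tab <- ingredient_energy_table(res, bundle$diets, bundle$compositions)
tab[tab$phase == "pre-initial",
    c("ingredient_id", "ame_kcal_kg", "amen_kcal_kg", "amc_dm_pct",
      "amc_ge_pct")]
#> # A tibble: 4 × 5
#>   ingredient_id ame_kcal_kg amen_kcal_kg amc_dm_pct amc_ge_pct
#>   <chr>               <dbl>        <dbl>      <dbl>      <dbl>
#> 1 Yeast I             2090.         1953       73.4       46.3
#> 2 Yeast II            1764          1537       70.1       36.0
#> 3 Yeast III           2223          2069       79.8       51.6
#> 4 Yeast IV            1674          1566       73.1       38.2
```

The pre-initial AME column is the published 2090 / 1764 / 2223 / 1674
kcal/kg, and each AMC_GE cell is `100 · AMEn / GE` recomputed from the
ingredient's own gross energy (e.g. `100 · 1566 / 4095 = 38.24`).

Fitting and selecting a prediction equation on a synthetic trial with known
truth:

```r
trial <- generate_trial(generator_config(seed = 1))
reps <- ingredient_energy_replicates(energy_result(trial$records),
                                     trial$diets, trial$compositions)
ds <- build_regression_dataset(reps, trial$compositions, "AME")
backward_eliminate(ds)$selected
#> Least-squares fit (AME), n = 96, k = 3
#>        age         CP         EE
#>  -32.67773   54.07766 2442.63729
#> SSE = 1068443; R2 (uncentered) = 0.9945; AIC = 902.467
```

The generating model was `−32·age + 49·CP + 2736·EE` with replicate noise
of 100 kcal/kg; the selection recovers the true support and the
coefficients within sampling error. (With four ingredients the composition
block has rank 4, so in a minority of seeds an equally-fitting collinear
substitute is selected instead — see the vignette's identifiability
discussion.)

## The analysis workflow

Numbered drivers under `analysis/` run the study as a sequence, writing
tables under `results/`:

1. `01_simulate.R` — generate a seeded four-phase trial with ground truth;
2. `02_energy.R` — unit energies, diet means, ingredient table, ANOVA/Tukey
   group statistics;
3. `03_fit.R` — regression datasets, backward elimination, fitted registry;
4. `04_validate.R` — published registry vs in vivo values, recomputed and
   published SSDs side by side;
5. `05_paper_checks.R` — internal-consistency checks of the packaged
   published tables.

Run each with `Rscript analysis/0X_*.R` from the repository root (step 1
before 2–3).

## Method vignette

`vignettes/metabolizable-energy.Rmd` documents the model and its
conventions: the nitrogen correction, the substitution pairing rule and its
consequences, centered vs uncentered R², the AIC and tie-breaking rules of
the elimination, what the synthetic generator does and does not emulate,
and the known internal inconsistencies of the published tables (preserved,
never repaired).
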