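# Shared oracles and builders, independent of the implementation paths they
# check.

# one collection record; defaults give DMI = 1 kg, GE in 4000, GE out 1500,
# N in 30 g, N out 10 g (NB = 20 g)
make_record <- function(unit_id = "u1", diet_id = "RD", phase = "pre-initial",
                        age_d = 6.5, feed_intake_g = 1000, diet_dm_pct = 100,
                        diet_ge_kcal_kg_dm = 4000, diet_n_pct_dm = 3,
                        excreta_dm_g = 200, excreta_ge_kcal_kg_dm = 7500,
                        excreta_n_pct_dm = 5) {
  tibble::tibble(
    unit_id = unit_id, diet_id = diet_id, phase = phase, age_d = age_d,
    feed_intake_g = feed_intake_g, diet_dm_pct = diet_dm_pct,
    diet_ge_kcal_kg_dm = diet_ge_kcal_kg_dm, diet_n_pct_dm = diet_n_pct_dm,
    excreta_dm_g = excreta_dm_g,
    excreta_ge_kcal_kg_dm = excreta_ge_kcal_kg_dm,
    excreta_n_pct_dm = excreta_n_pct_dm
  )
}

# normal-equations OLS oracle: solve X'X b = X'y directly
ols_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# random regression dataset over a predictor subset (canonical names)
random_dataset <- function(n, predictors, beta, sigma = 1,
                           intercept = 0) {
  ds <- tibble::as_tibble(setNames(
    lapply(predictors, function(p) runif(n, 0, 10)), predictors))
  X <- as.matrix(ds)
  ds$response <- intercept + drop(X %*% beta) + rnorm(n, 0, sigma)
  ds
}

# pairwise Tukey significance oracle through stats::aov + TukeyHSD
tukey_oracle_sig <- function(values, groups, alpha = 0.05) {
  d <- data.frame(y = values, g = factor(groups))
  tk <- TukeyHSD(aov(y ~ g, data = d))$g
  lv <- levels(d$g)
  sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  prs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(prs)) {
    a <- prs[[i]][1]; b <- prs[[i]][2]
    sig[a, b] <- sig[b, a] <- tk[i, "p adj"] < alpha
  }
  sig
}

# letters table -> logical sharing matrix in group order
letters_share <- function(lt) {
  k <- nrow(lt)
  share <- matrix(FALSE, k, k, dimnames = list(lt$group, lt$group))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    share[i, j] <- length(intersect(strsplit(lt$letters[i], "")[[1]],
                                    strsplit(lt$letters[j], "")[[1]])) > 0
  }
  share
}

run_default_pipeline <- function(seed, target = "AME", ...) {
  tr <- generate_trial(generator_config(seed = seed, ...))
  res <- suppressWarnings(energy_result(tr$records))
  reps <- ingredient_energy_replicates(res, tr$diets, tr$compositions)
  list(trial = tr,
       dataset = build_regression_dataset(reps, tr$compositions, target),
       replicates = reps, results = res)
}
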