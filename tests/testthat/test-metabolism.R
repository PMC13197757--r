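# Energy bookkeeping: nitrogen balance, AME/AMEn, metabolizability
# coefficients, substitution method, aggregation.

test_that("nitrogen balance is intake N minus excreta N", {
  expect_equal(nitrogen_balance(make_record()), 30 - 10)
  # identical ingestion and excretion
  expect_equal(nitrogen_balance(make_record(excreta_n_pct_dm = 15)), 0)
  # excreta N exceeding intake N: negative balance is allowed
  expect_lt(nitrogen_balance(make_record(excreta_n_pct_dm = 20)), 0)
})

test_that("energy results follow the defining formulas", {
  # NB = 0 forces AME = AMEn = (4000 - 1500) / 1
  r0 <- energy_result(make_record(excreta_n_pct_dm = 15))
  expect_equal(r0$ame_kcal_kg, 2500)
  expect_identical(r0$amen_kcal_kg, r0$ame_kcal_kg)
  # NB = 10 g: AMEn = 4000 - (1500 + 82.2)
  r1 <- energy_result(make_record(excreta_n_pct_dm = 10))
  expect_equal(r1$ame_kcal_kg, 2500)
  expect_equal(r1$amen_kcal_kg, 2417.8)
  expect_equal(r1$amc_dm_pct, 100 * (1000 - 200) / 1000)
  expect_equal(r1$amc_ge_pct, 100 * 2417.8 / 4000)
  expect_error(energy_result(make_record(feed_intake_g = 1e-20)),
               "feed_intake_g")
})

test_that("published ingredient table satisfies AMEn <= AME in every cell", {
  ing <- load_fixture("ingredient_energy")
  ame <- as.matrix(ing[ing$variable == "ame_kcal_kg",
                       c("I", "II", "III", "IV")])
  amen <- as.matrix(ing[ing$variable == "amen_kcal_kg",
                        c("I", "II", "III", "IV")])
  viol <- which(amen > ame, arr.ind = TRUE)
  # single printed slip: grower-2 Yeast IV has AMEn 781 > AME 779
  expect_equal(nrow(viol), 1)
  expect_equal(unname(viol[1, ]), c(4, 4))
  expect_equal(unname(amen[4, 4]), 781)
  expect_equal(unname(ame[4, 4]), 779)
})

test_that("nitrogen-correction identity and sign law hold on random records", {
  withr::with_seed(11, {
    for (i in 1:50) {
      rec <- make_record(
        feed_intake_g = runif(1, 500, 2500), diet_dm_pct = runif(1, 85, 95),
        diet_ge_kcal_kg_dm = runif(1, 3800, 4300),
        diet_n_pct_dm = runif(1, 2, 5),
        excreta_dm_g = runif(1, 100, 600),
        excreta_ge_kcal_kg_dm = runif(1, 2000, 6000),
        excreta_n_pct_dm = runif(1, 0, 8))
      res <- suppressWarnings(energy_result(rec))
      nb <- nitrogen_balance(rec)
      gap <- res$ame_kcal_kg - res$amen_kcal_kg
      expect_equal(gap, 8.22 * nb / res$dmi_kg, tolerance = 1e-9)
      expect_identical(nb >= 0, res$amen_kcal_kg <= res$ame_kcal_kg)
    }
  })
})

test_that("amc_ge reproduces the published coefficient cells", {
  expect_equal(round(amc_ge(1566, 4095), 2), 38.24)
  expect_equal(round(amc_ge(1670, 4268), 2), 39.13)
  expect_equal(amc_ge(4095, 4095), 100)
  expect_error(amc_ge(1500, 0), "positive")
})

test_that("substitution inverts the 70/30 diet mixing", {
  # diet-mean arithmetic for the published pre-initial diet III cell
  expect_equal(substitution_energy(2927, 3186, 0.3), (2927 - 0.7 * 3186) / 0.3,
               tolerance = 1e-12)
  expect_equal(substitution_energy(2927, 3186, 0.3), 2322.6667,
               tolerance = 1e-7)
  expect_equal(substitution_energy(3186, 3186, 0.3), 3186) # fixed point
  expect_equal(substitution_energy(2927, 3186, 1), 2927)   # full replacement
  expect_error(substitution_energy(2927, 3186, 0), "test_fraction")
  # exact inverse of mixing for random (r, x, f)
  withr::with_seed(21, {
    r <- runif(200, 2500, 4000)
    x <- runif(200, 500, 3000)
    f <- runif(200, 0.05, 1)
    mixed <- (1 - f) * r + f * x
    expect_equal(substitution_energy(mixed, r, f), x, tolerance = 1e-12)
  })
})

test_that("unit covariance: scaling energy concentrations scales energies", {
  # at zero nitrogen balance the correction term vanishes, so multiplying
  # every energy concentration by c scales AME and AMEn by c and leaves the
  # GE metabolizability coefficient unchanged
  base <- make_record(excreta_n_pct_dm = 15)
  for (c_scale in c(0.5, 2, 7)) {
    scaled <- base
    scaled$diet_ge_kcal_kg_dm <- base$diet_ge_kcal_kg_dm * c_scale
    scaled$excreta_ge_kcal_kg_dm <- base$excreta_ge_kcal_kg_dm * c_scale
    r0 <- energy_result(base)
    r1 <- energy_result(scaled)
    expect_equal(r1$ame_kcal_kg, c_scale * r0$ame_kcal_kg)
    expect_equal(r1$amen_kcal_kg, c_scale * r0$amen_kcal_kg)
    expect_equal(r1$amc_ge_pct, r0$amc_ge_pct)
  }
})

test_that("aggregation preserves means and refuses incomplete designs", {
  recs <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_record(unit_id = paste0("u", i))
  }))
  res <- energy_result(recs)
  diets <- trial_diets(character(0))[1, ] # reference only
  agg <- aggregate_by_diet(res, diets)
  expect_equal(agg$ame_kcal_kg, res$ame_kcal_kg[1]) # identical units
  expect_equal(agg$n_units, 6)
  # a designed diet with no units is an error, not a silent NA
  expect_error(aggregate_by_diet(res, trial_diets("A")), "TD-A")
  res_na <- res
  res_na$ame_kcal_kg[3] <- NA
  expect_error(aggregate_by_diet(res_na, diets), "missing unit result")
})

test_that("ingredient energy table recovers truth and recomputes AMC_GE", {
  b <- paper_like_dataset()
  res <- energy_result(b$records)
  tab <- ingredient_energy_table(res, b$diets, b$compositions)
  expect_equal(nrow(tab), 16) # 4 ingredients x 4 phases
  comp <- b$compositions
  ge <- comp$ge_kcal_kg[match(tab$ingredient_id, comp$ingredient_id)]
  expect_equal(tab$amc_ge_pct, 100 * tab$amen_kcal_kg / ge)
  # replicate pairing and diet-means pairing agree at zero noise
  tab_m <- ingredient_energy_table(res, b$diets, b$compositions,
                                   mode = "by_means")
  expect_equal(
    dplyr::arrange(tab_m[c("ingredient_id", "phase", "ame_kcal_kg")],
                   ingredient_id, phase),
    dplyr::arrange(tab[c("ingredient_id", "phase", "ame_kcal_kg")],
                   ingredient_id, phase))
  # a phase without reference-diet units is an error
  res_noref <- res[!(res$diet_id == "RD" & res$phase == "initial"), ]
  expect_error(
    ingredient_energy_replicates(res_noref, b$diets, b$compositions),
    "initial")
})
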