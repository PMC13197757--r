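# Packaged fixtures, typed readers/writers and their invariants.

test_that("packaged composition table matches the published values", {
  comp <- load_fixture("composition")
  expect_equal(nrow(comp), 4)
  y4 <- comp[comp$ingredient_id == "Yeast IV", ]
  expect_equal(y4$cp_pct, 21.12)
  expect_equal(y4$ndf_pct, 12.13)
  expect_equal(y4$mgd_um, 616)
  expect_equal(comp$ge_kcal_kg, c(4214, 4268, 4011, 4095))
  expect_equal(comp$ingredient_no, 1:4)
})

test_that("packaged equation registries carry the published coefficients", {
  ame <- load_fixture("ame_equations")
  expect_equal(nrow(ame), 10)
  e1 <- ame[ame$eq_id == 1, ]
  expect_equal(e1$intercept, 8905.51)
  expect_equal(e1$age, -32.1006)
  expect_equal(e1$DM, -81.048)
  expect_equal(e1$MGD, 0.50052)
  expect_true(is.na(e1$CP))
  # among the through-origin models the {age, CP, EE} one has the lowest
  # published AIC
  noint <- ame[is.na(ame$intercept), ]
  best <- noint[which.min(noint$aic), ]
  expect_equal(best$eq_id, 4L)
  expect_equal(sort(me_predictors()[!is.na(unlist(best[me_predictors()]))]),
               sort(c("age", "CP", "EE")))
  amen <- load_fixture("amen_equations")
  expect_equal(nrow(amen), 10)
  expect_equal(amen$intercept[amen$eq_id == 2], 14361.06)
})

test_that("packaged trial summaries and validation tables spot-check", {
  de <- load_fixture("diet_energy")
  expect_equal(nrow(de), 20)
  pre_ame <- de[de$phase == "pre-initial" & de$variable == "ame_kcal_kg", ]
  expect_equal(unlist(pre_ame[c("RD", "I", "II", "III", "IV")],
                      use.names = FALSE),
               c(3186, 2808, 2888, 2927, 2776))
  expect_equal(pre_ame$average, 2917)
  val <- load_fixture("validation")
  expect_setequal(unique(val$target), c("AME", "AMEn"))
  v7 <- val[val$target == "AME", ]
  expect_equal(v7$observed[v7$row == "Yeast 3"], 1452.50)
  expect_equal(v7$eq4[v7$row == "ssd"], 538453)
})

test_that("unknown fixture id is an explicit error naming valid ids", {
  expect_error(load_fixture("bogus"), "composition")
  expect_error(load_fixture("bogus"), "validation")
})

test_that("write/read round trip preserves every schema exactly", {
  comp <- load_fixture("composition")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_records(comp, tmp)
  back <- read_records(tmp, "composition")
  expect_equal(back, comp)
  expect_identical(back$cp_pct[4], 21.12)

  rec <- make_record(feed_intake_g = 1234.56789, excreta_ge_kcal_kg_dm = pi * 1e3)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, tmp2)
  expect_equal(read_records(tmp2, "collection"), rec)

  # empty table -> header-only file
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_records(comp[0, ], tmp3)
  expect_equal(length(readLines(tmp3)), 1L)
})

test_that("range and schema violations name the offending row and field", {
  comp <- load_fixture("composition")
  bad <- comp
  bad$dm_pct[2] <- -5
  expect_error(validate_records(bad, "composition"), "row 2.*dm_pct")
  bad2 <- comp[, setdiff(names(comp), "ndf_pct")]
  expect_error(validate_records(bad2, "composition"), "ndf_pct")
  rec <- make_record(feed_intake_g = 10, diet_dm_pct = 0)
  expect_error(validate_records(rec, "collection"), "diet_dm_pct")
})

test_that("equation registry round-trips through JSON", {
  eqs <- dplyr::bind_rows(
    equation_spec("AME", c(age = -32.1, EE = 2736.44), intercept = 12.5,
                  r2 = 0.9, aic = 100.25, eq_id = 1L),
    equation_spec("AMEn", c(CP = 47.377), source = "printed", eq_id = 2L)
  )
  tmp <- withr::local_tempfile(fileext = ".json")
  write_equations(eqs, tmp)
  expect_equal(read_equations(tmp), eqs)
})

test_that("phase and diet specs enforce their design invariants", {
  expect_error(phase_spec("initial", 11, 18, adaptation_days = 3),
               "window length")
  expect_error(phase_spec("initial", 11, 18, replicates = 1), "replicates")
  expect_error(diet_spec("RD", "reference", reference_fraction = 0.9),
               "test_fraction = 0")
  expect_error(diet_spec("T1", "test"), "test_ingredient_id")
  d <- trial_diets(c("A", "B"), inclusion = 0.30)
  expect_equal(nrow(d), 3)
  expect_equal(d$reference_fraction + d$test_fraction, rep(1, 3))
  expect_equal(phase_midpoint_age()[["pre-initial"]], 6.5)
  expect_equal(default_prediction_age(), 21.5)
})
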