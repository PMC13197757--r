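# Regression engine, AIC, backward elimination, equation evaluation and SSD
# validation.

test_that("exact lines are fitted exactly", {
  ds <- tibble::tibble(CP = c(0, 1, 2), response = c(1, 3, 5))
  f <- fit_least_squares(ds, "CP", with_intercept = TRUE)
  expect_equal(unname(f$coefficients), c(1, 2))
  expect_equal(f$r2, 1)
  expect_equal(f$r2_type, "centered")
  ds2 <- tibble::tibble(CP = c(1, 2, 4), response = c(2, 4, 8))
  f2 <- fit_least_squares(ds2, "CP", with_intercept = FALSE)
  expect_equal(unname(f2$coefficients), 2)
  expect_equal(f2$r2, 1)
  expect_equal(f2$r2_type, "uncentered")
})

test_that("coefficients match the normal-equations oracle on random data", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(10:30, 1)
      p <- sample(1:5, 1)
      preds <- sample(me_predictors(), p)
      with_int <- runif(1) < 0.5
      ds <- random_dataset(n, preds, beta = runif(p, -3, 3), sigma = 0.5)
      f <- fit_least_squares(ds, preds, with_intercept = with_int)
      X <- as.matrix(ds[f$predictors])
      if (with_int) X <- cbind(1, X)
      expect_equal(unname(f$coefficients), unname(ols_oracle(X, ds$response)),
                   tolerance = 1e-8)
      # residuals orthogonal to every predictor column
      res <- ds$response - drop(X %*% f$coefficients)
      expect_lt(max(abs(crossprod(X, res))) / max(1, sum(abs(ds$response))),
                1e-8)
    }
  })
})

test_that("rank deficiency errors name the collinear predictors", {
  withr::with_seed(32, {
    ds <- random_dataset(20, c("CP", "EE"), beta = c(1, 2))
    ds$NDF <- 2 * ds$CP + ds$EE
    expect_error(fit_least_squares(ds, c("CP", "EE", "NDF")), "NDF")
    f <- fit_least_squares(ds, c("CP", "EE", "NDF"), with_intercept = FALSE,
                           allow_rank_deficient = TRUE)
    expect_equal(f$rank, 2)
    expect_equal(f$k, 3)
  })
})

test_that("AIC follows the Gaussian-likelihood convention", {
  expect_equal(aic_of(list(n = 10, sse = 10, k = 2)), 6)
  # equal k, smaller SSE -> strictly smaller AIC
  expect_lt(aic_of(list(n = 10, sse = 5, k = 2)),
            aic_of(list(n = 10, sse = 10, k = 2)))
  expect_warning(val <- aic_of(list(n = 10, sse = 0, k = 2)), "perfect fit")
  expect_identical(val, -Inf)
})

test_that("adding a predictor never increases the SSE", {
  withr::with_seed(33, {
    for (i in 1:25) {
      ds <- random_dataset(25, c("age", "CP", "EE", "NDF"),
                           beta = runif(4, -2, 2), sigma = 1)
      for (k in 1:3) {
        f_small <- fit_least_squares(ds, me_predictors()[c(1, 3, 5, 6)][1:k],
                                     with_intercept = FALSE)
        f_big <- fit_least_squares(ds, me_predictors()[c(1, 3, 5, 6)][1:(k + 1)],
                                   with_intercept = FALSE)
        expect_lte(f_big$sse, f_small$sse + 1e-9)
      }
    }
  })
})

test_that("backward elimination discards pure-noise predictors", {
  withr::with_seed(34, {
    ds <- random_dataset(50, c("CP", "NDF"), beta = c(2, 0), sigma = 0.1)
    be <- backward_eliminate(ds, c("CP", "NDF"), with_intercept = FALSE,
                             min_predictors = 1, max_predictors = 2)
    expect_equal(be$selected$predictors, "CP")
    expect_equal(unname(be$selected$coefficients), 2, tolerance = 0.05)
  })
})

test_that("noise-free linear response keeps its generating support", {
  withr::with_seed(35, {
    ds <- random_dataset(40, me_predictors(), beta = c(-32, 0, 49, 0, 2736, 0, 0, 0),
                         sigma = 0)
    be <- suppressWarnings(
      backward_eliminate(ds, min_predictors = 3, max_predictors = 4))
    expect_true(all(c("age", "CP", "EE") %in% be$selected$predictors))
    expect_lt(be$selected$sse / sum(ds$response^2), 1e-16)
  })
})

test_that("greedy elimination is consistent with the all-subsets oracle", {
  withr::with_seed(36, {
    for (i in 1:10) {
      preds <- c("age", "CP", "MM", "EE", "NDF")
      beta <- c(3, -2, 0, 5, 0) + rnorm(5, 0, 0.2)
      ds <- random_dataset(30, preds, beta = beta, sigma = 0.3)
      be <- backward_eliminate(ds, preds, with_intercept = FALSE,
                               min_predictors = 1, max_predictors = 5)
      ex <- exhaustive_search(ds, preds, with_intercept = FALSE)
      # the exhaustive optimum is never worse than the greedy path's best
      expect_lte(ex$selected$aic, be$selected$aic + 1e-9)
      # with this signal strength the greedy path must reach a model whose
      # AIC is within one penalty unit of the global optimum
      expect_lt(be$selected$aic - ex$selected$aic, 2 + 1e-9)
    }
  })
  expect_error(backward_eliminate(tibble::tibble(CP = 1:5, response = 1:5),
                                  "CP", min_predictors = 3,
                                  max_predictors = 2),
               "max_predictors")
})

test_that("equation evaluation is the published linear form", {
  ame <- load_fixture("ame_equations")
  comp <- load_fixture("composition")
  zero <- comp[1, ]
  zero[c("dm_pct", "cp_pct", "mm_pct", "ee_pct", "ndf_pct")] <- 0
  zero$ge_kcal_kg <- 1e-9
  zero$mgd_um <- 1e-9
  # intercept-only limit of registry equation 1 at age 0
  expect_equal(evaluate_equation(ame[ame$eq_id == 1, ], zero, age_d = 0),
               8905.51, tolerance = 1e-6)
  # hand-computed value of the through-origin {age, CP, EE} equation for
  # the first sample at age 10: -321.253 + 844.75492 + 1012.4828
  e4 <- ame[ame$eq_id == 4, ]
  expect_equal(evaluate_equation(e4, comp[1, ], age_d = 10), 1535.9838,
               tolerance = 1e-4)
  # linearity: doubling EE raises the prediction by exactly coef * EE
  doubled <- comp[1, ]
  doubled$ee_pct <- 2 * doubled$ee_pct
  expect_equal(evaluate_equation(e4, doubled, 10) -
                 evaluate_equation(e4, comp[1, ], 10),
               2736.44 * comp$ee_pct[1], tolerance = 1e-9)
  expect_error(evaluate_equation(e4, comp[1, ], age_d = NA_real_), "age")
})

test_that("validation reports SSD recomputable from its own columns", {
  comp <- load_fixture("composition")
  eqs <- load_fixture("ame_equations")
  obs <- tibble::tibble(ingredient_id = comp$ingredient_id,
                        observed = c(1261.10, 1427.60, 1452.50, 1252.80))
  rep <- validate_against_observed(eqs, comp, obs, age_d = 20.7)
  expect_equal(nrow(rep$predictions), 4)
  expect_equal(ncol(rep$predictions), 12) # id + observed + 10 equations
  # SSD identity against the report's own columns
  for (j in seq_len(nrow(rep$ssd))) {
    col <- rep$ssd$equation[j]
    expect_equal(rep$ssd$ssd[j],
                 sum((rep$predictions[[col]] - rep$predictions$observed)^2))
    expect_equal(rep$ssd$mean_ssd[j], rep$ssd$ssd[j] / 4)
  }
  # predicted == observed -> SSD 0; hand case SSD 5
  ident <- validate_against_observed(
    equation_spec("AME", c(GE = 1)),
    comp, tibble::tibble(ingredient_id = comp$ingredient_id,
                         observed = comp$ge_kcal_kg), age_d = 0)
  expect_equal(ident$ssd$ssd, 0)
  expect_error(
    validate_against_observed(eqs, comp,
                              tibble::tibble(ingredient_id = "nope",
                                             observed = 1)),
    "mismatch")
})

test_that("hand SSD arithmetic: observed (1,2) vs predicted (0,0) gives 5", {
  comp <- load_fixture("composition")[1:2, ]
  rep <- validate_against_observed(
    equation_spec("AME", c(age = 1)), comp,
    tibble::tibble(ingredient_id = comp$ingredient_id, observed = c(1, 2)),
    age_d = 0)
  expect_equal(rep$predictions$eq_1, c(0, 0))
  expect_equal(rep$ssd$ssd, 5)
})

test_that("uncentered R2 exceeds centered R2 for through-origin energy fits", {
  pipe <- run_default_pipeline(seed = 301)
  f_no <- fit_least_squares(pipe$dataset, c("age", "CP", "EE"),
                            with_intercept = FALSE)
  f_int <- fit_least_squares(pipe$dataset, c("age", "CP", "EE"),
                             with_intercept = TRUE)
  expect_gt(f_no$r2, 0.9)
  expect_lt(f_int$r2, f_no$r2)
})
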