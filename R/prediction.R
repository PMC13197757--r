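# Regression engine and equation registry: least-squares fits over the
# canonical predictors, AIC-based backward elimination, evaluation of printed
# or fitted equations, and validation by sum of squared deviations.

#' Assemble a regression dataset from replicate-level ingredient estimates
#'
#' One observation per replicate-level substitution estimate, carrying the
#' collection-window age and the seven composition predictors of its
#' ingredient, with the chosen energy value as the response.
#'
#' @param replicates Output of [ingredient_energy_replicates()].
#' @param compositions Ingredient composition table.
#' @param target `"AME"` or `"AMEn"`.
#' @return Tibble with columns `ingredient_id`, `phase`, `age`, `DM`, `CP`,
#'   `MM`, `EE`, `NDF`, `MGD`, `GE`, `response` and attribute `target`.
#' @export
build_regression_dataset <- function(replicates, compositions,
                                     target = c("AME", "AMEn")) {
  target <- match.arg(target)
  compositions <- validate_records(compositions, "composition")
  comp <- compositions["ingredient_id"]
  for (p in names(.predictor_cols)) comp[[p]] <- compositions[[.predictor_cols[p]]]
  out <- replicates |>
    dplyr::inner_join(comp, by = "ingredient_id") |>
    dplyr::transmute(
      ingredient_id = .data$ingredient_id, phase = .data$phase,
      age = .data$age_d, .data$DM, .data$CP, .data$MM, .data$EE, .data$NDF,
      .data$MGD, .data$GE,
      response = if (target == "AME") .data$ame_kcal_kg else .data$amen_kcal_kg
    )
  if (anyNA(out[me_predictors()])) {
    stop("regression dataset has missing predictor values", call. = FALSE)
  }
  attr(out, "target") <- target
  out
}

#' Least-squares fit over a predictor subset
#'
#' Coefficients minimize the residual sum of squares via a QR factorization.
#' R-squared is centered (`1 - SSE / sum((y - mean(y))^2)`) when an intercept
#' is fitted and uncentered (`1 - SSE / sum(y^2)`) otherwise; the convention
#' used is recorded in the result. Through-origin models therefore report
#' the much larger uncentered R-squared typical of energy-prediction tables.
#'
#' @param data Regression dataset ([build_regression_dataset()]) or any
#'   tibble with the predictor columns and a `response` column.
#' @param predictors Subset of [me_predictors()].
#' @param with_intercept Fit an intercept?
#' @param allow_rank_deficient If `FALSE` (default), a rank-deficient
#'   predictor matrix is an error naming the aliased columns. If `TRUE`
#'   (used internally by [backward_eliminate()]), aliased coefficients are
#'   set to zero, the fit is the projection onto the column space, and `k`
#'   still counts all requested coefficients so that model selection
#'   penalizes aliased predictors.
#' @return Object of class `"me_fit"`: list with `equation`
#'   ([equation_spec()] row, `source = "fitted"`), `coefficients`, `se`,
#'   `n`, `k`, `rank`, `sse`, `r2`, `r2_type` (`"centered"`/`"uncentered"`),
#'   `aic`, `predictors`, `with_intercept`, `target`, `aliased`.
#' @export
fit_least_squares <- function(data, predictors, with_intercept = TRUE,
                              allow_rank_deficient = FALSE) {
  bad <- setdiff(predictors, me_predictors())
  if (length(bad)) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  predictors <- intersect(me_predictors(), predictors) # canonical order
  if (!length(predictors)) stop("need at least one predictor", call. = FALSE)
  y <- data$response
  X <- as.matrix(data[predictors])
  storage.mode(X) <- "double"
  if (with_intercept) X <- cbind("(Intercept)" = 1, X)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 1) {
    stop("need at least ", p + 1, " observations for ", p, " coefficients",
         call. = FALSE)
  }
  qx <- qr(X)
  aliased <- character(0)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[seq(qx$rank + 1, p)]]
    if (!allow_rank_deficient) {
      stop("rank-deficient predictor matrix; collinear column(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
  }
  beta <- qr.coef(qx, y)
  beta[is.na(beta)] <- 0
  fitted <- drop(qr.fitted(qx, y))
  res <- y - fitted
  sse <- sum(res^2)
  tss <- if (with_intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (tss > 0) 1 - sse / tss else NA_real_
  se <- setNames(rep(NA_real_, p), colnames(X))
  if (qx$rank == p && n > p) {
    sigma2 <- sse / (n - p)
    R <- qr.R(qx)
    V <- chol2inv(R)
    piv <- qx$pivot
    V <- V[order(piv), order(piv), drop = FALSE]
    se[] <- sqrt(sigma2 * diag(V))
  }
  coefs <- beta[predictors]
  intercept <- if (with_intercept) unname(beta["(Intercept)"]) else NA_real_
  target <- attr(data, "target") %||% "AME"
  fit <- list(
    equation = equation_spec(
      target = target,
      coefficients = coefs,
      intercept = intercept, r2 = r2, source = "fitted"
    ),
    coefficients = beta, se = se, n = n, k = p, rank = qx$rank, sse = sse,
    r2 = r2, r2_type = if (with_intercept) "centered" else "uncentered",
    predictors = predictors, with_intercept = with_intercept,
    target = target, aliased = aliased
  )
  fit$aic <- aic_of(fit)
  fit$equation$aic <- fit$aic
  class(fit) <- "me_fit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.me_fit <- function(x, ...) {
  cat("Least-squares fit (", x$target, "), n = ", x$n, ", k = ", x$k, "\n",
      sep = "")
  print(round(x$coefficients, 5))
  cat("SSE = ", format(x$sse), "; R2 (", x$r2_type, ") = ",
      round(x$r2, 4), "; AIC = ", round(x$aic, 4), "\n", sep = "")
  invisible(x)
}

#' Akaike information criterion of a fitted model
#'
#' Gaussian-likelihood convention `AIC = n * ln(SSE / n) + 2 * (k + 1)`, the
#' error variance counting as one estimated parameter. A perfect fit
#' (`SSE = 0`) is degenerate and returns `-Inf` with a warning.
#'
#' @param model An `"me_fit"` object, or a list with `n`, `sse`, `k`.
#' @return Scalar AIC (lower is better).
#' @export
aic_of <- function(model) {
  if (model$sse <= 0) {
    warning("perfect fit (SSE = 0): AIC degenerates to -Inf", call. = FALSE)
    return(-Inf)
  }
  model$n * log(model$sse / model$n) + 2 * (model$k + 1)
}

.fit_label <- function(predictors, with_intercept) {
  paste0(if (with_intercept) "1 + " else "", paste(predictors, collapse = " + "))
}

#' Stepwise backward elimination on AIC
#'
#' Starting from the model with every candidate predictor, repeatedly drops
#' the single predictor whose removal most lowers the AIC, stopping when no
#' removal improves it or when `min_predictors` is reached. Exact ties in
#' the drop AIC (which arise when predictors are aliased, e.g. seven
#' composition measures over four ingredients) are broken by the fixed
#' predictor order of [me_predictors()]: the tied predictor latest in that
#' order is dropped, so earlier-listed predictors are preferentially
#' retained.
#'
#' @param data Regression dataset.
#' @param start_predictors Candidate set (default all eight).
#' @param with_intercept Fit intercepts? Energy-prediction registries are
#'   conventionally through-origin, so the default is `FALSE`.
#' @param min_predictors,max_predictors Model-size window for the selected
#'   model (defaults 3-4). Elimination itself proceeds down to
#'   `min_predictors`; the selected model is the best-AIC visited model
#'   whose size falls inside the window (best overall if none does).
#' @param tie_tol Absolute AIC difference treated as a tie.
#' @return List: `selected` (`"me_fit"`), `models` (tibble of every visited
#'   model ranked by AIC: `label`, `n_predictors`, `sse`, `r2`, `aic`,
#'   `predictors` list-column), `path` (labels in elimination order).
#' @export
backward_eliminate <- function(data, start_predictors = me_predictors(),
                               with_intercept = FALSE, min_predictors = 3,
                               max_predictors = 4, tie_tol = 1e-7) {
  if (max_predictors < min_predictors) {
    stop("max_predictors must be >= min_predictors", call. = FALSE)
  }
  if (!length(start_predictors)) stop("empty start set", call. = FALSE)
  current <- intersect(me_predictors(), start_predictors)
  fit <- fit_least_squares(data, current, with_intercept,
                           allow_rank_deficient = TRUE)
  visited <- list(fit)
  path <- .fit_label(current, with_intercept)
  while (length(current) > min_predictors) {
    cand <- lapply(seq_along(current), function(i) {
      fit_least_squares(data, current[-i], with_intercept,
                        allow_rank_deficient = TRUE)
    })
    aics <- vapply(cand, function(f) f$aic, numeric(1))
    best <- min(aics)
    if (best >= fit$aic) break
    # tied best drops: remove the predictor latest in canonical order
    tied <- which(aics <= best + tie_tol)
    drop_i <- max(tied)
    fit <- cand[[drop_i]]
    current <- current[-drop_i]
    visited <- c(visited, list(fit))
    path <- c(path, .fit_label(current, with_intercept))
  }
  models <- dplyr::bind_rows(lapply(visited, function(f) {
    tibble::tibble(
      label = .fit_label(f$predictors, f$with_intercept),
      n_predictors = length(f$predictors), k = f$k, rank = f$rank,
      sse = f$sse, r2 = f$r2, aic = f$aic, predictors = list(f$predictors)
    )
  }))
  ord <- order(models$aic, models$n_predictors)
  models <- models[ord, ]
  visited <- visited[ord]
  in_window <- models$n_predictors >= min_predictors &
    models$n_predictors <= max_predictors
  selected <- if (any(in_window)) visited[[which(in_window)[1]]] else visited[[1]]
  list(selected = selected, models = models, path = path)
}

#' Exhaustive best-subset search on AIC
#'
#' Enumerates every full-rank predictor subset with size inside the window
#' and returns the one with the smallest AIC. Intended as the slow,
#' independent counterpart to [backward_eliminate()] for up to 8 candidates.
#'
#' @inheritParams backward_eliminate
#' @return List: `selected` (`"me_fit"`), `models` (tibble ranked by AIC).
#' @export
exhaustive_search <- function(data, start_predictors = me_predictors(),
                              with_intercept = FALSE, min_predictors = 1,
                              max_predictors = length(start_predictors)) {
  if (max_predictors < min_predictors) {
    stop("max_predictors must be >= min_predictors", call. = FALSE)
  }
  cands <- intersect(me_predictors(), start_predictors)
  subsets <- unlist(lapply(seq(min_predictors, min(max_predictors, length(cands))),
                           function(k) utils::combn(cands, k, simplify = FALSE)),
                    recursive = FALSE)
  fits <- list()
  for (s in subsets) {
    f <- tryCatch(fit_least_squares(data, s, with_intercept),
                  error = function(e) NULL)
    if (!is.null(f)) fits <- c(fits, list(f))
  }
  if (!length(fits)) stop("no full-rank subset in the size window", call. = FALSE)
  models <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      label = .fit_label(f$predictors, f$with_intercept),
      n_predictors = length(f$predictors), sse = f$sse, r2 = f$r2,
      aic = f$aic, predictors = list(f$predictors)
    )
  }))
  ord <- order(models$aic, models$n_predictors)
  list(selected = fits[[ord[1]]], models = models[ord, ])
}

.predictor_values <- function(comp, age_d) {
  comp <- validate_records(comp, "composition")
  vals <- c(age = age_d)
  for (p in names(.predictor_cols)) vals[p] <- comp[[.predictor_cols[p]]][1]
  vals
}

#' Evaluate a prediction equation for one ingredient
#'
#' `intercept (or 0) + sum(coefficient * predictor)`, with composition
#' predictors in their storage units (%, um, kcal/kg DM) and age in days.
#'
#' @param eq One-row equation tibble ([equation_spec()] row or one row of a
#'   loaded registry).
#' @param comp One-row composition table.
#' @param age_d Bird age (days) to plug into the `age` term.
#' @return Predicted energy value (kcal/kg DM).
#' @export
evaluate_equation <- function(eq, comp, age_d) {
  stopifnot(nrow(eq) == 1)
  vals <- .predictor_values(comp[1, ], age_d)
  used <- me_predictors()[!is.na(unlist(eq[me_predictors()]))]
  missing <- used[is.na(vals[used])]
  if (length(missing)) {
    stop("predictor value(s) missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  base <- if (is.na(eq$intercept)) 0 else eq$intercept
  base + sum(unlist(eq[used]) * vals[used])
}

#' Evaluate an equation registry over a composition table
#'
#' @param equations Equation tibble (one row per equation).
#' @param compositions Composition table (one row per ingredient).
#' @param age_d Scalar age (days); defaults to the phase-pooled prediction
#'   age of [default_prediction_age()].
#' @return Tibble: `ingredient_id` x one `eq_<id>` column per equation.
#' @export
evaluate_equations <- function(equations, compositions,
                               age_d = default_prediction_age()) {
  compositions <- validate_records(compositions, "composition")
  out <- tibble::tibble(ingredient_id = compositions$ingredient_id)
  for (i in seq_len(nrow(equations))) {
    id <- equations$eq_id[i]
    col <- paste0("eq_", ifelse(is.na(id), i, id))
    out[[col]] <- vapply(seq_len(nrow(compositions)), function(j) {
      evaluate_equation(equations[i, ], compositions[j, ], age_d)
    }, numeric(1))
  }
  out
}

#' Validate prediction equations against observed energy values
#'
#' Predicts each ingredient's energy with every equation and scores each
#' equation by the sum of squared deviations (SSD) from the observed in vivo
#' values, plus the mean SSD per ingredient. Optionally carries published
#' SSD figures side by side with the recomputed ones (they are reported, not
#' reconciled: the published basis is not disclosed).
#'
#' @param equations Equation tibble.
#' @param compositions Composition table.
#' @param observed Tibble with `ingredient_id` and `observed` (kcal/kg DM);
#'   the ingredient set must match `compositions` exactly.
#' @param age_d Scalar prediction age (days).
#' @param printed_ssd Optional numeric vector of published SSDs, one per
#'   equation.
#' @return List of tibbles: `predictions` (observed + one column per
#'   equation), `deviations` (long: predicted, observed, deviation), `ssd`
#'   (per equation: `ssd`, `mean_ssd`, and `printed_ssd` if supplied).
#' @export
validate_against_observed <- function(equations, compositions, observed,
                                      age_d = default_prediction_age(),
                                      printed_ssd = NULL) {
  compositions <- validate_records(compositions, "composition")
  extra <- setdiff(compositions$ingredient_id, observed$ingredient_id)
  missing <- setdiff(observed$ingredient_id, compositions$ingredient_id)
  if (length(extra) || length(missing)) {
    stop("ingredient mismatch between compositions and observed values; ",
         "only in compositions: {", paste(extra, collapse = ", "),
         "}; only in observed: {", paste(missing, collapse = ", "), "}",
         call. = FALSE)
  }
  preds <- evaluate_equations(equations, compositions, age_d)
  preds <- dplyr::inner_join(observed, preds, by = "ingredient_id")
  eq_cols <- setdiff(names(preds), c("ingredient_id", "observed"))
  deviations <- preds |>
    tidyr::pivot_longer(dplyr::all_of(eq_cols), names_to = "equation",
                        values_to = "predicted") |>
    dplyr::mutate(deviation = .data$predicted - .data$observed)
  ssd <- deviations |>
    dplyr::group_by(.data$equation) |>
    dplyr::summarise(ssd = sum(.data$deviation^2),
                     mean_ssd = mean(.data$deviation^2), .groups = "drop")
  ssd <- ssd[match(eq_cols, ssd$equation), ]
  if (!is.null(printed_ssd)) {
    stopifnot(length(printed_ssd) == nrow(ssd))
    ssd$printed_ssd <- printed_ssd
    ssd$printed_mean_ssd <- printed_ssd / nrow(preds)
  }
  list(predictions = preds, deviations = deviations, ssd = ssd,
       age_d = age_d)
}
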