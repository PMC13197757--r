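# Per-unit energy bookkeeping for total-collection trials and the
# substitution-method extraction of ingredient-level energy.
#
# Unit conventions: feed intake and excreta in grams over the collection
# window, concentrations on the DM basis (GE in kcal/kg DM, N in % of DM),
# energies reported per kg of DM intake. GE ingested (kcal) =
# intake_g/1000 * DM%/100 * diet GE; GE excreted = excreta_dm_g/1000 *
# excreta GE.

#' Nitrogen-correction constant (kcal per g retained N)
#' @export
K_NITROGEN <- 8.22

.dmi_g <- function(records) records$feed_intake_g * records$diet_dm_pct / 100

#' Nitrogen balance over the collection window
#'
#' N ingested minus N excreted (grams). Positive in growing birds retaining
#' nitrogen for tissue deposition; negative values are allowed.
#'
#' @param records Collection-record table (see [read_records()] schema
#'   `"collection"`).
#' @return Numeric vector, grams of N per record.
#' @export
nitrogen_balance <- function(records) {
  records <- validate_records(records, "collection")
  .dmi_g(records) * records$diet_n_pct_dm / 100 -
    records$excreta_dm_g * records$excreta_n_pct_dm / 100
}

#' Per-unit energy results
#'
#' For each experimental unit: AME = (GE ingested - GE excreted) / DMI;
#' AMEn subtracts additionally 8.22 kcal per gram of retained nitrogen,
#' removing the energy equivalent of tissue-deposited protein; the
#' metabolizability coefficient of dry matter is the percentage of DM intake
#' retained, and that of gross energy is AMEn as a percentage of the diet's
#' gross energy.
#'
#' @param records Collection-record table.
#' @return Tibble with one row per record: identifiers, `ame_kcal_kg`,
#'   `amen_kcal_kg`, `amc_dm_pct`, `amc_ge_pct`, `n_balance_g`, `dmi_kg`,
#'   `k_n`.
#' @export
energy_result <- function(records) {
  records <- validate_records(records, "collection")
  dmi_g <- .dmi_g(records)
  dmi_kg <- dmi_g / 1000
  ge_in <- dmi_kg * records$diet_ge_kcal_kg_dm
  ge_out <- records$excreta_dm_g / 1000 * records$excreta_ge_kcal_kg_dm
  nb <- nitrogen_balance(records)
  ame <- (ge_in - ge_out) / dmi_kg
  amen <- (ge_in - (ge_out + K_NITROGEN * nb)) / dmi_kg
  if (any(ame < 0)) {
    warning(sum(ame < 0), " record(s) with negative AME (possible under ",
            "noise at high test-ingredient inclusion)", call. = FALSE)
  }
  tibble::tibble(
    unit_id = records$unit_id, diet_id = records$diet_id,
    phase = records$phase, age_d = records$age_d,
    ame_kcal_kg = ame, amen_kcal_kg = amen,
    amc_dm_pct = 100 * (dmi_g - records$excreta_dm_g) / dmi_g,
    amc_ge_pct = 100 * amen / records$diet_ge_kcal_kg_dm,
    n_balance_g = nb, dmi_kg = dmi_kg, k_n = K_NITROGEN
  )
}

#' Metabolizability coefficient of gross energy
#'
#' @param amen_kcal_kg AMEn (kcal/kg DM).
#' @param ge_kcal_kg Gross energy of the same material (kcal/kg DM); must be
#'   positive.
#' @return Percentage, `100 * amen / ge`.
#' @export
amc_ge <- function(amen_kcal_kg, ge_kcal_kg) {
  if (any(ge_kcal_kg <= 0)) {
    stop("amc_ge: undefined ratio, gross energy must be positive", call. = FALSE)
  }
  100 * amen_kcal_kg / ge_kcal_kg
}

#' Substitution-method ingredient value
#'
#' Inverts the diet mixing: if a test diet is `(1 - f)` reference diet plus
#' `f` test ingredient (DM basis), the ingredient-level value of any additive
#' quantity (AME, AMEn, a metabolizability coefficient) is
#' `(test - (1 - f) * reference) / f`.
#'
#' @param test_diet_value,reference_diet_value Diet-level values (same units).
#' @param test_fraction Ingredient inclusion `f`, in (0, 1].
#' @return Ingredient-level value.
#' @export
substitution_energy <- function(test_diet_value, reference_diet_value,
                                test_fraction) {
  if (any(test_fraction <= 0) || any(test_fraction > 1)) {
    stop("substitution_energy: test_fraction must be in (0, 1]", call. = FALSE)
  }
  (test_diet_value - (1 - test_fraction) * reference_diet_value) / test_fraction
}

#' Per-diet means of unit-level energy results
#'
#' @param results Output of [energy_result()].
#' @param diets Diet table ([trial_diets()]); every diet x phase combination
#'   implied by `results`' phases must have at least one unit.
#' @return Tibble of per diet x phase means (`n_units`, mean AME, AMEn,
#'   AMC_DM, AMC_GE); replicate detail stays in `results` for downstream
#'   statistics.
#' @export
aggregate_by_diet <- function(results, diets) {
  if (anyNA(results[c("ame_kcal_kg", "amen_kcal_kg")])) {
    i <- which(is.na(results$ame_kcal_kg) | is.na(results$amen_kcal_kg))[1]
    stop("missing unit result for diet '", results$diet_id[i], "', phase '",
         results$phase[i], "'", call. = FALSE)
  }
  expected <- tidyr::expand_grid(diet_id = diets$diet_id,
                                 phase = unique(results$phase))
  have <- dplyr::distinct(results, .data$diet_id, .data$phase)
  gone <- dplyr::anti_join(expected, have, by = c("diet_id", "phase"))
  if (nrow(gone)) {
    stop("no units for diet '", gone$diet_id[1], "' in phase '",
         gone$phase[1], "'", call. = FALSE)
  }
  results |>
    dplyr::group_by(.data$diet_id, .data$phase) |>
    dplyr::summarise(
      n_units = dplyr::n(), age_d = mean(.data$age_d),
      ame_kcal_kg = mean(.data$ame_kcal_kg),
      amen_kcal_kg = mean(.data$amen_kcal_kg),
      amc_dm_pct = mean(.data$amc_dm_pct),
      amc_ge_pct = mean(.data$amc_ge_pct),
      .groups = "drop"
    )
}

#' Replicate-level ingredient energy by the substitution method
#'
#' With `mode = "per_replicate"` (default) each test-diet unit is paired with
#' the reference-diet phase mean, preserving replicate variance for ANOVA and
#' regression; `mode = "by_means"` applies the substitution to diet means
#' only (one row per ingredient x phase). The ingredient-level AMC_GE is
#' recomputed from the ingredient's own gross energy, not carried over from
#' the diet.
#'
#' @param results Output of [energy_result()].
#' @param diets Diet table; each phase needs the reference diet and at least
#'   one test diet.
#' @param compositions Ingredient composition table (for ingredient GE).
#' @param mode `"per_replicate"` or `"by_means"`.
#' @return Tibble with one row per test unit (or per ingredient x phase for
#'   `"by_means"`): `ingredient_id`, `phase`, `age_d`, `unit_id`,
#'   `ame_kcal_kg`, `amen_kcal_kg`, `amc_dm_pct`, `amc_ge_pct`.
#' @export
ingredient_energy_replicates <- function(results, diets, compositions,
                                         mode = c("per_replicate", "by_means")) {
  mode <- match.arg(mode)
  compositions <- validate_records(compositions, "composition")
  ref_ids <- diets$diet_id[diets$kind == "reference"]
  if (!length(ref_ids)) stop("no reference diet in the design", call. = FALSE)
  for (ph in unique(results$phase)) {
    if (!any(results$diet_id %in% ref_ids & results$phase == ph)) {
      stop("phase '", ph, "' lacks reference-diet units", call. = FALSE)
    }
  }
  ref_means <- results |>
    dplyr::filter(.data$diet_id %in% ref_ids) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      ref_ame = mean(.data$ame_kcal_kg), ref_amen = mean(.data$amen_kcal_kg),
      ref_amc_dm = mean(.data$amc_dm_pct), .groups = "drop"
    )
  test <- results |>
    dplyr::inner_join(
      dplyr::filter(diets, .data$kind == "test")[
        c("diet_id", "test_ingredient_id", "test_fraction")],
      by = "diet_id"
    )
  if (mode == "by_means") {
    test <- test |>
      dplyr::group_by(.data$diet_id, .data$test_ingredient_id,
                      .data$test_fraction, .data$phase) |>
      dplyr::summarise(
        unit_id = NA_character_, age_d = mean(.data$age_d),
        ame_kcal_kg = mean(.data$ame_kcal_kg),
        amen_kcal_kg = mean(.data$amen_kcal_kg),
        amc_dm_pct = mean(.data$amc_dm_pct), .groups = "drop"
      )
  }
  test |>
    dplyr::inner_join(ref_means, by = "phase") |>
    dplyr::inner_join(compositions[c("ingredient_id", "ge_kcal_kg")],
                      by = c(test_ingredient_id = "ingredient_id")) |>
    dplyr::transmute(
      ingredient_id = .data$test_ingredient_id, phase = .data$phase,
      age_d = .data$age_d, unit_id = .data$unit_id,
      ame_kcal_kg = substitution_energy(.data$ame_kcal_kg, .data$ref_ame,
                                        .data$test_fraction),
      amen_kcal_kg = substitution_energy(.data$amen_kcal_kg, .data$ref_amen,
                                         .data$test_fraction),
      amc_dm_pct = substitution_energy(.data$amc_dm_pct, .data$ref_amc_dm,
                                       .data$test_fraction),
      amc_ge_pct = amc_ge(.data$amen_kcal_kg, .data$ge_kcal_kg)
    )
}

#' Ingredient-level energy table (means over replicates)
#'
#' Averages the replicate-level substitution estimates within ingredient x
#' phase; AMC_GE is recomputed from the mean AMEn and the ingredient's gross
#' energy.
#'
#' @inheritParams ingredient_energy_replicates
#' @return Tibble with one row per ingredient x phase: means of AME, AMEn,
#'   AMC_DM, AMC_GE plus `n_units` and `method = "substitution"`.
#' @export
ingredient_energy_table <- function(results, diets, compositions,
                                    mode = c("per_replicate", "by_means")) {
  reps <- ingredient_energy_replicates(results, diets, compositions, mode)
  compositions <- validate_records(compositions, "composition")
  reps |>
    dplyr::group_by(.data$ingredient_id, .data$phase) |>
    dplyr::summarise(
      n_units = dplyr::n(), age_d = mean(.data$age_d),
      ame_kcal_kg = mean(.data$ame_kcal_kg),
      amen_kcal_kg = mean(.data$amen_kcal_kg),
      amc_dm_pct = mean(.data$amc_dm_pct), .groups = "drop"
    ) |>
    dplyr::inner_join(compositions[c("ingredient_id", "ge_kcal_kg")],
                      by = "ingredient_id") |>
    dplyr::mutate(
      amc_ge_pct = amc_ge(.data$amen_kcal_kg, .data$ge_kcal_kg),
      ge_kcal_kg = NULL, method = "substitution"
    )
}
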