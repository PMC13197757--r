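# Synthetic substitution-trial generator. Records are constructed by
# inverting the energy bookkeeping, so at zero noise the pipeline recovers
# the generating truth exactly; replicate noise enters through the excreta
# GE concentration and excreta N (assay error), never through intake.

#' Default composition sampling ranges
#'
#' Uniform low/high per predictor, spanning the packaged four-sample
#' composition table: DM 88-91%, CP 14-22%, MM 7-10%, EE 0.3-0.5%,
#' NDF 3-13%, GE 4000-4300 kcal/kg DM, MGD 600-950 um.
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
default_composition_ranges <- function() {
  list(
    dm_pct = c(88, 91), cp_pct = c(14, 22), mm_pct = c(7, 10),
    ee_pct = c(0.3, 0.5), ndf_pct = c(3, 13), ge_kcal_kg = c(4000, 4300),
    mgd_um = c(600, 950)
  )
}

#' Configuration for the synthetic trial generator
#'
#' The defaults emulate the standard four-phase substitution trial: 4
#' ingredients, 6 replicates per diet and phase, 30% test inclusion, a
#' through-origin true ingredient-AME model `-32*age + 49*CP + 2736*EE`
#' (kcal/kg DM; age in days at the collection-window midpoint), a constant
#' AME - AMEn gap of 156.5 kcal/kg (positive nitrogen balance of growing
#' birds), replicate noise of 100 kcal/kg on the diet-level energy scale,
#' and phase intakes near the published trial (765/1708/2398/2046 g).
#'
#' @param n_ingredients Number of test ingredients.
#' @param phases Phase table ([default_phases()]).
#' @param inclusion Test-ingredient fraction of test diets, in (0, 1].
#' @param composition_ranges Per-field uniform sampling ranges.
#' @param true_model List with `coefficients` (named, subset of
#'   [me_predictors()]) and `intercept` for the true ingredient AME.
#' @param amen_gap Mean AME - AMEn gap (kcal/kg), applied to every diet, so
#'   the ingredient-level gap equals it too; parameterized through nitrogen
#'   balance as `NB = gap * DMI_kg / 8.22`.
#' @param noise_sd_kcal Replicate noise SD, expressed on the
#'   ingredient-energy scale — the scale of the substitution estimates the
#'   trial exists to measure. It is realised on each unit's excreta GE
#'   concentration, scaled so the induced diet-level AME noise is
#'   `inclusion * noise_sd_kcal`; a replicate substitution estimate then
#'   carries SD of about `noise_sd_kcal`. The implied diet-level assay
#'   noise at the defaults (~30 kcal/kg, about 1% of AME) is typical of
#'   bomb-calorimetry precision.
#' @param noise_sd_n_pct Replicate noise SD on excreta N (% of DM),
#'   truncated at 0.
#' @param intake_mean_g Named per-phase mean as-fed intake over the
#'   collection window (g).
#' @param intake_rel_sd Relative SD of intake between units (animal
#'   variation, not measurement noise).
#' @param reference_ame Named per-phase reference-diet AME (kcal/kg DM).
#' @param amc_dm_pct Named per-phase diet-level DM metabolizability (%).
#' @param diet_ge_kcal_kg_dm,diet_dm_pct,diet_n_pct Diet assay values.
#' @param seed Integer seed; all randomness derives from it.
#' @return List of class `"me_generator_config"`.
#' @export
generator_config <- function(n_ingredients = 4, phases = default_phases(),
                             inclusion = 0.30,
                             composition_ranges = default_composition_ranges(),
                             true_model = list(
                               coefficients = c(age = -32, CP = 49, EE = 2736),
                               intercept = 0),
                             amen_gap = 156.5, noise_sd_kcal = 100,
                             noise_sd_n_pct = 0.1,
                             intake_mean_g = c("pre-initial" = 765,
                                               "initial" = 1708,
                                               "grower-1" = 2398,
                                               "grower-2" = 2046),
                             intake_rel_sd = 0.02,
                             reference_ame = c("pre-initial" = 3186,
                                               "initial" = 3607,
                                               "grower-1" = 3671,
                                               "grower-2" = 3404),
                             amc_dm_pct = c("pre-initial" = 64,
                                            "initial" = 72,
                                            "grower-1" = 76,
                                            "grower-2" = 83),
                             diet_ge_kcal_kg_dm = 3950, diet_dm_pct = 90,
                             diet_n_pct = 3.5, seed = 42) {
  stopifnot(inclusion > 0, inclusion <= 1, noise_sd_kcal >= 0,
            noise_sd_n_pct >= 0, n_ingredients >= 1)
  for (f in names(composition_ranges)) {
    r <- composition_ranges[[f]]
    if (!(r[1] < r[2])) stop("composition range for ", f,
                             " needs low < high", call. = FALSE)
  }
  bad <- setdiff(names(true_model$coefficients), me_predictors())
  if (length(bad)) stop("true_model uses unknown predictor(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg <- list(
    n_ingredients = n_ingredients, phases = phases, inclusion = inclusion,
    composition_ranges = composition_ranges, true_model = true_model,
    amen_gap = amen_gap, noise_sd_kcal = noise_sd_kcal,
    noise_sd_n_pct = noise_sd_n_pct, intake_mean_g = intake_mean_g,
    intake_rel_sd = intake_rel_sd, reference_ame = reference_ame,
    amc_dm_pct = amc_dm_pct, diet_ge_kcal_kg_dm = diet_ge_kcal_kg_dm,
    diet_dm_pct = diet_dm_pct, diet_n_pct = diet_n_pct, seed = seed
  )
  class(cfg) <- "me_generator_config"
  cfg
}

# true ingredient energy from the generating model at given age
.true_energy <- function(true_model, comp_row, age_d) {
  vals <- c(age = unname(age_d),
            setNames(unlist(comp_row[1, .predictor_cols], use.names = FALSE),
                     names(.predictor_cols)))
  (true_model$intercept %||% 0) +
    sum(true_model$coefficients * vals[names(true_model$coefficients)])
}

# invert the bookkeeping: one record per row of `targets`
# (diet_id, phase, age_d, intake_g, ame, amen, amc_dm) + diet assay scalars
.records_from_targets <- function(targets, diet_ge, diet_dm, diet_n,
                                  noise_sd_kcal, noise_sd_n_pct) {
  dmi_g <- targets$intake_g * diet_dm / 100
  dmi_kg <- dmi_g / 1000
  ge_in <- dmi_kg * diet_ge
  excreta_dm_g <- dmi_g * (1 - targets$amc_dm / 100)
  if (any(excreta_dm_g <= 0)) {
    stop("amc_dm_pct implies non-positive excreta dry matter", call. = FALSE)
  }
  ge_out <- ge_in - targets$ame * dmi_kg
  if (any(ge_out < 0)) {
    stop("reference_ame/true energies exceed diet_ge_kcal_kg_dm: ",
         "negative excreta energy implied", call. = FALSE)
  }
  excreta_ge <- ge_out / (excreta_dm_g / 1000)
  nb <- (targets$ame - targets$amen) * dmi_kg / K_NITROGEN
  n_out_g <- dmi_g * diet_n / 100 - nb
  if (any(n_out_g < 0)) {
    stop("amen_gap (or printed AME-AMEn gap) implies negative excreta N at ",
         "diet_n_pct = ", diet_n, "; raise diet_n_pct", call. = FALSE)
  }
  excreta_n <- 100 * n_out_g / excreta_dm_g
  n <- nrow(targets)
  if (noise_sd_kcal > 0) {
    excreta_ge <- excreta_ge +
      rnorm(n, 0, noise_sd_kcal) * dmi_kg / (excreta_dm_g / 1000)
    excreta_ge <- pmax(excreta_ge, 0)
  }
  if (noise_sd_n_pct > 0) {
    excreta_n <- pmax(excreta_n + rnorm(n, 0, noise_sd_n_pct), 0)
  }
  tibble::tibble(
    unit_id = paste0(targets$diet_id, "-", targets$phase, "-r", targets$rep),
    diet_id = targets$diet_id, phase = targets$phase, age_d = targets$age_d,
    feed_intake_g = targets$intake_g, diet_dm_pct = diet_dm,
    diet_ge_kcal_kg_dm = diet_ge, diet_n_pct_dm = diet_n,
    excreta_dm_g = excreta_dm_g, excreta_ge_kcal_kg_dm = excreta_ge,
    excreta_n_pct_dm = excreta_n
  )
}

#' Generate a complete synthetic substitution trial
#'
#' Draws ingredient compositions uniformly within the configured ranges,
#' computes the true ingredient AME from the generating model at each
#' phase's collection-window midpoint age, mixes test-diet energies as
#' `(1 - f) * reference + f * ingredient`, and constructs per-unit
#' collection records by inverting the energy formulas, so that noise-free
#' records yield exactly the true energies. All randomness derives from
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List: `compositions`, `diets`, `phases`, `records` (one per
#'   unit), `truth` (generating coefficients, per-ingredient true energies
#'   per phase, reference-diet energies per phase), `config`.
#' @export
generate_trial <- function(config = generator_config()) {
  stopifnot(inherits(config, "me_generator_config"))
  withr::with_seed(config$seed, {
    rng <- config$composition_ranges
    compositions <- tibble::tibble(
      ingredient_id = sprintf("ING-%02d", seq_len(config$n_ingredients)))
    for (f in names(rng)) {
      compositions[[f]] <- runif(config$n_ingredients, rng[[f]][1], rng[[f]][2])
    }
    compositions <- validate_records(compositions, "composition")
    diets <- trial_diets(compositions$ingredient_id, config$inclusion)
    mid <- phase_midpoint_age(config$phases)

    truth_ing <- tidyr::expand_grid(
      ingredient_id = compositions$ingredient_id,
      phase = config$phases$name
    )
    truth_ing$age_d <- mid[truth_ing$phase]
    truth_ing$true_ame <- vapply(seq_len(nrow(truth_ing)), function(i) {
      comp <- compositions[compositions$ingredient_id ==
                             truth_ing$ingredient_id[i], ]
      .true_energy(config$true_model, comp, truth_ing$age_d[i])
    }, numeric(1))
    truth_ing$true_amen <- truth_ing$true_ame - config$amen_gap

    truth_ref <- tibble::tibble(
      phase = config$phases$name,
      ame = unname(config$reference_ame[config$phases$name]),
      amen = unname(config$reference_ame[config$phases$name]) - config$amen_gap
    )

    targets <- tidyr::expand_grid(
      diet_id = diets$diet_id, phase = config$phases$name,
      rep = seq_len(config$phases$replicates[1])
    ) |>
      dplyr::left_join(diets[c("diet_id", "kind", "test_ingredient_id",
                               "test_fraction")], by = "diet_id") |>
      dplyr::left_join(truth_ref, by = "phase") |>
      dplyr::left_join(truth_ing, by = c(test_ingredient_id = "ingredient_id",
                                         "phase"))
    targets$age_d <- mid[targets$phase]
    f <- targets$test_fraction
    targets$ame_target <- ifelse(
      targets$kind == "reference", targets$ame,
      (1 - f) * targets$ame + f * targets$true_ame)
    targets$amen_target <- targets$ame_target - config$amen_gap
    targets$intake_g <- rnorm(
      nrow(targets), config$intake_mean_g[targets$phase],
      config$intake_rel_sd * config$intake_mean_g[targets$phase])
    if (any(targets$intake_g <= 0)) {
      stop("intake_rel_sd implies non-positive intake", call. = FALSE)
    }
    targets$amc_dm <- config$amc_dm_pct[targets$phase]
    rec_targets <- tibble::tibble(
      diet_id = targets$diet_id, phase = targets$phase, rep = targets$rep,
      age_d = targets$age_d, intake_g = targets$intake_g,
      ame = targets$ame_target, amen = targets$amen_target,
      amc_dm = targets$amc_dm
    )
    records <- .records_from_targets(
      rec_targets, config$diet_ge_kcal_kg_dm, config$diet_dm_pct,
      config$diet_n_pct, config$noise_sd_kcal * config$inclusion,
      config$noise_sd_n_pct)
    records <- validate_records(records, "collection")
    list(
      compositions = compositions, diets = diets, phases = config$phases,
      records = records,
      truth = list(
        coefficients = config$true_model$coefficients,
        intercept = config$true_model$intercept %||% 0,
        amen_gap = config$amen_gap,
        ingredients = truth_ing, reference = truth_ref
      ),
      config = config
    )
  })
}

#' Demonstration bundle anchored to the published trial
#'
#' A fixed four-ingredient bundle whose compositions equal the packaged
#' composition table and whose true ingredient energies per phase equal the
#' published ingredient-level means, with reference-diet energies, diet
#' intakes and DM metabolizability taken from the published diet-level
#' table. Test-diet energies are constructed by mixing
#' `(1 - f) * reference + f * ingredient` (the published diet-level test
#' cells are not themselves consistent with the substitution formula, so
#' mixing is what makes the bundle internally exact), and the per-phase diet
#' N is set to the minimum that keeps excreta N non-negative given the
#' published AME - AMEn gaps, plus a margin. At `noise_sd_kcal = 0` the full
#' pipeline reproduces the published ingredient AME/AMEn/AMC_DM exactly.
#'
#' @param noise_sd_kcal,noise_sd_n_pct Replicate noise (default 0: exact);
#'   `noise_sd_kcal` on the ingredient-energy scale as in
#'   [generator_config()].
#' @param replicates Units per diet and phase.
#' @param seed Seed for the noise draws.
#' @return Same bundle structure as [generate_trial()].
#' @export
paper_like_dataset <- function(noise_sd_kcal = 0, noise_sd_n_pct = 0,
                               replicates = 6, seed = 1) {
  compositions <- load_fixture("composition")
  diet_tbl <- load_fixture("diet_energy")
  ing_tbl <- load_fixture("ingredient_energy")
  phases <- default_phases()
  phases$replicates <- replicates
  mid <- phase_midpoint_age(phases)
  inclusion <- 0.30
  diets <- trial_diets(compositions$ingredient_id, inclusion)
  roman <- c("I", "II", "III", "IV")

  wide <- function(tbl, var, cols) {
    out <- tbl[tbl$variable == var, c("phase", cols)]
    out
  }
  ref <- tibble::tibble(
    phase = phases$name,
    ame = wide(diet_tbl, "ame_kcal_kg", "RD")$RD,
    amen = wide(diet_tbl, "amen_kcal_kg", "RD")$RD,
    amc_dm = wide(diet_tbl, "amc_dm_pct", "RD")$RD,
    intake = wide(diet_tbl, "feed_intake_g", "RD")$RD
  )
  truth_ing <- tidyr::expand_grid(ingredient_id = compositions$ingredient_id,
                                  phase = phases$name)
  truth_ing$age_d <- mid[truth_ing$phase]
  pick <- function(var) {
    m <- as.matrix(ing_tbl[ing_tbl$variable == var, roman])
    rownames(m) <- ing_tbl$phase[ing_tbl$variable == var]
    vapply(seq_len(nrow(truth_ing)), function(i) {
      col <- roman[match(truth_ing$ingredient_id[i], compositions$ingredient_id)]
      m[truth_ing$phase[i], col]
    }, numeric(1))
  }
  truth_ing$true_ame <- pick("ame_kcal_kg")
  truth_ing$true_amen <- pick("amen_kcal_kg")
  truth_ing$true_amc_dm <- pick("amc_dm_pct")
  intake_m <- as.matrix(diet_tbl[diet_tbl$variable == "feed_intake_g", roman])
  rownames(intake_m) <- diet_tbl$phase[diet_tbl$variable == "feed_intake_g"]

  targets <- tidyr::expand_grid(diet_id = diets$diet_id, phase = phases$name,
                                rep = seq_len(replicates)) |>
    dplyr::left_join(diets[c("diet_id", "kind", "test_ingredient_id",
                             "test_fraction")], by = "diet_id") |>
    dplyr::left_join(ref, by = "phase") |>
    dplyr::left_join(truth_ing, by = c(test_ingredient_id = "ingredient_id",
                                       "phase"))
  targets$age_d <- mid[targets$phase]
  is_ref <- targets$kind == "reference"
  f <- targets$test_fraction
  targets$ame_target <- ifelse(is_ref, targets$ame,
                               (1 - f) * targets$ame + f * targets$true_ame)
  targets$amen_target <- ifelse(is_ref, targets$amen,
                                (1 - f) * targets$amen + f * targets$true_amen)
  targets$amc_dm_target <- ifelse(is_ref, targets$amc_dm,
                                  (1 - f) * targets$amc_dm +
                                    f * targets$true_amc_dm)
  roman_of <- roman[match(targets$test_ingredient_id,
                          compositions$ingredient_id)]
  targets$intake_g <- ifelse(
    is_ref, targets$intake,
    intake_m[cbind(targets$phase, roman_of)])

  diet_ge <- 3950
  diet_dm <- 90
  records <- withr::with_seed(seed, dplyr::bind_rows(lapply(
    phases$name, function(ph) {
      sub <- targets[targets$phase == ph, ]
      gap_max <- max(sub$ame_target - sub$amen_target)
      # minimum feasible diet N for non-negative excreta N, plus margin
      diet_n <- ceiling(10 * (gap_max / K_NITROGEN / 10 + 0.5)) / 10
      .records_from_targets(
        tibble::tibble(diet_id = sub$diet_id, phase = sub$phase,
                       rep = sub$rep, age_d = sub$age_d,
                       intake_g = sub$intake_g, ame = sub$ame_target,
                       amen = sub$amen_target, amc_dm = sub$amc_dm_target),
        diet_ge, diet_dm, diet_n, noise_sd_kcal * inclusion, noise_sd_n_pct)
    })))
  records <- validate_records(records, "collection")
  list(
    compositions = compositions, diets = diets, phases = phases,
    records = records,
    truth = list(
      amen_gap = NA_real_,
      ingredients = truth_ing,
      reference = ref[c("phase", "ame", "amen")]
    ),
    config = list(inclusion = inclusion, diet_ge_kcal_kg_dm = diet_ge,
                  diet_dm_pct = diet_dm, noise_sd_kcal = noise_sd_kcal,
                  noise_sd_n_pct = noise_sd_n_pct, seed = seed)
  )
}
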