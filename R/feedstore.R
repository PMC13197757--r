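# Domain types, packaged fixtures, and CSV/JSON readers-writers for every
# tabular artifact the pipeline touches. All composition fields are stored on
# the dry-matter basis; any as-fed conversion is an explicit separate step.

#' Canonical predictor names for energy-prediction equations
#'
#' The eight admissible predictors, in the fixed order used everywhere in the
#' package (tie-breaking in model selection, column order in outputs):
#' bird age (days) and the seven physicochemical measures — dry matter (DM, %),
#' crude protein (CP, % DM), mineral matter (MM, % DM), ether extract
#' (EE, % DM), neutral detergent fiber (NDF, % DM), mean geometric particle
#' diameter (MGD, um) and gross energy (GE, kcal/kg DM).
#'
#' @return Character vector of length 8.
#' @export
me_predictors <- function() {
  c("age", "DM", "CP", "MM", "EE", "NDF", "MGD", "GE")
}

# predictor name -> composition column
.predictor_cols <- c(
  DM = "dm_pct", CP = "cp_pct", MM = "mm_pct", EE = "ee_pct",
  NDF = "ndf_pct", MGD = "mgd_um", GE = "ge_kcal_kg"
)

#' Specify one trial phase
#'
#' A phase is an 8-day window at a given bird age: an adaptation period
#' followed by total-excreta collection days. The collection-window age
#' assigned to its records is the midpoint of the collection days.
#'
#' @param name Phase label, one of `"pre-initial"`, `"initial"`,
#'   `"grower-1"`, `"grower-2"`.
#' @param age_start_d,age_end_d First and last bird age (days) of the window.
#' @param adaptation_days,collection_days Days of adaptation and of total
#'   collection; must sum to the window length.
#' @param birds_per_unit Birds housed per experimental unit.
#' @param replicates Experimental units per diet (>= 2).
#' @return One-row tibble.
#' @export
phase_spec <- function(name, age_start_d, age_end_d, adaptation_days = 4,
                       collection_days = 4, birds_per_unit = 6,
                       replicates = 6) {
  name <- match.arg(name, c("pre-initial", "initial", "grower-1", "grower-2"))
  if (!(age_end_d > age_start_d && age_start_d >= 1)) {
    stop("phase '", name, "': need age_end_d > age_start_d >= 1", call. = FALSE)
  }
  if (adaptation_days + collection_days != age_end_d - age_start_d + 1) {
    stop("phase '", name, "': adaptation_days + collection_days must equal ",
         "the window length ", age_end_d - age_start_d + 1, call. = FALSE)
  }
  if (replicates < 2) stop("phase '", name, "': replicates must be >= 2", call. = FALSE)
  tibble::tibble(
    name = name, age_start_d = age_start_d, age_end_d = age_end_d,
    adaptation_days = adaptation_days, collection_days = collection_days,
    birds_per_unit = birds_per_unit, replicates = replicates
  )
}

#' The four standard broiler growth phases
#'
#' Pre-initial (days 1-8), initial (11-18), grower 1 (21-28) and grower 2
#' (31-38), each with 4 adaptation + 4 collection days and 6 replicates;
#' housing density decreases with age (8, 6, 5, 4 birds per unit).
#'
#' @return Tibble with one row per phase.
#' @export
default_phases <- function() {
  dplyr::bind_rows(
    phase_spec("pre-initial", 1, 8, birds_per_unit = 8),
    phase_spec("initial", 11, 18, birds_per_unit = 6),
    phase_spec("grower-1", 21, 28, birds_per_unit = 5),
    phase_spec("grower-2", 31, 38, birds_per_unit = 4)
  )
}

#' Collection-window midpoint age of each phase
#'
#' @param phases Tibble from [phase_spec()] / [default_phases()].
#' @return Named numeric vector (days), e.g. 6.5 for collection days 5-8.
#' @export
phase_midpoint_age <- function(phases = default_phases()) {
  mid <- (phases$age_start_d + phases$adaptation_days + phases$age_end_d) / 2
  setNames(mid, phases$name)
}

#' Default scalar age for phase-pooled equation predictions
#'
#' The mean of the four phase collection-window midpoints (21.5 d for the
#' standard phases). Used when a single prediction age is needed for
#' ingredient-level (phase-pooled) validation.
#'
#' @inheritParams phase_midpoint_age
#' @return Scalar days.
#' @export
default_prediction_age <- function(phases = default_phases()) {
  mean(phase_midpoint_age(phases))
}

#' Specify a diet
#'
#' @param diet_id Diet label.
#' @param kind `"reference"` or `"test"`.
#' @param test_ingredient_id Ingredient fed in a test diet (absent for the
#'   reference diet).
#' @param reference_fraction,test_fraction Mixing proportions (must sum to 1
#'   exactly); the standard substitution design is 0.70/0.30 on the DM basis.
#' @param marker_pct Ferric-oxide marker inclusion (%); informational only —
#'   the marker delimits the collection window procedurally and enters no
#'   calculation.
#' @return One-row tibble.
#' @export
diet_spec <- function(diet_id, kind = c("reference", "test"),
                      test_ingredient_id = NA_character_,
                      reference_fraction = if (kind == "reference") 1 else 0.70,
                      test_fraction = 1 - reference_fraction,
                      marker_pct = 2.0) {
  kind <- match.arg(kind)
  if (reference_fraction + test_fraction != 1) {
    stop("diet '", diet_id, "': reference_fraction + test_fraction must be exactly 1",
         call. = FALSE)
  }
  if (kind == "reference" && test_fraction != 0) {
    stop("diet '", diet_id, "': a reference diet must have test_fraction = 0",
         call. = FALSE)
  }
  if (kind == "test" && is.na(test_ingredient_id)) {
    stop("diet '", diet_id, "': a test diet needs test_ingredient_id", call. = FALSE)
  }
  tibble::tibble(
    diet_id = diet_id, kind = kind,
    reference_fraction = reference_fraction, test_fraction = test_fraction,
    test_ingredient_id = test_ingredient_id, marker_pct = marker_pct
  )
}

#' Standard substitution-trial diet set
#'
#' One reference diet plus one 70/30 test diet per ingredient.
#'
#' @param ingredient_ids Character vector of ingredient labels.
#' @param inclusion Test-ingredient fraction of the test diets.
#' @return Tibble of diet specs.
#' @export
trial_diets <- function(ingredient_ids, inclusion = 0.30) {
  dplyr::bind_rows(
    diet_spec("RD", "reference"),
    dplyr::bind_rows(lapply(ingredient_ids, function(ing) {
      diet_spec(paste0("TD-", ing), "test", test_ingredient_id = ing,
                reference_fraction = 1 - inclusion)
    }))
  )
}

#' Build an equation specification
#'
#' Represents one prediction equation over the canonical predictors as a
#' one-row wide tibble (one column per predictor, `NA` = predictor absent).
#'
#' @param target `"AME"` or `"AMEn"`.
#' @param coefficients Named numeric vector; names drawn from [me_predictors()].
#' @param intercept Intercept (kcal/kg) or `NA` for a through-origin equation.
#' @param r2,aic Optional fit diagnostics.
#' @param source `"printed"` (published) or `"fitted"`.
#' @param eq_id Optional equation number.
#' @return One-row tibble with columns `target`, `eq_id`, `source`,
#'   `intercept`, the eight predictor columns, `r2`, `aic`.
#' @export
equation_spec <- function(target = c("AME", "AMEn"), coefficients,
                          intercept = NA_real_, r2 = NA_real_, aic = NA_real_,
                          source = c("fitted", "printed"), eq_id = NA_integer_) {
  target <- match.arg(target)
  source <- match.arg(source)
  bad <- setdiff(names(coefficients), me_predictors())
  if (length(bad)) {
    stop("unknown predictor name(s): ", paste(bad, collapse = ", "),
         "; valid names are ", paste(me_predictors(), collapse = ", "),
         call. = FALSE)
  }
  if (!length(coefficients) || all(coefficients == 0)) {
    stop("an equation needs at least one non-zero coefficient", call. = FALSE)
  }
  coefs <- setNames(rep(NA_real_, 8), me_predictors())
  coefs[names(coefficients)] <- coefficients
  tibble::tibble(
    target = target, eq_id = eq_id, source = source, intercept = intercept,
    !!!as.list(coefs), r2 = r2, aic = aic
  )
}

.fixture_ids <- c("composition", "diet_energy", "ingredient_energy",
                  "ame_equations", "amen_equations", "validation")

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "yeastME")
  if (!nzchar(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

.read_fixture_csv <- function(file) {
  readr::read_csv(.extdata(file), comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

.equations_from_json <- function(path) {
  reg <- jsonlite::fromJSON(path, simplifyVector = FALSE)$equations
  dplyr::bind_rows(lapply(reg, function(e) {
    equation_spec(
      target = e$target, coefficients = unlist(e$coefficients),
      intercept = if (is.null(e$intercept)) NA_real_ else e$intercept,
      r2 = if (is.null(e$r2)) NA_real_ else e$r2,
      aic = if (is.null(e$aic)) NA_real_ else e$aic,
      source = e$source, eq_id = as.integer(e$eq_id)
    )
  }))
}

#' Load a packaged table
#'
#' The tables that ship with the package: the four-sample physicochemical
#' composition, the diet-level and ingredient-level trial summaries, the
#' published AME / AMEn prediction-equation registries, and the published
#' observed-vs-predicted validation tables.
#'
#' @param table_id One of `"composition"`, `"diet_energy"`,
#'   `"ingredient_energy"`, `"ame_equations"`, `"amen_equations"`,
#'   `"validation"`.
#' @return A tibble of typed records; values match the published tables
#'   digit for digit. For `"validation"` the AME and AMEn tables are bound
#'   with a `target` column.
#' @export
load_fixture <- function(table_id) {
  if (length(table_id) != 1 || !table_id %in% .fixture_ids) {
    stop("unknown table_id '", paste(table_id, collapse = ","),
         "'; valid ids: ", paste(.fixture_ids, collapse = ", "), call. = FALSE)
  }
  switch(table_id,
    composition = validate_records(.read_fixture_csv("composition.csv"),
                                   "composition"),
    diet_energy = .read_fixture_csv("diet_energy.csv"),
    ingredient_energy = .read_fixture_csv("ingredient_energy.csv"),
    ame_equations = dplyr::filter(.equations_from_json(.extdata("equations.json")),
                                  .data$target == "AME"),
    amen_equations = dplyr::filter(.equations_from_json(.extdata("equations.json")),
                                   .data$target == "AMEn"),
    validation = dplyr::bind_rows(
      dplyr::mutate(.read_fixture_csv("validation_ame.csv"), target = "AME",
                    .before = 1),
      dplyr::mutate(.read_fixture_csv("validation_amen.csv"), target = "AMEn",
                    .before = 1)
    )
  )
}

# schema registry: required columns, their types, and per-field range checks
.schemas <- list(
  composition = list(
    character = "ingredient_id",
    numeric = c("dm_pct", "cp_pct", "mm_pct", "ee_pct", "ndf_pct",
                "ge_kcal_kg", "mgd_um"),
    ranges = list(
      dm_pct = c(0, 100), cp_pct = c(0, 100), mm_pct = c(0, 100),
      ee_pct = c(0, 100), ndf_pct = c(0, 100),
      ge_kcal_kg = c(1e-12, Inf), mgd_um = c(1e-12, Inf)
    )
  ),
  collection = list(
    character = c("unit_id", "diet_id", "phase"),
    numeric = c("age_d", "feed_intake_g", "diet_dm_pct", "diet_ge_kcal_kg_dm",
                "diet_n_pct_dm", "excreta_dm_g", "excreta_ge_kcal_kg_dm",
                "excreta_n_pct_dm"),
    ranges = list(
      age_d = c(0, Inf), feed_intake_g = c(1e-12, Inf),
      diet_dm_pct = c(1e-12, 100), diet_ge_kcal_kg_dm = c(0, Inf),
      diet_n_pct_dm = c(0, 100), excreta_dm_g = c(0, Inf),
      excreta_ge_kcal_kg_dm = c(0, Inf), excreta_n_pct_dm = c(0, 100)
    )
  )
)

#' Validate a table of typed records
#'
#' Checks required columns, numeric types and per-field ranges; for
#' compositions additionally CP + MM + EE <= 100, and for collection records
#' a positive dry-matter intake. Errors name the offending row and field.
#'
#' @param tbl A data frame.
#' @param schema `"composition"` or `"collection"`.
#' @return The validated tibble, row order preserved.
#' @export
validate_records <- function(tbl, schema = c("composition", "collection")) {
  schema <- match.arg(schema)
  spec <- .schemas[[schema]]
  tbl <- tibble::as_tibble(tbl)
  missing <- setdiff(c(spec$character, spec$numeric), names(tbl))
  if (length(missing)) {
    stop(schema, " table: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in spec$numeric) {
    v <- tbl[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(schema, " row ", ifelse(is.na(bad), 1, bad), ", field '", col,
           "': non-numeric value", call. = FALSE)
    }
    if (anyNA(v)) {
      stop(schema, " row ", which(is.na(v))[1], ", field '", col,
           "': missing value", call. = FALSE)
    }
    rng <- spec$ranges[[col]]
    out <- which(v < rng[1] | v > rng[2])
    if (length(out)) {
      stop(schema, " row ", out[1], ", field '", col, "': value ", v[out[1]],
           " outside [", rng[1], ", ", rng[2], "]", call. = FALSE)
    }
  }
  if (schema == "composition") {
    tot <- tbl$cp_pct + tbl$mm_pct + tbl$ee_pct
    if (any(tot > 100)) {
      stop("composition row ", which(tot > 100)[1],
           ": cp_pct + mm_pct + ee_pct exceeds 100", call. = FALSE)
    }
  }
  if (schema == "collection") {
    dmi <- tbl$feed_intake_g * tbl$diet_dm_pct / 100
    if (any(dmi <= 0)) {
      stop("collection row ", which(dmi <= 0)[1],
           ": dry-matter intake must be positive", call. = FALSE)
    }
  }
  tbl
}

#' Read typed records from a CSV file
#'
#' @param path CSV file (comma-separated, period decimal, UTF-8, header row
#'   mandatory; `#` lines are comments).
#' @param schema `"composition"` or `"collection"`.
#' @return Validated tibble, row order preserved.
#' @export
read_records <- function(path, schema = c("composition", "collection")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_records(tbl, schema)
}

#' Write records to CSV at full precision
#'
#' Stable column order, no rounding — rounding happens only in report
#' rendering ([render_group_table()] and friends).
#'
#' @param tbl Table of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(tbl, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", path,
                             call. = FALSE)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Write an equation registry to JSON
#'
#' @param equations Wide equation tibble ([equation_spec()] rows).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_equations <- function(equations, path) {
  recs <- lapply(seq_len(nrow(equations)), function(i) {
    row <- equations[i, ]
    coefs <- unlist(row[me_predictors()])
    coefs <- coefs[!is.na(coefs)]
    list(
      target = row$target, eq_id = row$eq_id, source = row$source,
      intercept = if (is.na(row$intercept)) NULL else row$intercept,
      coefficients = as.list(coefs),
      r2 = if (is.na(row$r2)) NULL else row$r2,
      aic = if (is.na(row$aic)) NULL else row$aic
    )
  })
  jsonlite::write_json(list(equations = recs), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an equation registry written by [write_equations()]
#'
#' @param path JSON file.
#' @return Wide equation tibble.
#' @export
read_equations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .equations_from_json(path)
}
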