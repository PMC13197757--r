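#!/usr/bin/env Rscript
# Step 4 — evaluate the published prediction-equation registries on the
# packaged composition table and score them against the published in vivo
# (phase-pooled) energy values by sum of squared deviations. The published
# SSD figures are carried side by side with the recomputed ones; they are
# metadata (their basis is not disclosed in the source) and are never
# reconciled.
#
# Output: results/{validation_ame.csv, validation_amen.csv,
#         validation_report.txt}

suppressPackageStartupMessages({
  library(yeastME)
  library(dplyr)
})

comp <- load_fixture("composition")
val <- load_fixture("validation")
age <- default_prediction_age()
lines_out <- character(0)

for (target in c("AME", "AMEn")) {
  eqs <- load_fixture(if (target == "AME") "ame_equations" else
    "amen_equations")
  vt <- val[val$target == target, ]
  feed <- vt[grepl("^Yeast", vt$row), ]
  obs <- tibble::tibble(
    ingredient_id = comp$ingredient_id,
    observed = feed$observed[match(paste("Yeast", comp$ingredient_no),
                                   feed$row)])
  printed <- unlist(vt[vt$row == "ssd", paste0("eq", 1:10)],
                    use.names = FALSE)
  rep <- validate_against_observed(eqs, comp, obs, age_d = age,
                                   printed_ssd = printed)
  out <- bind_rows(
    mutate(rep$predictions, row = ingredient_id, .before = 1),
    tibble::tibble(row = "ssd", !!!setNames(as.list(rep$ssd$ssd),
                                            rep$ssd$equation)),
    tibble::tibble(row = "ssd_published",
                   !!!setNames(as.list(rep$ssd$printed_ssd),
                               rep$ssd$equation)))
  write_records(select(out, -any_of("ingredient_id")),
                paste0("results/validation_", tolower(target), ".csv"))
  lines_out <- c(lines_out, paste0("== ", target, " (prediction age ",
                                   round(age, 1), " d) =="),
                 render_validation_table(rep), "")
  best <- rep$ssd$equation[which.min(rep$ssd$ssd)]
  cat(target, ": best equation by recomputed SSD is", best,
      "(SSD", round(min(rep$ssd$ssd), 1), "kcal^2 )\n")
}

writeLines(lines_out, "results/validation_report.txt")
cat("wrote results/validation_*.csv and results/validation_report.txt\n")
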