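# Rendering of trial-style summary tables. Rendering is one-way: rounded,
# letter-annotated strings for humans; computation always uses the
# full-precision tables.

.fmt <- function(x, digits) {
  ifelse(is.na(x), "", formatC(round(x, digits), format = "f",
                               digits = digits))
}

#' Render a lettered group-comparison table
#'
#' One text table per variable: treatment means with Tukey letters attached
#' as superscript-style suffixes, followed by the Average, P-value and SEM /
#' CV summary columns. Energies are rendered at 0 dp, percentages and
#' intakes at 2 dp; re-rendering identical input is byte-identical.
#'
#' @param stats Tibble with columns `variable`, `group`, `mean`, `letters`
#'   plus per-variable `p_value`, `sem`, `cv_pct` (as produced by the
#'   analysis drivers from [group_comparison()] output).
#' @return Character vector of report lines.
#' @export
render_group_table <- function(stats) {
  if (!nrow(stats)) return("variable | (no data)")
  lines <- character(0)
  for (v in unique(stats$variable)) {
    sub <- stats[stats$variable == v, ]
    digits <- if (grepl("kcal", v)) 0 else 2
    cells <- paste0(.fmt(sub$mean, digits),
                    ifelse(nzchar(sub$letters) & !is.na(sub$letters),
                           paste0("^", sub$letters), ""))
    lines <- c(lines, paste0(
      v, " | ", paste(sub$group, "=", cells, collapse = "  "),
      " | avg ", .fmt(mean(sub$mean), digits),
      " | P ", .fmt(sub$p_value[1], 3),
      " | SEM ", .fmt(sub$sem[1], 3),
      " | CV ", .fmt(sub$cv_pct[1], 3)
    ))
  }
  lines
}

#' Render an observed-vs-predicted validation table
#'
#' Ingredient rows with the observed value and one column per equation,
#' followed by Average, recomputed SSD and mean-SSD footer rows (and the
#' published SSDs side by side when present).
#'
#' @param report Output of [validate_against_observed()].
#' @return Character vector of report lines.
#' @export
render_validation_table <- function(report) {
  preds <- report$predictions
  eq_cols <- setdiff(names(preds), c("ingredient_id", "observed"))
  header <- paste(c("feed", "observed", eq_cols), collapse = " | ")
  rows <- vapply(seq_len(nrow(preds)), function(i) {
    paste(c(preds$ingredient_id[i], .fmt(preds$observed[i], 2),
            .fmt(unlist(preds[i, eq_cols]), 2)), collapse = " | ")
  }, character(1))
  avg <- paste(c("Average", .fmt(mean(preds$observed), 2),
                 .fmt(colMeans(as.matrix(preds[eq_cols])), 2)),
               collapse = " | ")
  ssd <- paste(c("SSD", "", .fmt(report$ssd$ssd, 1)), collapse = " | ")
  mssd <- paste(c("Mean SSD", "", .fmt(report$ssd$mean_ssd, 1)),
                collapse = " | ")
  out <- c(header, rows, avg, ssd, mssd)
  if ("printed_ssd" %in% names(report$ssd)) {
    out <- c(out,
             paste(c("SSD (published)", "", .fmt(report$ssd$printed_ssd, 1)),
                   collapse = " | "),
             paste(c("Mean SSD (published)", "",
                     .fmt(report$ssd$printed_mean_ssd, 1)), collapse = " | "))
  }
  out
}
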