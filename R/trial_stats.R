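# Descriptive-statistics surface of the trial tables: per-treatment means,
# SEM, CV, one-way ANOVA and Tukey compact letter display.

.check_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  if (anyNA(values) || anyNA(groups)) stop("missing values or group labels",
                                           call. = FALSE)
  split(values, factor(groups, levels = unique(groups)))
}

#' One-way analysis of variance with trial-table summaries
#'
#' Standard between/within decomposition. For balanced designs with r
#' replicates, `SEM = sqrt(MSE / r)`; unbalanced groups use the harmonic
#' mean of the group sizes and are flagged. `CV = 100 * sqrt(MSE) / grand
#' mean`. A zero within-group mean square is degenerate: F is 0 (p = 1)
#' when the group means coincide, infinite (p = 0) otherwise, and the case
#' is flagged.
#'
#' @param values Numeric response.
#' @param groups Treatment labels, parallel to `values`; at least 2 groups
#'   of at least 2 replicates each.
#' @return One-row tibble: `n_groups`, `f_stat`, `p_value`, `sem`, `cv_pct`,
#'   `msb`, `mse`, `df_between`, `df_within`, `grand_mean`, `balanced`,
#'   `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  g <- .check_groups(values, groups)
  if (length(g) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(g)
  if (any(sizes < 2)) stop("every group needs at least 2 replicates",
                           call. = FALSE)
  n <- sum(sizes)
  k <- length(g)
  grand <- mean(unlist(g))
  means <- vapply(g, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  msb <- ssb / (k - 1)
  mse <- ssw / (n - k)
  balanced <- length(unique(sizes)) == 1
  if (!balanced) {
    warning("unbalanced groups: SEM uses the harmonic mean replicate number",
            call. = FALSE)
  }
  r_eff <- if (balanced) sizes[[1]] else k / sum(1 / sizes)
  degenerate <- mse == 0
  if (degenerate) {
    warning("zero within-group variance: ANOVA is degenerate", call. = FALSE)
    f <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    f <- msb / mse
    p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  }
  tibble::tibble(
    n_groups = k, f_stat = f, p_value = p,
    sem = sqrt(mse / r_eff), cv_pct = 100 * sqrt(mse) / grand,
    msb = msb, mse = mse, df_between = k - 1, df_within = n - k,
    grand_mean = grand, balanced = balanced, degenerate = degenerate
  )
}

#' Pairwise Tukey(-Kramer) HSD p-values
#'
#' Studentized-range p-value for every treatment pair,
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))` referred to the
#' studentized range distribution with k means and N - k df.
#'
#' @inheritParams one_way_anova
#' @return Symmetric matrix of p-values with group names as dimnames.
#' @export
tukey_pairwise <- function(values, groups) {
  g <- .check_groups(values, groups)
  an <- suppressWarnings(one_way_anova(values, groups))
  k <- length(g)
  sizes <- lengths(g)
  means <- vapply(g, mean, numeric(1))
  p <- matrix(1, k, k, dimnames = list(names(g), names(g)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (an$mse == 0) {
        pij <- if (means[i] == means[j]) 1 else 0
      } else {
        q <- abs(means[i] - means[j]) /
          sqrt(an$mse / 2 * (1 / sizes[i] + 1 / sizes[j]))
        pij <- ptukey(q, nmeans = k, df = an$df_within, lower.tail = FALSE)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  p
}

# maximal cliques of the non-significance graph, brute force (k small)
.maximal_cliques <- function(nonsig) {
  k <- nrow(nonsig)
  if (k > 16) stop("compact letter display supports at most 16 groups",
                   call. = FALSE)
  subsets <- list()
  for (code in seq_len(2^k - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    ok <- TRUE
    if (length(members) > 1) {
      prs <- utils::combn(members, 2)
      ok <- all(nonsig[cbind(prs[1, ], prs[2, ])])
    }
    if (ok) subsets <- c(subsets, list(members))
  }
  is_max <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, logical(1))
  subsets[is_max]
}

#' Tukey compact letter display
#'
#' All pairwise Tukey HSD comparisons at level `alpha`; letters are the
#' maximal cliques of the non-significance graph, ordered and lettered from
#' the highest mean downward (so `"a"` marks the top mean). Two treatments
#' share a letter if and only if their difference is not significant.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per group, ordered by descending mean:
#'   `group`, `mean`, `letters`.
#' @export
tukey_letters <- function(values, groups, alpha = 0.05) {
  g <- .check_groups(values, groups)
  means <- vapply(g, mean, numeric(1))
  if (length(g) == 1) {
    return(tibble::tibble(group = names(g), mean = unname(means),
                          letters = "a"))
  }
  p <- tukey_pairwise(values, groups)
  ord <- order(-means)
  nonsig <- (p >= alpha)[ord, ord, drop = FALSE]
  cliques <- .maximal_cliques(nonsig)
  # letter cliques by the position of their best-ranked member
  cliques <- cliques[order(vapply(cliques, min, numeric(1)),
                           vapply(cliques, max, numeric(1)))]
  lab <- vapply(seq_along(ord), function(i) {
    paste(letters[which(vapply(cliques, function(cl) i %in% cl, logical(1)))],
          collapse = "")
  }, character(1))
  tibble::tibble(group = names(g)[ord], mean = unname(means[ord]),
                 letters = lab)
}

#' Group comparison summary for one trial variable
#'
#' Bundles the ANOVA summary and the lettered means the way the trial
#' tables present them.
#'
#' @inheritParams tukey_letters
#' @param variable Optional variable label carried into the output.
#' @return List with `anova` (one-row tibble, plus `variable`) and `means`
#'   (lettered means, descending).
#' @export
group_comparison <- function(values, groups, variable = NA_character_,
                             alpha = 0.05) {
  an <- one_way_anova(values, groups)
  an <- tibble::add_column(an, variable = variable, .before = 1)
  lt <- tukey_letters(values, groups, alpha)
  # letters only meaningful when the overall F is significant
  list(anova = an, means = lt, alpha = alpha)
}
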