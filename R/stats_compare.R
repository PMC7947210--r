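# Kit-comparison statistical decision cascade ---------------------------

#' Significance tier labels
#'
#' Maps p-values to the conventional reporting tiers `***` (< 0.001),
#' `**` (< 0.01), `*` (< 0.05), `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Choose the omnibus test and post-hoc for a kit comparison
#'
#' The decision cascade used to compare conversion kits on one metric:
#' Shapiro-Wilk normality per group, then Levene's test (mean-centred) for
#' variance homogeneity across groups.
#' \itemize{
#'   \item any group non-normal: Kruskal-Wallis omnibus with
#'     Bonferroni-corrected pairwise Wilcoxon post-hocs;
#'   \item normal but unequal variances: Welch's one-way ANOVA with
#'     Games-Howell post-hocs;
#'   \item normal and equal variances: one-way ANOVA with Tukey HSD.
#' }
#' The normality gate fails if any single group fails (conservative choice).
#'
#' @param values Numeric metric values.
#' @param group Kit labels, same length as `values`.
#' @param alpha Significance level of the two gate tests (default 0.05).
#' @return Object of class `comparison_plan`: `normality_ok`, `variance_ok`,
#'   `omnibus` (`"KRUSKAL_WALLIS"`, `"WELCH_ANOVA"` or `"ONEWAY_ANOVA"`),
#'   `posthoc` (`"BONFERRONI_PAIRWISE"`, `"GAMES_HOWELL"` or `"TUKEY_HSD"`),
#'   `alpha`, plus the per-group Shapiro table and the Levene p-value.
#' @export
plan_comparison <- function(values, group, alpha = 0.05) {
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  keep <- is.finite(values)
  values <- values[keep]; group <- group[keep]
  groups <- split(values, group)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  small <- names(groups)[lengths(groups) < 3]
  if (length(small) > 0) {
    stop("insufficient data (< 3 values) in group(s): ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  shapiro <- dplyr::bind_rows(lapply(names(groups), function(g) {
    x <- groups[[g]]
    p <- if (var(x) == 0) 0 else shapiro.test(x)$p.value
    tibble::tibble(group = g, n = length(x), shapiro_p = p)
  }))
  normality_ok <- all(shapiro$shapiro_p >= alpha)
  lev <- car::leveneTest(values ~ factor(group), center = mean)
  levene_p <- lev[["Pr(>F)"]][1]
  variance_ok <- levene_p >= alpha
  if (!normality_ok) {
    omnibus <- "KRUSKAL_WALLIS"; posthoc <- "BONFERRONI_PAIRWISE"
  } else if (!variance_ok) {
    omnibus <- "WELCH_ANOVA"; posthoc <- "GAMES_HOWELL"
  } else {
    omnibus <- "ONEWAY_ANOVA"; posthoc <- "TUKEY_HSD"
  }
  structure(list(normality_ok = normality_ok, variance_ok = variance_ok,
                 omnibus = omnibus, posthoc = posthoc, alpha = alpha,
                 shapiro = shapiro, levene_p = levene_p),
            class = "comparison_plan")
}

#' @export
print.comparison_plan <- function(x, ...) {
  cat(sprintf(
    "<comparison_plan> normality %s, equal variance %s -> %s + %s\n",
    if (x$normality_ok) "ok" else "FAIL",
    if (x$variance_ok) "ok" else "FAIL", x$omnibus, x$posthoc))
  invisible(x)
}

#' Games-Howell post-hoc test
#'
#' All pairwise comparisons under unequal variances and unequal group sizes:
#' the studentized-range statistic `q = |m_i - m_j| / sqrt((v_i/n_i +
#' v_j/n_j)/2)` referred to the Tukey distribution with Welch-Satterthwaite
#' degrees of freedom per pair and the number of groups as the range
#' parameter.
#'
#' @inheritParams plan_comparison
#' @return Tibble: `group1`, `group2`, `diff`, `se`, `statistic` (q), `df`,
#'   `p` (already familywise by construction), `tier`.
#' @export
games_howell <- function(values, group) {
  group <- as.character(group)
  groups <- split(values, group)
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  n <- vapply(groups, length, numeric(1))
  pairs <- utils::combn(names(groups), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se2 <- v[a] / n[a] + v[b] / n[b]
    se <- sqrt(se2 / 2)
    df <- se2^2 / ((v[a] / n[a])^2 / (n[a] - 1) + (v[b] / n[b])^2 / (n[b] - 1))
    q <- abs(m[a] - m[b]) / se
    p <- if (se == 0) 1 else stats::ptukey(q, nmeans = k, df = df,
                                           lower.tail = FALSE)
    tibble::tibble(group1 = a, group2 = b, diff = unname(m[a] - m[b]),
                   se = unname(se), statistic = unname(q), df = unname(df),
                   p = unname(p))
  })
  out <- dplyr::bind_rows(rows)
  out$tier <- significance_tier(out$p)
  out
}

#' Run the planned omnibus test and post-hoc comparisons
#'
#' Executes the omnibus test and matching post-hoc selected by
#' [plan_comparison()] (or a plan supplied explicitly) and reports the
#' pairwise table with adjusted p-values and significance tiers.
#'
#' @inheritParams plan_comparison
#' @param plan A `comparison_plan`; fitted from the data when `NULL`.
#' @return Object of class `comparison_result`: `plan`,
#'   `omnibus_statistic`, `omnibus_p`, `pairwise` tibble (`group1`,
#'   `group2`, `p` adjusted, `tier`).
#' @export
run_comparison <- function(values, group, plan = NULL, alpha = 0.05) {
  group <- as.character(group)
  keep <- is.finite(values)
  values <- values[keep]; group <- group[keep]
  if (is.null(plan)) plan <- plan_comparison(values, group, alpha = alpha)
  fg <- factor(group)
  if (var(values) == 0) {
    # degenerate data: no spread at all, nothing can be significant
    pairs <- utils::combn(levels(fg), 2)
    pairwise <- tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                               p = 1, tier = "ns")
    return(structure(list(plan = plan, omnibus_statistic = 0, omnibus_p = 1,
                          pairwise = pairwise),
                     class = "comparison_result"))
  }
  if (plan$omnibus == "KRUSKAL_WALLIS") {
    om <- kruskal.test(values, fg)
    stat <- unname(om$statistic); p <- om$p.value
    pw <- suppressWarnings(
      pairwise.wilcox.test(values, fg, p.adjust.method = "bonferroni",
                           exact = FALSE))
    tab <- as.data.frame(as.table(pw$p.value))
    tab <- tab[!is.na(tab$Freq), ]
    pairwise <- tibble::tibble(group1 = as.character(tab$Var2),
                               group2 = as.character(tab$Var1),
                               p = tab$Freq)
  } else if (plan$omnibus == "WELCH_ANOVA") {
    om <- oneway.test(values ~ fg, var.equal = FALSE)
    stat <- unname(om$statistic); p <- om$p.value
    gh <- games_howell(values, group)
    pairwise <- tibble::tibble(group1 = gh$group1, group2 = gh$group2,
                               p = gh$p)
  } else {
    fit <- aov(values ~ fg)
    s <- summary(fit)[[1]]
    stat <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
    tk <- TukeyHSD(fit)$fg
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble::tibble(
      group1 = vapply(nm, `[`, character(1), 1),
      group2 = vapply(nm, `[`, character(1), 2),
      p = unname(tk[, "p adj"]))
  }
  pairwise$tier <- significance_tier(pairwise$p)
  structure(list(plan = plan, omnibus_statistic = stat, omnibus_p = p,
                 pairwise = pairwise),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  print(x$plan)
  cat(sprintf("  omnibus statistic = %.4g, p = %.4g\n",
              x$omnibus_statistic, x$omnibus_p))
  sig <- x$pairwise[x$pairwise$tier != "ns", ]
  cat(sprintf("  %d/%d pairwise comparison(s) significant\n",
              nrow(sig), nrow(x$pairwise)))
  invisible(x)
}

#' Compare kits on every metric of a results table
#'
#' Runs the full plan-then-test cascade per metric column of a per-sample
#' results table (as produced by [evaluate_run()]).
#'
#' @param results Tibble with `kit` and the metric columns.
#' @param metrics Metric column names to compare.
#' @param alpha Gate significance level.
#' @return Named list of `comparison_result`, one per metric.
#' @export
compare_kits <- function(results,
                         metrics = c("conversion_efficiency",
                                     "degradation_level", "recovery"),
                         alpha = 0.05) {
  if (length(unique(results$kit)) < 2) {
    stop("need >= 2 kits to compare", call. = FALSE)
  }
  out <- lapply(metrics, function(mname) {
    run_comparison(results[[mname]], results$kit, alpha = alpha)
  })
  setNames(out, metrics)
}
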