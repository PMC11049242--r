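#' Two-group comparison with distribution-guided test selection
#'
#' Each group is checked for normality (Shapiro-Wilk); when both pass, the
#' groups are compared with Student's unpaired t-test, using Welch's
#' correction when a Brown-Forsythe (Levene, median-centred) test rejects
#' equality of variances; otherwise the Mann-Whitney (Wilcoxon rank-sum)
#' test is used.
#'
#' @param values_a,values_b numeric samples (>= 3 each).
#' @param normality_alpha alpha for the Shapiro-Wilk decision.
#' @param var_alpha alpha for the variance-equality decision.
#' @param labels group labels, length 2.
#' @param metric optional metric name carried into the result.
#' @return A `group_comparison`: list with `metric`, `groups` (n, mean,
#'   sem per group), `test`, `statistic`, `p_value`, and the selection
#'   diagnostics (`normal_a`, `normal_b`, `equal_var`).
#' @export
compare_two_groups <- function(values_a, values_b, normality_alpha = 0.05,
                               var_alpha = 0.05,
                               labels = c("A", "B"), metric = NULL) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("need at least 3 values per group")
  shapiro_ok <- function(x) {
    if (length(unique(x)) < 3) return(FALSE)
    shapiro.test(x)$p.value > normality_alpha
  }
  normal_a <- shapiro_ok(values_a)
  normal_b <- shapiro_ok(values_b)
  if (normal_a && normal_b) {
    g <- factor(rep(labels, c(length(values_a), length(values_b))))
    lev <- car::leveneTest(c(values_a, values_b) ~ g, center = median)
    equal_var <- lev[["Pr(>F)"]][1] > var_alpha
    ht <- t.test(values_a, values_b, var.equal = equal_var)
    test <- if (equal_var) "Student t" else "Welch t"
  } else {
    equal_var <- NA
    ht <- suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE))
    test <- "Mann-Whitney"
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  structure(list(
    metric = metric,
    groups = data.frame(group = labels,
                        n = c(length(values_a), length(values_b)),
                        mean = c(mean(values_a), mean(values_b)),
                        sem = c(sem(values_a), sem(values_b))),
    test = test, statistic = unname(ht$statistic),
    p_value = ht$p.value,
    normal_a = normal_a, normal_b = normal_b, equal_var = equal_var),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison", if (!is.null(x$metric)) paste0("[", x$metric, "]"),
      "\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}

#' Two-way factorial comparison with Tukey post-hoc contrasts
#'
#' Fits a two-way ANOVA with interaction on a larva-level metric table and
#' returns the ANOVA effects plus the full Tukey HSD pairwise table for the
#' factor-combination cells.
#'
#' @param table data.frame holding the response and two factors.
#' @param response response column name.
#' @param factor_a,factor_b factor column names (>= 2 levels each, >= 3
#'   observations per design cell, no empty cell).
#' @return A `factorial_comparison`: list with `anova` (term, df, F,
#'   p_value) and `posthoc` (Tukey pairwise table for `factor_a:factor_b`).
#' @export
compare_factorial <- function(table, response, factor_a, factor_b) {
  stopifnot(all(c(response, factor_a, factor_b) %in% names(table)))
  fa <- factor(table[[factor_a]])
  fb <- factor(table[[factor_b]])
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors need at least 2 levels")
  cell_n <- table(fa, fb)
  if (any(cell_n == 0)) stop("empty design cell(s): ",
                             paste(which(cell_n == 0), collapse = ", "))
  if (any(cell_n < 3)) stop("need at least 3 observations per design cell")
  d <- data.frame(y = table[[response]], A = fa, B = fb)
  fit <- aov(y ~ A * B, data = d)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  anova_tab <- data.frame(term = c(factor_a, factor_b,
                                   paste(factor_a, factor_b, sep = ":"),
                                   "Residuals")[seq_along(terms)],
                          df = an$Df, F = an$`F value`,
                          p_value = an$`Pr(>F)`)
  tk <- TukeyHSD(fit, "A:B")[["A:B"]]
  posthoc <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(anova = anova_tab, posthoc = posthoc,
                 response = response),
            class = "factorial_comparison")
}

#' @export
print.factorial_comparison <- function(x, ...) {
  cat("factorial_comparison on", x$response, "\n")
  print(x$anova, row.names = FALSE)
  cat("Tukey HSD (first contrasts):\n")
  print(head(x$posthoc, 4), row.names = FALSE)
  invisible(x)
}
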