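# Grouped comparative statistics: classical one-way ANOVA,
# Kruskal-Wallis, pairwise Welch t-tests, Pearson correlation with
# simple regression, and Spearman rank correlation, each returned as a
# one-row (or per-pair) tidy report so the full comparison table can be
# assembled by row-binding.

stat_report <- function(test, parameter_x, parameter_y, statistic = NA_real_,
                        df = NA_real_, df2 = NA_real_, p_value = NA_real_,
                        r_squared = NA_real_, f_value = NA_real_,
                        correlation = NA_real_) {
  tibble::tibble(
    test = test, parameter_x = parameter_x, parameter_y = parameter_y,
    statistic = statistic, df = df, df2 = df2, p_value = p_value,
    r_squared = r_squared, f_value = f_value, correlation = correlation,
    significant = !is.na(p_value) & p_value < 0.05
  )
}

pull2 <- function(data, col) {
  if (is.null(data)) col else dplyr::pull(data, {{ col }})
}

#' One-way analysis of variance across groups
#'
#' Classical one-way ANOVA of a parameter over group labels:
#' `F = MS_between / MS_within` on `(k - 1, n - k)` degrees of freedom,
#' with `R^2 = SS_between / SS_total`.
#'
#' @param data Data frame, or `NULL` to pass bare vectors.
#' @param value,group Columns (tidy-eval) or vectors: the parameter
#'   values and group labels.
#' @param parameter Label used in the report.
#' @return One-row tibble: `test`, `parameter_x`, `parameter_y`,
#'   `statistic` (= F), `df` (residual), `df2` (between), `p_value`,
#'   `r_squared`, `f_value`, `significant`.
#' @export
group_anova <- function(data = NULL, value, group, parameter = "value") {
  v <- pull2(data, {{ value }})
  g <- factor(pull2(data, {{ group }}))
  stopifnot(length(v) == length(g), nlevels(g) >= 2,
            length(v) > nlevels(g))
  if (stats::var(v) == 0) {
    # all values identical: no variance to partition
    return(stat_report("anova", "groups", parameter, statistic = 0,
                       df = length(v) - nlevels(g), df2 = nlevels(g) - 1,
                       p_value = 1, r_squared = 0, f_value = 0))
  }
  fit <- stats::aov(v ~ g)
  sm <- summary(fit)[[1]]
  ssb <- sm$`Sum Sq`[1]; ssw <- sm$`Sum Sq`[2]
  f <- sm$`F value`[1]
  stat_report("anova", "groups", parameter,
              statistic = f, df = sm$Df[2], df2 = sm$Df[1],
              p_value = sm$`Pr(>F)`[1],
              r_squared = ssb / (ssb + ssw), f_value = f)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected Kruskal-Wallis H with `k - 1` degrees of freedom and a
#' chi-squared p-value; invariant under strictly increasing transforms
#' of the values.
#'
#' @inheritParams group_anova
#' @return One-row tibble (`statistic` = H, `df` = k - 1).
#' @export
group_kruskal <- function(data = NULL, value, group, parameter = "value") {
  v <- pull2(data, {{ value }})
  g <- factor(pull2(data, {{ group }}))
  stopifnot(length(v) == length(g), nlevels(g) >= 2)
  if (length(unique(v)) == 1) {
    return(stat_report("kruskal_wallis", "groups", parameter,
                       statistic = 0, df = nlevels(g) - 1, p_value = 1))
  }
  kt <- stats::kruskal.test(v, g)
  stat_report("kruskal_wallis", "groups", parameter,
              statistic = unname(kt$statistic), df = unname(kt$parameter),
              p_value = kt$p.value)
}

#' Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite
#' fractional degrees of freedom and a two-sided p-value.
#'
#' @param a,b Numeric samples (each of length at least 2).
#' @param label_a,label_b Labels used in the report.
#' @param parameter Parameter label for the report.
#' @return One-row tibble (`statistic` = t, `df` fractional).
#' @export
welch_t_test <- function(a, b, label_a = "a", label_b = "b",
                         parameter = "value") {
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 values")
  }
  pair <- paste(label_a, "vs", label_b)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(stat_report("welch_t", parameter, pair, statistic = 0,
                         df = length(a) + length(b) - 2, p_value = 1))
    }
    stop("zero variance in both samples with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  stat_report("welch_t", parameter, pair,
              statistic = unname(tt$statistic),
              df = unname(tt$parameter), p_value = tt$p.value)
}

#' All pairwise Welch t-tests of a parameter between groups
#'
#' @inheritParams group_anova
#' @return Tibble with one row per unordered group pair (`C(k, 2)`
#'   rows).
#' @export
welch_pairwise <- function(data = NULL, value, group, parameter = "value") {
  v <- pull2(data, {{ value }})
  g <- factor(pull2(data, {{ group }}))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    welch_t_test(v[g == pr[1]], v[g == pr[2]],
                 label_a = paste("group", pr[1]),
                 label_b = paste("group", pr[2]),
                 parameter = parameter)
  })
}

#' Pearson correlation with simple linear regression
#'
#' Pearson's r between two parameters together with the ordinary
#' least-squares regression of y on x: `R^2 = r^2`, regression F on
#' `(1, n - 2)` degrees of freedom, two-sided p-value.
#'
#' @param data Data frame or `NULL`.
#' @param x,y Columns (tidy-eval) or numeric vectors.
#' @param label_x,label_y Report labels (default: the column names).
#' @return One-row tibble (`correlation` = r, `statistic` = t,
#'   `df` = n - 2, `r_squared`, `f_value`).
#' @export
pearson_regression <- function(data = NULL, x, y, label_x = NULL,
                               label_y = NULL) {
  xv <- pull2(data, {{ x }})
  yv <- pull2(data, {{ y }})
  label_x <- label_x %||% rlang::as_label(rlang::enquo(x))
  label_y <- label_y %||% rlang::as_label(rlang::enquo(y))
  stopifnot(length(xv) == length(yv), length(xv) >= 3)
  if (stats::var(xv) == 0) stop("x is constant; regression undefined")
  if (stats::var(yv) == 0) stop("y is constant; correlation undefined")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  fit <- summary(stats::lm(yv ~ xv))
  stat_report("pearson_regression", label_x, label_y,
              statistic = unname(ct$statistic), df = unname(ct$parameter),
              p_value = ct$p.value, r_squared = fit$r.squared,
              f_value = unname(fit$fstatistic[1]),
              correlation = unname(ct$estimate))
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks; the two-sided p-value uses
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @inheritParams pearson_regression
#' @return One-row tibble (`correlation` = rho).
#' @export
spearman_rho <- function(data = NULL, x, y, label_x = NULL, label_y = NULL) {
  xv <- pull2(data, {{ x }})
  yv <- pull2(data, {{ y }})
  label_x <- label_x %||% rlang::as_label(rlang::enquo(x))
  label_y <- label_y %||% rlang::as_label(rlang::enquo(y))
  stopifnot(length(xv) == length(yv), length(xv) >= 3)
  if (stats::var(xv) == 0 || stats::var(yv) == 0) {
    stop("constant input; rank correlation undefined")
  }
  rho <- stats::cor(rank(xv), rank(yv))
  n <- length(xv)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  stat_report("spearman", label_x, label_y,
              statistic = if (abs(rho) >= 1) Inf else tstat,
              df = n - 2, p_value = p, correlation = rho)
}

#' Per-group means with confidence intervals
#'
#' Group mean and t-based confidence interval
#' (`mean +/- t_{n-1, (1+level)/2} * s / sqrt(n)`) for one parameter,
#' the summary behind group-mean bar charts with 95% error bars.
#' Singleton groups get an undefined (NA) interval and a flag.
#'
#' @inheritParams group_anova
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per group: `group`, `n`, `mean`,
#'   `ci_low`, `ci_high`, `flag`.
#' @export
group_mean_ci <- function(data = NULL, value, group, level = 0.95,
                          parameter = "value") {
  v <- pull2(data, {{ value }})
  g <- factor(pull2(data, {{ group }}))
  purrr::map_dfr(levels(g), function(lv) {
    x <- v[g == lv]
    n <- length(x)
    m <- mean(x)
    if (n < 2) {
      return(tibble::tibble(parameter = parameter, group = lv, n = n,
                            mean = m, ci_low = NA_real_, ci_high = NA_real_,
                            flag = "singleton group: CI undefined"))
    }
    half <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
    tibble::tibble(parameter = parameter, group = lv, n = n, mean = m,
                   ci_low = m - half, ci_high = m + half, flag = "")
  })
}

# the four parameters compared across phylogenetic groups
GROUP_PARAMETERS <- c("biomass_yield", "ethanol_yield", "glc_cons_rate",
                      "growth_rate")

#' Run the full grouped comparison over an analysis set
#'
#' Reproduces the complete comparative-statistics table over the
#' 37-strain analysis set: Pearson correlation + regression and Spearman
#' rank correlation for (glucose consumption rate, biomass yield),
#' (glucose consumption rate, growth rate) and (ethanol yield, growth
#' rate); one-way ANOVA and Kruskal-Wallis of the four parameters
#' (biomass yield, ethanol yield, glucose consumption rate, growth rate)
#' across the four phylogenetic groups; and all six pairwise Welch
#' t-tests per parameter (38 rows in total).
#'
#' @param analysis_set Tibble from [build_analysis_set()] (columns
#'   `group` plus the four parameters).
#' @return Tibble of tidy test reports (38 rows).
#' @seealso [compare_group_stats()], [published_group_stats()]
#' @export
#' @examples
#' stats_tbl <- run_group_stats(build_analysis_set(load_reference_table()))
run_group_stats <- function(analysis_set) {
  stopifnot(all(c("group", GROUP_PARAMETERS) %in% names(analysis_set)))
  cor_pairs <- list(
    c("glc_cons_rate", "biomass_yield"),
    c("glc_cons_rate", "growth_rate"),
    c("ethanol_yield", "growth_rate")
  )
  pearson <- purrr::map_dfr(cor_pairs, function(pr) {
    pearson_regression(analysis_set, !!rlang::sym(pr[1]),
                       !!rlang::sym(pr[2]),
                       label_x = pr[1], label_y = pr[2])
  })
  spearman <- purrr::map_dfr(cor_pairs, function(pr) {
    spearman_rho(analysis_set, !!rlang::sym(pr[1]), !!rlang::sym(pr[2]),
                 label_x = pr[1], label_y = pr[2])
  })
  anova <- purrr::map_dfr(GROUP_PARAMETERS, function(p) {
    group_anova(analysis_set, !!rlang::sym(p), .data$group, parameter = p)
  })
  kw <- purrr::map_dfr(GROUP_PARAMETERS, function(p) {
    group_kruskal(analysis_set, !!rlang::sym(p), .data$group, parameter = p)
  })
  welch <- purrr::map_dfr(GROUP_PARAMETERS, function(p) {
    welch_pairwise(analysis_set, !!rlang::sym(p), .data$group,
                   parameter = p)
  })
  dplyr::bind_rows(pearson, spearman, anova, kw, welch)
}

#' Published comparative-statistics table
#'
#' The printed reference values of the grouped statistical analysis
#' (p-values, degrees of freedom, R-squared, F statistics and
#' correlations), packaged for per-cell comparison against a fresh
#' reproduction.
#'
#' @return Tibble in the same key layout as [run_group_stats()] output.
#' @export
published_group_stats <- function() {
  path <- system.file("extdata", "published_group_stats.tsv",
                      package = "crabtree", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Compare a reproduced statistics table against the published values
#'
#' Joins a [run_group_stats()] result with the packaged published table
#' and reports per-cell deviations (absolute and relative) for every
#' printed statistic.
#'
#' @param computed Tibble from [run_group_stats()].
#' @param published Reference tibble; defaults to
#'   [published_group_stats()].
#' @return Tibble with one row per (test, parameter pair, quantity):
#'   `computed`, `published`, `deviation`, `rel_deviation`.
#' @export
compare_group_stats <- function(computed,
                                published = published_group_stats()) {
  joined <- dplyr::inner_join(
    computed, published,
    by = c("test", "parameter_x", "parameter_y"),
    suffix = c("_computed", "_published")
  )
  quantities <- c("p_value", "df", "r_squared", "f_value", "correlation")
  purrr::map_dfr(quantities, function(q) {
    pub <- joined[[paste0(q, "_published")]]
    comp <- joined[[paste0(q, "_computed")]]
    keep <- !is.na(pub)
    tibble::tibble(
      test = joined$test[keep],
      parameter_x = joined$parameter_x[keep],
      parameter_y = joined$parameter_y[keep],
      quantity = q,
      computed = comp[keep],
      published = pub[keep],
      deviation = comp[keep] - pub[keep],
      rel_deviation = (comp[keep] - pub[keep]) / abs(pub[keep])
    )
  }) %>%
    dplyr::arrange(.data$test, .data$parameter_x, .data$parameter_y)
}
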