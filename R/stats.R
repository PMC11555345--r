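#' Group comparison with normality and variance pre-tests
#'
#' Runs Shapiro-Wilk normality per group, then either the
#' `dunnett_scheme` (Bartlett's homogeneity test followed by Dunnett's
#' many-to-one comparison against the control group, via multivariate-t
#' critical values) or the `ttest_scheme` (F-test of equal variances
#' followed by a two-sample, two-tailed Student's t-test with pooled
#' variance). Significance is declared at p < 0.05.
#'
#' @param data Data frame with the value and group columns.
#' @param value,group Column names (strings) of the measurement and the
#'   group factor.
#' @param design `"dunnett_scheme"` or `"ttest_scheme"` (the latter
#'   requires exactly two groups).
#' @param control Name of the control group (default: first level).
#' @param alpha Significance level (0.05).
#' @return Object of class `group_comparison`; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' d <- data.frame(v = c(1:5, 3:7), g = rep(c("a", "b"), each = 5))
#' tidy(group_comparison(d, "v", "g", design = "ttest_scheme"))
#' @export
group_comparison <- function(data, value = "value", group = "group",
                             design = c("dunnett_scheme", "ttest_scheme"),
                             control = NULL, alpha = 0.05) {
  design <- match.arg(design)
  v <- data[[value]]
  g <- factor(data[[group]])
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  ns <- table(g)
  if (any(ns < 3)) {
    stop("group_comparison: every group needs n >= 3 (got ",
         paste(ns, collapse = ", "), ")")
  }
  if (is.null(control)) control <- levels(g)[1]
  g <- stats::relevel(g, ref = control)
  shapiro <- lapply(levels(g), function(lv) stats::shapiro.test(v[g == lv]))
  names(shapiro) <- levels(g)
  if (design == "ttest_scheme") {
    if (nlevels(g) != 2) {
      stop("group_comparison: ttest_scheme requires exactly two groups")
    }
    vartest <- stats::var.test(v[g == levels(g)[2]], v[g == levels(g)[1]])
    loc <- stats::t.test(v[g == levels(g)[2]], v[g == levels(g)[1]],
                         var.equal = TRUE)
    location <- tibble::tibble(
      comparison = paste(levels(g)[2], "-", levels(g)[1]),
      estimate = mean(v[g == levels(g)[2]]) - mean(v[g == levels(g)[1]]),
      statistic = unname(loc$statistic),
      p_value = loc$p.value)
  } else {
    vartest <- stats::bartlett.test(v, g)
    df <- data.frame(v = v, g = g)
    fit <- stats::aov(v ~ g, data = df)
    dn <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(dn)
    location <- tibble::tibble(
      comparison = rownames(sm$linfct),
      estimate = as.numeric(sm$test$coefficients),
      statistic = as.numeric(sm$test$tstat),
      p_value = as.numeric(sm$test$pvalues))
  }
  structure(list(design = design, control = control, alpha = alpha,
                 groups = levels(g), n = as.integer(ns[levels(g)]),
                 means = tapply(v, g, mean),
                 shapiro = shapiro, variance_test = vartest,
                 location = location,
                 significant = location$p_value < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s, control '%s', groups: %s\n", x$design,
              x$control, paste(sprintf("%s (n=%d)", x$groups, x$n),
                               collapse = ", ")))
  vt <- x$variance_test
  cat(sprintf("  variance test (%s): p = %.4g\n", vt$method, vt$p.value))
  loc <- x$location
  for (i in seq_len(nrow(loc))) {
    cat(sprintf("  %s: diff = %.4g, p = %.4g%s\n", loc$comparison[i],
                loc$estimate[i], loc$p_value[i],
                if (loc$p_value[i] < x$alpha) " *" else ""))
  }
  invisible(x)
}

#' Regression of nucleolar beta-sheet ratio on nucleolus size
#'
#' Ordinary least squares of the largest-nucleolus mean ratio on the
#' largest-nucleolus cross-sectional size (pixel count), with the
#' two-sided p-value of the slope. An increasing trend links nucleolar
#' enlargement to beta-sheet accumulation in mononuclear cells.
#'
#' @param records Tibble with columns `largest_nucleolus_size` and
#'   `largest_nucleolus_mean_ratio` (e.g. [extract_cell_records()]).
#' @param size,ratio Alternative column names.
#' @return Object of class `size_ratio_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n` and the underlying `lm`
#'   fit. See [tidy()] / [glance()].
#' @export
size_ratio_regression <- function(records,
                                  size = "largest_nucleolus_size",
                                  ratio = "largest_nucleolus_mean_ratio") {
  x <- records[[size]]
  y <- records[[ratio]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("size_ratio_regression: need >= 3 finite records")
  if (stats::var(x) == 0) stop("size_ratio_regression: zero variance in nucleolus size")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # collinear inputs are legitimate
  p <- if (nrow(sm$coefficients) > 1 && !is.na(sm$coefficients[2, 4])) {
    sm$coefficients[2, 4]
  } else 0  # exact collinear fit: slope p-value degenerates to 0
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared, p_value = p,
                 n = length(x), fit = fit),
            class = "size_ratio_regression")
}

#' @export
print.size_ratio_regression <- function(x, ...) {
  cat(sprintf("<size_ratio_regression> n = %d: slope %.4g, intercept %.4g, R2 %.3f, p = %.4g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}
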