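#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an amide fit
#'
#' @param x An `amide_fit` from [fit_amide_band()].
#' @param ... Unused.
#' @return One row per component: `role`, `center`, `fwhm`,
#'   `amplitude`, `area`.
#' @export
tidy.amide_fit <- function(x, ...) x$components

#' @rdname tidy.amide_fit
#' @return For `glance`: one row with `rss`, `converged`, `mode`,
#'   `ratio` (g2/(g1+g2)) and `subtraction` (g2-g1).
#' @export
glance.amide_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, mode = x$mode,
                 ratio = unname(x$g[3] / (x$g[2] + x$g[3])),
                 subtraction = unname(x$g[3] - x$g[2]))
}

#' Tidy per-pixel amide fit maps
#'
#' @param x An `amide_fit_maps` from [fit_cube()].
#' @param ... Unused.
#' @return One row per pixel: `y`, `x`, `g0`, `g1`, `g2`, `rss`,
#'   `converged`.
#' @export
tidy.amide_fit_maps <- function(x, ...) {
  d <- dim(x$g0)
  tibble::tibble(y = rep(seq_len(d[1]), d[2]),
                 x = rep(seq_len(d[2]), each = d[1]),
                 g0 = as.vector(x$g0), g1 = as.vector(x$g1),
                 g2 = as.vector(x$g2), rss = as.vector(x$rss),
                 converged = as.vector(x$converged))
}

#' Tidy indicator maps
#'
#' @param x An `indicator_maps` object.
#' @param ... Unused.
#' @return One row per pixel: `y`, `x`, `ratio`, `subtraction`, `valid`.
#' @export
tidy.indicator_maps <- function(x, ...) {
  d <- dim(x$ratio)
  tibble::tibble(y = rep(seq_len(d[1]), d[2]),
                 x = rep(seq_len(d[2]), each = d[1]),
                 ratio = as.vector(x$ratio),
                 subtraction = as.vector(x$subtraction),
                 valid = as.vector(x$valid))
}

#' Tidy a group comparison
#'
#' @param x A [group_comparison()] result.
#' @param ... Unused.
#' @return One row per test: the per-group Shapiro-Wilk tests, the
#'   variance test, and the location test(s), with `test`,
#'   `comparison`, `statistic`, `p_value`, `significant`.
#' @export
tidy.group_comparison <- function(x, ...) {
  sw <- purrr::imap(x$shapiro, function(s, g) {
    tibble::tibble(test = "shapiro_wilk", comparison = g,
                   statistic = unname(s$statistic), p_value = s$p.value)
  })
  vt <- tibble::tibble(
    test = if (x$design == "dunnett_scheme") "bartlett" else "f_test",
    comparison = paste(x$groups, collapse = " | "),
    statistic = unname(x$variance_test$statistic),
    p_value = x$variance_test$p.value)
  loc <- dplyr::mutate(
    x$location,
    test = if (x$design == "dunnett_scheme") "dunnett" else "student_t",
    .before = 1)
  out <- dplyr::bind_rows(dplyr::bind_rows(sw), vt,
                          loc[c("test", "comparison", "statistic", "p_value")])
  dplyr::mutate(out, significant = .data$p_value < x$alpha)
}

#' @rdname tidy.group_comparison
#' @return For `glance`: one row with the design, group sizes and the
#'   smallest location-test p-value.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(design = x$design, n_groups = length(x$groups),
                 n_total = sum(x$n),
                 variance_p = x$variance_test$p.value,
                 location_p = min(x$location$p_value),
                 significant = any(x$significant))
}

#' Tidy the size-ratio regression
#'
#' @param x A [size_ratio_regression()] result.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.size_ratio_regression <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "size"),
                 estimate = unname(cf[, 1]), std_error = unname(cf[, 2]),
                 statistic = unname(cf[, 3]), p_value = unname(cf[, 4]))
}

#' @rdname tidy.size_ratio_regression
#' @return For `glance`: one row with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
glance.size_ratio_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p_value = x$p_value, n = x$n)
}
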