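#' Convert an area from square kilometres to square metres
#'
#' All internal computation uses SI units (metres, square metres); study areas
#' are usually reported in km^2 and must be converted before estimation.
#'
#' @param area_km2 Area in square kilometres. Must be positive.
#' @return Area in square metres (`area_km2 * 1e6`).
#' @examples
#' km2_to_m2(2000)
#' @export
km2_to_m2 <- function(area_km2) {
  if (!is.numeric(area_km2) || any(!is.finite(area_km2)) || any(area_km2 <= 0)) {
    gp_abort("`area_km2` must be a positive finite number.")
  }
  area_km2 * 1e6
}

#' Strip-transect abundance estimation (King method, Leopold modification)
#'
#' Estimates total population size from strip-transect counts as
#' \deqn{\hat N = \frac{A\,n}{2\,y\,x}}
#' where `A` is the study area (m^2), `n` the number of animals counted, `x`
#' the total transect distance (m) and `y` the mean perpendicular detection
#' distance (m); the factor 2 accounts for the band on each side of the
#' transect. The variance is
#' \deqn{S^2 = \frac{n(1-p)}{p^2} + \frac{n}{n+2}, \qquad p = n/\hat N,}
#' i.e. the classical binomial-sampling variance of \eqn{n/p} plus a
#' small-sample correction, and 95% confidence bounds use the normal
#' approximation \eqn{\hat N \pm 1.96\sqrt{S^2}}, floored at zero.
#'
#' A zero count is a defined degenerate case (`N_hat = 0`, `S2 = 0`,
#' degenerate interval), not an error, so that simulated surveys with empty
#' strips do not abort a pipeline run.
#'
#' @param surveys Data frame with one row per survey year and columns
#'   `year`, `n` (animals counted, non-negative), `x` (total transect
#'   distance, metres), `y` (mean perpendicular distance, metres) and `area`
#'   (total study area, square metres; see [km2_to_m2()]).
#' @param conf_z Normal quantile for the confidence bounds (default 1.96 for
#'   95%).
#' @return A tibble with columns `year`, `N_hat`, `p` (sampled fraction
#'   `n / N_hat`, `NA` when `N_hat` is 0), `S2`, `ci_low`, `ci_high`.
#' @examples
#' estimate_abundance(
#'   data.frame(year = 2000, n = 100, x = 1e5, y = 250, area = km2_to_m2(2000))
#' )
#' @export
estimate_abundance <- function(surveys, conf_z = 1.96) {
  surveys <- as_tibble(surveys)
  assert_columns(surveys, c("year", "n", "x", "y", "area"), "survey table")
  with(surveys, {
    if (any(!is.finite(n)) || any(n < 0)) {
      gp_abort("`n` must be a non-negative count.")
    }
    if (any(!is.finite(x)) || any(x <= 0) ||
        any(!is.finite(y)) || any(y <= 0) ||
        any(!is.finite(area)) || any(area <= 0)) {
      gp_abort("`x`, `y` and `area` must be positive (metres / square metres).")
    }
    if (any(area <= 2 * y * x)) {
      gp_abort("strip area 2*y*x must be smaller than the study area `area`.")
    }
  })

  surveys %>%
    mutate(
      N_hat = .data$area * .data$n / (2 * .data$y * .data$x),
      p = dplyr::if_else(.data$N_hat > 0, .data$n / .data$N_hat, NA_real_),
      S2 = dplyr::if_else(
        .data$n > 0,
        .data$n * (1 - .data$p) / .data$p^2 + .data$n / (.data$n + 2),
        0
      ),
      ci_low = pmax(0, .data$N_hat - conf_z * sqrt(.data$S2)),
      ci_high = .data$N_hat + conf_z * sqrt(.data$S2)
    ) %>%
    select("year", "N_hat", "p", "S2", "ci_low", "ci_high")
}

#' Plot an abundance series with confidence bounds
#'
#' @param estimates Output of [estimate_abundance()].
#' @return A ggplot object: estimated abundance by year with the 95% interval
#'   as a ribbon.
#' @export
plot_abundance <- function(estimates) {
  assert_columns(estimates, c("year", "N_hat", "ci_low", "ci_high"))
  ggplot2::ggplot(estimates, ggplot2::aes(x = .data$year, y = .data$N_hat)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Year", y = "Estimated abundance (individuals)")
}
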