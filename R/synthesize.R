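#' Configuration for the synthetic population generator
#'
#' Defaults emulate the study system: a 36-year density-dependent trajectory
#' on a 2000 km^2 ranch, with the growth-rate model
#' \eqn{\lambda_t = a + b\ln N_t + c_P P_t + c_W W_t + \epsilon_t} on the
#' \eqn{\lambda}-vs-\eqn{\ln N} scale, annual precipitation around 300 mm
#' (SD 60), mean winter temperature around 2.2 degrees C (SD 1.5), a sheep
#' series piecewise-linear between sparse censuses at 11-23 animals/km^2, and
#' strip-transect surveys covering about 21% of the area (half-width 250 m
#' along 840 km of transects).
#'
#' @param years Series length (default 36).
#' @param a,b Density-dependence intercept and slope on the
#'   \eqn{\lambda} vs \eqn{\ln N} scale (defaults 1.6373 and -0.0552).
#' @param c_precip,c_temp Climate effect sizes on \eqn{\lambda} per mm and
#'   per degree C (default 0).
#' @param sigma SD of the \eqn{\lambda} process noise (default 0.05).
#' @param N0 Initial total abundance (default 15000).
#' @param area_km2 Study area (default 2000).
#' @param transect_x_m Total transect length per year, metres
#'   (default 840000).
#' @param strip_y_m Strip half-width, metres (default 250).
#' @param lambda_floor Truncation floor for \eqn{\lambda_t} (default 0.05) so
#'   noise can never produce a non-positive population.
#' @param precip_mean,precip_sd,temp_mean,temp_sd Climate generator moments.
#' @param sheep_census_points Number of sheep censuses to interpolate between
#'   (default 5).
#' @param sheep_density_range Range of sheep density at a census,
#'   animals/km^2 (default `c(11, 23)`).
#' @param start_year First calendar year of the series (default 1977).
#' @param seed RNG seed; every draw in [simulate_trajectory()] and
#'   [observe_transects()] flows from it.
#' @return A list of class `gp_sim_config`.
#' @export
sim_config <- function(years = 36L,
                       a = 1.6373, b = -0.0552,
                       c_precip = 0, c_temp = 0,
                       sigma = 0.05,
                       N0 = 15000,
                       area_km2 = 2000,
                       transect_x_m = 840000,
                       strip_y_m = 250,
                       lambda_floor = 0.05,
                       precip_mean = 300, precip_sd = 60,
                       temp_mean = 2.2, temp_sd = 1.5,
                       sheep_census_points = 5L,
                       sheep_density_range = c(11, 23),
                       start_year = 1977L,
                       seed = 1L) {
  stopifnot(years >= 3L, N0 > 0, sigma >= 0, area_km2 > 0,
            transect_x_m > 0, strip_y_m > 0, lambda_floor > 0,
            sheep_census_points >= 2L)
  area_m2 <- km2_to_m2(area_km2)
  if (2 * strip_y_m * transect_x_m >= area_m2) {
    gp_abort("strip area must cover less than 100% of the study area.")
  }
  structure(
    as.list(environment()),
    class = "gp_sim_config"
  )
}

#' Simulate a density-dependent age-structured trajectory
#'
#' Generates the full synthetic study: the true abundance and growth-rate
#' series under the \eqn{\lambda = a + b\ln N + c_P P + c_W W + \epsilon}
#' model (with \eqn{N_{t+1} = \lambda_t N_t}), a female age structure
#' maintained by a base projection matrix rescaled each year so its dominant
#' eigenvalue equals the realized \eqn{\lambda_t}, climate and sheep
#' covariate series, and strip-transect survey summaries from
#' [observe_transects()]. Fully reproducible under `cfg$seed`. If the
#' population collapses below 2 individuals the simulation stops early and
#' the result is flagged.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `gp_sim`: list with `truth` (tibble `year`, `N`,
#'   `lambda`, `newborn_f`, `juvenile_f`, `adult_f`; `lambda` is `NA` for the
#'   final year), `covariates` (tibble `year`, `precip`, `winter_temp`,
#'   `sheep`), `surveys` (tibble `year`, `n`, `x`, `y`, `area`), `collapsed`
#'   flag and `config`.
#' @export
simulate_trajectory <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "gp_sim_config"))
  withr::with_seed(cfg$seed, {
    yrs <- seq.int(cfg$start_year, length.out = cfg$years)

    precip <- pmax(0, rnorm(cfg$years, cfg$precip_mean, cfg$precip_sd))
    wtemp <- rnorm(cfg$years, cfg$temp_mean, cfg$temp_sd)

    # sheep: piecewise linear between censuses at random interior years
    k <- cfg$sheep_census_points
    census_years <- sort(c(
      yrs[1L], yrs[cfg$years],
      if (k > 2L) sample(yrs[-c(1L, cfg$years)], k - 2L)
    ))
    census_sheep <- runif(k, cfg$sheep_density_range[1L],
                          cfg$sheep_density_range[2L]) * cfg$area_km2
    sheep <- approx(census_years, census_sheep, xout = yrs)$y

    # base matrix fixes the stable age distribution; yearly rescaling by
    # lambda_t / lambda(base) realizes N_{t+1} = lambda_t * N_t exactly once
    # the female vector is on that stable distribution
    base <- projection_matrix(0.35, 0.7, 0.85, 0.9)
    lam_base <- dominant_eigenvalue(base)
    v_stable <- Re(eigen(base)$vectors[, 1L])
    v_stable <- abs(v_stable) / sum(abs(v_stable))

    N <- numeric(cfg$years)
    lam <- rep(NA_real_, cfg$years)
    ages <- matrix(NA_real_, cfg$years, 3L)
    N[1L] <- cfg$N0
    ages[1L, ] <- v_stable * cfg$N0 / 2
    collapsed <- FALSE
    for (t in seq_len(cfg$years - 1L)) {
      lam[t] <- max(
        cfg$lambda_floor,
        cfg$a + cfg$b * log(N[t]) + cfg$c_precip * precip[t] +
          cfg$c_temp * wtemp[t] + rnorm(1L, 0, cfg$sigma)
      )
      N[t + 1L] <- lam[t] * N[t]
      ages[t + 1L, ] <- as.vector((lam[t] / lam_base) * base %*% ages[t, ])
      if (N[t + 1L] < 2) {
        collapsed <- TRUE
        keep <- seq_len(t + 1L)
        yrs <- yrs[keep]
        N <- N[keep]
        lam <- lam[keep]
        lam[t + 1L] <- NA_real_
        ages <- ages[keep, , drop = FALSE]
        precip <- precip[keep]
        wtemp <- wtemp[keep]
        sheep <- sheep[keep]
        break
      }
    }

    out <- structure(
      list(
        truth = tibble(
          year = yrs, N = N, lambda = lam,
          newborn_f = ages[, 1L], juvenile_f = ages[, 2L], adult_f = ages[, 3L]
        ),
        covariates = tibble(year = yrs, precip = precip, winter_temp = wtemp,
                            sheep = sheep),
        surveys = NULL,
        collapsed = collapsed,
        config = cfg
      ),
      class = "gp_sim"
    )
    out$surveys <- observe_transects(out, cfg, .reseed = FALSE)
    out
  })
}

#' Observe a simulated trajectory through strip-transect surveys
#'
#' Thins the true abundance through the survey geometry: the expected count
#' is \eqn{E[n_t] = N_t \cdot 2yx/A} (the fraction of the study area covered
#' by the strip), realized as a Poisson draw. The emitted survey rows report
#' the strip half-width as the mean perpendicular distance, so
#' [estimate_abundance()] inverts the thinning without detection bias.
#'
#' @param dataset A `gp_sim` from [simulate_trajectory()] (or any list with a
#'   `truth` tibble holding `year` and `N`).
#' @param cfg A [sim_config()] providing the survey geometry.
#' @param .reseed Reset the RNG to `cfg$seed` first (default `TRUE`; internal
#'   calls from [simulate_trajectory()] disable this to keep a single stream).
#' @return A tibble `year`, `n`, `x`, `y`, `area` (SI units) consumable by
#'   [estimate_abundance()].
#' @export
observe_transects <- function(dataset, cfg = dataset$config, .reseed = TRUE) {
  truth <- as_tibble(dataset$truth)
  assert_columns(truth, c("year", "N"), "truth table")
  area_m2 <- km2_to_m2(cfg$area_km2)
  coverage <- 2 * cfg$strip_y_m * cfg$transect_x_m / area_m2
  if (coverage >= 1) {
    gp_abort("strip area must cover less than 100% of the study area.")
  }
  draw <- function() rpois(nrow(truth), truth$N * coverage)
  n <- if (.reseed) withr::with_seed(cfg$seed + 1L, draw()) else draw()
  tibble(
    year = truth$year,
    n = n,
    x = cfg$transect_x_m,
    y = cfg$strip_y_m,
    area = area_m2
  )
}

#' @export
print.gp_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic trajectory: %d years from %d, N %.0f -> %.0f%s (seed %d)\n",
    nrow(x$truth), x$truth$year[1L], x$truth$N[1L],
    x$truth$N[nrow(x$truth)],
    if (x$collapsed) " [collapsed early]" else "", x$config$seed
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gp_sim <- function(object, ...) {
  est <- estimate_abundance(object$surveys)
  dat <- bind_rows(
    tibble(year = object$truth$year, N = object$truth$N, what = "true"),
    tibble(year = est$year, N = est$N_hat, what = "estimated")
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$N, colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Abundance (individuals)", colour = NULL)
}
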