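#' Linearly interpolate missing years in an annual series
#'
#' Missing values (absent years or `NA`s) are filled by linear interpolation
#' between the nearest known neighbours; known values are left untouched.
#' Interpolating a complete series is the identity. A missing value at either
#' boundary of the series cannot be bracketed and is an error — the package
#' never extrapolates.
#'
#' @param data Data frame with columns `year` and `value` (possibly `NA`);
#'   years need not be contiguous, gaps are treated as missing years.
#' @return A tibble `year`, `value`, `interpolated` covering every year from
#'   the first to the last, with `interpolated` flagging filled values.
#' @examples
#' interpolate_missing(data.frame(year = c(1985, 1987), value = c(100, 200)))
#' @export
interpolate_missing <- function(data) {
  data <- as_tibble(data)
  assert_columns(data, c("year", "value"), "annual series")
  data <- arrange(data, .data$year)
  if (anyDuplicated(data$year)) gp_abort("duplicate years in series.")
  known <- filter(data, is.finite(.data$value))
  if (nrow(known) < 1L) gp_abort("series has no known values.")
  years <- seq(min(data$year), max(data$year))
  if (!all(range(data$year) %in% known$year)) {
    gp_abort(
      "missing value at the series boundary: cannot interpolate without extrapolating."
    )
  }
  if (nrow(known) == 1L) {
    return(tibble(year = years, value = known$value, interpolated = FALSE))
  }
  filled <- approx(known$year, known$value, xout = years, method = "linear")$y
  tibble(
    year = years,
    value = filled,
    interpolated = !(years %in% known$year)
  )
}

#' Mean of a variable over the preceding T years
#'
#' The lag window for year \eqn{t} at depth \eqn{T} is the set of years
#' \eqn{\{t-1, \dots, t-T\}} — strictly prior years, excluding \eqn{t}
#' itself. Positions whose window extends before the start of the series get
#' `NA` (flagged, never back-filled).
#'
#' @param x Numeric vector of annual values, ordered by consecutive year.
#' @param lag Window depth `T` in years (integer >= 1).
#' @return Numeric vector of the same length: element `t` is
#'   `mean(x[(t - lag):(t - 1)])`, or `NA` when the window is incomplete.
#' @examples
#' lagged_mean(c(10, 20, 30, 40), lag = 2) # NA NA 15 25
#' @export
lagged_mean <- function(x, lag) {
  if (!is.numeric(lag) || length(lag) != 1L || lag < 1 || lag != round(lag)) {
    gp_abort("`lag` must be a single integer >= 1.")
  }
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n > lag) {
    cs <- cumsum(c(0, x))
    idx <- seq.int(lag + 1L, n)
    out[idx] <- (cs[idx] - cs[idx - lag]) / lag
  }
  out
}

#' Assemble the per-year regression table
#'
#' Joins the abundance, growth-rate and covariate series on calendar year and
#' derives the regression columns: natural-log abundances (`lnNtot`,
#' `lnSheep`), raw climate (`precip`, `winter_temp`) and the lagged means
#' `precip_T1` ... `precip_T7` and `winter_temp_T1` (see [lagged_mean()]).
#' The table keeps one row per year with a defined growth rate; rows whose
#' lag windows precede the data start carry `NA` in the affected columns and
#' are flagged `complete = FALSE` (downstream regressions drop them rather
#' than back-fill). Years with zero abundance cannot enter a log column and
#' are excluded with a warning.
#'
#' @param abundance Data frame `year`, `N_hat` (or `guanaco`): total guanaco
#'   abundance per year.
#' @param lambdas Data frame `year`, `lambda` (e.g. from [lambda_series()]).
#' @param covariates Data frame `year`, `precip`, `winter_temp`, `sheep`
#'   (precipitation mm/yr; June-August mean temperature, degrees C;
#'   interpolated sheep abundance, individuals).
#' @param precip_lags Integer vector of precipitation lag depths
#'   (default `1:7`).
#' @param temp_lags Integer vector of winter-temperature lag depths
#'   (default `1`).
#' @return A tibble with columns `year`, `lambda`, `lnNtot`, `lnSheep`,
#'   `precip`, `winter_temp`, the requested `precip_T*` / `winter_temp_T*`
#'   columns, and `complete`.
#' @export
build_covariate_table <- function(abundance, lambdas, covariates,
                                  precip_lags = 1:7, temp_lags = 1L) {
  abundance <- as_tibble(abundance)
  if (!"N_hat" %in% names(abundance) && "guanaco" %in% names(abundance)) {
    abundance <- rename(abundance, N_hat = "guanaco")
  }
  assert_columns(abundance, c("year", "N_hat"), "abundance table")
  abundance <- select(abundance, "year", "N_hat")
  lambdas <- as_tibble(lambdas)
  assert_columns(lambdas, c("year", "lambda"), "lambda table")
  lambdas <- select(lambdas, "year", "lambda")
  covariates <- as_tibble(covariates)
  assert_columns(covariates, c("year", "precip", "winter_temp", "sheep"),
                 "covariate table")
  covariates <- select(covariates, "year", "precip", "winter_temp", "sheep")
  covariates <- arrange(covariates, .data$year)
  if (nrow(covariates) > 1L && any(diff(covariates$year) != 1L)) {
    gp_abort("covariate years must be consecutive; interpolate first.")
  }

  # lagged columns are computed on the full covariate series before joining,
  # so the lag windows use every available year
  for (lg in precip_lags) {
    covariates[[paste0("precip_T", lg)]] <- lagged_mean(covariates$precip, lg)
  }
  for (lg in temp_lags) {
    covariates[[paste0("winter_temp_T", lg)]] <- lagged_mean(covariates$winter_temp, lg)
  }

  tab <- abundance %>%
    inner_join(lambdas, by = "year") %>%
    inner_join(covariates, by = "year") %>%
    arrange(.data$year)

  zero <- tab$N_hat <= 0 | tab$sheep <= 0
  if (any(zero)) {
    rlang::warn(sprintf(
      "excluding %d year(s) with zero abundance from the log-scale table: %s",
      sum(zero), paste(tab$year[zero], collapse = ", ")
    ))
    tab <- tab[!zero, ]
  }

  lag_cols <- c(
    if (length(precip_lags)) paste0("precip_T", precip_lags),
    if (length(temp_lags)) paste0("winter_temp_T", temp_lags)
  )
  tab$lnNtot <- log(tab$N_hat)
  tab$lnSheep <- log(tab$sheep)
  tab$complete <- Reduce(
    `&`, lapply(lag_cols, function(cl) !is.na(tab[[cl]])),
    rep(TRUE, nrow(tab))
  )
  select(tab, "year", "lambda", "lnNtot", "lnSheep", "precip", "winter_temp",
         dplyr::all_of(lag_cols), "complete")
}
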