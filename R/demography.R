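#' Build a three-age-class female-only projection matrix
#'
#' The model follows the standard Leslie-type structure for a species whose
#' females first reproduce as adults: newborn (chulengo), juvenile and adult
#' classes, reproduction only from adults, strict aging through the
#' subdiagonal, and an adult self-loop:
#' \preformatted{
#'   | 0    0    F_a |
#'   | S_n  0    0   |
#'   | 0    S_j  S_a |
#' }
#'
#' @param F_a Female newborns per adult female per year (>= 0).
#' @param S_n Newborn-to-juvenile annual survival, in \[0, 1\].
#' @param S_j Juvenile-to-adult annual survival, in \[0, 1\].
#' @param S_a Adult annual survival, in \[0, 1\].
#' @return A 3x3 numeric matrix with dimnames
#'   `c("newborn", "juvenile", "adult")`.
#' @examples
#' projection_matrix(0.35, 0.7, 0.85, 0.9)
#' @export
projection_matrix <- function(F_a, S_n, S_j, S_a) {
  pars <- c(F_a = F_a, S_n = S_n, S_j = S_j, S_a = S_a)
  if (any(!is.finite(pars)) || any(pars < 0)) {
    gp_abort("all matrix parameters must be finite and non-negative.")
  }
  if (any(c(S_n, S_j, S_a) > 1)) {
    gp_abort("survival probabilities S_n, S_j, S_a must not exceed 1.")
  }
  cls <- c("newborn", "juvenile", "adult")
  matrix(
    c(0, 0, F_a,
      S_n, 0, 0,
      0, S_j, S_a),
    nrow = 3, byrow = TRUE, dimnames = list(cls, cls)
  )
}

#' Project an age-structure one year forward
#'
#' @param m A 3x3 projection matrix from [projection_matrix()].
#' @param age A data frame (or single row) with columns `year`, `newborn_f`,
#'   `juvenile_f`, `adult_f` giving female abundance per age class.
#' @return A tibble of the same shape with the matrix applied and `year`
#'   incremented by one.
#' @export
project <- function(m, age) {
  stopifnot(is.matrix(m), identical(dim(m), c(3L, 3L)))
  age <- as_tibble(age)
  assert_columns(age, c("year", "newborn_f", "juvenile_f", "adult_f"), "age structure")
  v <- c(age$newborn_f, age$juvenile_f, age$adult_f)
  if (any(!is.finite(v)) || any(v < 0)) {
    gp_abort("age-class abundances must be finite and non-negative.")
  }
  w <- m %*% matrix(v, ncol = nrow(age))
  tibble(
    year = age$year + 1L,
    newborn_f = w[1L, ],
    juvenile_f = w[2L, ],
    adult_f = w[3L, ]
  )
}

#' Dominant (Perron) eigenvalue of a projection matrix
#'
#' For a non-negative matrix the largest-modulus eigenvalue is real and
#' non-negative (Perron-Frobenius); it is the finite rate of increase
#' \eqn{\lambda} of the population the matrix projects.
#'
#' @param m A non-negative square matrix, not identically zero.
#' @return The dominant eigenvalue as a single number.
#' @examples
#' dominant_eigenvalue(projection_matrix(1, 1, 1, 0)) # cube root of unity: 1
#' @export
dominant_eigenvalue <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (any(!is.finite(m)) || any(m < 0)) {
    gp_abort("matrix must be non-negative and finite.")
  }
  if (all(m == 0)) {
    gp_abort("matrix is identically zero: dominant eigenvalue is degenerate.")
  }
  ev <- eigen(m, only.values = TRUE)$values
  # Perron root: the largest-modulus eigenvalue is real for m >= 0, so the
  # largest real part is the dominant eigenvalue.
  max(Re(ev))
}

# Largest real root of the characteristic cubic
#   lambda^3 - S_a * lambda^2 - F_a * S_n * S_j = 0
# of the three-class matrix, vectorised over parameter vectors. Newton from an
# upper bound of the Perron root; used in the hot path of the SSQ fit where
# eigen() per candidate would dominate runtime.
perron_root <- function(F_a, S_n, S_j, S_a) {
  c0 <- F_a * S_n * S_j
  # start above the root: lambda* <= max(S_a, 1) + c0^(1/3) works since
  # f(S_a + c0^(1/3)) >= 0 for the monotone branch
  lam <- pmax(S_a, 0) + c0^(1 / 3) + 1e-9
  lam[c0 == 0] <- S_a[c0 == 0]
  live <- c0 > 0
  for (i in seq_len(60L)) {
    if (!any(live)) break
    f <- lam[live]^3 - S_a[live] * lam[live]^2 - c0[live]
    fp <- 3 * lam[live]^2 - 2 * S_a[live] * lam[live]
    step <- f / fp
    lam[live] <- lam[live] - step
    conv <- abs(step) < 1e-14 * pmax(1, lam[live])
    live[live] <- !conv
  }
  lam
}

#' Configuration for the per-year matrix fit
#'
#' @param mode `"stable"` (default) assumes each year's female vector sits at
#'   the stable age distribution of that year's matrix, so the predicted next
#'   total is \eqn{\lambda_t N_t}; `"structured"` projects the observed
#'   age-class composition instead (requires `structures` in
#'   [fit_yearly_matrices()]).
#' @param share_survival In `"stable"` mode, share `S_n` and `S_j` across
#'   years while `F_a` and `S_a` vary yearly (default `TRUE`).
#' @param F_max Upper bound on female newborns per adult female per year
#'   (default 1, singleton births).
#' @param sex_ratio Proportion of females in the population (default 0.5);
#'   total abundance is female abundance divided by this.
#' @param n_restarts Number of seeded random restarts for the
#'   bound-constrained optimizer (default 10).
#' @param seed RNG seed for the restarts; fixed by default so a fit is
#'   reproducible.
#' @param tol Convergence tolerance on the (relative) sum of squares
#'   (default 1e-8).
#' @param start Named starting values for `F_a`, `S_n`, `S_j`, `S_a`.
#' @return A list of class `gp_demography_config`.
#' @export
demography_config <- function(mode = c("stable", "structured"),
                              share_survival = TRUE,
                              F_max = 1,
                              sex_ratio = 0.5,
                              n_restarts = 10L,
                              seed = 20120918L,
                              tol = 1e-8,
                              start = c(F_a = 0.35, S_n = 0.7, S_j = 0.85, S_a = 0.9)) {
  mode <- match.arg(mode)
  stopifnot(F_max > 0, sex_ratio > 0, sex_ratio < 1, n_restarts >= 1, tol > 0)
  structure(
    list(
      mode = mode, share_survival = isTRUE(share_survival), F_max = F_max,
      sex_ratio = sex_ratio, n_restarts = as.integer(n_restarts),
      seed = as.integer(seed), tol = tol, start = start
    ),
    class = "gp_demography_config"
  )
}

# Analytic warm start for "stable" mode: given shared S_n, S_j and a target
# growth ratio r for one transition, pick S_a in its feasible interval and
# solve the characteristic cubic for F_a so lambda = r exactly (when r is
# achievable under the bounds).
warm_start_year <- function(r, S_n, S_j, F_max, S_a_pref = 0.9) {
  if (r <= 0) {
    return(c(F_a = 0, S_a = 0))
  }
  prod_sj <- S_n * S_j
  lo <- max(0, r - F_max * prod_sj / r^2)
  hi <- min(1, r)
  if (lo > hi) {
    # target ratio above the achievable Perron root: saturate
    return(c(F_a = F_max, S_a = 1))
  }
  S_a <- min(max(S_a_pref, lo), hi)
  F_a <- r^2 * (r - S_a) / prod_sj
  c(F_a = min(max(F_a, 0), F_max), S_a = S_a)
}

#' Fit one projection matrix per transition year to an abundance series
#'
#' Chooses, for each transition \eqn{t \to t+1}, the parameters of a
#' three-age-class female-only projection matrix so that the predicted total
#' population minimizes the sum of squared deviations (SSQ) from the observed
#' totals. Totals are converted to female vectors via the sex ratio (default
#' 50%, so total = 2 x female total).
#'
#' With only total counts the per-year vital rates are under-determined; the
#' fit is therefore defined by the documented constraint scheme (see
#' [demography_config()]): either the stable-age assumption (`"stable"`,
#' default, in which the SSQ pins down \eqn{\lambda_t} but not the individual
#' rates), or the observed age-class composition (`"structured"`). The
#' optimizer is bound-constrained (`optim(method = "L-BFGS-B")`), started from
#' an analytic warm start plus seeded random restarts, and never returns a
#' parameter set with higher SSQ than its best starting point.
#'
#' @param observed Data frame with columns `year` and `N_hat` (or `N`), the
#'   observed total abundance per year; at least two consecutive years, with
#'   missing years already interpolated.
#' @param structures Optional data frame `year`, `newborn_f`, `juvenile_f`,
#'   `adult_f` of observed age-class composition (used as proportions);
#'   switches the fit to `"structured"` mode.
#' @param config A [demography_config()].
#' @return An object of class `gp_demography_fit`: a list with `matrices`
#'   (tibble: `year`, `F_a`, `S_n`, `S_j`, `S_a`, `lambda`,
#'   `predicted_total`, `observed_total`, `ssq_contribution`), `ssq`,
#'   `converged`, `predicted_totals` and the `config` used. Use [tidy()] /
#'   [glance()] / [lambda_series()] on it.
#' @export
fit_yearly_matrices <- function(observed, structures = NULL,
                                config = demography_config()) {
  observed <- as_tibble(observed)
  if (!"N_hat" %in% names(observed) && "N" %in% names(observed)) {
    observed <- rename(observed, N_hat = "N")
  }
  assert_columns(observed, c("year", "N_hat"), "abundance series")
  observed <- arrange(observed, .data$year)
  if (nrow(observed) < 2L) {
    gp_abort("need at least two years of observed totals.")
  }
  if (any(diff(observed$year) != 1L)) {
    gp_abort("observed years must be consecutive; interpolate missing years first.")
  }
  if (any(!is.finite(observed$N_hat)) || any(observed$N_hat < 0)) {
    gp_abort("observed totals must be finite and non-negative.")
  }
  if (!is.null(structures)) {
    config$mode <- "structured"
  } else if (config$mode == "structured") {
    gp_abort("mode = 'structured' requires an age-structure table.")
  }

  fit <- switch(config$mode,
    stable = fit_stable_mode(observed, config),
    structured = fit_structured_mode(observed, structures, config)
  )

  years <- head(observed$year, -1L)
  pred <- fit$pred
  mat <- tibble(
    year = years,
    F_a = fit$F_a, S_n = fit$S_n, S_j = fit$S_j, S_a = fit$S_a,
    lambda = fit$lambda,
    predicted_total = pred,
    observed_total = tail(observed$N_hat, -1L),
    ssq_contribution = (pred - tail(observed$N_hat, -1L))^2
  )
  structure(
    list(
      matrices = mat,
      ssq = sum(mat$ssq_contribution),
      converged = fit$converged,
      predicted_totals = pred,
      observed = observed,
      config = config
    ),
    class = "gp_demography_fit"
  )
}

# "stable" mode: each year's female vector is at the stable age distribution,
# so predicted N_{t+1} = lambda(M_t) * N_t. Parameters: shared S_n, S_j (or
# per-year when share_survival = FALSE) plus per-year F_a, S_a.
fit_stable_mode <- function(observed, config) {
  N <- observed$N_hat
  m <- length(N) - 1L
  r <- ifelse(N[-length(N)] > 0, N[-1L] / N[-length(N)], 0)
  scale <- pmax(N[-1L], 1)

  objective <- function(theta) {
    S_n <- theta[1L]
    S_j <- theta[2L]
    F_a <- theta[2L + seq_len(m)]
    S_a <- theta[2L + m + seq_len(m)]
    lam <- perron_root(F_a, rep(S_n, m), rep(S_j, m), S_a)
    sum(((lam * N[-length(N)] - N[-1L]) / scale)^2)
  }

  ws <- vapply(
    r,
    warm_start_year,
    numeric(2L),
    S_n = config$start[["S_n"]], S_j = config$start[["S_j"]],
    F_max = config$F_max, S_a_pref = config$start[["S_a"]]
  )
  theta0 <- c(config$start[["S_n"]], config$start[["S_j"]], ws["F_a", ], ws["S_a", ])
  lower <- c(0, 0, rep(0, m), rep(0, m))
  upper <- c(1, 1, rep(config$F_max, m), rep(1, m))

  best <- optimise_multistart(objective, theta0, lower, upper, config)

  S_n <- best$par[1L]
  S_j <- best$par[2L]
  F_a <- best$par[2L + seq_len(m)]
  S_a <- best$par[2L + m + seq_len(m)]
  lam <- perron_root(F_a, rep(S_n, m), rep(S_j, m), S_a)
  list(
    F_a = F_a, S_n = rep(S_n, m), S_j = rep(S_j, m), S_a = S_a,
    lambda = lam, pred = lam * N[-length(N)], converged = best$converged
  )
}

# "structured" mode: project the observed composition, scaled to the observed
# total, through a fully free per-year matrix.
fit_structured_mode <- function(observed, structures, config) {
  structures <- as_tibble(structures)
  assert_columns(
    structures, c("year", "newborn_f", "juvenile_f", "adult_f"),
    "age-structure table"
  )
  N <- observed$N_hat
  years <- observed$year
  m <- length(N) - 1L
  out <- list(
    F_a = numeric(m), S_n = numeric(m), S_j = numeric(m), S_a = numeric(m),
    lambda = numeric(m), pred = numeric(m), converged = TRUE
  )
  for (t in seq_len(m)) {
    srow <- structures[structures$year == years[t], ]
    if (nrow(srow) != 1L) {
      gp_abort(sprintf("no age structure provided for year %d.", years[t]))
    }
    props <- c(srow$newborn_f, srow$juvenile_f, srow$adult_f)
    if (sum(props) <= 0) gp_abort("age-structure row sums to zero.")
    v <- props / sum(props) * N[t] * config$sex_ratio
    target <- N[t + 1L]
    scale <- max(target, 1)
    # predicted total is linear in the parameters:
    #   (F_a v3 + S_n v1 + S_j v2 + S_a v3) / sex_ratio
    objective <- function(theta) {
      pred <- (theta[1L] * v[3L] + theta[2L] * v[1L] +
                 theta[3L] * v[2L] + theta[4L] * v[3L]) / config$sex_ratio
      ((pred - target) / scale)^2
    }
    theta0 <- config$start[c("F_a", "S_n", "S_j", "S_a")]
    best <- optimise_multistart(
      objective, theta0,
      lower = rep(0, 4L), upper = c(config$F_max, 1, 1, 1), config
    )
    th <- best$par
    out$F_a[t] <- th[1L]
    out$S_n[t] <- th[2L]
    out$S_j[t] <- th[3L]
    out$S_a[t] <- th[4L]
    out$lambda[t] <- perron_root(th[1L], th[2L], th[3L], th[4L])
    out$pred[t] <- (th[1L] * v[3L] + th[2L] * v[1L] +
                      th[3L] * v[2L] + th[4L] * v[3L]) / config$sex_ratio
    out$converged <- out$converged && best$converged
  }
  out
}

# Bound-constrained local optimization from a deterministic warm start plus
# seeded random restarts; returns the best parameter set found. Never worse
# than the best starting point (the start itself is a candidate); stops early
# once the objective drops below the configured tolerance.
optimise_multistart <- function(objective, theta0, lower, upper, config) {
  starts <- list(theta0)
  extra <- config$n_restarts - 1L
  if (extra > 0L) {
    starts <- c(starts, withr::with_seed(config$seed, {
      lapply(seq_len(extra), function(i) runif(length(lower), lower, upper))
    }))
  }
  best <- list(par = theta0, value = objective(theta0), converged = FALSE)
  for (st in starts) {
    f0 <- objective(st)
    if (f0 < best$value) best <- list(par = st, value = f0, converged = FALSE)
    opt <- tryCatch(
      stats::optim(
        st, objective,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 500L, factr = 1e3)
      ),
      error = function(e) NULL
    )
    if (!is.null(opt) && opt$value < best$value) {
      best <- list(par = opt$par, value = opt$value, converged = opt$convergence == 0L)
    }
    if (best$value < config$tol) {
      best$converged <- TRUE
      break
    }
  }
  # a clean local minimum with positive SSQ is converged lack-of-fit, not
  # optimizer failure; warn only when no start converged at all
  if (best$value < config$tol) best$converged <- TRUE
  if (!best$converged) {
    rlang::warn("matrix fit did not converge; returning best parameters found.")
  }
  best
}

#' Extract the per-year finite rate of increase from a matrix fit
#'
#' @param fit A `gp_demography_fit` from [fit_yearly_matrices()].
#' @return A tibble `year`, `lambda` with one row per transition; the lambda
#'   for year `t` describes the transition `t` to `t + 1`.
#' @export
lambda_series <- function(fit) {
  stopifnot(inherits(fit, "gp_demography_fit"))
  select(fit$matrices, "year", "lambda")
}

#' @export
print.gp_demography_fit <- function(x, ...) {
  cat(sprintf(
    "Per-year projection-matrix fit (%s mode): %d transitions, SSQ = %.6g, %s\n",
    x$config$mode, nrow(x$matrices), x$ssq,
    if (x$converged) "converged" else "NOT converged"
  ))
  cat(sprintf(
    "lambda: min %.4f, median %.4f, max %.4f\n",
    min(x$matrices$lambda), stats::median(x$matrices$lambda), max(x$matrices$lambda)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gp_demography_fit <- function(x, ...) {
  x$matrices
}

#' @exportS3Method generics::glance
glance.gp_demography_fit <- function(x, ...) {
  tibble(
    ssq = x$ssq,
    n_transitions = nrow(x$matrices),
    converged = x$converged,
    mode = x$config$mode
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.gp_demography_fit <- function(object, ...) {
  obs <- object$observed
  pred <- tibble(
    year = object$matrices$year + 1L,
    total = object$matrices$predicted_total,
    what = "predicted"
  )
  dat <- bind_rows(
    tibble(year = obs$year, total = obs$N_hat, what = "observed"),
    pred
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$total, colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Year", y = "Total abundance", colour = NULL)
}
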