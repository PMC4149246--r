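#' Pairwise collinearity screen among candidate predictors
#'
#' Computes the Pearson correlation and its two-sided p value for every pair
#' of candidate predictor columns, and groups mutually correlated predictors
#' by transitive closure of the pairs significant at `alpha`. Constant
#' columns have undefined correlations; they are reported as `NA` rather
#' than dropped silently.
#'
#' @param table Data frame holding the predictor columns (e.g. from
#'   [build_covariate_table()]).
#' @param predictors Character vector of column names to screen; defaults to
#'   every numeric column except `year`, `lambda` and `complete`.
#' @param alpha Significance level for calling a pair correlated
#'   (default 0.05).
#' @return An object of class `gp_collinearity`: list with `pairs` (tibble
#'   `var1`, `var2`, `r`, `p_value`, `significant`), `r_matrix`, `p_matrix`,
#'   `groups` (list of character vectors, each a set of mutually correlated
#'   predictors) and `alpha`.
#' @export
collinearity_screen <- function(table, predictors = NULL, alpha = 0.05) {
  table <- as_tibble(table)
  if (is.null(predictors)) {
    predictors <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1))],
      c("year", "lambda", "complete")
    )
  }
  assert_columns(table, predictors, "covariate table")
  dat <- table[predictors]
  cc <- stats::complete.cases(dat)
  if (sum(cc) < 3L) gp_abort("need at least 3 complete rows for correlations.")
  dat <- dat[cc, ]

  k <- length(predictors)
  r_mat <- diag(1, k)
  p_mat <- matrix(NA_real_, k, k)
  dimnames(r_mat) <- dimnames(p_mat) <- list(predictors, predictors)
  diag(p_mat) <- 0
  pairs <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      xi <- dat[[i]]
      xj <- dat[[j]]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        r <- NA_real_
        p <- NA_real_
      } else {
        ct <- stats::cor.test(xi, xj, method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      r_mat[i, j] <- r_mat[j, i] <- r
      p_mat[i, j] <- p_mat[j, i] <- p
      pairs[[length(pairs) + 1L]] <- tibble(
        var1 = predictors[i], var2 = predictors[j], r = r, p_value = p,
        significant = !is.na(p) & p < alpha
      )
    }
  }
  pairs <- bind_rows(pairs)

  # transitive closure of significant pairs -> groups of correlated predictors
  adj <- !is.na(p_mat) & p_mat < alpha
  diag(adj) <- FALSE
  groups <- list()
  unseen <- rep(TRUE, k)
  for (i in seq_len(k)) {
    if (!unseen[i] || !any(adj[i, ])) next
    comp <- i
    frontier <- i
    while (length(frontier) > 0L) {
      nbr <- which(apply(adj[frontier, , drop = FALSE], 2, any))
      new <- setdiff(nbr, comp)
      comp <- c(comp, new)
      frontier <- new
    }
    unseen[comp] <- FALSE
    groups[[length(groups) + 1L]] <- predictors[sort(comp)]
  }

  structure(
    list(pairs = pairs, r_matrix = r_mat, p_matrix = p_mat,
         groups = groups, alpha = alpha, n = sum(cc)),
    class = "gp_collinearity"
  )
}

#' @export
print.gp_collinearity <- function(x, ...) {
  cat(sprintf(
    "Collinearity screen of %d predictors (n = %d, alpha = %g): %d significant pair(s)\n",
    ncol(x$r_matrix), x$n, x$alpha, sum(x$pairs$significant)
  ))
  if (length(x$groups)) {
    for (g in x$groups) cat("  group:", paste(g, collapse = ", "), "\n")
  } else {
    cat("  no correlated groups.\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gp_collinearity <- function(x, ...) {
  x$pairs
}

#' Ordinary least-squares fit of a response on named predictors
#'
#' Thin wrapper around [stats::lm()] that keeps the response/predictor names,
#' drops incomplete rows, and records the summaries the reporting layer
#' needs: coefficient table, R-squared, global F test and AIC. The AIC uses
#' the full Gaussian log-likelihood with estimated variance,
#' \eqn{AIC = n\log(2\pi\,RSS/n) + n + 2(k+2)} for `k` slope terms — the
#' convention of [stats::AIC()], so printed AICs are directly comparable with
#' mainstream statistical software.
#'
#' @param table Data frame with the response and predictor columns.
#' @param response Name of the response column (string).
#' @param predictors Character vector of predictor column names.
#' @return Object of class `gp_fit` wrapping the `lm` fit; supports
#'   [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
fit_ols <- function(table, response, predictors) {
  table <- as_tibble(table)
  assert_columns(table, c(response, predictors), "regression table")
  dat <- table[c(response, predictors)]
  dat <- dat[stats::complete.cases(dat), ]
  n <- nrow(dat)
  if (n <= length(predictors) + 1L) {
    gp_abort(sprintf(
      "need more complete rows (%d) than parameters (%d) to fit.",
      n, length(predictors) + 1L
    ))
  }
  qrx <- qr(cbind(1, as.matrix(dat[predictors])))
  if (qrx$rank < length(predictors) + 1L) {
    bad <- predictors[qrx$pivot[seq.int(qrx$rank + 1L, length(predictors) + 1L)] - 1L]
    gp_abort(paste0(
      "singular design: column(s) ", paste(bad, collapse = ", "),
      " are linearly dependent on the others."
    ))
  }
  fml <- stats::reformulate(predictors, response = response)
  model <- lm(fml, data = dat)
  structure(
    list(model = model, response = response, predictors = predictors, n = n),
    class = "gp_fit"
  )
}

#' @exportS3Method generics::tidy
tidy.gp_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @exportS3Method generics::glance
glance.gp_fit <- function(x, ...) {
  sm <- summary(x$model)
  fstat <- sm$fstatistic
  tibble(
    r.squared = sm$r.squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    statistic = unname(fstat[1L]),
    p.value = unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)),
    df = unname(fstat[2L]),
    df.residual = x$model$df.residual,
    AIC = AIC(x$model),
    nobs = x$n
  )
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "OLS fit: %s ~ %s  (n = %d)\n",
    x$response, paste(x$predictors, collapse = " + "), x$n
  ))
  print(tidy(x), n = Inf)
  g <- glance(x)
  cat(sprintf(
    "R2 = %.4f  F = %.3f (p = %.4g)  AIC = %.3f\n",
    g$r.squared, g$statistic, g$p.value, g$AIC
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gp_fit <- function(object, ...) {
  if (length(object$predictors) != 1L) {
    gp_abort("autoplot.gp_fit draws single-predictor fits only.")
  }
  dat <- object$model$model
  names(dat) <- c("y", "x")
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.5) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = object$predictors, y = object$response)
}

#' Fit the family of lagged-precipitation multiple regressions
#'
#' The lagged precipitation means are strongly correlated with each other, so
#' they cannot enter one model together; instead they are substituted one at
#' a time. Each member model regresses `lambda` on `lnNtot`, `lnSheep`,
#' `precip`, `winter_temp`, one `precip_Tk` and `winter_temp_T1`; the family
#' is ranked by AIC (ascending, ties broken by fewer predictors).
#'
#' By default every member is fitted on the rows complete for *all* lag
#' columns (the first `max(lags)` years are dropped), so the AICs compare
#' like with like; set `common_rows = FALSE` to let each member keep every
#' row complete for its own columns.
#'
#' @param table A covariate table from [build_covariate_table()].
#' @param lags Precipitation lag depths to sweep (default `1:7`).
#' @param common_rows Fit all members on a common row set (default `TRUE`).
#' @return Object of class `gp_family`: list with `fits` (named list of
#'   `gp_fit`, in AIC order), `summary` (tibble: `model`, `lag`, `AIC`,
#'   `r.squared`, `statistic`, `p.value`, `nobs`, in AIC order).
#' @export
regression_family <- function(table, lags = 1:7, common_rows = TRUE) {
  table <- as_tibble(table)
  lag_cols <- paste0("precip_T", lags)
  base <- c("lnNtot", "lnSheep", "precip", "winter_temp")
  assert_columns(table, c("lambda", base, lag_cols, "winter_temp_T1"),
                 "covariate table")
  if (common_rows) {
    keep <- stats::complete.cases(
      table[c("lambda", base, lag_cols, "winter_temp_T1")]
    )
    table <- table[keep, ]
  }
  fits <- lapply(lags, function(lg) {
    fit_ols(table, "lambda",
            c(base, paste0("precip_T", lg), "winter_temp_T1"))
  })
  names(fits) <- paste0("precip_T", lags)
  gl <- purrr::map_dfr(fits, glance, .id = "model")
  ord <- order(gl$AIC, lengths(lapply(fits, `[[`, "predictors")))
  structure(
    list(
      fits = fits[ord],
      summary = mutate(gl[ord, ], lag = lags[ord], .after = "model") %>%
        select("model", "lag", "AIC", "r.squared", "statistic", "p.value", "nobs")
    ),
    class = "gp_family"
  )
}

#' @export
print.gp_family <- function(x, ...) {
  cat("Lagged-precipitation regression family (best AIC first):\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gp_family <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy, .id = "model")
}

#' @exportS3Method generics::glance
glance.gp_family <- function(x, ...) {
  x$summary
}

#' Carrying capacity from the density-dependence regression
#'
#' Inverts the simple regression \eqn{\lambda = a + b \ln N} at equilibrium
#' (\eqn{\lambda = 1}): \eqn{K = \exp((1 - a)/b)}. A non-negative slope means
#' no equilibrium exists and is an error. Supply either a fitted simple
#' model (`lambda ~ lnNtot`) or the intercept and slope directly.
#'
#' @param fit A `gp_fit` of `lambda` on a single log-abundance predictor;
#'   alternatively leave `NULL` and pass `intercept` and `slope`.
#' @param area_km2 Study area in square kilometres, used for the density.
#' @param intercept,slope Regression coefficients on the
#'   \eqn{\lambda}-vs-\eqn{\ln N} scale (used when `fit` is `NULL`).
#' @return A tibble with columns `K` (individuals at equilibrium) and
#'   `density_per_km2`.
#' @examples
#' carrying_capacity(area_km2 = 2000, intercept = 1.6373, slope = -0.0552)
#' @export
carrying_capacity <- function(fit = NULL, area_km2, intercept = NULL, slope = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "gp_fit"))
    if (length(fit$predictors) != 1L) {
      gp_abort("carrying capacity requires the simple model lambda ~ lnNtot.")
    }
    cf <- coef(fit$model)
    intercept <- unname(cf[1L])
    slope <- unname(cf[2L])
  }
  if (is.null(intercept) || is.null(slope)) {
    gp_abort("supply either `fit` or both `intercept` and `slope`.")
  }
  if (!is.finite(slope) || slope >= 0) {
    gp_abort("no equilibrium: density-dependence slope must be negative.")
  }
  if (!is.numeric(area_km2) || area_km2 <= 0) {
    gp_abort("`area_km2` must be positive.")
  }
  K <- exp((1 - intercept) / slope)
  tibble(K = K, density_per_km2 = K / area_km2)
}
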