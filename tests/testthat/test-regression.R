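test_that("noise-free linear data are fitted exactly", {
  tab <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10))
  fit <- fit_ols(tab, "y", "x")
  # summary.lm warns about the zero-residual fit; the estimates are the point
  expect_equal(suppressWarnings(tidy(fit)$estimate), c(2, 3), tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit)$r.squared), 1, tolerance = 1e-10)
})

test_that("OLS matches a brute-force normal-equations oracle", {
  withr::with_seed(31, {
    for (case in 1:40) {
      n <- sample(10:30, 1)
      k <- sample(1:4, 1)
      X <- matrix(rnorm(n * k), n, k)
      y <- rnorm(n, 1 + X %*% runif(k, -2, 2), 0.5)
      tab <- tibble::as_tibble(as.data.frame(X)) %>%
        rlang::set_names(paste0("x", seq_len(k)))
      tab$y <- y
      fit <- fit_ols(tab, "y", paste0("x", seq_len(k)))
      # independent solve of (X'X) beta = X'y
      Xd <- cbind(1, X)
      beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
      expect_equal(unname(tidy(fit)$estimate), unname(beta), tolerance = 1e-8)
      # standard errors from sigma^2 (X'X)^-1
      rss <- sum((y - Xd %*% beta)^2)
      se <- sqrt(diag(solve(t(Xd) %*% Xd)) * rss / (n - k - 1))
      expect_equal(unname(tidy(fit)$std.error), unname(se), tolerance = 1e-8)
    }
  })
})

test_that("t statistics are estimate/SE and AIC ignores predictor order", {
  withr::with_seed(8, {
    tab <- tibble::tibble(a = rnorm(25), b = rnorm(25), c = rnorm(25))
    tab$y <- 1 + 0.5 * tab$a - tab$b + rnorm(25, 0, 0.3)
  })
  f1 <- fit_ols(tab, "y", c("a", "b", "c"))
  td <- tidy(f1)
  expect_equal(td$statistic, td$estimate / td$std.error, tolerance = 1e-12)
  f2 <- fit_ols(tab, "y", c("c", "b", "a"))
  expect_equal(glance(f1)$AIC, glance(f2)$AIC, tolerance = 1e-10)
  expect_equal(glance(f1)$r.squared, glance(f2)$r.squared, tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the offending column", {
  tab <- tibble::tibble(x1 = 1:10, y = rnorm(10))
  tab$x2 <- 2 * tab$x1
  expect_error(fit_ols(tab, "y", c("x1", "x2")), "x2")
  expect_error(fit_ols(tibble::tibble(y = 1:3, x = 1:3), "y", c("x", "z")), "z")
  # more parameters than rows
  expect_error(
    fit_ols(tibble::tibble(y = 1:3, a = rnorm(3), b = rnorm(3), c = rnorm(3)),
            "y", c("a", "b", "c")),
    class = "gp_error_user"
  )
})

test_that("slope estimates are calibrated under the regression model", {
  # coverage and unbiasedness are properties of OLS under its own model, so
  # the lnN design is held fixed (one generator trajectory at the study
  # scale) and fresh iid noise is drawn around the known line; feedback of
  # noise into later lnN values is a property of the full pipeline and is
  # bounded separately by the end-to-end recovery check. 2000 replicates keep
  # the Monte-Carlo error (~0.5 points) small against the 93% bound for a
  # true 2-SE coverage of P(|t_33| <= 2) = 94.6%.
  a_true <- 1.6373
  b_true <- -0.0552
  design <- simulate_trajectory(sim_config(seed = 7000, sigma = 0))
  lnN <- log(design$truth$N[1:35])
  n_reps <- 2000
  hits <- logical(n_reps)
  bias <- numeric(n_reps)
  withr::with_seed(71, {
    for (rep in seq_len(n_reps)) {
      tab <- tibble::tibble(
        lnNtot = lnN,
        lambda = a_true + b_true * lnN + rnorm(35, 0, 0.05)
      )
      td <- tidy(fit_ols(tab, "lambda", "lnNtot"))
      hits[rep] <- abs(td$estimate[2] - b_true) <= 2 * td$std.error[2]
      bias[rep] <- td$estimate[2] - b_true
    }
  })
  expect_gte(mean(hits), 0.93)
  expect_lt(abs(mean(bias)), 0.1 * abs(b_true))
})

test_that("climate terms reject at the nominal rate when they have no effect", {
  p_climate <- numeric(0)
  for (rep in seq_len(150)) {
    sim <- simulate_trajectory(sim_config(seed = 7200 + rep))
    tab <- build_covariate_table(
      dplyr::select(dplyr::rename(sim$truth, N_hat = "N"), "year", "N_hat"),
      dplyr::select(sim$truth, "year", "lambda")[!is.na(sim$truth$lambda), ],
      sim$covariates,
      precip_lags = 1, temp_lags = 1L
    )
    mfit <- fit_ols(tab, "lambda",
                    c("lnNtot", "lnSheep", "precip", "winter_temp"))
    mtd <- tidy(mfit)
    p_climate <- c(p_climate,
                   mtd$p.value[mtd$term %in% c("precip", "winter_temp")])
  }
  rate <- mean(p_climate < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("collinearity screen flags duplicates and groups transitively", {
  withr::with_seed(2, {
    x <- rnorm(36)
    tab <- tibble::tibble(x1 = x, x2 = x, x3 = rnorm(36))
  })
  sc <- collinearity_screen(tab, predictors = c("x1", "x2", "x3"))
  pair <- dplyr::filter(tidy(sc), var1 == "x1", var2 == "x2")
  expect_equal(pair$r, 1, tolerance = 1e-12)
  expect_true(pair$significant)
  expect_true(list(c("x1", "x2")) %in% sc$groups ||
                any(vapply(sc$groups, identical, logical(1), c("x1", "x2"))))

  # near-duplicate: a scaled copy plus vanishing noise
  withr::with_seed(3, {
    tab2 <- tibble::tibble(x1 = rnorm(36))
    tab2$x2 <- 2 * tab2$x1 + rnorm(36, 0, 1e-6)
  })
  sc2 <- collinearity_screen(tab2, predictors = c("x1", "x2"))
  expect_gt(dplyr::first(tidy(sc2)$r), 0.9999)

  # constant column: correlation undefined, reported as NA
  tab3 <- tibble::tibble(x1 = rnorm(10), x2 = rep(1, 10))
  sc3 <- collinearity_screen(tab3, predictors = c("x1", "x2"))
  expect_true(is.na(tidy(sc3)$r[1]))
})

test_that("independent predictors rarely form groups (type-I behaviour)", {
  grouped <- withr::with_seed(17, {
    vapply(seq_len(200), function(i) {
      tab <- tibble::tibble(x1 = rnorm(36), x2 = rnorm(36))
      length(collinearity_screen(tab, predictors = c("x1", "x2"))$groups) > 0
    }, logical(1))
  })
  expect_gte(mean(!grouped), 0.90)
})

test_that("regression family sweeps the lagged-precipitation variants", {
  sim <- simulate_trajectory(sim_config(seed = 404))
  est <- estimate_abundance(sim$surveys)
  lam <- dplyr::select(dplyr::filter(sim$truth, !is.na(lambda)),
                       "year", "lambda")
  tab <- build_covariate_table(est, lam, sim$covariates)
  fam <- regression_family(tab)
  expect_length(fam$fits, 7L)
  expect_equal(sort(fam$summary$lag), 1:7)
  # ranked by AIC ascending
  expect_true(!is.unsorted(fam$summary$AIC))
  # every member uses the same rows (common complete set)
  expect_equal(unique(fam$summary$nobs), nrow(tab) - 7L)
  # members regress on the documented predictor set
  expect_setequal(
    fam$fits[[1]]$predictors[1:4],
    c("lnNtot", "lnSheep", "precip", "winter_temp")
  )
  # identical lag columns give identical AICs
  tab2 <- tab
  for (k in 2:7) tab2[[paste0("precip_T", k)]] <- tab2$precip_T1
  fam2 <- regression_family(tab2)
  expect_equal(diff(range(fam2$summary$AIC)), 0, tolerance = 1e-10)
})

test_that("carrying capacity inverts the density-dependence line", {
  # printed-coefficient example: lambda = 1.6373 - 0.0552 lnN at lambda = 1
  cc <- carrying_capacity(area_km2 = 2000, intercept = 1.6373, slope = -0.0552)
  expect_equal(round(cc$K / 1000) * 1000, 103000)
  expect_equal(cc$density_per_km2, 51, tolerance = 0.02)
  # ln K = 0
  expect_equal(carrying_capacity(area_km2 = 1, intercept = 1, slope = -1)$K, 1)
  # closed form e^10
  expect_equal(
    carrying_capacity(area_km2 = 10, intercept = 2, slope = -0.1)$K,
    exp(10), tolerance = 1e-10
  )
  expect_error(carrying_capacity(area_km2 = 10, intercept = 2, slope = 0.1),
               "equilibrium")
  # from a fitted object: exact synthetic line
  tab <- tibble::tibble(lnNtot = seq(8, 11, length.out = 12))
  tab$lambda <- 1.6373 - 0.0552 * tab$lnNtot
  fit <- fit_ols(tab, "lambda", "lnNtot")
  cc2 <- carrying_capacity(fit, area_km2 = 2000)
  expect_equal(cc2$K, cc$K, tolerance = 1e-6)
  expect_error(carrying_capacity(fit, area_km2 = -1), class = "gp_error_user")
})
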