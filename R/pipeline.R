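#' Default pipeline configuration
#'
#' The pipeline exchanges every artifact as a headed UTF-8 CSV, so stages can
#' be run separately and re-entered. The configuration is a plain nested list
#' (readable from YAML via [read_pipeline_config()]): input paths, the
#' demography and lag settings, and the simulation block.
#'
#' @param paths Named list of input CSV paths: `surveys` (schema
#'   `year,n,x_m,y_m,area_km2`), `climate` (`year,precip_mm,winter_temp_c`),
#'   `sheep` (`year,sheep`), optional `structures`
#'   (`year,newborn_f,juvenile_f,adult_f`), and for a bare `regress` run,
#'   `covariates`.
#' @param area_km2 Study area used for densities (default 2000).
#' @param precip_lags,temp_lags Lag depths for [build_covariate_table()].
#' @param demography Argument list for [demography_config()].
#' @param simulation Argument list for [sim_config()].
#' @return A nested configuration list.
#' @export
pipeline_config <- function(paths = list(),
                            area_km2 = 2000,
                            precip_lags = 1:7,
                            temp_lags = 1L,
                            demography = list(),
                            simulation = list()) {
  list(
    paths = paths, area_km2 = area_km2,
    precip_lags = precip_lags, temp_lags = temp_lags,
    demography = demography, simulation = simulation
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys match the arguments
#'   of [pipeline_config()].
#' @return A configuration list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    gp_abort(sprintf("config file not found: %s", path))
  }
  user <- yaml::read_yaml(path)
  modifyList(pipeline_config(), user)
}

read_stage_csv <- function(path, required, what) {
  if (is.null(path) || !file.exists(path %||% "")) {
    gp_abort(sprintf("missing input file for %s: %s", what, path %||% "<unset>"))
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(dat, required, sprintf("%s (%s)", what, path))
  dat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage_csv <- function(data, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(data, path)
  path
}

write_manifest <- function(out_dir, stage, config, seed, inputs, outputs) {
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("guanacopop")),
    r_version = R.version.string,
    seed = seed,
    config_hash = rlang::hash(config),
    config = config,
    inputs = inputs,
    outputs = outputs
  )
  path <- file.path(out_dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

#' Run one pipeline stage
#'
#' Stages: `"simulate"` (write synthetic survey/climate/sheep/truth CSVs),
#' `"estimate-abundance"`, `"fit-matrices"`, `"build-covariates"`,
#' `"regress"`, and `"run-all"` (abundance through regression). Each stage
#' reads the CSVs named in `config$paths` (or the outputs of earlier stages
#' in `out_dir`), writes its artifacts into `out_dir`, and records a JSON
#' run manifest (inputs, configuration hash, seed, package and R versions)
#' sufficient to reproduce the run.
#'
#' @param stage Stage name (see above).
#' @param config Configuration list from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML config file.
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed for the stages that draw random numbers
#'   (simulation, matrix-fit restarts); overrides the config blocks.
#' @param verbose Print a line per artifact (default `FALSE`).
#' @return Invisibly, a named list of output file paths.
#' @export
run_stage <- function(stage, config = pipeline_config(), out_dir = ".",
                      seed = NULL, verbose = FALSE) {
  stages <- c("simulate", "estimate-abundance", "fit-matrices",
              "build-covariates", "regress", "run-all")
  if (!stage %in% stages) {
    gp_abort(sprintf(
      "unknown stage '%s'; expected one of: %s", stage,
      paste(stages, collapse = ", ")
    ))
  }
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  outputs <- switch(stage,
    "simulate" = stage_simulate(config, out_dir, seed, say),
    "estimate-abundance" = stage_abundance(config, out_dir, say),
    "fit-matrices" = stage_matrices(config, out_dir, seed, say),
    "build-covariates" = stage_covariates(config, out_dir, say),
    "regress" = stage_regress(config, out_dir, say),
    "run-all" = {
      o1 <- stage_abundance(config, out_dir, say)
      config$paths$abundance <- o1[["abundance"]]
      o2 <- stage_matrices(config, out_dir, seed, say)
      config$paths$matrices <- o2[["matrices"]]
      o3 <- stage_covariates(config, out_dir, say)
      config$paths$covariates <- o3[["covariates"]]
      o4 <- stage_regress(config, out_dir, say)
      c(o1, o2, o3, o4)
    }
  )
  manifest <- write_manifest(
    out_dir, stage, config, seed,
    inputs = config$paths, outputs = as.list(outputs)
  )
  invisible(c(outputs, manifest = manifest))
}

stage_simulate <- function(config, out_dir, seed, say) {
  args <- config$simulation %||% list()
  if (!is.null(seed)) args$seed <- as.integer(seed)
  cfg <- do.call(sim_config, args)
  sim <- simulate_trajectory(cfg)
  surveys <- transmute(
    sim$surveys,
    year = .data$year, n = .data$n, x_m = .data$x, y_m = .data$y,
    area_km2 = .data$area / 1e6
  )
  climate <- transmute(
    sim$covariates,
    year = .data$year, precip_mm = .data$precip,
    winter_temp_c = .data$winter_temp
  )
  out <- c(
    surveys = write_stage_csv(surveys, out_dir, "surveys.csv"),
    climate = write_stage_csv(climate, out_dir, "climate.csv"),
    sheep = write_stage_csv(select(sim$covariates, "year", "sheep"),
                            out_dir, "sheep.csv"),
    truth = write_stage_csv(sim$truth, out_dir, "truth.csv")
  )
  say("simulated %d years (seed %d)", nrow(sim$truth), cfg$seed)
  out
}

stage_abundance <- function(config, out_dir, say) {
  surveys <- read_stage_csv(
    config$paths$surveys, c("year", "n", "x_m", "y_m", "area_km2"),
    "survey table"
  )
  est <- estimate_abundance(transmute(
    surveys,
    year = .data$year, n = .data$n, x = .data$x_m, y = .data$y_m,
    area = km2_to_m2(.data$area_km2)
  ))
  out <- c(abundance = write_stage_csv(
    select(est, "year", "N_hat", "S2", "ci_low", "ci_high"),
    out_dir, "abundance.csv"
  ))
  say("estimated abundance for %d years", nrow(est))
  out
}

stage_matrices <- function(config, out_dir, seed, say) {
  abundance <- read_stage_csv(
    config$paths$abundance %||% file.path(out_dir, "abundance.csv"),
    c("year", "N_hat"), "abundance table"
  )
  args <- config$demography %||% list()
  if (!is.null(seed)) args$seed <- as.integer(seed)
  dcfg <- do.call(demography_config, args)
  structures <- NULL
  if (!is.null(config$paths$structures)) {
    structures <- read_stage_csv(
      config$paths$structures,
      c("year", "newborn_f", "juvenile_f", "adult_f"), "age-structure table"
    )
  }
  fit <- fit_yearly_matrices(abundance, structures, dcfg)
  out <- c(matrices = write_stage_csv(
    select(fit$matrices, "year", "lambda", "F_a", "S_n", "S_j", "S_a",
           "ssq_contribution"),
    out_dir, "matrices.csv"
  ))
  say("fitted %d matrices, SSQ = %.4g", nrow(fit$matrices), fit$ssq)
  out
}

stage_covariates <- function(config, out_dir, say) {
  abundance <- read_stage_csv(
    config$paths$abundance %||% file.path(out_dir, "abundance.csv"),
    c("year", "N_hat"), "abundance table"
  )
  matrices <- read_stage_csv(
    config$paths$matrices %||% file.path(out_dir, "matrices.csv"),
    c("year", "lambda"), "matrix table"
  )
  climate <- read_stage_csv(
    config$paths$climate, c("year", "precip_mm", "winter_temp_c"),
    "climate table"
  )
  sheep <- read_stage_csv(config$paths$sheep, c("year", "sheep"),
                          "sheep table")
  sheep_full <- interpolate_missing(rename(sheep, value = "sheep"))
  covs <- climate %>%
    transmute(year = .data$year, precip = .data$precip_mm,
              winter_temp = .data$winter_temp_c) %>%
    inner_join(transmute(sheep_full, year = .data$year, sheep = .data$value),
               by = "year")
  tab <- build_covariate_table(
    abundance, select(matrices, "year", "lambda"), covs,
    precip_lags = config$precip_lags %||% 1:7,
    temp_lags = config$temp_lags %||% 1L
  )
  out <- c(covariates = write_stage_csv(tab, out_dir, "covariates.csv"))
  say("built covariate table with %d rows", nrow(tab))
  out
}

stage_regress <- function(config, out_dir, say) {
  tab <- read_stage_csv(
    config$paths$covariates %||% file.path(out_dir, "covariates.csv"),
    c("lambda", "lnNtot", "lnSheep", "precip", "winter_temp",
      paste0("precip_T", config$precip_lags %||% 1:7), "winter_temp_T1"),
    "covariate table"
  )
  screen <- collinearity_screen(tab)
  fam <- regression_family(tab, lags = config$precip_lags %||% 1:7)
  simple <- fit_ols(tab, "lambda", "lnNtot")
  cc <- carrying_capacity(simple, area_km2 = config$area_km2 %||% 2000)

  fmt_fit <- function(f) {
    tidy(f) %>%
      rename(std_error = "std.error", t_value = "statistic",
             p_value = "p.value")
  }
  best <- fam$fits[[1L]]
  out <- c(
    collinearity = write_stage_csv(tidy(screen), out_dir, "collinearity.csv"),
    family_summary = write_stage_csv(
      fam$summary %>%
        rename(F_statistic = "statistic", F_pvalue = "p.value",
               R2 = "r.squared", n = "nobs"),
      out_dir, "family_summary.csv"
    ),
    best_model = write_stage_csv(fmt_fit(best), out_dir, "best_model.csv"),
    simple_model = write_stage_csv(fmt_fit(simple), out_dir,
                                   "simple_model.csv"),
    carrying_capacity = write_stage_csv(cc, out_dir, "carrying_capacity.csv")
  )
  g <- glance(simple)
  say("simple model: intercept %.4f, slope %.4f, AIC %.3f; K = %.0f",
      tidy(simple)$estimate[1L], tidy(simple)$estimate[2L], g$AIC, cc$K)
  out
}
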