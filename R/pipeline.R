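#' Default pipeline configuration
#'
#' Returns a fully synthetic configuration: simulate a survey with the
#' default study structure, fit and simplify the fully interacted model,
#' take the configured optimum/occurrence envelope, shift it +7 degC for
#' *S. cerevisiae*, simulate a Tmax raster and a strain table, and validate
#' the shifted envelope against it.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return a named list understood by [run_pipeline()]. Fields: `seed`;
#'   `survey` (a [survey_params()] or a CSV path); `formula` (model formula
#'   as string); `alpha`; `envelope` (list: `policy`, `optimum`,
#'   `occurrence`, `theta`); `offset_c`; `raster` (a list of
#'   [simulate_raster()] arguments, a [tmax_raster()], or an ASCII-grid
#'   path; `NULL` to skip validation); `strains` (a [strain_sim_params()],
#'   a data frame, a CSV path, or `NULL` to skip validation).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    survey = survey_params(seed = seed),
    formula = paste(
      "cbind(n_sp_positive, n_samples - n_sp_positive) ~",
      "girth_m * tmax_c * region * other_yeast_freq"),
    alpha = 0.05,
    envelope = list(policy = "fixed", optimum = c(22, 28),
                    occurrence = c(18, 31), theta = 0.5),
    offset_c = 7,
    raster = list(extent = c(-10, 40, 30, 60), resolution = 0.25,
                  base_c = 46, gradient_c_per_deg = -0.5, noise_c = 1),
    strains = strain_sim_params(seed = seed)
  )
}

stage_try <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full survey-to-validation pipeline
#'
#' Orchestrates simulate/load -> fit -> stepwise simplify -> envelope ->
#' shift -> classify -> report, writing every artifact plus a provenance
#' record into `out_dir`. Outputs are deterministic for a fixed
#' `config$seed`. Record counts after each filter are logged with
#' `message()` so the modelling exclusions stay auditable.
#'
#' @param config configuration list, see [default_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results: `trees`,
#'   `fit`, `deletion_log`, `envelope_sp`, `envelope_sc`, `classified`,
#'   `validation`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("yeastclim_run_")) {
  if (is.null(config$seed)) stop("config needs a 'seed'", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  trees <- stage_try("survey", {
    if (is.character(config$survey)) read_survey(config$survey)
    else if (inherits(config$survey, "survey_params"))
      simulate_survey(config$survey)
    else stop("'survey' must be a CSV path or survey_params")
  })
  write_survey(trees, file.path(out_dir, "survey.csv"))
  message("survey: ", nrow(trees), " trees, ",
          sum(is.na(trees$girth_m)), " with missing girth")

  sel <- stage_try("model", {
    f <- stats::as.formula(config$formula)
    suppressWarnings(stepwise_simplify(f, trees,
                                       alpha = config$alpha %||% 0.05))
  })
  message("model: ", nrow(sel$fit$model_frame), " trees used; final: ",
          deparse1(sel$formula))
  utils::write.csv(sel$log, file.path(out_dir, "deletion_log.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(term = names(coef(sel$fit)), estimate = coef(sel$fit),
               se = sel$fit$se, row.names = NULL),
    file.path(out_dir, "fit_summary.csv"), row.names = FALSE)

  env_sp <- stage_try("envelope", {
    e <- config$envelope %||% list(policy = "fixed")
    if (identical(e$policy, "threshold")) {
      grid <- seq(min(trees$tmax_c), max(trees$tmax_c), length.out = 200)
      curves <- lapply(stats::quantile(trees$girth_m, c(.25, .5, .75),
                                       na.rm = TRUE),
                       function(g) {
                         r <- sort(unique(trees$region))
                         predict_curve(sel$fit, g, r[length(r)], grid)
                       })
      derive_ranges(curves, policy = "threshold", theta = e$theta %||% 0.5)
    } else {
      derive_ranges(policy = "fixed",
                    optimum = e$optimum %||% c(22, 28),
                    occurrence = e$occurrence %||% c(18, 31))
    }
  })
  env_sc <- shift_envelope(env_sp, config$offset_c %||% 7)
  write_envelope_json(env_sp, file.path(out_dir, "envelope_paradoxus.json"))
  write_envelope_json(
    env_sc, file.path(out_dir, "envelope_cerevisiae.json"),
    provenance = list(derived_from = env_sp$species,
                      offset_c = config$offset_c %||% 7))

  classified <- NULL
  validation <- NULL
  if (!is.null(config$strains)) {
    grid <- stage_try("raster", {
      if (is.null(config$raster))
        stop("a raster is required to validate strain locations")
      if (inherits(config$raster, "tmax_raster")) config$raster
      else if (is.character(config$raster)) read_ascii_grid(config$raster)
      else do.call(simulate_raster,
                   c(config$raster, list(seed = config$seed + 1L)))
    })
    write_ascii_grid(grid, file.path(out_dir, "tmax.asc"))

    strains <- stage_try("strains", {
      if (is.character(config$strains)) read_strains(config$strains)
      else if (is.data.frame(config$strains)) config$strains
      else if (inherits(config$strains, "strain_sim_params"))
        simulate_strains(grid, env_sc, config$strains)
      else stop("'strains' must be a path, data frame or strain_sim_params")
    })
    n0 <- nrow(strains)
    strains <- filter_vineyard_strains(strains,
                                       config$vineyard_patterns %||%
                                         c("wine", "grape"))
    message("strains: ", n0, " read, ", nrow(strains),
            " retained after wine/grape filter")
    write_strains(strains, file.path(out_dir, "strains.csv"))

    classified <- stage_try("classify",
      classify_strains(strains, grid, env_sc$occurrence))
    validation <- summarize_validation(classified)
    write_strains(classified, file.path(out_dir, "classified_strains.csv"))
    utils::write.csv(validation,
                     file.path(out_dir, "validation_summary.csv"),
                     row.names = FALSE)
  }

  report <- c(
    sprintf("yeastclim pipeline report (seed %d)", config$seed),
    sprintf("trees: %d (%d missing girth); trees in model: %d",
            nrow(trees), sum(is.na(trees$girth_m)),
            nrow(sel$fit$model_frame)),
    sprintf("final model: %s", deparse1(sel$formula)),
    sprintf("residual deviance %.2f on %d df; %.1f%% of null deviance explained",
            sel$fit$deviance, sel$fit$df_residual,
            percent_deviance_explained(sel$fit)),
    sprintf("%s optimum [%g, %g] degC, occurrence [%g, %g] degC",
            env_sp$species, env_sp$optimum[1], env_sp$optimum[2],
            env_sp$occurrence[1], env_sp$occurrence[2]),
    sprintf("%s optimum [%g, %g] degC, occurrence [%g, %g] degC (offset +%g degC)",
            env_sc$species, env_sc$optimum[1], env_sc$optimum[2],
            env_sc$occurrence[1], env_sc$occurrence[2],
            config$offset_c %||% 7))
  if (!is.null(validation))
    report <- c(report, "", "strain validation by genotype class:",
                utils::capture.output(print(validation)))
  writeLines(report, file.path(out_dir, "report.txt"))

  prov <- list(
    package = "yeastclim",
    version = as.character(utils::packageVersion("yeastclim")),
    r_version = R.version.string,
    seed = config$seed,
    formula = config$formula,
    alpha = config$alpha %||% 0.05,
    offset_c = config$offset_c %||% 7,
    envelope = config$envelope)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(trees = trees, fit = sel$fit, deletion_log = sel$log,
                 envelope_sp = env_sp, envelope_sc = env_sc,
                 classified = classified, validation = validation,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
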