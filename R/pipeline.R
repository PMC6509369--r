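#' Configure a pipeline run
#'
#' Bundles everything a full seeded run needs: island configuration, ground
#' truth, buffer radius, output options.
#'
#' @param island an `oss_island_config` (default [island_config()]).
#' @param truth an `oss_truth` (default [truth_params()]).
#' @param radius_km buffer radius (default 2.06 km).
#' @param seed master seed; island/population/survey seeds derive from it.
#' @param asr_method forwarded to [local_asr()].
#' @param cell_km area-grid resolution.
#' @param spatial_check run [gaussian_correlation_check()] on each best
#'   residual model (default FALSE; the check is reported separately).
#' @param verbose print stage progress.
#' @return An object of class `oss_run_config`.
#' @export
run_config <- function(island = island_config(), truth = truth_params(),
                       radius_km = 2.06, seed = 1L,
                       asr_method = c("occasion", "season"),
                       cell_km = 0.05, spatial_check = FALSE,
                       verbose = FALSE) {
  stopifnot(inherits(island, "oss_island_config"), inherits(truth, "oss_truth"),
            radius_km > 0)
  island$seed <- as.integer(seed)
  structure(list(island = island, truth = truth, radius_km = radius_km,
                 seed = as.integer(seed), asr_method = match.arg(asr_method),
                 cell_km = cell_km, spatial_check = isTRUE(spatial_check),
                 verbose = isTRUE(verbose)),
            class = "oss_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `island`, `truth`, and scalar options (`radius_km`,
#' `seed`, `asr_method`, `cell_km`, `spatial_check`) map onto the arguments
#' of [island_config()], [truth_params()] and [run_config()].
#'
#' @param path YAML file path.
#' @return An `oss_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  island <- do.call(island_config, cfg$island %||% list())
  truth <- do.call(truth_params, cfg$truth %||% list())
  extra <- cfg[setdiff(names(cfg), c("island", "truth"))]
  do.call(run_config, c(list(island = island, truth = truth), extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny FNV-1a content hash so outputs can carry a config fingerprint
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes generate -> selection metrics -> stage-1 ASR models ->
#' residual-based AICc competitions -> post hoc climate regression as one
#' seeded run:
#' \enumerate{
#'   \item generate island, population and survey records; plant the
#'     configured ground-truth effects into the selection table;
#'   \item fit the stage-1 ASR mixed model for each response (`I`,
#'     `I_harem`, `I_mares_given_harem`) and extract standardized marginal
#'     residuals;
#'   \item compete the residual-based candidate set (null, year, and
#'     year x covariate for distance-to-water, unpaired-male density, total
#'     density) by AICc for each episode;
#'   \item when the distance-from-water model best explains the
#'     mate-acquisition residuals, extract its year-specific slopes and run
#'     the polynomial climate competition.
#' }
#'
#' @param config an `oss_run_config`.
#' @return An object of class `oss_run`: `island`, `records`, `selection` (planted
#'   selection table), `annual` (census summary), `stage1` (list of
#'   `oss_lmm` per response), `competitions` (list of `oss_competition`),
#'   `climate` (`oss_climate_fit` or NULL), `spatial` (list of
#'   `oss_spatial_check` or NULL), `saturation`, `dropped_rows`,
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "oss_run_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  say("stage generate: island + population + surveys (seed %d)", config$seed)
  island <- generate_island(config$island)
  population <- generate_population(island, config$truth)
  records <- simulate_surveys(population)
  say("  %d sighting records", nrow(records))
  say("stage metrics: selection table (radius %.2f km)", config$radius_km)
  sel <- selection_table(records, island$ponds, island,
                         radius_km = config$radius_km,
                         asr_method = config$asr_method,
                         cell_km = config$cell_km)
  dropped <- attr(sel, "dropped")
  islandwide <- islandwide_tests(sel)
  sel <- plant_effects(sel, config$truth, seed = config$seed + 13L)
  say("  %d male-year rows (%d undefined rows dropped)", nrow(sel), dropped)
  responses <- c("I", "I_harem", "I_mares_given_harem")
  stage1 <- list()
  resid_data <- sel
  for (resp in responses) {
    f <- stats::as.formula(paste(resp, "~ asr"))
    stage1[[resp]] <- fit_lmm(f, sel, group = "male_id")
    resid_data[[paste0("resid_", resp)]] <-
      extract_marginal_residuals(stage1[[resp]])
  }
  say("stage compete: residual-based candidate sets")
  competitions <- lapply(responses, function(resp) {
    compete_models(resid_data, paste0("resid_", resp), group = "male_id")
  })
  names(competitions) <- responses
  spatial <- NULL
  if (config$spatial_check) {
    say("stage spatial: Gaussian correlation check on best models")
    spatial <- lapply(competitions, function(cm) {
      gaussian_correlation_check(best_model(cm),
                                 resid_data[, c("x_km", "y_km")])
    })
  }
  climate <- NULL
  best_mares <- best_model(competitions$I_mares_given_harem)
  if (attr(best_mares, "model") == "year x dist_water_km" &&
      length(unique(sel$year)) >= 4) {
    say("stage posthoc: climate regression on annual water slopes")
    slopes <- year_slopes(best_mares, "dist_water_km")
    climate <- climate_fit(slopes, synth_climate(island))
  }
  sat <- saturation_analysis(records, config$radius_km)
  structure(list(island = island, records = records, selection = sel,
                 annual = annual_summary(records),
                 islandwide = islandwide,
                 stage1 = stage1, competitions = competitions,
                 climate = climate, spatial = spatial, saturation = sat,
                 dropped_rows = dropped, config = config,
                 config_hash = config_hash(config)),
            class = "oss_run")
}

#' @export
print.oss_run <- function(x, ...) {
  cat(sprintf("Pipeline run %s: %d records, %d male-year rows (%d dropped), %d males\n",
              x$config_hash, nrow(x$records), nrow(x$selection),
              x$dropped_rows, length(unique(x$selection$male_id))))
  for (resp in names(x$competitions)) {
    tab <- x$competitions[[resp]]$table
    cat(sprintf("  %-22s best: %-28s (w = %.2f, R2m = %.2f)\n", resp,
                tab$model[1], tab$weight[1], tab$marginal_r2[1]))
  }
  if (!is.null(x$climate)) {
    cat(sprintf("  climate winner: %s\n", x$climate$winner))
  }
  invisible(x)
}

#' Write the run's result tables as a CSV bundle
#'
#' Emits the census summary (year, population, adults, harems, harem size
#' with its 95% CI), one competition table per episode, the climate table
#' when available, the selection table, the saturation curve, and the truth
#' parameters echoed to YAML. Every CSV carries a header comment with the
#' seed and config hash.
#'
#' @param run an `oss_run`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
report_tables <- function(run, dir) {
  stopifnot(inherits(run, "oss_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# seed=%d config=%s", run$config$seed, run$config_hash)
  wr <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  paths <- c(annual_summary = wr(run$annual, "annual_summary"),
             islandwide = wr(run$islandwide, "islandwide_tests"),
             selection = wr(run$selection, "selection_table"),
             ponds = wr(run$island$ponds, "ponds"),
             saturation = wr(run$saturation$curve, "saturation_curve"))
  sat_json <- file.path(dir, "saturation.json")
  writeLines(sprintf(
    '{"a": %.6g, "b": %.6g, "r2": %.6g, "saturation_occasion": %s}',
    run$saturation$a, run$saturation$b, run$saturation$r2,
    if (run$saturation$reached) run$saturation$saturation_occasion else "null"),
    sat_json)
  paths["saturation_json"] <- sat_json
  for (resp in names(run$competitions)) {
    paths[paste0("competition_", resp)] <-
      wr(run$competitions[[resp]]$table, paste0("competition_", resp))
  }
  if (!is.null(run$climate)) {
    paths["climate"] <- wr(run$climate$table, "climate_competition")
  }
  truth_path <- file.path(dir, "truth_params.yaml")
  yaml::write_yaml(unclass(run$config$truth), truth_path)
  paths["truth"] <- truth_path
  invisible(paths)
}
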