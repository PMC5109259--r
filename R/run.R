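# Orchestration: one reproducible study run from configuration to summary
# tables, with an optional on-disk output bundle and a manifest recording
# everything needed to reproduce it bit-identically.

#' Build a run configuration
#'
#' @param seed Integer seed driving every random stage of the run.
#' @param n_iterations Monte Carlo iterations (>= 100).
#' @param parameter_table Exposure-factor table (tibble or CSV path);
#'   defaults to [default_exposure_parameters()].
#' @param metal_table Metal property table (tibble or CSV path); defaults to
#'   [default_metal_properties()].
#' @param summaries Concentration summary table (tibble or CSV path);
#'   defaults to [concentration_summaries()].
#' @param correlations Rank-correlation pairs; defaults to
#'   [default_correlations()] over the metals of `metal_table`.
#' @param study Scenario list; defaults to [build_default_study()].
#' @param sensitivity_method `"spearman"` or `"pearson"`.
#' @param top_k Rows per scenario in the sensitivity table.
#' @param threshold Safety threshold for exceedance probabilities.
#' @param out_dir Optional directory for the CSV/JSON output bundle.
#' @return A list of class `rpra_config`.
#' @export
run_config <- function(seed = 42L, n_iterations = 10000L,
                       parameter_table = NULL, metal_table = NULL,
                       summaries = NULL, correlations = NULL, study = NULL,
                       sensitivity_method = c("spearman", "pearson"),
                       top_k = 5L, threshold = 1, out_dir = NULL) {
  if (n_iterations < 100) abort("n_iterations must be >= 100")
  structure(
    list(seed = as.integer(seed), n_iterations = as.integer(n_iterations),
         parameter_table = parameter_table, metal_table = metal_table,
         summaries = summaries, correlations = correlations, study = study,
         sensitivity_method = match.arg(sensitivity_method),
         top_k = top_k, threshold = threshold, out_dir = out_dir),
    class = "rpra_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; table-valued keys
#' (`parameter_table`, `metal_table`, `summaries`) are file paths resolved
#' relative to the YAML file, and `correlations` is a list of
#' `[param1, param2, rho]` triples.
#'
#' @param path YAML file path.
#' @return An `rpra_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  corr <- NULL
  if (!is.null(raw$correlations)) {
    corr <- purrr::map(raw$correlations, function(tr) {
      if (length(tr) != 3L) abort("each correlation entry must be [param1, param2, rho]")
      correlation_pairs(tr[[1]], tr[[2]], as.numeric(tr[[3]]))
    }) |> dplyr::bind_rows()
  }
  run_config(
    seed = raw$seed %||% 42L,
    n_iterations = raw$n_iterations %||% 10000L,
    parameter_table = resolve(raw$parameter_table),
    metal_table = resolve(raw$metal_table),
    summaries = resolve(raw$summaries),
    correlations = corr,
    sensitivity_method = raw$sensitivity_method %||% "spearman",
    top_k = raw$top_k %||% 5L,
    threshold = raw$threshold %||% 1,
    out_dir = raw$out_dir
  )
}

as_table <- function(x, reader, default) {
  if (is.null(x)) return(default())
  if (is.character(x)) return(reader(x))
  tibble::as_tibble(x)
}

#' Run the full probabilistic risk assessment
#'
#' Executes the pipeline end to end: builds sampler specifications from the
#' exposure-factor table, the per-metal soil coefficients and the
#' concentration summaries; draws the correlated Monte Carlo sample matrix;
#' evaluates every scenario-route-metal hazard quotient; characterizes the
#' risk (scenario and route summaries, per-metal contribution shares,
#' cumulative-probability curves); and ranks parameter sensitivities per
#' scenario. If `config$out_dir` is set, writes the summary CSVs and a JSON
#' manifest (seed, iteration count, input digests) there.
#'
#' @param config An `rpra_config` from [run_config()] or [read_run_config()].
#' @return An object of class `rpra_run`: a list with elements `config`,
#'   `draws`, `hq`, `thq` (per scenario), `thq_by_metal`, `scenario_summary`,
#'   `route_summary`, `contributions`, `sensitivity` and `manifest`.
#' @examples
#' \donttest{
#' run <- run_study(run_config(seed = 7, n_iterations = 1000))
#' tidy(run)
#' }
#' @export
run_study <- function(config = run_config()) {
  if (!inherits(config, "rpra_config")) abort("config must come from run_config()")
  params <- as_table(config$parameter_table, read_parameter_table,
                     default_exposure_parameters)
  metals <- as_table(config$metal_table, default_metal_properties,
                     default_metal_properties)
  summaries <- as_table(config$summaries, concentration_summaries,
                        concentration_summaries)
  study <- config$study %||% build_default_study()
  correlations <- config$correlations %||% default_correlations(metals$metal)

  specs <- dplyr::bind_rows(
    validate_parameter_specs(params),
    metal_parameter_specs(metals),
    fit_summary_to_spec(summaries)
  )
  validate_parameter_specs(specs)

  draws <- draw_parameter_matrix(specs, n = config$n_iterations,
                                 seed = config$seed,
                                 correlations = correlations)
  hq <- compute_study_hq(draws, study = study, metals = metals)
  thq <- total_hq(hq, by = "scenario")
  thq_by_metal <- total_hq(hq, by = c("scenario", "metal"))

  scenario_summary <- summarize_risk(
    thq, by = "scenario", threshold = config$threshold,
    boot_se = TRUE, seed = param_stream_seed(config$seed, "bootstrap")
  )
  route_summary <- summarize_risk(hq, by = c("scenario", "route"),
                                  threshold = config$threshold)
  contributions <- contribution_shares(hq)
  sensitivity <- study_sensitivity(draws, thq, top_k = config$top_k,
                                   method = config$sensitivity_method)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rpra")),
    seed = config$seed,
    n_iterations = config$n_iterations,
    sensitivity_method = config$sensitivity_method,
    threshold = config$threshold,
    scenarios = names(study),
    input_digests = list(
      parameter_table = rlang::hash(params),
      metal_table = rlang::hash(metals),
      summaries = rlang::hash(summaries),
      correlations = rlang::hash(correlations)
    )
  )

  run <- structure(
    list(config = config, draws = draws, hq = hq, thq = thq,
         thq_by_metal = thq_by_metal, scenario_summary = scenario_summary,
         route_summary = route_summary, contributions = contributions,
         sensitivity = sensitivity, manifest = manifest),
    class = "rpra_run"
  )
  if (!is.null(config$out_dir)) write_study_outputs(run, config$out_dir)
  run
}

#' Write the output bundle of a study run
#'
#' Emits `scenario_summary.csv`, `route_summary.csv`, `contributions.csv`,
#' `sensitivity.csv`, `cumulative_probability.csv` and `manifest.json` into
#' `out_dir` (created if needed).
#'
#' @param run An `rpra_run` from [run_study()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_study_outputs <- function(run, out_dir) {
  if (!inherits(run, "rpra_run")) abort("run must come from run_study()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$scenario_summary, file.path(out_dir, "scenario_summary.csv"))
  readr::write_csv(run$route_summary, file.path(out_dir, "route_summary.csv"))
  readr::write_csv(run$contributions, file.path(out_dir, "contributions.csv"))
  readr::write_csv(tibble::as_tibble(run$sensitivity),
                   file.path(out_dir, "sensitivity.csv"))
  readr::write_csv(cumulative_probability(run$hq, by = c("scenario", "route")),
                   file.path(out_dir, "cumulative_probability.csv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Scenario names ordered by 95th-percentile total hazard quotient
#'
#' @param run An `rpra_run` from [run_study()].
#' @return Character vector of scenario names, highest p95 first.
#' @export
scenario_order <- function(run) {
  s <- run$scenario_summary
  s$scenario[order(-s$p95)]
}

#' @export
print.rpra_run <- function(x, ...) {
  cat("<rpra_run> seed ", x$config$seed, ", ", x$config$n_iterations,
      " iterations, ", nrow(x$thq), " scenarios\n", sep = "")
  cat("Scenario THQ summary (threshold ", x$config$threshold, "):\n", sep = "")
  print(x$scenario_summary, n = nrow(x$scenario_summary))
  invisible(x)
}
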