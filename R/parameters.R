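#' Declare an uncertain model parameter
#'
#' A parameter specification is one row of a parameter table: a named
#' quantity together with the distribution family used to generate its Monte
#' Carlo trial values. Three families are supported: `"point"` (a degenerate
#' constant), `"lognormal"` (parameterized by its *arithmetic* mean and
#' standard deviation, optionally truncated to `[min, max]` by rejection),
#' and `"triangular"` (`min`, `mode`, `max`; the mode defaults to the
#' declared mean clipped into the bounds).
#'
#' @param name Parameter identifier, e.g. `"BW"` or `"conc_RVS_As"`.
#' @param family One of `"point"`, `"lognormal"`, `"triangular"`.
#' @param mean Arithmetic mean in the declared units.
#' @param sd Arithmetic standard deviation (lognormal only; `0` collapses the
#'   distribution to the mean).
#' @param min,max Optional truncation bounds (lognormal) or support bounds
#'   (triangular, required).
#' @param mode Mode of a triangular distribution; defaults to `mean` clipped
#'   into `[min, max]`.
#' @param units Free-text units, carried through outputs.
#'
#' @return A one-row tibble with columns
#'   `name, family, mean, sd, min, max, mode, units`.
#' @examples
#' parameter_spec("BW", "lognormal", mean = 60, sd = 10, min = 40, max = 100,
#'                units = "kg")
#' @export
parameter_spec <- function(name, family = c("point", "lognormal", "triangular"),
                           mean, sd = NA_real_, min = NA_real_, max = NA_real_,
                           mode = NA_real_, units = NA_character_) {
  family <- match.arg(family)
  spec <- tibble::tibble(
    name = as.character(name), family = family,
    mean = as.numeric(mean), sd = as.numeric(sd),
    min = as.numeric(min), max = as.numeric(max),
    mode = as.numeric(mode), units = as.character(units)
  )
  validate_parameter_specs(spec)
  spec
}

#' Validate a parameter table
#'
#' Checks the structural invariants of a table of [parameter_spec()] rows:
#' `min <= mean <= max` where bounds are declared, nonnegative `sd`,
#' triangular rows with `min <= mode <= max`, strictly positive means for
#' lognormal rows, and unique names.
#'
#' @param specs A data frame with the columns of [parameter_spec()].
#' @return `specs`, invisibly (as a tibble), if valid; otherwise an error.
#' @export
validate_parameter_specs <- function(specs) {
  specs <- tibble::as_tibble(specs)
  needed <- c("name", "family", "mean")
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols)) {
    abort(paste0("parameter table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("sd", "min", "max", "mode")) {
    if (!col %in% names(specs)) specs[[col]] <- NA_real_
  }
  if (!"units" %in% names(specs)) specs$units <- NA_character_
  if (anyDuplicated(specs$name)) {
    abort(paste0("duplicated parameter name(s): ",
                 paste(unique(specs$name[duplicated(specs$name)]), collapse = ", ")))
  }
  bad_family <- setdiff(unique(specs$family), c("point", "lognormal", "triangular"))
  if (length(bad_family)) {
    abort(paste0("unknown distribution family: ", paste(bad_family, collapse = ", ")))
  }
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (!is.finite(s$mean)) abort(paste0("parameter '", s$name, "': mean must be finite"))
    if (s$family == "point") next
    if (is.finite(s$sd) && s$sd < 0) {
      abort(paste0("parameter '", s$name, "': sd must be >= 0"))
    }
    if (s$family == "lognormal") {
      if (s$mean <= 0) {
        abort(paste0("parameter '", s$name,
                     "': lognormal requires a positive mean"))
      }
      if (is.finite(s$min) && is.finite(s$max) && s$min > s$max) {
        abort(paste0("parameter '", s$name, "': min > max"))
      }
      if (is.finite(s$min) && s$min > s$mean) {
        abort(paste0("parameter '", s$name, "': min exceeds mean"))
      }
      if (is.finite(s$max) && s$max < s$mean) {
        abort(paste0("parameter '", s$name, "': max is below mean"))
      }
    }
    if (s$family == "triangular") {
      if (!is.finite(s$min) || !is.finite(s$max)) {
        abort(paste0("parameter '", s$name, "': triangular requires min and max"))
      }
      mode <- if (is.finite(s$mode)) s$mode else pmin(pmax(s$mean, s$min), s$max)
      if (s$min > mode || mode > s$max) {
        abort(paste0("parameter '", s$name, "': triangular requires min <= mode <= max"))
      }
    }
  }
  invisible(specs)
}

#' Read a parameter table from CSV
#'
#' Expected columns: `name, family, mean, sd, min, max, mode, units`
#' (extra columns such as `description` are carried along untouched).
#'
#' @param path CSV file path. The default is the exposure-factor table
#'   bundled with the package, see [default_exposure_parameters()].
#' @return A validated tibble of parameter specifications.
#' @export
read_parameter_table <- function(path) {
  specs <- readr::read_csv(path, show_col_types = FALSE)
  for (col in c("mean", "sd", "min", "max", "mode")) {
    if (col %in% names(specs)) specs[[col]] <- as.numeric(specs[[col]])
  }
  validate_parameter_specs(specs)
  tibble::as_tibble(specs)
}

#' Bundled default exposure-factor distributions
#'
#' A generic adult-receptor exposure-factor table (ingestion, inhalation and
#' dermal contact rates, exposure frequencies and durations, body weight,
#' skin surface areas, adherence factors, vegetable water content, soil
#' hydraulic properties and the leachate dilution factor). The values are
#' literature-typical defaults in the spirit of the Chinese Exposure Factors
#' Handbook and USEPA exposure-factor compilations; they are a stand-in
#' default, not site measurements, and any site-specific study should
#' override them via [read_parameter_table()].
#'
#' Indoor/daily and outdoor exposure frequencies are fixed at 350 and
#' 225 d/yr. Averaging time is not a row of this table: the non-carcinogenic
#' convention `AT = ED * 365` is applied per iteration by the scenario
#' engine.
#'
#' @return A tibble of parameter specifications (one row per factor).
#' @export
default_exposure_parameters <- function() {
  read_parameter_table(
    system.file("extdata", "default_exposure_parameters.csv",
                package = "rpra", mustWork = TRUE)
  )
}

#' Convert concentration summaries to sampler specifications
#'
#' Bridges field-survey summary rows (`stratum, metal, mean, sd, minimum,
#' maximum, units`) to truncated-lognormal parameter specifications named
#' `conc_<stratum>_<metal>`, ready for [draw_parameter_matrix()]. A summary
#' with `sd = 0` yields a distribution that samples to the constant mean.
#'
#' @param summary A data frame of concentration summaries, e.g. from
#'   [concentration_summaries()] or [summarize_field_data()].
#' @return A tibble of parameter specifications, one row per summary row.
#' @examples
#' fit_summary_to_spec(data.frame(stratum = "RVS", metal = "As", mean = 72.3,
#'                                sd = 26.8, minimum = 34.7, maximum = 106.3,
#'                                units = "mg/kg"))
#' @export
fit_summary_to_spec <- function(summary) {
  summary <- tibble::as_tibble(summary)
  needed <- c("stratum", "metal", "mean", "sd", "minimum", "maximum")
  missing_cols <- setdiff(needed, names(summary))
  if (length(missing_cols)) {
    abort(paste0("summary table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(summary$mean) | summary$mean <= 0)) {
    bad <- summary[!is.finite(summary$mean) | summary$mean <= 0, ]
    abort(paste0("nonpositive mean for ", paste(bad$stratum, bad$metal,
                 sep = "/", collapse = ", "), ": lognormal undefined"))
  }
  if (any(summary$minimum > summary$mean | summary$maximum < summary$mean)) {
    abort("summary with mean outside [minimum, maximum] is infeasible")
  }
  specs <- tibble::tibble(
    name = paste("conc", summary$stratum, summary$metal, sep = "_"),
    family = "lognormal",
    mean = summary$mean, sd = summary$sd,
    min = summary$minimum, max = summary$maximum,
    mode = NA_real_,
    units = if ("units" %in% names(summary)) summary$units else NA_character_
  )
  validate_parameter_specs(specs)
  specs
}
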