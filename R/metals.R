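#' Bundled default metal property table
#'
#' Route-specific chronic reference doses (oral, dermal, inhalation;
#' mg/kg/d), soil-water partition coefficients `kd` (L/kg), plant uptake
#' factors `puf` (dry-weight basis), dermal permeability constants `kp`
#' (cm/h), dermal absorption fractions `abs` and, for elemental Hg only, the
#' volatilization factor `vf` (m3/kg). Oral reference doses are standard
#' USEPA-style values; dermal doses apply the usual gastrointestinal
#' absorption adjustment. `kd` and `puf` are bundled defaults for
#' near-neutral riverine agricultural soils and should be replaced by
#' site-specific measurements where available; see the methods vignette for
#' how the defaults were chosen.
#'
#' @param path Optional CSV path overriding the bundled table (columns
#'   `metal, rfd_oral, rfd_dermal, rfd_inhalation, kd, puf, kp, abs, vf`).
#' @return A tibble with one row per metal.
#' @export
default_metal_properties <- function(path = NULL) {
  path <- path %||% system.file("extdata", "default_metal_properties.csv",
                                package = "rpra", mustWork = TRUE)
  props <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("metal", "rfd_oral", "rfd_dermal", "rfd_inhalation",
              "kd", "puf", "kp", "abs")
  missing_cols <- setdiff(needed, names(props))
  if (length(missing_cols)) {
    abort(paste0("metal property table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"vf" %in% names(props)) props$vf <- NA_real_
  vf_metals <- props$metal[is.finite(props$vf)]
  if (length(setdiff(vf_metals, "Hg"))) {
    abort("a volatilization factor is only meaningful for elemental Hg")
  }
  tibble::as_tibble(props)
}

# Uncertainty attached to the partition and uptake coefficients: both are
# order-of-magnitude-variable soil properties, so they enter the sampler as
# truncated lognormals with a fixed coefficient of variation.
KD_CV <- 0.6
PUF_CV <- 0.6

#' Sampler specifications for per-metal soil coefficients
#'
#' Expands a metal property table into `Kd_<metal>` and `PUF_<metal>`
#' parameter specifications (truncated lognormals with coefficient of
#' variation 0.6, bounded to roughly an order of magnitude around the mean),
#' ready to join the exposure-factor table in [draw_parameter_matrix()].
#'
#' @param metals A metal property table, see [default_metal_properties()].
#' @return A tibble of parameter specifications.
#' @export
metal_parameter_specs <- function(metals = default_metal_properties()) {
  dplyr::bind_rows(
    tibble::tibble(
      name = paste0("Kd_", metals$metal), family = "lognormal",
      mean = metals$kd, sd = KD_CV * metals$kd,
      min = metals$kd / 8, max = 5 * metals$kd,
      mode = NA_real_, units = "L/kg"
    ),
    tibble::tibble(
      name = paste0("PUF_", metals$metal), family = "lognormal",
      mean = metals$puf, sd = PUF_CV * metals$puf,
      min = metals$puf / 10, max = 4 * metals$puf,
      mode = NA_real_, units = "unitless"
    )
  )
}
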