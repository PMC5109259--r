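# Synthetic field survey generator: site-level concentration records with
# the statistical structure of the bundled multi-land-use summary table,
# so the full pipeline runs end to end without any external data.

#' Bundled concentration summary table
#'
#' Per-stratum, per-metal summary statistics (mean, sd, minimum, maximum,
#' units, number of sites) for a riverine drinking-water-supply survey:
#' four surface-soil land uses (riverbank and private vegetable plots RVS/
#' PVS, riverbank and public green spaces RGS/PGS), the 0-100 cm soil
#' profile feeding the groundwater leaching model, river surface sediments
#' and surface water, for As, Hg, Cd, Zn, Pb, Cu, Cr and Ni.
#'
#' @param path Optional CSV path overriding the bundled table.
#' @return A tibble with columns
#'   `stratum, metal, mean, sd, minimum, maximum, units, n_sites`.
#' @export
concentration_summaries <- function(path = NULL) {
  path <- path %||% system.file("extdata", "shunde_concentration_summaries.csv",
                                package = "rpra", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("stratum", "metal", "mean", "sd", "minimum", "maximum",
              "units", "n_sites")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols)) {
    abort(paste0("summary table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble::as_tibble(out)
}

SOIL_STRATA <- c("RVS", "RGS", "PVS", "PGS", "profile_0_100")
CO_CONTAMINATED <- c("As", "Cd", "Zn", "Pb", "Cu")

#' Generate a synthetic field-survey dataset
#'
#' Draws site-level concentrations per stratum and metal from truncated
#' lognormal distributions matching the summary rows (so minima and maxima
#' round-trip exactly; the realized mean shifts slightly below the declared
#' mean because truncation removes more upper than lower tail). Within each
#' site, rank correlation among the co-sourced metals (As, Cd, Zn, Pb, Cu by
#' default) emulates co-contamination from shared anthropogenic inputs. Soil
#' strata additionally carry a placeholder soil pH, uniform on [5.5, 7.5],
#' which downstream models record but do not use.
#'
#' @param summaries Summary table, see [concentration_summaries()].
#' @param seed Integer seed; the dataset is reproducible given
#'   `(summaries, seed, n_multiplier)`.
#' @param n_multiplier Multiplies each stratum's site count (>= 1), for
#'   large-sample checks of the generator.
#' @param site_correlation Target within-site rank correlation among
#'   `correlated_metals`.
#' @param correlated_metals Metals treated as co-contaminated.
#' @return A long tibble with columns
#'   `site_id, stratum, metal, concentration, units, soil_ph`.
#' @export
generate_field_data <- function(summaries = concentration_summaries(),
                                seed = 42L, n_multiplier = 1,
                                site_correlation = 0.5,
                                correlated_metals = CO_CONTAMINATED) {
  summaries <- tibble::as_tibble(summaries)
  if (n_multiplier < 1) abort("n_multiplier must be >= 1")
  if (any(summaries$maximum < summaries$mean) ||
      any(summaries$minimum > summaries$mean)) {
    abort("infeasible summary: mean outside [minimum, maximum]")
  }

  per_stratum <- split(summaries, summaries$stratum)
  rows <- purrr::imap(per_stratum, function(tab, stratum) {
    n_sites <- round(max(tab$n_sites) * n_multiplier)
    specs <- fit_summary_to_spec(tab)
    draws <- draw_parameter_matrix(
      specs, n = n_sites,
      seed = param_stream_seed(seed, paste0("stratum_", stratum))
    )
    pres <- intersect(paste("conc", stratum, correlated_metals, sep = "_"),
                      names(draws))
    if (length(pres) > 1L && site_correlation != 0) {
      combos <- utils::combn(pres, 2)
      draws <- induce_correlations(
        draws,
        correlation_pairs(combos[1, ], combos[2, ], site_correlation),
        seed = param_stream_seed(seed, paste0("cocontam_", stratum))
      )
    }
    ph <- if (stratum %in% SOIL_STRATA) {
      with_stream(param_stream_seed(seed, paste0("ph_", stratum)),
                  round(runif(n_sites, 5.5, 7.5), 2))
    } else {
      rep(NA_real_, n_sites)
    }
    long <- tidyr::pivot_longer(
      dplyr::mutate(draws,
                    site_id = sprintf("%s_%03d", stratum, seq_len(n_sites)),
                    soil_ph = ph),
      cols = dplyr::starts_with("conc_"),
      names_to = "metal", values_to = "concentration"
    )
    long$metal <- sub(paste0("^conc_", stratum, "_"), "", long$metal)
    long <- dplyr::left_join(long, tab[, c("metal", "units")], by = "metal")
    long$stratum <- stratum
    long[, c("site_id", "stratum", "metal", "concentration", "units", "soil_ph")]
  })
  dplyr::bind_rows(rows)
}

#' Summarize a field dataset back into a summary table
#'
#' Per stratum and metal: mean, sd, minimum, maximum, units and the number
#' of sites. Cells with fewer than two records are omitted with a warning.
#' The output feeds [fit_summary_to_spec()] directly, closing the
#' generate-summarize-sample loop.
#'
#' @param data A long field dataset, see [generate_field_data()] (columns
#'   `site_id, stratum, metal, concentration`; `units` optional).
#' @return A tibble in the layout of [concentration_summaries()].
#' @export
summarize_field_data <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("site_id", "stratum", "metal", "concentration")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("field dataset lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"units" %in% names(data)) data$units <- NA_character_
  out <- data |>
    dplyr::group_by(.data$stratum, .data$metal) |>
    dplyr::summarise(
      mean = mean(.data$concentration), sd = sd(.data$concentration),
      minimum = min(.data$concentration), maximum = max(.data$concentration),
      units = dplyr::first(.data$units),
      n_sites = dplyr::n_distinct(.data$site_id),
      n_records = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_records < 2L)) {
    warn(paste0("stratum/metal cell(s) with fewer than 2 records omitted: ",
                paste(out$stratum[out$n_records < 2L],
                      out$metal[out$n_records < 2L], sep = "/", collapse = ", ")))
    out <- out[out$n_records >= 2L, ]
  }
  out$n_records <- NULL
  out
}
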