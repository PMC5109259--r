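# Scenario assembly: each scenario binds a medium/land-use concentration
# stratum to a receptor and a set of active exposure routes, each route
# naming the exposure-factor columns it reads from the draw matrix.

ROUTES <- c("ingestion", "dermal", "inhalation", "vegetable")

#' Define an exposure scenario
#'
#' A scenario couples one concentration stratum (a land use or medium) to a
#' sensitive receptor and the exposure routes that receptor actually
#' experiences. Each route carries the names of the parameter columns it
#' uses, so the same kernel serves farmers (outdoor frequency, farmer
#' adherence) and swimmers (event frequency, whole-body skin area) without
#' special cases.
#'
#' @param name Scenario label, e.g. `"RVS"` or `"groundwater"`.
#' @param medium One of `"soil"`, `"sediment"`, `"surface_water"`,
#'   `"groundwater"`.
#' @param stratum Concentration stratum the scenario draws from (a `stratum`
#'   value of the summary table; the groundwater scenario uses the 0-100 cm
#'   soil profile and derives its water concentration by leaching).
#' @param receptor Free-text description of the sensitive population.
#' @param routes Named list of routes; each element is a named character
#'   vector mapping kernel arguments to parameter-column names, e.g.
#'   `list(ingestion = c(ir = "IR_s", ef = "EF_oa"))`. Allowed routes:
#'   `ingestion`, `dermal`, `inhalation`, `vegetable`.
#' @return An object of class `rpra_scenario`.
#' @export
scenario_definition <- function(name, medium, stratum, receptor, routes) {
  medium <- match.arg(medium, c("soil", "sediment", "surface_water", "groundwater"))
  bad <- setdiff(names(routes), ROUTES)
  if (length(bad)) {
    abort(paste0("scenario '", name, "': unknown route(s) ",
                 paste(bad, collapse = ", ")))
  }
  if (!length(routes)) abort(paste0("scenario '", name, "' has no routes"))
  if ("vegetable" %in% names(routes) && medium != "soil") {
    abort(paste0("scenario '", name,
                 "': the vegetable route applies only to cultivated soil"))
  }
  if ("inhalation" %in% names(routes) && medium != "soil") {
    abort(paste0("scenario '", name,
                 "': dust inhalation is modelled for soil scenarios only"))
  }
  structure(
    list(name = name, medium = medium, stratum = stratum,
         receptor = receptor, routes = routes),
    class = "rpra_scenario"
  )
}

#' @export
print.rpra_scenario <- function(x, ...) {
  cat("<rpra_scenario> ", x$name, " (", x$medium, ", stratum ", x$stratum,
      ")\n  receptor: ", x$receptor, "\n  routes: ",
      paste(names(x$routes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The default seven-scenario study design
#'
#' Three media and four soil land uses along an urbanized riverine drinking
#' water supply area: riverbank vegetable plots (RVS) and private vegetable
#' plots (PVS) expose farmers through soil ingestion, dermal contact, dust
#' inhalation and vegetable consumption; riverbank and public green spaces
#' (RGS, PGS) expose residents through the first three routes only;
#' groundwater fed by soil leaching exposes drinkers through ingestion only;
#' surface water exposes residents through daily water intake and dermal
#' contact while swimming; river sediments expose swimmers through
#' incidental ingestion and dermal contact. Sediment and water-dermal routes
#' run on the swimming event frequency `EF_sw`, soil routes on the outdoor
#' frequency `EF_oa`, and daily-intake routes (water, vegetables) on the
#' indoor/daily frequency `EF_ia`.
#'
#' @return A named list of seven [scenario_definition()] objects.
#' @export
build_default_study <- function() {
  farmer_soil <- function(name, stratum) {
    scenario_definition(
      name, "soil", stratum, "farmers working the plots",
      routes = list(
        ingestion  = c(ir = "IR_s", ef = "EF_oa"),
        dermal     = c(sa = "SA_o", af = "AF_sa", ef = "EF_oa"),
        inhalation = c(ir = "IR_a", ef = "EF_oa"),
        vegetable  = c(ir = "IR_v", theta = "theta_v", ef = "EF_ia")
      )
    )
  }
  resident_soil <- function(name, stratum) {
    scenario_definition(
      name, "soil", stratum, "residents with regular outdoor activity",
      routes = list(
        ingestion  = c(ir = "IR_s", ef = "EF_oa"),
        dermal     = c(sa = "SA_o", af = "AF_sr", ef = "EF_oa"),
        inhalation = c(ir = "IR_a", ef = "EF_oa")
      )
    )
  }
  list(
    RVS = farmer_soil("RVS", "RVS"),
    RGS = resident_soil("RGS", "RGS"),
    PVS = farmer_soil("PVS", "PVS"),
    PGS = resident_soil("PGS", "PGS"),
    groundwater = scenario_definition(
      "groundwater", "groundwater", "profile_0_100",
      "residents drinking shallow groundwater",
      routes = list(ingestion = c(ir = "IR_w", ef = "EF_ia"))
    ),
    surface_water = scenario_definition(
      "surface_water", "surface_water", "surface_water",
      "residents drinking and swimming in river water",
      routes = list(
        ingestion = c(ir = "IR_w", ef = "EF_ia"),
        dermal    = c(sa = "SA_sw", et = "ET_sw", ef = "EF_sw")
      )
    ),
    sediment = scenario_definition(
      "sediment", "sediment", "sediment",
      "residents contacting sediment while swimming",
      routes = list(
        ingestion = c(ir = "IR_sd", ef = "EF_sw"),
        dermal    = c(sa = "SA_sw", af = "AF_sd", ef = "EF_sw")
      )
    )
  )
}

need_cols <- function(draws, cols, where) {
  missing_cols <- setdiff(cols, names(draws))
  if (length(missing_cols)) {
    abort(paste0(where, ": draw matrix lacks column(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
}

# Per-iteration metal concentration for a scenario (ug/L for groundwater,
# derived by leaching; otherwise the sampled stratum concentration).
scenario_concentration <- function(draws, scenario, metal) {
  conc_col <- paste("conc", scenario$stratum, metal, sep = "_")
  if (scenario$medium == "groundwater") {
    kd_col <- paste0("Kd_", metal)
    need_cols(draws, c(conc_col, kd_col, "theta_w", "rho_b", "DF"),
              paste0("scenario '", scenario$name, "'"))
    conc_groundwater(draws[[conc_col]], draws[[kd_col]],
                     draws[["theta_w"]], draws[["rho_b"]], draws[["DF"]])
  } else {
    need_cols(draws, conc_col, paste0("scenario '", scenario$name, "'"))
    draws[[conc_col]]
  }
}

route_hq <- function(draws, scenario, route, binding, metal, props) {
  conc <- scenario_concentration(draws, scenario, metal)
  need_cols(draws, c(unname(binding[names(binding) != "theta"]),
                     "BW", "ED"),
            paste0("scenario '", scenario$name, "', route '", route, "'"))
  bw <- draws[["BW"]]
  ed <- draws[["ED"]]
  at <- ed * 365  # non-carcinogenic convention

  if (route == "ingestion") {
    hq_ingestion(conc, ir = draws[[binding[["ir"]]]],
                 ef = draws[[binding[["ef"]]]], ed = ed, bw = bw, at = at,
                 rfd = props$rfd_oral, medium = scenario$medium, metal = metal)
  } else if (route == "vegetable") {
    hq_vegetable(conc, puf = draws[[paste0("PUF_", metal)]],
                 ir_v = draws[[binding[["ir"]]]],
                 theta_v = draws[[binding[["theta"]]]],
                 ef = draws[[binding[["ef"]]]], ed = ed, bw = bw, at = at,
                 rfd = props$rfd_oral, metal = metal)
  } else if (route == "dermal" && scenario$medium %in% MEDIA_SOLID) {
    hq_dermal_solid(conc, sa = draws[[binding[["sa"]]]],
                    af = draws[[binding[["af"]]]], abs_frac = props$abs,
                    ef = draws[[binding[["ef"]]]], ed = ed, bw = bw, at = at,
                    rfd_dermal = props$rfd_dermal, metal = metal)
  } else if (route == "dermal") {
    hq_dermal_water(conc, kp = props$kp, sa = draws[[binding[["sa"]]]],
                    et = draws[[binding[["et"]]]],
                    ef_events = draws[[binding[["ef"]]]], ed = ed, bw = bw,
                    at = at, rfd_dermal = props$rfd_dermal, metal = metal)
  } else {
    hq_inhalation(conc, ir_a = draws[[binding[["ir"]]]],
                  ef = draws[[binding[["ef"]]]], ed = ed, bw = bw, at = at,
                  rfd_inhalation = props$rfd_inhalation,
                  pef = draws[["PEF"]], vf = props$vf, metal = metal)
  }
}

#' Compute per-iteration hazard quotients for a study
#'
#' Runs every (scenario, route, metal) combination of the study through its
#' exposure kernel on a shared draw matrix. The vegetable route additionally
#' needs `PUF_<metal>` columns, and the groundwater scenario needs
#' `Kd_<metal>`, `theta_w`, `rho_b` and `DF`.
#'
#' @param draws Draw matrix from [draw_parameter_matrix()].
#' @param study Named list of scenarios, see [build_default_study()].
#' @param metals Metal property table, see [default_metal_properties()].
#' @return A tibble of class `rpra_hq` with columns `scenario, route, metal`
#'   and a list-column `hq` holding one numeric vector per row.
#' @export
compute_study_hq <- function(draws, study = build_default_study(),
                             metals = default_metal_properties()) {
  draws <- tibble::as_tibble(draws)
  rows <- purrr::map(study, function(scenario) {
    purrr::map(names(scenario$routes), function(route) {
      binding <- scenario$routes[[route]]
      purrr::map(metals$metal, function(metal) {
        props <- as.list(metals[metals$metal == metal, ])
        hq_vec <- route_hq(draws, scenario, route, binding, metal, props)
        tibble::tibble(scenario = scenario$name, route = route,
                       metal = metal, hq = list(hq_vec))
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  class(out) <- c("rpra_hq", class(out))
  out
}

#' Total hazard quotient across routes and metals
#'
#' Sums per-iteration hazard quotients within each group, by default per
#' scenario across all routes and metals (the scenario THQ); `by =
#' c("scenario", "metal")` yields per-metal totals. Addition is exact
#' elementwise summation, so the THQ of a single route/metal equals that HQ
#' and removing a route can never increase the THQ.
#'
#' @param hq_tbl An `rpra_hq` tibble from [compute_study_hq()].
#' @param by Grouping columns retained in the output.
#' @return A tibble with the grouping columns and a list-column `thq` of
#'   per-iteration totals.
#' @export
total_hq <- function(hq_tbl, by = "scenario") {
  hq_tbl <- tibble::as_tibble(hq_tbl)
  lens <- unique(lengths(hq_tbl$hq))
  if (length(lens) != 1L) {
    abort("hazard-quotient vectors have mismatched iteration counts")
  }
  hq_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      thq = list(purrr::reduce(.data$hq, `+`)),
      .groups = "drop"
    )
}
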