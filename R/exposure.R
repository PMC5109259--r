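# Hazard-quotient kernels: the chronic-daily-intake / reference-dose models
# for each exposure route, vectorized over Monte Carlo iterations. Every
# kernel returns a dimensionless hazard quotient (or, for the groundwater
# leaching step, a concentration in ug/L). Unit bookkeeping is explicit:
# the medium-specific unit transfer factor is 1e-6 for solids (mg/kg) and
# 1e-3 for waters (ug/L), skin areas convert m2 -> cm2 via 1e4, and the
# water-dermal chain carries ug/L -> mg/cm3 as 1e-6.

MEDIA_SOLID <- c("soil", "sediment")
MEDIA_WATER <- c("surface_water", "groundwater")

#' Medium-specific unit transfer factor
#'
#' `1e-6` converts mg of metal per kg of ingested solid into mg per mg;
#' `1e-3` converts ug/L into mg/L for ingested water.
#'
#' @param medium One of `"soil"`, `"sediment"`, `"surface_water"`,
#'   `"groundwater"`.
#' @return A scalar unit factor.
#' @export
unit_factor <- function(medium) {
  medium <- match.arg(medium, c(MEDIA_SOLID, MEDIA_WATER))
  if (medium %in% MEDIA_SOLID) 1e-6 else 1e-3
}

check_positive <- function(..., .what = "exposure inputs") {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0(.what, ": '", nm, "' must be finite and strictly positive"))
    }
  }
  invisible(TRUE)
}

require_rfd <- function(rfd, route, metal = NULL) {
  if (is.null(rfd) || any(!is.finite(rfd)) || any(rfd <= 0)) {
    abort(paste0("missing or nonpositive reference dose for route '", route,
                 if (!is.null(metal)) paste0("', metal '", metal) else "", "'"))
  }
  invisible(TRUE)
}

#' Hazard quotient for ingestion of soil, sediment or water
#'
#' `HQ = C * IR * EF * ED * UF / (BW * AT * RfD_oral)` with the unit factor
#' chosen by medium ([unit_factor()]). Concentrations are mg/kg for solids
#' and ug/L for waters; declaring `conc_units` that disagree with the medium
#' is an error.
#'
#' @param conc Metal concentration in the medium (mg/kg or ug/L).
#' @param ir Ingestion rate (mg/d for solids, L/d for water).
#' @param ef Exposure frequency (d/yr for routine intake, events/yr for
#'   incidental sediment intake while swimming).
#' @param ed Exposure duration (yr).
#' @param bw Body weight (kg).
#' @param at Averaging time (d).
#' @param rfd Chronic oral reference dose (mg/kg/d).
#' @param medium Exposure medium, determines the unit factor.
#' @param conc_units Optional declared concentration units (`"mg/kg"` or
#'   `"ug/L"`), checked against the medium.
#' @param metal Optional metal name, used in error messages.
#' @return Hazard quotient per iteration (dimensionless).
#' @examples
#' hq_ingestion(conc = 100, ir = 100, ef = 350, ed = 24, bw = 60, at = 8760,
#'              rfd = 3e-4, medium = "soil")
#' @export
hq_ingestion <- function(conc, ir, ef, ed, bw, at, rfd,
                         medium = c(MEDIA_SOLID, MEDIA_WATER),
                         conc_units = NULL, metal = NULL) {
  medium <- match.arg(medium)
  expected <- if (medium %in% MEDIA_SOLID) "mg/kg" else "ug/L"
  if (!is.null(conc_units) && !is.na(conc_units) && conc_units != expected) {
    abort(paste0("concentration units '", conc_units, "' do not match medium '",
                 medium, "' (expected ", expected, ")"))
  }
  if (any(conc < 0)) abort("concentrations must be nonnegative")
  check_positive(ir = ir, ef = ef, ed = ed, bw = bw, at = at)
  require_rfd(rfd, "ingestion", metal)
  conc * ir * ef * ed * unit_factor(medium) / (bw * at * rfd)
}

#' Groundwater concentration from soil leaching
#'
#' Equilibrium soil-to-pore-water partitioning attenuated by a dilution
#' factor: `C_gw = 1000 * C_ts / ((Kd + theta_w / rho_b) * DF)`, in ug/L.
#' The estimate is monotone increasing in the soil-profile concentration and
#' decreasing in sorption and dilution.
#'
#' @param c_ts Metal concentration in the 0-100 cm soil profile (mg/kg).
#' @param kd Soil-water partition coefficient (L/kg).
#' @param theta_w Water-filled soil porosity (L water / L soil).
#' @param rho_b Dry soil bulk density (g/cm3).
#' @param df Dilution factor during transport to the aquifer (unitless).
#' @return Groundwater concentration per iteration (ug/L).
#' @examples
#' conc_groundwater(c_ts = 50, kd = 25, theta_w = 0.3, rho_b = 1.5, df = 20)
#' @export
conc_groundwater <- function(c_ts, kd, theta_w, rho_b, df) {
  if (any(c_ts < 0)) abort("soil concentrations must be nonnegative")
  check_positive(theta_w = theta_w, rho_b = rho_b, df = df,
                 .what = "leaching inputs")
  if (any(!is.finite(kd)) || any(kd < 0)) {
    abort("leaching inputs: 'kd' must be finite and nonnegative")
  }
  denom <- kd + theta_w / rho_b
  if (any(denom <= 0)) abort("kd + theta_w/rho_b must be positive")
  1000 * c_ts / (denom * df)
}

#' Hazard quotient for vegetable consumption
#'
#' Metal transfers from agricultural surface soil into edible tissue through
#' the plant uptake factor (dry-weight basis); the fresh-weight ingestion
#' rate is converted to dry weight via the vegetable water content:
#' `HQ = C_as * PUF * IR_v * (1 - theta_v) * EF * ED / (BW * AT * RfD_oral)`.
#'
#' @param c_as Metal concentration in agricultural surface soil (mg/kg).
#' @param puf Plant uptake factor, plant-dry-weight : soil (unitless).
#' @param ir_v Vegetable ingestion rate, fresh weight (kg/d).
#' @param theta_v Vegetable water content, in `[0, 1)`.
#' @inheritParams hq_ingestion
#' @return Hazard quotient per iteration.
#' @export
hq_vegetable <- function(c_as, puf, ir_v, theta_v, ef, ed, bw, at, rfd,
                         metal = NULL) {
  if (any(theta_v >= 1) || any(theta_v < 0)) {
    abort("vegetable water content theta_v must lie in [0, 1)")
  }
  if (any(c_as < 0) || any(puf < 0)) {
    abort("soil concentration and plant uptake factor must be nonnegative")
  }
  check_positive(ir_v = ir_v, ef = ef, ed = ed, bw = bw, at = at)
  require_rfd(rfd, "vegetable", metal)
  c_as * puf * ir_v * (1 - theta_v) * ef * ed / (bw * at * rfd)
}

#' Hazard quotient for dermal contact with soil or sediment
#'
#' `HQ = C * (SA * 1e4) * AF * ABS * EF * ED * 1e-6 / (BW * AT * RfD_dermal)`;
#' skin surface area is supplied in m2 and converted to cm2 internally.
#'
#' @param sa Exposed skin surface area (m2).
#' @param af Soil(or sediment)-to-skin adherence factor (mg/cm2).
#' @param abs_frac Dermal absorption fraction (unitless).
#' @param rfd_dermal Chronic dermal reference dose (mg/kg/d).
#' @inheritParams hq_ingestion
#' @return Hazard quotient per iteration.
#' @export
hq_dermal_solid <- function(conc, sa, af, abs_frac, ef, ed, bw, at,
                            rfd_dermal, metal = NULL) {
  if (any(conc < 0) || any(abs_frac < 0)) {
    abort("concentration and absorption fraction must be nonnegative")
  }
  check_positive(sa = sa, af = af, ef = ef, ed = ed, bw = bw, at = at)
  require_rfd(rfd_dermal, "dermal", metal)
  conc * (sa * 1e4) * af * abs_frac * ef * ed * 1e-6 / (bw * at * rfd_dermal)
}

#' Hazard quotient for dermal contact with water
#'
#' `HQ = C * Kp * (SA * 1e4) * ET * EF_sw * ED * 1e-6 / (BW * AT * RfD_dermal)`.
#' The combined `1e-6` factor is the ug -> mg conversion (`1e-3`) times the
#' L -> cm3 conversion (`1e-3`) that turns ug/L into mg/cm3, so the absorbed
#' dose `C * Kp * SA * ET` comes out in mg per event-day.
#'
#' @param kp Dermal permeability constant of the metal in water (cm/h).
#' @param et Water-contact time per event (h/event).
#' @param ef_events Event frequency (events/yr).
#' @inheritParams hq_dermal_solid
#' @return Hazard quotient per iteration.
#' @export
hq_dermal_water <- function(conc, kp, sa, et, ef_events, ed, bw, at,
                            rfd_dermal, metal = NULL) {
  if (any(conc < 0)) abort("concentrations must be nonnegative")
  if (is.null(kp) || any(!is.finite(kp)) || any(kp < 0)) {
    abort(paste0("dermal permeability constant missing",
                 if (!is.null(metal)) paste0(" for metal '", metal, "'") else ""))
  }
  check_positive(sa = sa, et = et, ef_events = ef_events, ed = ed,
                 bw = bw, at = at)
  require_rfd(rfd_dermal, "dermal (water)", metal)
  conc * kp * (sa * 1e4) * et * ef_events * ed * 1e-6 / (bw * at * rfd_dermal)
}

#' Hazard quotient for inhalation of soil dust and vapor
#'
#' Airborne exposure concentration combines the particulate (dust) pathway
#' and, where a volatilization factor exists (elemental Hg), the vapor
#' pathway additively:
#' `HQ = C * IR_a * EF * ED * (1/PEF + 1/VF) / (BW * AT * RfD_inhalation)`,
#' with the `1/VF` term zero for metals without a volatilization factor.
#'
#' @param ir_a Air inhalation rate (m3/d).
#' @param pef Particulate emission factor (m3/kg).
#' @param vf Volatilization factor (m3/kg) or `NA` for non-volatile metals.
#' @param rfd_inhalation Chronic inhalation reference dose (mg/kg/d).
#' @inheritParams hq_ingestion
#' @return Hazard quotient per iteration.
#' @export
hq_inhalation <- function(conc, ir_a, ef, ed, bw, at, rfd_inhalation,
                          pef, vf = NA_real_, metal = NULL) {
  if (any(conc < 0)) abort("concentrations must be nonnegative")
  check_positive(ir_a = ir_a, ef = ef, ed = ed, bw = bw, at = at, pef = pef)
  require_rfd(rfd_inhalation, "inhalation", metal)
  inv_vf <- if (length(vf) == 1L && !is.finite(vf)) 0 else {
    ifelse(is.finite(vf) & vf > 0, 1 / vf, 0)
  }
  conc * ir_a * ef * ed * (1 / pef + inv_vf) / (bw * at * rfd_inhalation)
}
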