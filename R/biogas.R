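#' Unit conversion constants
#'
#' `KWH_TO_MJ` converts kWh to MJ (3.6). `CH4_LHV_MJ_M3` is the lower heating
#' value of methane, 35.9 MJ per m3, used only as a sanity bound on CHP output.
#' `EUR_TO_USD` is the currency factor retained for display (1 EUR = 1.1 USD);
#' all computation is in USD.
#'
#' @name conversion-constants
#' @export
KWH_TO_MJ <- 3.6

#' @rdname conversion-constants
#' @export
CH4_LHV_MJ_M3 <- 35.9

#' @rdname conversion-constants
#' @export
EUR_TO_USD <- 1.1

#' Specify a co-digestion biogas/CHP plant
#'
#' Describes a wet single-stage mesophilic digester co-digesting fish residue
#' with liquid cattle manure, with a micro-turbine converting the biogas to
#' heat and power. All per-tonne outputs are keyed to t_RM, the tonne of fish
#' co-stream entering the upstream processing plant; `residue_input` and
#' `manure_input` give the digester feed on the same basis.
#'
#' @param residue_input Fish residue fed, t per t_RM (1.0 when the whole
#'   co-stream is digested; 0.13 for the two-stage concept's solid residue).
#' @param manure_input Cattle manure fed, t per t_RM.
#' @param biogas_yield Biogas yield, m3 per t of feed mixture (default 88).
#' @param methane_fraction Methane volume fraction of the biogas (default 0.65).
#' @param heat_output CHP heat output, kWh per t_RM.
#' @param electricity_output CHP electricity output, kWh per t_RM.
#' @param fertiliser_output Digestate returned as fertiliser, kg per t_RM.
#' @param digester_volume Digester volume, m3.
#' @param organic_loading_rate kg volatile solids per m3 per day.
#' @param ts_input Total-solids mass fraction of the feed mixture.
#' @param self_consumption_energy Plant parasitic energy, MJ per t_RM.
#' @param self_consumption_electricity Plant parasitic electricity, kWh per t_RM.
#' @return A `biogas_plant_spec` object.
#' @export
biogas_plant_spec <- function(residue_input,
                              manure_input = 5 * residue_input,
                              biogas_yield = 88,
                              methane_fraction = 0.65,
                              heat_output,
                              electricity_output,
                              fertiliser_output = 0,
                              digester_volume = 2300,
                              organic_loading_rate = 2,
                              ts_input = 0.121,
                              self_consumption_energy = 0,
                              self_consumption_electricity = 0) {
  obj <- structure(
    list(residue_input = residue_input, manure_input = manure_input,
         residue_to_manure_ratio = manure_input / residue_input,
         biogas_yield = biogas_yield, methane_fraction = methane_fraction,
         heat_output = heat_output, electricity_output = electricity_output,
         fertiliser_output = fertiliser_output,
         digester_volume = digester_volume,
         organic_loading_rate = organic_loading_rate, ts_input = ts_input,
         self_consumption_energy = self_consumption_energy,
         self_consumption_electricity = self_consumption_electricity),
    class = "biogas_plant_spec"
  )
  validate_biogas_plant_spec(obj)
  obj
}

#' Validate a biogas plant specification
#'
#' Checks that the methane fraction is a proper fraction, all outputs are
#' non-negative, and the CHP heat + electricity (in MJ) does not exceed the
#' chemical energy of the methane produced at LHV 35.9 MJ/m3.
#'
#' @param x A `biogas_plant_spec`.
#' @return `x`, invisibly, if valid.
#' @export
validate_biogas_plant_spec <- function(x) {
  num <- unlist(x[c("residue_input", "manure_input", "biogas_yield",
                    "heat_output", "electricity_output", "fertiliser_output",
                    "self_consumption_energy", "self_consumption_electricity")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("biogas plant quantities must be finite and non-negative", call. = FALSE)
  if (!is.finite(x$methane_fraction) ||
      x$methane_fraction <= 0 || x$methane_fraction >= 1)
    stop("methane_fraction must lie strictly between 0 and 1", call. = FALSE)
  if (x$residue_input > 0) {
    methane_mj <- (x$residue_input + x$manure_input) * x$biogas_yield *
      x$methane_fraction * CH4_LHV_MJ_M3
    chp_mj <- (x$heat_output + x$electricity_output) * KWH_TO_MJ
    if (chp_mj > methane_mj + 1e-9)
      stop("CHP heat+electricity (", round(chp_mj, 1),
           " MJ/tRM) exceeds methane chemical energy (",
           round(methane_mj, 1), " MJ/tRM)", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.biogas_plant_spec <- function(x, ...) {
  cat("<biogas_plant_spec>\n")
  cat(sprintf("  feed: %.3g t residue + %.3g t manure per t_RM (1:%.3g)\n",
              x$residue_input, x$manure_input, x$residue_to_manure_ratio))
  cat(sprintf("  biogas %.3g m3/t mixture, CH4 %.1f v.%%\n",
              x$biogas_yield, 100 * x$methane_fraction))
  cat(sprintf("  CHP: heat %.4g, electricity %.4g kWh/tRM; digestate %.4g kg/tRM\n",
              x$heat_output, x$electricity_output, x$fertiliser_output))
  invisible(x)
}

#' Combined heat and power output of the digestion plant
#'
#' Computes biogas, methane, heat and electricity for a given digester feed.
#' Biogas is feed mass times yield; methane is biogas times the methane
#' fraction. Heat and electricity scale linearly with the residue mass
#' relative to the specification's per-t_RM basis.
#'
#' @param residue_mass Fish residue fed, t.
#' @param manure_mass Cattle manure fed, t.
#' @param spec A `biogas_plant_spec`.
#' @param ratio_tol Relative tolerance on the residue:manure ratio before a
#'   warning is emitted (default 0.05).
#' @return A list with `biogas` (m3), `methane` (m3), `heat` (kWh),
#'   `electricity` (kWh).
#' @export
#' @examples
#' spec <- load_concept("I")$biogas
#' chp_output(1, 5, spec)  # 528 m3 biogas, 1213 kWh electricity
chp_output <- function(residue_mass, manure_mass, spec, ratio_tol = 0.05) {
  stopifnot(inherits(spec, "biogas_plant_spec"))
  if (!is.numeric(residue_mass) || !is.numeric(manure_mass) ||
      is.na(residue_mass) || is.na(manure_mass) ||
      residue_mass < 0 || manure_mass < 0)
    stop("feed masses must be non-negative numbers", call. = FALSE)
  if (residue_mass > 0) {
    ratio <- manure_mass / residue_mass
    if (abs(ratio - spec$residue_to_manure_ratio) >
        ratio_tol * spec$residue_to_manure_ratio)
      warning(sprintf(
        "feed ratio 1:%.2f deviates from the specified 1:%.2f", ratio,
        spec$residue_to_manure_ratio), call. = FALSE)
  }
  feed <- residue_mass + manure_mass
  scale <- if (spec$residue_input > 0) residue_mass / spec$residue_input else 0
  biogas <- feed * spec$biogas_yield
  list(biogas = biogas,
       methane = biogas * spec$methane_fraction,
       heat = spec$heat_output * scale,
       electricity = spec$electricity_output * scale)
}

#' Biomass energy potential of the CHP plant
#'
#' The energy potential realised from the digested biomass: CHP heat plus
#' electricity, converted to MJ per t_RM at 3.6 MJ/kWh.
#'
#' @param spec A `biogas_plant_spec`, or `NULL` (returns 0: no biogas branch).
#' @return Energy potential in MJ per t_RM.
#' @export
#' @examples
#' biomass_energy(load_concept("I")$biogas)  # (1562 + 1213) * 3.6 = 9990
biomass_energy <- function(spec) {
  if (is.null(spec)) return(0)
  stopifnot(inherits(spec, "biogas_plant_spec"))
  (spec$heat_output + spec$electricity_output) * KWH_TO_MJ
}
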