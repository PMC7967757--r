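#' Chemical composition of a digester feedstock
#'
#' Total solids, volatile solids, nutrients and fat of a feedstock (salmon
#' backbones, liquid cattle manure). Percentages are mass fractions of wet
#' weight (`ts`) or of total solids (`vs_of_ts`, `organic_c`); nutrients are
#' mg per kg wet weight.
#'
#' @param ts Total solids, wt.% (0-100).
#' @param vs_of_ts Volatile solids, wt.% of TS.
#' @param organic_c Organic carbon, wt.% of TS.
#' @param n,p,k Total nitrogen, phosphorus, potassium, mg/kg.
#' @param fat Fat, wt.%.
#' @param minor Named numeric vector of minor elements (mg/kg or wt.%).
#' @return A `feedstock_composition` object.
#' @export
feedstock_composition <- function(ts, vs_of_ts, organic_c, n, p, k,
                                  fat = 0, minor = numeric()) {
  vals <- c(ts = ts, vs_of_ts = vs_of_ts, organic_c = organic_c,
            n = n, p = p, k = k, fat = fat)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("composition values must be finite and non-negative", call. = FALSE)
  if (ts > 100 || vs_of_ts > 100)
    stop("ts and vs_of_ts are percentages and cannot exceed 100", call. = FALSE)
  structure(list(ts = ts, vs_of_ts = vs_of_ts, organic_c = organic_c,
                 n = n, p = p, k = k, fat = fat, minor = minor),
            class = "feedstock_composition")
}

#' Specify the receiving farms
#'
#' One farm of the regional system: arable area growing barley, its nutrient
#' requirement, the cattle manure produced, and the mixed-mineral-fertiliser
#' application rates on the manured and mineral-only sub-areas.
#'
#' @param n_farms Number of identical farms (default 4).
#' @param area_per_farm Arable area per farm, ha.
#' @param nutrient_requirement Named vector `c(N=, P=, K=)` in kg/ha.
#' @param manure_per_farm Manure produced per farm, t/a.
#' @param manure_application_rate Manure spread rate, t/ha.
#' @param mixed_fertiliser_rate_manured Mixed mineral fertiliser on the
#'   manured area, kg/ha.
#' @param mixed_fertiliser_rate_mineral_only Mixed mineral fertiliser on the
#'   area receiving no manure, kg/ha.
#' @param manured_area Manured sub-area, ha.
#' @param mineral_only_area Mineral-fertilised sub-area, ha. Together with
#'   `manured_area` it must sum to `area_per_farm`.
#' @return A `farm_spec` object.
#' @export
farm_spec <- function(n_farms = 4,
                      area_per_farm = 600,
                      nutrient_requirement = c(N = 110, P = 40, K = 80),
                      manure_per_farm = 12000,
                      manure_application_rate = 30,
                      mixed_fertiliser_rate_manured = 484,
                      mixed_fertiliser_rate_mineral_only = 534,
                      manured_area = 400,
                      mineral_only_area = 200) {
  vals <- c(n_farms, area_per_farm, manure_per_farm, manure_application_rate,
            mixed_fertiliser_rate_manured, mixed_fertiliser_rate_mineral_only,
            manured_area, mineral_only_area, nutrient_requirement)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("farm specification values must be finite and non-negative", call. = FALSE)
  if (abs(manured_area + mineral_only_area - area_per_farm) > 1e-9)
    stop("manured_area + mineral_only_area must equal area_per_farm", call. = FALSE)
  structure(list(
    n_farms = n_farms, area_per_farm = area_per_farm,
    nutrient_requirement = nutrient_requirement,
    manure_per_farm = manure_per_farm,
    manure_application_rate = manure_application_rate,
    mixed_fertiliser_rate_manured = mixed_fertiliser_rate_manured,
    mixed_fertiliser_rate_mineral_only = mixed_fertiliser_rate_mineral_only,
    manured_area = manured_area, mineral_only_area = mineral_only_area
  ), class = "farm_spec")
}

#' @export
print.farm_spec <- function(x, ...) {
  cat(sprintf("<farm_spec> %d farm(s) x %g ha (%g manured @ %g kg/ha + %g mineral-only @ %g kg/ha)\n",
              x$n_farms, x$area_per_farm, x$manured_area,
              x$mixed_fertiliser_rate_manured, x$mineral_only_area,
              x$mixed_fertiliser_rate_mineral_only))
  invisible(x)
}
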