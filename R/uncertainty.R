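#' Default factor-to-price mapping
#'
#' Maps the five varied market factors to the price-table items they move:
#' the raw-material factor moves the fish co-stream price; the energy factor
#' moves electricity (and, through the correlation groups, mineral
#' fertilisers and formic acid); fish oil moves both oil qualities; fish
#' protein moves hydrolysate and concentrate; fish meal moves meal and
#' silage.
#'
#' @return Named list: factor -> character vector of price items.
#' @export
default_factor_map <- function() {
  list(
    raw_material = "fish_costream",
    energy = "electricity",
    fish_oil = c("premium_oil", "oil"),
    fish_protein = c("fish_protein_hydrolysate", "fish_protein_concentrate"),
    fish_meal = c("meal", "silage")
  )
}

#' Configure the price-uncertainty analysis
#'
#' @param varied_factors Factors to vary; must be names of `factor_map`.
#' @param variation Half-width of the multiplicative price band (default
#'   0.20, i.e. prices move within +/-20%). Must satisfy `0 <= variation < 1`.
#' @param distribution Sampling distribution of the multiplier within
#'   `[1 - variation, 1 + variation]`: `"uniform"` (default) or
#'   `"triangular"` (mode 1).
#' @param iterations Number of Monte Carlo draws (default 10000).
#' @param seed Integer seed for the run.
#' @param correlation_groups Named character vector mapping a price item to
#'   the factor whose multiplier it reuses (default: mineral fertilisers and
#'   formic acid follow the energy price).
#' @param factor_map Factor-to-price-item mapping, by default
#'   [default_factor_map()].
#' @return An `uncertainty_config` object.
#' @export
uncertainty_config <- function(varied_factors = names(default_factor_map()),
                               variation = 0.20,
                               distribution = c("uniform", "triangular"),
                               iterations = 10000,
                               seed = 1L,
                               correlation_groups = c(
                                 mineral_fertilisers = "energy",
                                 formic_acid = "energy"),
                               factor_map = default_factor_map()) {
  distribution <- match.arg(distribution)
  if (!is.numeric(variation) || variation < 0 || variation >= 1)
    stop("variation must satisfy 0 <= variation < 1", call. = FALSE)
  if (!is.numeric(iterations) || iterations < 1)
    stop("iterations must be at least 1", call. = FALSE)
  unknown <- setdiff(varied_factors, names(factor_map))
  if (length(unknown))
    stop("unknown factor name(s): ", paste(unknown, collapse = ", "),
         "; known factors: ", paste(names(factor_map), collapse = ", "),
         call. = FALSE)
  bad_drv <- setdiff(unname(correlation_groups), names(factor_map))
  if (length(bad_drv))
    stop("correlation driver(s) not in factor_map: ",
         paste(bad_drv, collapse = ", "), call. = FALSE)
  structure(list(varied_factors = varied_factors, variation = variation,
                 distribution = distribution,
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 correlation_groups = correlation_groups,
                 factor_map = factor_map),
            class = "uncertainty_config")
}

# one multiplier per varied factor, consumed in factor-name-sorted order so
# results are stable regardless of the order factors were configured in
draw_multipliers <- function(cfg) {
  factors <- sort(cfg$varied_factors)
  v <- cfg$variation
  m <- vapply(factors, function(f) {
    if (cfg$distribution == "uniform") stats::runif(1, 1 - v, 1 + v)
    else 1 + v * (stats::runif(1) + stats::runif(1) - 1)
  }, numeric(1))
  stats::setNames(m, factors)
}

# apply a named multiplier vector to a price table
apply_multipliers <- function(base, cfg, multipliers) {
  out <- base
  for (f in names(multipliers)) {
    items <- cfg$factor_map[[f]]
    sel <- out$item %in% items
    out$price[sel] <- out$price[sel] * multipliers[[f]]
  }
  for (item in names(cfg$correlation_groups)) {
    driver <- cfg$correlation_groups[[item]]
    if (driver %in% names(multipliers)) {
      sel <- out$item == item
      out$price[sel] <- out$price[sel] * multipliers[[driver]]
    }
  }
  out
}

#' Draw a perturbed price table
#'
#' Multiplies each varied factor's price items by an independent draw from
#' `[1 - variation, 1 + variation]`; correlated items (by default mineral
#' fertilisers and formic acid) reuse their driver factor's multiplier.
#' Unvaried prices are untouched. Draws are consumed from the current RNG
#' stream in factor-name-sorted order; pass `multipliers` to bypass drawing.
#'
#' @param base A `price_table`.
#' @param cfg An `uncertainty_config`.
#' @param multipliers Optional named multiplier vector (one per varied
#'   factor) to apply instead of drawing.
#' @return A perturbed `price_table`.
#' @export
#' @examples
#' cfg <- uncertainty_config(seed = 7)
#' sample_prices(default_prices(), cfg,
#'               multipliers = c(energy = 1.2))  # fertilisers move with energy
sample_prices <- function(base, cfg, multipliers = NULL) {
  stopifnot(inherits(base, "price_table"), inherits(cfg, "uncertainty_config"))
  if (is.null(multipliers)) {
    multipliers <- draw_multipliers(cfg)
  } else {
    unknown <- setdiff(names(multipliers), names(cfg$factor_map))
    if (length(unknown))
      stop("unknown factor name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  apply_multipliers(base, cfg, multipliers)
}

#' Monte Carlo profit distribution
#'
#' Re-evaluates the full economic statement of a scenario under repeated
#' price draws. The deterministic baseline is computed first and recorded
#' unchanged; for a fixed seed the sample vector is reproducible, and the
#' sample stream does not depend on how iterations are chunked.
#'
#' @param scenario A `scenario_config`.
#' @param cfg An `uncertainty_config`.
#' @return A `profit_distribution`: list with `samples` (USD/a), `mean`,
#'   `sd`, `quantiles` (5/50/95%), `baseline`, `iterations`.
#' @export
#' @examples
#' run_monte_carlo(load_concept("IV"),
#'                 uncertainty_config(iterations = 200, seed = 1))
run_monte_carlo <- function(scenario, cfg) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(cfg, "uncertainty_config"))
  if (cfg$iterations < 1)
    stop("iterations must be at least 1", call. = FALSE)
  baseline <- economic_statement(scenario)$profit
  samples <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$iterations), function(i) {
      prices <- apply_multipliers(scenario$prices, cfg, draw_multipliers(cfg))
      economic_statement(scenario, prices = prices)$profit
    }, numeric(1))
  })
  structure(list(
    samples = samples,
    mean = mean(samples),
    sd = stats::sd(samples),
    quantiles = stats::quantile(samples, c(0.05, 0.5, 0.95), names = TRUE),
    baseline = baseline,
    iterations = cfg$iterations
  ), class = "profit_distribution")
}

#' @export
print.profit_distribution <- function(x, ...) {
  m <- function(v) sprintf("%.2f", v / 1e6)
  cat(sprintf("<profit_distribution> %d draws (million USD per year)\n",
              x$iterations))
  cat(sprintf("  baseline %s | mean %s | sd %s\n",
              m(x$baseline), m(x$mean), m(x$sd)))
  cat(sprintf("  q05 %s | median %s | q95 %s\n",
              m(x$quantiles[1]), m(x$quantiles[2]), m(x$quantiles[3])))
  invisible(x)
}

#' One-at-a-time sensitivity ranking
#'
#' Evaluates the profit with each varied factor pushed to its lower and upper
#' price bound while all other prices stay at baseline. Factors are ranked by
#' the swing `|profit_high - profit_low|`; ties are broken by factor name
#' order.
#'
#' @param scenario A `scenario_config`.
#' @param cfg An `uncertainty_config`.
#' @return A `sensitivity_result` data frame with columns `factor`,
#'   `profit_low`, `profit_high`, `swing`, `rank`, ordered by rank;
#'   attribute `baseline` carries the deterministic profit.
#' @export
#' @examples
#' sensitivity_ranking(load_concept("IV"), uncertainty_config())
sensitivity_ranking <- function(scenario, cfg) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(cfg, "uncertainty_config"))
  baseline <- economic_statement(scenario)$profit
  v <- cfg$variation
  factors <- sort(cfg$varied_factors)
  eval_at <- function(f, mult) {
    m <- stats::setNames(mult, f)
    economic_statement(
      scenario, prices = apply_multipliers(scenario$prices, cfg, m))$profit
  }
  lo <- vapply(factors, eval_at, numeric(1), mult = 1 - v)
  hi <- vapply(factors, eval_at, numeric(1), mult = 1 + v)
  swing <- abs(hi - lo)
  ord <- order(-swing, factors)
  out <- data.frame(factor = factors[ord],
                    profit_low = unname(lo[ord]),
                    profit_high = unname(hi[ord]),
                    swing = unname(swing[ord]),
                    rank = seq_along(factors),
                    stringsAsFactors = FALSE)
  class(out) <- c("sensitivity_result", "data.frame")
  attr(out, "baseline") <- baseline
  out
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> baseline profit %.2f million USD/a\n",
              attr(x, "baseline") / 1e6))
  df <- data.frame(factor = x$factor,
                   low = sprintf("%.2f", x$profit_low / 1e6),
                   high = sprintf("%.2f", x$profit_high / 1e6),
                   swing = sprintf("%.2f", x$swing / 1e6),
                   rank = x$rank)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
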