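#' Fuel draws for producing the reported harvest
#'
#' Treats every harvest report as one successful trip and evaluates the
#' fuel regression at each report's edible weight. Draw `d` of the total
#' uses draw `d` of both the kilogram matrix and the regression
#' coefficients, so the two posteriors propagate jointly.
#'
#' @param kg_draws matrix draws x reports of positive kilograms.
#' @param trip_posterior a `trip_posterior` with the same number of draws.
#' @return vector of total successful-trip fuel (litres), one per draw.
#' @export
harvest_fuel_draws <- function(kg_draws, trip_posterior) {
  d <- trip_posterior$draws
  if (nrow(kg_draws) != nrow(d)) {
    stop("harvest_fuel_draws: draw-count mismatch between kg draws (",
         nrow(kg_draws), ") and trip posterior (", nrow(d), ")",
         call. = FALSE)
  }
  if (ncol(kg_draws) == 0) return(rep(0, nrow(d)))
  if (any(kg_draws <= 0)) {
    stop("harvest_fuel_draws: kg draws must be positive", call. = FALSE)
  }
  log_kg <- log(kg_draws)
  rowSums(exp(d$a + d$b * log_kg))
}

#' Total fuel including unobserved failed trips
#'
#' Adds, per draw, the fuel of the negative-binomial number of failed
#' trips expected to accompany the reported (successful) harvests.
#'
#' @param success_fuel_draws vector from [harvest_fuel_draws()].
#' @param n_reports number of harvest reports (treated as successes).
#' @param trip_posterior a `trip_posterior` aligned with
#'   `success_fuel_draws`.
#' @param seed integer RNG seed for the failure simulation.
#' @return list with vectors `total`, `success`, `failed` (litres) and
#'   `n_failed` (counts), one element per draw.
#' @export
total_fuel_with_failures <- function(success_fuel_draws, n_reports,
                                     trip_posterior, seed = 1) {
  if (length(success_fuel_draws) != nrow(trip_posterior$draws)) {
    stop("total_fuel_with_failures: draw-count mismatch", call. = FALSE)
  }
  fails <- simulate_failures(n_reports, trip_posterior, seed = seed)
  list(total = success_fuel_draws + fails$failed_fuel_l,
       success = success_fuel_draws,
       failed = fails$failed_fuel_l,
       n_failed = fails$n_failed)
}

#' Gasoline cost draws
#'
#' @param fuel_draws vector of litres per draw.
#' @param price_cad_per_l positive price per litre.
#' @return vector of CAD per draw.
#' @export
gasoline_cost <- function(fuel_draws, price_cad_per_l) {
  if (!is.finite(price_cad_per_l) || price_cad_per_l <= 0) {
    stop("gasoline_cost: price must be positive", call. = FALSE)
  }
  fuel_draws * price_cad_per_l
}

#' Gasoline emissions draws (combustion plus shipping)
#'
#' Per litre: combustion emissions plus the emissions of shipping the
#' gasoline itself along the configured route (litres converted to
#' kilograms by density, times distance, times the per-kg-per-km factor of
#' each leg's mode at the chosen endpoint).
#'
#' @param fuel_draws vector of litres per draw.
#' @param fuel_config a `fuel_emission_config` from [harvest_config()].
#' @param endpoint `"low"` or `"high"` transport-emission endpoint.
#' @return vector of kg CO2e per draw.
#' @export
gasoline_emissions <- function(fuel_draws, fuel_config,
                               endpoint = c("low", "high")) {
  endpoint <- match.arg(endpoint)
  shipping_per_kg <- sum(vapply(fuel_config$route, function(leg) {
    ef <- fuel_config$transport_ef[[leg$mode]][[endpoint]]
    if (is.null(ef)) {
      stop("gasoline_emissions: no '", endpoint, "' factor for mode '",
           leg$mode, "'", call. = FALSE)
    }
    leg$km * ef
  }, numeric(1)))
  per_l <- fuel_config$combustion_ef_kg_per_l +
    fuel_config$gasoline_density_kg_per_l * shipping_per_kg
  fuel_draws * per_l
}
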