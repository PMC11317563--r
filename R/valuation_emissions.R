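#' Edible-weight draws per report
#'
#' Multiplies each latent harvest-count draw by the edible weight of the
#' species concerned (per species, not pooled by species type).
#'
#' @param deheap a `deheap_posterior`.
#' @param reports the harvest-report table the posterior was fitted to.
#' @param species validated species table.
#' @return matrix draws x reports of kilograms, columns named by report_id.
#' @export
edible_weight_draws <- function(deheap, reports, species) {
  resolve_species(reports, species)
  if (!identical(reports$report_id, deheap$report_id)) {
    stop("edible_weight_draws: reports do not match the posterior's reports",
         call. = FALSE)
  }
  w <- species$edible_weight_kg_per_animal[
    match(reports$species_code, species$species_code)]
  sweep(deheap$draws, 2, w, `*`)
}

## Per-report multiplier lookup shared by value and emissions propagation.
.report_categories <- function(reports, species) {
  species$replacement_category[match(reports$species_code,
                                     species$species_code)]
}

.report_classes <- function(reports, species) {
  species$taxon_class[match(reports$species_code, species$species_code)]
}

#' Substitution-value draws (CAD)
#'
#' Per draw and report: kilograms times the community price of the
#' replacement category, times the CPI adjustment.
#'
#' @param kg_draws matrix from [edible_weight_draws()].
#' @param reports harvest-report table (needs `community`).
#' @param species validated species table.
#' @param prices price table.
#' @param cpi_factor CPI adjustment factor.
#' @return matrix draws x reports of CAD.
#' @export
substitution_value <- function(kg_draws, reports, species, prices,
                               cpi_factor) {
  require_columns(reports, "community", "substitution_value")
  cat <- .report_categories(reports, species)
  key <- paste(reports$community, cat)
  pkey <- paste(prices$community, prices$replacement_category)
  pi <- match(key, pkey)
  if (any(is.na(pi))) {
    miss <- unique(key[is.na(pi)])
    stop("substitution_value: no price for (community, category): ",
         paste(miss, collapse = "; "), call. = FALSE)
  }
  price <- prices$price_cad_per_kg[pi]
  sweep(kg_draws, 2, price * cpi_factor, `*`)
}

#' Replacement-food emissions draws (kg CO2e)
#'
#' Per draw and report: kilograms times the scenario's per-kilogram
#' emission factor, which is the production ("to the farmgate" plus
#' processing) factor of the replacement category plus the transport term
#' summed over the community's route legs (distance times per-kg-per-km
#' factor for the leg's mode).
#'
#' @param kg_draws matrix from [edible_weight_draws()].
#' @param reports harvest-report table (needs `community`).
#' @param species validated species table.
#' @param scenario one `emission_scenario` from a [harvest_config()].
#' @return matrix draws x reports of kg CO2e.
#' @export
replacement_emissions <- function(kg_draws, reports, species, scenario) {
  require_columns(reports, "community", "replacement_emissions")
  cat <- .report_categories(reports, species)
  communities <- unique(reports$community)
  missing_route <- setdiff(communities, names(scenario$route_legs))
  if (length(missing_route) > 0) {
    stop("replacement_emissions: scenario '", scenario$label,
         "' has no route for: ", paste(missing_route, collapse = ", "),
         call. = FALSE)
  }
  transport_per_kg <- vapply(scenario$route_legs, function(legs) {
    sum(vapply(legs, function(l) l$km * scenario$transport_ef[[l$mode]],
               numeric(1)))
  }, numeric(1))
  ef <- scenario$production_ef[cat] +
    transport_per_kg[reports$community]
  sweep(kg_draws, 2, unname(ef), `*`)
}

#' Aggregate per-report draws by taxon class
#'
#' @param report_draws matrix draws x reports.
#' @param classes taxon class per report (e.g. from the species table).
#' @return matrix draws x (classes..., total); class columns sum exactly
#'   to the total in every draw.
#' @export
class_totals <- function(report_draws, classes) {
  stopifnot(ncol(report_draws) == length(classes))
  levels <- intersect(TAXON_CLASSES, unique(classes))
  out <- vapply(levels, function(cl) {
    rowSums(report_draws[, classes == cl, drop = FALSE])
  }, numeric(nrow(report_draws)))
  out <- cbind(out, total = rowSums(report_draws))
  out
}

#' Highest posterior density interval
#'
#' The shortest interval containing the stated mass of the sorted draws.
#' The interval spans `ceiling(mass * n)` inter-draw gaps (so
#' `ceiling(mass * n) + 1` draws); ties in width are broken by the lowest
#' start index.
#'
#' @param draws numeric vector of at least 10 posterior draws.
#' @param mass interval mass in (0, 1), default 0.90.
#' @return named vector `c(low, high)`.
#' @export
hpdi <- function(draws, mass = 0.90) {
  if (length(draws) < 10) {
    stop("hpdi: need at least 10 draws", call. = FALSE)
  }
  if (!is.finite(mass) || mass <= 0 || mass >= 1) {
    stop("hpdi: mass must be in (0, 1)", call. = FALSE)
  }
  x <- sort(draws)
  n <- length(x)
  gap <- min(ceiling(mass * n), n - 1)
  widths <- x[(1 + gap):n] - x[1:(n - gap)]
  i <- which.min(widths)   # which.min returns the first (lowest) minimum
  c(low = x[i], high = x[i + gap])
}

#' Summarise posterior draws
#'
#' @param draws numeric vector of draws.
#' @param label estimand name.
#' @param units unit string carried into the output.
#' @param mass HPDI mass.
#' @return one-row data frame: label, units, mean, sd, hpdi_low, hpdi_high.
#' @export
summarize_draws <- function(draws, label, units, mass = 0.90) {
  if (length(draws) == 0) {
    stop("summarize_draws: empty draws", call. = FALSE)
  }
  h <- hpdi(draws, mass)
  data.frame(label = label, units = units,
             mean = mean(draws), sd = sd(draws),
             hpdi_low = unname(h["low"]), hpdi_high = unname(h["high"]),
             stringsAsFactors = FALSE)
}

#' Summarise class totals of per-report draws
#'
#' Convenience wrapper producing one summary row per taxon class plus the
#' grand total, the shape of the package's reported tables.
#'
#' @param report_draws matrix draws x reports.
#' @param classes taxon class per report.
#' @param units unit string.
#' @param mass HPDI mass.
#' @return data frame with one row per class and a `total` row.
#' @export
summarize_by_class <- function(report_draws, classes, units, mass = 0.90) {
  totals <- class_totals(report_draws, classes)
  do.call(rbind, lapply(colnames(totals), function(cl) {
    summarize_draws(totals[, cl], cl, units, mass)
  }))
}
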