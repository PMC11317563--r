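## Closed vocabularies shared across the package.
TAXON_CLASSES <- c("bird", "fish", "mammal")
REPLACEMENT_CATEGORIES <- c("poultry", "fish_mix", "beef_pork_mix")
SCENARIO_LABELS <- c("barge_low", "barge_high", "foodmail_low", "foodmail_high")
TRANSPORT_MODES <- c("boat", "snowmobile", "atv")

config_error <- function(...) {
  stop(paste0(...), call. = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    config_error(what, ": missing column(s) ", paste(missing, collapse = ", "))
  }
}

#' Validate a species metadata table
#'
#' Each row maps one species code to its pooled species type (ecological /
#' technique group used for the deheaping priors), taxon class, edible
#' weight per animal, and market replacement category.
#'
#' @param species data frame with columns `species_code`, `species_type`,
#'   `taxon_class`, `edible_weight_kg_per_animal`, `replacement_category`.
#' @return the validated data frame, invisibly unchanged.
#' @export
validate_species <- function(species) {
  require_columns(species, c("species_code", "species_type", "taxon_class",
                             "edible_weight_kg_per_animal",
                             "replacement_category"), "species table")
  dup <- duplicated(species$species_code)
  if (any(dup)) {
    config_error("species table: duplicated species_code in row(s) ",
                 paste(which(dup), collapse = ", "))
  }
  bad <- which(!is.finite(species$edible_weight_kg_per_animal) |
                 species$edible_weight_kg_per_animal <= 0)
  if (length(bad) > 0) {
    config_error("species table: nonpositive edible_weight_kg_per_animal in row(s) ",
                 paste(bad, collapse = ", "))
  }
  bad <- which(!species$taxon_class %in% TAXON_CLASSES)
  if (length(bad) > 0) {
    config_error("species table: unknown taxon_class in row(s) ",
                 paste(bad, collapse = ", "),
                 " (allowed: ", paste(TAXON_CLASSES, collapse = ", "), ")")
  }
  bad <- which(!species$replacement_category %in% REPLACEMENT_CATEGORIES)
  if (length(bad) > 0) {
    config_error("species table: unknown replacement_category in row(s) ",
                 paste(bad, collapse = ", "))
  }
  invisible(species)
}

#' Validate a replacement-price table
#'
#' One row per (community, replacement_category) with the in-store price of
#' the replacement food in CAD per kilogram. The CPI factor rescales the
#' pricing-study prices to the survey year.
#'
#' @param prices data frame with columns `community`,
#'   `replacement_category`, `price_cad_per_kg`.
#' @param cpi_factor positive scalar consumer-price-index adjustment.
#' @return the validated data frame, invisibly.
#' @export
validate_prices <- function(prices, cpi_factor) {
  require_columns(prices, c("community", "replacement_category",
                            "price_cad_per_kg"), "price table")
  if (!is.numeric(cpi_factor) || length(cpi_factor) != 1 ||
      !is.finite(cpi_factor) || cpi_factor <= 0) {
    config_error("price table: cpi_factor must be a positive number")
  }
  bad <- which(!is.finite(prices$price_cad_per_kg) |
                 prices$price_cad_per_kg <= 0)
  if (length(bad) > 0) {
    config_error("price table: nonpositive price_cad_per_kg in row(s) ",
                 paste(bad, collapse = ", "))
  }
  bad <- which(!prices$replacement_category %in% REPLACEMENT_CATEGORIES)
  if (length(bad) > 0) {
    config_error("price table: unknown replacement_category in row(s) ",
                 paste(bad, collapse = ", "))
  }
  key <- paste(prices$community, prices$replacement_category)
  dup <- duplicated(key)
  if (any(dup)) {
    config_error("price table: duplicated (community, category) in row(s) ",
                 paste(which(dup), collapse = ", "))
  }
  invisible(prices)
}

validate_legs <- function(legs, where) {
  for (i in seq_along(legs)) {
    leg <- legs[[i]]
    if (is.null(leg$mode) || is.null(leg$km)) {
      config_error(where, ": leg ", i, " must have fields mode and km")
    }
    if (!is.finite(leg$km) || leg$km <= 0) {
      config_error(where, ": leg ", i, " has nonpositive km")
    }
  }
  invisible(legs)
}

## Materialise one transport scenario (e.g. "foodmail_high") from the raw
## config list: pick the route set by scenario family and the per-mode
## emission-factor endpoint by low/high.
build_scenario <- function(label, config) {
  parts <- strsplit(label, "_")[[1]]
  family <- parts[1]
  endpoint <- parts[2]
  routes <- config$routes[[family]]
  if (is.null(routes)) {
    config_error("config: no routes defined for scenario family '", family, "'")
  }
  ef <- vapply(config$transport_ef, function(x) {
    v <- x[[endpoint]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (any(is.na(ef))) {
    config_error("config: transport_ef missing '", endpoint, "' endpoint for mode(s) ",
                 paste(names(ef)[is.na(ef)], collapse = ", "))
  }
  if (any(ef < 0)) {
    config_error("config: negative transport emission factor for mode(s) ",
                 paste(names(ef)[ef < 0], collapse = ", "))
  }
  production_ef <- unlist(config$production_ef)
  if (!all(REPLACEMENT_CATEGORIES %in% names(production_ef))) {
    config_error("config: production_ef must cover ",
                 paste(REPLACEMENT_CATEGORIES, collapse = ", "))
  }
  if (any(production_ef < 0)) {
    config_error("config: negative production_ef")
  }
  for (comm in names(routes)) {
    validate_legs(routes[[comm]], paste0("config routes ", family, "/", comm))
    for (leg in routes[[comm]]) {
      if (!leg$mode %in% names(ef)) {
        config_error("config: route ", family, "/", comm,
                     " uses mode '", leg$mode, "' with no transport_ef entry")
      }
    }
  }
  structure(list(label = label,
                 production_ef = production_ef,
                 route_legs = routes,
                 transport_ef = ef),
            class = "emission_scenario")
}

## Gasoline constants plus the region-level shipping route for fuel.
build_fuel_config <- function(config) {
  fuel <- config$fuel
  if (is.null(fuel)) config_error("config: missing 'fuel' section")
  defaults <- list(gasoline_density_kg_per_l = 0.749,
                   combustion_ef_kg_per_l = 2.319,
                   fuel_price_cad_per_l = 1.76)
  for (nm in names(defaults)) {
    if (is.null(fuel[[nm]])) fuel[[nm]] <- defaults[[nm]]
    if (!is.finite(fuel[[nm]]) || fuel[[nm]] <= 0) {
      config_error("config fuel: ", nm, " must be positive")
    }
  }
  if (is.null(fuel$route)) config_error("config fuel: missing shipping 'route'")
  validate_legs(fuel$route, "config fuel route")
  ef <- config$transport_ef
  for (leg in fuel$route) {
    if (!leg$mode %in% names(ef)) {
      config_error("config fuel route uses mode '", leg$mode,
                   "' with no transport_ef entry")
    }
  }
  fuel$transport_ef <- ef
  structure(fuel, class = "fuel_emission_config")
}

#' Assemble and validate a configuration bundle
#'
#' Combines the species table, price table, and scenario/constants config
#' into one validated bundle, materialising all four emission scenarios
#' (`barge_low`, `barge_high`, `foodmail_low`, `foodmail_high`).
#'
#' @param species species metadata data frame (see [validate_species()]).
#' @param prices price data frame (see [validate_prices()]).
#' @param config nested list (typically parsed from YAML) with elements
#'   `cpi_factor`, `production_ef`, `transport_ef` (per mode, `low`/`high`),
#'   `routes` (per family `barge`/`foodmail`, per community, list of legs
#'   with `mode` and `km`), and `fuel` (gasoline constants plus `route`).
#' @return an object of class `harvest_config`: a list with elements
#'   `species`, `prices`, `cpi_factor`, `scenarios` (named list of four),
#'   and `fuel`.
#' @export
harvest_config <- function(species, prices, config) {
  validate_species(species)
  cpi <- config$cpi_factor
  if (is.null(cpi)) config_error("config: missing cpi_factor")
  validate_prices(prices, cpi)
  scenarios <- lapply(SCENARIO_LABELS, build_scenario, config = config)
  names(scenarios) <- SCENARIO_LABELS
  structure(list(species = species,
                 prices = prices,
                 cpi_factor = cpi,
                 scenarios = scenarios,
                 fuel = build_fuel_config(config)),
            class = "harvest_config")
}

#' Load configuration tables from disk
#'
#' Reads the species CSV, price CSV and YAML config and returns a validated
#' [harvest_config()] bundle.
#'
#' @param species_file,prices_file paths to CSV files.
#' @param config_file path to a YAML file.
#' @return a `harvest_config` bundle.
#' @export
load_tables <- function(species_file, prices_file, config_file) {
  for (f in c(species_file, prices_file, config_file)) {
    if (!file.exists(f)) config_error("file not found: ", f)
  }
  species <- read.csv(species_file, stringsAsFactors = FALSE)
  prices <- read.csv(prices_file, stringsAsFactors = FALSE)
  config <- yaml::read_yaml(config_file)
  harvest_config(species, prices, config)
}

#' Path to the bundled synthetic example configuration
#'
#' The packaged species weights, prices, emission factors and route
#' distances are synthetic: realistic in order of magnitude for the western
#' Canadian Arctic but not measured values.
#'
#' @return named character vector of three file paths.
#' @export
example_config_paths <- function() {
  c(species = system.file("extdata", "species_synthetic.csv",
                          package = "harvestcarbon", mustWork = TRUE),
    prices = system.file("extdata", "prices_synthetic.csv",
                         package = "harvestcarbon", mustWork = TRUE),
    config = system.file("extdata", "config_synthetic.yaml",
                         package = "harvestcarbon", mustWork = TRUE))
}

#' Check that every harvest report resolves to a known species
#'
#' @param reports harvest-report data frame with a `species_code` column.
#' @param species validated species table.
#' @return invisibly, `reports`.
#' @export
resolve_species <- function(reports, species) {
  require_columns(reports, "species_code", "harvest reports")
  unresolved <- setdiff(unique(reports$species_code), species$species_code)
  if (length(unresolved) > 0) {
    config_error("harvest reports reference unknown species code(s): ",
                 paste(unresolved, collapse = ", "))
  }
  invisible(reports)
}

#' Write posterior summary tables to CSV
#'
#' One file per estimand (e.g. edible weight, substitution value, one per
#' emission scenario, fuel), each holding mean / SD / 90% HPDI rows per
#' taxon class plus the total. Output is byte-stable for identical input.
#'
#' @param summaries named list of data frames as produced by
#'   [summarize_draws()] rows bound together.
#' @param out_dir directory to write into (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_summary_tables <- function(summaries, out_dir) {
  if (length(summaries) == 0 || is.null(names(summaries))) {
    config_error("write_summary_tables: need a non-empty named list of summaries")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(summaries)) {
    df <- summaries[[nm]]
    if (is.null(df) || nrow(df) == 0) {
      config_error("write_summary_tables: empty summary for '", nm, "'")
    }
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(df, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
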