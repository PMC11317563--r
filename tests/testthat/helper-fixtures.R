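## In-code fixtures shared across test files. Everything is built at test
## time; no binary data.

fixture_species <- function() {
  data.frame(
    species_code = c("CAGO", "BDWF", "ARCH", "CARI", "RISE"),
    species_type = c("geese", "whitefish", "char_trout", "caribou", "seals"),
    taxon_class = c("bird", "fish", "fish", "mammal", "mammal"),
    edible_weight_kg_per_animal = c(2.4, 2.5, 2.4, 46, 22),
    replacement_category = c("poultry", "fish_mix", "fish_mix",
                             "beef_pork_mix", "beef_pork_mix"),
    stringsAsFactors = FALSE
  )
}

fixture_prices <- function() {
  expand <- expand.grid(community = c("Aklavik", "Ulukhaktok"),
                        replacement_category = c("poultry", "fish_mix",
                                                 "beef_pork_mix"),
                        stringsAsFactors = FALSE)
  expand$price_cad_per_kg <- c(13.5, 15.5, 31, 34, 25, 27.5)
  expand
}

fixture_config <- function() {
  list(
    cpi_factor = 0.989,
    production_ef = list(poultry = 2.6, fish_mix = 3.3, beef_pork_mix = 12.5),
    transport_ef = list(road = list(low = 8e-05, high = 1.2e-04),
                        rail = list(low = 2e-05, high = 5e-05),
                        barge = list(low = 2e-05, high = 6e-05),
                        air = list(low = 8e-04, high = 1.5e-03)),
    routes = list(
      barge = list(
        Aklavik = list(list(mode = "road", km = 1150),
                       list(mode = "barge", km = 1900)),
        Ulukhaktok = list(list(mode = "road", km = 1150),
                          list(mode = "barge", km = 2700))),
      foodmail = list(
        Aklavik = list(list(mode = "road", km = 3550),
                       list(mode = "air", km = 110)),
        Ulukhaktok = list(list(mode = "road", km = 3550),
                          list(mode = "air", km = 900)))),
    fuel = list(gasoline_density_kg_per_l = 0.749,
                combustion_ef_kg_per_l = 2.319,
                fuel_price_cad_per_l = 1.76,
                route = list(list(mode = "rail", km = 1500),
                             list(mode = "barge", km = 1900)))
  )
}

fixture_bundle <- function() {
  harvest_config(fixture_species(), fixture_prices(), fixture_config())
}

## The packaged synthetic configuration, covering all six communities.
packaged_bundle <- function() {
  paths <- example_config_paths()
  load_tables(paths["species"], paths["prices"], paths["config"])
}

## Small harvest-report table on the fixture species/communities.
fixture_reports <- function(counts = c(10, 20, 5, 2, 1),
                            communities = "Aklavik") {
  sp <- fixture_species()
  n <- length(counts)
  data.frame(
    report_id = sprintf("r%03d", seq_len(n)),
    community = rep_len(communities, n),
    month = rep_len(1:12, n),
    species_code = rep_len(sp$species_code, n),
    reported_count = counts,
    missing = is.na(counts),
    stringsAsFactors = FALSE
  )
}

## Hand-built posterior objects for propagation tests where the draw
## values must be exactly known.
fake_deheap <- function(draws, report_id = sprintf("r%03d", seq_len(ncol(draws)))) {
  colnames(draws) <- report_id
  structure(list(draws = draws, report_id = report_id,
                 missing = rep(FALSE, ncol(draws)),
                 converged = TRUE),
            class = "deheap_posterior")
}

fake_trip_posterior <- function(theta = 0.75, a = 2, b = 0.5, sigma = 0.3,
                                mu_f = 3, sigma_f = 0.4, n = 100) {
  structure(list(draws = data.frame(theta = rep_len(theta, n),
                                    a = rep_len(a, n), b = rep_len(b, n),
                                    sigma = rep_len(sigma, n),
                                    mu_f = rep_len(mu_f, n),
                                    sigma_f = rep_len(sigma_f, n)),
                 n_success = NA, n_fail = NA, converged = TRUE),
            class = "trip_posterior")
}

## Independent brute-force HPDI oracle: O(n^2) scan over all index pairs
## spanning at least the required number of gaps.
brute_force_hpdi <- function(draws, mass = 0.9) {
  x <- sort(draws)
  n <- length(x)
  gap <- min(ceiling(mass * n), n - 1)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i >= gap && (x[j] - x[i]) < (best[2] - best[1])) {
        best <- c(x[i], x[j])
      }
    }
  }
  best
}
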