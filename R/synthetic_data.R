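ISR_COMMUNITIES <- c("Aklavik", "Inuvik", "Paulatuk", "Sachs Harbour",
                     "Tuktoyaktuk", "Ulukhaktok")

#' Heaping rule for recalled counts
#'
#' Recalled harvest counts cluster on round numbers, and larger estimates
#' are rounder: small catches are reported (close to) exactly, mid-sized
#' catches to the nearest multiple of 5, larger ones to the nearest 10 or
#' 50. The real reporting mechanism is unobservable, so the rule is held in
#' a parameter object rather than hard-coded; ground truth is carried
#' alongside generated data so that no result depends on this rule being
#' literally true.
#'
#' @param exact_below counts below this are reported to the nearest integer
#'   (minimum 1).
#' @param multiples rounding grain for each size band.
#' @param breaks band boundaries: counts below `breaks[1]` use
#'   `multiples[1]`, counts in `[breaks[1], breaks[2])` use `multiples[2]`,
#'   counts at or above `breaks[2]` use `multiples[3]`.
#' @return an object of class `heap_rule`.
#' @export
heap_rule <- function(exact_below = 5, multiples = c(5, 10, 50),
                      breaks = c(100, 250)) {
  stopifnot(exact_below > 0, length(multiples) == 3, length(breaks) == 2,
            all(multiples > 0), all(diff(breaks) > 0))
  structure(list(exact_below = exact_below, multiples = multiples,
                 breaks = breaks), class = "heap_rule")
}

#' Heap a true count into its reported value
#'
#' @param count vector of positive true counts.
#' @param rule a [heap_rule()].
#' @return integer-valued reported counts (always at least 1).
#' @export
heap <- function(count, rule = heap_rule()) {
  if (any(!is.finite(count) | count <= 0)) {
    stop("heap: counts must be positive", call. = FALSE)
  }
  grain <- ifelse(count < rule$exact_below, 1,
           ifelse(count < rule$breaks[1], rule$multiples[1],
           ifelse(count < rule$breaks[2], rule$multiples[2],
                  rule$multiples[3])))
  pmax(round(count / grain) * grain, 1)
}

#' Default per-species-type harvest-size distributions
#'
#' Lognormal parameters (mean and SD of the log count per report) for the
#' species types in the bundled synthetic species table, chosen to emulate
#' typical recall-survey reports: single large mammals, small groups of
#' seals and geese, and catches of tens of fish. Types not listed fall back
#' to `fallback`.
#'
#' @param species_types character vector of types to cover.
#' @param fallback c(log_mean, log_sd) used for unlisted types.
#' @return data frame with columns `species_type`, `log_mean`, `log_sd`.
#' @export
harvest_truth_params <- function(species_types, fallback = c(1.5, 0.8)) {
  defaults <- list(
    geese      = c(2.2, 0.8),
    ducks      = c(2.0, 0.8),
    ptarmigan  = c(2.3, 0.9),
    whitefish  = c(3.0, 1.0),
    inconnu    = c(2.5, 1.0),
    char_trout = c(2.6, 1.0),
    caribou    = c(0.6, 0.6),
    muskox     = c(0.3, 0.4),
    seals      = c(0.5, 0.5),
    moose      = c(0.1, 0.3)
  )
  pars <- t(vapply(species_types, function(tp) {
    if (!is.null(defaults[[tp]])) defaults[[tp]] else fallback
  }, numeric(2)))
  data.frame(species_type = species_types,
             log_mean = pars[, 1], log_sd = pars[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a heaped harvest-report table with known truth
#'
#' True counts are drawn lognormally per species type, then heaped with
#' `rule`; a fixed share of reports has the count blanked and flagged
#' missing, emulating recall-survey data-entry errors (completely at
#' random). Communities and months are assigned uniformly.
#'
#' @param species validated species table.
#' @param n_reports number of reports to generate.
#' @param truth data frame as from [harvest_truth_params()]; defaults to
#'   the built-in per-type parameters.
#' @param missing_frac share of reports flagged missing (default emulates
#'   64 flagged records among 2,388).
#' @param seed integer RNG seed, recorded in the returned truth.
#' @param rule heaping rule.
#' @return list with `reports` (data frame: report_id, community, month,
#'   species_code, reported_count, missing) and `truth` (list with
#'   per-report `true_count`, the per-type parameters, the rule, and seed).
#' @export
simulate_harvest_reports <- function(species, n_reports = 2388,
                                     truth = NULL,
                                     missing_frac = 64 / 2388,
                                     seed = 1,
                                     rule = heap_rule()) {
  validate_species(species)
  if (nrow(species) == 0) stop("simulate_harvest_reports: empty species table",
                               call. = FALSE)
  stopifnot(n_reports > 0, missing_frac >= 0, missing_frac < 1)
  if (is.null(truth)) truth <- harvest_truth_params(unique(species$species_type))
  set.seed(seed)
  idx <- sample.int(nrow(species), n_reports, replace = TRUE)
  type <- species$species_type[idx]
  pars <- truth[match(type, truth$species_type), ]
  if (any(is.na(pars$log_mean))) {
    stop("simulate_harvest_reports: truth params missing for type(s) ",
         paste(unique(type[is.na(pars$log_mean)]), collapse = ", "),
         call. = FALSE)
  }
  true_count <- rlnorm(n_reports, pars$log_mean, pars$log_sd)
  reported <- heap(true_count, rule)
  missing <- rep(FALSE, n_reports)
  n_missing <- round(missing_frac * n_reports)
  if (n_missing > 0) {
    missing[sample.int(n_reports, n_missing)] <- TRUE
  }
  reported[missing] <- NA_real_
  reports <- data.frame(
    report_id = sprintf("r%04d", seq_len(n_reports)),
    community = sample(ISR_COMMUNITIES, n_reports, replace = TRUE),
    month = sample.int(12, n_reports, replace = TRUE),
    species_code = species$species_code[idx],
    reported_count = reported,
    missing = missing,
    stringsAsFactors = FALSE
  )
  list(reports = reports,
       truth = list(true_count = true_count,
                    species_type_params = truth,
                    rule = rule,
                    seed = seed))
}

#' Default trip-process parameters
#'
#' Conditions emulating a season of instrumented harvesting trips: three
#' quarters of trips succeed; successful trips harvest tens of kilograms
#' and burn fuel following a square-root power law of harvest size
#' (log-log slope 0.5) around 50 L per typical trip; failed trips burn
#' lognormal fuel with log-mean 3 and log-SD 0.4 (about 22 L).
#'
#' @param theta_true success probability.
#' @param intercept_true,slope_true,resid_sd_true log-fuel regression on
#'   log edible kg for successful trips.
#' @param failed_fuel_log_mean,failed_fuel_log_sd lognormal fuel for failed
#'   trips.
#' @param kg_log_mean,kg_log_sd lognormal edible weight of successful trips.
#' @return named list of parameters.
#' @export
trip_truth_params <- function(theta_true = 0.75,
                              intercept_true = 2.0,
                              slope_true = 0.5,
                              resid_sd_true = 0.5,
                              failed_fuel_log_mean = 3.0,
                              failed_fuel_log_sd = 0.4,
                              kg_log_mean = log(30),
                              kg_log_sd = 1.0) {
  stopifnot(theta_true > 0, theta_true <= 1, resid_sd_true > 0,
            failed_fuel_log_sd > 0, kg_log_sd > 0)
  list(theta_true = theta_true, intercept_true = intercept_true,
       slope_true = slope_true, resid_sd_true = resid_sd_true,
       failed_fuel_log_mean = failed_fuel_log_mean,
       failed_fuel_log_sd = failed_fuel_log_sd,
       kg_log_mean = kg_log_mean, kg_log_sd = kg_log_sd)
}

#' Simulate a trip-record table with known truth
#'
#' Each trip succeeds with probability `theta_true`. Successful trips draw
#' an individual edible weight lognormally and fuel from the log-log
#' regression; failed trips harvest nothing and draw fuel from a separate
#' lognormal. Transport mode and participant count are assigned at random.
#' Mirroring how interviewees report, snowmobile and ATV trips with
#' several participants carry the group total in `edible_kg` (individual
#' weight times participants), while fuel remains individual;
#' [divide_group_harvests()] recovers the individual harvest exactly.
#'
#' @param n_trips number of trips.
#' @param truth list as from [trip_truth_params()].
#' @param seed integer RNG seed.
#' @return list with `trips` (data frame: trip_id, mode, participants,
#'   fuel_l, edible_kg, success) and `truth` (the parameters plus seed).
#' @export
simulate_trips <- function(n_trips = 132, truth = trip_truth_params(),
                           seed = 1) {
  stopifnot(n_trips > 0)
  if (is.null(truth$theta_true) || truth$theta_true <= 0 ||
      truth$theta_true > 1) {
    stop("simulate_trips: theta_true must be in (0, 1]", call. = FALSE)
  }
  set.seed(seed)
  success <- rbinom(n_trips, 1, truth$theta_true) == 1
  edible_kg <- numeric(n_trips)
  fuel_l <- numeric(n_trips)
  ns <- sum(success)
  if (ns > 0) {
    kg <- rlnorm(ns, truth$kg_log_mean, truth$kg_log_sd)
    edible_kg[success] <- kg
    fuel_l[success] <- exp(truth$intercept_true +
                             truth$slope_true * log(kg) +
                             rnorm(ns, 0, truth$resid_sd_true))
  }
  nf <- n_trips - ns
  if (nf > 0) {
    fuel_l[!success] <- rlnorm(nf, truth$failed_fuel_log_mean,
                               truth$failed_fuel_log_sd)
  }
  mode <- sample(TRANSPORT_MODES, n_trips, replace = TRUE,
                 prob = c(0.3, 0.5, 0.2))
  participants <- sample.int(4, n_trips, replace = TRUE,
                             prob = c(0.55, 0.25, 0.12, 0.08))
  ## Machine trips report the group harvest; boats report the boat total
  ## (here one boat = the individual record).
  group <- mode %in% c("snowmobile", "atv")
  trips <- data.frame(
    trip_id = sprintf("t%03d", seq_len(n_trips)),
    mode = mode,
    participants = participants,
    fuel_l = fuel_l,
    edible_kg = ifelse(group, edible_kg * participants, edible_kg),
    success = success,
    stringsAsFactors = FALSE
  )
  truth$seed <- seed
  list(trips = trips, truth = truth)
}

#' Divide group harvests by participant count
#'
#' Interviewees report individual expenses but often group harvests. To
#' avoid overestimating returns, snowmobile and ATV group trips have their
#' harvest divided by the participant count (as if each participant ran
#' their own machine); boat trips keep the total harvest (one boat, many
#' people).
#'
#' @param trips trip-record data frame with `mode`, `participants`,
#'   `edible_kg`.
#' @return the table with adjusted `edible_kg`.
#' @export
divide_group_harvests <- function(trips) {
  require_columns(trips, c("mode", "participants", "edible_kg"), "trip table")
  if (any(trips$participants < 1)) {
    stop("divide_group_harvests: participants must be >= 1", call. = FALSE)
  }
  bad <- setdiff(unique(trips$mode), TRANSPORT_MODES)
  if (length(bad) > 0) {
    stop("divide_group_harvests: unknown mode(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  divide <- trips$mode %in% c("snowmobile", "atv")
  trips$edible_kg <- ifelse(divide, trips$edible_kg / trips$participants,
                            trips$edible_kg)
  trips
}
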