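#' Trip-model sampler settings
#'
#' Priors are weakly informative, following the mildly-regulating
#' convention for log-scale models: standard normal on the regression
#' intercept and slope and on the failed-trip log-fuel mean, Beta(1, 1) on
#' the success probability, half-normal(1) on both SDs.
#'
#' @param chains number of MCMC chains (>= 2).
#' @param iter iterations per chain (first half is warmup).
#' @param n_keep post-warmup draws retained after thinning.
#' @param seed integer RNG seed.
#' @param pseudo_counts Beta pseudo-counts added to both the success and
#'   failure tallies; set > 0 to fit tables with no observed failure (or
#'   success), in which case the parameters of the unobservable side are
#'   sampled from their priors.
#' @param rhat_threshold convergence threshold for split R-hat.
#' @return an object of class `trip_settings`.
#' @export
trip_settings <- function(chains = 3, iter = 4000, n_keep = 1000, seed = 1,
                          pseudo_counts = 0, rhat_threshold = 1.01) {
  stopifnot(chains >= 2, iter >= 20, n_keep >= 10, pseudo_counts >= 0)
  structure(list(chains = chains, iter = iter, n_keep = n_keep, seed = seed,
                 pseudo_counts = pseudo_counts,
                 rhat_threshold = rhat_threshold),
            class = "trip_settings")
}

## One random-walk Metropolis step on log(sd) for a normal model with
## known residual sum of squares; half-normal(1) prior on sd, with the
## log-scale Jacobian.
.rwm_log_sd <- function(sigma, n, rss, step = 0.25) {
  lt <- function(s) -n * log(s) - rss / (2 * s^2) - s^2 / 2 + log(s)
  prop <- sigma * exp(step * rnorm(1))
  if (log(runif(1)) < lt(prop) - lt(sigma)) prop else sigma
}

#' Fit the Bernoulli-success and fuel-regression trip model
#'
#' Three sub-models share one joint posterior: trip success is Bernoulli
#' with probability `theta` (flat Beta(1, 1) prior, sampled by Metropolis
#' on the logit; the Beta conjugate posterior is the test oracle); for
#' successful trips log fuel is normal in log edible weight (intercept
#' `a`, slope `b`, residual SD `sigma`); for failed trips log fuel is
#' normal with mean `mu_f` and SD `sigma_f`. Records with nonpositive fuel
#' are excluded with a message.
#'
#' @param trips trip-record data frame with `fuel_l`, `edible_kg`, and
#'   optionally `success` (defaults to `edible_kg > 0`).
#' @param settings a [trip_settings()].
#' @return object of class `trip_posterior`: list with `draws` (data frame
#'   of `theta`, `a`, `b`, `sigma`, `mu_f`, `sigma_f`), `n_success`,
#'   `n_fail`, `diagnostics`, `converged`, `settings`.
#' @export
fit_trip_model <- function(trips, settings = trip_settings()) {
  require_columns(trips, c("fuel_l", "edible_kg"), "fit_trip_model")
  if (is.null(trips$success)) trips$success <- trips$edible_kg > 0
  if (any(trips$success != (trips$edible_kg > 0))) {
    stop("fit_trip_model: success flag inconsistent with edible_kg > 0",
         call. = FALSE)
  }
  drop <- !is.finite(trips$fuel_l) | trips$fuel_l <= 0
  if (any(drop)) {
    message(sprintf("fit_trip_model: excluding %d record(s) with nonpositive fuel",
                    sum(drop)))
    trips <- trips[!drop, ]
  }
  ns <- sum(trips$success)
  nf <- sum(!trips$success)
  p <- settings$pseudo_counts
  if ((ns == 0 || nf == 0) && p == 0) {
    stop("fit_trip_model: table has no observed ",
         if (ns == 0) "success" else "failure",
         "; set pseudo_counts > 0 in trip_settings() to proceed",
         call. = FALSE)
  }

  x <- log(trips$edible_kg[trips$success])
  y <- log(trips$fuel_l[trips$success])
  z <- log(trips$fuel_l[!trips$success])
  ## Sufficient statistics for the regression block.
  X <- cbind(1, x)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)
  sum_z <- sum(z)
  zz <- sum(z^2)

  warmup <- floor(settings$iter / 2)
  kept <- settings$iter - warmup
  keep_idx <- thin_indices(kept, ceiling(settings$n_keep / settings$chains))
  pars <- c("theta", "a", "b", "sigma", "mu_f", "sigma_f")

  set.seed(settings$seed)
  chains_out <- list()
  for (ch in seq_len(settings$chains)) {
    theta <- rbeta(1, 1 + ns + p, 1 + nf + p)
    ab <- c(rnorm(1, 0, 1), rnorm(1, 0, 1))
    sigma <- abs(rnorm(1, 0, 1)) + 0.2
    mu_f <- rnorm(1, 0, 1)
    sigma_f <- abs(rnorm(1, 0, 1)) + 0.2
    rows <- matrix(NA_real_, kept, 6, dimnames = list(NULL, pars))
    for (it in seq_len(settings$iter)) {
      ## (a, b) | sigma: conjugate bivariate normal (N(0,1) priors).
      if (ns > 0) {
        prec <- XtX / sigma^2 + diag(2)
        V <- solve(prec)
        m <- V %*% (Xty / sigma^2)
        ab <- as.vector(m + t(chol(V)) %*% rnorm(2))
        rss <- yty - 2 * sum(ab * Xty) + sum(ab * (XtX %*% ab))
        sigma <- .rwm_log_sd(sigma, ns, rss)
      } else {
        ab <- rnorm(2, 0, 1)
        sigma <- abs(rnorm(1, 0, 1)) + 1e-8
      }
      ## theta: Metropolis on the logit, flat Beta prior (+ pseudo-counts).
      l <- log(theta / (1 - theta))
      lp <- function(l_) {
        t_ <- 1 / (1 + exp(-l_))
        (ns + p) * log(t_) + (nf + p) * log(1 - t_) + log(t_) + log(1 - t_)
      }
      lprop <- l + 0.4 * rnorm(1)
      if (log(runif(1)) < lp(lprop) - lp(l)) l <- lprop
      theta <- 1 / (1 + exp(-l))
      ## Failed-trip log-fuel: Gibbs on mu_f, Metropolis on sigma_f.
      if (nf > 0) {
        prec_f <- 1 + nf / sigma_f^2
        mu_f <- rnorm(1, (sum_z / sigma_f^2) / prec_f, sqrt(1 / prec_f))
        rss_f <- zz - 2 * mu_f * sum_z + nf * mu_f^2
        sigma_f <- .rwm_log_sd(sigma_f, nf, rss_f)
      } else {
        mu_f <- rnorm(1, 0, 1)
        sigma_f <- abs(rnorm(1, 0, 1)) + 1e-8
      }
      if (it > warmup) {
        rows[it - warmup, ] <- c(theta, ab[1], ab[2], sigma, mu_f, sigma_f)
      }
    }
    chains_out[[ch]] <- rows
  }

  half <- floor(kept / 2)
  n_mat <- sum_mat <- sumsq_mat <- NULL
  for (ch in seq_len(settings$chains)) {
    for (hf in 1:2) {
      rg <- if (hf == 1) seq_len(half) else (half + 1):(2 * half)
      blk <- chains_out[[ch]][rg, , drop = FALSE]
      n_mat <- cbind(n_mat, rep(half, 6))
      sum_mat <- cbind(sum_mat, colSums(blk))
      sumsq_mat <- cbind(sumsq_mat, colSums(blk^2))
    }
  }
  rhat <- split_rhat_from_moments(n_mat, sum_mat, sumsq_mat)
  converged <- all(rhat <= settings$rhat_threshold)
  if (!converged) {
    warning(sprintf("fit_trip_model: split R-hat > %.3f (max %.4f); result flagged",
                    settings$rhat_threshold, max(rhat)), call. = FALSE)
  }
  draws <- do.call(rbind, lapply(chains_out,
                                 function(m) m[keep_idx, , drop = FALSE]))
  if (nrow(draws) > settings$n_keep) {
    draws <- draws[thin_indices(nrow(draws), settings$n_keep), , drop = FALSE]
  }
  structure(list(draws = as.data.frame(draws),
                 n_success = ns, n_fail = nf,
                 diagnostics = data.frame(parameter = pars, rhat = rhat),
                 converged = converged,
                 settings = settings),
            class = "trip_posterior")
}

#' @export
print.trip_posterior <- function(x, ...) {
  cat(sprintf("Trip-model posterior: %d successes, %d failures, %d kept draws\n",
              x$n_success, x$n_fail, nrow(x$draws)))
  cat(sprintf("  posterior mean theta %.3f, slope %.3f; max R-hat %.4f\n",
              mean(x$draws$theta), mean(x$draws$b), max(x$diagnostics$rhat)))
  invisible(x)
}

#' Posterior predictive fuel for one harvest
#'
#' Per posterior draw, expected fuel for a successful trip harvesting
#' `edible_kg`: `exp(a + b * log(kg))`.
#'
#' @param edible_kg positive scalar harvest weight (kg).
#' @param posterior a `trip_posterior`.
#' @return vector of fuel draws (litres), one per posterior draw.
#' @export
predict_fuel <- function(edible_kg, posterior) {
  if (!is.finite(edible_kg) || edible_kg <= 0) {
    stop("predict_fuel: edible_kg must be positive", call. = FALSE)
  }
  exp(posterior$draws$a + posterior$draws$b * log(edible_kg))
}

#' Expected number of unobserved failed trips
#'
#' Under a Bernoulli trip process, the failures accompanying `n_success`
#' observed successes are negative-binomial with expectation
#' `n_success * (1 - theta) / theta`.
#'
#' @param n_success number of observed successful trips.
#' @param theta success probability in (0, 1].
#' @return expected failure count.
#' @export
expected_failures <- function(n_success, theta) {
  if (any(theta <= 0) || any(theta > 1)) {
    stop("expected_failures: theta must be in (0, 1]", call. = FALSE)
  }
  n_success * (1 - theta) / theta
}

#' Simulate unobserved failed trips and their fuel
#'
#' Per posterior draw, the failure count is negative-binomial
#' (successes fixed at `n_success`, success probability `theta` from that
#' draw) and the total failed-trip fuel is the sum of that many lognormal
#' draws from the failed-trip fuel distribution.
#'
#' @param n_success number of observed successes (>= 1).
#' @param posterior a `trip_posterior`.
#' @param seed integer RNG seed.
#' @return data frame with one row per posterior draw: `n_failed`,
#'   `failed_fuel_l`.
#' @export
simulate_failures <- function(n_success, posterior, seed = 1) {
  stopifnot(n_success >= 1)
  set.seed(seed)
  d <- posterior$draws
  n_failed <- rnbinom(nrow(d), size = n_success, prob = d$theta)
  failed_fuel <- vapply(seq_len(nrow(d)), function(i) {
    if (n_failed[i] == 0) return(0)
    sum(rlnorm(n_failed[i], d$mu_f[i], d$sigma_f[i]))
  }, numeric(1))
  data.frame(n_failed = n_failed, failed_fuel_l = failed_fuel)
}

#' Persist trip-model draws
#'
#' @param posterior a `trip_posterior`.
#' @param draws_file output CSV path.
#' @return invisibly, the path.
#' @export
write_trip_draws <- function(posterior, draws_file) {
  write.csv(posterior$draws, draws_file, row.names = FALSE)
  invisible(draws_file)
}
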