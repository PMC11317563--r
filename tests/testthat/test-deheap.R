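test_that("species-type moments are plug-in log moments with a floored SD", {
  reports <- data.frame(species_type = rep("geese", 3),
                        reported_count = c(10, 10, 10), missing = FALSE)
  m <- species_type_moments(reports, sd_floor = 0.5)
  expect_equal(m$prior_log_mean, log(10))
  expect_equal(m$prior_log_sd, 0.5)        # zero variance -> floor

  reports <- data.frame(species_type = rep("geese", 2),
                        reported_count = c(10, 100), missing = FALSE)
  m <- species_type_moments(reports)
  expect_equal(m$prior_log_mean, (log(10) + log(100)) / 2, tolerance = 1e-10)
  expect_equal(m$prior_log_mean, 3.4539, tolerance = 1e-4)
  expect_equal(m$prior_log_sd, sd(log(c(10, 100))))

  two <- data.frame(species_type = c("geese", "geese", "seals", "seals"),
                    reported_count = c(5, 20, 1, 2), missing = FALSE)
  m <- species_type_moments(two)
  expect_equal(nrow(m), 2)
  expect_equal(m$prior_log_mean[m$species_type == "seals"],
               mean(log(c(1, 2))))

  gone <- data.frame(species_type = c("geese", "seals"),
                     reported_count = c(10, NA), missing = c(FALSE, TRUE))
  expect_error(species_type_moments(gone), "seals")
})

test_that("the closed-form log posterior is the precision-weighted combination", {
  # flat-prior limit: posterior collapses onto the observation
  p <- conjugate_log_posterior(log(50), 0.15, 0, 1e6)
  expect_equal(unname(p["mean"]), log(50), tolerance = 1e-6)
  expect_equal(unname(p["sd"]), 0.15, tolerance = 1e-6)
  # equal precisions: midpoint
  p <- conjugate_log_posterior(4, 0.3, 2, 0.3)
  expect_equal(unname(p["mean"]), 3)
  # worked case
  p <- conjugate_log_posterior(log(50), 0.15, 3, 1)
  expect_equal(unname(p["mean"]), 3.8920, tolerance = 1e-4)
  expect_error(conjugate_log_posterior(1, -0.1, 0, 1), "positive")
  expect_error(conjugate_log_posterior(1, 0.1, 0, 0), "positive")
})

test_that("lognormal_sd follows the median parameterisation, checked by Monte Carlo", {
  expect_equal(lognormal_sd(10, 0.15), 1.52554, tolerance = 1e-5)
  expect_equal(lognormal_sd(1, 0.15), 0.152554, tolerance = 1e-5)
  expect_lt(lognormal_sd(5, 1e-8), 1e-6)   # degenerate limit
  set.seed(42)
  mc <- sd(rlnorm(400000, log(10), 0.15))
  expect_equal(lognormal_sd(10, 0.15), mc, tolerance = 0.01)
  expect_error(lognormal_sd(-1, 0.15), "positive")
  expect_error(lognormal_sd(10, 0), "positive")
})

test_that("single-report MCMC matches the conjugate closed form", {
  sp <- fixture_species()
  reports <- fixture_reports(counts = 45)[1, ]
  moments <- data.frame(species_type = "geese", prior_log_mean = 3,
                        prior_log_sd = 1, n_obs = 10)
  post <- fit_deheap(reports, sp,
                     deheap_config(chains = 3, iter = 4000, n_keep = 300,
                                   seed = 9),
                     moments = moments)
  oracle <- conjugate_log_posterior(log(45), 0.15, 3, 1)
  lg <- log(post$draws[, 1])
  n <- length(lg)
  se_mean <- oracle["sd"] / sqrt(n)
  expect_lt(abs(mean(lg) - oracle["mean"]), 3 * se_mean)
  expect_lt(abs(sd(lg) - oracle["sd"]), 3 * oracle["sd"] / sqrt(2 * n))
  expect_true(post$converged)
})

test_that("posterior means shrink strictly toward the species-type mean", {
  sp <- fixture_species()
  counts <- c(rep(30, 10), 45)
  reports <- fixture_reports(counts = counts)
  reports$species_code <- "CAGO"            # one group centred near 30
  post <- suppressWarnings(
    fit_deheap(reports, sp,
               deheap_config(chains = 2, iter = 2000, n_keep = 400,
                             seed = 3)))
  prior_mu <- post$moments$prior_log_mean
  lg_mean <- colMeans(log(post$draws))
  # the 45-report's latent sits strictly between the group mean and 45
  expect_gt(lg_mean[11], prior_mu)
  expect_lt(lg_mean[11], log(45))
  # on the natural scale: between 30 and 45
  expect_gt(mean(post$draws[, 11]), 30)
  expect_lt(mean(post$draws[, 11]), 45)
  # every observed report shrinks toward the prior mean
  dir_ok <- (lg_mean >= pmin(log(counts), prior_mu) - 1e-6) &
    (lg_mean <= pmax(log(counts), prior_mu) + 1e-6)
  expect_true(all(dir_ok))
})

test_that("missing reports are imputed from their species-type distribution", {
  sp <- fixture_species()
  counts <- c(rep(c(20, 30, 40), 20), NA, NA)
  reports <- fixture_reports(counts = counts)
  reports$species_code <- "CAGO"
  post <- suppressWarnings(
    fit_deheap(reports, sp,
               deheap_config(chains = 2, iter = 2000, n_keep = 500,
                             seed = 8)))
  m <- post$moments
  miss_draws <- log(post$draws[, is.na(counts), drop = FALSE])
  n <- nrow(miss_draws)
  for (j in 1:2) {
    expect_lt(abs(mean(miss_draws[, j]) - m$prior_log_mean),
              4 * m$prior_log_sd / sqrt(n))
    expect_lt(abs(sd(miss_draws[, j]) - m$prior_log_sd),
              4 * m$prior_log_sd / sqrt(2 * n))
  }
})

test_that("no-pooling mode frees observed reports from the group prior", {
  sp <- fixture_species()
  # a report of 200 in a group whose other members sit near 5: pooled mode
  # drags it down, no-pooling leaves it at the observation
  counts <- c(rep(5, 30), 200)
  reports <- fixture_reports(counts = counts)
  reports$species_code <- "CAGO"
  pooled <- suppressWarnings(
    fit_deheap(reports, sp,
               deheap_config(chains = 2, iter = 4000, n_keep = 400,
                             seed = 4)))
  nopool <- suppressWarnings(
    fit_deheap(reports, sp,
               deheap_config(pooling = "no_pooling", chains = 2,
                             iter = 4000, n_keep = 400, seed = 4)))
  lg_np <- log(nopool$draws[, 31])
  expect_lt(abs(mean(lg_np) - log(200)), 0.04)
  expect_lt(abs(sd(lg_np) - 0.15), 0.03)
  # pooled mode shrinks the outlier by more than the conjugate closed form
  # predicts as a minimum discernible amount; no-pooling barely moves it
  shrink_pooled <- log(200) - mean(log(pooled$draws[, 31]))
  shrink_np <- log(200) - mean(lg_np)
  expect_gt(shrink_pooled, 0.1)
  expect_gt(shrink_pooled, 5 * abs(shrink_np))
  # imputation still uses the species-type distribution in both modes
  counts[15] <- NA
  reports <- fixture_reports(counts = counts)
  reports$species_code <- "CAGO"
  nopool2 <- suppressWarnings(
    fit_deheap(reports, sp,
               deheap_config(pooling = "no_pooling", chains = 2,
                             iter = 1000, n_keep = 200, seed = 4)))
  imput <- log(nopool2$draws[, 15])
  expect_lt(abs(mean(imput) - nopool2$moments$prior_log_mean),
            4 * nopool2$moments$prior_log_sd / sqrt(length(imput)))
})

test_that("identical seed and config give identical draws; nonconvergence is flagged", {
  sp <- fixture_species()
  reports <- fixture_reports()
  cfg <- deheap_config(chains = 2, iter = 500, n_keep = 100, seed = 21)
  a <- suppressWarnings(fit_deheap(reports, sp, cfg))
  b <- suppressWarnings(fit_deheap(reports, sp, cfg))
  expect_identical(a$draws, b$draws)
  expect_identical(a$diagnostics, b$diagnostics)

  strict <- deheap_config(chains = 2, iter = 500, n_keep = 100, seed = 21,
                          rhat_threshold = 0.5)
  expect_warning(flagged <- fit_deheap(reports, sp, strict), "R-hat")
  expect_false(flagged$converged)
  expect_true(all(flagged$diagnostics$rhat > 0))
})
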