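test_that("edible-weight draws multiply counts by per-species weights", {
  sp <- fixture_species()
  reports <- fixture_reports(counts = c(10, 20, 5, 2, 1))
  dh <- fake_deheap(matrix(2, nrow = 20, ncol = 5),
                    report_id = reports$report_id)
  kg <- edible_weight_draws(dh, reports, sp)
  expect_equal(unname(kg[1, ]), 2 * sp$edible_weight_kg_per_animal)
  expect_equal(unname(kg[1, 4]), 2 * 46)
  expect_equal(sd(kg[, 1]), 0)             # zero-variance in, zero out

  reports$species_code[1] <- "XXXX"
  expect_error(edible_weight_draws(dh, reports, sp), "XXXX")
})

test_that("class totals are additive in every draw", {
  set.seed(3)
  sp <- fixture_species()
  reports <- fixture_reports()
  dh <- fake_deheap(matrix(rlnorm(100 * 5), nrow = 100),
                    report_id = reports$report_id)
  kg <- edible_weight_draws(dh, reports, sp)
  classes <- sp$taxon_class[match(reports$species_code, sp$species_code)]
  totals <- class_totals(kg, classes)
  expect_equal(rowSums(totals[, colnames(totals) != "total"]),
               unname(totals[, "total"]))
  expect_equal(unname(totals[, "total"]), rowSums(kg))
})

test_that("substitution value applies community prices and the CPI factor", {
  sp <- fixture_species()
  reports <- fixture_reports(counts = 10)[1, ]   # CAGO, poultry, Aklavik
  dh <- fake_deheap(matrix(10 / 2.4, nrow = 10, ncol = 1), "r001")
  kg <- edible_weight_draws(dh, reports, sp)     # 10 kg in every draw
  prices <- fixture_prices()
  prices$price_cad_per_kg[prices$community == "Aklavik" &
                            prices$replacement_category == "poultry"] <- 26
  val <- substitution_value(kg, reports, sp, prices, 0.989)
  expect_equal(unname(val[1, 1]), 257.14)
  # cpi = 1: value is exactly kg x price
  expect_equal(unname(substitution_value(kg, reports, sp, prices, 1)[1, 1]),
               260)
  # doubling all prices doubles every draw
  prices2 <- prices
  prices2$price_cad_per_kg <- prices2$price_cad_per_kg * 2
  expect_equal(substitution_value(kg, reports, sp, prices2, 0.989),
               2 * val)
  # missing price cell errors
  expect_error(substitution_value(kg, transform(reports, community = "Moosonee"),
                                  sp, prices, 1), "Moosonee")
})

test_that("replacement emissions combine production and route transport", {
  sp <- fixture_species()
  reports <- fixture_reports(counts = 1)[1, ]
  dh <- fake_deheap(matrix(1 / 2.4, nrow = 10, ncol = 1), "r001")
  kg <- edible_weight_draws(dh, reports, sp)     # exactly 1 kg
  cfg <- fixture_config()
  cfg$production_ef$poultry <- 15
  cfg$transport_ef$road <- list(low = 1e-04, high = 1e-04)
  cfg$routes$barge$Aklavik <- list(list(mode = "road", km = 3000))
  b <- harvest_config(sp, fixture_prices(), cfg)
  em <- replacement_emissions(kg, reports, sp, b$scenarios$barge_low)
  expect_equal(unname(em[1, 1]), 15 + 3000 * 1e-04)  # 15.3 kg CO2e

  # zero-length route: production term only
  cfg$routes$barge$Aklavik <- list()
  b <- harvest_config(sp, fixture_prices(), cfg)
  em0 <- replacement_emissions(kg, reports, sp, b$scenarios$barge_low)
  expect_equal(unname(em0[1, 1]), 15)

  # missing route for the community errors
  expect_error(replacement_emissions(kg, transform(reports, community = "Kugluktuk"),
                                     sp, b$scenarios$barge_low), "Kugluktuk")
})

test_that("scenario ordering is monotone when one EF set dominates legwise", {
  set.seed(8)
  b <- fixture_bundle()
  sp <- fixture_species()
  reports <- fixture_reports(communities = c("Aklavik", "Ulukhaktok"))
  dh <- fake_deheap(matrix(rlnorm(50 * 5, 1, 0.5), nrow = 50),
                    report_id = reports$report_id)
  kg <- edible_weight_draws(dh, reports, sp)
  low_barge <- rowSums(replacement_emissions(kg, reports, sp,
                                             b$scenarios$barge_low))
  high_fm <- rowSums(replacement_emissions(kg, reports, sp,
                                           b$scenarios$foodmail_high))
  high_barge <- rowSums(replacement_emissions(kg, reports, sp,
                                              b$scenarios$barge_high))
  expect_true(all(high_fm >= low_barge))
  expect_true(all(high_barge >= low_barge))
})

test_that("hpdi matches its brute-force oracle on a varied corpus", {
  expect_equal(unname(hpdi(1:100, 0.9)), c(1, 91))   # frozen convention
  expect_equal(unname(hpdi(rep(4.2, 25))), c(4.2, 4.2))
  set.seed(12)
  corpus <- list()
  for (n in c(10, 23, 50, 100, 147, 200)) {
    corpus <- c(corpus,
                list(rnorm(n), rlnorm(n, 2, 0.8), runif(n, -5, 5),
                     sample(1:9, n, replace = TRUE)))   # heavy ties
  }
  for (x in corpus) {
    for (mass in c(0.5, 0.9, 0.95)) {
      expect_equal(unname(hpdi(x, mass)), brute_force_hpdi(x, mass))
    }
  }
  # symmetric unimodal sample: HPDI close to the central quantile interval
  z <- rnorm(5000)
  h <- hpdi(z, 0.9)
  q <- quantile(z, c(0.05, 0.95))
  expect_lt(abs(h["low"] - q[1]), 0.15)
  expect_lt(abs(h["high"] - q[2]), 0.15)
  expect_error(hpdi(1:5), "at least 10")
  expect_error(hpdi(1:100, 1.2), "mass")
})

test_that("summaries carry mean/SD/HPDI and stay additive and linear", {
  s <- summarize_draws(rep(7, 50), "const", "kg")
  expect_equal(s$sd, 0)
  expect_equal(s$hpdi_low, 7)
  expect_equal(s$hpdi_high, 7)

  set.seed(4)
  draws <- matrix(rlnorm(200 * 6, 1, 0.6), nrow = 200)
  classes <- rep(c("bird", "fish", "mammal"), each = 2)
  bc <- summarize_by_class(draws, classes, "kg")
  expect_equal(sum(bc$mean[bc$label != "total"]),
               bc$mean[bc$label == "total"])
  # scaling every weight by c scales every mean by c
  bc3 <- summarize_by_class(3 * draws, classes, "kg")
  expect_equal(bc3$mean, 3 * bc$mean)
  expect_equal(bc3$hpdi_low, 3 * bc$hpdi_low)

  z <- rnorm(2000, 10, 2)
  s <- summarize_draws(z, "x", "kg")
  expect_lt(abs(s$mean - 10), 3 * 2 / sqrt(2000))
  expect_error(summarize_draws(numeric(0), "x", "kg"), "empty")
})

test_that("reported emissions intensity is consistent with the summaries", {
  set.seed(9)
  sp <- fixture_species()
  reports <- fixture_reports(communities = "Ulukhaktok")
  dh <- fake_deheap(matrix(rlnorm(80 * 5, 1, 0.4), nrow = 80),
                    report_id = reports$report_id)
  b <- fixture_bundle()
  kg <- edible_weight_draws(dh, reports, sp)
  em <- replacement_emissions(kg, reports, sp, b$scenarios$foodmail_high)
  classes <- sp$taxon_class[match(reports$species_code, sp$species_code)]
  kg_sum <- summarize_by_class(kg, classes, "kg")
  em_sum <- summarize_by_class(em, classes, "kg CO2e")
  pipeline_ratio <- mean(rowSums(em)) / mean(rowSums(kg))
  summary_ratio <- em_sum$mean[em_sum$label == "total"] /
    kg_sum$mean[kg_sum$label == "total"]
  expect_equal(pipeline_ratio, summary_ratio)
})
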