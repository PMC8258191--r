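test_that("control summaries match the closed-form t statistic", {
  set.seed(1)
  # construct 72 gains with exactly the requested mean and sd
  z <- as.numeric(scale(rnorm(72)))
  gains <- 0.016 + 0.011 * z
  cs <- summarize_controls(gains)
  t_oracle <- mean(gains) * sqrt(72) / sd(gains)
  expect_equal(cs$t_stat, t_oracle, tolerance = 1e-10)
  expect_equal(cs$t_stat, 12.3377, tolerance = 1e-3)
  expect_equal(cs$df, 71L)
  expect_lt(cs$p_value, 0.001)
  expect_equal(cs$threshold, 4 * sd(gains))

  cs2 <- summarize_controls(0.016 + 0.01075 * z)
  expect_equal(cs2$threshold, 0.043, tolerance = 1e-12)
})

test_that("degenerate controls are flagged, never silently dropped", {
  expect_warning(cs <- summarize_controls(rep(0, 10)), "zero spread")
  expect_equal(cs$mean_error, 0)
  expect_equal(cs$threshold, 0)
  expect_true(is.na(cs$t_stat))
  expect_error(summarize_controls(0.01), "two control")
})

test_that("error subtraction and the 4-SD reliability filter", {
  res <- correct_and_filter(c(0.200, 0.050, 0.016), paper_controls())
  expect_equal(res$corrected, c(0.184, 0.034, 0.000))
  expect_equal(res$reliable, c(TRUE, FALSE, FALSE))
})

test_that("raising the sd multiplier never gains reliable records", {
  set.seed(42)
  gains <- abs(rnorm(200, 0.05, 0.05))
  sdc <- 0.011
  n_rel <- vapply(seq(0, 8, by = 0.5), function(m) {
    sum(correct_and_filter(gains, list(mean_error = 0.016,
                                       threshold = m * sdc))$reliable)
  }, integer(1))
  expect_true(all(diff(n_rel) <= 0))
})

test_that("formalin correction inverts the assumed loss", {
  expect_equal(formalin_correct(0.6, 0.40), 1.0)
  expect_equal(formalin_correct(0, 0.25), 0)
  expect_equal(round(formalin_multiplier(0.40), 2), 1.67)
  expect_error(formalin_correct(1, 1), "loss")
})

test_that("areal standardization follows the split/subsample/net fractions", {
  expect_equal(standardize_to_area(1, split = 8, n_subsamples = 5), 640)
  expect_equal(standardize_to_area(1, split = 4, n_subsamples = 100), 16)
  expect_equal(standardize_to_area(2, split = 16, n_subsamples = 10),
    2 * standardize_to_area(2, split = 16, n_subsamples = 20))
  expect_error(standardize_to_area(1, split = 6, n_subsamples = 5), "split")
  expect_error(standardize_to_area(1, split = 4, n_subsamples = 0), "n_subsamples")
})

test_that("individual dry weights reproduce published sample quotients", {
  expect_equal(round(individual_dw(12.496, 4128), 4), 0.0030)
  expect_equal(round(individual_dw(83.827, 30933), 4), 0.0027)
  expect_equal(individual_dw(0.184, 1), 0.184)
  expect_error(individual_dw(1, 0), "n_individuals")
})

test_that("carbon demand fractions bracket the settling flux", {
  f <- carbon_demand_fraction(278.6, c(70, 6))
  expect_equal(round(f[1], 1), 0.4)
  expect_equal(round(f[2], 0), 5)
  expect_equal(carbon_demand_fraction(0, 10), 0)
  expect_error(carbon_demand_fraction(1, -2), "positive")
})

test_that("carbon and energy conversion applies the Table factors", {
  rec <- data.frame(sample_id = "C_E1",
                    taxon_name = c("Calanus spp.", "Bivalvia", "Oithona spp."),
                    stage_tag = NA, n_individuals = c(10, 5, 3),
                    areal_biomass = c(100, 10, 0),
                    reliable = TRUE,
                    carbon_factor = c(0.502, 0.208, 0.465),
                    energy_factor = c(26.889, 7.039, 18.691))
  out <- convert_composition(rec)
  expect_equal(out$carbon, c(50.2, 2.08, 0))
  expect_equal(out$energy[1], 2688.9)
  rec$carbon_factor[2] <- NA
  expect_warning(out2 <- convert_composition(rec), "skipped")
  expect_equal(nrow(out2), 2)
})

test_that("size classes honour the stage exceptions", {
  expect_equal(assign_size_class("Calanus spp.", "nauplii"), "SMZ")
  expect_equal(assign_size_class("Calanus spp.", "copepodites"), "LMZ")
  expect_equal(assign_size_class("Calanus spp.", NA), "LMZ")
  expect_equal(assign_size_class("Limacina retroversa", NA), "LMZ")
  expect_equal(assign_size_class("Oikopleura spp.", NA), "LMZ")
  expect_equal(assign_size_class("Oithona spp.", NA), "SMZ")
  expect_equal(assign_size_class("oithona   spp.", NA), "SMZ")  # fuzzy match
})

test_that("composition fractions form unit partitions per sample", {
  sim <- simulate_survey(default_scenario(), seed = 11)
  est <- process_survey(sim$survey)
  fr <- partition_size_and_group(est$biomass)
  nonempty <- est$summaries$total_biomass > 0
  expect_true(all(abs(fr$frac_holo + fr$frac_mero + fr$frac_ichthyo - 1)[nonempty] < 1e-9))
  expect_true(all(abs(fr$frac_smz + fr$frac_lmz - 1)[nonempty] < 1e-9))
})

test_that("a single-taxon sample carries a unit fraction", {
  rec <- data.frame(sample_id = "C_E1", taxon_name = "Calanus spp.",
                    stage_tag = NA, n_individuals = 5, raw_gain = 1,
                    corrected_mass = 1, reliable = TRUE, areal_biomass = 64,
                    plankton_group = "holoplankton", size_class = "LMZ",
                    carbon_factor = 0.502, energy_factor = 26.889)
  s <- summarize_samples(rec)
  expect_equal(s$frac_holo, 1)
  expect_equal(s$frac_lmz, 1)
  expect_equal(s$dominant_taxon, "Calanus spp.")
})

test_that("the chain is record-order invariant and zeroes the mean gain", {
  sim <- simulate_survey(trimmed_scenario(), seed = 12)
  est1 <- process_survey(sim$survey)
  shuffled <- sim$survey
  set.seed(1)
  perm <- sample(nrow(shuffled$weighings))
  shuffled$weighings <- shuffled$weighings[perm, ]
  est2 <- process_survey(shuffled)
  a <- est1$biomass[order(est1$biomass$sample_id, est1$biomass$taxon_name,
                          est1$biomass$stage_tag), ]
  b <- est2$biomass[order(est2$biomass$sample_id, est2$biomass$taxon_name,
                          est2$biomass$stage_tag), ]
  expect_equal(a$areal_biomass, b$areal_biomass)
  expect_equal(est1$summaries$total_biomass[order(est1$summaries$sample_id)],
               est2$summaries$total_biomass[order(est2$summaries$sample_id)])

  # raw gain equal to the mean error corrects to exactly zero pre-formalin
  cf <- correct_and_filter(0.016, paper_controls())
  expect_identical(cf$corrected, 0)
  expect_false(cf$reliable)
})
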