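registry <- load_reference_tables()$formulas
row_of <- function(id) registry[registry$method_id == id, ]

test_that("formula evaluation matches independent arithmetic", {
  expect_equal(evaluate_formula(row_of("calanus_i"), 2.5),
               0.006458 * 2.5^3.9, tolerance = 1e-12)
  expect_equal(evaluate_formula(row_of("calanus_i"), 2.5), 0.230, tolerance = 2e-3)
  expect_equal(evaluate_formula(row_of("calanus_iii"), 2.5),
               0.0084 * 2.5^3.4333 / 0.9, tolerance = 1e-12)
  expect_equal(evaluate_formula(row_of("calanus_iii"), 2.5), 0.217, tolerance = 2e-3)
  expect_equal(evaluate_formula(row_of("calanus_ii"), 2.5),
               10^(0.735 * 2.5 - 2.5), tolerance = 1e-12)
  # Oithona masses come back converted from ug to mg
  expect_equal(evaluate_formula(row_of("oithona_iv"), 500),
               3.405e-10 * 500^3.643 * 1e-3, tolerance = 1e-12)
  expect_equal(evaluate_formula(row_of("oithona_iv"), 500), 0.00231, tolerance = 2e-3)
  expect_error(evaluate_formula(row_of("calanus_i"), 0), "positive")
})

test_that("the fixed Oithona method ignores length", {
  for (pl in c(1, 200, 500, 5000))
    expect_equal(evaluate_formula(row_of("oithona_i"), pl), 0.003)
  expect_equal(sample_calculated_mean(c(300, 900, 4000), row_of("oithona_i")), 0.003)
})

test_that("non-fixed formulas are strictly increasing in length", {
  for (id in registry$method_id[registry$functional_form != "fixed"]) {
    f <- row_of(id)
    grid_um <- seq(100, 5000, by = 25)
    pl <- if (f$length_unit == "mm") grid_um / 1000 else grid_um
    expect_true(all(diff(evaluate_formula(f, pl)) > 0), label = id)
  }
})

test_that("unit conversion from canonical um round-trips", {
  for (id in c("oithona_ii", "oithona_iv", "oithona_v")) {
    f <- row_of(id)
    direct <- evaluate_formula(f, 437)
    via_um <- dw_from_length_um(f, 437)
    expect_equal(via_um, direct, tolerance = 1e-12)
  }
  # mm-based formulas receive um/1000
  expect_equal(dw_from_length_um(row_of("calanus_i"), 2500),
               evaluate_formula(row_of("calanus_i"), 2.5), tolerance = 1e-12)
})

test_that("log forms use base 10 (cross-method consistency at 2.5 mm)", {
  vals <- c(i = evaluate_formula(row_of("calanus_i"), 2.5),
            ii = evaluate_formula(row_of("calanus_ii"), 2.5),
            iii = evaluate_formula(row_of("calanus_iii"), 2.5))
  expect_gt(vals["ii"], 0.1)
  expect_lt(vals["ii"], 1.0)
  expect_lt(max(vals) / min(vals), 2)
})

test_that("sample means average transformed values, not mean lengths", {
  f <- row_of("calanus_i")
  m <- sample_calculated_mean(c(2000, 3000), f)
  expect_equal(m, mean(dw_from_length_um(f, c(2000, 3000))), tolerance = 1e-12)
  # Jensen: convex power means the average of evaluations exceeds the
  # evaluation at the average length
  expect_gt(m, dw_from_length_um(f, 2500))
  expect_equal(sample_calculated_mean(1234, f), dw_from_length_um(f, 1234))
  expect_error(sample_calculated_mean(numeric(0), f), "length")
})

test_that("performance bands are closed at 80 and 120 percent", {
  expect_equal(mesozoo:::band_label(c(79.999, 80, 100, 120, 120.001)),
               c("under", "satisfactory", "satisfactory", "satisfactory", "over"))
})

test_that("event summaries aggregate stations order-invariantly", {
  cmp <- data.frame(sample_id = c("C_E1", "B_E1", "T_E1", "C_E2"),
                    method_id = "calanus_i",
                    relative_percent = c(90, 100, 110, 95))
  s <- event_summary(cmp)
  e1 <- s[s$event_id == "E1", ]
  expect_equal(e1$mean_percent, 100)
  expect_equal(e1$sd_percent, 10)
  e2 <- s[s$event_id == "E2", ]
  expect_true(is.na(e2$sd_percent))
  expect_equal(e2$n_stations, 1L)
  s2 <- event_summary(cmp[c(4, 3, 1, 2), ])
  expect_equal(s2[order(s2$event_id), ], s[order(s$event_id), ],
               ignore_attr = TRUE)
})

test_that("a survey whose truth equals calanus_i is satisfactory everywhere", {
  sc <- ideal_obs(calanus_scenario(), error_sd = 0)
  sim <- simulate_survey(sc, seed = 31)
  est <- suppressWarnings(process_survey(sim$survey))
  cmp <- compare_methods(est, sim$survey$lengths)
  ci <- cmp[cmp$method_id == "calanus_i", ]
  expect_gt(nrow(ci), 10)
  expect_true(all(ci$band == "satisfactory"))
  # error-free observation of the generating formula is exact
  expect_true(all(abs(ci$relative_percent - 100) < 1e-6))
})

test_that("truth heavier than every formula drives all methods under 80%", {
  sc <- ideal_obs(calanus_scenario(coef_scale = 2), error_sd = 0)
  sim <- simulate_survey(sc, seed = 32)
  est <- suppressWarnings(process_survey(sim$survey))
  cmp <- compare_methods(est, sim$survey$lengths)
  expect_true(all(cmp$band == "under"))
  expect_true(all(cmp$relative_percent < 80))
})
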