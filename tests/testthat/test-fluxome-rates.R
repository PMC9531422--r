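# Biomass-specific rates, respiration, totals, fold changes and dilution.

make_series <- function(time, volume, cdw, conc, unit = "g_per_L",
                        species = "p", feed_rate = 0, feed_conc = 0,
                        molar_mass = 100, offgas = NULL) {
  d <- tibble::tibble(time = time, volume = volume, cdw = cdw,
                      feed_rate = feed_rate)
  d[[paste0("conc_", species)]] <- conc
  process_timeseries(d, stats::setNames(unit, species),
                     feed_conc = stats::setNames(feed_conc, species),
                     molar_mass = stats::setNames(molar_mass, species),
                     offgas = offgas)
}

test_that("specific_rate matches hand arithmetic on a constant-volume batch", {
  # V = 1 L, X = 10 g/L, product +1 mmol/L over 1 h -> 0.1 mmol/gCDW/h
  s <- make_series(time = c(0, 0.5, 1), volume = 1, cdw = 10,
                   conc = c(0, 0.5, 1), unit = "mmol_per_L")
  expect_equal(specific_rate(s, "p", c(0, 1)), 0.1, tolerance = 1e-12)
  # uptake convention flips the sign
  s2 <- make_series(time = c(0, 1), volume = 1, cdw = 10,
                    conc = c(1, 0), unit = "mmol_per_L")
  expect_equal(specific_rate(s2, "p", c(0, 1), kind = "uptake"), 0.1)
})

test_that("no concentration change and no feed gives a zero rate", {
  s <- make_series(time = 0:3, volume = 2, cdw = 5, conc = 4)
  expect_equal(specific_rate(s, "p", c(0, 3)), 0)
})

test_that("rates are invariant to the concentration unit", {
  mm <- 180.16
  s_g <- make_series(time = c(0, 1), volume = 1, cdw = 10,
                     conc = c(0, 0.18016), unit = "g_per_L", molar_mass = mm)
  s_m <- make_series(time = c(0, 1), volume = 1, cdw = 10,
                     conc = c(0, 1), unit = "mmol_per_L", molar_mass = mm)
  expect_equal(specific_rate(s_g, "p", c(0, 1)),
               specific_rate(s_m, "p", c(0, 1)), tolerance = 1e-12)
})

test_that("specific_rate rejects degenerate inputs", {
  s <- make_series(time = c(0, 1), volume = 1, cdw = 0, conc = c(0, 1))
  expect_error(specific_rate(s, "p", c(0, 1)), "biomass")
  s2 <- make_series(time = 0:2, volume = 1, cdw = 1, conc = 0:2)
  expect_error(specific_rate(s2, "p", c(0.4, 0.6)), "two samples")
})

test_that("respiration rates match the hand gas balance", {
  og <- tibble::tibble(time = c(0, 1), o2_in = 21, o2_out = 20,
                       co2_in = 0, co2_out = 1, gas_flow = 60)
  s <- make_series(time = c(0, 1), volume = 1, cdw = 10, conc = 0,
                   offgas = og)
  rr <- respiration_rates(s, c(0, 1))
  # 60 L/h * 1 % / 24.05 L/mol / (1 L * 10 g/L) = 2.4948 mmol/gCDW/h
  expect_equal(unname(rr["OUR"]), 2.4948, tolerance = 1e-4)
  expect_equal(unname(rr["CPR"]), 2.4948, tolerance = 1e-4)
})

test_that("equal inlet and outlet oxygen gives zero OUR", {
  og <- tibble::tibble(time = c(0, 1), o2_in = 21, o2_out = 21,
                       co2_in = 0.04, co2_out = 0.04, gas_flow = 60)
  s <- make_series(time = c(0, 1), volume = 1, cdw = 10, conc = 0, offgas = og)
  expect_equal(unname(respiration_rates(s, c(0, 1))["OUR"]), 0)
})

test_that("total_amount is volume times concentration plus sampled mass", {
  s <- make_series(time = c(0, 1), volume = 15, cdw = 10, conc = 10)
  expect_equal(total_amount(s, "p", 1), 150)
  log <- tibble::tibble(time = 0.5, mass_g = 5)
  expect_equal(total_amount(s, "p", 1, sampling_log = log), 155)
  expect_error(total_amount(s, "p", 2), "span")
})

test_that("constant concentration under dilution tracks the volume", {
  s <- make_series(time = 0:4, volume = seq(10, 14, by = 1), cdw = 10,
                   conc = 2)
  amounts <- vapply(0:4, function(t) total_amount(s, "p", t), 0)
  expect_equal(amounts, 2 * seq(10, 14, by = 1))
})

test_that("fold change reproduces the observed MGO rate ratio", {
  # glycerol-reactor MGO formation: 0.002 (stage 2) -> 0.053 (stage 3),
  # the observed factor-of-26 increase
  expect_equal(fold_change(0.002, 0.053), 26.5)
  expect_equal(fold_change(3, 3), 1)
  expect_error(fold_change(0, 1), "zero")
})

test_that("dilution fraction is zero without volume change", {
  s <- make_series(time = c(0, 1), volume = 1, cdw = 10, conc = c(2, 1))
  expect_equal(dilution_explained_fraction(s, "p", c(0, 1)), 0)
  s2 <- make_series(time = c(0, 1), volume = 1, cdw = 10, conc = c(1, 2))
  expect_error(dilution_explained_fraction(s2, "p", c(0, 1)), "decreasing")
})

test_that("pure dilution is fully explained by the volume increase", {
  v <- seq(10, 12, length.out = 5)
  s <- make_series(time = seq(0, 2, length.out = 5), volume = v, cdw = 10,
                   conc = 20 * v[1] / v)
  expect_equal(dilution_explained_fraction(s, "p", c(0, 2)), 1,
               tolerance = 1e-9)
})
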