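test_that("glucose equivalent and available carbon follow the hydrolysis stoichiometry", {
  corn <- corn_substrate()
  # 183.3 * 1.11 + 5 = 208.463, reported as 208.5
  expect_equal(glucose_equivalent(corn), 208.463, tolerance = 1e-12)
  expect_equal(round(glucose_equivalent(corn), 1), 208.5)
  expect_equal(
    glucose_equivalent(substrate_spec(100, 100, hydrolysis_factor = 1.11)), 111
  )
  expect_equal(
    glucose_equivalent(substrate_spec(200, 183.3, hydrolysis_factor = 1.11)),
    203.463
  )
  expect_equal(available_carbon(208.5), 6.95)
  expect_equal(available_carbon(180), 6)
  expect_equal(available_carbon(203.5), 203.5 * 6 / 180)
  expect_equal(round(available_carbon(corn), 2), 6.95)
})

test_that("substrate validation rejects impossible loadings", {
  expect_error(substrate_spec(200, 0), class = "fermbalance_validation_error")
  expect_error(substrate_spec(100, 183.3), class = "fermbalance_validation_error")
  expect_error(substrate_spec(200, 183.3, added_glucose = -1),
               class = "fermbalance_validation_error")
  expect_error(substrate_spec(200, 183.3, hydrolysis_factor = 0.9),
               class = "fermbalance_validation_error")
  expect_error(available_carbon(0), class = "fermbalance_validation_error")
})

test_that("CO2 inference is one mole per mole of ethanol", {
  # printed CO2 rows come from unrounded ethanol; rounded inputs land within 0.01
  expect_within(co2_from_ethanol(98.13), 93.87, 0.01)
  expect_within(co2_from_ethanol(62.20), 59.50, 0.01)
  expect_equal(co2_from_ethanol(0), 0)
  expect_equal(co2_from_ethanol(46), 44)
  expect_error(co2_from_ethanol(-1), class = "fermbalance_validation_error")
})

test_that("carbon conversion reproduces the benchmark values", {
  m2n <- data.frame(glucose = 0.09, glycerol = 3.73, acetic_acid = 0,
                    ethanol = 98.13, maltose = 0.96, co2 = 93.87)
  er <- data.frame(glucose = 0.22, glycerol = 3.18, acetic_acid = 0.64,
                   ethanol = 89.35, maltose = 1.95, co2 = 85.46)
  expect_equal(round(carbon_conversion(m2n, 208.5, co2 = "measured")), 94)
  expect_equal(round(carbon_conversion(er, 208.5, co2 = "measured")), 87)
  # inferred CO2 gives the same integer percent
  expect_equal(round(carbon_conversion(m2n[-6], 208.5)), 94)
  expect_equal(round(carbon_conversion(er[-6], 208.5)), 87)
  zero <- data.frame(glucose = 0, glycerol = 0, acetic_acid = 0,
                     ethanol = 0, maltose = 0)
  expect_equal(carbon_conversion(zero, 208.5), 0)
})

test_that("theoretical full conversion closes the carbon balance at exactly 100%", {
  for (ge in c(50, 208.463, 300)) {
    prof <- data.frame(glucose = 0, glycerol = 0, acetic_acid = 0,
                       maltose = 0, ethanol = ge * 92 / 180,
                       co2 = ge * 88 / 180)
    expect_equal(carbon_conversion(prof, ge, co2 = "measured"), 100,
                 tolerance = 1e-12)
    # inferred CO2 from the same ethanol closes identically
    expect_equal(carbon_conversion(prof[-6], ge), 100, tolerance = 1e-12)
  }
})

test_that("inferred CO2 carbon is exactly half the ethanol carbon", {
  eth <- c(0.5, 46, 98.13)
  expect_equal(co2_from_ethanol(eth) * 1 / 44, (eth * 2 / 46) / 2,
               tolerance = 1e-14)
})

test_that("conversion is strictly monotone in every analyte", {
  base <- data.frame(glucose = 1, glycerol = 2, acetic_acid = 0.5,
                     ethanol = 50, maltose = 1)
  ref <- carbon_conversion(base, 208.5)
  for (col in names(base)) {
    bumped <- base
    bumped[[col]] <- bumped[[col]] + 0.5
    expect_gt(carbon_conversion(bumped, 208.5), ref)
  }
})

test_that("conversion and yield are invariant to joint rescaling", {
  prof <- data.frame(glucose = 1.5, glycerol = 3, acetic_acid = 0.4,
                     ethanol = 60, maltose = 1.1)
  for (c in c(0.2, 3, 11.5)) {
    scaled <- prof * c
    expect_equal(carbon_conversion(scaled, 208.5 * c),
                 carbon_conversion(prof, 208.5), tolerance = 1e-12)
    expect_equal(ethanol_yield_pct(prof$ethanol * c, 208.5 * c),
                 ethanol_yield_pct(prof$ethanol, 208.5), tolerance = 1e-12)
  }
})

test_that("conversions above 105% raise a data-inconsistency warning", {
  over <- data.frame(glucose = 300, glycerol = 0, acetic_acid = 0,
                     ethanol = 0, maltose = 0)
  expect_warning(carbon_conversion(over, 208.5),
                 class = "fermbalance_inconsistency_warning")
  expect_error(
    carbon_conversion(
      data.frame(glucose = -1, glycerol = 0, acetic_acid = 0,
                 ethanol = 0, maltose = 0), 208.5),
    class = "fermbalance_validation_error"
  )
})

test_that("yield and productivity reproduce the benchmark values", {
  expect_equal(round(ethanol_yield_pct(62.20, 208.5)), 60)
  expect_equal(round(ethanol_yield_pct(98.13, 208.5)), 94)
  expect_equal(ethanol_yield_pct(0, 208.5), 0)
  expect_error(ethanol_yield_pct(10, 0), class = "fermbalance_validation_error")
  expect_equal(round(ethanol_productivity(62.20, 192), 2), 0.32)
  expect_equal(round(ethanol_productivity(98.13, 192), 2), 0.51)
  expect_equal(ethanol_productivity(0, 192), 0)
  expect_error(ethanol_productivity(10, 0), class = "fermbalance_validation_error")
})

test_that("total products sums all six analytes with CO2 inferred if needed", {
  col2 <- data.frame(glucose = 46.30, glycerol = 6.64, maltose = 1.03,
                     acetic_acid = 1.66, ethanol = 62.20, co2 = 59.50)
  expect_equal(total_products(col2, co2 = "measured"), 177.33)
  single <- data.frame(glucose = 0, glycerol = 0, acetic_acid = 0,
                       maltose = 0, ethanol = 46)
  expect_equal(total_products(single), 90)
  zero <- data.frame(glucose = 0, glycerol = 0, acetic_acid = 0,
                     maltose = 0, ethanol = 0)
  expect_equal(total_products(zero), 0)
})

test_that("fold changes reproduce the benchmark comparisons", {
  expect_equal(round(fold_change(51.71, 33.14), 1), 1.6)
  expect_equal(round(fold_change(15.30, 3.99), 1), 3.8)
  expect_equal(fold_change(7.7, 7.7), 1)
  expect_error(fold_change(1, 0), class = "fermbalance_validation_error")
})

test_that("full-table sweep matches every published summary row", {
  corn <- corn_substrate()
  for (case in list(
    list(products = flask_products(), printed = flask_printed()),
    list(products = industrial_products(), printed = industrial_printed())
  )) {
    s <- summarize_fermentation(case$products, corn, co2 = "measured")
    expect_within(round(s$carbon_conversion_pct), case$printed$conversion, 1)
    expect_within(round(s$ethanol_yield_pct), case$printed$yield, 1)
    expect_within(round(s$productivity, 2), case$printed$productivity, 0.01)
    expect_within(round(s$total_products, 2), case$printed$total, 0.02)
    # printed CO2 rows are the stoichiometric inference from printed ethanol
    expect_within(co2_from_ethanol(case$products$ethanol), case$products$co2, 0.011)
  }
})

test_that("summarize_fermentation vectorizes and validates time courses", {
  corn <- corn_substrate()
  one <- data.frame(strain = "M2n_T1", time_h = 192, glucose = 0.09,
                    glycerol = 3.73, acetic_acid = 0, ethanol = 98.13,
                    maltose = 0.96)
  s <- summarize_fermentation(one, corn)
  expect_equal(round(s$carbon_conversion_pct), 94)
  expect_equal(round(s$ethanol_yield_pct), 94)
  expect_equal(round(s$productivity, 2), 0.51)

  expect_equal(nrow(summarize_fermentation(one[0, ], corn)), 0)

  two <- rbind(one, one)
  two$time_h <- c(96, 192)
  s2 <- summarize_fermentation(two, corn)
  expect_equal(s2$carbon_conversion_pct[1], s2$carbon_conversion_pct[2])
  expect_equal(s2$productivity[1], 2 * s2$productivity[2])

  dup <- two
  dup$time_h <- c(96, 96)
  expect_error(summarize_fermentation(dup, corn),
               class = "fermbalance_validation_error")
})

test_that("analysis objects expose tidy, glance and autoplot", {
  corn <- corn_substrate()
  fit <- analyze_fermentation(industrial_products(), corn, co2 = "measured")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 12)
  g <- glance(fit)
  expect_equal(g$n_profiles, 12)
  expect_equal(round(g$max_ethanol, 2), 98.13)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
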