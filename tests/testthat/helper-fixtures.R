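# Shared fixtures: the bundled benchmark tables plus the published summary
# rows they must reproduce (transcribed once here, frozen).

# all(|actual - expected| <= tol), with epsilon slack so a difference of
# exactly tol is not lost to binary representation
expect_within <- function(actual, expected, tol) {
  testthat::expect_lte(max(abs(actual - expected)), tol + 1e-9)
}

corn_substrate <- function() substrate_spec(200, 183.3, added_glucose = 5)

flask_products <- function() {
  read_products(fermbalance_example("products_flask_Y294_192h.csv"))
}

industrial_products <- function() {
  read_products(fermbalance_example("products_industrial_192h.csv"))
}

industrial_coverage <- function() {
  read_coverage(fermbalance_example("coverage_industrial.csv"))
}

# Published summary rows for the 7 laboratory-strain columns, in file order.
flask_printed <- function() {
  tibble::tibble(
    total        = c(103.21, 177.33, 101.04, 111.95, 89.60, 99.20, 112.65),
    conversion   = c(50, 85, 49, 54, 43, 48, 54),
    yield        = c(46, 60, 47, 51, 41, 45, 51),
    productivity = c(0.25, 0.32, 0.25, 0.28, 0.23, 0.24, 0.28)
  )
}

# Published summary rows for the 12 industrial-strain columns, in file order.
industrial_printed <- function() {
  tibble::tibble(
    total        = c(192.51, 195.77, 196.07, 199.98, 180.79, 196.78,
                     207.00, 196.33, 208.63, 204.25, 169.66, 173.62),
    conversion   = c(92, 94, 94, 96, 87, 94, 99, 94, 100, 98, 81, 83),
    yield        = c(92, 93, 93, 94, 86, 94, 78, 61, 73, 55, 60, 26),
    productivity = c(0.50, 0.51, 0.51, 0.51, 0.47, 0.51,
                     0.42, 0.33, 0.40, 0.30, 0.33, 0.14)
  )
}

# Published copy-number ratios (in coverage-file target order:
# ER temA, ER temG_Opt, M2n temA, M2n temG_Opt).
printed_copy_ratios <- function() c(4.46, 7.20, 0.92, 0.99)
printed_copy_calls <- function() c(4L, 7L, 1L, 1L)
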