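PRODUCT_ANALYTES <- c("glucose", "maltose", "glycerol", "acetic_acid", "ethanol")

# Pulls the analyte columns out of a products data frame, validates them, and
# fills in co2 (inferred from ethanol unless measured values are present and
# trusted). Returns a tibble of the six analyte concentrations.
prepare_products <- function(products, table = carbon_table(),
                             co2 = c("infer", "measured")) {
  co2 <- rlang::arg_match(co2)
  products <- as_tibble(products)
  analyte_cols <- intersect(names(products), table$analyte)
  missing <- setdiff(PRODUCT_ANALYTES, names(products))
  if (length(missing) > 0) {
    stop_validation(paste0(
      "products table is missing analyte column(s): ",
      paste(missing, collapse = ", "), "."
    ))
  }
  unknown <- setdiff(analyte_cols, table$analyte)
  if (length(unknown) > 0) {
    stop_validation(paste0("unknown analyte(s): ", paste(unknown, collapse = ", "), "."))
  }
  conc <- products[analyte_cols]
  for (col in analyte_cols) check_number(conc[[col]], col, min = 0)
  if (co2 == "infer" || is.null(conc[["co2"]])) {
    conc$co2 <- co2_from_ethanol(conc$ethanol)
  }
  conc
}

#' Infer evolved CO2 from the ethanol titre
#'
#' Alcoholic fermentation releases one mole of CO2 per mole of ethanol, so
#' the CO2 evolved (never measured directly in shake-bottle fermentations)
#' is deduced from the ethanol concentration as `ethanol * 44/46`.
#'
#' @param ethanol Ethanol concentration(s), g/l.
#' @return CO2 in g/l, full precision (reports round to 2 decimals).
#' @examples
#' co2_from_ethanol(98.13) # 93.87 after rounding
#' @export
co2_from_ethanol <- function(ethanol) {
  check_number(ethanol, "ethanol", min = 0)
  ethanol * 44 / 46
}

#' Estimated carbon conversion of the substrate
#'
#' The fraction (as a percent) of the substrate's available carbon recovered
#' in fermentation products, on a mol-carbon basis:
#' \deqn{100 \times \frac{\sum_a c_a \, n_a / M_a}{\mathrm{GE} \times 6/180}}
#' where \eqn{c_a} is the concentration of analyte \eqn{a} (g/l), \eqn{n_a}
#' its carbon atoms per molecule, \eqn{M_a} its molar mass, and GE the
#' substrate's glucose equivalent. The sum runs over residual glucose and
#' maltose, glycerol, acetic acid, ethanol, and CO2 (inferred from ethanol
#' unless measured). Ethanol and its stoichiometric CO2 together account for
#' all six carbons of each fermented glucose, so a complete fermentation of
#' fully hydrolysed substrate gives exactly 100%.
#'
#' @param products Data frame with one row per strain/time point and analyte
#'   columns `glucose`, `maltose`, `glycerol`, `acetic_acid`, `ethanol` and
#'   optionally `co2`, in g/l.
#' @param substrate A [substrate_spec()], or a numeric glucose equivalent in
#'   g/l.
#' @param table A [carbon_table()].
#' @param co2 `"infer"` (default) replaces any co2 column with the
#'   stoichiometric value from ethanol; `"measured"` uses a supplied co2
#'   column as-is.
#' @return Numeric vector of conversions, percent, full precision (reports
#'   round to integers). Values above 105% trigger a data-inconsistency
#'   warning: products cannot contain more carbon than the substrate supplied.
#' @examples
#' prof <- data.frame(glucose = 0.09, glycerol = 3.73, acetic_acid = 0,
#'                    ethanol = 98.13, maltose = 0.96)
#' carbon_conversion(prof, 208.5) # ~94.4
#' @export
carbon_conversion <- function(products, substrate, table = carbon_table(),
                              co2 = c("infer", "measured")) {
  conc <- prepare_products(products, table, co2)
  pc <- product_carbon(conc, table)
  conv <- 100 * pc / available_carbon(substrate)
  if (any(conv > 105)) {
    warn(
      sprintf(
        "carbon conversion above 105%% (max %.1f%%): product carbon exceeds substrate carbon; check concentrations and substrate spec.",
        max(conv)
      ),
      class = "fermbalance_inconsistency_warning"
    )
  }
  conv
}

# mol carbon per litre summed over analyte columns
product_carbon <- function(conc, table = carbon_table()) {
  cpg <- carbon_per_gram(table)
  cols <- intersect(names(conc), names(cpg))
  as.numeric(as.matrix(conc[cols]) %*% cpg[cols])
}

#' Ethanol yield as percent of the theoretical maximum
#'
#' Observed ethanol per gram of available glucose, normalised by the
#' theoretical maximum yield factor:
#' `100 * (ethanol / glucose_equiv) / theoretical_factor`.
#'
#' @param ethanol Ethanol titre, g/l.
#' @param glucose_equiv Available glucose (the substrate's glucose
#'   equivalent), g/l; may be a [substrate_spec()], in which case its
#'   `theoretical_factor` is also used.
#' @param theoretical_factor Maximum g ethanol per g glucose (default 0.50;
#'   see [substrate_spec()]).
#' @return Percent of theoretical yield, full precision (reports round to
#'   integers).
#' @examples
#' ethanol_yield_pct(62.20, 208.5) # ~59.7, reported as 60
#' @export
ethanol_yield_pct <- function(ethanol, glucose_equiv, theoretical_factor = 0.50) {
  if (inherits(glucose_equiv, "substrate_spec")) {
    theoretical_factor <- glucose_equiv$theoretical_factor
    glucose_equiv <- glucose_equivalent(glucose_equiv)
  }
  check_number(ethanol, "ethanol", min = 0)
  check_number(glucose_equiv, "glucose_equiv", min = 0, strict = TRUE)
  check_number(theoretical_factor, "theoretical_factor", min = 0, strict = TRUE)
  100 * (ethanol / glucose_equiv) / theoretical_factor
}

#' Volumetric ethanol productivity
#'
#' Ethanol produced per hour of fermentation, g/l/h, on total elapsed time
#' from inoculation (not an interval rate).
#'
#' @param ethanol Ethanol titre, g/l.
#' @param elapsed_h Elapsed fermentation time, hours (> 0).
#' @return g/l/h, full precision (reports round to 2 decimals).
#' @examples
#' ethanol_productivity(62.20, 192) # ~0.32
#' @export
ethanol_productivity <- function(ethanol, elapsed_h) {
  check_number(ethanol, "ethanol", min = 0)
  check_number(elapsed_h, "elapsed_h", min = 0, strict = TRUE)
  ethanol / elapsed_h
}

#' Total mass of fermentation products
#'
#' Sum of the six analyte concentrations (CO2 included, inferred from ethanol
#' when absent).
#'
#' @inheritParams carbon_conversion
#' @return g/l per row, full precision (reports round to 2 decimals).
#' @export
total_products <- function(products, table = carbon_table(),
                           co2 = c("infer", "measured")) {
  conc <- prepare_products(products, table, co2)
  rowSums(as.matrix(conc))
}

#' Fold change between two measurements
#'
#' @param numerator,denominator Positive measurements on the same scale
#'   (titres, activities, ...); `denominator > 0`.
#' @return `numerator / denominator`, full precision (reports round to 1
#'   decimal).
#' @examples
#' fold_change(51.71, 33.14) # 1.6-fold
#' @export
fold_change <- function(numerator, denominator) {
  check_number(numerator, "numerator")
  check_number(denominator, "denominator", min = 0, strict = TRUE)
  numerator / denominator
}

#' Summarise a fermentation time course
#'
#' Applies the full carbon-balance accounting to each row of a product table:
#' CO2 inference, product carbon, estimated carbon conversion, percent of
#' theoretical ethanol yield, volumetric productivity and total product mass.
#' All values are returned at full precision; [render_report()] applies the
#' conventional rounding (integer percents, 2-decimal titres and rates).
#'
#' @param products Data frame with analyte columns (see [carbon_conversion()])
#'   and optionally `strain` and `time_h`. Within each strain, time points
#'   must be strictly increasing.
#' @inheritParams carbon_conversion
#' @return A tibble with one row per input row: `strain`, `time_h`,
#'   `glucose_equivalent`, `available_carbon`, the six analyte
#'   concentrations, `product_carbon`, `carbon_conversion_pct`,
#'   `ethanol_yield_pct`, `productivity` and `total_products`.
#' @examples
#' corn <- substrate_spec(200, 183.3, added_glucose = 5)
#' prof <- data.frame(strain = "M2n T1", time_h = 192, glucose = 0.09,
#'                    glycerol = 3.73, acetic_acid = 0, ethanol = 98.13,
#'                    maltose = 0.96)
#' summarize_fermentation(prof, corn)
#' @export
summarize_fermentation <- function(products, substrate, table = carbon_table(),
                                   co2 = c("infer", "measured")) {
  products <- as_tibble(products)
  if (nrow(products) == 0) {
    return(tibble(
      strain = character(), time_h = double(), glucose_equivalent = double(),
      available_carbon = double(), glucose = double(), maltose = double(),
      glycerol = double(), acetic_acid = double(), ethanol = double(),
      co2 = double(), product_carbon = double(), carbon_conversion_pct = double(),
      ethanol_yield_pct = double(), productivity = double(),
      total_products = double()
    ))
  }
  strain <- if ("strain" %in% names(products)) as.character(products$strain) else "sample"
  time_h <- if ("time_h" %in% names(products)) products$time_h else NA_real_
  if (!all(is.na(time_h))) {
    check_number(time_h[!is.na(time_h)], "time_h", min = 0, strict = TRUE)
    bad <- tapply(time_h, strain, function(t) any(diff(t) <= 0))
    if (any(unlist(bad), na.rm = TRUE)) {
      stop_validation("time points must be strictly increasing within each strain.")
    }
  }
  conc <- prepare_products(products, table, co2)
  ge <- glucose_equivalent(substrate)
  pc <- product_carbon(conc, table)
  dplyr::bind_cols(
    tibble(
      strain = strain,
      time_h = time_h,
      glucose_equivalent = ge,
      available_carbon = available_carbon(substrate)
    ),
    conc[c("glucose", "maltose", "glycerol", "acetic_acid", "ethanol", "co2")],
    tibble(
      product_carbon = pc,
      carbon_conversion_pct = carbon_conversion(products, substrate, table, co2),
      ethanol_yield_pct = ethanol_yield_pct(conc$ethanol, substrate),
      productivity = ifelse(is.na(time_h), NA_real_, conc$ethanol / time_h),
      total_products = rowSums(as.matrix(conc))
    )
  )
}

#' Analyse a fermentation product table
#'
#' Convenience wrapper pairing [summarize_fermentation()] output with the
#' substrate specification it was computed under; supports [tidy()],
#' [glance()] and [ggplot2::autoplot()].
#'
#' @inheritParams summarize_fermentation
#' @return A `ferm_analysis` object.
#' @examples
#' corn <- substrate_spec(200, 183.3, added_glucose = 5)
#' sim <- simulate_fermentation(ferm_sim_config(substrate = corn, seed = 1))
#' fit <- analyze_fermentation(sim, corn)
#' glance(fit)
#' @export
analyze_fermentation <- function(products, substrate, table = carbon_table(),
                                 co2 = c("infer", "measured")) {
  summary <- summarize_fermentation(products, substrate, table, co2)
  structure(
    list(summary = summary, substrate = substrate, carbon_table = table),
    class = "ferm_analysis"
  )
}

#' @export
print.ferm_analysis <- function(x, ...) {
  cat(sprintf(
    "<ferm_analysis> %d profile(s), %d strain(s); glucose equivalent %.1f g/l\n",
    nrow(x$summary), dplyr::n_distinct(x$summary$strain),
    glucose_equivalent(x$substrate)
  ))
  print(x$summary, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname analyze_fermentation
#' @param x A `ferm_analysis` object.
#' @param ... Unused.
#' @export
tidy.ferm_analysis <- function(x, ...) x$summary

#' @rdname analyze_fermentation
#' @method glance ferm_analysis
#' @export
glance.ferm_analysis <- function(x, ...) {
  s <- x$summary
  last <- s[order(s$time_h), ]
  last <- last[!duplicated(last$strain, fromLast = TRUE), ]
  tibble(
    n_profiles = nrow(s),
    n_strains = dplyr::n_distinct(s$strain),
    glucose_equivalent = glucose_equivalent(x$substrate),
    available_carbon = available_carbon(x$substrate),
    max_ethanol = max(s$ethanol),
    final_conversion_pct = mean(last$carbon_conversion_pct),
    final_yield_pct = mean(last$ethanol_yield_pct)
  )
}

#' @rdname analyze_fermentation
#' @param object A `ferm_analysis` object.
#' @method autoplot ferm_analysis
#' @export
autoplot.ferm_analysis <- function(object, ...) {
  s <- object$summary
  if (all(is.na(s$time_h))) {
    return(
      ggplot2::ggplot(s, ggplot2::aes(x = .data$strain, y = .data$carbon_conversion_pct)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "Estimated carbon conversion (%)") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(
    s,
    ggplot2::aes(x = .data$time_h, y = .data$carbon_conversion_pct, colour = .data$strain)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Fermentation time (h)", y = "Estimated carbon conversion (%)",
      colour = "Strain"
    ) +
    ggplot2::theme_minimal()
}
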