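#' Carbon accounting table for fermentation analytes
#'
#' The stoichiometric constants that drive the carbon-balance statistic: for
#' each analyte, the number of carbon atoms per molecule and the molar mass in
#' g/mol. Dividing a concentration in g/l by the molar mass and multiplying by
#' the carbon count converts it to mol carbon per litre.
#'
#' The default table covers the six carbon-bearing species tracked in a
#' raw-starch ethanol fermentation: residual maltose and glucose, the
#' overflow metabolites glycerol and acetic acid, ethanol, and CO2 (one mole
#' evolved per mole of ethanol formed).
#'
#' @param entries Optional data frame with columns `analyte`, `carbon_atoms`
#'   and `molar_mass` to replace or extend the default table. Rows whose
#'   `analyte` matches a default entry override it.
#' @return A tibble with columns `analyte` (character), `carbon_atoms`
#'   (integer) and `molar_mass` (double, g/mol).
#' @examples
#' carbon_table()
#' # track an extra analyte
#' carbon_table(data.frame(analyte = "lactic_acid", carbon_atoms = 3, molar_mass = 90))
#' @export
carbon_table <- function(entries = NULL) {
  tbl <- tibble(
    analyte      = c("maltose", "glucose", "glycerol", "acetic_acid", "ethanol", "co2"),
    carbon_atoms = c(12L, 6L, 3L, 2L, 2L, 1L),
    molar_mass   = c(342, 180, 92, 60, 46, 44)
  )
  if (!is.null(entries)) {
    entries <- as_tibble(entries)
    required <- c("analyte", "carbon_atoms", "molar_mass")
    if (!all(required %in% names(entries))) {
      stop_validation("`entries` needs columns analyte, carbon_atoms, molar_mass.")
    }
    entries <- dplyr::mutate(entries,
      carbon_atoms = as.integer(.data$carbon_atoms),
      molar_mass = as.double(.data$molar_mass)
    )
    tbl <- dplyr::bind_rows(
      dplyr::anti_join(tbl, entries, by = "analyte"),
      entries[required]
    )
  }
  validate_carbon_table(tbl)
}

validate_carbon_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  if (anyDuplicated(tbl$analyte)) {
    stop_validation("carbon table has duplicated analyte names.")
  }
  check_number(tbl$carbon_atoms, "carbon_atoms", min = 1)
  check_number(tbl$molar_mass, "molar_mass", min = 0, strict = TRUE)
  tbl
}

# mol carbon per g of analyte, named by analyte
carbon_per_gram <- function(table = carbon_table()) {
  stats::setNames(table$carbon_atoms / table$molar_mass, table$analyte)
}
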