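#' Specify the fermentation substrate loading
#'
#' Describes the carbohydrate fed to a raw-starch fermentation: the as-is
#' starch loading, its dry-weight basis, and any free glucose added to the
#' medium. Complete hydrolysis of starch adds one water per glycosidic bond,
#' so each gram of dry starch yields `hydrolysis_factor` grams of glucose
#' (1.11 by default).
#'
#' @param starch_as_is As-is (wet) starch loading, g/l. Carried for reporting.
#' @param starch_dry Dry-weight starch loading, g/l. Must satisfy
#'   `0 < starch_dry <= starch_as_is`.
#' @param added_glucose Free glucose added to the medium, g/l.
#' @param hydrolysis_factor Grams of glucose released per gram of dry starch
#'   on complete hydrolysis; must exceed 1 (water addition).
#' @param theoretical_factor Maximum grams of ethanol per gram of glucose used
#'   to normalise yields. The stoichiometric bound is 0.511; the default 0.50
#'   is the conventional value used in published raw-starch fermentation
#'   tables and reproduces them after integer rounding.
#' @return An object of class `substrate_spec`.
#' @examples
#' # 200 g/l raw corn starch (183.3 g/l dry weight) plus 5 g/l glucose
#' corn <- substrate_spec(200, 183.3, added_glucose = 5)
#' glucose_equivalent(corn)
#' @export
substrate_spec <- function(starch_as_is, starch_dry = starch_as_is,
                           added_glucose = 0, hydrolysis_factor = 1.11,
                           theoretical_factor = 0.50) {
  check_number(starch_as_is, "starch_as_is", min = 0, strict = TRUE)
  check_number(starch_dry, "starch_dry", min = 0, strict = TRUE)
  if (starch_dry > starch_as_is) {
    stop_validation("`starch_dry` cannot exceed `starch_as_is`.")
  }
  check_number(added_glucose, "added_glucose", min = 0)
  check_number(hydrolysis_factor, "hydrolysis_factor", min = 1, strict = TRUE)
  check_number(theoretical_factor, "theoretical_factor", min = 0, strict = TRUE)
  structure(
    list(
      starch_as_is = starch_as_is, starch_dry = starch_dry,
      added_glucose = added_glucose, hydrolysis_factor = hydrolysis_factor,
      theoretical_factor = theoretical_factor
    ),
    class = "substrate_spec"
  )
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat("<substrate_spec>\n")
  cat(sprintf("  starch: %.1f g/l as-is (%.1f g/l dry)\n", x$starch_as_is, x$starch_dry))
  cat(sprintf("  added glucose: %.1f g/l\n", x$added_glucose))
  cat(sprintf("  glucose equivalent: %.1f g/l (factor %.2f)\n",
              glucose_equivalent(x), x$hydrolysis_factor))
  cat(sprintf("  theoretical ethanol yield: %.3f g/g glucose\n", x$theoretical_factor))
  invisible(x)
}

#' Glucose equivalent of a substrate loading
#'
#' Mass of glucose obtainable from complete hydrolysis of the dry starch plus
#' any glucose supplied directly:
#' `starch_dry * hydrolysis_factor + added_glucose`.
#'
#' @param substrate A [substrate_spec()].
#' @return Glucose equivalent in g/l (full precision; reports round to 1
#'   decimal).
#' @examples
#' glucose_equivalent(substrate_spec(200, 183.3, added_glucose = 5)) # 208.46
#' @export
glucose_equivalent <- function(substrate) {
  stopifnot(inherits(substrate, "substrate_spec"))
  substrate$starch_dry * substrate$hydrolysis_factor + substrate$added_glucose
}

#' Available carbon in the fully hydrolysed substrate
#'
#' Converts a glucose equivalent (g/l) to mol carbon per litre: six carbon
#' atoms per 180 g/mol of glucose. A 208.5 g/l glucose equivalent carries
#' 6.95 mol carbon per litre.
#'
#' @param glucose_equiv Glucose equivalent, g/l; may also be a
#'   [substrate_spec()].
#' @return mol carbon per litre.
#' @examples
#' available_carbon(208.5) # 6.95
#' @export
available_carbon <- function(glucose_equiv) {
  if (inherits(glucose_equiv, "substrate_spec")) {
    glucose_equiv <- glucose_equivalent(glucose_equiv)
  }
  check_number(glucose_equiv, "glucose_equiv", min = 0, strict = TRUE)
  glucose_equiv * 6 / 180
}
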