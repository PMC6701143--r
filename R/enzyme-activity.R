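#' Amylase activity in units per millilitre
#'
#' One enzyme unit (U) releases one micromole of glucose per minute under the
#' assay conditions; activity is expressed per millilitre of culture
#' supernatant: `glucose_umol / minutes / volume_ml`.
#'
#' @param glucose_umol Glucose released during the assay, micromoles.
#' @param minutes Assay duration, minutes (> 0).
#' @param volume_ml Supernatant volume assayed, ml (> 0).
#' @return Activity in U/ml, full precision (reports round to 2 decimals).
#' @examples
#' activity_units(27.6, 10, 2) # 1.38 U/ml
#' @export
activity_units <- function(glucose_umol, minutes, volume_ml) {
  check_number(glucose_umol, "glucose_umol", min = 0)
  check_number(minutes, "minutes", min = 0, strict = TRUE)
  check_number(volume_ml, "volume_ml", min = 0, strict = TRUE)
  glucose_umol / minutes / volume_ml
}

#' Fold difference between two activities
#'
#' @param a,b Activities in U/ml; `b > 0`.
#' @return `a / b`, full precision (reports round to 1 decimal).
#' @examples
#' activity_fold(15.30, 3.99) # 3.8-fold
#' @export
activity_fold <- function(a, b) fold_change(a, b)

#' Summarise an enzyme-assay table
#'
#' Converts raw assay measurements (micromoles of glucose released over a
#' timed incubation of a supernatant volume) to U/ml, keeping the assay
#' condition labels: substrate form (raw vs soluble starch), loading,
#' temperature and assay chemistry (reducing-sugar vs glucose-only
#' detection, a reporting label only).
#'
#' @param assays Data frame with columns `glucose_umol`, `minutes`,
#'   `volume_ml` and optionally `strain`, `substrate_form`, `substrate_load`,
#'   `temperature`, `assay_kind`.
#' @return The input as a tibble with an `activity_u_ml` column appended.
#' @examples
#' summarize_assays(data.frame(strain = "ER T12", substrate_form = "raw",
#'                             glucose_umol = 27.6, minutes = 10, volume_ml = 2))
#' @export
summarize_assays <- function(assays) {
  assays <- as_tibble(assays)
  required <- c("glucose_umol", "minutes", "volume_ml")
  missing <- setdiff(required, names(assays))
  if (length(missing) > 0) {
    stop_validation(paste0(
      "assay table is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  if ("substrate_form" %in% names(assays)) {
    bad <- setdiff(unique(assays$substrate_form), c("raw", "soluble"))
    if (length(bad) > 0) {
      stop_validation(paste0(
        "substrate_form must be 'raw' or 'soluble'; got: ",
        paste(bad, collapse = ", "), "."
      ))
    }
  }
  dplyr::mutate(
    assays,
    activity_u_ml = activity_units(.data$glucose_umol, .data$minutes, .data$volume_ml)
  )
}
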