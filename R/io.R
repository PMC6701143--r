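PRODUCTS_SCHEMA <- c("strain", "time_h", "glucose", "maltose", "glycerol",
                     "acetic_acid", "ethanol")
COVERAGE_SCHEMA <- c("sample", "gene", "avg_coverage", "role")
ASSAYS_SCHEMA <- c("strain", "substrate_form", "substrate_load", "temperature",
                   "assay_kind", "glucose_umol", "minutes", "volume_ml")

stop_io <- function(msg, ...) {
  abort(msg, class = "fermbalance_io_error", ...)
}

read_checked_csv <- function(path, required, optional = character(),
                             numeric_cols) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_validation(sprintf(
      "malformed value in %s at row %d, column %d (expected %s).",
      basename(path), probs$row[1], probs$col[1], probs$expected[1]
    ))
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_validation(sprintf(
      "%s is missing required column(s): %s.",
      basename(path), paste(missing, collapse = ", ")
    ))
  }
  unknown <- setdiff(names(df), c(required, optional))
  if (length(unknown) > 0) {
    stop_validation(sprintf(
      "%s has unknown column(s): %s.",
      basename(path), paste(unknown, collapse = ", ")
    ))
  }
  for (col in intersect(numeric_cols, names(df))) {
    # a header-only file guesses every column as character; coerce
    if (nrow(df) == 0) df[[col]] <- as.double(df[[col]])
    if (!is.numeric(df[[col]])) {
      stop_validation(sprintf(
        "column '%s' in %s is not numeric.", col, basename(path)
      ))
    }
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "negative value in %s at row %d, column '%s'.",
        basename(path), bad[1], col
      ))
    }
  }
  df
}

#' Read a fermentation product table
#'
#' Reads a CSV of product concentrations with the schema
#' `strain,time_h,glucose,maltose,glycerol,acetic_acid,ethanol[,co2]`
#' (g/l; `co2` optional — it is normally inferred from ethanol). Unknown
#' columns, missing columns, negative concentrations and malformed numbers
#' are rejected with errors naming the offending row and column.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated product profiles.
#' @examples
#' read_products(fermbalance_example("products_industrial_192h.csv"))
#' @export
read_products <- function(path) {
  read_checked_csv(
    path,
    required = PRODUCTS_SCHEMA, optional = "co2",
    numeric_cols = c("time_h", "glucose", "maltose", "glycerol",
                     "acetic_acid", "ethanol", "co2")
  )
}

#' Read a per-gene coverage table
#'
#' Schema: `sample,gene,avg_coverage,role` with role `target` or
#' `housekeeping`.
#'
#' @inheritParams read_products
#' @return A validated coverage tibble for [estimate_copy_number()].
#' @examples
#' read_coverage(fermbalance_example("coverage_industrial.csv"))
#' @export
read_coverage <- function(path) {
  df <- read_checked_csv(
    path,
    required = COVERAGE_SCHEMA, numeric_cols = "avg_coverage"
  )
  validate_coverage(df)
}

#' Read an enzyme-assay measurement table
#'
#' Schema: `strain,substrate_form,substrate_load,temperature,assay_kind,`
#' `glucose_umol,minutes,volume_ml`.
#'
#' @inheritParams read_products
#' @return A validated assay tibble for [summarize_assays()].
#' @export
read_assays <- function(path) {
  read_checked_csv(
    path,
    required = ASSAYS_SCHEMA,
    numeric_cols = c("substrate_load", "temperature", "glucose_umol",
                     "minutes", "volume_ml")
  )
}

#' Read a substrate specification from a YAML config
#'
#' Keys: `starch_as_is`, `starch_dry`, `added_glucose`, `hydrolysis_factor`,
#' `theoretical_factor` (the last three optional, with the
#' [substrate_spec()] defaults).
#'
#' @inheritParams read_products
#' @return A [substrate_spec()].
#' @examples
#' read_substrate(fermbalance_example("substrate_corn.yml"))
#' @export
read_substrate <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("starch_as_is", "starch_dry", "added_glucose",
                                   "hydrolysis_factor", "theoretical_factor"))
  if (length(unknown) > 0) {
    stop_validation(sprintf(
      "unknown substrate key(s): %s.", paste(unknown, collapse = ", ")
    ))
  }
  if (is.null(cfg$starch_as_is)) stop_validation("substrate config needs `starch_as_is`.")
  args <- c(list(starch_as_is = cfg$starch_as_is),
            cfg[setdiff(names(cfg), "starch_as_is")])
  do.call(substrate_spec, args)
}

#' Path to a bundled example dataset
#'
#' The package ships a benchmark dataset from a raw-starch CBP study:
#' 192-h product tables for amylolytic industrial (ER T12, M2n T1, with and
#' without granular-starch-enzyme supplementation, 30/37 degC) and laboratory
#' Y294 strains, per-gene sequencing coverage for the two sequenced
#' industrial strains, amylase activities, and the corn-starch substrate
#' config.
#'
#' @param file File name; with no argument, lists the available files.
#' @return Full path to the installed file.
#' @examples
#' fermbalance_example()
#' @export
fermbalance_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "fermbalance")))
  }
  path <- system.file("extdata", file, package = "fermbalance")
  if (path == "") stop_io(sprintf("no bundled file '%s'.", file))
  path
}

#' Assemble an analysis report
#'
#' Bundles fermentation summaries, copy-number estimates and activity rows
#' with a provenance block (inputs, parameters, active carbon table, package
#' version) for rendering.
#'
#' @param fermentation Optional tibble from [summarize_fermentation()].
#' @param copy_number Optional tibble from [estimate_copy_number()].
#' @param activity Optional tibble from [summarize_assays()].
#' @param inputs Named list or character vector recording input files.
#' @param params Named list of parameter values worth recording.
#' @param table The [carbon_table()] in force.
#' @return A `ferm_report` object.
#' @export
build_report <- function(fermentation = NULL, copy_number = NULL,
                         activity = NULL, inputs = list(), params = list(),
                         table = carbon_table()) {
  structure(
    list(
      fermentation = if (!is.null(fermentation)) as_tibble(fermentation),
      copy_number = if (!is.null(copy_number)) as_tibble(copy_number),
      activity = if (!is.null(activity)) as_tibble(activity),
      provenance = list(
        inputs = inputs, params = params,
        carbon_table = as.data.frame(table),
        package_version = as.character(utils::packageVersion("fermbalance"))
      )
    ),
    class = "ferm_report"
  )
}

# report-table rounding conventions: integer percents, 2-decimal
# concentrations/rates, 1-decimal glucose equivalent, 2-decimal ratios
round_fermentation <- function(df) {
  dplyr::mutate(
    df,
    glucose_equivalent = round_half_up(.data$glucose_equivalent, 1),
    available_carbon = round_half_up(.data$available_carbon, 2),
    dplyr::across(
      dplyr::any_of(c("glucose", "maltose", "glycerol", "acetic_acid",
                      "ethanol", "co2", "total_products")),
      ~ round_half_up(.x, 2)
    ),
    product_carbon = round_half_up(.data$product_carbon, 3),
    carbon_conversion_pct = round_half_up(.data$carbon_conversion_pct),
    ethanol_yield_pct = round_half_up(.data$ethanol_yield_pct),
    productivity = round_half_up(.data$productivity, 2)
  )
}

#' Render a report as TSV or JSON
#'
#' TSV output applies the conventional table rounding (integer conversion
#' and yield percents, 2-decimal concentrations and productivities, 2-decimal
#' copy ratios); JSON output keeps full precision and round-trips losslessly
#' through [read_report_json()]. Field order is stable, so identical inputs
#' render byte-identical text.
#'
#' @param report A `ferm_report` from [build_report()].
#' @param format `"tsv"` or `"json"`.
#' @return A single string of rendered text.
#' @export
render_report <- function(report, format = c("tsv", "json")) {
  stopifnot(inherits(report, "ferm_report"))
  format <- rlang::arg_match(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      unclass(report), digits = NA, auto_unbox = TRUE, null = "null", pretty = TRUE
    )))
  }
  sections <- list()
  if (!is.null(report$fermentation)) {
    sections$fermentation <- round_fermentation(report$fermentation)
  }
  if (!is.null(report$copy_number)) {
    sections$copy_number <- dplyr::mutate(
      report$copy_number,
      housekeeping_mean = round_half_up(.data$housekeeping_mean, 2),
      ratio = round_half_up(.data$ratio, 2)
    )
  }
  if (!is.null(report$activity)) {
    sections$activity <- dplyr::mutate(
      report$activity,
      activity_u_ml = round_half_up(.data$activity_u_ml, 2)
    )
  }
  chunks <- purrr::imap_chr(sections, function(df, name) {
    paste0(
      "# ", name, "\n",
      readr::format_tsv(dplyr::mutate(df, dplyr::across(
        dplyr::where(is.numeric), ~ format(.x, trim = TRUE, scientific = FALSE)
      )))
    )
  })
  paste0(paste(chunks, collapse = "\n"), collapse = "")
}

#' Parse a JSON report back into a `ferm_report`
#'
#' @param text JSON text produced by `render_report(report, "json")`.
#' @return A `ferm_report`; rendering it again reproduces the input text.
#' @export
read_report_json <- function(text) {
  parsed <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  structure(
    list(
      fermentation = if (!is.null(parsed$fermentation)) as_tibble(parsed$fermentation),
      copy_number = if (!is.null(parsed$copy_number)) as_tibble(parsed$copy_number),
      activity = if (!is.null(parsed$activity)) as_tibble(parsed$activity),
      provenance = parsed$provenance
    ),
    class = "ferm_report"
  )
}
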