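DEFAULT_HOUSEKEEPING <- c("ACT1", "ALG9", "PGK1", "TFC1")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

validate_coverage <- function(coverage) {
  coverage <- as_tibble(coverage)
  required <- c("gene", "avg_coverage", "role")
  missing <- setdiff(required, names(coverage))
  if (length(missing) > 0) {
    stop_validation(paste0(
      "coverage table is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  if (!"sample" %in% names(coverage)) coverage$sample <- "sample"
  bad_role <- setdiff(unique(coverage$role), c("target", "housekeeping"))
  if (length(bad_role) > 0) {
    stop_validation(paste0(
      "role must be 'target' or 'housekeeping'; got: ",
      paste(bad_role, collapse = ", "), "."
    ))
  }
  check_number(coverage$avg_coverage, "avg_coverage", min = 0)
  for (s in unique(coverage$sample)) {
    sub <- coverage[coverage$sample == s, ]
    if (!any(sub$role == "housekeeping")) {
      stop_validation(sprintf("sample '%s' has no housekeeping genes.", s))
    }
    if (!any(sub$role == "target")) {
      stop_validation(sprintf("sample '%s' has no target genes.", s))
    }
    hk <- sub$avg_coverage[sub$role == "housekeeping"]
    if (any(hk <= 0)) {
      stop_validation(sprintf("sample '%s' has zero housekeeping coverage.", s))
    }
  }
  coverage
}

#' Mean coverage of the housekeeping panel
#'
#' Unweighted arithmetic mean of the average sequencing depths of the
#' housekeeping genes, per sample. Housekeeping genes (by default the
#' single-copy references ACT1, ALG9, PGK1 and TFC1) anchor the depth that
#' corresponds to one genomic copy.
#'
#' @param coverage Data frame with columns `gene`, `avg_coverage`, `role`
#'   (`"target"` or `"housekeeping"`), and optionally `sample`.
#' @param weights Optional named numeric vector of per-gene weights for a
#'   weighted mean (e.g. gene lengths).
#' @return A tibble with columns `sample` and `housekeeping_mean` (full
#'   precision).
#' @examples
#' cov <- data.frame(gene = c("temA", "ACT1", "ALG9", "PGK1", "TFC1"),
#'                   avg_coverage = c(152, 35, 34, 34, 34),
#'                   role = c("target", rep("housekeeping", 4)))
#' housekeeping_mean(cov) # 34.25
#' @export
housekeeping_mean <- function(coverage, weights = NULL) {
  coverage <- validate_coverage(coverage)
  hk <- coverage[coverage$role == "housekeeping", ]
  if (!is.null(weights)) {
    missing_w <- setdiff(unique(hk$gene), names(weights))
    if (length(missing_w) > 0) {
      stop_validation(paste0(
        "weights missing for housekeeping gene(s): ",
        paste(missing_w, collapse = ", "), "."
      ))
    }
    hk$w <- weights[hk$gene]
  } else {
    hk$w <- 1
  }
  hk |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      housekeeping_mean = stats::weighted.mean(.data$avg_coverage, .data$w),
      .groups = "drop"
    )
}

#' Estimate integrated-gene copy number from coverage ratios
#'
#' In whole-genome sequencing, read depth over a locus scales with its
#' genomic copy number. The copy number of an integrated cassette is
#' therefore estimated as the ratio of the target gene's average coverage to
#' the mean coverage of a single-copy housekeeping panel; the nearest integer
#' (half away from zero) is the called copy number, and the fractional ratio
#' is always reported alongside.
#'
#' @inheritParams housekeeping_mean
#' @param genes Target genes to estimate; defaults to every `role == "target"`
#'   row. Unknown genes raise a lookup error.
#' @return A tibble of class `copynum_tbl` with columns `sample`, `gene`,
#'   `avg_coverage`, `housekeeping_mean`, `ratio` and `copies` (integer).
#' @examples
#' cov <- data.frame(
#'   gene = c("temA", "temG_Opt", "ALG9", "TFC1", "PGK1", "ACT1"),
#'   avg_coverage = c(152, 245, 34, 34, 34, 35),
#'   role = c("target", "target", rep("housekeeping", 4))
#' )
#' estimate_copy_number(cov) # 4 and 7 copies
#' @export
estimate_copy_number <- function(coverage, genes = NULL, weights = NULL) {
  coverage <- validate_coverage(coverage)
  targets <- coverage[coverage$role == "target", ]
  if (!is.null(genes)) {
    unknown <- setdiff(genes, targets$gene)
    if (length(unknown) > 0) {
      stop_lookup(paste0(
        "target gene(s) not in coverage table: ", paste(unknown, collapse = ", "), "."
      ))
    }
    targets <- targets[targets$gene %in% genes, ]
  }
  hk <- housekeeping_mean(coverage, weights)
  out <- targets |>
    dplyr::left_join(hk, by = "sample") |>
    dplyr::mutate(
      ratio = .data$avg_coverage / .data$housekeeping_mean,
      copies = as.integer(round_half_up(.data$ratio))
    ) |>
    dplyr::select("sample", "gene", "avg_coverage", "housekeeping_mean", "ratio", "copies")
  class(out) <- c("copynum_tbl", class(out))
  out
}

#' @rdname estimate_copy_number
#' @param object A `copynum_tbl`.
#' @param ... Unused.
#' @method autoplot copynum_tbl
#' @export
autoplot.copynum_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gene, y = .data$ratio)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(
      yintercept = seq_len(max(object$copies, 1)),
      linetype = "dotted", colour = "grey60"
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$copies), vjust = -0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::labs(x = NULL, y = "Coverage ratio (copies)") +
    ggplot2::theme_minimal()
}

#' Average coverage from a per-position depth vector
#'
#' Collapses a per-base read-depth export (e.g. `samtools depth` output for
#' one gene) to the average coverage used by [estimate_copy_number()].
#'
#' @param depths Non-empty vector of non-negative per-position depths.
#' @return Arithmetic mean depth.
#' @examples
#' depth_to_coverage(c(10, 10, 10)) # 10
#' @export
depth_to_coverage <- function(depths) {
  if (length(depths) == 0) stop_validation("`depths` is empty.")
  check_number(depths, "depths", min = 0)
  mean(depths)
}
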