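# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configure a synthetic fermentation time course
#'
#' Defines the generative model for synthetic product tables: substrate
#' carbon is released by a logistic hydrolysis curve
#' \eqn{h(t) = 1 / (1 + e^{-k (t - t_{1/2})})} and partitioned among product
#' pools by fixed carbon fractions; the ethanol+CO2 pool splits its carbon
#' 2:1 between ethanol and CO2 (two of each fermented glucose's six carbons
#' leave as CO2). Carbon is converted to g/l via the carbon table and
#' independent Gaussian measurement noise is added to each analyte, then
#' clipped at zero.
#'
#' Defaults emulate the benchmark fermentations bundled with the package:
#' 200 g/l raw corn starch (183.3 g/l dry) plus 5 g/l glucose, sampled every
#' 24 h to 192 h; hydrolysis reaching ~99.5% by 192 h; a product spectrum
#' dominated by ethanol+CO2 (95% of product carbon) with small glycerol,
#' acetate and residual-sugar pools; 1 g/l measurement noise, typical of
#' HPLC replicate scatter.
#'
#' @param substrate A [substrate_spec()].
#' @param h_mid Hydrolysis midpoint, hours (time at 50% hydrolysis).
#' @param h_steepness Logistic steepness, per hour.
#' @param partition Named carbon fractions for `ethanol_co2`, `glycerol`,
#'   `acetic_acid`, `glucose`, `maltose`; must be non-negative and sum to 1.
#' @param noise_sd Additive Gaussian noise on each analyte, g/l.
#' @param timepoints Sampling times, hours, strictly increasing.
#' @param seed Integer seed; all draws flow from this one generator.
#' @return A `ferm_sim_config` object.
#' @export
ferm_sim_config <- function(substrate = substrate_spec(200, 183.3, added_glucose = 5),
                            h_mid = 60, h_steepness = 0.04,
                            partition = c(
                              ethanol_co2 = 0.95, glycerol = 0.02,
                              acetic_acid = 0.005, glucose = 0.01,
                              maltose = 0.015
                            ),
                            noise_sd = 1, timepoints = seq(24, 192, by = 24),
                            seed = 1L) {
  stopifnot(inherits(substrate, "substrate_spec"))
  pools <- c("ethanol_co2", "glycerol", "acetic_acid", "glucose", "maltose")
  if (!setequal(names(partition), pools)) {
    stop_validation(paste0("partition must name exactly: ", paste(pools, collapse = ", "), "."))
  }
  partition <- partition[pools]
  check_number(partition, "partition", min = 0)
  if (abs(sum(partition) - 1) > 1e-12) {
    stop_validation(sprintf("partition fractions must sum to 1 (got %.15f).", sum(partition)))
  }
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(timepoints, "timepoints", min = 0, strict = TRUE)
  if (any(diff(timepoints) <= 0)) {
    stop_validation("timepoints must be strictly increasing.")
  }
  check_number(h_steepness, "h_steepness", min = 0, strict = TRUE)
  structure(
    list(
      substrate = substrate, h_mid = h_mid, h_steepness = h_steepness,
      partition = partition, noise_sd = noise_sd, timepoints = timepoints,
      seed = as.integer(seed)
    ),
    class = "ferm_sim_config"
  )
}

logistic_hydrolysis <- function(t, h_mid, h_steepness) {
  1 / (1 + exp(-h_steepness * (t - h_mid)))
}

#' Simulate a fermentation product time course
#'
#' Generates one synthetic product table under the generative model of
#' [ferm_sim_config()]. At each time point the hydrolysed carbon is
#' `h(t) * available_carbon(substrate)`; with zero noise the estimated
#' carbon conversion recovered by [carbon_conversion()] equals `100 * h(t)`
#' exactly, which makes the generator the ground truth for the whole
#' analysis chain. Output is deterministic for a fixed seed.
#'
#' CO2 is not included in the output: like the real measurements, it is left
#' to downstream stoichiometric inference from ethanol.
#'
#' @param config A [ferm_sim_config()].
#' @param strain Strain label for the output rows.
#' @return A tibble with columns `strain`, `time_h`, `glucose`, `maltose`,
#'   `glycerol`, `acetic_acid`, `ethanol` (g/l).
#' @examples
#' cfg <- ferm_sim_config(noise_sd = 0, seed = 42)
#' sim <- simulate_fermentation(cfg)
#' carbon_conversion(sim, cfg$substrate) # equals 100 * h(t)
#' @export
simulate_fermentation <- function(config, strain = "sim") {
  stopifnot(inherits(config, "ferm_sim_config"))
  tbl <- carbon_table()
  g_per_c <- stats::setNames(tbl$molar_mass / tbl$carbon_atoms, tbl$analyte)
  avail <- available_carbon(config$substrate)
  with_seed(config$seed, {
    rows <- purrr::map(config$timepoints, function(t) {
      h <- logistic_hydrolysis(t, config$h_mid, config$h_steepness)
      carbon <- h * avail * config$partition
      # ethanol takes 2/3 of the pool's carbon, CO2 the rest; CO2 itself is
      # re-inferred downstream so only ethanol is emitted
      conc <- c(
        glucose = unname(carbon["glucose"] * g_per_c["glucose"]),
        maltose = unname(carbon["maltose"] * g_per_c["maltose"]),
        glycerol = unname(carbon["glycerol"] * g_per_c["glycerol"]),
        acetic_acid = unname(carbon["acetic_acid"] * g_per_c["acetic_acid"]),
        ethanol = unname(carbon["ethanol_co2"] * (2 / 3) * g_per_c["ethanol"])
      )
      noisy <- pmax(conc + stats::rnorm(length(conc), 0, config$noise_sd), 0)
      tibble(strain = strain, time_h = t, !!!as.list(noisy))
    })
    dplyr::bind_rows(rows)
  })
}

#' Configure a synthetic coverage table
#'
#' Generative model for sequencing depth: every position of a gene draws a
#' Poisson read depth with mean `base_depth * copies`, where housekeeping
#' genes carry one copy. The reported `avg_coverage` is the mean over
#' `gene_length` positions, mirroring how per-gene average depth is computed
#' from alignments.
#'
#' Defaults mirror the bundled benchmark: targets `temA` (4 copies) and
#' `temG_Opt` (7 copies), housekeeping panel ACT1/ALG9/PGK1/TFC1 at ~34x,
#' and a 1500 bp gene (about the median yeast coding sequence).
#'
#' @param true_copies Named positive integers: copy number per target gene.
#' @param base_depth Mean depth of a single-copy locus (> 0).
#' @param gene_length Positions per gene (>= 1).
#' @param housekeeping Housekeeping gene names (single-copy).
#' @param seed Integer seed.
#' @return A `coverage_sim_config` object.
#' @export
coverage_sim_config <- function(true_copies = c(temA = 4, temG_Opt = 7),
                                base_depth = 34, gene_length = 1500,
                                housekeeping = DEFAULT_HOUSEKEEPING,
                                seed = 1L) {
  if (is.null(names(true_copies)) || any(names(true_copies) == "")) {
    stop_validation("`true_copies` must be a named vector of target genes.")
  }
  check_number(true_copies, "true_copies", min = 1)
  check_number(base_depth, "base_depth", min = 0, strict = TRUE)
  check_number(gene_length, "gene_length", min = 1)
  structure(
    list(
      true_copies = true_copies, base_depth = base_depth,
      gene_length = as.integer(gene_length),
      housekeeping = housekeeping, seed = as.integer(seed)
    ),
    class = "coverage_sim_config"
  )
}

#' Simulate a per-gene coverage table
#'
#' @param config A [coverage_sim_config()].
#' @param sample Sample label for the output rows.
#' @return A coverage tibble (`sample`, `gene`, `avg_coverage`, `role`)
#'   suitable for [estimate_copy_number()]; deterministic for a fixed seed.
#' @examples
#' cov <- simulate_coverage(coverage_sim_config(seed = 7))
#' estimate_copy_number(cov)
#' @export
simulate_coverage <- function(config, sample = "sim") {
  stopifnot(inherits(config, "coverage_sim_config"))
  genes <- c(names(config$true_copies), config$housekeeping)
  copies <- c(config$true_copies, rep(1, length(config$housekeeping)))
  roles <- c(
    rep("target", length(config$true_copies)),
    rep("housekeeping", length(config$housekeeping))
  )
  with_seed(config$seed, {
    avg <- vapply(copies, function(k) {
      mean(stats::rpois(config$gene_length, lambda = config$base_depth * k))
    }, numeric(1))
    tibble(sample = sample, gene = genes, avg_coverage = avg, role = roles)
  })
}
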