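# Simulation configuration. Defaults emulate the compiled study collection:
# 50 datasets spread over six continents (weights follow the compilation's
# continental distribution), 3-30 sites each, sampling years 2014-2023,
# nested basin/country/continent species pools, continent-dependent barcode
# reference-database coverage (weakest in Africa and South America), and a
# logit-linear congruence model with beta noise. Read depths are scaled down
# from the tens-of-thousands-to-millions range of real runs to keep simulated
# tables small.

#' Continents recognized by the generator
#' @export
edna_continents <- c("Africa", "Asia", "Europe", "North America",
                     "Oceania", "South America")

#' Simulation configuration
#'
#' @param n_datasets number of datasets in the collection.
#' @param continent_weights named sampling weights over the six continents.
#' @param year_range integer interval of sampling years.
#' @param sites_range integer interval of per-dataset site counts (min >= 3).
#' @param pool_sizes named integers `c(basin=, country=, continent=)`,
#'   strictly increasing basin < country < continent.
#' @param nesting optional fractions `c(country=, basin=)` in (0,1]; when
#'   supplied, country/basin pool sizes are derived from the continent size
#'   (`country = ceiling(f_country * continent)`, `basin = ceiling(f_basin *
#'   country)`) and override `pool_sizes[1:2]`.
#' @param refdb_coverage named per-continent probability that a pool species
#'   carries a barcode record.
#' @param depth_lognormal `c(meanlog=, sdlog=)` of per-dataset median site
#'   read totals; within-dataset site totals vary around the dataset median
#'   with `site_depth_sdlog`.
#' @param site_depth_sdlog between-site log-sd of read totals.
#' @param congruence_coefs named logit-scale coefficients
#'   `c(intercept=, log_reads=, year=, richness=)` for the expected
#'   shared-species proportion. Year is centered at `min(year_range)`,
#'   log reads at `depth_lognormal["meanlog"]`, richness at
#'   `richness_center`.
#' @param beta_coverage logit-scale effect of realized basin-scale reference
#'   coverage (centered at its weighted configured mean) on congruence.
#' @param beta_precision beta precision phi > 0 of the congruence noise.
#' @param unique_abundance_shift delta < 0: log-scale abundance penalty for
#'   species unique to the reanalysis.
#' @param richness_range interval of latent per-dataset community sizes.
#' @param richness_center centering constant for the richness predictor.
#' @param occupancy per-site presence probability of a detected species.
#' @param prop_custom probability a dataset originally used a custom
#'   reference database.
#' @param extra_local_rate named probabilities `c(global=, custom=)` that a
#'   basin-pool species missed by the reanalysis appears in the original
#'   assignment (category-3 species).
#' @param false_positive_mean Poisson mean of off-basin species added to the
#'   original assignment (category-4 species).
#' @param global_noise_mean Poisson mean of off-basin reference-database
#'   species entering the uncorrected (global) reanalysis.
#' @param barcode_weights named weights over barcode regions.
#' @param synonym_noise_rate probability in [0,1) that a species label is
#'   replaced by a synonym variant in the emitted tables.
#' @param seed integer seed; fixed seed gives byte-identical collections.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_datasets = 50,
                       continent_weights = c("Africa" = 1, "Asia" = 15,
                                             "Europe" = 17, "North America" = 12,
                                             "Oceania" = 4, "South America" = 9),
                       year_range = c(2014L, 2023L),
                       sites_range = c(3L, 30L),
                       pool_sizes = c(basin = 50L, country = 200L, continent = 800L),
                       nesting = NULL,
                       refdb_coverage = c("Africa" = 0.35, "Asia" = 0.75,
                                          "Europe" = 0.80, "North America" = 0.85,
                                          "Oceania" = 0.60, "South America" = 0.45),
                       depth_lognormal = c(meanlog = log(2e4), sdlog = 1),
                       site_depth_sdlog = 0.4,
                       congruence_coefs = c(intercept = -0.3, log_reads = 0.3,
                                            year = 0.15, richness = -0.02),
                       beta_coverage = 2,
                       beta_precision = 30,
                       unique_abundance_shift = -1,
                       richness_range = c(8L, 45L),
                       richness_center = 20,
                       occupancy = 0.7,
                       prop_custom = 21 / 58,
                       extra_local_rate = c(global = 0.05, custom = 0.25),
                       false_positive_mean = 2,
                       global_noise_mean = 3,
                       barcode_weights = c("12S" = 0.88, "16S" = 0.05,
                                           "COI" = 0.05, "CytB" = 0.02),
                       synonym_noise_rate = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_datasets = as.integer(n_datasets),
    continent_weights = continent_weights,
    year_range = as.integer(year_range),
    sites_range = as.integer(sites_range),
    pool_sizes = pool_sizes,
    nesting = nesting,
    refdb_coverage = refdb_coverage,
    depth_lognormal = depth_lognormal,
    site_depth_sdlog = site_depth_sdlog,
    congruence_coefs = congruence_coefs,
    beta_coverage = beta_coverage,
    beta_precision = beta_precision,
    unique_abundance_shift = unique_abundance_shift,
    richness_range = as.integer(richness_range),
    richness_center = richness_center,
    occupancy = occupancy,
    prop_custom = prop_custom,
    extra_local_rate = extra_local_rate,
    false_positive_mean = false_positive_mean,
    global_noise_mean = global_noise_mean,
    barcode_weights = barcode_weights,
    synonym_noise_rate = synonym_noise_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_datasets < 0) abort("invalid config: n_datasets must be >= 0")
  if (!all(edna_continents %in% names(cfg$continent_weights))) {
    abort("invalid config: continent_weights must name all six continents")
  }
  if (!all(edna_continents %in% names(cfg$refdb_coverage))) {
    abort("invalid config: refdb_coverage must name all six continents")
  }
  check_prob(cfg$refdb_coverage, "refdb_coverage")
  check_prob(cfg$occupancy, "occupancy")
  check_prob(cfg$prop_custom, "prop_custom")
  check_prob(cfg$extra_local_rate, "extra_local_rate")
  check_prob(cfg$synonym_noise_rate, "synonym_noise_rate", right_open = TRUE)
  if (cfg$sites_range[1] < 3) abort("invalid config: sites_range min must be >= 3")
  if (diff(cfg$year_range) < 0 || diff(cfg$sites_range) < 0) {
    abort("invalid config: ranges must be non-decreasing")
  }
  if (!is.null(cfg$nesting)) {
    check_prob(cfg$nesting, "nesting")
    if (any(cfg$nesting <= 0)) abort("invalid config: nesting fractions must be in (0,1]")
    cont <- cfg$pool_sizes[["continent"]]
    country <- ceiling(cfg$nesting[["country"]] * cont)
    basin <- ceiling(cfg$nesting[["basin"]] * country)
    cfg$pool_sizes <- c(basin = basin, country = country, continent = cont)
  }
  ps <- cfg$pool_sizes
  if (!all(c("basin", "country", "continent") %in% names(ps))) {
    abort("invalid config: pool_sizes must name basin, country, continent")
  }
  if (!(ps[["basin"]] <= ps[["country"]] && ps[["country"]] <= ps[["continent"]])) {
    abort("invalid config: pool_sizes must be non-decreasing basin <= country <= continent")
  }
  if (is.null(cfg$nesting) &&
      !(ps[["basin"]] < ps[["country"]] && ps[["country"]] < ps[["continent"]])) {
    abort("invalid config: pool_sizes must be strictly increasing basin < country < continent")
  }
  if (cfg$beta_precision <= 0) abort("invalid config: beta_precision must be > 0")
  if (cfg$richness_range[1] < 1) abort("invalid config: richness_range min must be >= 1")
  needed <- c("intercept", "log_reads", "year", "richness")
  if (!all(needed %in% names(cfg$congruence_coefs))) {
    abort("invalid config: congruence_coefs must name intercept, log_reads, year, richness")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_datasets, "datasets, seed", x$seed, "\n")
  cat("  pools (basin/country/continent):",
      paste(x$pool_sizes[c("basin", "country", "continent")], collapse = "/"), "\n")
  cat("  years", paste(x$year_range, collapse = "-"),
      "| sites", paste(x$sites_range, collapse = "-"), "\n")
  cat("  congruence coefs:",
      paste(sprintf("%s=%.3g", names(x$congruence_coefs), x$congruence_coefs),
            collapse = ", "),
      sprintf("| coverage=%.3g, phi=%.3g, delta=%.3g",
              x$beta_coverage, x$beta_precision, x$unique_abundance_shift), "\n")
  invisible(x)
}
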