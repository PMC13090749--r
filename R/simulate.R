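# Synthetic multi-dataset collections. The generator starts at assigned read
# tables (no raw reads, PCR, or ASV error profiles) and emulates the features
# the downstream analysis leans on: nested local species pools, regionally
# varying reference-database coverage, a logit-linear congruence model with
# beta noise, a log-abundance penalty for species unique to the reanalysis,
# and synonym noise on emitted species labels. Every dataset is rendered from
# its own derived seed so appending datasets never perturbs earlier ones.

species_namespace <- function(continent, size) {
  # Canonical binomials: one genus per 5 species so genus-level collapses are
  # non-trivial. Continent pools are disjoint by construction.
  cc <- c("Africa" = "Afro", "Asia" = "Asio", "Europe" = "Euro",
          "North America" = "Boreo", "Oceania" = "Oceano",
          "South America" = "Austro")[[continent]]
  genus <- sprintf("%sgenus%03d", cc, ceiling(seq_len(size) / 5))
  epithet <- sprintf("fish%03d", seq_len(size))
  paste(genus, epithet)
}

#' Generate a nested pool hierarchy for one continent
#'
#' Basin, country, and continent species pools with basin drawn from country
#' and country from continent, so `basin %in% country %in% continent` holds by
#' construction and the set sizes equal the configured sizes.
#'
#' @param config a [sim_config()].
#' @param continent one of [edna_continents].
#' @param seed optional seed; defaults to the config seed.
#' @return list with character vectors `basin`, `country`, `continent` and a
#'   `labels` list naming the three regions.
#' @export
sim_pool_hierarchy <- function(config, continent, seed = config$seed) {
  continent <- match.arg(continent, edna_continents)
  set.seed(seed)
  ps <- config$pool_sizes
  cont <- species_namespace(continent, ps[["continent"]])
  country <- sort(sample(cont, ps[["country"]]))
  basin <- sort(sample(country, ps[["basin"]]))
  list(
    basin = basin, country = country, continent = cont,
    labels = list(basin = paste0(continent, ":basin"),
                  country = paste0(continent, ":country"),
                  continent = continent)
  )
}

#' Generate a barcode reference database over a species pool
#'
#' Every pool species is included independently with probability
#' `coverage_prob`; `off_pool` additional non-pool taxa may be appended, as
#' real reference databases hold taxa outside any local pool.
#'
#' @param pool character vector of canonical species names.
#' @param coverage_prob inclusion probability in \[0,1\].
#' @param off_pool character vector of off-pool taxa to append.
#' @param primer primer/barcode label attached as an attribute.
#' @param seed optional seed (uses the current RNG stream when `NULL`).
#' @return character vector of species with barcode records.
#' @export
sim_reference_db <- function(pool, coverage_prob, off_pool = character(),
                             primer = "12S", seed = NULL) {
  check_prob(coverage_prob, "coverage_prob")
  if (!is.null(seed)) set.seed(seed)
  keep <- stats::runif(length(pool)) < coverage_prob
  out <- sort(unique(c(pool[keep], off_pool)))
  attr(out, "primer") <- primer
  out
}

# Region structure shared by all datasets of a collection: 2 countries per
# continent, 2 basins per country, plus one reference database per barcode
# covering each continent's pool at its configured probability.
sim_regions <- function(config) {
  set.seed(derive_seed(config$seed, 0))
  regions <- list()
  pools_long <- list()
  for (cont in edna_continents) {
    cont_pool <- species_namespace(cont, config$pool_sizes[["continent"]])
    countries <- list()
    for (j in 1:2) {
      country_pool <- sort(sample(cont_pool, config$pool_sizes[["country"]]))
      basins <- list()
      for (k in 1:2) {
        basins[[k]] <- sort(sample(country_pool, config$pool_sizes[["basin"]]))
      }
      names(basins) <- sprintf("%s:C%d:B%d", cont, j, 1:2)
      countries[[sprintf("%s:C%d", cont, j)]] <-
        list(pool = country_pool, basins = basins)
    }
    regions[[cont]] <- list(pool = cont_pool, countries = countries)
  }
  off_pool <- paste("Exoticgenus", sprintf("fish%03d", 1:40))
  refdb <- list()
  for (bc in names(config$barcode_weights)) {
    sp <- character()
    for (cont in edna_continents) {
      keep <- stats::runif(length(regions[[cont]]$pool)) <
        config$refdb_coverage[[cont]]
      sp <- c(sp, regions[[cont]]$pool[keep])
    }
    sp <- c(sp, off_pool[stats::runif(length(off_pool)) < 0.5])
    refdb[[bc]] <- sort(unique(sp))
  }
  list(regions = regions, refdb = refdb)
}

# One synonym variant per canonical name; the "x" suffix cannot collide with
# canonical epithets, which all end in digits.
sim_synonyms <- function(species) {
  synonym_table(variants = c(paste0(species, "x"), species),
                canonicals = c(species, species),
                provenance = "synthetic")
}

center_values <- function(config) {
  w <- config$continent_weights[edna_continents]
  list(
    log_reads = config$depth_lognormal[["meanlog"]],
    year = min(config$year_range),
    richness = config$richness_center,
    coverage = sum(w * config$refdb_coverage[edna_continents]) / sum(w)
  )
}

# Expected shared-species proportion on the logit scale, then beta noise.
congruence_mean <- function(config, log_reads, year, richness, coverage) {
  ct <- center_values(config)
  b <- config$congruence_coefs
  eta <- b[["intercept"]] +
    b[["log_reads"]] * (log_reads - ct$log_reads) +
    b[["year"]] * (year - ct$year) +
    b[["richness"]] * (richness - ct$richness) +
    config$beta_coverage * (coverage - ct$coverage)
  plogis(eta)
}

#' Generate one dataset
#'
#' Renders a global-assignment read table (species restricted to the
#' reference database), the matching original assignment (species set and
#' per-site presence), and the dataset metadata row. The expected
#' shared-species proportion follows the config's logit-linear congruence
#' model with beta noise at precision phi; species unique to the reanalysis
#' carry the log-abundance shift delta.
#'
#' @param config a [sim_config()].
#' @param pools output of [sim_pool_hierarchy()] (or one entry of the
#'   collection's region structure).
#' @param refdb character vector of reference-database species.
#' @param metadata list with `dataset_id`, `continent`, `year`, `barcode`,
#'   `refdb_type`, and optionally `country`/`basin` labels.
#' @param seed integer seed for this dataset.
#' @return list with `reads` (a read table), `original_species`,
#'   `original_presence` (species x site logical tibble), `metadata` (one-row
#'   tibble), and `truth` (shared/unique memberships and the drawn
#'   congruence probability).
#' @export
sim_dataset <- function(config, pools, refdb, metadata, seed = config$seed) {
  if (!length(pools$basin)) abort("invalid config: empty basin pool")
  set.seed(seed)
  n_sites <- sample(config$sites_range[1]:config$sites_range[2], 1)
  sites <- sprintf("S%02d", seq_len(n_sites))

  # Latent basin community and its detected (covered) part.
  rr <- pmin(config$richness_range, length(pools$basin))
  latent <- sample(pools$basin, sample(rr[1]:rr[2], 1))
  detected <- intersect(latent, refdb)
  covered_basin <- intersect(pools$basin, refdb)
  if (!length(detected)) {
    if (!length(covered_basin)) {
      abort("invalid config: reference database covers no basin-pool species")
    }
    detected <- sample(covered_basin, 1)
  }

  # Off-basin reference-database species entering the uncorrected assignment:
  # mostly congeners from the same continent, occasionally (1/4 of the noise
  # mean) taxa from other continents or outside any pool, as global
  # assignments against worldwide references produce.
  off_basin_cand <- setdiff(intersect(pools$continent, refdb), pools$basin)
  off_cont_cand <- setdiff(refdb, pools$continent)
  n_noise <- min(stats::rpois(1, config$global_noise_mean), length(off_basin_cand))
  n_off <- min(stats::rpois(1, config$global_noise_mean / 4), length(off_cont_cand))
  global_noise <- c(
    if (n_noise > 0) sample(off_basin_cand, n_noise) else character(),
    if (n_off > 0) sample(off_cont_cand, n_off) else character()
  )

  # Congruence: which detected species the original assignment also found.
  coverage <- length(covered_basin) / length(pools$basin)
  depth <- config$depth_lognormal
  mu_d <- stats::rnorm(1, depth[["meanlog"]], depth[["sdlog"]])
  year <- sample(config$year_range[1]:config$year_range[2], 1)
  mu_p <- congruence_mean(config, mu_d, year, length(detected), coverage)
  phi <- config$beta_precision
  p_true <- stats::rbeta(1, mu_p * phi, (1 - mu_p) * phi)
  shared <- detected[stats::runif(length(detected)) < p_true]

  # Original assignment: shared + missed local species + off-basin noise.
  elr <- config$extra_local_rate[[metadata$refdb_type]]
  missed <- setdiff(pools$basin, detected)
  extra_local <- missed[stats::runif(length(missed)) < elr]
  fp_cand <- setdiff(pools$continent, pools$basin)
  n_fp <- min(stats::rpois(1, config$false_positive_mean), length(fp_cand))
  extra_nonlocal <- if (n_fp > 0) sample(fp_cand, n_fp) else character()
  original <- sort(unique(c(shared, extra_local, extra_nonlocal)))

  # Read table over the global assignment, multinomial per site with
  # log-normal species effects; unique-to-reanalysis species shifted by delta.
  table_species <- sort(unique(c(detected, global_noise)))
  is_unique <- !(table_species %in% shared)
  logw <- stats::rnorm(length(table_species), 0, 1) +
    config$unique_abundance_shift * is_unique
  occ <- matrix(stats::runif(length(table_species) * n_sites) < config$occupancy,
                nrow = length(table_species))
  empty <- colSums(occ) == 0
  if (any(empty)) occ[which.max(logw), empty] <- TRUE
  totals <- pmax(1, round(stats::rlnorm(n_sites, mu_d, config$site_depth_sdlog)))
  counts <- matrix(0L, length(table_species), n_sites,
                   dimnames = list(table_species, sites))
  w <- exp(logw)
  for (s in seq_len(n_sites)) {
    ws <- w * occ[, s]
    counts[, s] <- stats::rmultinom(1, totals[s], ws)[, 1]
  }
  reads <- as_read_table(
    as_tibble(counts, rownames = "species"),
    dataset_id = metadata$dataset_id
  )

  # Original per-site presence: shared species occupy where the reanalysis
  # saw reads (with detection slack), extras occupy sites independently.
  pres <- matrix(FALSE, length(original), n_sites,
                 dimnames = list(original, sites))
  sh <- intersect(original, shared)
  if (length(sh)) {
    seen <- counts[sh, , drop = FALSE] > 0
    pres[sh, ] <- seen & matrix(stats::runif(length(seen)) < 0.9, nrow = length(sh))
  }
  ex <- setdiff(original, shared)
  if (length(ex)) {
    pres[ex, ] <- matrix(stats::runif(length(ex) * n_sites) < 0.5, nrow = length(ex))
  }

  md <- tibble(
    dataset_id = metadata$dataset_id,
    continent = metadata$continent,
    country = metadata$country %||% NA_character_,
    basin = metadata$basin %||% NA_character_,
    year = as.integer(year),
    barcode = metadata$barcode,
    refdb_type = metadata$refdb_type,
    n_sites = n_sites,
    median_fish_reads = stats::median(colSums(counts))
  )
  list(
    reads = reads,
    original_species = original,
    original_presence = as_tibble(pres, rownames = "species"),
    metadata = md,
    truth = list(p_true = p_true, mu_p = mu_p, shared = sort(shared),
                 extra_local = sort(extra_local),
                 extra_nonlocal = sort(extra_nonlocal),
                 detected = sort(detected), coverage = coverage)
  )
}

#' Generate a full synthetic collection
#'
#' @param config a [sim_config()].
#' @return An `edna_collection`: list with `datasets` (nested tibble, one row
#'   per dataset with list-columns `reads`, `original_species`,
#'   `original_presence`), `pools` (long tibble dataset_id/scale/species),
#'   `refdb` (tibble primer/species), `synonyms`, and `truth` (generating
#'   parameters, per-dataset memberships, canonical-name map, realized
#'   coverage). When `config$synonym_noise_rate > 0`, species labels in the
#'   emitted read tables and original lists carry synonym noise; the truth
#'   record and pools stay canonical. [harmonize_collection()] restores
#'   canonical labels exactly.
#' @export
sim_collection <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  world <- sim_regions(config)
  all_species <- sort(unique(c(
    unlist(lapply(world$regions, `[[`, "pool"), use.names = FALSE),
    unlist(world$refdb, use.names = FALSE)
  )))
  synonyms <- sim_synonyms(all_species)

  n <- config$n_datasets
  rows <- vector("list", n)
  truth_ds <- vector("list", n)
  pools_rows <- vector("list", n)
  vmap <- variant_map(synonyms)
  for (i in seq_len(n)) {
    # per-dataset metadata stream, separate from the rendering stream, so
    # appending datasets never perturbs earlier ones
    set.seed((derive_seed(config$seed, i + 1) + 104729) %% 2147483629)
    cont <- sample(edna_continents, 1,
                   prob = config$continent_weights[edna_continents])
    barcode_i <- sample(names(config$barcode_weights), 1,
                        prob = config$barcode_weights)
    refdb_type_i <- if (stats::runif(1) < config$prop_custom) "custom" else "global"
    country_lab <- sprintf("%s:C%d", cont, sample(1:2, 1))
    country <- world$regions[[cont]]$countries[[country_lab]]
    basin_lab <- names(country$basins)[sample(1:2, 1)]
    pools <- list(basin = country$basins[[basin_lab]],
                  country = country$pool,
                  continent = world$regions[[cont]]$pool)
    id <- sprintf("D%03d", i)
    ds <- sim_dataset(
      config, pools, world$refdb[[barcode_i]],
      metadata = list(dataset_id = id, continent = cont, country = country_lab,
                      basin = basin_lab, barcode = barcode_i,
                      refdb_type = refdb_type_i),
      seed = derive_seed(config$seed, i + 1)
    )
    if (config$synonym_noise_rate > 0) {
      set.seed(derive_seed(config$seed, i + 1) %% 2147483629 + 13)
      ds$reads$species <- inject_species_noise(ds$reads$species, synonyms,
                                               config$synonym_noise_rate,
                                               vars = vmap)
      ds$original_species <- inject_species_noise(ds$original_species, synonyms,
                                                  config$synonym_noise_rate,
                                                  vars = vmap)
    }
    rows[[i]] <- ds$metadata %>%
      mutate(reads = list(ds$reads),
             original_species = list(ds$original_species),
             original_presence = list(ds$original_presence))
    truth_ds[[i]] <- c(list(dataset_id = id), ds$truth)
    pools_rows[[i]] <- bind_rows(
      tibble(dataset_id = id, scale = "basin", region = basin_lab,
             species = pools$basin),
      tibble(dataset_id = id, scale = "country", region = country_lab,
             species = pools$country),
      tibble(dataset_id = id, scale = "continent", region = cont,
             species = pools$continent)
    )
  }

  collection <- list(
    datasets = if (n > 0) bind_rows(rows) else empty_datasets_tbl(),
    pools = if (n > 0) bind_rows(pools_rows) else
      tibble(dataset_id = character(), scale = character(),
             region = character(), species = character()),
    refdb = bind_rows(imap(world$refdb, ~ tibble(primer = .y, species = .x))),
    synonyms = synonyms,
    truth = list(
      config = config,
      congruence_coefs = config$congruence_coefs,
      beta_coverage = config$beta_coverage,
      datasets = truth_ds,
      canonical_map = setNames(all_species, all_species),
      realized_coverage = map_dbl(truth_ds, "coverage") %>%
        setNames(map_chr(truth_ds, "dataset_id"))
    )
  )
  collection <- structure(collection, class = "edna_collection")
  # without synonym noise the emitted labels are already canonical
  if (config$synonym_noise_rate == 0) attr(collection, "harmonized") <- TRUE
  collection
}

empty_datasets_tbl <- function() {
  tibble(dataset_id = character(), continent = character(),
         country = character(), basin = character(), year = integer(),
         barcode = character(), refdb_type = character(), n_sites = integer(),
         median_fish_reads = double(),
         reads = list(), original_species = list(), original_presence = list())
}

#' @export
print.edna_collection <- function(x, ...) {
  cat("<edna_collection>", nrow(x$datasets), "datasets,",
      length(unique(x$pools$species)), "pool species,",
      length(unique(x$refdb$primer)), "reference databases\n")
  if (nrow(x$datasets)) print(count(x$datasets, .data$continent))
  invisible(x)
}

#' Inject synonym noise into a read table
#'
#' Each species label is independently replaced by one of its synonym
#' variants with probability `rate`; read counts are untouched. Every table
#' species must have at least one non-identity variant in the synonym table.
#'
#' @param table a read table.
#' @param synonyms a [synonym_table()].
#' @param rate replacement probability in \[0,1).
#' @return a read table with noisy labels.
#' @export
inject_name_noise <- function(table, synonyms, rate) {
  check_prob(rate, "rate", right_open = TRUE)
  out <- table
  out$species <- inject_species_noise(table$species, synonyms, rate)
  out
}

inject_species_noise <- function(species, synonyms, rate, vars = NULL) {
  if (is.null(vars)) vars <- variant_map(synonyms)
  idx <- match(species, names(vars))
  if (anyNA(idx)) {
    abort("every species must have at least one synonym variant")
  }
  hit <- stats::runif(length(species)) < rate
  out <- species
  out[hit] <- vapply(vars[idx[hit]], function(v) {
    if (length(v) == 1) v else sample(v, 1)
  }, character(1))
  out
}

variant_map <- function(synonyms) {
  keep <- synonyms$variant != synonyms$canonical
  split(synonyms$variant[keep], synonyms$canonical[keep])
}

#' Restore canonical names across a collection
#'
#' Applies [harmonize_read_table()] to every read table and
#' [standardize_names()] to every original species list. Idempotent; with the
#' collection's complete synonym table this exactly inverts the generator's
#' synonym noise.
#'
#' @param collection an `edna_collection`.
#' @param unresolved passed to [harmonize_read_table()].
#' @return the harmonized collection.
#' @export
harmonize_collection <- function(collection, unresolved = "keep") {
  if (isTRUE(attr(collection, "harmonized"))) return(collection)
  syn <- collection$synonyms
  collection$datasets <- collection$datasets %>%
    mutate(
      reads = map(.data$reads, harmonize_read_table, synonyms = syn,
                  unresolved = unresolved),
      original_species = map(.data$original_species, function(sp) {
        if (!length(sp)) return(character())
        std <- standardize_names(sp, syn)
        sort(unique(std[!is.na(std)]))
      })
    )
  attr(collection, "harmonized") <- TRUE
  collection
}

#' Directly simulate a dataset-level congruence table
#'
#' The fast path through the congruence model: draws per-dataset predictors
#' and a beta-distributed shared-species proportion from the same logit-linear
#' model the full generator embeds, without rendering read tables. Used for
#' large calibration sweeps of the beta-regression stage.
#'
#' @param config a [sim_config()].
#' @param n number of datasets (default `config$n_datasets`).
#' @param seed seed (default `config$seed`).
#' @return tibble with dataset_id, continent, year, median_fish_reads,
#'   richness, refdb_type, coverage, and `p_sp`.
#' @export
sim_congruence_table <- function(config = sim_config(), n = config$n_datasets,
                                 seed = config$seed) {
  set.seed(seed)
  ct <- center_values(config)
  cont <- sample(edna_continents, n, replace = TRUE,
                 prob = config$continent_weights[edna_continents])
  coverage <- config$refdb_coverage[cont]
  year <- sample(config$year_range[1]:config$year_range[2], n, replace = TRUE)
  mu_d <- stats::rnorm(n, config$depth_lognormal[["meanlog"]],
                       config$depth_lognormal[["sdlog"]])
  rich <- sample(config$richness_range[1]:config$richness_range[2], n,
                 replace = TRUE)
  mu_p <- congruence_mean(config, mu_d, year, rich, coverage)
  phi <- config$beta_precision
  p <- stats::rbeta(n, mu_p * phi, (1 - mu_p) * phi)
  tibble(
    dataset_id = sprintf("D%03d", seq_len(n)),
    continent = cont,
    year = as.integer(year),
    median_fish_reads = exp(mu_d),
    richness = rich,
    refdb_type = ifelse(stats::runif(n) < config$prop_custom,
                        "custom", "global"),
    coverage = unname(coverage),
    p_sp = p
  )
}
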