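# In-code fixtures shared across tests.

tiny_read_table <- function(id = "T1") {
  as_read_table(
    tibble::tibble(species = c("Salmo trutta", "Barbus barbus"),
                   S01 = c(10L, 30L), S02 = c(20L, 40L)),
    dataset_id = id
  )
}

# Random read table over a random species subset; positive site totals.
random_read_table <- function(n_species = 8, n_sites = 4, id = "R1") {
  sp <- sort(sample(sprintf("Genus%02d fish%02d", 1:20, 1:20), n_species))
  m <- matrix(rpois(n_species * n_sites, 30), n_species, n_sites)
  m[cbind(sample(n_species, n_sites, replace = TRUE), seq_len(n_sites))] <-
    m[cbind(sample(n_species, n_sites, replace = TRUE), seq_len(n_sites))] + 1L
  tab <- tibble::as_tibble(m, .name_repair = ~ sprintf("S%02d", seq_len(n_sites)))
  as_read_table(dplyr::bind_cols(tibble::tibble(species = sp), tab), dataset_id = id)
}

tiny_synonyms <- function() {
  synonym_table(
    variants = c("Salmo fario", "Salmo trutta", "Barbus barbus"),
    canonicals = c("Salmo trutta", "Salmo trutta", "Barbus barbus")
  )
}

# A small, fast collection for structural unit tests.
small_config <- function(seed = 42, n_datasets = 8, ...) {
  sim_config(
    n_datasets = n_datasets,
    pool_sizes = c(basin = 25, country = 60, continent = 150),
    sites_range = c(3, 8),
    richness_range = c(5, 15),
    seed = seed,
    ...
  )
}

small_collection <- function(seed = 42, ...) {
  sim_collection(small_config(seed = seed, ...))
}

# Euclidean distance matrix from an explicit point configuration.
config_dist <- function(x) {
  stats::dist(x)
}
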