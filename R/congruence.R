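# Species-identity congruence between original and reanalyzed assignments.
# Reanalyzed assignments are corrected to the basin-scale local pool, species
# are partitioned into four categories (shared; unique to the reanalysis;
# unique to the original but basin-local; unique to the original and not
# local), and the two overlap statistics are computed per dataset:
#   p_sp   = |shared| / |reanalyzed species|
#   p_read = reads assigned to shared species / all reads in the reanalysis
# plus the two per-species relative-abundance indices
#   a_i = total-read share across the dataset
#   b_i = mean within-site read share.

#' Restrict species (or a read table) to a local pool
#'
#' @param x character vector of species, or a read table.
#' @param pool local species pool (non-empty).
#' @return same shape as `x`, keeping only pool species. An empty result is
#'   allowed (site richness 0).
#' @export
correct_to_pool <- function(x, pool) {
  if (!length(pool)) abort("pool must be non-empty")
  if (inherits(x, "read_table") || is.data.frame(x)) {
    out <- x[x$species %in% pool, , drop = FALSE]
    return(as_read_table(out, dataset_id = attr(x, "dataset_id")))
  }
  x[x %in% pool]
}

#' Four-category species-identity partition
#'
#' @param original species set of the original assignment.
#' @param reanalyzed_basin species set of the basin-corrected reanalysis;
#'   must be a subset of `basin_pool`.
#' @param basin_pool basin-scale local species pool.
#' @return a `category_partition` list with components `shared`,
#'   `unique_reanalysis`, `unique_original_local`, `unique_original_nonlocal`
#'   — pairwise disjoint, union = `original` union `reanalyzed_basin`.
#' @export
classify_species <- function(original, reanalyzed_basin, basin_pool) {
  original <- unique(original)
  reanalyzed_basin <- unique(reanalyzed_basin)
  out_of_pool <- setdiff(reanalyzed_basin, basin_pool)
  if (length(out_of_pool)) {
    abort(paste0("reanalyzed species outside the basin pool: ",
                 paste(head(out_of_pool, 5), collapse = ", ")))
  }
  structure(list(
    shared = sort(intersect(original, reanalyzed_basin)),
    unique_reanalysis = sort(setdiff(reanalyzed_basin, original)),
    unique_original_local = sort(intersect(setdiff(original, reanalyzed_basin),
                                           basin_pool)),
    unique_original_nonlocal = sort(setdiff(setdiff(original, reanalyzed_basin),
                                            basin_pool))
  ), class = "category_partition")
}

#' @export
print.category_partition <- function(x, ...) {
  cat("<category_partition>\n")
  for (nm in names(x)) cat(" ", nm, ":", length(x[[nm]]), "species\n")
  invisible(x)
}

#' @method tidy category_partition
#' @export
tidy.category_partition <- function(x, ...) {
  tibble(category = names(x), n_species = lengths(x),
         species = map(x, identity))
}

#' Proportion of shared species
#'
#' `|shared| / (|shared| + |unique to reanalysis|)`: the share of reanalyzed
#' species that the original assignment also found.
#'
#' @param partition a [classify_species()] result.
#' @return proportion in \[0,1\].
#' @export
prop_shared_species <- function(partition) {
  n_rean <- length(partition$shared) + length(partition$unique_reanalysis)
  if (n_rean == 0) abort("undefined proportion: no reanalyzed species")
  length(partition$shared) / n_rean
}

#' Proportion of reads assigned to shared species
#'
#' @param table basin-corrected reanalysis read table with positive total.
#' @param shared character vector of shared species.
#' @return shared-species reads / all reads.
#' @export
prop_shared_reads <- function(table, shared) {
  m <- read_counts(table)
  tot <- sum(m)
  if (tot == 0) abort("undefined proportion: zero total reads")
  sum(m[rownames(m) %in% shared, , drop = FALSE]) / tot
}

#' Dataset-total relative read abundance per species (a index)
#'
#' @param table a read table with positive grand total.
#' @return tibble (species, a) with `sum(a) == 1`.
#' @export
species_total_relabund <- function(table) {
  m <- read_counts(table)
  tot <- sum(m)
  if (tot == 0) abort("undefined index: zero total reads")
  tibble(species = rownames(m), a = unname(rowSums(m)) / tot)
}

#' Mean within-site relative abundance per species (b index)
#'
#' Sites with zero total reads are dropped from the mean (the site count is
#' decremented accordingly); with every included site total positive the
#' index sums to 1 over species.
#'
#' @param table a read table with at least one non-empty site.
#' @return tibble (species, b) with `sum(b) == 1`.
#' @export
species_mean_site_relabund <- function(table) {
  m <- read_counts(table)
  keep <- colSums(m) > 0
  if (!any(keep)) abort("undefined index: all sites have zero reads")
  m <- m[, keep, drop = FALSE]
  props <- sweep(m, 2, colSums(m), "/")
  tibble(species = rownames(m), b = unname(rowMeans(props)))
}

#' Species in the original assignment's extra-local category with barcodes
#'
#' @param unique_original_local character vector (category-3 species).
#' @param refdb reference-database species.
#' @return integer count, at most `length(unique_original_local)`.
#' @export
extra_local_barcode_count <- function(unique_original_local, refdb) {
  length(intersect(unique_original_local, refdb))
}

#' Per-dataset congruence report
#'
#' For every dataset with an original species list: basin-corrects the
#' reanalysis, partitions species into the four identity categories, and
#' computes `p_sp`, `p_read`, and the number of extra local species with
#' barcode records. Datasets lacking an original species list are omitted
#' with a warning (they remain usable for richness comparison).
#'
#' @param collection an `edna_collection`.
#' @param scale pool scale used for the correction (default basin).
#' @return a `congruence_report` tibble.
#' @export
congruence_report <- function(collection, scale = "basin") {
  collection <- index_pools(harmonize_collection(collection))
  ds <- collection$datasets
  rows <- map(seq_len(nrow(ds)), function(i) {
    id <- ds$dataset_id[i]
    original <- ds$original_species[[i]]
    if (!length(original)) {
      warn(paste0("dataset ", id, " has no original species list; omitted"))
      return(NULL)
    }
    pool <- dataset_pool(collection, id, scale)
    reads <- ds$reads[[i]]
    corrected <- correct_to_pool(reads, pool)
    rean_sp <- intersect(resolved_species(corrected), pool)
    part <- classify_species(original, rean_sp, pool)
    refdb <- dataset_refdb(collection, ds$barcode[i])
    tot <- sum(read_counts(corrected))
    tibble(
      dataset_id = id, continent = ds$continent[i], year = ds$year[i],
      refdb_type = ds$refdb_type[i],
      median_fish_reads = ds$median_fish_reads[i],
      n_shared = length(part$shared),
      n_unique_rean = length(part$unique_reanalysis),
      n_unique_orig_local = length(part$unique_original_local),
      n_unique_orig_nonlocal = length(part$unique_original_nonlocal),
      richness = length(rean_sp),
      p_sp = if (length(rean_sp)) prop_shared_species(part) else NA_real_,
      p_read = if (tot > 0) prop_shared_reads(corrected, part$shared) else NA_real_,
      extra_local_with_barcode =
        extra_local_barcode_count(part$unique_original_local, refdb)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("congruence_report", class(out))
  out
}

#' Per-species abundance index table
#'
#' For every dataset with an original species list, computes the a and b
#' relative-abundance indices over the basin-corrected reanalysis and flags
#' each species as shared with the original assignment or unique to the
#' reanalysis.
#'
#' @inheritParams congruence_report
#' @return tibble (dataset_id, continent, year, refdb_type, species,
#'   shared_flag, a, b).
#' @export
abundance_table <- function(collection, scale = "basin") {
  collection <- index_pools(harmonize_collection(collection))
  ds <- collection$datasets
  rows <- map(seq_len(nrow(ds)), function(i) {
    original <- ds$original_species[[i]]
    if (!length(original)) return(NULL)
    pool <- dataset_pool(collection, ds$dataset_id[i], scale)
    corrected <- correct_to_pool(ds$reads[[i]], pool)
    corrected <- corrected[corrected$species %in% resolved_species(corrected), ]
    if (!nrow(corrected) || sum(read_counts(corrected)) == 0) return(NULL)
    ab <- left_join(species_total_relabund(corrected),
                    species_mean_site_relabund(corrected), by = "species")
    ab %>% mutate(
      dataset_id = ds$dataset_id[i], continent = ds$continent[i],
      year = ds$year[i], refdb_type = ds$refdb_type[i],
      shared_flag = .data$species %in% original,
      .before = 1
    )
  })
  bind_rows(rows)
}

#' Total corrected species counts by scale
#'
#' Distinct species across all datasets for the uncorrected reanalysis and
#' for each pool-scale correction; with nested pools the totals satisfy
#' basin <= country <= continent <= uncorrected.
#'
#' @param collection an `edna_collection`.
#' @return tibble (scale, n_species) for global, continent, country, basin,
#'   plus the original assignments' total.
#' @export
species_totals <- function(collection) {
  collection <- index_pools(harmonize_collection(collection))
  ds <- collection$datasets
  per_scale <- function(scale) {
    sp <- map(seq_len(nrow(ds)), function(i) {
      assigned <- resolved_species(ds$reads[[i]])
      if (scale == "global") return(assigned)
      intersect(assigned, dataset_pool(collection, ds$dataset_id[i], scale))
    })
    length(unique(unlist(sp)))
  }
  tibble(
    scale = c("original", "global", "continent", "country", "basin"),
    n_species = c(length(unique(unlist(ds$original_species))),
                  per_scale("global"), per_scale("continent"),
                  per_scale("country"), per_scale("basin"))
  )
}

#' Plot a congruence report as stacked category bars
#' @param object a [congruence_report()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot congruence_report
#' @export
autoplot.congruence_report <- function(object, ...) {
  dat <- object %>%
    tidyr::pivot_longer(c("n_shared", "n_unique_rean", "n_unique_orig_local",
                          "n_unique_orig_nonlocal"),
                        names_to = "category", values_to = "n")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dataset_id, y = .data$n,
                                    fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~refdb_type, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "species") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5))
}
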