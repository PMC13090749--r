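# Reference-database coverage auditing. Coverage is the proportion of the
# local species pool represented in the barcode reference database; the
# local-assignment proportion is the share of (uncorrected) assigned taxa
# that belong to the pool. Both are computed at species and genus resolution
# and at the basin, country, and continent scales. At genus resolution both
# sets are collapsed to genera before intersecting, so a genus counts as
# covered when any congeneric species has a barcode record.

collapse_resolution <- function(x, resolution) {
  if (resolution == "genus") unique(genus_of(x)) else unique(x)
}

#' Coverage of a local species pool by a reference database
#'
#' @param pool character vector: the local species pool (canonical names).
#' @param refdb character vector: taxa with barcode records. May contain taxa
#'   outside the pool.
#' @param resolution `"species"` or `"genus"`.
#' @return proportion of pool taxa represented in the reference database.
#' @export
pool_coverage <- function(pool, refdb, resolution = c("species", "genus")) {
  resolution <- match.arg(resolution)
  pool <- collapse_resolution(pool, resolution)
  if (!length(pool)) abort("undefined coverage: empty species pool")
  refdb <- collapse_resolution(refdb, resolution)
  length(intersect(pool, refdb)) / length(pool)
}

#' Proportion of assigned taxa that are local
#'
#' @param assigned character vector of taxa in the (uncorrected) assignment.
#' @param pool local species pool.
#' @param resolution `"species"` or `"genus"`.
#' @return `|assigned inter pool| / |assigned|`.
#' @export
assigned_local_proportion <- function(assigned, pool,
                                      resolution = c("species", "genus")) {
  resolution <- match.arg(resolution)
  assigned <- collapse_resolution(assigned, resolution)
  if (!length(assigned)) abort("undefined proportion: empty assigned set")
  pool <- collapse_resolution(pool, resolution)
  length(intersect(assigned, pool)) / length(assigned)
}

# Pool lookups are frequent inner-loop operations; index the long pools
# table once per report call.
index_pools <- function(collection) {
  if (!is.null(attr(collection, "pool_index"))) return(collection)
  attr(collection, "pool_index") <-
    split(collection$pools$species,
          paste(collection$pools$dataset_id, collection$pools$scale))
  collection
}

dataset_pool <- function(collection, id, scale) {
  idx <- attr(collection, "pool_index")
  if (!is.null(idx)) {
    return(idx[[paste(id, scale)]] %||% character())
  }
  collection$pools %>%
    filter(.data$dataset_id == id, .data$scale == !!scale) %>%
    pull(.data$species)
}

dataset_refdb <- function(collection, barcode) {
  collection$refdb %>% filter(.data$primer == barcode) %>% pull(.data$species)
}

#' Coverage report over a collection
#'
#' One record per dataset x scale x resolution combination: reference-database
#' coverage of the local pool and the proportion of taxa in the uncorrected
#' assignment that are local. Combinations whose pool is missing are flagged
#' (`absent = TRUE`, proportions `NA`) rather than dropped.
#'
#' @param collection an `edna_collection` (harmonized first).
#' @return a `coverage_report` tibble with columns dataset_id, continent,
#'   scale, resolution, coverage, local_assignment_proportion, absent.
#' @export
coverage_report <- function(collection) {
  collection <- index_pools(harmonize_collection(collection))
  ds <- collection$datasets
  grid <- tidyr::expand_grid(
    dataset_id = ds$dataset_id,
    scale = c("basin", "country", "continent"),
    resolution = c("species", "genus")
  )
  rows <- pmap(grid, function(dataset_id, scale, resolution) {
    row <- ds[ds$dataset_id == dataset_id, ]
    pool <- dataset_pool(collection, dataset_id, scale)
    refdb <- dataset_refdb(collection, row$barcode)
    assigned <- resolved_species(row$reads[[1]])
    if (!length(pool)) {
      return(tibble(dataset_id = dataset_id, continent = row$continent,
                    scale = scale, resolution = resolution,
                    coverage = NA_real_,
                    local_assignment_proportion = NA_real_, absent = TRUE))
    }
    tibble(
      dataset_id = dataset_id, continent = row$continent,
      scale = scale, resolution = resolution,
      coverage = pool_coverage(pool, refdb, resolution),
      local_assignment_proportion =
        if (length(assigned)) assigned_local_proportion(assigned, pool, resolution)
        else NA_real_,
      absent = FALSE
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("coverage_report", class(out))
  out
}

#' Plot a coverage report
#'
#' Boxplots of coverage and local-assignment proportion by continent,
#' faceted by scale, at one resolution.
#'
#' @param object a [coverage_report()] tibble.
#' @param resolution which resolution to plot.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, resolution = "species", ...) {
  dat <- object %>%
    filter(.data$resolution == !!resolution, !.data$absent) %>%
    tidyr::pivot_longer(c("coverage", "local_assignment_proportion"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$continent, y = .data$value,
                                    fill = .data$continent)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::facet_grid(metric ~ factor(scale, c("basin", "country", "continent"))) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none")
}
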