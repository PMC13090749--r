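# Collection readers/writers. On disk a collection is a directory of UTF-8
# text tables: one TSV read table per dataset (rows = species, columns =
# sites), one CSV original-assignment presence table per dataset, pools.csv
# (dataset_id, scale, region, species), refdb.tsv (primer, species),
# metadata.csv, synonyms.csv, truth.json, and a manifest.json tying them
# together with a format version.

COLLECTION_FORMAT <- "1.0"

#' Write a collection to a directory
#'
#' @param collection an `edna_collection`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- collection$datasets
  reads_files <- character(nrow(ds))
  orig_files <- character(nrow(ds))
  for (i in seq_len(nrow(ds))) {
    id <- ds$dataset_id[i]
    reads_files[i] <- paste0("reads_", id, ".tsv")
    readr::write_tsv(ds$reads[[i]], file.path(dir, reads_files[i]))
    orig_files[i] <- paste0("original_", id, ".csv")
    pres <- ds$original_presence[[i]]
    if (is.null(pres)) {
      pres <- tibble(species = ds$original_species[[i]])
    }
    readr::write_csv(pres, file.path(dir, orig_files[i]))
  }
  readr::write_csv(collection$pools, file.path(dir, "pools.csv"))
  readr::write_tsv(collection$refdb, file.path(dir, "refdb.tsv"))
  readr::write_csv(ds %>% select(-"reads", -"original_species",
                                 -"original_presence"),
                   file.path(dir, "metadata.csv"))
  readr::write_csv(as_tibble(collection$synonyms),
                   file.path(dir, "synonyms.csv"))
  if (!is.null(collection$truth)) {
    truth <- collection$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest <- list(
    format_version = COLLECTION_FORMAT,
    datasets = setNames(
      map(seq_len(nrow(ds)),
          ~ list(reads = reads_files[.x], original = orig_files[.x])),
      ds$dataset_id),
    pools = "pools.csv", refdb = "refdb.tsv", metadata = "metadata.csv",
    synonyms = "synonyms.csv"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a collection from a directory
#'
#' Validates every referenced file, harmonizes species names through the
#' synonym table, and fails with a descriptive error listing the violation
#' (missing file, duplicate dataset id, negative count) otherwise.
#'
#' @param dir collection directory containing `manifest.json`.
#' @param harmonize apply [harmonize_collection()] after reading.
#' @return an `edna_collection`.
#' @export
read_collection <- function(dir, harmonize = TRUE) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) abort(paste0("missing manifest: ", mf_path))
  manifest <- jsonlite::read_json(mf_path)
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort(paste0("manifest references absent file: ", f))
    p
  }
  metadata <- readr::read_csv(need(manifest$metadata), show_col_types = FALSE)
  if (anyDuplicated(metadata$dataset_id)) {
    abort(paste0("duplicate dataset id: ",
                 metadata$dataset_id[duplicated(metadata$dataset_id)][1]))
  }
  ids <- names(manifest$datasets)
  if (!setequal(ids, metadata$dataset_id)) {
    abort("manifest datasets and metadata.csv dataset ids disagree")
  }
  reads <- map(ids, function(id) {
    tab <- readr::read_tsv(need(manifest$datasets[[id]]$reads),
                           show_col_types = FALSE)
    tryCatch(as_read_table(tab, dataset_id = id),
             error = function(e) {
               abort(paste0("dataset ", id, ": ", conditionMessage(e)))
             })
  })
  originals <- map(ids, function(id) {
    readr::read_csv(need(manifest$datasets[[id]]$original),
                    show_col_types = FALSE)
  })
  pools <- readr::read_csv(need(manifest$pools), show_col_types = FALSE)
  refdb <- readr::read_tsv(need(manifest$refdb), show_col_types = FALSE)
  syn_tab <- readr::read_csv(need(manifest$synonyms), show_col_types = FALSE)
  synonyms <- synonym_table(syn_tab$variant, syn_tab$canonical,
                            provenance = syn_tab$provenance %||% "file")
  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  }
  ord <- match(metadata$dataset_id, ids)
  datasets <- metadata %>%
    mutate(
      reads = reads[ord],
      original_species = map(originals[ord], function(o) {
        if (!nrow(o)) character() else sort(unique(o$species))
      }),
      original_presence = map(originals[ord], function(o) {
        if (ncol(o) > 1) o else NULL
      })
    )
  collection <- structure(
    list(datasets = datasets, pools = pools, refdb = refdb,
         synonyms = synonyms, truth = truth),
    class = "edna_collection")
  if (harmonize) collection <- harmonize_collection(collection)
  collection
}

#' Run configuration for the analysis pipeline
#'
#' @param scale pool scale for correction.
#' @param resolution coverage resolution(s) reported.
#' @param n_perm permutations for community tests.
#' @param seed integer seed (required for any stochastic stage).
#' @param min_fish_reads sensitivity-filter threshold (0 disables).
#' @param unresolved unresolved-name policy.
#' @param out output directory or `NULL` for in-memory results only.
#' @return a `run_config` list.
#' @export
run_config <- function(scale = "basin", resolution = "species", n_perm = 999,
                       seed = 1, min_fish_reads = 0,
                       unresolved = c("exclude", "include"), out = NULL) {
  scale <- match.arg(scale, c("basin", "country", "continent", "global"))
  resolution <- match.arg(resolution, c("species", "genus"))
  unresolved <- match.arg(unresolved)
  if (n_perm < 1) abort("n_perm must be >= 1")
  structure(list(scale = scale, resolution = resolution,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 min_fish_reads = min_fish_reads, unresolved = unresolved,
                 out = out),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments.
#' @param ... overrides taking precedence over the file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the full analysis pipeline on a collection
#'
#' Harmonizes names, applies the sensitivity filter, then chains the
#' coverage, congruence, community, and model stages and assembles the
#' report. Every stochastic stage is seeded from `config$seed`.
#'
#' @param collection an `edna_collection` (or a directory path readable by
#'   [read_collection()]).
#' @param config a [run_config()].
#' @return list with `coverage`, `congruence`, `abundance`,
#'   `species_totals`, `community`, `models`, `group_tests`, `filter_report`,
#'   and `provenance`; written to `config$out` when set.
#' @export
run_pipeline <- function(collection, config = run_config()) {
  if (is.character(collection)) collection <- read_collection(collection)
  collection <- harmonize_collection(collection)
  filt <- if (config$min_fish_reads > 0) {
    sensitivity_filter(collection, config$min_fish_reads)
  } else list(collection = collection, report = tibble())
  collection <- filt$collection

  coverage <- coverage_report(collection)
  congruence <- suppressWarnings(congruence_report(collection, scale = config$scale))
  abundance <- abundance_table(collection, scale = config$scale)
  totals <- species_totals(collection)
  community <- community_tests(collection, n_perm = config$n_perm,
                               seed = config$seed)

  congr_model <- fit_beta_glm(
    congruence %>% filter(!is.na(.data$p_sp)) %>%
      mutate(year_c = .data$year - min(.data$year)),
    p_sp ~ log(median_fish_reads) + year_c + richness + refdb_type
  )
  read_model <- fit_beta_glm(
    congruence %>% filter(!is.na(.data$p_read)) %>%
      mutate(year_c = .data$year - min(.data$year)),
    p_read ~ log(median_fish_reads) + year_c + richness + refdb_type
  )
  abund_a <- fit_abundance_mixed(abundance, index = "a")
  abund_b <- fit_abundance_mixed(abundance, index = "b")
  rich <- richness_pairs(collection, scale = "global")
  rich_model <- if (nrow(rich)) fit_nb_glmm_richness(rich) else NULL

  cov_species <- coverage %>%
    filter(.data$resolution == config$resolution,
           .data$scale == ifelse(config$scale == "global", "basin",
                                 config$scale),
           !.data$absent)
  gt <- list(
    coverage_by_continent = group_tests(cov_species$coverage,
                                        cov_species$continent),
    p_sp_by_continent = {
      ok <- !is.na(congruence$p_sp)
      group_tests(congruence$p_sp[ok], congruence$continent[ok])
    }
  )

  results <- list(
    coverage = coverage, congruence = congruence, abundance = abundance,
    species_totals = totals, community = community,
    models = list(p_sp = congr_model, p_read = read_model,
                  abundance_a = abund_a, abundance_b = abund_b,
                  richness = rich_model),
    group_tests = gt,
    filter_report = filt$report,
    provenance = list(
      package_version = as.character(utils::packageVersion("ednacongr")),
      seed = config$seed, n_perm = config$n_perm, scale = config$scale,
      resolution = config$resolution, min_fish_reads = config$min_fish_reads,
      n_datasets = nrow(collection$datasets),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )
  if (!is.null(config$out)) write_report(results, config$out)
  results
}

#' Write pipeline outputs as a structured report
#'
#' Tables go to CSV, test and model summaries to a machine-readable
#' `report.json` that re-parses to the same values; sections whose stage is
#' absent are marked absent rather than dropped.
#'
#' @param results output of [run_pipeline()] (any subset of its elements).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  if (!length(results)) abort("need at least one stage output")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tbl <- function(x, f) {
    if (!is.null(x) && nrow(x)) readr::write_csv(x, file.path(dir, f))
  }
  write_tbl(results$coverage, "coverage.csv")
  write_tbl(results$congruence, "congruence.csv")
  write_tbl(results$abundance, "abundance.csv")
  write_tbl(results$species_totals, "species_totals.csv")
  if (!is.null(results$community)) {
    write_tbl(results$community$tests, "community_tests.csv")
    write_tbl(results$community$nmds, "nmds.csv")
  }
  model_json <- map(results$models %||% list(), function(m) {
    if (is.null(m)) return("absent")
    list(coefficients = m$coefficients, glance = glance(m))
  })
  json <- list(
    provenance = results$provenance %||% "absent",
    species_totals = results$species_totals %||% "absent",
    community_tests = if (is.null(results$community)) "absent" else
      results$community$tests,
    models = if (length(model_json)) model_json else "absent",
    group_tests = if (is.null(results$group_tests)) "absent" else
      map(results$group_tests, function(g) {
        list(kruskal = g$kruskal, letters = as.list(g$letters),
             wilcoxon_p = g$wilcoxon_p)
      }),
    filter_report = results$filter_report %||% "absent"
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
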