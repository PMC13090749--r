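# Name canonicalization. All cross-table comparisons (coverage, congruence,
# community structure) run on a common namespace of canonical binomials;
# synonym harmonization replaces the live taxonomic-backbone lookups used in
# large compilations with an explicit two-column synonym table.

#' Build a synonym table
#'
#' @param variants character vector of variant names.
#' @param canonicals character vector of canonical binomials, same length.
#' @param provenance optional provenance tag per entry (recycled).
#' @return A `synonym_table` tibble with columns `variant`, `canonical`,
#'   `provenance`. Canonical names are fixed points: any canonical appearing
#'   as a variant must map to itself, and no variant may map to two
#'   canonicals.
#' @export
synonym_table <- function(variants, canonicals, provenance = "user") {
  tab <- tibble(
    variant = normalize_name(variants),
    canonical = normalize_name(canonicals),
    provenance = provenance
  )
  tab <- distinct(tab, .data$variant, .data$canonical, .keep_all = TRUE)
  dup <- tab$variant[duplicated(tab$variant)]
  if (length(dup)) {
    abort(paste0("variant maps to two canonicals: ", paste(unique(dup), collapse = ", ")))
  }
  fixed <- tab$variant %in% tab$canonical & tab$variant != tab$canonical
  if (any(fixed)) {
    abort(paste0("canonical names must be fixed points; offending variants: ",
                 paste(tab$variant[fixed], collapse = ", ")))
  }
  class(tab) <- c("synonym_table", class(tab))
  attr(tab, "lc_variant") <- tolower(tab$variant)
  tab
}

#' Read a synonym table from a two-column CSV (variant, canonical)
#' @param path file path.
#' @return a `synonym_table`.
#' @export
read_synonym_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  synonym_table(tab[[1]], tab[[2]],
                provenance = if ("provenance" %in% names(tab)) tab$provenance else "file")
}

# Whitespace collapse, Unicode NFC, first token capitalized, epithets lowered
# only in their first character? No: case is preserved except for matching,
# which is case-insensitive after NFC.
normalize_name <- function(x) {
  x <- stringr::str_squish(enc2utf8(x))
  stringi_nfc(x)
}

# stringi is not a dependency; base R can NFC via iconv on most builds, but
# compose-normalization is a no-op for ASCII names, so fall back gracefully.
stringi_nfc <- function(x) {
  out <- tryCatch(iconv(x, from = "UTF-8", to = "UTF-8"), error = function(e) x)
  ifelse(is.na(out), x, out)
}

canonical_shaped <- function(x) {
  stringr::str_detect(x, "^[A-Z][^\\s]*( [^\\s]+)?$")
}

#' Standardize species names against a synonym table
#'
#' Whitespace and Unicode are normalized first; matching against the synonym
#' table is case-insensitive. Names absent from the table are returned
#' unchanged when they already look like a canonical binomial ("Genus" or
#' "Genus epithet", first token capitalized) and are otherwise returned as
#' `NA` — an unresolved marker, not an error.
#'
#' @param raw character vector of raw names (no empty strings).
#' @param synonyms a [synonym_table()], or `NULL` for normalization only.
#' @return character vector of canonical names, `NA` where unresolved.
#' @export
standardize_names <- function(raw, synonyms = NULL) {
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    abort("raw names must be non-empty strings")
  }
  x <- normalize_name(raw)
  if (!is.null(synonyms)) {
    lc <- attr(synonyms, "lc_variant") %||% tolower(synonyms$variant)
    idx <- match(tolower(x), lc)
    hit <- !is.na(idx)
    x[hit] <- synonyms$canonical[idx[hit]]
  }
  ifelse(canonical_shaped(x), x, NA_character_)
}

#' Genus component of canonical names
#'
#' Species-rank binomials collapse to their first token; genus-rank names
#' (single token) are returned unchanged, making the operation idempotent.
#'
#' @param name character vector of canonical names.
#' @return character vector of genus names.
#' @export
genus_of <- function(name) {
  stringr::str_split_i(name, stringr::fixed(" "), 1)
}

#' Harmonize a read table onto canonical names
#'
#' Species labels are standardized; rows whose labels canonicalize to the same
#' binomial are merged by summing counts, so the grand read total is
#' conserved. Unresolved labels are either kept under their normalized name
#' with an `unresolved` attribute listing them (`unresolved = "keep"`) or
#' dropped (`"drop"`); they are excluded from species-level statistics either
#' way.
#'
#' @param table a read table.
#' @param synonyms a [synonym_table()] or `NULL`.
#' @param unresolved `"keep"` or `"drop"`.
#' @return a harmonized read table, rows sorted by species name.
#' @export
harmonize_read_table <- function(table, synonyms = NULL,
                                 unresolved = c("keep", "drop")) {
  unresolved <- match.arg(unresolved)
  table <- as_read_table(table, dataset_id = attr(table, "dataset_id"))
  canon <- standardize_names(table$species, synonyms)
  norm <- normalize_name(table$species)
  label <- ifelse(is.na(canon), norm, canon)
  unres <- unique(label[is.na(canon)])
  keep <- if (unresolved == "drop") !is.na(canon) else rep(TRUE, length(label))
  m <- read_counts(table)[keep, , drop = FALSE]
  label <- label[keep]
  agg <- rowsum(m, group = label)
  out <- as_tibble(agg, rownames = "species") %>% arrange(.data$species)
  out <- as_read_table(out, dataset_id = attr(table, "dataset_id"))
  unres <- sort(intersect(unres, out$species))
  if (length(unres)) attr(out, "unresolved") <- unres
  out
}

#' Species labels usable for species-level statistics
#' @param table a harmonized read table.
#' @return character vector excluding unresolved labels.
#' @export
resolved_species <- function(table) {
  setdiff(table$species, attr(table, "unresolved") %||% character())
}
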